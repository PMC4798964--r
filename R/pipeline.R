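# Config-driven orchestration: simulate -> segment -> dmr -> atac ->
# concord -> cluster -> kmer, with per-stage outputs, a JSON report of the
# headline statistics and full seed logging.  Every random draw derives
# deterministically from the config's global seed, so re-running with the
# same config overwrites the outputs byte-identically.

PIPELINE_STAGES <- c("simulate", "segment", "dmr", "atac", "concord",
                     "cluster", "kmer")

#' Run the full synthetic-epigenome analysis pipeline
#'
#' Simulates rodlike and conelike replicates (plus a hybrid sample for the
#' clustering stage), then runs the enabled downstream stages and writes
#' their outputs under `outdir`: allc tables, fragment/peak BEDs, segment
#' and DMR BEDs, distance matrices with Newick dendrograms, the k-mer model
#' and a `report.json` collecting the headline statistics (per-type LMR/peak
#' overlap and inaccessible fractions, DMR counts by direction, DMV counts,
#' k-mer auROC, ...).
#'
#' @param config A [simulation_config()].
#' @param outdir Output directory (created if needed).
#' @param stages Subset of `r paste(PIPELINE_STAGES, collapse = ", ")`;
#'   `simulate` is always implied.  Later stages require the earlier ones in
#'   that list.
#' @param write_raw Also write the (large) allc and fragment files
#'   (default `TRUE`).
#' @param kmer_train,kmer_test Per-class sequence counts for the k-mer
#'   stage.
#' @return The report, invisibly (also written as JSON).
#' @export
run_pipeline <- function(config = simulation_config(), outdir,
                         stages = PIPELINE_STAGES, write_raw = TRUE,
                         kmer_train = 1000L, kmer_test = 300L) {
  stages <- unique(c("simulate", match.arg(stages, PIPELINE_STAGES,
                                           several.ok = TRUE)))
  need <- function(st, dep) {
    if (st %in% stages && !dep %in% stages)
      stop(sprintf("stage '%s' requires stage '%s'", st, dep))
  }
  need("concord", "segment"); need("concord", "atac")
  need("dmr", "simulate"); need("cluster", "simulate")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed, stages = stages)

  truth <- build_truth(config)
  cfg_echo <- unclass(config)
  cfg_echo$motif_pwm <- apply(config$motif_pwm, 2, as.numeric,
                              simplify = FALSE)
  jsonlite::write_json(cfg_echo, file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  data.table::fwrite(truth_table(truth), file.path(outdir, "truth.tsv"),
                     sep = "\t")
  write_tss(truth$tss, file.path(outdir, "tss.tsv"))
  types <- c("rodlike", "conelike")
  reps <- seq_len(config$replicates)
  meths <- list()
  for (ct in c(types, "hybrid")) for (r in reps) {
    m <- simulate_methylome(truth, ct, r)
    meths[[m$label]] <- m
    if (write_raw) write_allc(m, file.path(outdir, paste0(m$label,
                                                          ".allc.tsv")))
  }
  atac <- list()
  for (ct in types) for (r in reps) {
    a <- simulate_accessibility(truth, ct, r)
    atac[[sprintf("%s_R%d", ct, r)]] <- a
    if (write_raw) {
      write_bed(a$fragments, file.path(outdir,
                                       sprintf("%s_R%d.fragments.bed", ct, r)))
      write_narrowpeak(a$peaks, file.path(outdir,
                                          sprintf("%s_R%d.peaks.narrowPeak",
                                                  ct, r)))
    }
  }
  report$n_regions_planted <- length(truth$regions)

  segs <- NULL
  if ("segment" %in% stages) {
    segs <- lapply(types, function(ct) {
      pooled <- pool_methylomes(meths[paste0(ct, "_R", reps)], label = ct)
      s <- segment_hypomethylated(pooled, segmentation_params(
        seed = derive_seed(config$seed, 6L, ct)))
      write_segments_bed(s, file.path(outdir, paste0(ct, ".segments.bed")))
      s
    })
    names(segs) <- types
    dmvs <- lapply(segs, call_dmv)
    report$segmentation <- lapply(types, function(ct) {
      list(n_segments = length(segs[[ct]]),
           n_umr = sum(mcols(segs[[ct]])$klass == "UMR"),
           n_lmr = sum(mcols(segs[[ct]])$klass == "LMR"),
           n_dmv = length(dmvs[[ct]]))
    })
    names(report$segmentation) <- types
    write_segments_bed(merge_dmv_union(dmvs),
                       file.path(outdir, "dmv_union.bed"))
  }

  if ("dmr" %in% stages) {
    dms <- call_dms(meths[paste0("rodlike_R", reps)],
                    meths[paste0("conelike_R", reps)])
    dmrs <- join_dms_to_dmr(dms)
    write_dmrs_bed(dmrs, file.path(outdir, "dmrs.bed"))
    report$dmr <- list(
      n_dms_significant = sum(dms$significant),
      n_dmr = length(dmrs),
      n_rod_hypo = sum(mcols(dmrs)$direction == "A<B"),
      n_cone_hypo = sum(mcols(dmrs)$direction == "A>B"))
    expr <- simulate_expression(truth)
    data.table::fwrite(expr, file.path(outdir, "expression.tsv"), sep = "\t")
    if (length(dmrs) >= 3) {
      prof <- meth_expr_correlation_profile(
        dmrs, truth$tss, setNames(expr$log2fc, expr$gene))
      data.table::fwrite(prof, file.path(outdir, "meth_expr_profile.tsv"),
                         sep = "\t")
      report$dmr$min_meth_expr_r <- suppressWarnings(min(prof$r,
                                                         na.rm = TRUE))
    }
  }

  cons <- NULL
  if ("atac" %in% stages) {
    peak_sets <- lapply(atac, `[[`, "peaks")
    cons <- consensus_peaks(peak_sets)
    frag_sets <- lapply(atac, `[[`, "fragments")
    pc <- count_peak_fragments(cons, frag_sets)
    dp <- differential_peaks(pc$counts, pc$lib_sizes,
                             grep("rodlike", names(frag_sets), value = TRUE),
                             grep("conelike", names(frag_sets), value = TRUE))
    mcols(cons)$class <- dp$class
    mcols(cons)$signalValue <- dp$fold
    write_narrowpeak(cons, file.path(outdir, "consensus_peaks.narrowPeak"))
    report$atac <- list(n_consensus = length(cons),
                        n_rod_enriched = sum(dp$class == "A-enriched"),
                        n_cone_enriched = sum(dp$class == "B-enriched"),
                        n_shared = sum(dp$class == "shared"))
  }

  if ("concord" %in% stages) {
    report$concordance <- list()
    for (ct in types) {
      lmrs <- segs[[ct]][mcols(segs[[ct]])$klass == "LMR"]
      frags <- do.call(c, unname(lapply(
        atac[paste0(ct, "_R", reps)], `[[`, "fragments")))
      rep_ct <- concordance_report(lmrs, cons, frags)
      write_concordance_report(
        rep_ct, file.path(outdir, paste0(ct, ".concordance.tsv")),
        file.path(outdir, paste0(ct, ".concordance.json")))
      report$concordance[[ct]] <- list(
        n_lmr = rep_ct$n_regions,
        fraction_overlapping = rep_ct$fraction_overlapping,
        fraction_inaccessible = rep_ct$fraction_inaccessible)
    }
  }

  if ("cluster" %in% stages) {
    pd <- pearson_distance_matrix(meths)
    write_distance_matrix(pd, file.path(outdir, "meth_distance.tsv"))
    hc <- hierarchical_cluster(pd)
    writeLines(dendrogram_newick(hc), file.path(outdir,
                                                "meth_dendrogram.nwk"))
    report$cluster <- list(meth_newick = dendrogram_newick(hc))
    if (length(atac)) {
      jd <- jaccard_distance_matrix(lapply(atac, `[[`, "peaks"))
      write_distance_matrix(jd, file.path(outdir, "peak_distance.tsv"))
      report$cluster$peak_newick <-
        dendrogram_newick(hierarchical_cluster(jd))
    }
  }

  if ("kmer" %in% stages) {
    tr <- simulate_sequences(truth, n_pos = kmer_train, n_neg = kmer_train,
                             seed_offset = 0L)
    te <- simulate_sequences(truth, n_pos = kmer_test, n_neg = kmer_test,
                             seed_offset = 1L)
    model <- train_kmer_model(tr$pos, tr$neg,
                              seed = derive_seed(config$seed, 7L))
    write_kmer_model(model, file.path(outdir, "kmer_model.tsv"))
    if (write_raw) {
      write_fasta(setNames(tr$pos, sprintf("pos_%d", seq_along(tr$pos))),
                  file.path(outdir, "train_pos.fa"))
      write_fasta(setNames(tr$neg, sprintf("neg_%d", seq_along(tr$neg))),
                  file.path(outdir, "train_neg.fa"))
    }
    sc <- score_sequences(model, c(te$pos, te$neg))
    report$kmer <- list(
      auroc = auroc(sc, c(rep(TRUE, length(te$pos)),
                          rep(FALSE, length(te$neg)))))
  }

  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
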