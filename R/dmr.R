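# Differential methylation: per-CpG beta-binomial testing with replicates,
# block joining into DMRs, multi-sample group-specific hypo-DMR selection,
# DMV methylation contrasts and the methylation/expression correlation
# profile around TSSs.

#' DMR-calling parameters
#'
#' @param site_fdr Per-site BH-adjusted significance threshold (default
#'   0.01).
#' @param max_gap Maximum bp between consecutive significant sites joined
#'   into one block (default 250).
#' @param min_sites Minimum significant sites per DMR (default 2).
#' @param shrink_weight Pseudo-degrees-of-freedom pulling per-site
#'   dispersion estimates toward the genome-wide mean (default 20).
#' @return List of class `dmr_params`.
#' @export
dmr_params <- function(site_fdr = 0.01, max_gap = 250L, min_sites = 2L,
                       shrink_weight = 20) {
  stopifnot(site_fdr > 0, site_fdr < 1, max_gap >= 0, min_sites >= 1,
            shrink_weight >= 0)
  structure(list(site_fdr = site_fdr, max_gap = as.integer(max_gap),
                 min_sites = as.integer(min_sites),
                 shrink_weight = shrink_weight),
            class = "dmr_params")
}

# stack replicate CG records into one long table
stack_group <- function(ms, group) {
  rbindlist(lapply(seq_along(ms), function(i) {
    dt <- ms[[i]]$records[context == "CG" & cov > 0,
                          .(chrom, pos, strand, mc, cov)]
    dt[, `:=`(group = group, rep = i)]
    dt
  }))
}

#' Call differentially methylated sites between two groups
#'
#' For every CG site (matched by chrom, pos, strand) covered in at least one
#' replicate of each group, a beta-binomial Wald test on the arcsine-sqrt
#' transformed replicate levels is performed.  Per-site dispersions come
#' from a method-of-moments estimator shrunk toward the genome-wide mean
#' (weight `shrink_weight`); replicate levels are combined by
#' inverse-variance weighting, and the two-sided Wald p-values are
#' BH-adjusted genome-wide.  Sites covered in only one group are skipped and
#' counted in `attr(result, "n_skipped")`.
#'
#' @param groupA,groupB Lists of `methylome` objects (>= 1 replicate each).
#' @param params A [dmr_params()].
#' @return `data.table` with per-site pooled levels, `delta` (A - B),
#'   `direction` (`"A<B"`/`"A>B"`), `p_value`, `q_value` and `significant`.
#' @export
call_dms <- function(groupA, groupB, params = dmr_params()) {
  stopifnot(length(groupA) >= 1, length(groupB) >= 1)
  long <- rbind(stack_group(groupA, "A"), stack_group(groupB, "B"))
  long[, p_hat := mc / cov]

  # group-level pooled levels and residual chi-square for dispersion
  grp <- long[, .(mc = sum(as.numeric(mc)), cov = sum(as.numeric(cov)),
                  n_rep = .N), by = .(chrom, pos, strand, group)]
  grp[, p_bar := mc / cov]
  long <- grp[, .(chrom, pos, strand, group, p_bar, n_rep)][
    long, on = c("chrom", "pos", "strand", "group")]
  long[, chi := ifelse(p_bar > 0 & p_bar < 1,
                       (p_hat - p_bar)^2 * cov / (p_bar * (1 - p_bar)), 0)]

  site <- long[, .(chi = sum(chi),
                   df = sum(tabulate(match(group, c("A", "B")), 2L) - 1L),
                   nbar = mean(cov),
                   nA = sum(group == "A"), nB = sum(group == "B")),
               by = .(chrom, pos, strand)]
  n_skipped <- site[nA == 0 | nB == 0, .N]
  site <- site[nA > 0 & nB > 0]
  site[, df := pmax(nA - 1L, 0L) + pmax(nB - 1L, 0L)]
  site[, phi_hat := ifelse(df > 0 & nbar > 1,
                           pmax((chi / df - 1) / (nbar - 1), 0), NA_real_)]
  phi_bar <- mean(site$phi_hat, na.rm = TRUE)
  if (!is.finite(phi_bar)) phi_bar <- 0
  w <- params$shrink_weight
  site[, phi := ifelse(is.na(phi_hat), phi_bar,
                       (w * phi_bar + df * phi_hat) / (w + df))]
  site[, phi := pmin(phi, 0.95)]

  long <- site[, .(chrom, pos, strand, phi)][
    long, on = c("chrom", "pos", "strand"), nomatch = NULL]
  long[, y := asin(sqrt(p_hat))]
  long[, v := (1 + (cov - 1) * phi) / (4 * cov)]
  gstat <- long[, .(y = sum(y / v) / sum(1 / v), V = 1 / sum(1 / v),
                    mc = sum(as.numeric(mc)), cov = sum(as.numeric(cov))),
                by = .(chrom, pos, strand, group)]
  wide <- dcast(gstat, chrom + pos + strand ~ group,
                value.var = c("y", "V", "mc", "cov"))
  wide <- wide[!is.na(y_A) & !is.na(y_B)]
  wide[, level_a := mc_A / cov_A]
  wide[, level_b := mc_B / cov_B]
  wide[, delta := level_a - level_b]
  wide[, z := (y_A - y_B) / sqrt(V_A + V_B)]
  wide[, p_value := 2 * pnorm(-abs(z))]
  wide[, q_value := p.adjust(p_value, method = "BH")]
  wide[, direction := ifelse(delta < 0, "A<B", "A>B")]
  wide[, significant := q_value < params$site_fdr & delta != 0]
  out <- wide[, .(chrom, pos, strand, level_a, level_b, delta, direction,
                  p_value, q_value, significant)]
  setkey(out, chrom, pos)
  setattr(out, "n_skipped", n_skipped)
  out[]
}

#' Join significant DMSs into DMRs
#'
#' Significant sites of the same direction are chained into blocks whenever
#' consecutive sites lie within `max_gap` bp; a block whose interval contains
#' a significant site of the opposite direction is removed entirely; blocks
#' with at least `min_sites` member sites become DMRs spanning their first to
#' last site.  Input order is irrelevant (sorting is internal).
#'
#' @param dms Output of [call_dms()].
#' @param params A [dmr_params()].
#' @return Sorted `GRanges` with `direction`, `n_sites`, `level_a`,
#'   `level_b` and `delta` (mean over member sites).
#' @export
join_dms_to_dmr <- function(dms, params = dmr_params()) {
  sig <- as.data.table(dms)[significant == TRUE]
  if (nrow(sig) == 0) return(GRanges())
  setkey(sig, chrom, pos)
  sig[, block := cumsum(c(1L, (diff(pos) > params$max_gap) * 1L)),
      by = .(chrom, direction)]
  blocks <- sig[, .(start = min(pos), end = max(pos), n_sites = .N,
                    level_a = mean(level_a), level_b = mean(level_b),
                    delta = mean(delta)),
                by = .(chrom, direction, block)]
  # drop blocks containing an opposite-direction significant site
  opp <- sig[, .(chrom, pos, dir_op = direction)]
  blocks[, removed := FALSE]
  for (i in seq_len(nrow(blocks))) {
    hit <- opp[chrom == blocks$chrom[i] & dir_op != blocks$direction[i] &
                 pos >= blocks$start[i] & pos <= blocks$end[i]]
    if (nrow(hit) > 0) blocks$removed[i] <- TRUE
  }
  blocks <- blocks[removed == FALSE & n_sites >= params$min_sites]
  if (nrow(blocks) == 0) return(GRanges())
  gr <- GRanges(blocks$chrom, IRanges(blocks$start, blocks$end))
  mcols(gr)$direction <- blocks$direction
  mcols(gr)$n_sites <- blocks$n_sites
  mcols(gr)$level_a <- blocks$level_a
  mcols(gr)$level_b <- blocks$level_b
  mcols(gr)$delta <- blocks$delta
  sort(gr)
}

#' Select group-specific hypo-methylated regions
#'
#' Retains candidate regions hypo-methylated in every in-group sample and in
#' no out-group sample (e.g. hypo in both photoreceptor samples but in none
#' of the cortical samples).
#'
#' @param candidates `GRanges` of candidate regions.
#' @param hypo_calls Logical matrix or data.frame, one row per candidate and
#'   one named column per sample.
#' @param in_group,out_group Character vectors of sample names.
#' @return The retained subset of `candidates`.
#' @export
group_specific_hypo_dmr <- function(candidates, hypo_calls, in_group,
                                    out_group) {
  hc <- as.matrix(hypo_calls)
  missing <- setdiff(c(in_group, out_group), colnames(hc))
  if (length(missing))
    stop("samples missing from hypo_calls: ", paste(missing, collapse = ", "))
  stopifnot(nrow(hc) == length(candidates))
  keep <- rowSums(!hc[, in_group, drop = FALSE]) == 0 &
    rowSums(hc[, out_group, drop = FALSE]) == 0
  candidates[keep]
}

#' Pairwise Fisher tests of DMV methylation across samples
#'
#' For every DMV and ordered sample pair, Fisher's exact test on the 2x2
#' table of pooled (methylated, unmethylated) read counts; BH correction is
#' applied across all DMV x pair tests.  Pairs where either sample has zero
#' coverage in the DMV are skipped and flagged.
#'
#' @param dmvs `GRanges` of (merged) DMVs.
#' @param samples List of `methylome` objects (>= 2), ideally named.
#' @param alpha_fdr Adjusted significance threshold (default 1e-10).
#' @return `data.table` with `dmv`, `sample_a`, `sample_b`, levels, `p_value`,
#'   `q_value`, `significant` and `skipped`.
#' @export
dmv_fisher_test <- function(dmvs, samples, alpha_fdr = 1e-10) {
  stopifnot(length(samples) >= 2)
  labs <- names(samples) %||% paste0("sample", seq_along(samples))
  counts <- lapply(samples, region_meth_counts, regions = dmvs)
  pairs <- combn(length(samples), 2)
  res <- rbindlist(lapply(seq_len(ncol(pairs)), function(pi) {
    i <- pairs[1, pi]; j <- pairs[2, pi]
    ci <- counts[[i]]; cj <- counts[[j]]
    data.table(dmv = seq_along(dmvs), sample_a = labs[i], sample_b = labs[j],
               mc_a = ci$mc, cov_a = ci$cov, mc_b = cj$mc, cov_b = cj$cov)
  }))
  res[, skipped := cov_a == 0 | cov_b == 0]
  res[, p_value := NA_real_]
  ok <- which(!res$skipped)
  res$p_value[ok] <- vapply(ok, function(r) {
    fisher.test(matrix(c(res$mc_a[r], res$cov_a[r] - res$mc_a[r],
                         res$mc_b[r], res$cov_b[r] - res$mc_b[r]),
                       nrow = 2))$p.value
  }, numeric(1))
  res[, q_value := p.adjust(p_value, method = "BH")]
  res[, significant := !is.na(q_value) & q_value < alpha_fdr]
  res[, level_a := ifelse(cov_a > 0, mc_a / cov_a, NA_real_)]
  res[, level_b := ifelse(cov_b > 0, mc_b / cov_b, NA_real_)]
  res[, .(dmv, sample_a, sample_b, level_a, level_b, p_value, q_value,
          significant, skipped)]
}

#' Methylation/expression correlation profile around TSSs
#'
#' Each DMR is assigned to its nearest TSS; its signed, strand-oriented
#' offset (downstream positive) indexes a 1-kb bin in a +/- `window` around
#' the TSS.  Within every bin holding at least 3 DMRs, the Pearson
#' correlation between the DMR methylation difference (`delta`) and the
#' assigned gene's expression log2 ratio is reported; sparser bins are
#' missing.  DMRs whose gene lacks an expression value are dropped and
#' counted.
#'
#' @param dmrs `GRanges` from [join_dms_to_dmr()] (needs a `delta` column).
#' @param tss `GRanges` width-1 TSSs with `gene` metadata; TSS strand
#'   orients the offset sign.
#' @param expr_log2fc Named numeric vector, gene -> expression log2 ratio.
#' @param window Half-window in bp (default 1e5).
#' @param bin Bin width in bp (default 1000).
#' @return `data.table` with `offset` (bin lower edge, signed), `n` and `r`;
#'   `attr(,"n_dropped")` counts DMRs without expression values.
#' @export
meth_expr_correlation_profile <- function(dmrs, tss, expr_log2fc,
                                          window = 1e5, bin = 1000) {
  stopifnot(window %% bin == 0)
  mid0 <- (start(dmrs) - 1L) + width(dmrs) %/% 2L
  midgr <- GRanges(seqnames(dmrs), IRanges(mid0 + 1L, width = 1L))
  tss_u <- tss; strand(tss_u) <- "*"
  h <- harmonize(midgr, tss_u)
  idx <- GenomicRanges::nearest(h$a, h$b)
  ok <- !is.na(idx)
  off <- rep(NA_real_, length(dmrs))
  off[ok] <- mid0[ok] - (start(tss)[idx[ok]] - 1L)
  neg <- ok & as.character(strand(tss))[idx] == "-"
  off[which(neg)] <- -off[which(neg)]
  gene <- rep(NA_character_, length(dmrs))
  gene[ok] <- mcols(tss)$gene[idx[ok]]
  fc <- expr_log2fc[gene]
  dropped <- sum(ok & is.na(fc))
  keep <- ok & !is.na(fc) & off >= -window & off < window
  dt <- data.table(off = off[keep], delta = mcols(dmrs)$delta[keep],
                   fc = as.numeric(fc[keep]))
  dt[, bin_lo := floor(off / bin) * bin]
  prof <- dt[, .(n = .N,
                 r = if (.N >= 3) suppressWarnings(cor(delta, fc))
                 else NA_real_),
             by = .(offset = bin_lo)]
  setkey(prof, offset)
  setattr(prof, "n_dropped", dropped)
  prof[]
}

#' Write DMRs as extended BED
#'
#' BED6+ columns: interval, direction (name), number of significant sites
#' (score), strand, per-group levels and delta.
#'
#' @param dmrs `GRanges` from [join_dms_to_dmr()].
#' @param path Output path.
#' @export
write_dmrs_bed <- function(dmrs, path) {
  x <- sort(dmrs)
  df <- data.table(chrom = as.character(seqnames(x)), start = start(x) - 1L,
                   end = end(x), name = mcols(x)$direction,
                   score = mcols(x)$n_sites, strand = ".",
                   level_a = mcols(x)$level_a, level_b = mcols(x)$level_b,
                   delta = mcols(x)$delta)
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
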