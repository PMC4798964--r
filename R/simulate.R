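# Synthetic-epigenome generator.  Plants known regulatory region classes on
# a small genome and emits methylomes, accessibility fragments/peaks, DNA
# sequences and expression tables with the statistical structure the
# analysis assumes (beta-binomial count noise, bisulfite non-conversion,
# replicate structure), together with a ground-truth table used by the
# parameter-recovery tests.
#
# Region classes and their per-cell-type states:
#   PROMOTER_UMR       hypo-methylated (0.06) and accessible in every type.
#   ACTIVE_ENHANCER    hypo-methylated (0.24) + accessible in its active
#                      type(s) ("both", "rodlike" or "conelike"); methylated
#                      background elsewhere.
#   VESTIGIAL_ENHANCER hypo-methylated but INACCESSIBLE in its adult type;
#                      methylated in the other adult type; hypo + accessible
#                      in the fetal-like profile (its earlier developmental
#                      state).
#   DMV_TF_LOCUS       multi-kb, very low methylation, with cell-type
#                      methylation contrasts ("rod_low" vs "rod_high").
#   BACKGROUND         everything else (0.80).
# The hybrid profile is a convex 50/50 combination of the rodlike and
# conelike states at every region.

CELLTYPES <- c("rodlike", "conelike", "hybrid", "fetal_like", "cortexlike")

# deterministic per-stage / per-sample seed derivation from the global seed
derive_seed <- function(seed, stage, celltype = NULL, replicate = 0L) {
  idx <- if (is.null(celltype)) 0L else match(celltype, CELLTYPES)
  as.integer((as.numeric(seed) + 7919 * stage + 104729 * idx +
                13 * replicate) %% 2147483647)
}

#' Simulation configuration
#'
#' Defaults describe a 2 x 5 Mb genome whose planted region counts realise a
#' vestigial-enhancer fraction of 0.30 among rodlike LMR-class regions
#' (60 / (60 + 60 + 80)) and 0.05 among conelike ones (8 / (8 + 60 + 92)).
#' Class methylation levels are anchored at 0.06 (promoter UMRs), 0.24
#' (enhancer LMRs) and 0.80 (background); DMV loci carry the two observed
#' cross-cell-type patterns (rod-low: 0.067 vs 0.120; rod-high: 0.135 vs
#' 0.080).
#'
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param n_promoter_umr,n_enh_shared,n_enh_rod,n_enh_cone Planted counts of
#'   promoter UMRs and active enhancers (shared / rodlike- / conelike-
#'   specific).
#' @param n_vest_rod,n_vest_cone Vestigial enhancers of each adult type.
#' @param n_dmv DMV-bearing TF loci.
#' @param len_promoter,len_enh,len_dmv Length ranges (bp) per class.
#' @param spacing_bg,spacing_regul Mean CpG spacing (bp) in background and
#'   in regulatory regions.
#' @param level_umr,level_lmr,level_bg Class methylation levels.
#' @param dmv_levels Named list with `rod_low` and `rod_high` 2-vectors of
#'   (rodlike, conelike) levels.
#' @param depth Mean per-site read coverage (Poisson).
#' @param replicates Replicates per cell type.
#' @param dispersion Beta-binomial dispersion of per-site levels.
#' @param lambda_nc Bisulfite non-conversion rate.
#' @param mch_rates Named per-cell-type mCH levels.
#' @param ch_spacing Mean spacing of emitted CH sites (bp).
#' @param access_strength Expected fragments per bp in accessible regions.
#' @param weak_frac Relative accessibility of a cell-type-specific active
#'   enhancer in the other adult type (default 0.25, i.e. a four-fold
#'   planted accessibility difference with no peak emitted on the weak
#'   side).
#' @param background_frag_rate Expected background fragments per bp.
#' @param sub100_frac Fraction of fragments below 100 bp.
#' @param peak_jitter Per-replicate peak boundary jitter (bp).
#' @param expr_fold Minimum TPM fold difference of cell-type-specific genes.
#' @param tpm_floor Expression floor for "expressed" flagged genes.
#' @param hybrid_mix Mixing coefficient of the hybrid profile.
#' @param motif_pwm 4 x L position weight matrix planted in positive
#'   sequences (rows A, C, G, T).
#' @param min_region_gap Minimum bp between planted regions.
#' @param seed Mandatory global seed; every random draw derives from it.
#' @return List of class `sim_config`.
#' @export
simulation_config <- function(chrom_lengths = c(chr1 = 5e6, chr2 = 5e6),
                              n_promoter_umr = 60L, n_enh_shared = 60L,
                              n_enh_rod = 80L, n_enh_cone = 92L,
                              n_vest_rod = 60L, n_vest_cone = 8L,
                              n_dmv = 12L,
                              len_promoter = c(1500, 2500),
                              len_enh = c(400, 800),
                              len_dmv = c(5500, 9000),
                              spacing_bg = 50, spacing_regul = 40,
                              level_umr = 0.06, level_lmr = 0.24,
                              level_bg = 0.80,
                              dmv_levels = list(rod_low = c(0.067, 0.120),
                                                rod_high = c(0.135, 0.080)),
                              depth = 10, replicates = 2L, dispersion = 0.02,
                              lambda_nc = 0.005,
                              mch_rates = c(rodlike = 0.0012,
                                            conelike = 0.0044,
                                            hybrid = 0.0028,
                                            fetal_like = 0.0010,
                                            cortexlike = 0.0120),
                              ch_spacing = 100,
                              access_strength = 0.05, weak_frac = 0.25,
                              background_frag_rate = 4e-7,
                              sub100_frac = 0.7, peak_jitter = 25L,
                              expr_fold = 5, tpm_floor = 30,
                              hybrid_mix = 0.5,
                              motif_pwm = default_motif_pwm(),
                              min_region_gap = 2000L,
                              seed = 1L) {
  stopifnot(!is.null(seed), all(chrom_lengths > 0),
            n_promoter_umr >= 0, n_enh_shared >= 0, n_enh_rod >= 0,
            n_enh_cone >= 0, n_vest_rod >= 0, n_vest_cone >= 0, n_dmv >= 0,
            depth > 0, replicates >= 1, dispersion >= 0, dispersion < 1,
            lambda_nc >= 0, lambda_nc < 1, hybrid_mix >= 0, hybrid_mix <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Default planted motif
#'
#' An 8-bp homeodomain-like consensus (`TGGATTAG`) with 0.85 weight on the
#' consensus base per position.
#'
#' @param consensus Consensus string.
#' @param p_major Probability of the consensus base.
#' @return 4 x nchar(consensus) matrix, rows A/C/G/T.
#' @export
default_motif_pwm <- function(consensus = "TGGATTAG", p_major = 0.9) {
  bases <- c("A", "C", "G", "T")
  cols <- strsplit(consensus, "")[[1]]
  pwm <- vapply(cols, function(b) {
    p <- rep((1 - p_major) / 3, 4)
    p[match(b, bases)] <- p_major
    p
  }, numeric(4))
  rownames(pwm) <- bases
  pwm
}

# Poisson-process positions with mean spacing `spacing` on [1, len]
poisson_positions <- function(len, spacing) {
  n <- rpois(1, len / spacing)
  if (n == 0) return(integer(0))
  sort(sample.int(len, min(n, len)))
}

# place n intervals of the given lengths, pairwise separated by >= gap
place_regions <- function(lens, genome, gap, max_retries = 2000L) {
  chroms <- names(genome$chrom_lengths)
  clen <- genome$chrom_lengths
  si <- genome_seqinfo(genome)
  ord <- order(lens, decreasing = TRUE)
  occ_s <- setNames(lapply(chroms, function(ch)
    as.integer(start(genome$gaps[seqnames(genome$gaps) == ch]))), chroms)
  occ_e <- setNames(lapply(chroms, function(ch)
    as.integer(end(genome$gaps[seqnames(genome$gaps) == ch]))), chroms)
  out_chrom <- character(length(lens)); out_start <- integer(length(lens))
  for (i in ord) {
    L <- lens[i]
    avail <- pmax(clen - L + 1, 0)
    placed <- FALSE
    for (t in seq_len(max_retries)) {
      ch <- sample(chroms, 1L, prob = avail)
      s <- sample.int(avail[[ch]], 1L)
      cs <- max(1L, s - as.integer(gap))           # gap-padded candidate
      ce <- cs + L + 2L * as.integer(gap) - 1L
      if (!any(cs <= occ_e[[ch]] & ce >= occ_s[[ch]])) {
        occ_s[[ch]] <- c(occ_s[[ch]], s)
        occ_e[[ch]] <- c(occ_e[[ch]], s + L - 1L)
        out_chrom[i] <- ch; out_start[i] <- s
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place planted regions without overlap; ",
                      "reduce counts or region gap")
  }
  GRanges(out_chrom, IRanges(out_start, width = lens), seqinfo = si)
}

#' Build the planted ground truth
#'
#' Places all region classes without overlap, assigns per-cell-type true
#' methylation levels and accessibility strengths, generates the CpG / CH
#' site coordinates shared by every simulated sample, and lays out genes
#' (promoter genes at region centres; enhancer-linked genes 2-6 kb
#' downstream of their region).  Deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return List of class `epi_truth` with elements `genome`, `config`,
#'   `regions` (GRanges with `region_id`, `class`, `subtype`), `true_meth`
#'   and `access` (region x cell-type matrices), `tss`, `genes`, `cpg` and
#'   `ch` site tables.
#' @export
build_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genome <- genome_spec(config$chrom_lengths)
  with_seed_or_not(derive_seed(config$seed, 1L), {
    cls <- c(rep("PROMOTER_UMR", config$n_promoter_umr),
             rep("ACTIVE_ENHANCER",
                 config$n_enh_shared + config$n_enh_rod + config$n_enh_cone),
             rep("VESTIGIAL_ENHANCER", config$n_vest_rod + config$n_vest_cone),
             rep("DMV_TF_LOCUS", config$n_dmv))
    subtype <- c(rep("none", config$n_promoter_umr),
                 rep("both", config$n_enh_shared),
                 rep("rodlike", config$n_enh_rod),
                 rep("conelike", config$n_enh_cone),
                 rep("rodlike", config$n_vest_rod),
                 rep("conelike", config$n_vest_cone),
                 rep_len(c("rod_low", "rod_high"), config$n_dmv))
    lens <- integer(length(cls))
    rng <- function(r, n) as.integer(round(runif(n, r[1], r[2])))
    lens[cls == "PROMOTER_UMR"] <- rng(config$len_promoter,
                                       sum(cls == "PROMOTER_UMR"))
    lens[cls %in% c("ACTIVE_ENHANCER", "VESTIGIAL_ENHANCER")] <-
      rng(config$len_enh,
          sum(cls %in% c("ACTIVE_ENHANCER", "VESTIGIAL_ENHANCER")))
    lens[cls == "DMV_TF_LOCUS"] <- rng(config$len_dmv,
                                       sum(cls == "DMV_TF_LOCUS"))
    regions <- place_regions(lens, genome, config$min_region_gap)
    mcols(regions)$region_id <- sprintf("region_%d", seq_along(regions))
    mcols(regions)$class <- as.character(cls)
    mcols(regions)$subtype <- as.character(subtype)

    # per-cell-type true methylation
    nr <- length(regions)
    tm <- matrix(config$level_bg, nr, length(CELLTYPES),
                 dimnames = list(mcols(regions)$region_id, CELLTYPES))
    prom <- cls == "PROMOTER_UMR"
    tm[prom, ] <- config$level_umr
    enh <- cls == "ACTIVE_ENHANCER"
    tm[enh & subtype %in% c("both", "rodlike"), "rodlike"] <- config$level_lmr
    tm[enh & subtype %in% c("both", "conelike"), "conelike"] <- config$level_lmr
    vest <- cls == "VESTIGIAL_ENHANCER"
    tm[vest & subtype == "rodlike", "rodlike"] <- config$level_lmr
    tm[vest & subtype == "conelike", "conelike"] <- config$level_lmr
    tm[enh | vest, "fetal_like"] <- config$level_lmr
    dmv <- cls == "DMV_TF_LOCUS"
    for (pat in c("rod_low", "rod_high")) {
      lv <- config$dmv_levels[[pat]]
      tm[dmv & subtype == pat, "rodlike"] <- lv[1]
      tm[dmv & subtype == pat, "conelike"] <- lv[2]
      tm[dmv & subtype == pat, "fetal_like"] <- min(lv)
      tm[dmv & subtype == pat, "cortexlike"] <- mean(lv)
    }
    tm[, "hybrid"] <- config$hybrid_mix * tm[, "rodlike"] +
      (1 - config$hybrid_mix) * tm[, "conelike"]

    # accessibility strength (expected fragments per bp)
    s <- config$access_strength
    ac <- matrix(0, nr, length(CELLTYPES),
                 dimnames = dimnames(tm))
    ac[prom, ] <- s
    ac[enh & subtype %in% c("both", "rodlike"), "rodlike"] <- s
    ac[enh & subtype %in% c("both", "conelike"), "conelike"] <- s
    # specific enhancers keep weak, sub-peak accessibility in the other type
    ac[enh & subtype == "rodlike", "conelike"] <- s * config$weak_frac
    ac[enh & subtype == "conelike", "rodlike"] <- s * config$weak_frac
    ac[enh | vest, "fetal_like"] <- s
    ac[, "hybrid"] <- config$hybrid_mix * ac[, "rodlike"] +
      (1 - config$hybrid_mix) * ac[, "conelike"]
    ac[prom, "cortexlike"] <- s
    peak_emit <- ac > 0 & ac >= s - 1e-12

    # genes: promoter genes at region centres; regulatory-region genes with
    # a TSS 2-6 kb downstream of the region on the + strand
    gene_id <- sprintf("gene_%d", seq_along(regions))
    is_gene <- prom | enh | vest
    tss_pos0 <- integer(nr)
    tss_pos0[prom] <- (start(regions)[prom] - 1L) +
      width(regions)[prom] %/% 2L
    reg <- which((enh | vest))
    tss_pos0[reg] <- pmin(end(regions)[reg] +
                            as.integer(round(runif(length(reg), 2000, 6000))),
                          config$chrom_lengths[
                            as.character(seqnames(regions))[reg]] - 1L)
    spec_vec <- rep("none", nr)
    spec_vec[enh & subtype == "rodlike"] <- "rodlike"
    spec_vec[enh & subtype == "conelike"] <- "conelike"
    genes <- data.table(gene = gene_id[is_gene],
                        region_id = mcols(regions)$region_id[is_gene],
                        chrom = as.character(seqnames(regions))[is_gene],
                        tss_pos0 = tss_pos0[is_gene],
                        strand = "+",
                        specificity = spec_vec[is_gene])
    tss <- GRanges(genes$chrom, IRanges(genes$tss_pos0 + 1L, width = 1L),
                   strand = genes$strand, seqinfo = genome_seqinfo(genome))
    mcols(tss)$gene <- genes$gene

    # CpG sites: background process plus densification inside regions
    cpg <- rbindlist(lapply(names(config$chrom_lengths), function(ch) {
      L <- config$chrom_lengths[[ch]]
      pos <- poisson_positions(L, config$spacing_bg)
      extra_rate <- 1 / config$spacing_regul - 1 / config$spacing_bg
      reg_ch <- regions[seqnames(regions) == ch]
      if (extra_rate > 0 && length(reg_ch)) {
        extra <- unlist(lapply(seq_along(reg_ch), function(i) {
          w <- width(reg_ch)[i]
          n <- rpois(1, w * extra_rate)
          if (n == 0) integer(0) else
            start(reg_ch)[i] + sort(sample.int(w, min(n, w))) - 1L
        }))
        pos <- sort(unique(c(pos, extra)))
      }
      data.table(chrom = ch, pos = as.integer(pos))
    }))
    sites_gr <- GRanges(cpg$chrom, IRanges(cpg$pos, width = 1L))
    ov <- findOverlaps(sites_gr, regions)
    cpg[, region := 0L]
    cpg$region[queryHits(ov)] <- subjectHits(ov)

    ch_sites <- rbindlist(lapply(names(config$chrom_lengths), function(ch) {
      data.table(chrom = ch,
                 pos = poisson_positions(config$chrom_lengths[[ch]],
                                         config$ch_spacing))
    }))

    structure(list(genome = genome, config = config, regions = regions,
                   true_meth = tm, access = ac, peak_emit = peak_emit,
                   tss = tss, genes = genes, cpg = cpg, ch = ch_sites),
              class = "epi_truth")
  })
}

#' @export
print.epi_truth <- function(x, ...) {
  cat(sprintf("epi_truth: %d planted regions (%s), %d CpG sites, seed %s\n",
              length(x$regions),
              paste(names(table(mcols(x$regions)$class)),
                    table(mcols(x$regions)$class), collapse = ", ",
                    sep = ":"),
              nrow(x$cpg), format(x$config$seed)))
  invisible(x)
}

#' Flat ground-truth table
#'
#' @param truth An `epi_truth`.
#' @return `data.table` with one row per planted region: coordinates
#'   (0-based start), class, subtype, per-cell-type true methylation level
#'   and accessibility flag, and the linked gene (if any).
#' @export
truth_table <- function(truth) {
  r <- truth$regions
  dt <- data.table(region_id = mcols(r)$region_id,
                   chrom = as.character(seqnames(r)),
                   start = start(r) - 1L, end = end(r),
                   class = mcols(r)$class, subtype = mcols(r)$subtype)
  for (ct in CELLTYPES) {
    dt[[paste0("meth_", ct)]] <- truth$true_meth[, ct]
    dt[[paste0("accessible_", ct)]] <- truth$peak_emit[, ct]
  }
  dt <- merge(dt, truth$genes[, .(region_id, gene)], by = "region_id",
              all.x = TRUE, sort = FALSE)
  dt[order(chrom, start)]
}

# beta-binomial draw with mean p, dispersion phi, sizes n (vectorised)
rbetabinom <- function(n_sites, size, p, phi) {
  p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
  if (phi <= 0) return(rbinom(n_sites, size, p))
  a <- p * (1 - phi) / phi
  b <- (1 - p) * (1 - phi) / phi
  rbinom(n_sites, size, rbeta(n_sites, a, b))
}

#' Simulate one methylome replicate
#'
#' Per CpG site: coverage ~ Poisson(`depth`); the true level comes from the
#' site's region class and the cell-type profile (background elsewhere),
#' shifted by bisulfite non-conversion (`p_obs = mu + (1 - mu) * lambda`);
#' methylated counts are beta-binomial.  CH sites are emitted at the
#' profile's mCH rate.  Sites with zero drawn coverage are dropped
#' (unobserved).  Deterministic given (config seed, cell type, replicate).
#'
#' @param truth An `epi_truth`.
#' @param celltype One of `r paste(CELLTYPES, collapse = ", ")`.
#' @param replicate Replicate number (>= 1).
#' @return A `methylome` labelled `<celltype>_R<replicate>` carrying the
#'   config's `lambda_nc`.
#' @export
simulate_methylome <- function(truth, celltype = CELLTYPES,
                               replicate = 1L) {
  celltype <- match.arg(celltype)
  config <- truth$config
  with_seed_or_not(derive_seed(config$seed, 2L, celltype, replicate), {
    mu <- rep(config$level_bg, nrow(truth$cpg))
    inreg <- truth$cpg$region > 0L
    mu[inreg] <- truth$true_meth[truth$cpg$region[inreg], celltype]
    p_obs <- mu + (1 - mu) * config$lambda_nc
    cov <- rpois(length(mu), config$depth)
    mc <- integer(length(mu))
    pos_cov <- cov > 0
    mc[pos_cov] <- rbetabinom(sum(pos_cov), cov[pos_cov], p_obs[pos_cov],
                              config$dispersion)
    cg <- data.table(chrom = truth$cpg$chrom, pos = truth$cpg$pos,
                     strand = "+", context = "CG", mc = mc, cov = cov)[
                       cov > 0]
    rate <- unname(config$mch_rates[celltype])
    pch <- rate + (1 - rate) * config$lambda_nc
    covh <- rpois(nrow(truth$ch), config$depth)
    mch <- integer(length(covh))
    okh <- covh > 0
    mch[okh] <- rbinom(sum(okh), covh[okh], pch)
    chh <- data.table(chrom = truth$ch$chrom, pos = truth$ch$pos,
                      strand = "+", context = "CH", mc = mch, cov = covh)[
                        cov > 0]
    methylome(rbind(cg, chh), label = sprintf("%s_R%d", celltype, replicate),
              lambda_nc = config$lambda_nc)
  })
}

#' Pool replicate methylomes
#'
#' Sums counts across replicates at matching (chrom, pos, strand, context).
#'
#' @param ms List of `methylome` objects with equal `lambda_nc`.
#' @param label Label of the pooled methylome.
#' @return A `methylome`.
#' @export
pool_methylomes <- function(ms, label = "pooled") {
  all <- rbindlist(lapply(ms, function(m) m$records))
  pooled <- all[, .(mc = sum(mc), cov = sum(cov)),
                by = .(chrom, pos, strand, context)]
  methylome(pooled, label = label, lambda_nc = ms[[1]]$lambda_nc)
}

#' Simulate one accessibility replicate
#'
#' Accessible regions receive Poisson(`strength * length`) fragments placed
#' uniformly within the region; a low uniform background covers the whole
#' genome.  Fragment lengths are a mixture of sub-100 bp (fraction
#' `sub100_frac`, 40-99 bp) and longer (100-250 bp) fragments.  Peaks are
#' emitted, with per-replicate boundary jitter, only at regions whose
#' accessibility is at full strength in this cell type (weakly accessible
#' regions yield fragments but no peak).
#'
#' @inheritParams simulate_methylome
#' @return List with `fragments` (`GRanges`), `peaks` (`GRanges`) and
#'   `library_size` (total fragments).
#' @export
simulate_accessibility <- function(truth, celltype = CELLTYPES,
                                   replicate = 1L) {
  celltype <- match.arg(celltype)
  config <- truth$config
  si <- genome_seqinfo(truth$genome)
  with_seed_or_not(derive_seed(config$seed, 3L, celltype, replicate), {
    strength <- truth$access[, celltype]
    acc <- which(strength > 0)
    frag <- list()
    for (i in acc) {
      lam <- strength[i] * width(truth$regions)[i]
      n <- rpois(1, lam)
      if (n == 0) next
      len <- ifelse(runif(n) < config$sub100_frac,
                    as.integer(round(runif(n, 40, 99))),
                    as.integer(round(runif(n, 100, 250))))
      lo <- start(truth$regions)[i]
      hi <- pmax(end(truth$regions)[i] - len, lo)
      st <- as.integer(floor(runif(n, lo, hi + 1)))
      frag[[length(frag) + 1L]] <-
        data.table(chrom = as.character(seqnames(truth$regions))[i],
                   start = st, len = len)
    }
    total_len <- sum(config$chrom_lengths)
    nbg <- rpois(1, total_len * config$background_frag_rate)
    if (nbg > 0) {
      ch <- sample(names(config$chrom_lengths), nbg, replace = TRUE,
                   prob = config$chrom_lengths)
      len <- ifelse(runif(nbg) < config$sub100_frac,
                    as.integer(round(runif(nbg, 40, 99))),
                    as.integer(round(runif(nbg, 100, 250))))
      st <- as.integer(floor(runif(nbg, 1,
                                   config$chrom_lengths[ch] - len)))
      frag[[length(frag) + 1L]] <- data.table(chrom = ch, start = st,
                                              len = len)
    }
    frags <- if (length(frag)) {
      fd <- rbindlist(frag)
      sort(GRanges(fd$chrom, IRanges(fd$start, width = fd$len),
                   seqinfo = si))
    } else GRanges(seqinfo = si)
    acc <- which(truth$peak_emit[, celltype])
    jit <- as.integer(round(runif(2 * length(acc), -config$peak_jitter,
                                  config$peak_jitter)))
    peaks <- if (length(acc)) {
      pk <- truth$regions[acc]
      st <- pmax(start(pk) + jit[seq_along(acc)], 1L)
      en <- pmax(end(pk) + jit[length(acc) + seq_along(acc)], st + 50L)
      sort(GRanges(seqnames(pk), IRanges(st, en), seqinfo = si))
    } else GRanges(seqinfo = si)
    list(fragments = frags, peaks = peaks, library_size = length(frags))
  })
}

#' Simulate motif-planted positive and GC-matched negative sequences
#'
#' Positives are random sequences (per-sequence GC drawn uniformly in
#' `gc_range`) carrying a homotypic cluster of PWM-sampled motif instances:
#' `1 + Poisson(extra_motifs)` instances at non-overlapping random offsets,
#' so every positive contains at least one.  Negatives reuse the same
#' per-sequence GC values, keeping the mean GC difference far below the 2%
#' tolerance.
#'
#' @param truth An `epi_truth` (supplies the config and its PWM).
#' @param n_pos,n_neg Sequence counts.
#' @param seq_len Sequence length (default 500).
#' @param gc_range Per-sequence GC content range.
#' @param extra_motifs Poisson mean of additional motif instances per
#'   positive (default 1; 0 gives exactly one instance each).
#' @param seed_offset Added to the derived seed, letting callers draw
#'   independent sequence sets from one config.
#' @return List with `pos`, `neg` (character vectors), `pwm` and
#'   `motif_start` (list of 1-based insert offsets per positive).
#' @export
simulate_sequences <- function(truth, n_pos = 1000L, n_neg = 1000L,
                               seq_len = 500L, gc_range = c(0.40, 0.50),
                               extra_motifs = 1, seed_offset = 0L) {
  config <- truth$config
  pwm <- config$motif_pwm
  wlen <- ncol(pwm)
  stopifnot(seq_len > wlen)
  with_seed_or_not(derive_seed(config$seed, 4L) + seed_offset, {
    bases <- c("A", "C", "G", "T")
    rand_seq <- function(n, gc) {
      vapply(seq_len(n), function(i) {
        p <- c((1 - gc[i]) / 2, gc[i] / 2, gc[i] / 2, (1 - gc[i]) / 2)
        paste(sample(bases, seq_len, replace = TRUE, prob = p),
              collapse = "")
      }, character(1))
    }
    gc_pos <- runif(n_pos, gc_range[1], gc_range[2])
    gc_neg <- if (n_neg == n_pos) gc_pos else
      runif(n_neg, gc_range[1], gc_range[2])
    pos <- rand_seq(n_pos, gc_pos)
    neg <- rand_seq(n_neg, gc_neg)
    sample_instance <- function()
      paste(apply(pwm, 2, function(p) sample(bases, 1, prob = p)),
            collapse = "")
    motif_start <- vector("list", n_pos)
    for (i in seq_len(n_pos)) {
      n_inst <- 1L + rpois(1, extra_motifs)
      placed <- integer(0)
      for (j in seq_len(n_inst)) {
        for (try_i in 1:50) {
          st <- sample.int(seq_len - wlen + 1L, 1L)
          if (!any(abs(st - placed) < wlen)) { placed <- c(placed, st); break }
        }
      }
      s <- pos[i]
      for (st in placed)
        s <- paste0(substr(s, 1, st - 1), sample_instance(),
                    substr(s, st + wlen, seq_len))
      pos[i] <- s
      motif_start[[i]] <- sort(placed)
    }
    list(pos = pos, neg = neg, pwm = pwm, motif_start = motif_start)
  })
}

#' Simulate the expression table
#'
#' Cell-type-specific genes (those linked to rodlike- or conelike-specific
#' active enhancers) are expressed above `tpm_floor` in their own type with
#' at least `expr_fold`-fold difference over the other type; other genes
#' sit near a ratio of 1 (|log2| < 0.5).  The hybrid column is the 50/50
#' mixture.  Genes near hypo-methylated regulatory regions thereby receive
#' the high expression level, planting the methylation/expression
#' anti-correlation.
#'
#' @param truth An `epi_truth`.
#' @return `data.table` with `gene`, per-cell-type TPM, `log2fc`
#'   (log2 rodlike/conelike) and `specificity`.
#' @export
simulate_expression <- function(truth) {
  config <- truth$config
  g <- copy(truth$genes)
  with_seed_or_not(derive_seed(config$seed, 5L), {
    n <- nrow(g)
    hi <- runif(n, 2 * config$tpm_floor, 200)
    lo <- hi / (config$expr_fold * runif(n, 1.0, 1.6))
    base <- runif(n, 10, 120)
    ratio <- 2^runif(n, -0.45, 0.45)
    tpm_rod <- base * sqrt(ratio)
    tpm_cone <- base / sqrt(ratio)
    rod_spec <- g$specificity == "rodlike"
    cone_spec <- g$specificity == "conelike"
    tpm_rod[rod_spec] <- hi[rod_spec]
    tpm_cone[rod_spec] <- lo[rod_spec]
    tpm_cone[cone_spec] <- hi[cone_spec]
    tpm_rod[cone_spec] <- lo[cone_spec]
    data.table(gene = g$gene, rodlike = tpm_rod, conelike = tpm_cone,
               hybrid = config$hybrid_mix * tpm_rod +
                 (1 - config$hybrid_mix) * tpm_cone,
               log2fc = log2(tpm_rod / tpm_cone),
               specificity = g$specificity)
  })
}
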