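# Methylome segmentation into un-methylated regions (UMRs), low-methylated
# regions (LMRs) and DNA methylation valleys (DMVs).
#
# The segmentation is a deliberately simplified re-implementation of the
# MethylSeekR-style procedure: per-CpG levels are smoothed with a running
# mean over `smooth_k` sites, maximal runs below the methylation cutoff `m`
# become candidate segments, and a minimum-CpG threshold is calibrated
# against coordinate-shuffled null methylomes so that the expected number of
# surviving null segments is at most `seg_fdr` times the observed count.
# The original tool's two-dimensional (m, n) FDR grid is collapsed to a
# one-dimensional search over the CpG count at fixed m.

#' Segmentation parameters
#'
#' @param m_cutoff Smoothed-methylation threshold below which CpGs are
#'   candidate members of a hypo-methylated segment (default 0.5).
#' @param seg_fdr Target false discovery rate for segments (default 0.05).
#' @param smooth_k CpGs per running-mean smoothing window (default 3,
#'   centred, truncated at chromosome ends).
#' @param umr_min_cpgs CpG count at or above which a segment is a UMR rather
#'   than an LMR (default 30).
#' @param n_null Number of coordinate-shuffled null methylomes used for the
#'   FDR calibration (default 10).
#' @param seed Optional seed for the null shuffles.
#' @return List of class `segmentation_params`.
#' @export
segmentation_params <- function(m_cutoff = 0.5, seg_fdr = 0.05, smooth_k = 3L,
                                umr_min_cpgs = 30L, n_null = 10L,
                                seed = NULL) {
  stopifnot(m_cutoff > 0, m_cutoff < 1, seg_fdr > 0, seg_fdr < 1,
            smooth_k >= 1, umr_min_cpgs >= 2, n_null >= 1)
  structure(list(m_cutoff = m_cutoff, seg_fdr = seg_fdr,
                 smooth_k = as.integer(smooth_k),
                 umr_min_cpgs = as.integer(umr_min_cpgs),
                 n_null = as.integer(n_null), seed = seed),
            class = "segmentation_params")
}

# centred running mean with truncated edge windows
runmean_trunc <- function(x, k) {
  n <- length(x)
  if (k <= 1L || n == 1L) return(x)
  hlo <- (k - 1L) %/% 2L
  hhi <- k - 1L - hlo
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - hlo, 1L)
  hi <- pmin(seq_len(n) + hhi, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# candidate hypo runs for one chromosome; returns data.table of runs
hypo_runs <- function(pos, mc, cov, m_cutoff, smooth_k) {
  sm <- runmean_trunc(mc / cov, smooth_k)
  below <- sm < m_cutoff
  if (!any(below)) return(NULL)
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.table(i0 = starts[keep], i1 = ends[keep])
}

candidate_segments <- function(dt, m_cutoff, smooth_k) {
  dt[, {
    runs <- hypo_runs(pos, mc, cov, m_cutoff, smooth_k)
    if (is.null(runs)) NULL else {
      csm <- cumsum(c(0, as.numeric(mc)))
      csc <- cumsum(c(0, as.numeric(cov)))
      runs[, .(start = pos[i0], end = pos[i1], n_cpg = i1 - i0 + 1L,
               mean_meth = (csm[i1 + 1L] - csm[i0]) /
                 (csc[i1 + 1L] - csc[i0]))]
    }
  }, by = chrom]
}

#' Segment a methylome into UMRs and LMRs
#'
#' See the module description above for the algorithm.  Segment intervals
#' span the first to the last member CpG.  Surviving segments with at least
#' `umr_min_cpgs` covered CpGs are classed `UMR`, the rest `LMR`.
#'
#' @param m A `methylome` with covered CG sites.
#' @param params A [segmentation_params()].
#' @param max_len Optional post-filter: drop segments with width `>=
#'   max_len` bp (e.g. `5000` restricts to the sub-5 kb UMRs/LMRs used for
#'   accessibility concordance summaries).
#' @return Sorted `GRanges` with metadata `n_cpg`, `mean_meth` and `klass`
#'   (factor UMR/LMR); the calibrated minimum CpG count is stored in
#'   `metadata()$min_cpgs`.
#' @export
segment_hypomethylated <- function(m, params = segmentation_params(),
                                   max_len = NULL) {
  sites <- m$records[context == "CG" & cov > 0]
  if (nrow(sites) < params$smooth_k)
    stop("fewer covered CpGs than the smoothing window")
  setkey(sites, chrom, pos)
  obs <- candidate_segments(sites, params$m_cutoff, params$smooth_k)
  empty <- GRanges()
  metadata(empty)$min_cpgs <- NA_integer_
  if (is.null(obs) || nrow(obs) == 0) return(empty)

  # null: permute (mc, cov) tuples over the fixed CpG coordinates
  null_ncpg <- with_seed_or_not(params$seed, {
    unlist(lapply(seq_len(params$n_null), function(b) {
      perm <- sample.int(nrow(sites))
      ndt <- data.table(chrom = sites$chrom, pos = sites$pos,
                        mc = sites$mc[perm], cov = sites$cov[perm])
      nseg <- candidate_segments(ndt, params$m_cutoff, params$smooth_k)
      if (is.null(nseg)) integer(0) else nseg$n_cpg
    }))
  })

  max_n <- max(obs$n_cpg)
  min_cpgs <- NA_integer_
  for (n in seq_len(max_n)) {
    obs_ge <- sum(obs$n_cpg >= n)
    null_ge <- sum(null_ncpg >= n) / params$n_null
    if (obs_ge > 0 && null_ge <= params$seg_fdr * obs_ge) {
      min_cpgs <- n
      break
    }
  }
  if (is.na(min_cpgs)) {
    warning("no CpG-count threshold reaches the requested segment FDR; ",
            "returning zero segments")
    return(empty)
  }
  keep <- obs[n_cpg >= min_cpgs]
  gr <- GRanges(keep$chrom, IRanges(keep$start, keep$end))
  mcols(gr)$n_cpg <- keep$n_cpg
  mcols(gr)$mean_meth <- keep$mean_meth
  mcols(gr)$klass <- factor(ifelse(keep$n_cpg >= params$umr_min_cpgs,
                                   "UMR", "LMR"), levels = c("UMR", "LMR"))
  gr <- sort(gr)
  if (!is.null(max_len)) gr <- gr[width(gr) < max_len]
  metadata(gr)$min_cpgs <- min_cpgs
  gr
}

#' Call DNA methylation valleys from segmented UMRs
#'
#' A DMV is a UMR at least `min_len` bp long with pooled methylation at or
#' below `max_mean_meth`.  This is a pure filter: the output is a subset of
#' the input UMRs.
#'
#' @param segments Output of [segment_hypomethylated()].
#' @param min_len Minimum length in bp (default 5000).
#' @param max_mean_meth Maximum mean methylation, inclusive (default 0.15).
#' @return `GRanges` of DMVs.
#' @export
call_dmv <- function(segments, min_len = 5000L, max_mean_meth = 0.15) {
  stopifnot(min_len > 0, max_mean_meth > 0, max_mean_meth < 1)
  segments[mcols(segments)$klass == "UMR" &
             width(segments) >= min_len &
             mcols(segments)$mean_meth <= max_mean_meth]
}

#' Union of DMV sets across samples
#'
#' Merges overlapping and book-ended intervals; idempotent.
#'
#' @param dmv_sets List of `GRanges`.
#' @return Merged `GRanges`.
#' @export
merge_dmv_union <- function(dmv_sets) {
  stopifnot(length(dmv_sets) >= 1)
  lv <- unique(unlist(lapply(dmv_sets, seqlevels)))
  sets <- lapply(dmv_sets, function(g) { seqlevels(g) <- lv; granges(g) })
  reduce(sort(do.call(c, unname(sets))))
}

#' Classify DMVs by overlapping chromatin marks
#'
#' Overlap (>= 1 bp) with H3K27me3 peaks only gives `polycomb`, with H3K4me3
#' only gives `active`, with both `both`, with neither `neither`.
#'
#' @param dmvs `GRanges` of DMVs.
#' @param k27me3,k4me3 `GRanges` peak sets (possibly empty).
#' @return Factor of length `length(dmvs)`.
#' @export
classify_dmv_chromatin <- function(dmvs, k27me3, k4me3) {
  ovl <- function(peaks) {
    if (length(peaks) == 0) return(rep(FALSE, length(dmvs)))
    h <- harmonize(dmvs, peaks)
    countOverlaps(h$a, h$b) > 0
  }
  p <- ovl(k27me3); a <- ovl(k4me3)
  cls <- ifelse(p & a, "both", ifelse(p, "polycomb",
                                      ifelse(a, "active", "neither")))
  factor(cls, levels = c("polycomb", "active", "both", "neither"))
}

#' Write segments or DMVs as BED6
#'
#' Class goes in the name field, mean methylation (x 1000, rounded) in the
#' score field.
#'
#' @param segments `GRanges` with `klass` and `mean_meth` metadata.
#' @param path Output path.
#' @export
write_segments_bed <- function(segments, path) {
  x <- sort(segments)
  df <- data.table(chrom = as.character(seqnames(x)), start = start(x) - 1L,
                   end = end(x),
                   name = as.character(mcols(x)$klass %||%
                                         rep("segment", length(x))),
                   score = round((mcols(x)$mean_meth %||%
                                    rep(0, length(x))) * 1000),
                   strand = ".")
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
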