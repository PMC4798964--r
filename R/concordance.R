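# Methylation / accessibility concordance: per-region accessibility
# summaries, the bootstrap Kolmogorov-Smirnov test used to compare signal
# distributions, and the DMR-around-TSS density matrix.

#' Concordance report for a set of hypo-methylated regions
#'
#' Quantifies accessibility at each region from sub-nucleosomal fragments
#' (FPKM), flags regions overlapping accessibility peaks (>= 1 bp) and
#' regions showing no sign of accessibility (FPKM strictly below
#' `fpkm_floor`), and aggregates the fractions.
#'
#' @param regions `GRanges` (e.g. LMRs or hypo-DMRs).
#' @param peaks `GRanges` of accessibility peaks.
#' @param fragments `GRanges` of raw fragments (length-filtered internally).
#' @param library_size Library size used for FPKM; default is the number of
#'   fragments surviving the length filter.
#' @param params An [accessibility_params()].
#' @return List of class `concordance_report` with counts, fractions and the
#'   per-region `fpkm` and `overlaps` vectors.
#' @export
concordance_report <- function(regions, peaks, fragments, library_size = NULL,
                               params = accessibility_params()) {
  frags <- filter_short_fragments(fragments, params)
  if (is.null(library_size)) library_size <- length(frags)
  fpkm <- region_fpkm(frags, regions, library_size)
  ovl <- intersect_fraction(regions, peaks)
  h <- harmonize(regions, reduce(peaks))
  flags <- countOverlaps(h$a, h$b) > 0
  inacc <- fpkm < params$fpkm_floor
  structure(list(n_regions = length(regions),
                 n_overlapping = ovl$n_overlap,
                 fraction_overlapping = ovl$fraction,
                 n_inaccessible = sum(inacc),
                 fraction_inaccessible = if (length(regions)) mean(inacc) else 0,
                 fpkm = fpkm, overlaps = flags,
                 library_size = library_size),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf(paste0("concordance_report: %d regions; %.1f%% overlap peaks; ",
                     "%.1f%% inaccessible (< FPKM floor)\n"),
              x$n_regions, 100 * x$fraction_overlapping,
              100 * x$fraction_inaccessible))
  invisible(x)
}

#' Write a concordance report
#'
#' Per-region TSV (`fpkm`, `overlaps_peak`, `inaccessible`) plus a JSON
#' summary of the aggregate fractions.
#'
#' @param report A `concordance_report`.
#' @param tsv_path,json_path Output paths (either may be `NULL`).
#' @export
write_concordance_report <- function(report, tsv_path = NULL,
                                     json_path = NULL) {
  if (!is.null(tsv_path)) {
    data.table::fwrite(data.table(
      fpkm = report$fpkm, overlaps_peak = report$overlaps,
      inaccessible = report$fpkm < 0.1), tsv_path, sep = "\t")
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(report[c("n_regions", "n_overlapping",
                                  "fraction_overlapping", "n_inaccessible",
                                  "fraction_inaccessible", "library_size")],
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}

# two-sample KS D statistic (ties handled by evaluating at tie-group ends)
ks_stat <- function(x, y) {
  n <- length(x); m <- length(y)
  v <- c(x, y)
  g <- c(rep(1L, n), rep(0L, m))
  o <- order(v)
  v <- v[o]; g <- g[o]
  cx <- cumsum(g) / n
  cy <- cumsum(1L - g) / m
  at_end <- c(v[-1] != v[-(n + m)], TRUE)
  max(abs(cx - cy)[at_end])
}

#' Bootstrap Kolmogorov-Smirnov test
#'
#' Two-sample KS D on the observed data; the p-value is the fraction of
#' `nboot` resamples of the pooled data (with replacement, original group
#' sizes, ties permitted) whose D is at least the observed D, with a +1
#' continuity correction.  Identical inputs give D = 0, p = 1.
#'
#' @param a,b Numeric vectors (length >= 5 each).
#' @param nboot Bootstrap resamples (default 1000, minimum 100).
#' @param seed Optional seed; the same seed reproduces the p-value.
#' @return List with `statistic` (D) and `p_value`.
#' @export
bootstrap_ks <- function(a, b, nboot = 1000L, seed = NULL) {
  if (length(a) < 5 || length(b) < 5)
    stop("bootstrap_ks needs at least 5 values per sample")
  stopifnot(nboot >= 100)
  D <- ks_stat(a, b)
  pooled <- c(a, b)
  n <- length(a); m <- length(b); N <- n + m
  hits <- with_seed_or_not(seed, {
    sum(vapply(seq_len(nboot), function(i) {
      idx <- sample.int(N, N, replace = TRUE)
      ks_stat(pooled[idx[seq_len(n)]], pooled[idx[n + seq_len(m)]])
    }, numeric(1)) >= D - 1e-12)
  })
  list(statistic = D, p_value = (1 + hits) / (nboot + 1))
}

# column-mass-preserving vertical running mean: row j's mass is spread
# uniformly over the rows whose window (half-widths from `w`) covers j
smooth_rows_mass <- function(M, w) {
  n <- nrow(M)
  if (w <= 1L || n <= 1L) return(M)
  hlo <- (w - 1L) %/% 2L
  hhi <- w - 1L - hlo
  cover <- pmin(seq_len(n) + hlo, n) - pmax(seq_len(n) - hhi, 1L) + 1L
  U <- M / cover
  cs <- rbind(0, apply(U, 2, cumsum))
  lo <- pmax(seq_len(n) - hlo, 1L)
  hi <- pmin(seq_len(n) + hhi, n)
  cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]
}

#' DMR density matrix around TSSs
#'
#' Builds an indicator matrix with one row per DMR and one column per
#' `bin`-bp offset bin spanning +/- `window` around the DMR's nearest TSS
#' (signed, strand-oriented offsets; downstream positive).  Rows are ordered
#' by `order_key` (e.g. decreasing accessibility rank) and then smoothed
#' vertically with a mass-preserving running mean over `smooth_rows` rows
#' (truncated windows at the edges, renormalised so every column keeps its
#' total mass).
#'
#' @param dmrs `GRanges`.
#' @param tss `GRanges` width-1 TSSs with `gene` metadata.
#' @param window Half-window bp (default 1e5); must be divisible by `bin`.
#' @param bin Bin width bp (default 1000).
#' @param smooth_rows Vertical smoothing window in rows (default 50).
#' @param order_key Numeric vector (length = DMRs); rows sorted by
#'   decreasing key.  Default keeps input order.
#' @return List with `raw` and `smoothed` matrices (excluded DMRs dropped),
#'   `offsets` (bin lower edges) and `n_excluded` (DMRs beyond the window or
#'   without a TSS).
#' @export
dmr_tss_density <- function(dmrs, tss, window = 1e5, bin = 1000,
                            smooth_rows = 50L, order_key = NULL) {
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
  inside <- ok & off >= -window & off < window
  n_excluded <- sum(!inside)
  off <- off[inside]
  key <- if (is.null(order_key)) rev(seq_along(off)) else order_key[inside]
  ord <- order(key, decreasing = TRUE)
  off <- off[ord]
  ncol <- as.integer(2 * window / bin)
  raw <- matrix(0, nrow = length(off), ncol = ncol)
  colbin <- floor((off + window) / bin) + 1L
  raw[cbind(seq_along(off), colbin)] <- 1
  list(raw = raw, smoothed = smooth_rows_mass(raw, as.integer(smooth_rows)),
       offsets = seq(-window, window - bin, by = bin),
       n_excluded = n_excluded)
}
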