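# Chromatin accessibility: fragment filtering, consensus peaks across
# samples, and differential-accessibility classification of consensus peaks.

#' Accessibility analysis parameters
#'
#' @param frag_max_len Exclusive fragment length cap in bp; only fragments
#'   shorter than this (sub-nucleosomal) are used for signal quantification
#'   (default 100).
#' @param fpkm_floor FPKM below which a region is called inaccessible,
#'   strict inequality (default 0.1).
#' @param fold_thresh Fold difference that must be exceeded (strictly) for a
#'   differential peak call (default 2).
#' @param peak_fdr BH-adjusted significance threshold for differential peaks
#'   (default 0.01).
#' @param min_overlap_samples Peak sets that must support a consensus peak
#'   (default 2).
#' @return List of class `accessibility_params`.
#' @export
accessibility_params <- function(frag_max_len = 100L, fpkm_floor = 0.1,
                                 fold_thresh = 2, peak_fdr = 0.01,
                                 min_overlap_samples = 2L) {
  stopifnot(frag_max_len > 0, fpkm_floor > 0, fold_thresh > 1, peak_fdr > 0,
            peak_fdr < 1, min_overlap_samples >= 1)
  structure(list(frag_max_len = as.integer(frag_max_len),
                 fpkm_floor = fpkm_floor, fold_thresh = fold_thresh,
                 peak_fdr = peak_fdr,
                 min_overlap_samples = as.integer(min_overlap_samples)),
            class = "accessibility_params")
}

#' Keep sub-nucleosomal fragments
#'
#' Retains fragments strictly shorter than `frag_max_len` bp (a 100 bp
#' fragment is excluded at the default).
#'
#' @param frags `GRanges` of fragments.
#' @param params An [accessibility_params()].
#' @return Filtered `GRanges`.
#' @export
filter_short_fragments <- function(frags, params = accessibility_params()) {
  frags[width(frags) < params$frag_max_len]
}

#' Consensus peaks across samples
#'
#' Merges all input peaks and keeps merged intervals supported by (an
#' overlapping peak in) at least `min_overlap_samples` of the input sets.
#'
#' @param peak_sets Named list of `GRanges`, one per sample/replicate (>= 2).
#' @param params An [accessibility_params()].
#' @return `GRanges` of consensus peaks with a `support` metadata column.
#' @export
consensus_peaks <- function(peak_sets, params = accessibility_params()) {
  stopifnot(length(peak_sets) >= 2)
  lv <- unique(unlist(lapply(peak_sets, seqlevels)))
  sets <- lapply(peak_sets, function(g) { seqlevels(g) <- lv; granges(g) })
  merged <- reduce(sort(do.call(c, unname(sets))))
  support <- Reduce(`+`, lapply(sets, function(g)
    as.integer(countOverlaps(merged, g) > 0L)))
  out <- merged[support >= params$min_overlap_samples]
  mcols(out)$support <- support[support >= params$min_overlap_samples]
  out
}

#' Tabulate fragment counts over peaks
#'
#' @param peaks `GRanges` of (consensus) peaks.
#' @param frag_sets Named list of `GRanges` fragment sets, one per sample.
#' @return List with `counts` (matrix peaks x samples) and `lib_sizes`.
#' @export
count_peak_fragments <- function(peaks, frag_sets) {
  counts <- vapply(frag_sets, function(fr) {
    h <- harmonize(peaks, fr)
    countOverlaps(h$a, h$b)
  }, integer(length(peaks)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = length(peaks))
  colnames(counts) <- names(frag_sets)
  list(counts = counts, lib_sizes = vapply(frag_sets, length, integer(1)))
}

# two-sided exact binomial p-value, vectorised over (x, n) with fixed prob
binom_p2 <- function(x, n, prob) {
  vapply(seq_along(x), function(i) {
    if (n[i] == 0) return(1)
    binom.test(x[i], n[i], p = prob)$p.value
  }, numeric(1))
}

#' Classify consensus peaks by differential accessibility
#'
#' Counts are scaled to the mean library size; the fold change is the ratio
#' of group means of the normalised counts.  Significance comes from a
#' two-sided exact binomial test of the pooled group-A count against the
#' library-size expectation, BH-corrected across peaks.  A peak is
#' `A-enriched` when fold > `fold_thresh` and q < `peak_fdr` (symmetric for
#' B); a fold of exactly `fold_thresh` or below, or a non-significant test,
#' gives `shared`.  Peaks with zero counts in both groups are `shared` and
#' flagged.
#'
#' @param counts Matrix of raw fragment counts, peaks x samples.
#' @param lib_sizes Named numeric vector of library sizes per sample.
#' @param groupA,groupB Character vectors of sample (column) names.
#' @param params An [accessibility_params()].
#' @return `data.table` with `fold` (A over B, normalised), `p_value`,
#'   `q_value`, `class` (factor A-enriched/B-enriched/shared) and
#'   `zero_flag`.
#' @export
differential_peaks <- function(counts, lib_sizes, groupA, groupB,
                               params = accessibility_params()) {
  stopifnot(all(c(groupA, groupB) %in% colnames(counts)))
  sc <- mean(lib_sizes[c(groupA, groupB)])
  norm <- sweep(counts, 2, sc / lib_sizes[colnames(counts)], `*`)
  mA <- rowMeans(norm[, groupA, drop = FALSE])
  mB <- rowMeans(norm[, groupB, drop = FALSE])
  fold <- mA / mB
  a <- rowSums(counts[, groupA, drop = FALSE])
  b <- rowSums(counts[, groupB, drop = FALSE])
  libA <- sum(lib_sizes[groupA]); libB <- sum(lib_sizes[groupB])
  p <- binom_p2(a, a + b, libA / (libA + libB))
  q <- p.adjust(p, method = "BH")
  cls <- rep("shared", nrow(counts))
  cls[q < params$peak_fdr & is.finite(fold) & fold > params$fold_thresh] <-
    "A-enriched"
  cls[q < params$peak_fdr & mA > 0 &
        (mB / mA) > params$fold_thresh] <- "B-enriched"
  cls[q < params$peak_fdr & mA == 0 & mB > 0] <- "B-enriched"
  cls[q < params$peak_fdr & mB == 0 & mA > 0] <- "A-enriched"
  zero <- a + b == 0
  cls[zero] <- "shared"
  data.table(fold = fold, p_value = p, q_value = q,
             class = factor(cls, levels = c("A-enriched", "B-enriched",
                                            "shared")),
             zero_flag = zero)
}
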