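# Epigenomic distance between samples: 1 - Pearson r of binned methylation
# levels, 1 - Jaccard of peak sets, and hierarchical clustering with Newick
# export.

#' Pairwise 1 - r distance from binned methylation
#'
#' Methylomes are binned ([bin_meth_levels()]); for every sample pair the
#' Pearson correlation is computed over bins covered in both samples
#' (pairwise-complete, not listwise), requiring at least `min_common_bins`
#' shared bins.
#'
#' @param methylomes Named list of `methylome` objects (>= 2).
#' @param bin_size Bin width bp (default 500).
#' @param min_common_bins Minimum shared covered bins per pair (default 100).
#' @return List of class `distance_matrix` with `labels`, `values`
#'   (symmetric, zero diagonal) and `metric = "one_minus_r"`.
#' @export
pearson_distance_matrix <- function(methylomes, bin_size = 500L,
                                    min_common_bins = 100L) {
  stopifnot(length(methylomes) >= 2)
  labs <- names(methylomes) %||%
    vapply(methylomes, function(m) m$label, character(1))
  bins <- lapply(methylomes, bin_meth_levels, bin_size = bin_size)
  k <- length(bins)
  d <- matrix(0, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    mm <- merge(bins[[i]][, .(chrom, bin_start, la = level)],
                bins[[j]][, .(chrom, bin_start, lb = level)],
                by = c("chrom", "bin_start"))
    if (nrow(mm) < min_common_bins)
      stop(sprintf("samples '%s' and '%s' share only %d covered bins (< %d)",
                   labs[i], labs[j], nrow(mm), min_common_bins))
    r <- cor(mm$la, mm$lb)
    d[i, j] <- d[j, i] <- 1 - r
  }
  structure(list(labels = labs, values = d, metric = "one_minus_r"),
            class = "distance_matrix")
}

#' Pairwise 1 - Jaccard distance between peak sets
#'
#' @param peak_sets Named list of `GRanges` (>= 2).  An empty set has
#'   distance 1 to every other set (flagged in `attr(,"empty_sets")`).
#' @return A `distance_matrix` with `metric = "one_minus_jaccard"`.
#' @export
jaccard_distance_matrix <- function(peak_sets) {
  stopifnot(length(peak_sets) >= 2)
  labs <- names(peak_sets) %||% paste0("set", seq_along(peak_sets))
  k <- length(peak_sets)
  d <- matrix(0, k, k, dimnames = list(labs, labs))
  empty <- vapply(peak_sets, function(g) length(g) == 0, logical(1))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    d[i, j] <- d[j, i] <- if (empty[i] || empty[j]) 1 else
      1 - jaccard_index(peak_sets[[i]], peak_sets[[j]])
  }
  out <- structure(list(labels = labs, values = d,
                        metric = "one_minus_jaccard"),
                   class = "distance_matrix")
  attr(out, "empty_sets") <- labs[empty]
  out
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("distance_matrix (%s), %d samples\n", x$metric,
              length(x$labels)))
  print(round(x$values, 4))
  invisible(x)
}

#' Hierarchical clustering of a distance matrix
#'
#' Agglomerative clustering (`stats::hclust`) with the chosen linkage.
#' Input columns/rows are first ordered by label so that the resulting tree
#' does not depend on sample input order.
#'
#' @param d A `distance_matrix`.
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @return An `hclust` object.
#' @export
hierarchical_cluster <- function(d, linkage = c("average", "complete",
                                                "single")) {
  linkage <- match.arg(linkage)
  v <- d$values
  if (!isTRUE(all.equal(v, t(v))))
    stop("distance matrix is not symmetric")
  ord <- order(rownames(v))
  v <- v[ord, ord]
  hclust(as.dist(v), method = linkage)
}

#' Newick string of a dendrogram
#'
#' @param hc An `hclust` object.
#' @return Single Newick string with branch lengths.
#' @export
dendrogram_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}

#' Write a distance matrix as TSV
#'
#' @param d A `distance_matrix`.
#' @param path Output path.
#' @export
write_distance_matrix <- function(d, path) {
  dt <- data.table(sample = rownames(d$values), as.data.table(d$values))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
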