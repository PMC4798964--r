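# Genome specification, region containers, interval arithmetic and the
# standard-format I/O shared by every analysis stage.
#
# Coordinate conventions: all on-disk interval formats (BED, narrowPeak,
# bedGraph) are 0-based half-open; in memory every interval lives in a
# `GRanges` (1-based, closed), with the conversion confined to the readers
# and writers below.  Methylome positions are 1-based both on disk and in
# memory (allc convention).

#' Genome specification
#'
#' Bundles chromosome lengths with an optional set of excluded (gap /
#' unmappable) intervals.  The gaps are honoured by [shuffle_matched()] and by
#' the synthetic-epigenome generator.
#'
#' @param chrom_lengths Named integer/numeric vector of chromosome lengths in
#'   bp.
#' @param gaps Optional `GRanges` of excluded intervals; must lie within the
#'   declared chromosome lengths.
#' @return An object of class `genome_spec` with elements `chrom_lengths` and
#'   `gaps`.
#' @export
genome_spec <- function(chrom_lengths, gaps = NULL) {
  stopifnot(length(chrom_lengths) >= 1, !is.null(names(chrom_lengths)),
            all(nzchar(names(chrom_lengths))), all(chrom_lengths > 0))
  chrom_lengths <- setNames(as.numeric(chrom_lengths), names(chrom_lengths))
  if (is.null(gaps)) {
    gaps <- GRanges(seqinfo = Seqinfo(names(chrom_lengths),
                                      as.integer(chrom_lengths)))
  } else {
    stopifnot(is(gaps, "GRanges"))
    bad <- !as.character(seqnames(gaps)) %in% names(chrom_lengths)
    if (any(bad)) stop("gap intervals on chromosomes absent from the genome")
    if (any(end(gaps) > chrom_lengths[as.character(seqnames(gaps))]))
      stop("gap intervals extend beyond declared chromosome lengths")
  }
  structure(list(chrom_lengths = chrom_lengths, gaps = gaps),
            class = "genome_spec")
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf("genome_spec: %d chromosomes, %.3g Mb total, %d gap intervals\n",
              length(x$chrom_lengths), sum(x$chrom_lengths) / 1e6,
              length(x$gaps)))
  invisible(x)
}

genome_seqinfo <- function(genome) {
  Seqinfo(names(genome$chrom_lengths), as.integer(genome$chrom_lengths))
}

#' Construct a region set from 0-based half-open coordinates
#'
#' Convenience constructor converting BED-convention coordinates into the
#' `GRanges` used throughout the package.  Output is sorted by
#' (chromosome, start).
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end 0-based half-open interval bounds (`end > start`).
#' @param name,score,strand Optional BED-style annotation columns.
#' @param label Optional label stored in `metadata(x)$label`.
#' @return A sorted `GRanges`.
#' @export
region_set <- function(chrom, start, end, name = NULL, score = NULL,
                       strand = NULL, label = NULL) {
  stopifnot(all(start >= 0), all(end > start), all(nzchar(chrom)))
  gr <- GRanges(chrom, IRanges(start + 1L, end),
                strand = strand %||% "*")
  if (!is.null(name)) mcols(gr)$name <- name
  if (!is.null(score)) mcols(gr)$score <- score
  gr <- sort(gr)
  if (!is.null(label)) metadata(gr)$label <- label
  gr
}

check_same_namespace <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) return(invisible(TRUE))
  sa <- unique(as.character(seqnames(a)))
  sb <- unique(as.character(seqnames(b)))
  if (!any(sa %in% sb))
    stop("region sets share no chromosome names; mismatched genome spec?")
  invisible(TRUE)
}

# Put two GRanges on a merged seqlevel universe so set operations do not warn.
harmonize <- function(a, b) {
  lv <- union(seqlevels(a), seqlevels(b))
  seqlevels(a) <- lv
  seqlevels(b) <- lv
  list(a = a, b = b)
}

#' Fraction of intervals in `a` overlapping `b`
#'
#' Counts intervals in `a` having at least `min_bp` bp of overlap with the
#' merged union of `b` (the "overlap by >= 1 bp" convention used for
#' peak/region concordance tallies).
#'
#' @param a,b `GRanges` region sets on the same genome.
#' @param min_bp Minimum overlap in bp (default 1).
#' @return List with `n`, `n_overlap` and `fraction`.
#' @export
intersect_fraction <- function(a, b, min_bp = 1L) {
  stopifnot(is(a, "GRanges"), is(b, "GRanges"), min_bp >= 1)
  check_same_namespace(a, b)
  h <- harmonize(a, reduce(b))
  novl <- sum(countOverlaps(h$a, h$b, minoverlap = as.integer(min_bp)) > 0L)
  n <- length(a)
  list(n = n, n_overlap = novl,
       fraction = if (n == 0L) 0 else novl / n)
}

#' Jaccard index of two region sets
#'
#' Total intersection bp over total union bp, after merging overlapping and
#' book-ended intervals within each set.  Two empty sets have Jaccard 0 by
#' definition.
#'
#' @param a,b `GRanges` region sets.
#' @return A number in `[0, 1]`.
#' @export
jaccard_index <- function(a, b) {
  stopifnot(is(a, "GRanges"), is(b, "GRanges"))
  h <- harmonize(reduce(a), reduce(b))
  inter <- sum(as.numeric(width(GenomicRanges::intersect(h$a, h$b))))
  uni <- sum(as.numeric(width(h$a))) + sum(as.numeric(width(h$b))) - inter
  if (uni == 0) 0 else inter / uni
}

#' Size-matched random region shuffles
#'
#' Draws `n_repeats` independent placements of the input length multiset onto
#' the mappable genome (chromosomes minus gaps).  Within each repeat the
#' placed intervals are mutually non-overlapping and avoid the gaps; the
#' length multiset is conserved exactly.  Placement is longest-first with
#' rejection sampling (at most `max_retries` proposals per interval) so that
#' long intervals are not starved of space.
#'
#' @param a `GRanges` whose interval lengths are to be matched.
#' @param genome A [genome_spec()].
#' @param n_repeats Number of independent shuffles (default 10).
#' @param seed Optional integer seed; the same seed reproduces the output
#'   exactly.
#' @param max_retries Proposals per interval before giving up.
#' @return A list of `n_repeats` sorted `GRanges`.
#' @export
shuffle_matched <- function(a, genome, n_repeats = 10L, seed = NULL,
                            max_retries = 1000L) {
  stopifnot(is(a, "GRanges"), inherits(genome, "genome_spec"), n_repeats >= 1)
  lens <- sort(width(a), decreasing = TRUE)
  chroms <- names(genome$chrom_lengths)
  clen <- genome$chrom_lengths
  si <- genome_seqinfo(genome)
  gap_s <- split(start(genome$gaps),
                 factor(as.character(seqnames(genome$gaps)), chroms))
  gap_e <- split(end(genome$gaps),
                 factor(as.character(seqnames(genome$gaps)), chroms))
  with_seed_or_not(seed, {
    lapply(seq_len(n_repeats), function(rep_i) {
      occ_s <- lapply(gap_s, as.integer)   # plain-vector interval lists:
      occ_e <- lapply(gap_e, as.integer)   # much faster than growing GRanges
      out_chrom <- character(length(lens))
      out_start <- integer(length(lens))
      for (i in seq_along(lens)) {
        L <- lens[i]
        avail <- pmax(clen - L + 1, 0)
        if (sum(avail) == 0)
          stop(sprintf("shuffle repeat %d: no chromosome can hold a %d bp interval",
                       rep_i, L))
        placed <- FALSE
        for (try_i in seq_len(max_retries)) {
          ch <- sample(chroms, 1L, prob = avail)
          s <- sample.int(avail[[ch]], 1L)          # 1-based start
          if (!any(s <= occ_e[[ch]] & s + L - 1L >= occ_s[[ch]])) {
            occ_s[[ch]] <- c(occ_s[[ch]], s)
            occ_e[[ch]] <- c(occ_e[[ch]], s + L - 1L)
            out_chrom[i] <- ch
            out_start[i] <- s
            placed <- TRUE
            break
          }
        }
        if (!placed)
          stop(sprintf("shuffle repeat %d: failed to place a %d bp interval after %d retries",
                       rep_i, L, max_retries))
      }
      sort(GRanges(out_chrom, IRanges(out_start, width = lens), seqinfo = si))
    })
  })
}

#' Per-region FPKM from fragment records
#'
#' Fragments per kilobase of region per million library fragments: for each
#' region, the number of overlapping fragments (>= 1 bp) times `1e9 /
#' (region length * library_size)`.
#'
#' @param fragments `GRanges` of (already length-filtered) fragments.
#' @param regions `GRanges` of regions to quantify.
#' @param library_size Total fragments in the library (> 0).
#' @return Numeric vector, one FPKM per region.
#' @export
region_fpkm <- function(fragments, regions, library_size) {
  stopifnot(library_size > 0)
  h <- harmonize(regions, fragments)
  cnt <- countOverlaps(h$a, h$b)
  cnt * 1e9 / (as.numeric(width(regions)) * library_size)
}

#' Distance of regions to the nearest TSS, with proximity buckets
#'
#' The distance is the unsigned bp separation between the region midpoint
#' (0-based `start + floor(width / 2)`) and the nearest annotated TSS on the
#' same chromosome.  Buckets: `<10 kb` for d < 10000, `10-100 kb` for
#' 10000 <= d <= 100000, `>100 kb` beyond.  Regions on chromosomes without
#' any TSS get `NA` distance and are flagged.
#'
#' @param regions `GRanges`.
#' @param tss `GRanges` of width-1 TSS positions with a `gene` metadata
#'   column (see [read_tss()]).
#' @return `data.frame` with `distance`, `bucket`, `gene` and `flagged`.
#' @export
tss_distance_classify <- function(regions, tss) {
  stopifnot(is(regions, "GRanges"), is(tss, "GRanges"))
  mid0 <- (start(regions) - 1L) + width(regions) %/% 2L
  midgr <- GRanges(seqnames(regions), IRanges(mid0 + 1L, width = 1L))
  tss_u <- tss
  strand(tss_u) <- "*"
  h <- harmonize(midgr, tss_u)
  idx <- GenomicRanges::nearest(h$a, h$b)
  dist <- rep(NA_real_, length(regions))
  gene <- rep(NA_character_, length(regions))
  ok <- !is.na(idx)
  dist[ok] <- abs(mid0[ok] - (start(tss_u)[idx[ok]] - 1L))
  if (!is.null(mcols(tss)$gene)) gene[ok] <- mcols(tss)$gene[idx[ok]]
  bucket <- rep(NA_character_, length(regions))
  bucket[ok & dist < 1e4] <- "<10 kb"
  bucket[ok & dist >= 1e4 & dist <= 1e5] <- "10-100 kb"
  bucket[ok & dist > 1e5] <- ">100 kb"
  data.frame(distance = dist,
             bucket = factor(bucket, levels = c("<10 kb", "10-100 kb", ">100 kb")),
             gene = gene, flagged = !ok)
}

# ---- standard-format I/O ---------------------------------------------------

#' Read / write BED and narrowPeak files
#'
#' Thin wrappers around `rtracklayer` handling the 0-based half-open
#' convention; writers always emit coordinate-sorted records.
#'
#' @param path File path.
#' @name region_io
NULL

narrowpeak_cols <- c(signalValue = "numeric", pValue = "numeric",
                     qValue = "numeric", peak = "integer")

#' @rdname region_io
#' @export
read_bed <- function(path) {
  sort(rtracklayer::import(path, format = "BED"))
}

#' @rdname region_io
#' @param x `GRanges` to write.
#' @export
write_bed <- function(x, path) {
  rtracklayer::export(sort(x), path, format = "BED")
  invisible(path)
}

#' @rdname region_io
#' @export
read_narrowpeak <- function(path) {
  sort(rtracklayer::import(path, format = "BED", extraCols = narrowpeak_cols))
}

#' @rdname region_io
#' @export
write_narrowpeak <- function(x, path) {
  x <- sort(x)
  df <- data.table(
    chrom = as.character(seqnames(x)), start = start(x) - 1L, end = end(x),
    name = mcols(x)$name %||% paste0("peak_", seq_along(x)),
    score = round(mcols(x)$score %||% 0),
    strand = ".",
    signalValue = mcols(x)$signalValue %||% 0,
    pValue = mcols(x)$pValue %||% -1,
    qValue = mcols(x)$qValue %||% -1,
    peak = mcols(x)$peak %||% (width(x) %/% 2L))
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname region_io
#' @export
read_bedgraph <- function(path) {
  sort(rtracklayer::import(path, format = "bedGraph"))
}

#' Read / write tab-separated TSS annotations
#'
#' Four columns: gene, chrom, 0-based position, strand.  In memory, TSSs are
#' width-1 `GRanges` with a `gene` metadata column.
#'
#' @param path File path.
#' @export
read_tss <- function(path) {
  dt <- data.table::fread(path, header = TRUE,
                          col.names = c("gene", "chrom", "pos", "strand"))
  gr <- GRanges(dt$chrom, IRanges(dt$pos + 1L, width = 1L), strand = dt$strand)
  mcols(gr)$gene <- dt$gene
  sort(gr)
}

#' @rdname read_tss
#' @param x Width-1 `GRanges` with `gene` metadata.
#' @export
write_tss <- function(x, path) {
  x <- sort(x)
  dt <- data.table(gene = mcols(x)$gene, chrom = as.character(seqnames(x)),
                   pos = start(x) - 1L, strand = as.character(strand(x)))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
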