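# Per-cytosine methylation data model: allc-style I/O, pooled region /
# binned / global methylation levels, bisulfite non-conversion adjustment.

#' Construct a methylome
#'
#' A methylome holds per-cytosine counts in a `data.table` with columns
#' `chrom`, `pos` (1-based), `strand` (+/-), `context` ("CG" or "CH"), `mc`
#' (methylated reads) and `cov` (total reads), sorted by (chrom, pos), plus
#' the sample's bisulfite non-conversion rate `lambda_nc`.
#'
#' Plus- and minus-strand records of a symmetric CpG are kept as separate
#' rows; all pooled statistics in this package sum counts across strands.
#'
#' @param records `data.frame`/`data.table` with the columns above.
#' @param label Sample label.
#' @param lambda_nc Bisulfite non-conversion rate in `[0, 1)`.
#' @return An object of class `methylome`.
#' @export
methylome <- function(records, label = "sample", lambda_nc = 0) {
  stopifnot(lambda_nc >= 0, lambda_nc < 1)
  dt <- as.data.table(records)
  need <- c("chrom", "pos", "strand", "context", "mc", "cov")
  if (!all(need %in% names(dt)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  stopifnot(all(dt$mc >= 0), all(dt$cov >= 0), all(dt$mc <= dt$cov),
            all(dt$context %in% c("CG", "CH")))
  setkey(dt, chrom, pos)
  structure(list(records = dt, label = label, lambda_nc = lambda_nc),
            class = "methylome")
}

#' @export
print.methylome <- function(x, ...) {
  ncg <- sum(x$records$context == "CG")
  cat(sprintf("methylome '%s': %d sites (%d CG, %d CH), lambda_nc = %g\n",
              x$label, nrow(x$records), ncg, nrow(x$records) - ncg,
              x$lambda_nc))
  invisible(x)
}

#' Read / write allc-style per-cytosine tables
#'
#' Tab-separated columns: chrom, pos (1-based), strand, tri-nucleotide
#' context, mc, cov and an optional methylation-call flag.  Contexts starting
#' with "CG" are normalised to "CG"; everything else is "CH".  The writer
#' emits the call flag as 1 when a one-sided binomial test of `mc` out of
#' `cov` against the non-conversion rate is significant at 0.05.
#'
#' @param path File path.
#' @param label Sample label for the returned methylome.
#' @param lambda_nc Non-conversion rate to attach.
#' @return [read_allc()] returns a `methylome`.
#' @export
read_allc <- function(path, label = basename(path), lambda_nc = 0) {
  dt <- data.table::fread(path, header = FALSE)
  if (ncol(dt) < 6) stop("allc file needs at least 6 columns")
  dt <- dt[, 1:6]
  setnames(dt, c("chrom", "pos", "strand", "tri", "mc", "cov"))
  dt[, context := ifelse(startsWith(tri, "CG"), "CG", "CH")]
  methylome(dt[, .(chrom, pos, strand, context, mc, cov)],
            label = label, lambda_nc = lambda_nc)
}

#' @rdname read_allc
#' @param m A `methylome`.
#' @export
write_allc <- function(m, path) {
  dt <- copy(m$records)
  lam <- max(m$lambda_nc, 1e-9)
  dt[, tri := ifelse(context == "CG", "CGN", "CHH")]
  dt[, flag := as.integer(pbinom(mc - 1L, cov, lam, lower.tail = FALSE) < 0.05 &
                            cov > 0)]
  data.table::fwrite(dt[, .(chrom, pos, strand, tri, mc, cov, flag)],
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

# internal: methylome records of one context as a width-1 GRanges
meth_sites_gr <- function(m, context = "CG") {
  dt <- m$records[context, on = "context"][cov > 0]
  list(gr = GRanges(dt$chrom, IRanges(dt$pos, width = 1L)), dt = dt)
}

#' Pooled methylation level of regions
#'
#' Count-weighted level `sum(mc) / sum(cov)` over the covered sites of the
#' requested context inside each region (not a mean of per-site ratios).
#' Regions without covered sites get `NA`, never 0.
#'
#' @param m A `methylome`.
#' @param regions `GRanges` (one or many regions).
#' @param context `"CG"` or `"CH"`.
#' @return Numeric vector of levels in `[0, 1]`, one per region.
#' @export
region_meth_level <- function(m, regions, context = "CG") {
  s <- meth_sites_gr(m, context)
  h <- harmonize(regions, s$gr)
  ov <- findOverlaps(h$a, h$b)
  mc <- rep(0, length(regions)); cv <- rep(0, length(regions))
  if (length(ov)) {
    agg <- rowsum(cbind(s$dt$mc[subjectHits(ov)], s$dt$cov[subjectHits(ov)]),
                  group = queryHits(ov))
    idx <- as.integer(rownames(agg))
    mc[idx] <- agg[, 1]; cv[idx] <- agg[, 2]
  }
  ifelse(cv > 0, mc / cv, NA_real_)
}

#' Per-region pooled counts (mc, cov)
#'
#' @inheritParams region_meth_level
#' @return `data.frame` with columns `mc` and `cov`, one row per region.
#' @export
region_meth_counts <- function(m, regions, context = "CG") {
  s <- meth_sites_gr(m, context)
  h <- harmonize(regions, s$gr)
  ov <- findOverlaps(h$a, h$b)
  mc <- rep(0, length(regions)); cv <- rep(0, length(regions))
  if (length(ov)) {
    agg <- rowsum(cbind(s$dt$mc[subjectHits(ov)], s$dt$cov[subjectHits(ov)]),
                  group = queryHits(ov))
    idx <- as.integer(rownames(agg))
    mc[idx] <- agg[, 1]; cv[idx] <- agg[, 2]
  }
  data.frame(mc = mc, cov = cv)
}

# linear non-conversion correction with clipping at zero
adjust_nonconversion <- function(p_hat, lambda) {
  pmax(0, (p_hat - lambda) / (1 - lambda))
}

#' Global methylation levels, non-conversion adjusted
#'
#' Raw pooled levels per context are corrected for bisulfite non-conversion
#' with the linear adjustment `p_adj = max(0, (p_hat - lambda) / (1 -
#' lambda))`.  The percentage of all methylcytosines in the CH context is
#' computed from the adjusted methylcytosine masses (`p_adj * total
#' coverage` per context).
#'
#' @param m A `methylome`.
#' @return List with `mcg` (mCG/CG), `mch` (mCH/CH), `total_mc` (mC/C over
#'   both contexts) and `pct_mc_ch` (percent of methylcytosines in CH
#'   context); entries are `NA` for contexts without covered sites.
#' @export
global_levels <- function(m) {
  lam <- m$lambda_nc
  agg <- m$records[cov > 0, .(mc = sum(as.numeric(mc)),
                              cov = sum(as.numeric(cov))), by = context]
  lvl <- function(ctx) {
    r <- agg[context == ctx]
    if (nrow(r) == 0 || r$cov == 0) return(c(NA_real_, 0))
    c(adjust_nonconversion(r$mc / r$cov, lam), r$cov)
  }
  cg <- lvl("CG"); ch <- lvl("CH")
  mass_cg <- if (is.na(cg[1])) 0 else cg[1] * cg[2]
  mass_ch <- if (is.na(ch[1])) 0 else ch[1] * ch[2]
  tot_cov <- cg[2] + ch[2]
  list(mcg = cg[1], mch = ch[1],
       total_mc = if (tot_cov > 0) (mass_cg + mass_ch) / tot_cov else NA_real_,
       pct_mc_ch = if (mass_cg + mass_ch > 0)
         100 * mass_ch / (mass_cg + mass_ch) else NA_real_)
}

#' Binned methylation levels
#'
#' Pools counts in fixed-size bins tiling each chromosome from coordinate 0;
#' a site at 1-based position `pos` falls in bin `floor((pos - 1) /
#' bin_size)`.  Bins without covered sites are absent from the output and
#' are treated as missing downstream.
#'
#' @param m A `methylome`.
#' @param bin_size Bin width in bp (default 500).
#' @param context `"CG"` or `"CH"`.
#' @return `data.table` with `chrom`, `bin_start` (0-based), `mc`, `cov`,
#'   `level`, keyed by (chrom, bin_start).
#' @export
bin_meth_levels <- function(m, bin_size = 500L, context = "CG") {
  stopifnot(bin_size > 0)
  ctx <- context
  dt <- m$records[context == ctx & cov > 0]
  out <- dt[, .(mc = sum(as.numeric(mc)), cov = sum(as.numeric(cov))),
            by = .(chrom, bin_start = ((pos - 1L) %/% as.integer(bin_size)) *
                     as.integer(bin_size))]
  out[, level := mc / cov]
  setkey(out, chrom, bin_start)
  out[]
}
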