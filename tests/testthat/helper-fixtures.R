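# Shared fixtures.  Expensive simulated objects are built once per session
# and reused across test files (test files run in one process).

.fix <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fix[[name]])) assign(name, force(expr), envir = .fix)
  get(name, envir = .fix)
}

# desk-scale config exercising every region class
small_config <- function(seed = 42, ...) {
  simulation_config(chrom_lengths = c(chr1 = 6e5, chr2 = 6e5),
                    n_promoter_umr = 10, n_enh_shared = 8, n_enh_rod = 10,
                    n_enh_cone = 12, n_vest_rod = 8, n_vest_cone = 2,
                    n_dmv = 4, seed = seed, ...)
}

small_truth <- function() cached("small_truth", build_truth(small_config()))

# the full stated world: 2 x 5 Mb, vestigial fractions 0.30 / 0.05
default_truth <- function() {
  cached("default_truth", build_truth(simulation_config(seed = 101)))
}

default_methylomes <- function(celltype) {
  cached(paste0("meth_", celltype), {
    lapply(1:2, function(r) simulate_methylome(default_truth(), celltype, r))
  })
}

default_segments <- function(celltype) {
  cached(paste0("seg_", celltype), {
    pooled <- pool_methylomes(default_methylomes(celltype), celltype)
    segment_hypomethylated(pooled, segmentation_params(seed = 11))
  })
}

default_accessibility <- function(celltype) {
  cached(paste0("acc_", celltype), {
    lapply(1:2, function(r)
      simulate_accessibility(default_truth(), celltype, r))
  })
}

# trained k-mer model at the full 1000/1000 stated size, plus held-out sets
kmer_fixture <- function() {
  cached("kmer_fixture", {
    tr <- simulate_sequences(default_truth(), n_pos = 1000, n_neg = 1000)
    te <- simulate_sequences(default_truth(), n_pos = 300, n_neg = 300,
                             seed_offset = 1)
    model <- train_kmer_model(tr$pos, tr$neg, seed = 1)
    list(train = tr, test = te, model = model,
         test_scores = score_sequences(model, c(te$pos, te$neg)),
         test_labels = rep(c(TRUE, FALSE), each = 300))
  })
}

# ---- small constructors ----------------------------------------------------

gr <- function(chrom, start0, end0, ...) {
  region_set(chrom = chrom, start = start0, end = end0, ...)
}

make_methylome <- function(pos, mc, cov, chrom = "chr1", context = "CG",
                           strand = "+", label = "m", lambda_nc = 0) {
  methylome(data.frame(chrom = chrom, pos = pos, strand = strand,
                       context = context, mc = mc, cov = cov),
            label = label, lambda_nc = lambda_nc)
}

# methylome with a constant-level background and optional planted runs;
# deterministic counts (mc = round(level * cov))
flat_methylome <- function(n_sites = 200, spacing = 50, level = 0.8,
                           cov = 10, plants = list()) {
  pos <- seq(spacing, by = spacing, length.out = n_sites)
  lev <- rep(level, n_sites)
  for (p in plants) lev[p$idx] <- p$level
  make_methylome(pos, mc = round(lev * cov), cov = rep(cov, n_sites))
}

random_regions <- function(n, chroms = c("chrA", "chrB"), genome_len = 5e4,
                           max_len = 400) {
  start <- sample.int(genome_len - max_len, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  gr(sample(chroms, n, replace = TRUE), start, start + len)
}

# ---- independent brute-force oracles --------------------------------------

# all-pairs overlap: interval i of a overlaps b if any pairwise overlap > 0
bf_intersect_fraction <- function(a, b) {
  ac <- as.character(GenomicRanges::seqnames(a))
  bc <- as.character(GenomicRanges::seqnames(b))
  as0 <- GenomicRanges::start(a) - 1L; ae0 <- GenomicRanges::end(a)
  bs0 <- GenomicRanges::start(b) - 1L; be0 <- GenomicRanges::end(b)
  hit <- vapply(seq_along(a), function(i) {
    any(ac[i] == bc & pmin(ae0[i], be0) - pmax(as0[i], bs0) > 0)
  }, logical(1))
  list(n_overlap = sum(hit), fraction = mean(hit))
}

# per-bp membership vectors on a small genome
bf_jaccard <- function(a, b, chroms, genome_len) {
  memb <- function(x) {
    v <- logical(length(chroms) * genome_len)
    xc <- as.character(GenomicRanges::seqnames(x))
    for (i in seq_along(x)) {
      off <- (match(xc[i], chroms) - 1L) * genome_len
      v[(off + GenomicRanges::start(x)[i]):(off + GenomicRanges::end(x)[i])] <- TRUE
    }
    v
  }
  va <- memb(a); vb <- memb(b)
  inter <- sum(va & vb); uni <- sum(va | vb)
  if (uni == 0) 0 else inter / uni
}

bf_auroc <- function(scores, labels) {
  sp <- scores[labels]; sn <- scores[!labels]
  tot <- 0
  for (x in sp) tot <- tot + sum(x > sn) + 0.5 * sum(x == sn)
  tot / (length(sp) * length(sn))
}

# two-sided Fisher p for a 2x2 table via the hypergeometric mass function
bf_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p0 <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p0 * (1 + 1e-7)])
}

# fraction of planted regions overlapped by >= 1 called region (optionally
# with a matching class), and the false-call fraction
recovery_stats <- function(called, planted, want_class = NULL) {
  hit <- vapply(seq_along(planted), function(i) {
    ov <- IRanges::subsetByOverlaps(called, planted[i])
    if (length(ov) == 0) return(FALSE)
    if (is.null(want_class)) TRUE else
      any(as.character(S4Vectors::mcols(ov)$klass) == want_class[i])
  }, logical(1))
  false_frac <- if (length(called) == 0) 0 else
    1 - intersect_fraction(called, planted)$fraction
  list(recovered = mean(hit), false_frac = false_frac)
}
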