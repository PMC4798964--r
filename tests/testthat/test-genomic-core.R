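# Interval arithmetic, shuffling, signal quantification, TSS distances and
# the standard-format I/O.

test_that("intersect_fraction handles the basic contracts", {
  a <- gr("chr1", c(0, 200), c(100, 300))
  b <- gr("chr1", 50, 150)
  r <- intersect_fraction(a, b)
  expect_equal(r$fraction, 0.5)
  expect_equal(r$n_overlap, 1L)
  expect_equal(intersect_fraction(a, a)$fraction, 1.0)
  expect_error(intersect_fraction(a, gr("chrZ", 0, 10)), "chromosome")
  # min_bp is respected
  expect_equal(intersect_fraction(a, b, min_bp = 51)$fraction, 0)
})

test_that("intersect_fraction and jaccard match brute-force oracles", {
  withr::with_seed(7, {
    for (rep_i in 1:3) {
      a <- random_regions(200)
      b <- random_regions(200)
      expect_identical(intersect_fraction(a, b)$n_overlap,
                       bf_intersect_fraction(a, b)$n_overlap)
      expect_equal(jaccard_index(a, b),
                   bf_jaccard(a, b, c("chrA", "chrB"), 5e4 + 400))
    }
  })
})

test_that("jaccard handles identity, disjoint, book-ended and empty sets", {
  a <- gr("chr1", c(0, 1000), c(100, 1100))
  expect_equal(jaccard_index(a, a), 1.0)
  expect_equal(jaccard_index(a, gr("chr1", 5000, 6000)), 0.0)
  expect_equal(jaccard_index(gr("chr1", 0, 100), gr("chr1", 50, 150)),
               50 / 150)
  expect_equal(jaccard_index(GRanges(), GRanges()), 0)
  # book-ended intervals merge before computing
  split2 <- gr("chr1", c(0, 50), c(50, 100))
  expect_equal(jaccard_index(split2, gr("chr1", 0, 100)), 1.0)
})

test_that("shuffle_matched conserves lengths, avoids gaps and is seeded", {
  genome <- genome_spec(c(chr1 = 1e5, chr2 = 1e5),
                        gaps = gr("chr1", 40000, 60000))
  a <- gr("chr1", c(0, 1000, 5000, 9000), c(500, 1800, 5200, 12000))
  out <- shuffle_matched(a, genome, n_repeats = 10, seed = 7)
  expect_length(out, 10)
  for (s in out) {
    expect_setequal(width(s), width(a))
    expect_equal(sum(countOverlaps(s, genome$gaps)), 0L)
    expect_true(all(countOverlaps(s, s) == 1L))  # mutually non-overlapping
  }
  out2 <- shuffle_matched(a, genome, n_repeats = 10, seed = 7)
  expect_identical(as.data.frame(out[[3]]), as.data.frame(out2[[3]]))
  # byte-identical BED serialisation under the same seed
  f1 <- tempfile(fileext = ".bed"); f2 <- tempfile(fileext = ".bed")
  write_bed(out[[1]], f1); write_bed(out2[[1]], f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("shuffle occupancy is near-uniform on a gapless genome", {
  genome <- genome_spec(c(chr1 = 2e4))
  a <- gr("chr1", seq(0, 900, by = 100), seq(50, 950, by = 100))
  reps <- shuffle_matched(a, genome, n_repeats = 300, seed = 5)
  cover <- numeric(4)  # occupancy in 4 windows of 5 kb
  w <- gr("chr1", c(0, 5000, 10000, 15000), c(5000, 10000, 15000, 20000))
  for (s in reps) {
    cover <- cover + vapply(seq_len(4), function(i)
      sum(width(GenomicRanges::intersect(reduce(s), w[i]))), numeric(1))
  }
  occ <- cover / (300 * 5000)
  expected <- sum(width(a)) / 2e4
  expect_true(all(abs(occ - expected) / expected < 0.05))
})

test_that("region_fpkm follows the definition and its invariances", {
  region <- gr("chr1", 1000, 2000)
  frags <- gr("chr1", seq(1100, 1900, length.out = 10),
              seq(1150, 1950, length.out = 10))
  expect_equal(region_fpkm(frags, region, 1e6), 10.0)
  expect_equal(region_fpkm(GRanges(), region, 1e6), 0.0)
  expect_equal(region_fpkm(frags, region, 2e6),
               region_fpkm(frags, region, 1e6) / 2)
  perm <- frags[c(4, 1, 9, 2, 8, 10, 3, 6, 5, 7)]
  expect_equal(region_fpkm(perm, region, 1e6),
               region_fpkm(frags, region, 1e6))
})

test_that("tss_distance_classify uses midpoints and the stated buckets", {
  tss <- GRanges("chr1", IRanges(10001, width = 1), strand = "+")
  mcols(tss)$gene <- "g1"
  r <- tss_distance_classify(gr("chr1", 10500, 11000), tss)
  expect_equal(r$distance, 750)
  expect_equal(as.character(r$bucket), "<10 kb")
  # bucket edges: 10 kb belongs to the middle bucket, >100 kb to the far one
  regions <- gr("chr1", c(34900, 19900, 209950), c(35100, 20100, 210050))
  r <- tss_distance_classify(regions, tss)
  expect_equal(as.character(r$bucket), c("10-100 kb", "10-100 kb", ">100 kb"))
  expect_equal(r$distance, c(10000, 25000, 200000))  # region_set sorts input
  # chromosome without a TSS is flagged
  r2 <- tss_distance_classify(gr("chr9", 0, 100), tss)
  expect_true(r2$flagged)
  expect_true(is.na(r2$distance))
})

test_that("BED / narrowPeak / TSS round trips preserve coordinates", {
  x <- gr("chr1", c(100, 5000), c(700, 5600),
          name = c("a", "b"), score = c(1, 2))
  f <- tempfile(fileext = ".bed")
  write_bed(x, f)
  y <- read_bed(f)
  expect_equal(start(y), start(x))
  expect_equal(end(y), end(x))
  np <- tempfile(fileext = ".narrowPeak")
  mcols(x)$signalValue <- c(3.5, 7.25)
  write_narrowpeak(x, np)
  z <- read_narrowpeak(np)
  expect_equal(start(z), start(x))
  expect_equal(mcols(z)$signalValue, c(3.5, 7.25))
  bg <- tempfile(fileext = ".bedGraph")
  writeLines(c("chr1\t0\t100\t2.5", "chr1\t100\t200\t0.5"), bg)
  sig <- read_bedgraph(bg)
  expect_equal(start(sig), c(1, 101))
  expect_equal(mcols(sig)$score, c(2.5, 0.5))
  tssf <- tempfile(fileext = ".tsv")
  tss <- GRanges("chr2", IRanges(501, width = 1), strand = "-")
  mcols(tss)$gene <- "gX"
  write_tss(tss, tssf)
  tss2 <- read_tss(tssf)
  expect_equal(start(tss2), 501L)
  expect_equal(mcols(tss2)$gene, "gX")
  expect_equal(as.character(strand(tss2)), "-")
})
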