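# Synthetic-epigenome generator: determinism, planted structure, noise
# model and the emitted data products.

test_that("build_truth is deterministic and plants the requested regions", {
  cfg <- small_config(seed = 99)
  t1 <- build_truth(cfg)
  t2 <- build_truth(cfg)
  expect_identical(truth_table(t1), truth_table(t2))
  tab <- table(mcols(t1$regions)$class)
  expect_equal(unname(tab["PROMOTER_UMR"]), 10)
  expect_equal(unname(tab["VESTIGIAL_ENHANCER"]), 10)
  expect_equal(unname(tab["ACTIVE_ENHANCER"]), 30)
  expect_equal(unname(tab["DMV_TF_LOCUS"]), 4)
  # planted regions are mutually disjoint
  expect_true(all(countOverlaps(t1$regions, t1$regions) == 1L))
  # vestigial state: hypo + inaccessible in its type, methylated in the other
  vest <- mcols(t1$regions)$class == "VESTIGIAL_ENHANCER" &
    mcols(t1$regions)$subtype == "rodlike"
  expect_true(all(t1$true_meth[vest, "rodlike"] < 0.5))
  expect_true(all(t1$true_meth[vest, "conelike"] > 0.5))
  expect_true(all(!t1$peak_emit[vest, "rodlike"]))
  expect_true(all(t1$access[vest, "rodlike"] == 0))
  # ... and accessible + hypo in the fetal-like profile
  expect_true(all(t1$peak_emit[vest, "fetal_like"]))
  expect_true(all(t1$true_meth[vest, "fetal_like"] < 0.5))
  # hybrid is the exact convex mixture
  expect_equal(t1$true_meth[, "hybrid"],
               0.5 * t1$true_meth[, "rodlike"] +
                 0.5 * t1$true_meth[, "conelike"])
})

test_that("simulated methylomes are reproducible and replicate-variable", {
  tr <- small_truth()
  m1 <- simulate_methylome(tr, "rodlike", 1)
  m1b <- simulate_methylome(tr, "rodlike", 1)
  expect_identical(m1$records, m1b$records)
  f1 <- tempfile(); f2 <- tempfile()
  write_allc(m1, f1); write_allc(m1b, f2)
  expect_identical(readLines(f1), readLines(f2))   # byte-identical emission
  m2 <- simulate_methylome(tr, "rodlike", 2)
  expect_false(identical(m1$records$mc, m2$records$mc))
  # same expectations: genome-wide levels agree closely across replicates
  expect_equal(global_levels(m1)$mcg, global_levels(m2)$mcg,
               tolerance = 0.01)
})

test_that("methylome noise model recovers planted levels", {
  # background-only world: global adjusted mCG should recover 0.8 within
  # 2 standard errors (beta-binomial design effect included)
  cfg <- simulation_config(chrom_lengths = c(chr1 = 5e5),
                           n_promoter_umr = 0, n_enh_shared = 0,
                           n_enh_rod = 0, n_enh_cone = 0, n_vest_rod = 0,
                           n_vest_cone = 0, n_dmv = 0, depth = 20,
                           seed = 31)
  tr <- build_truth(cfg)
  m <- simulate_methylome(tr, "rodlike", 1)
  g <- global_levels(m)
  cg <- m$records[context == "CG"]
  n_reads <- sum(cg$cov)
  deff <- 1 + (mean(cg$cov) - 1) * cfg$dispersion
  se <- sqrt(0.8 * 0.2 * deff / n_reads)
  expect_lt(abs(g$mcg - 0.8), 2 * se)
  # mCH rate zero: raw level ~ lambda, adjusted ~ 0
  cfg0 <- simulation_config(chrom_lengths = c(chr1 = 5e5),
                            n_promoter_umr = 0, n_enh_shared = 0,
                            n_enh_rod = 0, n_enh_cone = 0, n_vest_rod = 0,
                            n_vest_cone = 0, n_dmv = 0, depth = 20,
                            mch_rates = c(rodlike = 0, conelike = 0,
                                          hybrid = 0, fetal_like = 0,
                                          cortexlike = 0),
                            seed = 32)
  m0 <- simulate_methylome(build_truth(cfg0), "rodlike", 1)
  ch <- m0$records[context == "CH"]
  raw <- sum(ch$mc) / sum(ch$cov)
  expect_lt(abs(raw - cfg0$lambda_nc), 0.002)
  expect_lt(global_levels(m0)$mch, 0.002)
})

test_that("accessibility follows the planted rates", {
  tr <- small_truth()
  cfg <- tr$config
  a1 <- simulate_accessibility(tr, "rodlike", 1)
  a1b <- simulate_accessibility(tr, "rodlike", 1)
  expect_identical(as.data.frame(a1$fragments), as.data.frame(a1b$fragments))
  # expected vestigial FPKM from the default config's rate arithmetic is
  # below 0.1 (region width cancels: rate * 1e9 / library)
  trd <- default_truth()
  cfgd <- trd$config
  exp_lib <- sum(trd$access[, "rodlike"] * width(trd$regions)) *
    cfgd$sub100_frac
  exp_fpkm <- cfgd$background_frag_rate * cfgd$sub100_frac * 1e9 / exp_lib
  expect_lt(exp_fpkm, 0.1)
  # zero strength -> only background fragments
  tr0 <- build_truth(small_config(seed = 77, access_strength = 0))
  a0 <- simulate_accessibility(tr0, "rodlike", 1)
  expect_lte(length(a0$fragments), 10)
  expect_length(a0$peaks, 0)
  # doubling strength roughly doubles the planted fragment count
  tr2 <- build_truth(small_config(seed = 42, access_strength = 0.1))
  a2 <- simulate_accessibility(tr2, "rodlike", 1)
  expect_equal(length(a2$fragments) / length(a1$fragments), 2,
               tolerance = 0.15)
})

test_that("sequence simulation plants motifs and matches GC", {
  tr <- small_truth()
  sq <- simulate_sequences(tr, n_pos = 120, n_neg = 120, seq_len = 300)
  gc <- function(s) {
    v <- strsplit(paste(s, collapse = ""), "")[[1]]
    mean(v %in% c("G", "C"))
  }
  expect_lt(abs(gc(sq$pos) - gc(sq$neg)), 0.02)
  expect_true(all(nchar(sq$pos) == 300), all(nchar(sq$neg) == 300))
  # PWM scan oracle: at least 99% of positives carry a detectable instance
  hit <- vapply(sq$pos, function(s) {
    length(Biostrings::matchPWM(sq$pwm, s, min.score = "65%")) > 0
  }, logical(1))
  expect_gte(mean(hit), 0.99)
  # a zero-entropy motif appears verbatim in every positive
  cfg1 <- small_config(seed = 5,
                       motif_pwm = default_motif_pwm("TGGATTAG", 1))
  sq1 <- simulate_sequences(build_truth(cfg1), n_pos = 50, n_neg = 10,
                            seq_len = 200)
  expect_true(all(grepl("TGGATTAG", sq1$pos, fixed = TRUE)))
})

test_that("expression simulation obeys the fold and floor rules", {
  tr <- small_truth()
  ex <- simulate_expression(tr)
  expect_true(all(ex$rodlike >= 0 & ex$conelike >= 0))
  rod <- ex[specificity == "rodlike"]
  expect_true(all(rod$rodlike / rod$conelike >= 5))
  expect_true(all(rod$rodlike >= 30))
  none <- ex[specificity == "none"]
  expect_true(all(abs(none$log2fc) < 0.5))
  expect_equal(ex$hybrid, 0.5 * ex$rodlike + 0.5 * ex$conelike)
})
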