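# Differential methylation: site testing, block joining, group-specific
# selection, DMV Fisher contrasts and the methylation/expression profile.

# hand-built DMS table helper
dms_table <- function(pos, direction, significant = TRUE, chrom = "chr1",
                      delta = ifelse(direction == "A<B", -0.5, 0.5)) {
  data.table::data.table(chrom = chrom, pos = pos, strand = "+",
                         level_a = 0.5 + delta / 2,
                         level_b = 0.5 - delta / 2, delta = delta,
                         direction = direction, p_value = 1e-6,
                         q_value = 1e-4, significant = significant)
}

test_that("identical counts give p = 1 and no flag", {
  m <- make_methylome(pos = c(100, 200), mc = c(3, 7), cov = c(10, 10))
  dms <- call_dms(list(m, m), list(m, m))
  expect_equal(dms$p_value, c(1, 1))
  expect_false(any(dms$significant))
})

test_that("sites covered in only one group are skipped and counted", {
  a <- make_methylome(pos = c(100, 200), mc = c(1, 1), cov = c(10, 10))
  b <- make_methylome(pos = 100, mc = 9, cov = 10)
  dms <- call_dms(list(a), list(b))
  expect_equal(nrow(dms), 1)
  expect_equal(attr(dms, "n_skipped"), 1L)
})

test_that("join_dms_to_dmr reproduces the gap, direction and size rules", {
  p <- dmr_params()
  # gap rule: 100,200,600 at max_gap 250 -> blocks {100,200} and {600}
  d1 <- join_dms_to_dmr(dms_table(c(100, 200, 600), "A<B"), p)
  expect_length(d1, 1)
  expect_equal(c(start(d1), end(d1)), c(100, 200))
  expect_equal(mcols(d1)$n_sites, 2L)
  # opposite-direction site inside the block removes the whole block
  d2 <- join_dms_to_dmr(rbind(dms_table(c(100, 200), "A<B"),
                              dms_table(150, "A>B")), p)
  expect_length(d2, 0)
  # single isolated significant site is not a DMR
  expect_length(join_dms_to_dmr(dms_table(100, "A<B"), p), 0)
  # non-significant sites play no role
  d3 <- join_dms_to_dmr(rbind(dms_table(c(100, 200), "A<B"),
                              dms_table(150, "A>B", significant = FALSE)), p)
  expect_length(d3, 1)
})

test_that("DMR joining is order-invariant and direction-consistent", {
  tab <- rbind(dms_table(c(100, 300, 450, 5000, 5100), "A<B"),
               dms_table(c(2000, 2100, 5050), "A>B"))
  withr::with_seed(1, perm <- tab[sample(nrow(tab))])
  d_a <- join_dms_to_dmr(tab)
  d_b <- join_dms_to_dmr(perm)
  expect_identical(as.data.frame(d_a), as.data.frame(d_b))
  # no DMR interval contains an opposite-direction significant site
  for (i in seq_along(d_a)) {
    opp <- tab[direction != mcols(d_a)$direction[i] & significant == TRUE]
    inside <- opp$pos >= start(d_a)[i] & opp$pos <= end(d_a)[i]
    expect_false(any(inside))
  }
  # per direction, intervals are disjoint
  for (dir in c("A<B", "A>B")) {
    dd <- d_a[mcols(d_a)$direction == dir]
    if (length(dd) > 1) expect_true(all(countOverlaps(dd, dd) == 1L))
  }
})

test_that("DMS calling flags planted differences with correct direction", {
  withr::with_seed(9, {
    n_null <- 3000; n_diff <- 300
    mkrep <- function(p_vec) {
      make_methylome(pos = seq_len(length(p_vec)) * 60,
                     mc = rbinom(length(p_vec), 30, p_vec),
                     cov = rep(30, length(p_vec)))
    }
    pa <- c(rep(0.5, n_null), rep(0.8, n_diff))
    pb <- c(rep(0.5, n_null), rep(0.2, n_diff))
    ga <- list(mkrep(pa), mkrep(pa))
    gb <- list(mkrep(pb), mkrep(pb))
    dms <- call_dms(ga, gb)
    planted <- dms[pos > n_null * 60]
    expect_gte(mean(planted$significant & planted$direction == "A>B"), 0.9)
    null_part <- dms[pos <= n_null * 60]
    expect_lte(mean(null_part$significant), 0.01)
  })
})

test_that("group_specific_hypo_dmr applies the all-in / none-out rule", {
  cand <- gr("chr1", c(0, 100, 200) * 10, c(50, 150, 250) * 10)
  calls <- cbind(rod = c(TRUE, TRUE, TRUE), cone = c(TRUE, TRUE, FALSE),
                 exc = c(FALSE, TRUE, FALSE), pv = c(FALSE, TRUE, FALSE))
  keep <- group_specific_hypo_dmr(cand, calls, c("rod", "cone"),
                                  c("exc", "pv"))
  expect_length(keep, 1)
  expect_equal(start(keep), 1)       # hypo everywhere -> excluded
  expect_error(group_specific_hypo_dmr(cand, calls, c("rod", "missing"),
                                       "exc"), "missing")
})

test_that("dmv_fisher_test matches the hypergeometric oracle", {
  dmv <- gr("chr1", 0, 10000)
  m1 <- make_methylome(pos = c(100, 200), mc = c(5, 5), cov = c(50, 50))
  m2 <- make_methylome(pos = c(100, 200), mc = c(45, 45), cov = c(50, 50))
  res <- dmv_fisher_test(dmv, list(a = m1, b = m2))
  expect_equal(res$p_value, bf_fisher_p(10, 90, 90, 10), tolerance = 1e-10)
  expect_lt(res$p_value, 1e-10)
  expect_true(res$significant)
  # identical tables: p = 1
  res2 <- dmv_fisher_test(dmv, list(a = m1, b = m1))
  expect_equal(res2$p_value, 1)
  expect_false(res2$significant)
  # zero coverage in one sample is skipped and flagged
  m0 <- make_methylome(pos = 99999, mc = 0, cov = 1)
  res3 <- dmv_fisher_test(dmv, list(a = m1, b = m0))
  expect_true(res3$skipped)
  expect_true(is.na(res3$p_value))
})

test_that("doubling Fisher counts never increases p at fixed odds ratio", {
  for (mc1 in c(5, 10, 20)) for (mc2 in c(30, 40)) {
    p1 <- bf_fisher_p(mc1, 50 - mc1, mc2, 50 - mc2)
    p2 <- bf_fisher_p(2 * mc1, 100 - 2 * mc1, 2 * mc2, 100 - 2 * mc2)
    expect_lte(p2, p1 + 1e-12)
  }
})

test_that("meth/expr correlation profile finds planted anti-correlation", {
  withr::with_seed(5, {
    n <- 60
    tss <- GRanges("chr1", IRanges(seq(1e5, by = 2e5, length.out = n),
                                   width = 1), strand = "+")
    mcols(tss)$gene <- paste0("g", seq_len(n))
    offs <- sample(c(2000, 3500, 5000), n, replace = TRUE)
    delta <- runif(n, -0.5, 0.5)
    dmrs <- GRanges("chr1", IRanges(start(tss) + offs - 100, width = 200))
    mcols(dmrs)$delta <- delta
    fc <- setNames(-delta * 2, paste0("g", seq_len(n)))
    prof <- meth_expr_correlation_profile(dmrs, tss, fc)
    populated <- prof[!is.na(r)]
    expect_gt(nrow(populated), 0)
    expect_true(all(abs(populated$r + 1) < 1e-8))
    expect_true(all(prof$n[is.na(prof$r)] < 3))
    # permuted expression kills the correlation on average
    perm_r <- replicate(50, {
      fcp <- setNames(sample(fc), names(fc))
      pr <- meth_expr_correlation_profile(dmrs, tss, fcp)
      mean(pr$r, na.rm = TRUE)
    })
    expect_lt(abs(mean(perm_r, na.rm = TRUE)), 0.15)
    # genes absent from the expression map are dropped and counted
    pr2 <- meth_expr_correlation_profile(dmrs, tss, fc[1:30])
    expect_equal(attr(pr2, "n_dropped"), 30)
  })
})

test_that("end-to-end DMR recovery on planted differential regions", {
  # 100 rodlike-specific enhancers at delta 0.5, coverage 30
  cfg <- simulation_config(chrom_lengths = c(chr1 = 3e6, chr2 = 3e6),
                           n_promoter_umr = 0, n_enh_shared = 0,
                           n_enh_rod = 100, n_enh_cone = 0, n_vest_rod = 0,
                           n_vest_cone = 0, n_dmv = 0,
                           len_enh = c(600, 800), level_lmr = 0.30,
                           depth = 30, seed = 1234)
  tr <- build_truth(cfg)
  rods <- lapply(1:2, function(r) simulate_methylome(tr, "rodlike", r))
  cones <- lapply(1:2, function(r) simulate_methylome(tr, "conelike", r))
  dmrs <- join_dms_to_dmr(call_dms(rods, cones))
  planted <- tr$regions
  hit <- vapply(seq_along(planted), function(i) {
    ov <- IRanges::subsetByOverlaps(dmrs, planted[i])
    if (length(ov) == 0) return(FALSE)
    inter <- sum(width(GenomicRanges::intersect(granges(ov), planted[i])))
    any(mcols(ov)$direction == "A<B") &&
      inter >= 0.5 * width(planted[i]) &&
      inter >= 0.5 * max(width(ov))
  }, logical(1))
  expect_gte(mean(hit), 0.9)
  false_frac <- 1 - intersect_fraction(dmrs, planted)$fraction
  expect_lt(false_frac, 0.05)
})
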