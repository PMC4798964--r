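# Gapped k-mer featurisation, linear model, auROC and enrichment.

test_that("featurisation counts per window equal choose(l, k)", {
  p <- kmer_params()
  f <- featurize(strrep("ACGT", 5), p)          # 20 bp -> 11 windows
  expect_equal(attr(f, "n_windows"), 11)
  expect_equal(sum(f$count), 11 * choose(10, 6))
  expect_true(all(f$count > 0))
  # too-short sequence gives an empty vector
  f0 <- featurize("ACGTACGT", p)
  expect_equal(nrow(f0), 0)
  # windows containing N are skipped
  fn <- featurize(paste0(strrep("A", 9), "N", strrep("C", 9)), p)
  expect_equal(attr(fn, "n_windows"), 0)
})

test_that("featurisation is reverse-complement symmetric when collapsing", {
  withr::with_seed(8, {
    for (i in 1:5) {
      s <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                 collapse = "")
      rc <- chartr("ACGT", "TGCA",
                   paste(rev(strsplit(s, "")[[1]]), collapse = ""))
      f1 <- featurize(s); f2 <- featurize(rc)
      expect_identical(f1$id, f2$id)
      expect_identical(f1$count, f2$count)
    }
  })
  # without collapsing the symmetry generally breaks
  p0 <- kmer_params(revcomp_collapse = FALSE)
  s <- "ACGTAAGGTCACGTAAGGTC"
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  expect_false(identical(featurize(s, p0)$id, featurize(rc, p0)$id))
})

test_that("scoring is linear and matches the dense dot-product oracle", {
  fix <- kmer_fixture()
  model <- fix$model
  withr::with_seed(12, {
    seqs <- vapply(1:4, function(i)
      paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
            collapse = ""), character(1))
  })
  for (s in seqs) {
    f <- featurize(s, model$params)
    expect_equal(score_sequences(model, s),
                 sum(model$weights[f$id] * f$count))
  }
  # no usable window scores zero
  expect_equal(score_sequences(model, "ACGT"), 0)
  # all-zero weights score everything zero
  z <- model; z$weights[] <- 0
  expect_equal(score_sequences(z, seqs), rep(0, 4))
})

test_that("auroc matches the all-pairs oracle and handles ties", {
  expect_equal(auroc(c(1, 2, 3, 10, 11), c(F, F, F, T, T)), 1.0)
  expect_equal(auroc(c(1, 1, 1, 1), c(T, F, T, F)), 0.5)
  expect_error(auroc(1:3, c(TRUE, TRUE, TRUE)), "classes")
  withr::with_seed(33, {
    for (i in 1:3) {
      sc <- sample(1:40, 150, replace = TRUE)   # force ties
      lab <- runif(150) < 0.4
      if (!any(lab) || all(lab)) next
      expect_equal(auroc(sc, lab), bf_auroc(sc, lab))
    }
  })
})

test_that("expression discretisation and top-decile enrichment", {
  ec <- expression_class(c(0, 1, 2, 3, 3), n_replicates = 3)
  expect_equal(ec$high, c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_error(expression_class(4, n_replicates = 3))
  # all-high gives enrichment exactly 1
  expect_equal(top_decile_enrichment(runif(20), rep(TRUE, 20)), 1)
  # perfectly informative scores with a 10% high fraction give 10
  high <- c(rep(TRUE, 10), rep(FALSE, 90))
  scores <- ifelse(high, 1, 0)
  expect_equal(top_decile_enrichment(scores, high), 10)
  # zero high fraction is undefined
  expect_warning(e <- top_decile_enrichment(runif(20), rep(FALSE, 20)))
  expect_true(is.na(e))
})

test_that("model serialisation round-trips weights and params", {
  fix <- kmer_fixture()
  f <- tempfile(fileext = ".tsv")
  write_kmer_model(fix$model, f)
  m2 <- read_kmer_model(f)
  expect_equal(m2$params$l, 10L)
  expect_equal(m2$n_pos, fix$model$n_pos)
  expect_equal(m2$weights, fix$model$weights, tolerance = 1e-12)
  # header is a single JSON comment line
  expect_match(readLines(f, n = 1), "^#\\{")
})

test_that("top weights are consistent with the planted motif", {
  fix <- kmer_fixture()
  pwm <- fix$train$pwm
  consensus <- paste(rownames(pwm)[apply(pwm, 2, which.max)], collapse = "")
  rc <- chartr("ACGT", "TGCA",
               paste(rev(strsplit(consensus, "")[[1]]), collapse = ""))
  top <- order(fix$model$weights, decreasing = TRUE)[1:20]
  feats <- kmer_feature_string(top, fix$model$params)
  # a feature "matches" if its informative bases align with the consensus
  # (either strand) at some offset
  matches_motif <- function(fs, motif) {
    l <- nchar(fs)
    for (off in -(l - 1):(nchar(motif) - 1)) {
      ok <- TRUE
      for (i in seq_len(l)) {
        ch <- substr(fs, i, i)
        if (ch == ".") next
        mi <- i + off
        if (mi < 1 || mi > nchar(motif)) { ok <- FALSE; break }
        if (substr(motif, mi, mi) != ch) { ok <- FALSE; break }
      }
      if (ok) return(TRUE)
    }
    FALSE
  }
  hits <- vapply(feats, function(fs)
    matches_motif(fs, consensus) || matches_motif(fs, rc), logical(1))
  expect_gte(mean(hits), 0.75)
})

test_that("FASTA round trip preserves sequences and names", {
  seqs <- c(alpha = "ACGTACGTAC", beta = "TTTTGGGGCC")
  f <- tempfile(fileext = ".fa")
  write_fasta(seqs, f)
  expect_identical(read_fasta(f), seqs)
  expect_equal(readLines(f)[1], ">alpha")
})

test_that("training errors on unusable classes", {
  expect_error(train_kmer_model(character(0), "ACGTACGTACGTAC"))
  expect_error(train_kmer_model("ACG", strrep("ACGT", 10)), "usable windows")
})
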