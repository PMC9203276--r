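test_that("BH adjustment matches the step-up oracle and propagates NA", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(c(0.01, NA, 0.5)), c(0.02, NA, 0.5))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "quantchip_data_error")

  set.seed(1)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p))
    # monotone in p-rank and idempotent
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
    expect_equal(bh_adjust(adj), oracle_bh(adj))
    expect_true(all(adj >= p - 1e-12))
  }
})

test_that("identical counts in both conditions give a null result", {
  m <- matrix(50L, nrow = 4, ncol = 6)
  rownames(m) <- paste0("f", 1:4)
  colnames(m) <- paste0("s", 1:6)
  design <- tibble::tibble(sample = colnames(m), condition = rep(c("A", "B"), each = 3))
  out <- nb_wald_test(m, design, "A", "B")
  expect_true(all(abs(out$log2fc) < 1e-8))
  expect_true(all(out$pvalue > 0.5))
})

test_that("all-zero features are excluded from testing and adjustment", {
  fx <- nb_fixture(20, 100, 100, 0.05, seed = 2)
  fx$counts[1, ] <- 0L
  out <- nb_wald_test(fx$counts, fx$design, "A", "B")
  expect_equal(out$log2fc[1], 0)
  expect_true(is.na(out$pvalue[1]))
  expect_true(is.na(out$padj[1]))
  expect_false(anyNA(out$pvalue[-1]))
})

test_that("the Wald test is approximately calibrated on null NB data", {
  fx <- nb_fixture(800, 100, 100, 0.05, seed = 3)
  out <- nb_wald_test(fx$counts, fx$design, "A", "B")
  frac <- mean(out$pvalue < 0.05, na.rm = TRUE)
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.08)
})

test_that("log2 fold changes are recovered with small bias", {
  fx <- nb_fixture(600, 100, 400, 0.05, seed = 4)
  out <- nb_wald_test(fx$counts, fx$design, "A", "B")
  expect_lt(abs(mean(out$log2fc) - 2), 0.1)
})

test_that("size factors rescale conditions as specified", {
  fx <- nb_fixture(300, 200, 200, 0.02, seed = 5)
  sf <- setNames(c(1, 1, 1, 2, 2, 2), colnames(fx$counts))
  doubled <- fx$counts
  doubled[, 4:6] <- doubled[, 4:6] * 2L
  out <- nb_wald_test(doubled, fx$design, "A", "B", size_factors = sf)
  expect_lt(abs(mean(out$log2fc)), 0.05)
  expect_error(
    nb_wald_test(fx$counts, fx$design, "A", "B",
      size_factors = setNames(rep(0, 6), colnames(fx$counts))
    ),
    class = "quantchip_config_error"
  )
  expect_error(
    nb_wald_test(fx$counts, fx$design[1:4, ], "A", "B"),
    class = "quantchip_config_error"
  )
})

test_that("estimates agree with DESeq2 under fixed size factors", {
  skip_if_not_installed("DESeq2")
  fx <- nb_fixture(300, 80, 240, 0.05, seed = 6)
  out <- nb_wald_test(fx$counts, fx$design, "A", "B")
  dds <- suppressMessages(DESeq2::DESeqDataSetFromMatrix(
    fx$counts,
    S4Vectors::DataFrame(condition = factor(fx$design$condition, c("A", "B"))),
    ~condition
  ))
  DESeq2::sizeFactors(dds) <- rep(1, 6)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  res <- DESeq2::results(dds, contrast = c("condition", "B", "A"))
  expect_gt(cor(out$log2fc, res$log2FoldChange, use = "complete.obs"), 0.98)
  expect_lt(mean(abs(out$log2fc - res$log2FoldChange), na.rm = TRUE), 0.1)
  # significance calls mostly agree at FDR 5%
  both <- !is.na(out$padj) & !is.na(res$padj)
  agree <- mean((out$padj < 0.05) == (res$padj < 0.05), na.rm = TRUE)
  expect_gt(agree, 0.9)
})

test_that("significance calls apply the FDR and fold-change thresholds", {
  diff <- tibble::tibble(
    feature = c("a", "b", "c", "d"),
    log2fc = c(0.7, 0.5, -0.7, 2),
    padj = c(0.04, 0.04, 0.04, 0.2)
  )
  out <- call_significant(diff, alpha = 0.05, fc_threshold = 1.5)
  expect_equal(out$significant_up, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(out$significant_down, c(FALSE, FALSE, TRUE, FALSE))
  # RNA rule: fold change 2 reproduces |log2FC| > 1
  rna <- call_significant(
    tibble::tibble(feature = "x", log2fc = 1.01, padj = 0.01),
    fc_threshold = 2
  )
  expect_true(rna$significant_up)
  rna2 <- call_significant(
    tibble::tibble(feature = "x", log2fc = 0.99, padj = 0.01),
    fc_threshold = 2
  )
  expect_false(rna2$significant_up)
})

test_that("class response reproduces hand-computed Cohen's d", {
  # class {2,3,4} against all = {2,3,4,0,0,0,0}
  lfc <- setNames(c(2, 3, 4, 0, 0, 0, 0), paste0("g", 1:7))
  out <- class_response(lfc, paste0("g", 1:3), label = "toy")
  mean_all <- 9 / 7
  pooled <- sqrt(((3 - 1) * var(c(2, 3, 4)) + (7 - 1) * var(c(2, 3, 4, 0, 0, 0, 0))) / (3 + 7 - 2))
  expect_equal(out$cohens_d, (3 - mean_all) / pooled)
  expect_equal(out$median_class_lfc, 3)
  expect_equal(out$n_class, 3)
  expect_equal(out$n_all, 7)
})

test_that("small-group Wilcoxon p equals exact enumeration", {
  set.seed(8)
  for (i in 1:10) {
    lfc <- setNames(round(rnorm(8), 2), paste0("g", 1:8))
    members <- paste0("g", sample(8, sample(2:4, 1)))
    out <- class_response(lfc, members)
    cls <- unname(lfc[members])
    expect_equal(out$wilcoxon_p, oracle_ranksum_exact(cls, unname(lfc)))
  }
})

test_that("class equal to background gives null response statistics", {
  lfc <- setNames(rep(c(-1, 0, 1, 2), 5), paste0("g", 1:20))
  out <- class_response(lfc, paste0("g", 1:20), label = "all")
  expect_equal(out$cohens_d, 0)
  expect_gt(out$wilcoxon_p, 0.9)
  # degenerate spread: d undefined
  flat <- class_response(setNames(rep(1, 5), paste0("g", 1:5)), c("g1", "g2"))
  expect_true(is.na(flat$cohens_d))
})

test_that("Wilcoxon p is invariant under monotone transforms", {
  set.seed(9)
  lfc <- setNames(rnorm(60), paste0("g", 1:60))
  members <- paste0("g", 1:12)
  p1 <- class_response(lfc, members)$wilcoxon_p
  p2 <- class_response(exp(lfc), members)$wilcoxon_p
  expect_equal(p1, p2)
})

test_that("median-of-ratios size factors track library scaling", {
  set.seed(10)
  m <- matrix(rnbinom(400 * 4, mu = 100, size = 20), ncol = 4)
  m[, 2] <- m[, 2] * 3L
  colnames(m) <- paste0("s", 1:4)
  sf <- estimate_size_factors(m)
  expect_equal(unname(sf[2] / sf[1]), 3, tolerance = 0.1)
})

test_that("RPGC pseudo-counts scale with width over fragment length", {
  expect_equal(rpgc_to_counts(1.5, 2000, 150), 20L)
  expect_equal(rpgc_to_counts(c(0, 0.3), c(2000, 1000), 100), c(0L, 3L))
})
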