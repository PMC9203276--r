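flags_fixture <- function(n = 40, seed = 21) {
  set.seed(seed)
  tibble::tibble(
    gene_id = sprintf("g%03d", seq_len(n)),
    k4_naive = sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.8, 0.2)),
    k4_primed = sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.8, 0.2)),
    k27_naive = sample(c(TRUE, FALSE), n, replace = TRUE),
    k27_primed = sample(c(TRUE, FALSE), n, replace = TRUE)
  )
}

diff_fixture <- function(genes, seed = 22) {
  set.seed(seed)
  tibble::tibble(
    feature = genes,
    log2fc = rnorm(length(genes), sd = 1.5),
    padj = runif(length(genes))
  )
}

test_that("promoter positivity is called against the genome median", {
  quant <- tibble::tibble(
    region_id = c("at_median", "tenfold", "below"),
    mean_rpgc = c(1, 10, 0.4)
  )
  out <- call_k4_positive(quant, genome_median = 1, min_fold = 2)
  expect_equal(out$positive, c(FALSE, TRUE, FALSE))
  expect_error(
    call_k4_positive(quant, genome_median = 0),
    "degenerate",
    class = "quantchip_config_error"
  )
})

test_that("classification follows the five-class decision rules", {
  flags <- tibble::tibble(
    gene_id = c("naive_up", "k4_neg", "common", "k4_only", "primed_up"),
    k4_naive = c(TRUE, FALSE, TRUE, TRUE, TRUE),
    k4_primed = c(TRUE, FALSE, TRUE, TRUE, TRUE),
    k27_naive = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    k27_primed = c(FALSE, TRUE, TRUE, FALSE, TRUE)
  )
  diff <- tibble::tibble(
    feature = flags$gene_id,
    log2fc = c(1.2, 1.2, 0.1, 0.1, -1.2), # naive over primed
    padj = c(0.01, 0.01, 0.6, 0.6, 0.01)
  )
  out <- classify_promoters(flags, diff)
  expect_equal(
    out$class,
    c("naive_bivalent", "k4_negative", "common_bivalent", "k4_only", "primed_bivalent")
  )
})

test_that("classes partition every promoter exactly once", {
  flags <- flags_fixture()
  diff <- diff_fixture(flags$gene_id)
  out <- classify_promoters(flags, diff)
  expect_equal(nrow(out), nrow(flags))
  expect_true(all(out$class %in% quantchip:::PROMOTER_CLASSES))
  expect_equal(sum(table(out$class)), nrow(flags))
})

test_that("swapping the naive and primed labels swaps the state-specific classes", {
  flags <- flags_fixture(n = 60, seed = 31)
  diff <- diff_fixture(flags$gene_id, seed = 32)
  fwd <- classify_promoters(flags, diff)
  swapped_flags <- flags |>
    dplyr::rename(
      k4_naive = k4_primed, k4_primed = k4_naive,
      k27_naive = k27_primed, k27_primed = k27_naive
    )
  swapped_diff <- diff |> dplyr::mutate(log2fc = -log2fc)
  rev <- classify_promoters(swapped_flags, swapped_diff)
  fc <- table(factor(fwd$class, quantchip:::PROMOTER_CLASSES))
  rc <- table(factor(rev$class, quantchip:::PROMOTER_CLASSES))
  expect_equal(fc[["naive_bivalent"]], rc[["primed_bivalent"]])
  expect_equal(fc[["primed_bivalent"]], rc[["naive_bivalent"]])
  expect_equal(fc[["common_bivalent"]], rc[["common_bivalent"]])
  expect_equal(fc[["k4_only"]], rc[["k4_only"]])
  expect_equal(fc[["k4_negative"]], rc[["k4_negative"]])
})

test_that("promoters without a differential row are omitted with a warning", {
  flags <- flags_fixture(n = 5)
  diff <- diff_fixture(flags$gene_id[1:4])
  expect_warning(out <- classify_promoters(flags, diff), "omitted")
  expect_equal(nrow(out), 4)
})

test_that("the switch table cross-tabulates mark gains and losses", {
  genes <- c("stable1", "stable2", "klf4_like", "k27_up")
  k4 <- tibble::tibble(
    feature = genes, log2fc = c(0, 0.1, 2, 0), padj = c(0.9, 0.8, 0.001, 0.9)
  )
  k27 <- tibble::tibble(
    feature = genes, log2fc = c(0.1, 0, -2.5, 1.8), padj = c(0.7, 0.9, 0.001, 0.001)
  )
  st <- class_switch_table(k4, k27)
  expect_equal(sum(st$counts$n), length(genes))
  klf4_cell <- st$per_gene[st$per_gene$feature == "klf4_like", ]
  expect_equal(klf4_cell$k4_status, "up")
  expect_equal(klf4_cell$k27_status, "down")

  all_stable <- class_switch_table(
    dplyr::mutate(k4, padj = 1), dplyr::mutate(k27, padj = 1)
  )
  expect_equal(nrow(all_stable$counts), 1)
  expect_equal(all_stable$counts$n, length(genes))
  expect_equal(all_stable$counts$k4_status, "stable")
})

test_that("derepression analysis gates, stratifies and counts K27-marked promoters", {
  genes <- sprintf("g%02d", 1:20)
  rna <- tibble::tibble(
    feature = genes,
    log2fc = c(rep(2, 5), rep(0, 12), rep(-2, 3)),
    padj = c(rep(0.001, 5), rep(0.8, 12), rep(0.001, 3))
  )
  classes <- tibble::tibble(
    gene_id = genes,
    class = rep(c("naive_bivalent", "k4_only", "common_bivalent", "k4_negative"), 5)
  )
  k27 <- tibble::tibble(gene_id = genes, k27_pos = rep(c(TRUE, FALSE), 10))
  out <- suppressWarnings(derepression_analysis(rna, classes, k27, fc_threshold = 2))
  expect_equal(out$n_up, 5)
  expect_equal(out$n_down, 3)
  expect_setequal(out$derepressed, genes[1:5])
  expect_equal(out$frac_k27_positive, mean(k27$k27_pos[1:5]))
  expect_true(all(out$class_response$class %in% unique(classes$class)))
})

test_that("H2Aub change at derepressed genes summarizes per-stratum folds", {
  genes <- sprintf("g%02d", 1:12)
  strata <- tibble::tibble(
    gene_id = genes, stratum = rep(c("bivalent", "k27_devoid"), each = 6)
  )
  # all fold changes exactly 1: zero median loss
  flat <- tibble::tibble(feature = genes, log2fc = 0)
  out <- h2aub_change_at_derepressed(flat, genes, strata)
  expect_equal(out$median_loss_pct, c(0, 0))

  # known 15% loss in one stratum
  diff <- tibble::tibble(
    feature = genes,
    log2fc = c(rep(log2(0.85), 6), rep(0, 6))
  )
  out2 <- h2aub_change_at_derepressed(diff, genes, strata)
  expect_equal(out2$median_fold[out2$stratum == "bivalent"], 0.85)
  expect_equal(out2$median_loss_pct[out2$stratum == "bivalent"], 15)

  # medians and quartiles match the quantile oracle
  set.seed(44)
  rnd <- tibble::tibble(feature = genes, log2fc = rnorm(12))
  out3 <- h2aub_change_at_derepressed(rnd, genes, strata)
  for (s in unique(strata$stratum)) {
    vals <- rnd$log2fc[match(strata$gene_id[strata$stratum == s], rnd$feature)]
    expect_equal(
      out3$median_fold[out3$stratum == s], 2^median(vals)
    )
    expect_equal(
      out3$q25_fold[out3$stratum == s], 2^unname(quantile(vals, 0.25))
    )
  }

  expect_warning(
    h2aub_change_at_derepressed(diff, genes[1:6], strata),
    "omitted"
  )
  expect_error(
    h2aub_change_at_derepressed(diff, character(0), strata),
    class = "quantchip_data_error"
  )
})
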