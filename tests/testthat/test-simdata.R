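test_that("invalid configurations are rejected with the offending field named", {
  expect_error(sim_config(dup_rate = 1.5), "dup_rate", class = "quantchip_config_error")
  expect_error(sim_config(replicates = 1), "replicates", class = "quantchip_config_error")
  expect_error(sim_config(x_boost = -1), "x_boost", class = "quantchip_config_error")
  expect_error(
    sim_config(expr_dispersion_range = c(-0.1, 0.1)),
    "expr_dispersion_range",
    class = "quantchip_config_error"
  )
  expect_error(sim_config(x_chrom = "chr9"), "x_chrom", class = "quantchip_config_error")
  expect_error(
    sim_config(k27_promoter_rpgc = 50) |> simulate_landscape(),
    "k27_promoter_rpgc",
    class = "quantchip_config_error"
  )
})

test_that("density profiles have genome-wide mean one and carry no global level", {
  model <- simulate_landscape(small_sim_config())
  for (mark in names(model$density)) {
    for (cond in names(model$density[[mark]])) {
      prof <- model$density[[mark]][[cond]]
      mu <- quantchip:::profile_mean(prof, model$chrom_sizes, names(model$chrom_sizes))
      expect_equal(mu, 1, tolerance = 1e-9)
      expect_true(all(unlist(prof) >= 0))
    }
  }
})

test_that("X boost controls the naive H3K27me3 X-to-autosome density ratio", {
  sizes <- function(model) names(model$chrom_sizes)
  ratio <- function(model) {
    prof <- model$density$H3K27me3$naive_untreated
    auto <- setdiff(sizes(model), model$x_chrom)
    quantchip:::profile_mean(prof, model$chrom_sizes, model$x_chrom) /
      quantchip:::profile_mean(prof, model$chrom_sizes, auto)
  }
  flat <- simulate_landscape(small_sim_config(x_boost = 1))
  expect_equal(ratio(flat), 1, tolerance = 0.02)
  boosted <- simulate_landscape(small_sim_config(x_boost = 2))
  expect_equal(ratio(boosted), 2, tolerance = 0.02)
})

test_that("EZH2i residual sets the true global-factor ratio exactly", {
  model <- simulate_landscape(small_sim_config(ezh2i_residual = 0.03))
  g <- model$global_factor$H3K27me3
  expect_equal(g[["naive_ezh2i"]] / g[["naive_untreated"]], 0.03, tolerance = 1e-12)
  expect_equal(g[["primed_ezh2i"]] / g[["primed_untreated"]], 0.03, tolerance = 1e-12)
})

test_that("landscape and pools are bit-identical under a fixed seed", {
  cfg <- small_sim_config(seed = 9)
  expect_identical(simulate_landscape(cfg), simulate_landscape(cfg))
  model <- simulate_landscape(cfg)
  p1 <- simulate_pool(model, cfg)
  p2 <- simulate_pool(model, cfg)
  expect_identical(p1$pools, p2$pools)
  expect_identical(p1$truth, p2$truth)
  expect_identical(
    simulate_expression(model, cfg)$counts,
    simulate_expression(model, cfg)$counts
  )
})

test_that("promoter truth is balanced over exactly the five classes", {
  model <- simulate_landscape(small_sim_config())
  counts <- table(model$promoter_truth)
  expect_setequal(names(counts), quantchip:::PROMOTER_CLASSES)
  expect_true(all(counts == 20)) # 100 promoters, 5 classes
})

test_that("clean tags give zero duplicates and exact design barcodes", {
  cfg <- small_sim_config(dup_rate = 0, tag_error_rate = 0, marks = "H3K27me3")
  model <- simulate_landscape(cfg)
  out <- simulate_pool(model, cfg)
  expect_false(any(out$truth$is_duplicate))
  for (pool in names(out$pools)) {
    expect_true(all(out$pools[[pool]]$barcode_obs %in% out$layout$barcodes$barcode))
  }
})

test_that("duplicate fraction matches the configured rate within binomial error", {
  cfg <- small_sim_config(depth = 10000, dup_rate = 0.2, marks = "H3K27me3")
  model <- simulate_landscape(cfg)
  out <- simulate_pool(model, cfg)
  n <- nrow(out$truth)
  frac <- mean(out$truth$is_duplicate)
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / n))
})

test_that("truth table accounts for every emitted read exactly once", {
  cfg <- small_sim_config(marks = "H3K27me3")
  model <- simulate_landscape(cfg)
  out <- simulate_pool(model, cfg)
  all_ids <- unlist(lapply(out$pools, function(p) p$read_id), use.names = FALSE)
  expect_equal(sort(all_ids), sort(out$truth$read_id))
  expect_false(anyDuplicated(out$truth$read_id) > 0)
})

test_that("expression counts respond to class-linked effects as configured", {
  # no effects: condition means agree within Monte Carlo error
  cfg0 <- sim_config(
    seed = 5, depth = 1000, n_promoters = 500,
    repression_log2 = 0, derepression_log2 = 0,
    expr_dispersion_range = c(0.01, 0.02)
  )
  model0 <- simulate_landscape(cfg0)
  ex0 <- simulate_expression(model0, cfg0)
  m <- as.matrix(ex0$counts[, -1])
  cond <- ex0$design$condition[match(colnames(m), ex0$design$sample)]
  cm <- sapply(split(seq_len(ncol(m)), cond), function(j) rowMeans(m[, j]))
  # aggregate over genes: the mean condition/overall ratio stays near 1
  ratios <- colMeans(cm / rowMeans(cm))
  expect_true(all(abs(ratios - 1) < 0.02))

  # +1 log2 derepression: naive-bivalent genes double upon treatment
  cfg1 <- sim_config(
    seed = 6, depth = 1000, n_promoters = 500,
    repression_log2 = 1, derepression_log2 = 1
  )
  model1 <- simulate_landscape(cfg1)
  ex1 <- simulate_expression(model1, cfg1)
  nb <- names(model1$promoter_truth)[model1$promoter_truth == "naive_bivalent"]
  m1 <- as.matrix(ex1$counts[, -1])
  rownames(m1) <- ex1$counts$gene_id
  des <- ex1$design
  mean_of <- function(cond) {
    rowMeans(m1[nb, des$sample[des$condition == cond], drop = FALSE])
  }
  ratio <- mean(mean_of("naive_ezh2i") / mean_of("naive_untreated"))
  expect_equal(ratio, 2, tolerance = 0.1)

  expect_error(
    simulate_expression(model1, sim_config(expr_dispersion_range = c(0, 0.1))),
    class = "quantchip_config_error"
  )
})
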