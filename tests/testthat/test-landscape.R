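test_that("genome bins tile each chromosome with a truncated last bin", {
  bins <- make_bins(c(chrA = 25000L), width = 10000L)
  expect_equal(bins$start, c(0L, 10000L, 20000L))
  expect_equal(bins$end, c(10000L, 20000L, 25000L))
  sizes <- c(chr1 = 500000L, chr2 = 123456L)
  all_bins <- make_bins(sizes)
  expect_equal(sum(all_bins$end - all_bins$start), sum(sizes))
  expect_error(make_bins(sizes, width = 0), class = "quantchip_config_error")
})

test_that("promoter windows are strand-aware and clipped at chromosome edges", {
  tss <- tibble::tibble(
    chrom = "chr1", pos = c(5000L, 5000L, 300L),
    strand = c("+", "-", "+"), gene_id = c("g1", "g2", "g3")
  )
  w <- promoter_windows(tss, flank_up = 1000, flank_down = 1000)
  expect_equal(w$start[1], 4000L)
  expect_equal(w$end[1], 6000L)
  asym <- promoter_windows(tss[2, ], flank_up = 1000, flank_down = 500)
  expect_equal(c(asym$start, asym$end), c(4500L, 6000L))
  clipped <- promoter_windows(tss[3, ], flank_up = 1000, flank_down = 1000)
  expect_equal(c(clipped$start, clipped$end), c(0L, 1300L))
})

test_that("region summaries equal the per-base brute-force average", {
  set.seed(33)
  sizes <- c(chr1 = 2000L, chr2 = 1500L)
  tr <- structure(
    list(
      coverage = list(chr1 = runif(40), chr2 = runif(30)),
      resolution = 50L, chrom_sizes = sizes, factor = 1,
      fragment_length = 150L, n_reads = NA_integer_, sample_id = "r"
    ),
    class = "scaled_track"
  )
  # uniform track: every region mean equals the constant
  flat <- tr
  flat$coverage <- list(chr1 = rep(2.5, 40), chr2 = rep(2.5, 30))
  regs <- tibble::tibble(
    chrom = c("chr1", "chr2"), start = c(13L, 0L), end = c(987L, 1500L)
  )
  expect_equal(summarize_regions(flat, regs)$mean_rpgc, c(2.5, 2.5))

  # whole-genome region recovers the global mean
  whole <- tibble::tibble(chrom = names(sizes), start = 0L, end = unname(sizes))
  got <- summarize_regions(tr, whole)
  expect_equal(
    sum(got$mean_rpgc * got$width) / sum(got$width), track_mean(tr)
  )

  # 50 random regions vs 1 bp brute force
  rand <- tibble::tibble(
    chrom = sample(names(sizes), 50, replace = TRUE)
  ) |>
    dplyr::mutate(
      start = vapply(chrom, function(ch) sample.int(sizes[[ch]] - 10L, 1), 1L),
      end = pmin(start + sample.int(400L, 50), sizes[chrom])
    )
  got <- summarize_regions(tr, rand)
  want <- vapply(seq_len(50), function(i) {
    oracle_region_mean(tr, rand$chrom[i], rand$start[i], rand$end[i])
  }, numeric(1))
  expect_equal(got$mean_rpgc, want)

  expect_error(
    summarize_regions(tr, tibble::tibble(chrom = "chr1", start = 0L, end = 99999L)),
    class = "quantchip_data_error"
  )
})

test_that("region aggregation is linear in the track", {
  set.seed(12)
  sizes <- c(chr1 = 1000L)
  mk <- function(v) {
    structure(
      list(
        coverage = list(chr1 = v), resolution = 50L, chrom_sizes = sizes,
        factor = 1, fragment_length = 150L, n_reads = NA_integer_,
        sample_id = "x"
      ),
      class = "scaled_track"
    )
  }
  v1 <- runif(20)
  v2 <- runif(20)
  regs <- tibble::tibble(chrom = "chr1", start = c(10L, 400L), end = c(390L, 950L))
  s_comb <- summarize_regions(mk(3 * v1 + 2 * v2), regs)$mean_rpgc
  s_parts <- 3 * summarize_regions(mk(v1), regs)$mean_rpgc +
    2 * summarize_regions(mk(v2), regs)$mean_rpgc
  expect_equal(s_comb, s_parts)
})

test_that("chromosome statistics normalize shares and recover concentration", {
  sizes <- c(chr1 = 1000L, chr2 = 500L, chrX = 500L)
  mk <- function(c1, c2, cx) {
    structure(
      list(
        coverage = list(chr1 = rep(c1, 20), chr2 = rep(c2, 10), chrX = rep(cx, 10)),
        resolution = 50L, chrom_sizes = sizes, factor = 1,
        fragment_length = 150L, n_reads = NA_integer_, sample_id = "x"
      ),
      class = "scaled_track"
    )
  }
  one <- chromosome_stats(mk(4, 0, 0), "chrX")
  expect_equal(one$table$share[one$table$chrom == "chr1"], 1)
  expect_equal(sum(one$table$share), 1)

  unif <- chromosome_stats(mk(2, 2, 2), "chrX")
  expect_true(all(abs(unif$table$mean_rpgc - 2) < 1e-12))
  expect_equal(unif$table$share, unname(sizes / sum(sizes)))
  expect_equal(unif$x_over_autosome_density, 1)

  boosted <- chromosome_stats(mk(1, 1, 3), "chrX")
  expect_equal(boosted$x_over_autosome_density, 3)
  expect_error(chromosome_stats(mk(1, 1, 1), "chrZ"), class = "quantchip_config_error")
})

test_that("per-chromosome fold-change medians match the sort-based oracle", {
  tss <- tibble::tibble(
    chrom = rep(c("chr1", "chr2", "chr3"), each = 3),
    pos = 1L, strand = "+", gene_id = paste0("g", 1:9)
  )
  diff0 <- tibble::tibble(feature = paste0("g", 1:9), log2fc = 0)
  out0 <- per_chromosome_fc_summary(diff0, tss)
  expect_true(all(out0$median_log2fc == 0))

  diff1 <- tibble::tibble(feature = paste0("g", 1:3), log2fc = c(-1, 0, 2))
  out1 <- suppressWarnings(per_chromosome_fc_summary(diff1, tss))
  expect_equal(out1$median_log2fc[out1$chrom == "chr1"], 0)
  expect_warning(per_chromosome_fc_summary(diff1, tss), "omitted")

  set.seed(50)
  diff2 <- tibble::tibble(feature = paste0("g", 1:9), log2fc = rnorm(9))
  out2 <- per_chromosome_fc_summary(diff2, tss)
  for (ch in out2$chrom) {
    vals <- diff2$log2fc[match(tss$gene_id[tss$chrom == ch], diff2$feature)]
    expect_equal(
      out2$median_log2fc[out2$chrom == ch],
      sort(vals)[(length(vals) + 1) / 2]
    )
  }
})
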