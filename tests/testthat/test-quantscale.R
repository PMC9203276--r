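toy_track <- function(values, chrom_sizes = c(chr1 = 500L), resolution = 50L,
                      factor = 1) {
  # build a track directly from per-bin values for oracle-style tests
  structure(
    list(
      coverage = values, resolution = resolution, chrom_sizes = chrom_sizes,
      factor = factor, fragment_length = 150L,
      n_reads = NA_integer_, sample_id = "toy"
    ),
    class = "scaled_track"
  )
}

test_that("INRC is the ratio of unique ChIP to input reads", {
  expect_equal(compute_inrc(1000, 1000), 1.0)
  expect_equal(compute_inrc(2000, 500), 4.0)
  expect_error(compute_inrc(100, 0, sample = "s1"), "s1", class = "quantchip_data_error")
})

test_that("INRC over simulated samples equals element-wise division of counts", {
  cfg <- small_sim_config(marks = "H3K27me3")
  model <- simulate_landscape(cfg)
  out <- simulate_pool(model, cfg)
  chip <- mark_duplicates(demultiplex(out$pools$H3K27me3, out$layout))
  input <- mark_duplicates(demultiplex(out$pools$input, out$layout))
  tbl <- inrc_table(chip$stats, input$stats, mark = "H3K27me3")
  expect_equal(nrow(tbl), 12)
  by_hand <- chip$stats$unique_molecules[match(tbl$sample_id, chip$stats$sample_id)] /
    input$stats$unique_molecules[match(tbl$sample_id, input$stats$sample_id)]
  expect_equal(tbl$inrc, by_hand)
})

test_that("scale factors preserve INRC ratios and anchor the pooled reference at 1", {
  tbl <- tibble::tibble(
    sample_id = c("ref_rep1", "ref_rep2", "s_rep1", "s_rep2"),
    condition = c("ref", "ref", "s", "s"),
    chip_unique = c(1000, 1000, 2000, 2000),
    input_unique = c(1250, 1250, 1250, 1250)
  )
  tbl$inrc <- compute_inrc(tbl$chip_unique, tbl$input_unique)
  sf <- compute_scale_factors(tbl, "ref", genome_size = 2e6)
  expect_equal(sf$table$global_level[sf$table$condition == "s"], c(2, 2))
  expect_equal(sf$table$global_level[sf$table$condition == "ref"], c(1, 1))
  expect_equal(sf$reference_inrc, 0.8)
  expect_error(
    compute_scale_factors(tbl, "missing", 2e6),
    class = "quantchip_config_error"
  )
})

test_that("the reference track has mean RPGC one and conserves mass", {
  cfg <- small_sim_config(marks = "H3K27me3")
  model <- simulate_landscape(cfg)
  out <- simulate_pool(model, cfg)
  chip <- mark_duplicates(demultiplex(out$pools$H3K27me3, out$layout))
  input <- mark_duplicates(demultiplex(out$pools$input, out$layout))
  tbl <- inrc_table(chip$stats, input$stats)
  # pooled reference: combine the three naive_untreated replicates
  pooled <- tbl |>
    dplyr::group_by(condition) |>
    dplyr::summarise(
      chip_unique = sum(chip_unique), input_unique = sum(input_unique),
      .groups = "drop"
    ) |>
    dplyr::mutate(sample_id = condition, inrc = chip_unique / input_unique)
  sf <- compute_scale_factors(pooled, "naive_untreated", sum(model$chrom_sizes))
  ref_row <- sf$table[sf$table$condition == "naive_untreated", ]
  reads <- chip$reads |>
    dplyr::filter(!is_duplicate, startsWith(sample_id, "naive_untreated"))
  track <- build_scaled_track(reads, model$chrom_sizes, ref_row$factor)
  expect_equal(track_mean(track), 1, tolerance = 1e-6)
  # conservation: integral equals factor * reads * fragment length
  integral <- sum(sapply(names(track$coverage), function(ch) {
    sum(track$coverage[[ch]] * quantchip:::bin_widths_for(track, ch))
  }))
  expect_equal(integral, ref_row$factor * nrow(reads) * 150, tolerance = 1e-6)
})

test_that("tracks are linear in read counts at fixed factors", {
  reads <- tibble::tibble(
    chrom = "chr1", pos = c(10L, 120L, 301L), strand = c("+", "-", "+")
  )
  sizes <- c(chr1 = 1000L)
  t1 <- build_scaled_track(reads, sizes, factor = 2)
  t2 <- build_scaled_track(dplyr::bind_rows(reads, reads), sizes, factor = 2)
  expect_equal(t2$coverage$chr1, 2 * t1$coverage$chr1)
})

test_that("out-of-bounds reads raise a data error", {
  sizes <- c(chr1 = 1000L)
  expect_error(
    build_scaled_track(
      tibble::tibble(chrom = "chr1", pos = 1000L, strand = "+"), sizes, 1
    ),
    class = "quantchip_data_error"
  )
  expect_error(
    build_scaled_track(
      tibble::tibble(chrom = "chr9", pos = 10L, strand = "+"), sizes, 1
    ),
    class = "quantchip_data_error"
  )
})

test_that("global levels are invariant to uniform count rescaling", {
  tbl <- tibble::tibble(
    sample_id = paste0("c", 1:4, "_rep1"),
    condition = paste0("c", 1:4),
    chip_unique = c(500, 1500, 800, 2400),
    input_unique = c(1000, 1000, 900, 1100)
  )
  tbl$inrc <- compute_inrc(tbl$chip_unique, tbl$input_unique)
  sf1 <- compute_scale_factors(tbl, "c1", 1e6)
  tbl2 <- tbl |>
    dplyr::mutate(
      chip_unique = chip_unique * 7, input_unique = input_unique * 7,
      inrc = chip_unique / input_unique
    )
  sf2 <- compute_scale_factors(tbl2, "c1", 1e6)
  expect_equal(sf1$table$global_level, sf2$table$global_level)
})

test_that("track median is the width-weighted median of bin values", {
  tr <- toy_track(list(chr1 = c(1, 1, 1, 5, 5, 5, 5, 9, 9, 2)))
  v <- rep(c(1, 1, 1, 5, 5, 5, 5, 9, 9, 2), each = 50)
  expect_equal(track_median(tr), median(v))
})

test_that("bedGraph round-trips through write and read", {
  tr <- toy_track(list(chr1 = c(0.5, 1.25, 0, 3)), chrom_sizes = c(chr1 = 200L))
  path <- tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, path)
  back <- read_bedgraph(path)
  expect_equal(back$score, c(0.5, 1.25, 0, 3))
  expect_equal(back$start, c(0L, 50L, 100L, 150L))
  expect_equal(back$end, c(50L, 100L, 150L, 200L))
})
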