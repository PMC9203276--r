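#' Tile a genome into fixed-width bins
#'
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @param width Bin width in bp (default 10000, the resolution used for
#'   genome-wide differential-bin analyses).
#' @return Tibble region set: `chrom`, `start`, `end` (0-based half-open),
#'   `region_id`; the last bin of each chromosome is truncated at the
#'   chromosome end.
#' @examples
#' make_bins(c(chr1 = 25000), width = 10000)
#' @export
make_bins <- function(chrom_sizes, width = 10000L) {
  if (width <= 0) abort_config("bin width must be positive")
  purrr::map_dfr(names(chrom_sizes), function(ch) {
    starts <- seq(0L, chrom_sizes[[ch]] - 1L, by = width)
    tibble(
      chrom = ch, start = starts,
      end = pmin(starts + as.integer(width), chrom_sizes[[ch]])
    )
  }) |>
    mutate(region_id = sprintf("%s:%d-%d", .data$chrom, .data$start, .data$end))
}

#' Strand-aware promoter windows around TSSs
#'
#' @param tss Tibble with `chrom`, `pos`, `strand`, `gene_id`.
#' @param flank_up,flank_down Window extent upstream/downstream of the TSS
#'   in bp (default 1000 each, a conventional bivalency window).
#' @param chrom_sizes Optional named vector; when given, windows are clipped
#'   to chromosome bounds.
#' @return Tibble region set: `chrom`, `start`, `end`, `region_id`
#'   (= gene_id), `strand`. On the + strand the window is
#'   `[pos - flank_up, pos + flank_down)`; mirrored on the - strand.
#' @export
promoter_windows <- function(tss, flank_up = 1000L, flank_down = 1000L,
                             chrom_sizes = NULL) {
  if (flank_up < 0 || flank_down < 0) abort_config("flanks must be >= 0")
  out <- as_tibble(tss) |>
    mutate(
      start = ifelse(.data$strand == "+", .data$pos - flank_up, .data$pos - flank_down),
      end = ifelse(.data$strand == "+", .data$pos + flank_down, .data$pos + flank_up),
      start = pmax(0L, as.integer(.data$start)),
      region_id = .data$gene_id
    ) |>
    select("chrom", "start", "end", "region_id", "strand")
  if (!is.null(chrom_sizes)) {
    out <- mutate(out, end = pmin(.data$end, chrom_sizes[.data$chrom]))
  }
  out
}

#' Length-weighted mean RPGC over a region set
#'
#' Treats the track as piecewise constant over its bins and averages it over
#' each region, weighting partially overlapped bins by the overlap length.
#'
#' @param track A [build_scaled_track()] result.
#' @param regions Region tibble (`chrom`, `start`, `end`, optional
#'   `region_id`), 0-based half-open.
#' @return Tibble: `region_id`, `chrom`, `start`, `end`, `width`,
#'   `mean_rpgc`.
#' @export
summarize_regions <- function(track, regions) {
  regions <- as_tibble(regions)
  if (!"region_id" %in% names(regions)) {
    regions$region_id <- sprintf("%s:%d-%d", regions$chrom, regions$start, regions$end)
  }
  bad <- !(regions$chrom %in% names(track$chrom_sizes)) |
    regions$start < 0 | regions$end > track$chrom_sizes[regions$chrom] |
    regions$start >= regions$end
  if (any(bad)) {
    abort_data(paste(
      "regions outside chromosome bounds or empty:",
      paste(utils::head(regions$region_id[bad], 5), collapse = ", ")
    ))
  }
  res <- track$resolution
  mean_rpgc <- numeric(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    v <- track$coverage[[regions$chrom[i]]]
    s <- regions$start[i]
    e <- regions$end[i]
    b0 <- s %/% res + 1L
    b1 <- (e - 1L) %/% res + 1L
    idx <- b0:b1
    # overlap of the region with each touched bin
    bin_start <- (idx - 1L) * res
    bin_end <- pmin(bin_start + res, track$chrom_sizes[[regions$chrom[i]]])
    ov <- pmin(bin_end, e) - pmax(bin_start, s)
    mean_rpgc[i] <- sum(v[idx] * ov) / (e - s)
  }
  regions |>
    mutate(width = .data$end - .data$start, mean_rpgc = mean_rpgc) |>
    select("region_id", "chrom", "start", "end", "width", "mean_rpgc")
}

#' Per-chromosome signal summary with X-to-autosome ratios
#'
#' @param track A [build_scaled_track()] result.
#' @param x_chrom Name of the X chromosome.
#' @return List of class `chrom_summary`: `table` (tibble: chrom, length,
#'   mean_rpgc, integrated = mean x length, share of genome total),
#'   `x_over_autosome_density` (X density over the length-weighted autosomal
#'   mean density) and `x_share` (fraction of the total signal on X). Shares
#'   sum to one.
#' @export
chromosome_stats <- function(track, x_chrom) {
  if (!x_chrom %in% names(track$chrom_sizes)) {
    abort_config(sprintf("unknown chromosome '%s'", x_chrom))
  }
  tbl <- purrr::map_dfr(names(track$coverage), function(ch) {
    w <- bin_widths_for(track, ch)
    tibble(
      chrom = ch, length = unname(track$chrom_sizes[[ch]]),
      mean_rpgc = sum(track$coverage[[ch]] * w) / track$chrom_sizes[[ch]]
    )
  }) |>
    mutate(
      integrated = .data$mean_rpgc * .data$length,
      share = .data$integrated / sum(.data$integrated)
    )
  auto <- filter(tbl, .data$chrom != x_chrom)
  auto_density <- sum(auto$integrated) / sum(auto$length)
  x_density <- tbl$mean_rpgc[tbl$chrom == x_chrom]
  structure(
    list(
      table = tbl,
      x_over_autosome_density = x_density / auto_density,
      x_share = tbl$share[tbl$chrom == x_chrom]
    ),
    class = "chrom_summary"
  )
}

#' Median log2 fold change by chromosome
#'
#' @param diff Differential-result tibble keyed by gene (`feature`,
#'   `log2fc`).
#' @param tss Tibble mapping genes to chromosomes (`gene_id`, `chrom`).
#' @return Tibble: `chrom`, `n_genes`, `median_log2fc` (finite values only).
#'   Chromosomes without mappable genes are omitted with a warning.
#' @export
per_chromosome_fc_summary <- function(diff, tss) {
  joined <- as_tibble(diff) |>
    inner_join(select(as_tibble(tss), "gene_id", "chrom"),
      by = c(feature = "gene_id")
    )
  empty <- setdiff(unique(tss$chrom), unique(joined$chrom))
  if (length(empty) > 0) {
    warn(paste("chromosomes without genes omitted:", paste(empty, collapse = ", ")))
  }
  joined |>
    filter(is.finite(.data$log2fc)) |>
    group_by(.data$chrom) |>
    summarise(
      n_genes = dplyr::n(),
      median_log2fc = median(.data$log2fc),
      .groups = "drop"
    )
}
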