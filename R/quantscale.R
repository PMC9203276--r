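#' Input-normalized read count (INRC)
#'
#' The quantitative anchor of multiplexed ChIP: the number of unique mapped
#' ChIP reads divided by the number of unique mapped input reads carrying the
#' same barcode. Because ChIP and input share the pool, this cancels uneven
#' barcode representation and is proportional to the amount of epitope.
#'
#' @param chip_unique Unique ChIP read count(s).
#' @param input_unique Matched unique input read count(s).
#' @param sample Optional sample label(s) used in error messages.
#' @return `chip_unique / input_unique` (vectorized).
#' @examples
#' compute_inrc(2000, 500)
#' @export
compute_inrc <- function(chip_unique, input_unique, sample = NULL) {
  bad <- which(!is.finite(input_unique) | input_unique <= 0)
  if (length(bad) > 0) {
    lab <- if (!is.null(sample)) paste(sample[bad], collapse = ", ") else paste(bad, collapse = ", ")
    abort_data(sprintf("non-positive input read count for sample(s): %s", lab))
  }
  chip_unique / input_unique
}

#' Assemble an INRC table from ChIP and input dedup statistics
#'
#' Joins per-sample unique read counts of a ChIP pool with its matched input
#' pool by sample id and computes the INRC.
#'
#' @param chip_stats,input_stats Per-sample stats tibbles from
#'   [mark_duplicates()] (columns `sample_id`, `unique_molecules`), for the
#'   ChIP and the input pool.
#' @param mark Mark label recorded in the output.
#' @return Tibble: mark, sample_id, condition, replicate, chip_unique,
#'   input_unique, inrc. Condition/replicate are parsed from sample ids of
#'   the form `<condition>_rep<k>` when possible.
#' @export
inrc_table <- function(chip_stats, input_stats, mark = "ChIP") {
  tbl <- chip_stats |>
    select(sample_id = "sample_id", chip_unique = "unique_molecules") |>
    inner_join(
      select(input_stats, sample_id = "sample_id", input_unique = "unique_molecules"),
      by = "sample_id"
    )
  tbl |>
    mutate(
      mark = mark,
      condition = sub("_rep[0-9]+$", "", .data$sample_id),
      replicate = suppressWarnings(as.integer(sub("^.*_rep", "", .data$sample_id))),
      inrc = compute_inrc(.data$chip_unique, .data$input_unique, .data$sample_id)
    ) |>
    select("mark", "sample_id", "condition", "replicate", "chip_unique", "input_unique", "inrc")
}

#' Reference-anchored global scale factors
#'
#' Scales every sample relative to a reference condition: the reference
#' (pooled over replicates) is scaled to a mean reads-per-genome-coverage of
#' exactly 1 (1x RPGC), and each sample's global level is its INRC divided by
#' the pooled reference INRC. A sample's track factor is chosen so that its
#' genome-wide mean RPGC equals its global level (`factor = genome_size *
#' global_level / (unique_reads * fragment_length)`), preserving the INRC
#' ratios exactly.
#'
#' @param table INRC tibble from [inrc_table()] (columns `sample_id`,
#'   `condition`, `chip_unique`, `input_unique`, `inrc`).
#' @param reference Name of the reference condition (pooled replicates).
#' @param genome_size Genome size in bp (use 3095978588 for hg38; for
#'   synthetic genomes the sum of chromosome lengths).
#' @param fragment_length Fragment extension length in bp (default 150).
#' @return Object of class `scale_factors`: list with `table` (input plus
#'   `global_level` and `factor` columns), `reference`, `reference_inrc`,
#'   `genome_size`, `fragment_length`.
#' @examples
#' tbl <- tibble::tibble(
#'   sample_id = c("a_rep1", "a_rep2", "b_rep1", "b_rep2"),
#'   condition = c("a", "a", "b", "b"),
#'   chip_unique = c(800, 820, 1600, 1650),
#'   input_unique = c(1000, 1020, 1000, 1030)
#' )
#' tbl$inrc <- compute_inrc(tbl$chip_unique, tbl$input_unique)
#' sf <- compute_scale_factors(tbl, "a", genome_size = 2e6)
#' sf$table$global_level
#' @export
compute_scale_factors <- function(table, reference, genome_size,
                                  fragment_length = 150L) {
  table <- as_tibble(table)
  if (!reference %in% table$condition) {
    abort_config(sprintf("reference condition '%s' not present in the INRC table", reference))
  }
  ref <- filter(table, .data$condition == reference)
  # pooled-replicate reference INRC
  ref_inrc <- sum(ref$chip_unique) / sum(ref$input_unique)
  out <- table |>
    mutate(
      global_level = .data$inrc / ref_inrc,
      factor = genome_size * .data$global_level / (.data$chip_unique * fragment_length)
    )
  structure(
    list(
      table = out, reference = reference, reference_inrc = ref_inrc,
      genome_size = genome_size, fragment_length = as.integer(fragment_length)
    ),
    class = "scale_factors"
  )
}

#' @export
print.scale_factors <- function(x, ...) {
  cat(sprintf(
    "<scale_factors> reference '%s' (pooled INRC %.4g), genome %.4g bp, fragment %d bp\n",
    x$reference, x$reference_inrc, x$genome_size, x$fragment_length
  ))
  print(x$table)
  invisible(x)
}

#' Build a quantitatively scaled coverage track
#'
#' Extends each deduplicated read to a fixed fragment length towards 3',
#' accumulates per-basepair coverage, averages it over fixed-width bins and
#' multiplies by the sample's scale factor, yielding RPGC units. Fragments
#' that would overrun a chromosome end are shifted back to fit, so the track
#' integral is exactly `factor * reads * fragment_length`.
#'
#' @param reads Tibble of deduplicated reads for one sample (`chrom`, `pos`,
#'   `strand`; rows flagged duplicate should be removed beforehand).
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @param factor Scale factor for this sample (from
#'   [compute_scale_factors()]).
#' @param fragment_length Fragment extension in bp (default 150).
#' @param resolution Bin width in bp (default 50).
#' @param sample_id Optional label stored in the track metadata.
#' @return Object of class `scaled_track`: list with `coverage` (named list
#'   of per-chromosome numeric vectors, RPGC per bin), `resolution`,
#'   `chrom_sizes`, `factor`, `fragment_length`, `n_reads`, `sample_id`.
#' @export
build_scaled_track <- function(reads, chrom_sizes, factor,
                               fragment_length = 150L, resolution = 50L,
                               sample_id = NA_character_) {
  reads <- as_tibble(reads)
  if (nrow(reads) > 0) {
    bad <- !(reads$chrom %in% names(chrom_sizes)) |
      reads$pos < 0 | reads$pos >= chrom_sizes[reads$chrom]
    if (any(bad)) {
      abort_data(sprintf(
        "%d read(s) fall outside chromosome bounds (first: %s:%d)",
        sum(bad), reads$chrom[which(bad)[1]], reads$pos[which(bad)[1]]
      ))
    }
  }
  fl <- as.integer(fragment_length)
  coverage <- list()
  for (ch in names(chrom_sizes)) {
    len <- chrom_sizes[[ch]]
    nb <- ceiling(len / resolution)
    r <- reads[reads$chrom == ch, ]
    cov <- numeric(len)
    if (nrow(r) > 0) {
      start <- ifelse(r$strand == "+", r$pos, r$pos - fl + 1L)
      # shift fragments fully inside the chromosome to conserve mass
      start <- pmax(0L, pmin(as.integer(start), len - fl))
      ends <- start + fl
      d <- numeric(len + 1)
      tab_s <- tabulate(start + 1L, nbins = len)
      tab_e <- tabulate(ends + 1L, nbins = len + 1L)
      d[seq_len(len)] <- tab_s
      d <- d - tab_e
      cov <- cumsum(d[seq_len(len)])
    }
    # bin means (last bin may be shorter)
    full <- (nb - 1) * resolution
    m <- colMeans(matrix(cov[seq_len(full)], nrow = resolution))
    last <- mean(cov[(full + 1):len])
    coverage[[ch]] <- c(m, last) * factor
  }
  structure(
    list(
      coverage = coverage, resolution = as.integer(resolution),
      chrom_sizes = chrom_sizes, factor = factor, fragment_length = fl,
      n_reads = nrow(reads), sample_id = sample_id
    ),
    class = "scaled_track"
  )
}

#' Genome-wide mean RPGC of a track
#' @param track A [build_scaled_track()] result.
#' @return Length-weighted mean RPGC over the genome.
#' @export
track_mean <- function(track) {
  tot <- 0
  for (ch in names(track$coverage)) {
    w <- bin_widths_for(track, ch)
    tot <- tot + sum(track$coverage[[ch]] * w)
  }
  tot / sum(track$chrom_sizes)
}

#' Genome-wide median RPGC of a track
#'
#' Width-weighted median over all bins; the background level used by
#' positivity calls.
#' @param track A [build_scaled_track()] result.
#' @return Median RPGC.
#' @export
track_median <- function(track) {
  v <- unlist(track$coverage, use.names = FALSE)
  w <- unlist(purrr::map(names(track$coverage), function(ch) bin_widths_for(track, ch)),
    use.names = FALSE
  )
  o <- order(v)
  cw <- cumsum(w[o]) / sum(w)
  v[o][which(cw >= 0.5)[1]]
}

bin_widths_for <- function(track, ch) {
  nb <- length(track$coverage[[ch]])
  w <- rep(track$resolution, nb)
  w[nb] <- track$chrom_sizes[[ch]] - (nb - 1) * track$resolution
  w
}

#' @export
print.scaled_track <- function(x, ...) {
  cat(sprintf(
    "<scaled_track> %s: %d chromosomes at %d bp, %d reads, factor %.4g, mean RPGC %.4f\n",
    x$sample_id %||% "?", length(x$coverage), x$resolution, x$n_reads,
    x$factor, track_mean(x)
  ))
  invisible(x)
}

#' Tidy a scaled track into a bedGraph-shaped tibble
#'
#' @param x A `scaled_track`.
#' @param ... Unused.
#' @return Tibble with `chrom`, `start`, `end` (0-based half-open) and
#'   `score` (RPGC).
#' @method as_tibble scaled_track
#' @export
as_tibble.scaled_track <- function(x, ...) {
  purrr::map_dfr(names(x$coverage), function(ch) {
    v <- x$coverage[[ch]]
    starts <- (seq_along(v) - 1L) * x$resolution
    tibble(
      chrom = ch, start = starts,
      end = pmin(starts + x$resolution, x$chrom_sizes[[ch]]),
      score = v
    )
  })
}
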