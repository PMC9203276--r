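#' Write tagged reads as FASTQ (read 1)
#'
#' The sequence is the 14 nt tag prefix (6 nt UMI + 8 nt barcode) followed
#' by a fixed stuffer; alignment is never performed on these records, the
#' true coordinates travel in the tagged-record TSV instead.
#'
#' @param reads Tibble with `read_id`, `umi`, `barcode_obs`.
#' @param path Output file.
#' @param stuffer_length Length of the constant 3' stuffer (default 36).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, stuffer_length = 36L) {
  stuffer <- strrep("A", stuffer_length)
  seqs <- paste0(reads$umi, reads$barcode_obs, stuffer)
  qual <- strrep("I", nchar(seqs[1] %||% ""))
  lines <- as.vector(rbind(
    paste0("@", reads$read_id), seqs, "+", rep(qual, length(seqs))
  ))
  writeLines(lines, path)
  invisible(path)
}

#' Write a region set as BED (0-based half-open)
#'
#' @param regions Tibble with `chrom`, `start`, `end` and optional
#'   `region_id`/`strand`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  regions <- as_tibble(regions)
  out <- tibble(
    chrom = regions$chrom, start = regions$start, end = regions$end,
    name = if ("region_id" %in% names(regions)) regions$region_id else ".",
    score = 0L,
    strand = if ("strand" %in% names(regions)) regions$strand else "."
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read a BED file (0-based half-open)
#'
#' @param path BED file with at least chrom/start/end, optional name and
#'   strand columns.
#' @return Tibble: `chrom`, `start`, `end`, and when present `region_id`,
#'   `strand`. Malformed lines raise a data error naming the file and line.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  bad <- which(n_fields < 3)
  if (length(bad) > 0) {
    abort_data(sprintf("malformed BED record in %s at line %d", path, bad[1]))
  }
  starts <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2)))
  ends <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3)))
  bad <- which(is.na(starts) | is.na(ends) | starts < 0 | ends <= starts)
  if (length(bad) > 0) {
    abort_data(sprintf("invalid BED coordinates in %s at line %d", path, bad[1]))
  }
  out <- tibble(
    chrom = vapply(fields, `[[`, "", 1),
    start = starts, end = ends
  )
  if (all(n_fields >= 4)) out$region_id <- vapply(fields, `[[`, "", 4)
  if (all(n_fields >= 6)) out$strand <- vapply(fields, `[[`, "", 6)
  out
}

#' Write a scaled track as 4-column bedGraph
#'
#' @param track A [build_scaled_track()] result.
#' @param path Output file.
#' @param digits Decimal places written (fixed so re-runs are byte
#'   identical; default 6).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, digits = 6) {
  tbl <- as_tibble(track)
  tbl$score <- formatC(tbl$score, format = "f", digits = digits)
  readr::write_tsv(tbl, path, col_names = FALSE)
  invisible(path)
}

#' Read a 4-column bedGraph into a tibble
#'
#' @param path bedGraph file (chrom, start, end, score; 0-based half-open).
#' @return Tibble: `chrom`, `start`, `end`, `score`.
#' @export
read_bedgraph <- function(path) {
  readr::read_tsv(path,
    col_names = c("chrom", "start", "end", "score"),
    col_types = readr::cols(
      chrom = readr::col_character(), start = readr::col_integer(),
      end = readr::col_integer(), score = readr::col_double()
    ),
    progress = FALSE
  )
}

#' Read tagged reads back from FASTQ
#'
#' Parses the 6 nt UMI and 8 nt barcode from the first 14 nt of each read 1
#' sequence. Coordinates are not recovered (FASTQ carries none); the result
#' is suitable for demultiplexing statistics or joining with a
#' tagged-record TSV.
#'
#' @param path FASTQ file (read 1).
#' @param umi_length,barcode_length Tag geometry (defaults 6 and 8).
#' @return Tibble: `read_id`, `umi`, `barcode_obs`.
#' @export
read_fastq_tags <- function(path, umi_length = 6L, barcode_length = 8L) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) {
    abort_data(sprintf("truncated FASTQ file: %s", path))
  }
  ids <- lines[seq(1, length(lines), by = 4)]
  seqs <- lines[seq(2, length(lines), by = 4)]
  if (!all(startsWith(ids, "@"))) {
    abort_data(sprintf("malformed FASTQ header in %s", path))
  }
  if (any(nchar(seqs) < umi_length + barcode_length)) {
    abort_data(sprintf("reads shorter than the %d nt tag in %s", umi_length + barcode_length, path))
  }
  tibble(
    read_id = sub("^@", "", ids),
    umi = substr(seqs, 1, umi_length),
    barcode_obs = substr(seqs, umi_length + 1, umi_length + barcode_length)
  )
}
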