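#' Construct and validate a barcode layout
#'
#' A barcode layout maps 8 nt sample barcodes to sample identifiers and fixes
#' the tag geometry of read 1: a 6 nt unique molecular identifier (UMI)
#' followed by an 8 nt sample barcode (`NNNNNN` + barcode). Demultiplexing
#' tolerates up to `max_mismatch` substitutions per barcode; to guarantee that
#' every read within tolerance of some barcode is within tolerance of exactly
#' one, the barcode set must have minimum pairwise Hamming distance
#' `2 * max_mismatch + 1`.
#'
#' @param barcodes Tibble or data frame with columns `barcode` (8-mers over
#'   ACGT) and `sample_id`, or a named character vector of barcodes (names =
#'   sample ids).
#' @param umi_length UMI length in nt (default 6).
#' @param max_mismatch Maximum barcode mismatches tolerated at demultiplexing
#'   (default 1).
#' @return An object of class `barcode_layout`: a list with elements
#'   `barcodes` (tibble), `umi_length`, `barcode_length`, `max_mismatch`.
#' @examples
#' layout <- barcode_layout(c(s1 = "AAAAAAAA", s2 = "TTTTTTTT"))
#' layout$barcode_length
#' @export
barcode_layout <- function(barcodes, umi_length = 6L, max_mismatch = 1L) {
  if (is.character(barcodes)) {
    barcodes <- tibble(sample_id = names(barcodes), barcode = unname(barcodes))
  }
  barcodes <- as_tibble(barcodes)
  if (!all(c("barcode", "sample_id") %in% names(barcodes))) {
    abort_config("barcode table must have columns 'barcode' and 'sample_id'")
  }
  bc <- barcodes$barcode
  if (length(unique(nchar(bc))) != 1) {
    abort_config("all barcodes must have the same length")
  }
  if (any(grepl("[^ACGT]", bc))) {
    abort_config("barcodes must use alphabet {A,C,G,T}")
  }
  if (anyDuplicated(bc) || anyDuplicated(barcodes$sample_id)) {
    abort_config("barcodes and sample ids must be unique")
  }
  d <- hamming_pairwise(bc)
  min_d <- if (length(bc) > 1) min(d[upper.tri(d)]) else Inf
  need <- 2L * max_mismatch + 1L
  if (min_d < need) {
    abort_config(sprintf(
      "barcode set violates the distance invariant: minimum pairwise Hamming distance %d < %d (= 2*max_mismatch + 1)",
      min_d, need
    ))
  }
  structure(
    list(
      barcodes = barcodes,
      umi_length = as.integer(umi_length),
      barcode_length = nchar(bc[[1]]),
      max_mismatch = as.integer(max_mismatch)
    ),
    class = "barcode_layout"
  )
}

#' Generate a synthetic barcode set with a minimum pairwise distance
#'
#' Greedy rejection sampling of 8-mers until `n` barcodes at pairwise Hamming
#' distance `>= min_dist` are found. Deterministic for a fixed seed.
#'
#' @param n Number of barcodes.
#' @param length Barcode length in nt (default 8).
#' @param min_dist Minimum pairwise Hamming distance (default 3, which
#'   guarantees unambiguous one-mismatch demultiplexing).
#' @param seed Integer seed.
#' @return Character vector of barcodes.
#' @export
make_barcode_set <- function(n, length = 8L, min_dist = 3L, seed = 1L) {
  with_local_seed(seed, {
    accepted <- character(0)
    mats <- list()
    tries <- 0
    while (length(accepted) < n) {
      tries <- tries + 1
      if (tries > 100000) {
        abort_config("could not generate barcode set: too many rejections")
      }
      cand <- random_kmers(1, length)
      ok <- TRUE
      if (length(accepted) > 0) {
        m <- string_to_char_matrix(accepted, length)
        if (any(hamming_to_one(m, cand) < min_dist)) ok <- FALSE
      }
      if (ok) accepted <- c(accepted, cand)
    }
    accepted
  })
}
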