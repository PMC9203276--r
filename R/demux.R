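#' Demultiplex pooled reads by sample barcode
#'
#' Assigns each read to a sample when its observed barcode lies within
#' `layout$max_mismatch` substitutions (default one mismatch) of exactly one
#' design barcode; otherwise the read is left `UNASSIGNED`. Because a valid
#' layout has minimum pairwise barcode distance `2 * max_mismatch + 1`, an
#' observed barcode can never be within tolerance of two design barcodes, so
#' assignment is unambiguous by construction.
#'
#' @param reads Tibble of tagged reads with at least a `barcode_obs` column
#'   (plus typically `umi`, `chrom`, `pos`, `strand`).
#' @param layout A [barcode_layout()].
#' @return The input tibble with a `sample_id` column added (`"UNASSIGNED"`
#'   where no barcode matched), carrying a `demux_stats` attribute: a tibble
#'   of per-sample assigned counts including the unassigned tally.
#' @examples
#' layout <- barcode_layout(c(s1 = "AAAAAAAA", s2 = "TTTTTTTT"))
#' reads <- tibble::tibble(barcode_obs = c("AAAAAAAA", "AAAAAAAT", "AAAATTTT"))
#' demultiplex(reads, layout)$sample_id
#' @export
demultiplex <- function(reads, layout) {
  stopifnot(inherits(layout, "barcode_layout"))
  reads <- as_tibble(reads)
  if (!"barcode_obs" %in% names(reads)) {
    abort_data("reads must carry a 'barcode_obs' column")
  }
  bc_design <- layout$barcodes$barcode
  ids <- layout$barcodes$sample_id
  obs <- reads$barcode_obs
  if (any(nchar(obs) != layout$barcode_length)) {
    abort_data("observed barcodes inconsistent with layout barcode length")
  }
  assigned <- ids[match(obs, bc_design)]
  todo <- which(is.na(assigned))
  if (length(todo) > 0 && layout$max_mismatch > 0) {
    # operate on unique unmatched barcodes; tolerance search per design barcode
    u <- unique(obs[todo])
    m <- string_to_char_matrix(u, layout$barcode_length)
    best <- rep(NA_character_, length(u))
    n_hit <- integer(length(u))
    for (k in seq_along(bc_design)) {
      d <- hamming_to_one(m, bc_design[k])
      hit <- d <= layout$max_mismatch
      n_hit <- n_hit + hit
      best[hit] <- ids[k]
    }
    best[n_hit != 1L] <- NA_character_ # unassigned if not exactly one match
    assigned[todo] <- best[match(obs[todo], u)]
  }
  assigned[is.na(assigned)] <- "UNASSIGNED"
  reads$sample_id <- assigned
  stats <- tibble(sample_id = c(ids, "UNASSIGNED")) |>
    left_join(count(reads, .data$sample_id, name = "assigned"), by = "sample_id") |>
    mutate(assigned = tidyr::replace_na(.data$assigned, 0L))
  stopifnot(sum(stats$assigned) == nrow(reads))
  attr(reads, "demux_stats") <- stats
  reads
}

#' Mark PCR duplicates by position and UMI
#'
#' Within each (sample, chromosome, position, strand) group, reads are
#' considered copies of the same molecule when their UMIs are within
#' `umi_mismatch` substitutions of each other; molecules are the connected
#' components of the resulting UMI graph. One representative read per
#' component is retained (the most frequent UMI, ties broken by lexicographic
#' order, first occurrence); all other reads are flagged duplicates.
#'
#' @param reads Tibble of assigned reads with columns `sample_id`, `umi`,
#'   `chrom`, `pos`, `strand` (reads with `sample_id == "UNASSIGNED"` are
#'   dropped with a warning).
#' @param umi_mismatch Maximum substitutions between UMIs of the same
#'   molecule (default 1).
#' @return List of class `dedup_result`: `reads` (input plus logical
#'   `is_duplicate`), and `stats` (per-sample tibble: total, unique_molecules,
#'   duplicates).
#' @export
mark_duplicates <- function(reads, umi_mismatch = 1L) {
  reads <- as_tibble(reads)
  need <- c("sample_id", "umi", "chrom", "pos", "strand")
  if (!all(need %in% names(reads))) {
    abort_data(paste("reads must carry columns:", paste(need, collapse = ", ")))
  }
  if (length(unique(nchar(reads$umi))) > 1) {
    abort_data("UMI lengths are inconsistent across reads")
  }
  if (any(reads$sample_id == "UNASSIGNED")) {
    warn("dropping UNASSIGNED reads before duplicate marking")
    reads <- filter(reads, .data$sample_id != "UNASSIGNED")
  }
  n <- nrow(reads)
  if (n == 0) {
    return(structure(
      list(
        reads = mutate(reads, is_duplicate = logical(0)),
        stats = tibble(
          sample_id = character(0), total = integer(0),
          unique_molecules = integer(0), duplicates = integer(0)
        )
      ),
      class = "dedup_result"
    ))
  }

  key <- paste(reads$sample_id, reads$chrom, reads$pos, reads$strand, sep = "\r")
  # collapse identical (key, umi): only the first occurrence of each distinct
  # UMI can represent a molecule, every further copy is a duplicate outright
  ku <- paste(key, reads$umi, sep = "\r")
  ord <- order(ku, seq_len(n)) # stable: first occurrence first
  first_of_ku <- !duplicated(ku[ord])
  is_dup <- rep(TRUE, n)

  # distinct UMIs per key
  rep_idx <- ord[first_of_ku] # row index of first occurrence of each (key,umi)
  ku_mult <- as.integer(table(factor(ku, levels = ku[rep_idx])))
  k_key <- key[rep_idx]

  # keys with a single distinct UMI: that UMI is the molecule
  multi <- k_key %in% unique(k_key[duplicated(k_key)])
  is_dup[rep_idx[!multi]] <- FALSE

  if (any(multi)) {
    # resolve the (rare) keys holding several distinct UMIs via connected
    # components over pairwise Hamming distance <= umi_mismatch
    idx_split <- split(which(multi), k_key[multi])
    for (grp in idx_split) {
      umis <- reads$umi[rep_idx[grp]]
      mult <- ku_mult[grp]
      d <- hamming_pairwise(umis)
      edges <- which(d <= umi_mismatch & upper.tri(d), arr.ind = TRUE)
      comp <- edge_components(length(umis), edges)
      for (cc in unique(comp)) {
        members <- which(comp == cc)
        # representative: highest multiplicity, ties by lexicographic UMI
        o <- members[order(-mult[members], umis[members])]
        is_dup[rep_idx[grp[o[1]]]] <- FALSE
      }
    }
  }

  reads$is_duplicate <- is_dup
  stats <- reads |>
    group_by(.data$sample_id) |>
    summarise(
      total = dplyr::n(),
      unique_molecules = sum(!.data$is_duplicate),
      duplicates = sum(.data$is_duplicate),
      .groups = "drop"
    )
  stopifnot(all(stats$unique_molecules + stats$duplicates == stats$total))
  structure(list(reads = reads, stats = stats), class = "dedup_result")
}

#' Remove reads overlapping blacklisted regions
#'
#' Optional post-deduplication filter subtracting a BED-style region set.
#'
#' @param reads Tibble with `chrom` and `pos` columns.
#' @param blacklist Tibble with `chrom`, `start`, `end` (0-based half-open),
#'   or `NULL` for no filtering.
#' @return Filtered tibble.
#' @export
remove_blacklisted <- function(reads, blacklist = NULL) {
  if (is.null(blacklist) || nrow(blacklist) == 0) {
    return(reads)
  }
  bad <- rep(FALSE, nrow(reads))
  for (i in seq_len(nrow(blacklist))) {
    bad <- bad | (reads$chrom == blacklist$chrom[i] &
      reads$pos >= blacklist$start[i] & reads$pos < blacklist$end[i])
  }
  reads[!bad, ]
}
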