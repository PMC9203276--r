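# Independent oracles used across tests. These deliberately use naive,
# brute-force implementations kept separate from the package code paths.

# Hamming distance between two equal-length strings
oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Brute-force duplicate marking: enumerate all read pairs, union groups when
# two reads share (sample, chrom, pos, strand) and have UMIs within
# `umi_mismatch`; unique molecules = number of groups per sample.
oracle_dedup_counts <- function(reads, umi_mismatch = 1) {
  n <- nrow(reads)
  group <- seq_len(n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_loc <- reads$sample_id[i] == reads$sample_id[j] &&
        reads$chrom[i] == reads$chrom[j] &&
        reads$pos[i] == reads$pos[j] &&
        reads$strand[i] == reads$strand[j]
      if (same_loc && oracle_hamming(reads$umi[i], reads$umi[j]) <= umi_mismatch) {
        old <- group[j]
        group[group == old] <- group[i]
      }
    }
  }
  stats <- tapply(group, reads$sample_id, function(g) length(unique(g)))
  tibble::tibble(
    sample_id = names(stats),
    unique_molecules = as.integer(stats)
  ) |> dplyr::arrange(sample_id)
}

# Step-up Benjamini-Hochberg, written from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Type-7 quantile from the interpolation formula
oracle_quantile7 <- function(x, q) {
  x <- sort(x)
  h <- (length(x) - 1) * q + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
}

# Exact two-sided rank-sum p via complete enumeration over group assignments
# (midranks for ties), doubling the smaller tail
oracle_ranksum_exact <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  sets <- utils::combn(length(r), n1)
  w_all <- apply(sets, 2, function(idx) sum(r[idx]))
  eps <- 1e-9
  min(1, 2 * min(mean(w_all <= w_obs + eps), mean(w_all >= w_obs - eps)))
}

# Per-base expansion of a scaled track for brute-force region averaging
oracle_region_mean <- function(track, chrom, start, end) {
  v <- track$coverage[[chrom]]
  per_bp <- rep(v, each = track$resolution)[seq_len(track$chrom_sizes[[chrom]])]
  mean(per_bp[(start + 1):end])
}

random_reads_fixture <- function(n, n_samples = 2, n_pos = 5, umi_pool = NULL) {
  if (is.null(umi_pool)) {
    umi_pool <- c(
      "AAAAAA", "AAAAAT", "AAAATT", "TTTTTT", "GGGGGG", "GGGGGA",
      "CCCCCC", "ACGTAC", "ACGTAT", "TGCATG"
    )
  }
  tibble::tibble(
    sample_id = paste0("s", sample.int(n_samples, n, replace = TRUE)),
    chrom = "chr1",
    pos = sample.int(n_pos, n, replace = TRUE) * 100L,
    strand = sample(c("+", "-"), n, replace = TRUE),
    umi = sample(umi_pool, n, replace = TRUE)
  )
}
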