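#' Evaluate an expression with a local random seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so generators are pure functions of their seed without
#' clobbering the session RNG.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

abort_config <- function(msg) abort(msg, class = "quantchip_config_error")
abort_data <- function(msg) abort(msg, class = "quantchip_data_error")

DNA_BASES <- c("A", "C", "G", "T")

#' Split equal-length strings into a character matrix (one row per string)
#' @noRd
string_to_char_matrix <- function(x, width) {
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
    ncol = width, byrow = TRUE
  )
}

#' Hamming distance between one string and a vector of equal-length strings
#' @noRd
hamming_to_one <- function(char_mat, s) {
  sc <- strsplit(s, "", fixed = TRUE)[[1]]
  rowSums(char_mat != matrix(sc, nrow = nrow(char_mat), ncol = length(sc), byrow = TRUE))
}

#' Pairwise Hamming distance matrix for a set of equal-length strings
#' @noRd
hamming_pairwise <- function(x) {
  n <- length(x)
  if (n <= 1) {
    return(matrix(0L, n, n))
  }
  m <- string_to_char_matrix(x, nchar(x[[1]]))
  d <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
    }
  }
  d
}

#' Random DNA k-mers
#' @noRd
random_kmers <- function(n, k) {
  if (n == 0) {
    return(character(0))
  }
  m <- matrix(sample(DNA_BASES, n * k, replace = TRUE), nrow = n, ncol = k)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Apply per-base substitution errors to DNA strings
#'
#' Each base is substituted (to a different base) independently with
#' probability `rate`.
#' @noRd
mutate_tags <- function(x, rate) {
  if (rate <= 0 || length(x) == 0) {
    return(x)
  }
  k <- nchar(x[[1]])
  n_err <- rbinom(length(x), k, rate)
  # single-substitution reads (the bulk) handled vectorized
  one <- which(n_err == 1L)
  if (length(one) > 0) {
    pos <- sample.int(k, length(one), replace = TRUE)
    old <- substr(x[one], pos, pos)
    new <- DNA_BASES[(match(old, DNA_BASES) - 1L + sample.int(3L, length(one), replace = TRUE)) %% 4L + 1L]
    substr(x[one], pos, pos) <- new
  }
  multi <- which(n_err >= 2L)
  for (i in multi) {
    chars <- strsplit(x[[i]], "", fixed = TRUE)[[1]]
    pos <- sample.int(k, n_err[i])
    for (p in pos) {
      chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1)
    }
    x[i] <- paste(chars, collapse = "")
  }
  x
}

#' Connected components of an undirected graph given as an edge list
#'
#' Union-find over `n` nodes; edges as a 2-column integer matrix. Returns an
#' integer component label per node (labels are arbitrary but consistent).
#' @noRd
edge_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(edges) > 0) {
    for (e in seq_len(nrow(edges))) {
      a <- find(edges[e, 1])
      b <- find(edges[e, 2])
      if (a != b) parent[a] <- b
    }
  }
  vapply(seq_len(n), find, integer(1))
}
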