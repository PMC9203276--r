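PROMOTER_CLASSES <- c(
  "primed_bivalent", "naive_bivalent", "common_bivalent",
  "k4_only", "k4_negative"
)

DEFAULT_CONDITIONS <- c(
  "naive_untreated", "naive_ezh2i", "primed_untreated", "primed_ezh2i"
)

DEFAULT_MARKS <- c("H3K27me3", "H3K4me3", "H2Aub")

#' Simulation configuration
#'
#' Collects every tunable of the synthetic experiment: the pooled-ChIP design
#' (conditions x replicates x marks plus a matched input), sequencing depth
#' and PCR-duplication rate, tag (UMI + barcode) substitution error rate, the
#' synthetic genome geometry, and the effect sizes that shape the chromatin
#' and expression landscapes. Defaults emulate a naive/primed human embryonic
#' stem cell design treated or not with an EZH2 inhibitor: globally high
#' naive H3K27me3 relative to primed, near-complete H3K27me3 loss under
#' EZH2i, a two-fold X-chromosome H3K27me3 boost in the naive state, and
#' class-linked repression/derepression of bivalent genes.
#'
#' @param seed Integer seed; every generator is a pure function of the
#'   configuration including this seed.
#' @param depth Expected unique-read depth per sample for the reference
#'   condition (reads; other samples scale with their true global factor).
#' @param dup_rate Probability that an emitted read is a PCR re-sample of an
#'   existing (coordinate, UMI) molecule.
#' @param tag_error_rate Per-base substitution probability in the 14 nt
#'   UMI + barcode prefix.
#' @param conditions,replicates,marks Design lists. `replicates` must be >= 2.
#' @param chrom_sizes Named integer vector of chromosome lengths (bp).
#' @param x_chrom Name of the designated X chromosome.
#' @param density_bin Resolution (bp) of the true density profiles.
#' @param state_width Width (bp) of chromatin-state segments.
#' @param n_promoters Number of promoters (split equally over the five
#'   classes).
#' @param flank Promoter half-window (bp) used when imprinting class signal.
#' @param k27_promoter_rpgc Absolute H3K27me3 level (RPGC, relative to the
#'   naive-untreated genome mean of 1) at K27-marked promoters; identical in
#'   both states for the common class, so the state difference at common
#'   promoters is nil while the diffuse background carries the global gap.
#' @param k4_promoter_rpgc Absolute H3K4me3 level (RPGC) at K4-positive
#'   promoters (both states).
#' @param k27_primed_bg_frac Primed diffuse H3K27me3 background as a
#'   fraction of the naive background (the "diffuse gain" of the naive
#'   state, inverted).
#' @param h2aub_fold Promoter enrichment fold over background for H2Aub
#'   (multiplicative).
#' @param x_boost Fold enrichment of naive-state H3K27me3 on the X
#'   chromosome.
#' @param ezh2i_residual Fraction of H3K27me3 remaining under EZH2i.
#' @param h2aub_primed_level True global H2Aub level of primed vs naive.
#' @param h2aub_derepressed_loss Fractional loss of promoter H2Aub at
#'   derepressed bivalent genes under EZH2i (0.15 = 15 percent).
#' @param barcode_rep_sd Lognormal sd of per-barcode representation in the
#'   pool (the unevenness the input normalization corrects).
#' @param expr_mean_range,expr_dispersion_range Log-uniform ranges of
#'   negative-binomial baseline means and dispersions for expression counts.
#' @param repression_log2 Log2 repression of naive-bivalent genes in the
#'   naive state (mirrored for primed-bivalent in primed).
#' @param derepression_log2 Log2 derepression of those genes upon EZH2i.
#' @param global_factors Optional override: list keyed by mark of named
#'   per-condition true global levels (replaces the built-in defaults).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       depth = 1e5,
                       dup_rate = 0.1,
                       tag_error_rate = 0.005,
                       conditions = DEFAULT_CONDITIONS,
                       replicates = 3L,
                       marks = DEFAULT_MARKS,
                       chrom_sizes = c(
                         chr1 = 500000L, chr2 = 450000L, chr3 = 400000L,
                         chr4 = 350000L, chrX = 300000L
                       ),
                       x_chrom = "chrX",
                       density_bin = 200L,
                       state_width = 10000L,
                       n_promoters = 500L,
                       flank = 1000L,
                       k27_promoter_rpgc = 2.5,
                       k4_promoter_rpgc = 2,
                       k27_primed_bg_frac = 0.1,
                       h2aub_fold = 3,
                       x_boost = 2,
                       ezh2i_residual = 0.05,
                       h2aub_primed_level = 0.5,
                       h2aub_derepressed_loss = 0.15,
                       barcode_rep_sd = 0.1,
                       expr_mean_range = c(50, 500),
                       expr_dispersion_range = c(0.01, 0.1),
                       repression_log2 = 1.5,
                       derepression_log2 = 1.5,
                       global_factors = NULL) {
  config <- list(
    seed = as.integer(seed), depth = depth, dup_rate = dup_rate,
    tag_error_rate = tag_error_rate, conditions = conditions,
    replicates = as.integer(replicates), marks = marks,
    chrom_sizes = chrom_sizes, x_chrom = x_chrom,
    density_bin = as.integer(density_bin),
    state_width = as.integer(state_width),
    n_promoters = as.integer(n_promoters), flank = as.integer(flank),
    k27_promoter_rpgc = k27_promoter_rpgc,
    k4_promoter_rpgc = k4_promoter_rpgc,
    k27_primed_bg_frac = k27_primed_bg_frac,
    h2aub_fold = h2aub_fold,
    x_boost = x_boost, ezh2i_residual = ezh2i_residual,
    h2aub_primed_level = h2aub_primed_level,
    h2aub_derepressed_loss = h2aub_derepressed_loss,
    barcode_rep_sd = barcode_rep_sd,
    expr_mean_range = expr_mean_range,
    expr_dispersion_range = expr_dispersion_range,
    repression_log2 = repression_log2,
    derepression_log2 = derepression_log2,
    global_factors = global_factors
  )
  validate_sim_config(config)
  structure(config, class = "sim_config")
}

validate_sim_config <- function(config) {
  probs <- c("dup_rate", "tag_error_rate")
  for (p in probs) {
    v <- config[[p]]
    if (!is.numeric(v) || v < 0 || v > 1) {
      abort_config(sprintf("invalid configuration: '%s' must be a probability in [0,1]", p))
    }
  }
  folds <- c(
    "k27_promoter_rpgc", "k4_promoter_rpgc", "k27_primed_bg_frac",
    "h2aub_fold", "x_boost", "ezh2i_residual", "h2aub_primed_level"
  )
  for (p in folds) {
    v <- config[[p]]
    if (!is.numeric(v) || v <= 0) {
      abort_config(sprintf("invalid configuration: '%s' must be > 0", p))
    }
  }
  if (config$replicates < 2) {
    abort_config("invalid configuration: 'replicates' must be >= 2")
  }
  if (config$depth <= 0) {
    abort_config("invalid configuration: 'depth' must be positive")
  }
  if (config$h2aub_derepressed_loss < 0 || config$h2aub_derepressed_loss >= 1) {
    abort_config("invalid configuration: 'h2aub_derepressed_loss' must be in [0,1)")
  }
  if (any(config$expr_dispersion_range <= 0)) {
    abort_config("invalid configuration: 'expr_dispersion_range' must be positive")
  }
  if (is.null(names(config$chrom_sizes)) || any(config$chrom_sizes <= 0)) {
    abort_config("invalid configuration: 'chrom_sizes' must be a named vector of positive lengths")
  }
  if (!config$x_chrom %in% names(config$chrom_sizes)) {
    abort_config("invalid configuration: 'x_chrom' not found in 'chrom_sizes'")
  }
  invisible(config)
}

parse_condition_state <- function(condition) {
  dplyr::case_when(
    startsWith(condition, "naive") ~ "naive",
    startsWith(condition, "primed") ~ "primed",
    TRUE ~ NA_character_
  )
}

parse_condition_treated <- function(condition) {
  grepl("ezh2i", condition, fixed = TRUE)
}

#' True global levels implied by a configuration
#'
#' @param config A [sim_config()].
#' @return List keyed by mark of named per-condition global factors
#'   (dimensionless, relative to the naive untreated reference).
#' @keywords internal
#' @noRd
build_global_factors <- function(config) {
  conditions <- config$conditions
  state <- parse_condition_state(conditions)
  treated <- parse_condition_treated(conditions)
  out <- list()
  for (mark in config$marks) {
    g <- rep(1, length(conditions))
    if (mark == "H2Aub") {
      g[state == "primed" & !is.na(state)] <- config$h2aub_primed_level
      # global H2Aub is essentially insensitive to EZH2i; losses are local
    }
    names(g) <- conditions
    out[[mark]] <- g
  }
  out
}

#' Simulate a genome with known modification landscapes
#'
#' Builds the simulation truth: a small multi-chromosome genome, a TSS set
#' with each promoter assigned to one of the five bivalency classes, 10 kb
#' chromatin-state segments, and for every (mark, condition) a true relative
#' density profile (genome-wide mean 1) plus a true global factor. Promoter
#' classes are imprinted as local density elevations: H3K4me3 at every
#' K4-positive class in all conditions; H3K27me3 at naive-bivalent promoters
#' in naive conditions, primed-bivalent in primed, common-bivalent in both;
#' H2Aub at all bivalent promoters, reduced by `h2aub_derepressed_loss` at
#' the state-specific bivalent class under EZH2i. Naive-state H3K27me3
#' density on the X chromosome is multiplied by `x_boost`.
#'
#' @param config A [sim_config()].
#' @return An object of class `genome_model`: list with `chrom_sizes`,
#'   `tss` (tibble chrom/pos/strand/gene_id), `states` (tibble
#'   chrom/start/end/state), `x_chrom`, `promoter_truth` (named character),
#'   `density` (list mark -> condition -> per-chromosome numeric vectors),
#'   `global_factor` (list mark -> named numeric), `bin_width`, `flank`.
#' @examples
#' model <- simulate_landscape(sim_config(n_promoters = 50, depth = 1000))
#' table(model$promoter_truth)
#' @export
simulate_landscape <- function(config) {
  validate_sim_config(config)
  with_local_seed(config$seed, {
    sizes <- config$chrom_sizes
    bw <- config$density_bin
    chroms <- names(sizes)

    # --- TSS set: promoters allocated to chromosomes proportional to length,
    # evenly spaced, alternating strand
    alloc <- diff(round(config$n_promoters * cumsum(c(0, sizes)) / sum(sizes)))
    names(alloc) <- chroms
    tss <- purrr::map2_dfr(chroms, alloc, function(ch, n) {
      if (n == 0) {
        return(tibble())
      }
      spacing <- sizes[[ch]] / n
      pos <- round((seq_len(n) - 0.5) * spacing)
      tibble(
        chrom = ch, pos = as.integer(pos),
        strand = rep_len(c("+", "-"), n)
      )
    })
    tss$gene_id <- sprintf("gene_%04d", seq_len(nrow(tss)))

    # --- five-class truth: a seeded class order cycled along genomic
    # order, so classes are exactly balanced genome-wide and near-balanced
    # per chromosome (keeps chromosome-level summaries free of allocation
    # noise)
    n <- nrow(tss)
    labels <- rep(sample(PROMOTER_CLASSES), length.out = n)
    promoter_truth <- setNames(labels, tss$gene_id)

    # --- chromatin-state segments: polycomb_target if the segment holds a
    # K27-marked promoter, active_promoter if a K4-only one, else background
    states <- purrr::map_dfr(chroms, function(ch) {
      starts <- seq(0L, sizes[[ch]] - 1L, by = config$state_width)
      tibble(
        chrom = ch, start = starts,
        end = pmin(starts + config$state_width, sizes[[ch]])
      )
    })
    biv_classes <- c("primed_bivalent", "naive_bivalent", "common_bivalent")
    seg_label <- rep("quiescent", nrow(states))
    for (i in seq_len(nrow(tss))) {
      cls <- promoter_truth[[tss$gene_id[i]]]
      hit <- which(states$chrom == tss$chrom[i] &
        states$start <= tss$pos[i] & states$end > tss$pos[i])
      if (cls %in% biv_classes) {
        seg_label[hit] <- "polycomb_target"
      } else if (cls == "k4_only" && seg_label[hit] == "quiescent") {
        seg_label[hit] <- "active_promoter"
      }
    }
    states$state <- seg_label

    # --- density profiles
    state_of <- parse_condition_state(config$conditions)
    treated <- parse_condition_treated(config$conditions)
    names(state_of) <- names(treated) <- config$conditions

    n_bins <- ceiling(sizes / bw)
    bin_w <- purrr::map(chroms, function(ch) {
      w <- rep(bw, n_bins[[ch]])
      w[length(w)] <- sizes[[ch]] - (n_bins[[ch]] - 1) * bw
      w
    })
    names(bin_w) <- chroms

    promoter_bins <- purrr::map(seq_len(nrow(tss)), function(i) {
      lo <- max(0L, tss$pos[i] - config$flank)
      hi <- min(sizes[[tss$chrom[i]]], tss$pos[i] + config$flank)
      list(chrom = tss$chrom[i], bins = (lo %/% bw + 1L):((hi - 1L) %/% bw + 1L))
    })

    enriched_classes <- function(mark, condition) {
      st <- state_of[[condition]]
      if (mark == "H3K4me3") {
        return(setdiff(PROMOTER_CLASSES, "k4_negative"))
      }
      if (mark == "H3K27me3") {
        cls <- "common_bivalent"
        if (is.na(st)) {
          return(biv_classes)
        }
        if (st == "naive") cls <- c(cls, "naive_bivalent")
        if (st == "primed") cls <- c(cls, "primed_bivalent")
        return(cls)
      }
      biv_classes # H2Aub and any other mark: all bivalent promoters
    }

    # footprint (bp) of the promoter windows per class, from the bins used
    class_bp <- setNames(numeric(length(PROMOTER_CLASSES)), PROMOTER_CLASSES)
    for (i in seq_len(nrow(tss))) {
      cls <- promoter_truth[[tss$gene_id[i]]]
      class_bp[cls] <- class_bp[cls] + length(promoter_bins[[i]]$bins) * bw
    }
    genome_bp <- sum(sizes)

    set_promoters <- function(prof, cls_on, value_for) {
      for (i in seq_len(nrow(tss))) {
        cls <- promoter_truth[[tss$gene_id[i]]]
        if (!cls %in% cls_on) next
        pb <- promoter_bins[[i]]
        prof[[pb$chrom]][pb$bins] <- value_for(cls)
      }
      prof
    }

    # H3K27me3 and H3K4me3 are built in absolute units (RPGC relative to the
    # naive-untreated genome mean): promoters sit at fixed absolute targets in
    # every state where their class is marked, while the diffuse background
    # carries the naive/primed global difference -- the naive "diffuse gain".
    # The true global level of each condition is then the genome mean of its
    # absolute profile, and the stored density is that profile normalized to
    # mean 1. H2Aub uses multiplicative promoter folds with a global level
    # set per state.
    density <- list()
    global_factor <- build_global_factors(config)
    for (mark in config$marks) {
      density[[mark]] <- list()
      absolute_mark <- mark %in% c("H3K27me3", "H3K4me3")
      if (absolute_mark) {
        A <- if (mark == "H3K27me3") config$k27_promoter_rpgc else config$k4_promoter_rpgc
        on_ref <- if (mark == "H3K27me3") {
          c("common_bivalent", "naive_bivalent")
        } else {
          setdiff(PROMOTER_CLASSES, "k4_negative")
        }
        f_on <- sum(class_bp[on_ref]) / genome_bp
        bg_naive <- (1 - f_on * A) / (1 - f_on)
        if (bg_naive <= 0) {
          abort_config(sprintf(
            "invalid configuration: '%s' too high for the promoter footprint (background would be negative)",
            if (mark == "H3K27me3") "k27_promoter_rpgc" else "k4_promoter_rpgc"
          ))
        }
      }
      for (cond in config$conditions) {
        st <- state_of[[cond]]
        tr <- treated[[cond]]
        if (absolute_mark) {
          bg <- bg_naive
          if (mark == "H3K27me3" && !is.na(st) && st == "primed") {
            bg <- bg_naive * config$k27_primed_bg_frac
          }
          prof <- purrr::map(chroms, function(ch) rep(bg, n_bins[[ch]]))
          names(prof) <- chroms
          prof <- set_promoters(prof, enriched_classes(mark, cond), function(cls) A)
          if (mark == "H3K27me3" && !is.na(st) && st == "naive") {
            prof[[config$x_chrom]] <- prof[[config$x_chrom]] * config$x_boost
          }
          if (mark == "H3K27me3" && tr) {
            prof <- purrr::map(prof, ~ .x * config$ezh2i_residual)
          }
        } else {
          fold <- config$h2aub_fold
          loss_class <- if (!is.na(st) && st == "naive") {
            "naive_bivalent"
          } else if (!is.na(st)) {
            "primed_bivalent"
          } else {
            NA_character_
          }
          prof <- purrr::map(chroms, function(ch) rep(1, n_bins[[ch]]))
          names(prof) <- chroms
          prof <- set_promoters(prof, enriched_classes(mark, cond), function(cls) {
            if (tr && !is.na(loss_class) && cls == loss_class) {
              fold * (1 - config$h2aub_derepressed_loss)
            } else {
              fold
            }
          })
          prof <- purrr::map(prof, ~ .x * global_factor[[mark]][[cond]])
        }
        gf <- sum(purrr::map2_dbl(prof, bin_w, ~ sum(.x * .y))) / genome_bp
        global_factor[[mark]][[cond]] <- gf
        density[[mark]][[cond]] <- purrr::map(prof, ~ .x / gf)
      }
      # user overrides replace the derived global level, keeping the shape
      if (!is.null(config$global_factors[[mark]])) {
        ov <- config$global_factors[[mark]]
        global_factor[[mark]][names(ov)] <- ov
      }
    }

    structure(
      list(
        chrom_sizes = sizes, tss = tss, states = states,
        x_chrom = config$x_chrom, promoter_truth = promoter_truth,
        density = density, global_factor = global_factor,
        bin_width = bw, flank = config$flank
      ),
      class = "genome_model"
    )
  })
}

#' Mean density of a model profile over a chromosome subset
#' @noRd
profile_mean <- function(profile, chrom_sizes, chroms) {
  tot <- 0
  len <- 0
  for (ch in chroms) {
    nb <- length(profile[[ch]])
    w <- rep(chrom_sizes[[ch]] / nb, nb) # bins are equal width except possibly last
    w[nb] <- chrom_sizes[[ch]] - (nb - 1) * w[1]
    tot <- tot + sum(profile[[ch]] * w)
    len <- len + chrom_sizes[[ch]]
  }
  tot / len
}

# assign UMIs such that distinct molecules at the same (chrom,pos,strand)
# are >= 2 substitutions apart, making the truth unambiguous for 1-mismatch
# component deduplication
assign_umis <- function(chrom, pos, strand, umi_length) {
  n <- length(pos)
  umi <- random_kmers(n, umi_length)
  key <- paste(chrom, pos, strand)
  dup_keys <- unique(key[duplicated(key)])
  if (length(dup_keys) > 0) {
    idx_by_key <- split(seq_len(n), key)
    for (k in dup_keys) {
      idx <- idx_by_key[[k]]
      repeat {
        d <- hamming_pairwise(umi[idx])
        bad <- which(colSums(d < 2) > 1) # any partner within distance 1
        if (length(bad) <= 0) break
        umi[idx[bad[-1]]] <- random_kmers(length(bad) - 1, umi_length)
        if (length(bad) == 1) break
      }
    }
  }
  umi
}

#' Simulate pooled tagged-read libraries
#'
#' Emits, for every mark, one pooled library holding all (condition,
#' replicate) samples, plus one pooled input library, mirroring a multiplexed
#' ChIP design where barcoded samples are combined before
#' immunoprecipitation. Each read carries an observed 6 nt UMI and 8 nt
#' barcode (with substitution errors at `tag_error_rate`) and a true genomic
#' coordinate sampled proportional to the model density; the number of
#' molecules per sample is proportional to depth x barcode representation x
#' true global factor, so the input-normalized read count downstream recovers
#' the global factor. PCR duplicates re-emit an existing (coordinate, UMI)
#' molecule. Input libraries are uniform over the genome.
#'
#' @param model A [simulate_landscape()] result.
#' @param config The same [sim_config()].
#' @param layout Optional [barcode_layout()]; defaults to a generated set
#'   with minimum pairwise Hamming distance 3, one barcode per
#'   (condition, replicate).
#' @return List with `pools` (named list of read tibbles: read_id, umi,
#'   barcode_obs, chrom, pos, strand), `truth` (tibble: read_id, pool,
#'   condition, replicate, sample_id, is_duplicate), and `layout`.
#' @export
simulate_pool <- function(model, config, layout = NULL) {
  validate_sim_config(config)
  samples <- tidyr::expand_grid(
    condition = config$conditions,
    replicate = seq_len(config$replicates)
  ) |>
    mutate(sample_id = sprintf("%s_rep%d", .data$condition, .data$replicate))
  if (is.null(layout)) {
    bc <- make_barcode_set(nrow(samples), seed = config$seed + 7L)
    layout <- barcode_layout(setNames(bc, samples$sample_id))
  }
  if (nrow(layout$barcodes) < nrow(samples)) {
    abort_config(sprintf(
      "barcode layout has %d barcodes but the design needs %d samples",
      nrow(layout$barcodes), nrow(samples)
    ))
  }
  samples <- samples |>
    left_join(layout$barcodes, by = "sample_id")
  if (anyNA(samples$barcode)) {
    abort_config("barcode layout does not cover all design sample ids")
  }

  with_local_seed(config$seed + 1L, {
    sizes <- model$chrom_sizes
    chroms <- names(sizes)
    bw <- model$bin_width
    # barcode representation is a property of the sample, shared by the ChIP
    # pools and the input pool (this is what INRC corrects)
    rep_factor <- exp(rnorm(nrow(samples), 0, config$barcode_rep_sd))

    sample_reads <- function(pool, cond, repl, barcode, r_s) {
      gf <- if (pool == "input") 1 else model$global_factor[[pool]][[cond]]
      n_total <- rpois(1, config$depth * r_s * gf)
      if (n_total == 0) {
        return(list(reads = tibble(), truth = tibble()))
      }
      n_dup <- rbinom(1, n_total, config$dup_rate)
      n_uni <- n_total - n_dup
      if (pool == "input") {
        ch <- sample(chroms, n_uni, replace = TRUE, prob = sizes / sum(sizes))
        pos <- as.integer(floor(runif(n_uni) * sizes[ch]))
      } else {
        prof <- model$density[[pool]][[cond]]
        lens <- vapply(prof, length, integer(1))
        flat <- unlist(prof, use.names = FALSE)
        bin <- sample.int(length(flat), n_uni, replace = TRUE, prob = flat)
        chrom_idx <- rep(seq_along(lens), lens)[bin]
        ch <- chroms[chrom_idx]
        local_bin <- bin - cumsum(c(0, lens))[chrom_idx] - 1L
        pos <- as.integer(pmin(local_bin * bw + floor(runif(n_uni) * bw), sizes[ch] - 1L))
      }
      strand <- sample(c("+", "-"), n_uni, replace = TRUE)
      umi <- assign_umis(ch, pos, strand, layout$umi_length)
      is_dup <- rep(FALSE, n_uni)
      if (n_dup > 0) {
        src <- sample.int(n_uni, n_dup, replace = TRUE)
        ch <- c(ch, ch[src])
        pos <- c(pos, pos[src])
        strand <- c(strand, strand[src])
        umi <- c(umi, umi[src])
        is_dup <- c(is_dup, rep(TRUE, n_dup))
      }
      umi_obs <- mutate_tags(umi, config$tag_error_rate)
      bc_obs <- mutate_tags(rep(barcode, n_total), config$tag_error_rate)
      id <- sprintf("%s:%s_rep%d:%07d", pool, cond, repl, seq_len(n_total))
      list(
        reads = tibble(
          read_id = id, umi = umi_obs, barcode_obs = bc_obs,
          chrom = ch, pos = pos, strand = strand
        ),
        truth = tibble(
          read_id = id, pool = pool, condition = cond,
          replicate = repl, sample_id = sprintf("%s_rep%d", cond, repl),
          is_duplicate = is_dup
        )
      )
    }

    pools <- list()
    truths <- list()
    for (pool in c(config$marks, "input")) {
      parts <- purrr::pmap(
        list(samples$condition, samples$replicate, samples$barcode, rep_factor),
        function(cond, repl, bc, r_s) sample_reads(pool, cond, repl, bc, r_s)
      )
      reads <- bind_rows(purrr::map(parts, "reads"))
      # shuffle to emulate pooling
      reads <- reads[sample.int(nrow(reads)), ]
      pools[[pool]] <- reads
      truths[[pool]] <- bind_rows(purrr::map(parts, "truth"))
    }
    list(pools = pools, truth = bind_rows(truths), layout = layout)
  })
}

#' Simulate an expression count matrix with class-linked effects
#'
#' Generates negative-binomial counts for every gene in the model across the
#' full design. Naive-bivalent genes are repressed (`-repression_log2`) in
#' naive conditions and derepressed by `+derepression_log2` upon EZH2i in the
#' naive state; primed-bivalent genes mirror this in the primed state. All
#' other classes carry no effect.
#'
#' @param model A [simulate_landscape()] result (must carry
#'   `promoter_truth`).
#' @param config The same [sim_config()].
#' @return List with `counts` (tibble: gene_id + one column per sample),
#'   `design` (tibble: sample, condition, replicate), and `truth_effects`
#'   (tibble: gene_id, condition, log2_effect).
#' @export
simulate_expression <- function(model, config) {
  validate_sim_config(config)
  if (is.null(model$promoter_truth)) {
    abort_config("model lacks promoter_truth; run simulate_landscape() first")
  }
  with_local_seed(config$seed + 2L, {
    genes <- names(model$promoter_truth)
    n <- length(genes)
    base_mean <- exp(runif(n, log(config$expr_mean_range[1]), log(config$expr_mean_range[2])))
    dispersion <- exp(runif(n, log(config$expr_dispersion_range[1]), log(config$expr_dispersion_range[2])))

    design <- tidyr::expand_grid(
      condition = config$conditions,
      replicate = seq_len(config$replicates)
    ) |>
      mutate(sample = sprintf("%s_rep%d", .data$condition, .data$replicate))

    state_of <- parse_condition_state(config$conditions)
    treated <- parse_condition_treated(config$conditions)

    effect_for <- function(cls, cond_idx) {
      st <- state_of[cond_idx]
      tr <- treated[cond_idx]
      own <- (cls == "naive_bivalent" & !is.na(st) & st == "naive") |
        (cls == "primed_bivalent" & !is.na(st) & st == "primed")
      e <- ifelse(own, -config$repression_log2, 0)
      e + ifelse(own & tr, config$derepression_log2, 0)
    }

    cls <- unname(model$promoter_truth[genes])
    counts <- matrix(0L, nrow = n, ncol = nrow(design))
    effects <- list()
    for (j in seq_len(nrow(design))) {
      ci <- match(design$condition[j], config$conditions)
      e <- effect_for(cls, ci)
      mu <- base_mean * 2^e
      counts[, j] <- rnbinom(n, mu = mu, size = 1 / dispersion)
      effects[[j]] <- e
    }
    colnames(counts) <- design$sample
    truth_effects <- tibble(
      gene_id = rep(genes, length(config$conditions)),
      condition = rep(config$conditions, each = n),
      log2_effect = unlist(effects[match(config$conditions, design$condition)], use.names = FALSE)
    )
    list(
      counts = bind_cols(tibble(gene_id = genes), as_tibble(counts)),
      design = design,
      truth_effects = truth_effects
    )
  })
}

#' Simulate single-cell gating fixtures
#'
#' Generates (a) an immunofluorescence intensity table with a control sample
#' and a treated sample containing a known fraction of marker-positive nuclei
#' at elevated intensity, and (b) a pseudotime table where untreated control
#' cells sit mostly below a bifurcation and treated cells are shifted
#' towards activated fates with branch labels.
#'
#' @param seed Integer seed.
#' @param n_cells Cells per sample.
#' @param positive_fraction Fraction of treated nuclei that are truly
#'   marker-positive.
#' @param positive_fold Intensity fold of positive nuclei over the control
#'   mean.
#' @return List with `intensity` (object_id, sample, is_control, intensity)
#'   and `pseudotime` (cell_id, treatment, pseudotime, branch) tibbles.
#' @export
simulate_gating_tables <- function(seed = 1L, n_cells = 500L,
                                   positive_fraction = 0.4,
                                   positive_fold = 3) {
  with_local_seed(seed + 3L, {
    ctrl <- exp(rnorm(n_cells, log(100), 0.3))
    n_pos <- round(n_cells * positive_fraction)
    trt <- c(
      exp(rnorm(n_cells - n_pos, log(100), 0.3)),
      exp(rnorm(n_pos, log(100 * positive_fold), 0.3))
    )
    intensity <- tibble(
      object_id = sprintf("cell_%04d", seq_len(2 * n_cells)),
      sample = rep(c("untreated", "treated"), each = n_cells),
      is_control = rep(c(TRUE, FALSE), each = n_cells),
      intensity = c(ctrl, trt)
    )

    pt_ctrl <- stats::rgamma(n_cells, shape = 2, scale = 1.5)
    pt_trt <- stats::rgamma(n_cells, shape = 4, scale = 2.0)
    pt <- tibble(
      cell_id = sprintf("sc_%04d", seq_len(2 * n_cells)),
      treatment = rep(c("untreated", "treated"), each = n_cells),
      pseudotime = c(pt_ctrl, pt_trt)
    )
    bif <- unname(quantile(pt_ctrl, 0.99))
    pt$branch <- ifelse(
      pt$pseudotime <= bif, "pre_bifurcation",
      sample(c("trophectoderm", "mesoderm"), 2 * n_cells, replace = TRUE)
    )
    list(intensity = intensity, pseudotime = pt)
  })
}
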