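BIVALENT_CLASSES <- c("primed_bivalent", "naive_bivalent", "common_bivalent")

#' Pipeline configuration
#'
#' Bundles the simulation configuration with every downstream threshold.
#' Thresholds default to the study's printed values (ChIP significance
#' padj < 0.05 with fold change > 1.5; RNA FDR < 5 percent with fold
#' change 2; marker gate at 1.5x the control mean; ground-state gate at the
#' 95 percent control quantile) and to documented module defaults otherwise.
#'
#' @param sim A [sim_config()].
#' @param reference Reference condition scaled to 1x RPGC (pooled
#'   replicates).
#' @param alpha FDR cutoff for all differential calls.
#' @param chip_fc,rna_fc Fold-change cutoffs for ChIP and RNA calls.
#' @param k4_min_fold,k27_min_fold Promoter positivity folds over the
#'   genome median (3 for the broad H3K27me3 mark keeps the boosted naive X
#'   background below threshold; 2 for the sharper H3K4me3 peaks).
#' @param flank Promoter half-window (bp).
#' @param bin_width Genome bin width (bp) for bin-level summaries.
#' @param fragment_length Fragment extension (bp).
#' @param resolution Track bin width (bp).
#' @param gate_q Control quantile of the ground-state gate.
#' @param intensity_factor Marker-gate multiplier over the control mean.
#' @param write_tracks Write pooled bedGraph tracks (default TRUE).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            reference = "naive_untreated",
                            alpha = 0.05,
                            chip_fc = 1.5,
                            rna_fc = 2,
                            k4_min_fold = 2,
                            k27_min_fold = 3,
                            flank = 1000L,
                            bin_width = 10000L,
                            fragment_length = 150L,
                            resolution = 50L,
                            gate_q = 0.95,
                            intensity_factor = 1.5,
                            write_tracks = TRUE) {
  if (alpha <= 0 || alpha >= 1) abort_config("alpha must lie in (0,1)")
  if (gate_q <= 0 || gate_q >= 1) abort_config("gate_q must lie in (0,1)")
  if (chip_fc <= 1 || rna_fc <= 1) abort_config("fold-change cutoffs must exceed 1")
  if (!reference %in% sim$conditions) {
    abort_config(sprintf("reference condition '%s' not in the design", reference))
  }
  structure(
    list(
      sim = sim, reference = reference, alpha = alpha, chip_fc = chip_fc,
      rna_fc = rna_fc, k4_min_fold = k4_min_fold,
      k27_min_fold = k27_min_fold, flank = as.integer(flank),
      bin_width = as.integer(bin_width),
      fragment_length = as.integer(fragment_length),
      resolution = as.integer(resolution), gate_q = gate_q,
      intensity_factor = intensity_factor, write_tracks = write_tracks
    ),
    class = "pipeline_config"
  )
}

write_config_yaml <- function(config, path) {
  ser <- config
  ser$sim <- unclass(ser$sim)
  ser$sim$chrom_sizes <- as.list(ser$sim$chrom_sizes)
  yaml::write_yaml(unclass(ser), path)
  invisible(path)
}

pooled_condition_reads <- function(dedup, truth = NULL) {
  # non-duplicate assigned reads annotated with condition
  dedup$reads |>
    filter(!.data$is_duplicate) |>
    mutate(condition = sub("_rep[0-9]+$", "", .data$sample_id))
}

pooled_inrc <- function(inrc) {
  inrc |>
    group_by(.data$mark, .data$condition) |>
    summarise(
      chip_unique = sum(.data$chip_unique),
      input_unique = sum(.data$input_unique),
      .groups = "drop"
    ) |>
    mutate(
      sample_id = .data$condition,
      inrc = compute_inrc(.data$chip_unique, .data$input_unique, .data$sample_id)
    )
}

#' Run the full synthetic pipeline
#'
#' Executes simulate -> demultiplex -> deduplicate -> scale -> quantify ->
#' differential test -> classify -> respond -> gate -> report on a seeded
#' synthetic experiment and writes every stage output (TSV/BED/bedGraph)
#' plus a manifest into `outdir`. Re-running with the same configuration
#' reproduces identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory stage results: `model`,
#'   `scale_factors`, `pooled_tracks`, `diff` (list of `nb_diff` tables),
#'   `classes`, `class_accuracy`, `switch`, `derepression`, `h2aub_response`,
#'   `chrom_stats`, `gates`, `paths`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile("quantchip_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- config$sim
  log_path <- file.path(outdir, "pipeline.log")
  logf <- function(fmt, ...) {
    cat(sprintf(paste0(fmt, "\n"), ...), file = log_path, append = TRUE)
  }
  cat("", file = log_path)

  # --- stage: simulate -------------------------------------------------
  logf("stage simulate: seed %d, depth %g reads/sample", sim$seed, sim$depth)
  model <- simulate_landscape(sim)
  pool_out <- simulate_pool(model, sim)
  expr <- simulate_expression(model, sim)
  gating_tbl <- simulate_gating_tables(seed = sim$seed)

  write_bed(
    model$tss |> mutate(start = .data$pos, end = .data$pos + 1L, region_id = .data$gene_id),
    file.path(outdir, "tss.bed")
  )
  write_bed(
    model$states |> mutate(region_id = .data$state),
    file.path(outdir, "states.bed")
  )
  readr::write_tsv(pool_out$layout$barcodes, file.path(outdir, "barcodes.tsv"))
  readr::write_tsv(
    tibble(gene_id = names(model$promoter_truth), class = unname(model$promoter_truth)),
    file.path(outdir, "promoter_truth.tsv")
  )
  readr::write_tsv(
    purrr::imap_dfr(model$global_factor, function(g, mark) {
      tibble(mark = mark, condition = names(g), global_factor = unname(g))
    }),
    file.path(outdir, "global_factors.tsv")
  )
  readr::write_tsv(expr$counts, file.path(outdir, "rna_counts.tsv"))
  write_config_yaml(config, file.path(outdir, "config.yaml"))

  # --- stage: demux + dedup -------------------------------------------
  genome_size <- sum(model$chrom_sizes)
  dedups <- list()
  demux_stats <- list()
  truth_counts <- pool_out$truth |>
    group_by(.data$pool, .data$sample_id) |>
    summarise(
      true_reads = dplyr::n(), true_duplicates = sum(.data$is_duplicate),
      .groups = "drop"
    )
  for (pool in names(pool_out$pools)) {
    assigned <- demultiplex(pool_out$pools[[pool]], pool_out$layout)
    demux_stats[[pool]] <- attr(assigned, "demux_stats") |> mutate(pool = pool)
    dedups[[pool]] <- mark_duplicates(assigned)
    logf(
      "stage demux/dedup [%s]: %d reads in, %d assigned, %d unique molecules",
      pool, nrow(assigned),
      sum(assigned$sample_id != "UNASSIGNED"),
      sum(dedups[[pool]]$stats$unique_molecules)
    )
  }
  pool_out$pools <- NULL # free the raw reads
  readr::write_tsv(bind_rows(demux_stats), file.path(outdir, "demux_stats.tsv"))
  readr::write_tsv(
    bind_rows(purrr::imap(dedups, function(d, pool) mutate(d$stats, pool = pool))) |>
      left_join(truth_counts, by = c("pool", "sample_id")),
    file.path(outdir, "dedup_stats.tsv")
  )

  # --- stage: scale ----------------------------------------------------
  inrc <- purrr::map_dfr(sim$marks, function(mark) {
    inrc_table(dedups[[mark]]$stats, dedups$input$stats, mark = mark)
  })
  readr::write_tsv(inrc, file.path(outdir, "inrc.tsv"))
  sf_rep <- purrr::map(sim$marks, function(mk) {
    compute_scale_factors(
      filter(inrc, .data$mark == mk), config$reference,
      genome_size, config$fragment_length
    )
  })
  names(sf_rep) <- sim$marks
  inrc_pooled <- pooled_inrc(inrc)
  sf_pool <- purrr::map(sim$marks, function(mk) {
    compute_scale_factors(
      filter(inrc_pooled, .data$mark == mk), config$reference,
      genome_size, config$fragment_length
    )
  })
  names(sf_pool) <- sim$marks
  readr::write_tsv(
    bind_rows(purrr::map(sf_rep, tidy)) |> mutate(level = "replicate") |>
      bind_rows(bind_rows(purrr::map(sf_pool, tidy)) |> mutate(level = "pooled")),
    file.path(outdir, "scale_factors.tsv")
  )
  logf("stage scale: reference '%s' at 1x RPGC", config$reference)

  # --- stage: tracks ---------------------------------------------------
  make_track <- function(mark, reads, factor, id) {
    build_scaled_track(
      reads, model$chrom_sizes, factor,
      fragment_length = config$fragment_length,
      resolution = config$resolution, sample_id = id
    )
  }
  pooled_tracks <- list()
  rep_tracks <- list()
  for (mark in sim$marks) {
    reads_mark <- pooled_condition_reads(dedups[[mark]])
    tab_pool <- sf_pool[[mark]]$table
    tab_rep <- sf_rep[[mark]]$table
    for (cond in sim$conditions) {
      fac <- tab_pool$factor[tab_pool$condition == cond]
      pooled_tracks[[mark]][[cond]] <- make_track(
        mark, filter(reads_mark, .data$condition == cond), fac,
        paste(mark, cond, sep = ".")
      )
    }
    for (sid in tab_rep$sample_id) {
      fac <- tab_rep$factor[tab_rep$sample_id == sid]
      rep_tracks[[mark]][[sid]] <- make_track(
        mark, filter(reads_mark, .data$sample_id == sid), fac,
        paste(mark, sid, sep = ".")
      )
    }
    if (config$write_tracks) {
      for (cond in sim$conditions) {
        write_bedgraph(
          pooled_tracks[[mark]][[cond]],
          file.path(outdir, sprintf("%s_%s.bedgraph", mark, cond))
        )
      }
    }
  }
  logf("stage tracks: %d pooled, %d per-replicate", length(sim$marks) * length(sim$conditions), length(sim$marks) * nrow(sf_rep[[1]]$table))

  # --- stage: quantify -------------------------------------------------
  bins <- make_bins(model$chrom_sizes, config$bin_width)
  windows <- promoter_windows(model$tss,
    flank_up = config$flank,
    flank_down = config$flank, chrom_sizes = model$chrom_sizes
  )
  states <- model$states |> mutate(region_id = sprintf("%s_%d", .data$state, dplyr::row_number()))

  summarize_pooled <- function(regions, label) {
    purrr::imap_dfr(pooled_tracks, function(by_cond, mark) {
      purrr::imap_dfr(by_cond, function(track, cond) {
        summarize_regions(track, regions) |>
          mutate(mark = mark, condition = cond)
      })
    }) |>
      mutate(set = label)
  }
  bin_summary <- summarize_pooled(bins, "bins")
  promoter_summary <- summarize_pooled(windows, "promoters")
  state_summary <- summarize_pooled(states, "states") |>
    mutate(state = sub("_[0-9]+$", "", .data$region_id)) |>
    group_by(.data$mark, .data$condition, .data$state) |>
    summarise(
      mean_rpgc = sum(.data$mean_rpgc * .data$width) / sum(.data$width),
      .groups = "drop"
    )
  readr::write_tsv(bin_summary, file.path(outdir, "bin_summary.tsv"))
  readr::write_tsv(promoter_summary, file.path(outdir, "promoter_summary.tsv"))
  readr::write_tsv(state_summary, file.path(outdir, "state_summary.tsv"))

  chrom_stats <- purrr::imap_dfr(pooled_tracks, function(by_cond, mark) {
    purrr::imap_dfr(by_cond, function(track, cond) {
      cs <- chromosome_stats(track, model$x_chrom)
      cs$table |>
        mutate(
          mark = mark, condition = cond,
          x_over_autosome_density = cs$x_over_autosome_density,
          x_share = cs$x_share
        )
    })
  })
  readr::write_tsv(chrom_stats, file.path(outdir, "chromosome_summary.tsv"))

  # --- stage: differential tests --------------------------------------
  chip_design <- tidyr::expand_grid(
    condition = sim$conditions, replicate = seq_len(sim$replicates)
  ) |>
    mutate(sample = sprintf("%s_rep%d", .data$condition, .data$replicate))
  chip_counts <- function(mark) {
    mats <- purrr::imap(rep_tracks[[mark]], function(track, sid) {
      s <- summarize_regions(track, windows)
      setNames(rpgc_to_counts(s$mean_rpgc, s$width, config$fragment_length), s$region_id)
    })
    m <- do.call(cbind, mats)
    m
  }
  diff <- list()
  diff$k27_state <- nb_wald_test(
    chip_counts("H3K27me3"), chip_design,
    condition_a = "primed_untreated", condition_b = "naive_untreated"
  )
  diff$k4_state <- nb_wald_test(
    chip_counts("H3K4me3"), chip_design,
    condition_a = "primed_untreated", condition_b = "naive_untreated"
  )
  diff$h2aub_ezh2i <- nb_wald_test(
    chip_counts("H2Aub"), chip_design,
    condition_a = "naive_untreated", condition_b = "naive_ezh2i"
  )
  rna_counts <- expr$counts
  rna_mat <- as.matrix(rna_counts[, -1])
  rownames(rna_mat) <- rna_counts$gene_id
  diff$rna_ezh2i <- nb_wald_test(
    rna_mat,
    expr$design |> select(sample = "sample", condition = "condition"),
    condition_a = "naive_untreated", condition_b = "naive_ezh2i",
    size_factors = estimate_size_factors(rna_mat)
  )
  for (nm in names(diff)) {
    readr::write_tsv(tidy(diff[[nm]]), file.path(outdir, sprintf("diff_%s.tsv", nm)))
  }
  per_chrom_fc <- bind_rows(
    per_chromosome_fc_summary(diff$k27_state, model$tss) |> mutate(comparison = "k27_naive_vs_primed"),
    per_chromosome_fc_summary(diff$rna_ezh2i, model$tss) |> mutate(comparison = "rna_ezh2i_vs_untreated")
  )
  readr::write_tsv(per_chrom_fc, file.path(outdir, "per_chromosome_fc.tsv"))
  logf("stage diff: %d promoter features tested", nrow(diff$k27_state))

  # --- stage: classify -------------------------------------------------
  pos_call <- function(mark, cond, min_fold) {
    track <- pooled_tracks[[mark]][[cond]]
    quant <- promoter_summary |>
      filter(.data$mark == .env$mark, .data$condition == .env$cond)
    call_k4_positive(quant, track_median(track), min_fold)
  }
  k4_naive <- pos_call("H3K4me3", "naive_untreated", config$k4_min_fold)
  k4_primed <- pos_call("H3K4me3", "primed_untreated", config$k4_min_fold)
  k27_naive <- pos_call("H3K27me3", "naive_untreated", config$k27_min_fold)
  k27_primed <- pos_call("H3K27me3", "primed_untreated", config$k27_min_fold)
  genes <- k4_naive$gene_id
  flags <- tibble(
    gene_id = genes,
    k4_naive = k4_naive$positive[match(genes, k4_naive$gene_id)],
    k4_primed = k4_primed$positive[match(genes, k4_primed$gene_id)],
    k27_naive = k27_naive$positive[match(genes, k27_naive$gene_id)],
    k27_primed = k27_primed$positive[match(genes, k27_primed$gene_id)]
  )
  classes <- classify_promoters(flags, diff$k27_state,
    alpha = config$alpha, fc_threshold = config$chip_fc
  )
  class_accuracy <- mean(
    classes$class == unname(model$promoter_truth[classes$gene_id])
  )
  readr::write_tsv(tidy(classes), file.path(outdir, "promoter_classes.tsv"))
  logf("stage classify: %.1f%% agreement with simulation truth", 100 * class_accuracy)

  bivalent_genes <- classes$gene_id[classes$class %in% BIVALENT_CLASSES]
  switch <- class_switch_table(diff$k4_state, diff$k27_state,
    promoters = bivalent_genes,
    alpha = config$alpha, fc_threshold = config$chip_fc
  )
  readr::write_tsv(switch$counts, file.path(outdir, "switch_table.tsv"))

  # --- stage: respond --------------------------------------------------
  k27_flags <- tibble(
    gene_id = flags$gene_id,
    k27_pos = flags$k27_naive | flags$k27_primed
  )
  derep <- derepression_analysis(diff$rna_ezh2i, classes, k27_flags,
    alpha = config$alpha, fc_threshold = config$rna_fc
  )
  readr::write_tsv(derep$class_response, file.path(outdir, "class_response.tsv"))
  writeLines(derep$derepressed, file.path(outdir, "derepressed_genes.txt"))
  strata <- tibble(
    gene_id = flags$gene_id,
    stratum = ifelse(k27_flags$k27_pos, "bivalent", "k27_devoid")
  )
  h2aub_response <- suppressWarnings(
    h2aub_change_at_derepressed(diff$h2aub_ezh2i, derep$derepressed, strata)
  )
  readr::write_tsv(h2aub_response, file.path(outdir, "h2aub_response.tsv"))
  logf(
    "stage respond: %d derepressed, %d repressed genes", derep$n_up,
    derep$n_down
  )

  # --- stage: gate -----------------------------------------------------
  marker <- gate_marker_positive(gating_tbl$intensity, factor = config$intensity_factor)
  ground <- gate_ground_state(gating_tbl$pseudotime, "untreated", q = config$gate_q)
  split <- split_activated(gating_tbl$pseudotime, ground$threshold)
  readr::write_tsv(marker$per_sample, file.path(outdir, "marker_gate.tsv"))
  readr::write_tsv(
    ground$per_treatment |> mutate(threshold = ground$threshold),
    file.path(outdir, "pseudotime_gate.tsv")
  )
  readr::write_tsv(count(split, .data$treatment, .data$label), file.path(outdir, "elc_labels.tsv"))
  logf("stage gate: pseudotime threshold %.3f", ground$threshold)

  # --- manifest --------------------------------------------------------
  cfg_path <- file.path(outdir, "config.yaml")
  manifest <- list(
    package = "quantchip",
    version = as.character(utils::packageVersion("quantchip")),
    seed = sim$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    outputs = sort(setdiff(list.files(outdir), "manifest.yaml"))
  )
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))

  report_summary(outdir)

  invisible(list(
    model = model, scale_factors = list(replicate = sf_rep, pooled = sf_pool),
    pooled_tracks = pooled_tracks, diff = diff, classes = classes,
    class_accuracy = class_accuracy, switch = switch, derepression = derep,
    h2aub_response = h2aub_response, chrom_stats = chrom_stats,
    gates = list(marker = marker, ground = ground, split = split),
    paths = list(outdir = outdir)
  ))
}

#' Summarize a pipeline run directory
#'
#' Reads the stage outputs back from disk, cross-checks their counts and
#' writes a single `report.md` (plus `report.tsv` with the headline
#' quantities). Regeneration is idempotent.
#'
#' @param run_dir Directory produced by [run_pipeline()].
#' @return Invisibly, a named list of summary tibbles.
#' @export
report_summary <- function(run_dir) {
  need <- function(f) {
    p <- file.path(run_dir, f)
    if (!file.exists(p)) {
      warn(sprintf("missing stage output '%s'; report will have gaps", f))
      return(NULL)
    }
    readr::read_tsv(p, show_col_types = FALSE, progress = FALSE)
  }
  sf <- need("scale_factors.tsv")
  classes <- need("promoter_classes.tsv")
  switch_tbl <- need("switch_table.tsv")
  response <- need("class_response.tsv")
  marker <- need("marker_gate.tsv")
  ptgate <- need("pseudotime_gate.tsv")
  chrom <- need("chromosome_summary.tsv")

  lines <- c("# quantchip run summary", "")
  key <- list()
  if (!is.null(sf)) {
    glob <- sf |>
      filter(.data$level == "pooled") |>
      select("mark", "condition", "global_level")
    lines <- c(lines, "## Global levels (pooled replicates, relative to reference)", "")
    lines <- c(lines, knit_tsv(glob), "")
    key$global_levels <- glob
  }
  if (!is.null(classes)) {
    cc <- count(classes, .data$class)
    lines <- c(lines, "## Promoter classes", "", knit_tsv(cc), "")
    key$class_counts <- cc
  }
  if (!is.null(switch_tbl)) {
    lines <- c(lines, "## Mark switches at bivalent promoters", "", knit_tsv(switch_tbl), "")
    key$switches <- switch_tbl
  }
  if (!is.null(response)) {
    lines <- c(lines, "## Class response to EZH2i (RNA)", "", knit_tsv(response), "")
    key$class_response <- response
  }
  if (!is.null(chrom)) {
    xr <- chrom |>
      distinct(.data$mark, .data$condition, .data$x_over_autosome_density, .data$x_share)
    lines <- c(lines, "## X-chromosome enrichment", "", knit_tsv(xr), "")
    key$x_ratios <- xr
  }
  if (!is.null(marker)) {
    lines <- c(lines, "## Marker gate (% positive)", "", knit_tsv(marker), "")
    key$marker_gate <- marker
  }
  if (!is.null(ptgate)) {
    lines <- c(lines, "## Ground-state gate", "", knit_tsv(ptgate), "")
    key$pseudotime_gate <- ptgate
  }
  writeLines(lines, file.path(run_dir, "report.md"))
  if (!is.null(sf) && !is.null(classes)) {
    headline <- tibble(
      quantity = c(
        "n_promoters",
        paste0("n_", sort(unique(classes$class)))
      ),
      value = c(nrow(classes), as.integer(table(classes$class)[sort(unique(classes$class))]))
    )
    readr::write_tsv(headline, file.path(run_dir, "report.tsv"))
  }
  invisible(key)
}

knit_tsv <- function(tbl) {
  num <- vapply(tbl, is.numeric, logical(1))
  tbl[num] <- lapply(tbl[num], function(x) signif(x, 4))
  header <- paste(names(tbl), collapse = " | ")
  sep <- paste(rep("---", ncol(tbl)), collapse = " | ")
  rows <- apply(tbl, 1, function(r) paste(r, collapse = " | "))
  c(paste("|", header, "|"), paste("|", sep, "|"), paste("|", rows, "|"))
}

#' Load a pipeline configuration from YAML
#'
#' Reads a configuration written by [run_pipeline()] (or by hand in the
#' same layout) and revalidates every field through [sim_config()] and
#' [pipeline_config()].
#'
#' @param path YAML file with a `sim` block plus the threshold fields of
#'   [pipeline_config()].
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$sim)) {
    abort_config(sprintf("configuration %s lacks a 'sim' block", path))
  }
  sim_args <- raw$sim
  sim_args$chrom_sizes <- unlist(sim_args$chrom_sizes)
  known_sim <- intersect(names(sim_args), names(formals(sim_config)))
  sim <- do.call(sim_config, sim_args[known_sim])
  top <- raw[setdiff(names(raw), "sim")]
  known_top <- intersect(names(top), names(formals(pipeline_config)))
  do.call(pipeline_config, c(list(sim = sim), top[known_top]))
}
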