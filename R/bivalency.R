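#' Call mark positivity at promoters against the genome background
#'
#' A promoter is positive for a mark in a condition when its window mean
#' RPGC is at least `min_fold` times the genome-wide median RPGC of that
#' track. The rule is deliberately simple and config-exposed; the threshold
#' used is recorded as an attribute.
#'
#' @param promoter_quant Tibble from [summarize_regions()] on promoter
#'   windows (`region_id`, `mean_rpgc`).
#' @param genome_median Genome-wide median RPGC of the same track (see
#'   [track_median()]).
#' @param min_fold Positivity fold over the median (default 2).
#' @return Tibble: `gene_id`, `mean_rpgc`, `positive`.
#' @export
call_k4_positive <- function(promoter_quant, genome_median, min_fold = 2) {
  if (!is.finite(genome_median) || genome_median <= 0) {
    abort_config("degenerate track: genome median RPGC is zero or non-finite")
  }
  out <- as_tibble(promoter_quant) |>
    transmute(
      gene_id = .data$region_id,
      mean_rpgc = .data$mean_rpgc,
      positive = .data$mean_rpgc >= min_fold * genome_median
    )
  attr(out, "threshold") <- min_fold * genome_median
  attr(out, "min_fold") <- min_fold
  out
}

#' Assign promoters to the five bivalency classes
#'
#' Every promoter receives exactly one class from its H3K4me3 positivity in
#' the two states, its H3K27me3 positivity, and the differential H3K27me3
#' test between states:
#' * `k4_negative` - H3K4me3-negative in both states (regardless of
#'   H3K27me3);
#' * `naive_bivalent` - K4-positive, H3K27me3 significantly higher in naive
#'   (`padj < alpha`, fold > `fc_threshold`) and K27-positive in naive;
#' * `primed_bivalent` - the mirror image;
#' * `common_bivalent` - K4-positive, K27-positive in both states with no
#'   significant state difference;
#' * `k4_only` - K4-positive without promoter H3K27me3.
#' The rules are evaluated in this order, so classes partition the promoter
#' set.
#'
#' @param flags Tibble with `gene_id` and logical columns `k4_naive`,
#'   `k4_primed`, `k27_naive`, `k27_primed` (positivity calls per state).
#' @param k27_diff Differential H3K27me3 result at promoters with `log2fc`
#'   oriented naive over primed (`feature`, `log2fc`, `padj`).
#' @param alpha,fc_threshold Significance thresholds (defaults 0.05 and
#'   1.5).
#' @return Tibble of class `promoter_classes`: flags plus `log2fc`, `padj`,
#'   `class`.
#' @export
classify_promoters <- function(flags, k27_diff, alpha = 0.05,
                               fc_threshold = 1.5) {
  flags <- as_tibble(flags)
  need <- c("gene_id", "k4_naive", "k4_primed", "k27_naive", "k27_primed")
  if (!all(need %in% names(flags))) {
    abort_data(paste("flags must carry columns:", paste(need, collapse = ", ")))
  }
  missing <- setdiff(flags$gene_id, k27_diff$feature)
  if (length(missing) > 0) {
    warn(sprintf(
      "%d promoter(s) lack a differential H3K27me3 row and are omitted (first: %s)",
      length(missing), missing[1]
    ))
    flags <- filter(flags, !.data$gene_id %in% missing)
  }
  lfc_cut <- log2(fc_threshold)
  out <- flags |>
    inner_join(
      select(as_tibble(k27_diff), "feature", "log2fc", "padj"),
      by = c(gene_id = "feature")
    ) |>
    mutate(
      sig = !is.na(.data$padj) & .data$padj < alpha & abs(.data$log2fc) > lfc_cut,
      class = dplyr::case_when(
        !.data$k4_naive & !.data$k4_primed ~ "k4_negative",
        .data$sig & .data$log2fc > 0 & .data$k27_naive ~ "naive_bivalent",
        .data$sig & .data$log2fc < 0 & .data$k27_primed ~ "primed_bivalent",
        .data$k27_naive & .data$k27_primed ~ "common_bivalent",
        TRUE ~ "k4_only"
      )
    ) |>
    select(-"sig")
  class(out) <- c("promoter_classes", class(out))
  attr(out, "alpha") <- alpha
  attr(out, "fc_threshold") <- fc_threshold
  out
}

status_from_diff <- function(diff, alpha, fc_threshold) {
  sig <- call_significant(diff, alpha = alpha, fc_threshold = fc_threshold)
  as_tibble(sig) |>
    transmute(
      feature = .data$feature,
      status = dplyr::case_when(
        .data$significant_up ~ "up",
        .data$significant_down ~ "down",
        TRUE ~ "stable"
      )
    )
}

#' Cross-tabulate H3K4me3 and H3K27me3 switches between states
#'
#' Classifies every promoter as up/down/stable for each mark (naive over
#' primed) and counts the nine combinations, keeping example gene ids per
#' cell.
#'
#' @param k4_diff,k27_diff Differential results at promoters (naive vs
#'   primed) for the two marks.
#' @param promoters Optional character vector restricting the promoter set
#'   (e.g. bivalent promoters only).
#' @param alpha,fc_threshold Thresholds for [call_significant()] (defaults
#'   0.05, 1.5).
#' @param n_examples Gene ids retained per cell (default 5).
#' @return List of class `switch_table`: `counts` (tibble `k4_status`,
#'   `k27_status`, `n`, `examples`) and `per_gene` (tibble `feature`,
#'   `k4_status`, `k27_status`).
#' @export
class_switch_table <- function(k4_diff, k27_diff, promoters = NULL,
                               alpha = 0.05, fc_threshold = 1.5,
                               n_examples = 5L) {
  k4 <- status_from_diff(k4_diff, alpha, fc_threshold)
  k27 <- status_from_diff(k27_diff, alpha, fc_threshold)
  per_gene <- inner_join(k4, k27,
    by = "feature",
    suffix = c("_k4", "_k27")
  ) |>
    rename(k4_status = "status_k4", k27_status = "status_k27")
  if (!is.null(promoters)) {
    per_gene <- filter(per_gene, .data$feature %in% promoters)
  }
  counts <- per_gene |>
    group_by(.data$k4_status, .data$k27_status) |>
    summarise(
      n = dplyr::n(),
      examples = paste(utils::head(.data$feature, n_examples), collapse = ","),
      .groups = "drop"
    )
  structure(list(counts = counts, per_gene = per_gene), class = "switch_table")
}

#' @export
print.switch_table <- function(x, ...) {
  cat(sprintf("<switch_table> %d promoters\n", nrow(x$per_gene)))
  print(x$counts)
  invisible(x)
}

#' Class-stratified transcriptional response to H3K27me3 loss
#'
#' Calls derepressed genes from an RNA differential result (EZH2i vs
#' untreated; significant up at `alpha` and `fc_threshold`), computes
#' per-class Wilcoxon/Cohen's d response statistics of the log2 fold-change
#' distributions against all genes, and reports the fraction of derepressed
#' genes whose promoter carries H3K27me3.
#'
#' @param rna_diff Differential expression result (`feature`, `log2fc`,
#'   `padj`).
#' @param classes A [classify_promoters()] table (or tibble `gene_id`,
#'   `class`).
#' @param k27_flags Tibble `gene_id`, `k27_pos` (logical: promoter
#'   H3K27me3-positive).
#' @param alpha,fc_threshold Thresholds (defaults 0.05 and 2, the RNA rule
#'   FDR < 5 percent, |log2FC| > 1).
#' @return List of class `derepression_result`: `class_response` (tibble,
#'   one row per non-empty class), `derepressed` / `repressed` (gene id
#'   vectors), `n_up`, `n_down`, `frac_k27_positive`.
#' @export
derepression_analysis <- function(rna_diff, classes, k27_flags,
                                  alpha = 0.05, fc_threshold = 2) {
  sig <- call_significant(rna_diff, alpha = alpha, fc_threshold = fc_threshold)
  derepressed <- sig$feature[sig$significant_up]
  repressed <- sig$feature[sig$significant_down]
  lfc <- setNames(rna_diff$log2fc, rna_diff$feature)

  cls_tbl <- as_tibble(classes)
  responses <- list()
  for (cl in unique(cls_tbl$class)) {
    members <- cls_tbl$gene_id[cls_tbl$class == cl]
    members <- intersect(members, names(lfc)[is.finite(lfc)])
    if (length(members) == 0) {
      warn(sprintf("class '%s' empty after filtering; response omitted", cl))
      next
    }
    responses[[cl]] <- class_response(lfc, members, label = cl)
  }
  frac <- NA_real_
  if (length(derepressed) > 0 && !is.null(k27_flags)) {
    k27 <- as_tibble(k27_flags)
    frac <- mean(k27$k27_pos[match(derepressed, k27$gene_id)], na.rm = TRUE)
  }
  structure(
    list(
      class_response = bind_rows(responses),
      derepressed = derepressed, repressed = repressed,
      n_up = length(derepressed), n_down = length(repressed),
      frac_k27_positive = frac
    ),
    class = "derepression_result"
  )
}

#' @export
print.derepression_result <- function(x, ...) {
  cat(sprintf(
    "<derepression_result> %d up, %d down; %.1f%% of upregulated genes have K27-marked promoters\n",
    x$n_up, x$n_down, 100 * x$frac_k27_positive
  ))
  print(x$class_response)
  invisible(x)
}

#' H2Aub fold-change at derepressed genes, by promoter stratum
#'
#' Summarizes the distribution of promoter H2Aub fold changes (EZH2i vs
#' untreated) over derepressed genes, stratified into bivalent versus
#' H3K27me3-devoid promoters.
#'
#' @param h2aub_diff Differential H2Aub result at promoters (`feature`,
#'   `log2fc`).
#' @param derepressed Character vector of derepressed gene ids (must be
#'   non-empty).
#' @param strata Tibble `gene_id`, `stratum` (e.g. "bivalent",
#'   "k27_devoid").
#' @return Tibble: `stratum`, `n`, `median_fold`, `q25_fold`, `q75_fold`,
#'   `median_loss_pct` (100 x (1 - median fold)). Empty strata are omitted
#'   with a warning.
#' @export
h2aub_change_at_derepressed <- function(h2aub_diff, derepressed, strata) {
  if (length(derepressed) == 0) {
    abort_data("derepressed gene set is empty")
  }
  tbl <- as_tibble(strata) |>
    filter(.data$gene_id %in% derepressed) |>
    inner_join(
      select(as_tibble(h2aub_diff), "feature", "log2fc"),
      by = c(gene_id = "feature")
    ) |>
    filter(is.finite(.data$log2fc))
  empty <- setdiff(unique(strata$stratum), unique(tbl$stratum))
  if (length(empty) > 0) {
    warn(paste("strata with no derepressed genes omitted:", paste(empty, collapse = ", ")))
  }
  tbl |>
    group_by(.data$stratum) |>
    summarise(
      n = dplyr::n(),
      median_fold = 2^median(.data$log2fc),
      q25_fold = 2^unname(quantile(.data$log2fc, 0.25)),
      q75_fold = 2^unname(quantile(.data$log2fc, 0.75)),
      .groups = "drop"
    ) |>
    mutate(median_loss_pct = 100 * (1 - .data$median_fold))
}
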