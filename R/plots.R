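#' Plot global levels by condition
#'
#' Bar chart of the INRC-derived global levels (relative to the reference
#' condition) per sample, one panel per mark when a `mark` column is
#' present.
#'
#' @param table Tidy scale-factor tibble (from [tidy()] on a
#'   [compute_scale_factors()] result, or several bound together) with
#'   `condition`, `global_level` and optionally `mark`.
#' @return A ggplot object.
#' @export
plot_global_levels <- function(table) {
  p <- ggplot2::ggplot(
    table,
    ggplot2::aes(x = .data$condition, y = .data$global_level)
  ) +
    ggplot2::stat_summary(fun = mean, geom = "col", fill = "grey70") +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = NULL, y = "global level (relative to reference)",
      title = "Global levels by condition"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if ("mark" %in% names(table)) {
    p <- p + ggplot2::facet_wrap(~mark, scales = "free_y")
  }
  p
}

#' @describeIn build_scaled_track Coverage plot of a scaled track (one line
#'   per chromosome, RPGC units).
#' @param object A `scaled_track`.
#' @param ... Unused.
#' @method autoplot scaled_track
#' @export
autoplot.scaled_track <- function(object, ...) {
  tbl <- as_tibble(object)
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$start, y = .data$score)) +
    ggplot2::geom_step(linewidth = 0.2) +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::labs(
      x = "position (bp)", y = "RPGC",
      title = object$sample_id %||% "scaled track"
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn nb_wald_test Volcano plot of a differential result.
#' @param object An `nb_diff` tibble.
#' @param ... Unused.
#' @method autoplot nb_diff
#' @export
autoplot.nb_diff <- function(object, ...) {
  tbl <- tidy(object) |> filter(!is.na(.data$padj))
  ggplot2::ggplot(
    tbl,
    ggplot2::aes(x = .data$log2fc, y = -log10(pmax(.data$padj, 1e-300)))
  ) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::labs(
      x = "log2 fold change", y = "-log10 adjusted p",
      title = sprintf(
        "%s vs %s", attr(object, "condition_b") %||% "B",
        attr(object, "condition_a") %||% "A"
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot class-stratified response statistics
#'
#' @param response Tibble from [class_response()] rows (e.g. the
#'   `class_response` element of [derepression_analysis()]).
#' @return A ggplot object showing Cohen's d per class.
#' @export
plot_class_response <- function(response) {
  ggplot2::ggplot(
    response,
    ggplot2::aes(x = .data$class, y = .data$cohens_d)
  ) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(
      x = NULL, y = "Cohen's d vs all genes",
      title = "Class-stratified transcriptional response"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot per-chromosome signal shares
#'
#' @param summary A [chromosome_stats()] result.
#' @return A ggplot object: share of total signal per chromosome.
#' @export
plot_chromosome_shares <- function(summary) {
  ggplot2::ggplot(
    summary$table,
    ggplot2::aes(x = .data$chrom, y = .data$share)
  ) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::labs(
      x = NULL, y = "share of total signal",
      title = "Chromosome share of integrated signal"
    ) +
    ggplot2::theme_minimal()
}
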