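#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method tidy scale_factors
#' @export
tidy.scale_factors <- function(x, ...) x$table

#' @method glance scale_factors
#' @export
glance.scale_factors <- function(x, ...) {
  tibble(
    reference = x$reference, reference_inrc = x$reference_inrc,
    genome_size = x$genome_size, fragment_length = x$fragment_length,
    n_samples = nrow(x$table)
  )
}

#' @method tidy nb_diff
#' @export
tidy.nb_diff <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "nb_diff")
  as_tibble(out)
}

#' @method glance nb_diff
#' @export
glance.nb_diff <- function(x, ...) {
  tibble(
    n_features = nrow(x),
    n_tested = sum(!is.na(x$pvalue)),
    n_up = if ("significant_up" %in% names(x)) sum(x$significant_up) else NA_integer_,
    n_down = if ("significant_down" %in% names(x)) sum(x$significant_down) else NA_integer_,
    median_log2fc = median(x$log2fc[is.finite(x$log2fc)]),
    condition_a = attr(x, "condition_a") %||% NA_character_,
    condition_b = attr(x, "condition_b") %||% NA_character_
  )
}

#' @method tidy dedup_result
#' @export
tidy.dedup_result <- function(x, ...) x$stats

#' @method glance dedup_result
#' @export
glance.dedup_result <- function(x, ...) {
  tibble(
    n_samples = nrow(x$stats),
    total = sum(x$stats$total),
    unique_molecules = sum(x$stats$unique_molecules),
    duplicates = sum(x$stats$duplicates),
    duplicate_rate = sum(x$stats$duplicates) / max(1, sum(x$stats$total))
  )
}

#' @method tidy promoter_classes
#' @export
tidy.promoter_classes <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "promoter_classes")
  as_tibble(out)
}

#' @method glance promoter_classes
#' @export
glance.promoter_classes <- function(x, ...) {
  counts <- table(factor(x$class, levels = PROMOTER_CLASSES))
  bind_cols(
    tibble(n_promoters = nrow(x)),
    as_tibble(as.list(counts))
  )
}

#' @method tidy chrom_summary
#' @export
tidy.chrom_summary <- function(x, ...) x$table

#' @method glance chrom_summary
#' @export
glance.chrom_summary <- function(x, ...) {
  tibble(
    n_chromosomes = nrow(x$table),
    x_over_autosome_density = x$x_over_autosome_density,
    x_share = x$x_share
  )
}

#' @method tidy switch_table
#' @export
tidy.switch_table <- function(x, ...) x$counts

#' @method tidy marker_gate
#' @export
tidy.marker_gate <- function(x, ...) x$per_sample

#' @method glance marker_gate
#' @export
glance.marker_gate <- function(x, ...) {
  tibble(threshold = x$threshold, control_mean = x$control_mean)
}

#' @method tidy pseudotime_gate
#' @export
tidy.pseudotime_gate <- function(x, ...) x$per_treatment

#' @method glance pseudotime_gate
#' @export
glance.pseudotime_gate <- function(x, ...) {
  tibble(threshold = x$threshold, n_cells = nrow(x$cells))
}

#' @method tidy derepression_result
#' @export
tidy.derepression_result <- function(x, ...) x$class_response

#' @method glance derepression_result
#' @export
glance.derepression_result <- function(x, ...) {
  tibble(
    n_up = x$n_up, n_down = x$n_down,
    frac_k27_positive = x$frac_k27_positive
  )
}
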