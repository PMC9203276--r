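#' Control-anchored marker-positivity gate
#'
#' An object (nucleus/cell) is called marker-positive when its mean
#' intensity is strictly above `factor` times the mean intensity of the
#' matching control objects. The gate is scale-invariant: multiplying every
#' intensity (controls included) by a positive constant leaves the calls
#' unchanged.
#'
#' @param table Tibble with one row per object: an intensity column, a
#'   `sample` label and a logical `is_control` flag.
#' @param channel Name of the intensity column (default "intensity").
#' @param factor Threshold multiplier over the control mean (default 1.5).
#' @return List of class `marker_gate`: `objects` (input plus `positive`),
#'   `per_sample` (tibble `sample`, `n`, `n_positive`, `percent_positive`),
#'   `threshold`, `control_mean`.
#' @examples
#' tbl <- tibble::tibble(
#'   sample = rep(c("ctrl", "trt"), each = 3),
#'   is_control = rep(c(TRUE, FALSE), each = 3),
#'   intensity = c(90, 100, 110, 140, 151, 200)
#' )
#' gate_marker_positive(tbl)$per_sample
#' @export
gate_marker_positive <- function(table, channel = "intensity", factor = 1.5) {
  table <- as_tibble(table)
  if (!channel %in% names(table)) {
    abort_data(sprintf("intensity column '%s' not found", channel))
  }
  if (!any(table$is_control)) {
    abort_config("no control objects: the gate threshold is anchored on the matching control sample")
  }
  control_mean <- mean(table[[channel]][table$is_control])
  threshold <- factor * control_mean
  table$positive <- table[[channel]] > threshold # strictly above
  per_sample <- table |>
    group_by(.data$sample) |>
    summarise(
      n = dplyr::n(),
      n_positive = sum(.data$positive),
      percent_positive = 100 * mean(.data$positive),
      .groups = "drop"
    )
  structure(
    list(
      objects = table, per_sample = per_sample,
      threshold = threshold, control_mean = control_mean
    ),
    class = "marker_gate"
  )
}

#' Ground-state gate by control pseudotime quantile
#'
#' Sets the threshold at the `q` quantile (linear interpolation between
#' order statistics) of the control cells' pseudotime; cells strictly below
#' it are labelled `ground`, all others `activated`. By construction about a
#' fraction `q` of control cells is labelled ground.
#'
#' @param table Tibble with `pseudotime` and `treatment` columns.
#' @param control_label Value of `treatment` identifying control cells.
#' @param q Control quantile (default 0.95, i.e. the assumption that 95
#'   percent of untreated cells are in the ground state).
#' @return List of class `pseudotime_gate`: `cells` (input plus `state`),
#'   `threshold`, `per_treatment` (tibble `treatment`, `n`,
#'   `fraction_ground`).
#' @export
gate_ground_state <- function(table, control_label, q = 0.95) {
  if (q <= 0 || q >= 1) {
    abort_config("q must lie strictly between 0 and 1")
  }
  table <- as_tibble(table)
  ctrl <- table$pseudotime[table$treatment == control_label]
  if (length(ctrl) == 0) {
    abort_config(sprintf("no control cells with treatment '%s'", control_label))
  }
  if (any(!is.finite(table$pseudotime)) || any(table$pseudotime < 0)) {
    abort_data("pseudotime values must be finite and non-negative")
  }
  threshold <- unname(quantile(ctrl, q, type = 7))
  table$state <- ifelse(table$pseudotime < threshold, "ground", "activated")
  per_treatment <- table |>
    group_by(.data$treatment) |>
    summarise(
      n = dplyr::n(),
      fraction_ground = mean(.data$state == "ground"),
      .groups = "drop"
    )
  structure(
    list(cells = table, threshold = threshold, per_treatment = per_treatment),
    class = "pseudotime_gate"
  )
}

#' Split activated cells by trajectory branch
#'
#' Refines the ground/activated split into four labels: ground cells are
#' `gELC`; activated cells still on the pre-bifurcation branch are `aELC`;
#' activated cells past the bifurcation become `TaELC`
#' (trophectoderm-activated) or `MaELC` (mesoderm-activated) by branch.
#' Activated cells without a branch label are flagged `unclassified`.
#'
#' @param table Tibble with `pseudotime` and `branch` columns; `branch`
#'   takes values `pre_bifurcation`, `trophectoderm`, `mesoderm` (NA
#'   allowed below the threshold).
#' @param threshold Pseudotime threshold from [gate_ground_state()].
#' @return The table with a `label` column in
#'   `{gELC, aELC, TaELC, MaELC, unclassified}`.
#' @export
split_activated <- function(table, threshold) {
  table <- as_tibble(table)
  table$label <- dplyr::case_when(
    table$pseudotime < threshold ~ "gELC",
    table$branch == "pre_bifurcation" ~ "aELC",
    table$branch == "trophectoderm" ~ "TaELC",
    table$branch == "mesoderm" ~ "MaELC",
    TRUE ~ "unclassified"
  )
  n_un <- sum(table$label == "unclassified")
  if (n_un > 0) {
    warn(sprintf("%d activated cell(s) lack a branch label; flagged unclassified", n_un))
  }
  table
}
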