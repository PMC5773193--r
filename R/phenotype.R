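#' Normalized microcephaly index
#'
#' The head-diameter-to-body-length ratio of each animal, normalized by the
#' mean ratio of a designated control group (uninjected or wildtype), so
#' the control group has mean index 1 and the index is invariant to any
#' common magnification of the measurements.
#'
#' @param records Tibble with `animal_id`, `group`, `head_diameter`,
#'   `body_length` (same arbitrary units within a study).
#' @param control_group Name of the control group used for normalization.
#' @return The input tibble with added columns `ratio` and `mi`.
#' @export
#' @examples
#' rec <- tibble::tibble(
#'   animal_id = c("c1", "c2", "t1"),
#'   group = c("control", "control", "ko"),
#'   head_diameter = c(0.25, 0.25, 0.23),
#'   body_length = c(1, 1, 1)
#' )
#' microcephaly_index(rec, "control")
microcephaly_index <- function(records, control_group) {
  need <- c("animal_id", "group", "head_diameter", "body_length")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    abort(sprintf("phenotype table missing column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  if (any(records$head_diameter <= 0) || any(records$body_length <= 0)) {
    abort("head_diameter and body_length must be positive")
  }
  if (any(records$head_diameter >= records$body_length)) {
    abort("head_diameter must be smaller than body_length")
  }
  ctrl <- records$group == control_group
  if (!any(ctrl)) {
    abort(sprintf("control group '%s' has no records", control_group))
  }
  records |>
    mutate(
      ratio = .data$head_diameter / .data$body_length,
      mi = .data$ratio / mean(.data$ratio[.data$group == control_group])
    )
}

#' Per-group microcephaly index summary
#'
#' @param records Output of [microcephaly_index()].
#' @return Tibble per group: `n`, `median_mi` (midpoint convention for even
#'   group sizes), `mean_mi`.
#' @export
mi_group_summary <- function(records) {
  if (!"mi" %in% names(records)) {
    abort("records lack an 'mi' column; run microcephaly_index() first")
  }
  records |>
    group_by(.data$group) |>
    summarise(n = n(), median_mi = median(.data$mi),
              mean_mi = mean(.data$mi), .groups = "drop")
}
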