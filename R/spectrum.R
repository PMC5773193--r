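#' Per-animal indel size fractions
#'
#' For each target, the fraction of mutated reads that carry at least one
#' in-window indel of each signed size (negative = deletion length,
#' positive = insertion length). The denominator is the animal's mutated
#' reads for that target; because a read can carry several distinct indels
#' (one per size counted), fractions across sizes may sum to more than 1.
#' Also totals in-window indel events by kind for the deletion/insertion
#' split.
#'
#' @param events Output of [window_indel_events()] for one animal.
#' @param classified Output of [classify_reads()] for the same reads.
#' @return Tibble per target: `target_id`, nested `size_fractions`
#'   (`size`, `n_reads_with`, `fraction`), `n_mutated_reads`,
#'   `n_del_events`, `n_ins_events`. Targets with zero mutated reads get an
#'   empty `size_fractions` table.
#' @export
indel_size_fractions <- function(events, classified) {
  mutated <- classified |>
    filter(.data$status == "mutated") |>
    group_by(.data$target_id) |>
    summarise(n_mutated_reads = sum(.data$count), .groups = "drop")

  all_targets <- classified |> distinct(.data$target_id)

  per_size <- events |>
    distinct(.data$target_id, .data$read_id, .data$count, .data$size) |>
    group_by(.data$target_id, .data$size) |>
    summarise(n_reads_with = sum(.data$count), .groups = "drop")

  ev_counts <- events |>
    group_by(.data$target_id) |>
    summarise(
      n_del_events = sum(.data$count[.data$kind == "deletion"]),
      n_ins_events = sum(.data$count[.data$kind == "insertion"]),
      .groups = "drop"
    )

  all_targets |>
    left_join(mutated, by = "target_id") |>
    mutate(n_mutated_reads = ifelse(is.na(.data$n_mutated_reads), 0L,
                                    .data$n_mutated_reads)) |>
    left_join(ev_counts, by = "target_id") |>
    mutate(
      n_del_events = ifelse(is.na(.data$n_del_events), 0L, .data$n_del_events),
      n_ins_events = ifelse(is.na(.data$n_ins_events), 0L, .data$n_ins_events),
      size_fractions = map2(.data$target_id, .data$n_mutated_reads, function(tid, nmut) {
        sz <- per_size |> filter(.data$target_id == tid)
        if (!nrow(sz) || nmut == 0L) return(empty_size_fractions())
        tibble(size = sz$size, n_reads_with = sz$n_reads_with,
               fraction = sz$n_reads_with / nmut) |>
          arrange(.data$size)
      })
    ) |>
    select("target_id", "size_fractions", "n_mutated_reads",
           "n_del_events", "n_ins_events")
}

#' Cohort indel profile per sgRNA target
#'
#' Averages each animal's per-size indel fractions over the cohort (animals
#' with zero mutated reads for a target contribute nothing to that target's
#' mean — a fraction of zero reads is undefined) and computes the
#' event-level deletion/insertion split over all animals' in-window events.
#' The most frequent indel (`top_indel`) is the size with the largest mean
#' fraction; ties break toward smaller absolute size, deletions before
#' insertions.
#'
#' @param cohort_quant Per-animal quantification table carrying `animal_id`,
#'   `target_id`, nested `size_fractions` and `n_del_events`/`n_ins_events`
#'   columns, e.g. rows of [quantify_sample()] bound over animals or the
#'   `quant` table of [quantify_cohort()].
#' @return An object of class `indel_profile`: a tibble per target with
#'   nested `size_frequencies` (`size`, `mean_frequency`, `n_animals`),
#'   `deletion_fraction`, `insertion_fraction`, `top_indel_size`,
#'   `top_indel_frequency` and `n_animals` (animals with mutated reads).
#' @export
indel_profile <- function(cohort_quant) {
  need <- c("animal_id", "target_id", "size_fractions")
  miss <- setdiff(need, names(cohort_quant))
  if (length(miss)) {
    abort(sprintf("cohort table missing column(s): %s", paste(miss, collapse = ", ")))
  }
  if (!nrow(cohort_quant)) abort("empty cohort")

  long <- cohort_quant |>
    select("animal_id", "target_id", "size_fractions") |>
    tidyr::unnest("size_fractions")

  contributing <- cohort_quant |>
    filter(map_int(.data$size_fractions, nrow) > 0L |
             .data$n_mutated_reads > 0L) |>
    group_by(.data$target_id) |>
    summarise(n_animals = dplyr::n_distinct(.data$animal_id), .groups = "drop")

  freq <- long |>
    group_by(.data$target_id, .data$size) |>
    summarise(sum_fraction = sum(.data$fraction),
              n_with = dplyr::n(), .groups = "drop") |>
    left_join(contributing, by = "target_id") |>
    mutate(mean_frequency = .data$sum_fraction / .data$n_animals)

  splits <- cohort_quant |>
    group_by(.data$target_id) |>
    summarise(n_del = sum(.data$n_del_events), n_ins = sum(.data$n_ins_events),
              .groups = "drop") |>
    mutate(
      deletion_fraction = ifelse(.data$n_del + .data$n_ins > 0,
                                 .data$n_del / (.data$n_del + .data$n_ins), NA_real_),
      insertion_fraction = ifelse(.data$n_del + .data$n_ins > 0,
                                  .data$n_ins / (.data$n_del + .data$n_ins), NA_real_)
    )

  targets <- unique(cohort_quant$target_id)
  res <- tibble(target_id = targets) |>
    mutate(
      size_frequencies = map(.data$target_id, function(tid) {
        f <- freq |> filter(.data$target_id == tid)
        tibble(size = f$size, mean_frequency = f$mean_frequency,
               n_animals_with = f$n_with) |>
          arrange(.data$size)
      }),
      top = map(.data$size_frequencies, top_indel),
      top_indel_size = map_int(.data$top, "size"),
      top_indel_frequency = map_dbl(.data$top, "frequency")
    ) |>
    select(-"top") |>
    left_join(splits |> select("target_id", "deletion_fraction",
                               "insertion_fraction"),
              by = "target_id") |>
    left_join(contributing, by = "target_id")
  class(res) <- c("indel_profile", class(res))
  res
}

# argmax of mean frequency; ties -> smaller |size|, deletions before insertions
top_indel <- function(size_freq) {
  if (!nrow(size_freq)) {
    return(list(size = NA_integer_, frequency = NA_real_))
  }
  o <- order(-size_freq$mean_frequency, abs(size_freq$size), size_freq$size)
  list(size = size_freq$size[o[1]], frequency = size_freq$mean_frequency[o[1]])
}

#' Cohort deletion/insertion split for one target
#'
#' Event-level split of all in-window indel events across a cohort's
#' mutated reads.
#'
#' @param events Bound [window_indel_events()] tables over animals.
#' @return Tibble per target: `n_events`, `deletion_fraction`,
#'   `insertion_fraction` (NA when no events).
#' @export
deletion_insertion_split <- function(events) {
  events |>
    group_by(.data$target_id) |>
    summarise(
      n_events = sum(.data$count),
      deletion_fraction = sum(.data$count[.data$kind == "deletion"]) / sum(.data$count),
      insertion_fraction = sum(.data$count[.data$kind == "insertion"]) / sum(.data$count),
      .groups = "drop"
    )
}

#' Plot a cohort indel profile
#'
#' Bar chart of mean per-size indel frequency (deletions negative, to the
#' left; insertions positive), faceted by target, with the top indel marked.
#'
#' @param object An `indel_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.indel_profile <- function(object, ...) {
  long <- as_tibble(object) |>
    select("target_id", "size_frequencies") |>
    tidyr::unnest("size_frequencies")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$size, y = .data$mean_frequency,
                                     fill = .data$size < 0)) +
    ggplot2::geom_col(show.legend = TRUE) +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "#D55E00", `FALSE` = "#0072B2"),
      labels = c(`TRUE` = "deletion", `FALSE` = "insertion"),
      name = NULL
    ) +
    ggplot2::facet_wrap(~target_id) +
    ggplot2::labs(x = "indel size (bp deleted < 0 < bp inserted)",
                  y = "mean fraction of mutated reads") +
    ggplot2::theme_minimal()
}
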