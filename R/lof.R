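#' Probability of at least one mutation on each allele
#'
#' In a mosaic diploid F0 animal the fraction of wildtype alleles at sgRNA
#' `r`'s locus estimates the probability `q_r` that a given allele carries
#' no mutation there. The product of the `q_r` over a pooled sgRNA panel is
#' the probability an allele is wildtype at every targeted locus, so
#'
#' \deqn{P(M) = \left(1 - \prod_r q_r\right)^2}
#'
#' is the probability that each of the two alleles carries at least one
#' mutation. With a single sgRNA this reduces to `(1 - q)^2`.
#'
#' @param q Numeric vector of per-sgRNA wildtype fractions, one element per
#'   sgRNA in the pool (length 1 for a single sgRNA).
#' @return `P(M)`, a probability in `[0, 1]`.
#' @export
#' @examples
#' p_mut(c(0.5, 0.4, 0.2))  # 0.9216
#' p_mut(0.204)             # single sgRNA, ~0.6336
p_mut <- function(q) {
  if (!length(q)) abort("need at least one wildtype fraction")
  q <- assert_probability(q, "wildtype fraction q")
  (1 - prod(q))^2
}

#' Probability of at least one frameshift mutation on each allele
#'
#' The non-frameshift fraction at sgRNA `r`'s locus is `q_r + im_r + nm_r`
#' (wildtype, in-frame-mutated and non-coding-mutated alleles). Then
#'
#' \deqn{P(F) = \left(1 - \prod_r (q_r + im_r + nm_r)\right)^2.}
#'
#' @param q,im,nm Equal-length numeric vectors of per-sgRNA wildtype,
#'   in-frame and non-coding fractions (of all alleles/reads, so that
#'   `q + fs + im + nm = 1`).
#' @return `P(F)`, a probability in `[0, 1]`.
#' @export
#' @examples
#' p_fs(0.9, 0.05, 0.02)  # (1 - 0.97)^2 = 9e-04
p_fs <- function(q, im, nm) {
  if (!length(q)) abort("need at least one wildtype fraction")
  if (length(im) != length(q) || length(nm) != length(q)) {
    abort("q, im and nm must have equal length")
  }
  q <- assert_probability(q, "wildtype fraction q")
  im <- assert_probability(im, "in-frame fraction im")
  nm <- assert_probability(nm, "non-coding fraction nm")
  s <- q + im + nm
  if (any(s > 1 + 1e-9)) {
    abort("q + im + nm exceeds 1 for at least one sgRNA")
  }
  (1 - prod(pmin(s, 1)))^2
}

#' Per-animal biallelic loss-of-function estimates
#'
#' Applies the [p_mut()] / [p_fs()] model to a per-animal per-target
#' fraction table, producing one single-sgRNA estimate per target
#' (`scope = target_id`) and one pooled estimate over the animal's full
#' panel (`scope = "pooled"`). The pooled estimate is marked unavailable
#' (`NA`) for animals where any panel target lacks sufficient coverage.
#'
#' @param quant Tibble with columns `animal_id`, `target_id`, `q`, `im`,
#'   `nm` (e.g. from [quantify_cohort()] or read from a fraction TSV).
#'   `NA` fractions mean insufficient coverage.
#' @return An object of class `lof_estimate`: a tibble `animal_id`, `scope`,
#'   `p_mut`, `p_fs` with per-target and pooled rows.
#' @export
estimate_lof <- function(quant) {
  need <- c("animal_id", "target_id", "q", "im", "nm")
  miss <- setdiff(need, names(quant))
  if (length(miss)) {
    abort(sprintf("fraction table missing column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  est <- quant |>
    group_by(.data$animal_id) |>
    dplyr::group_modify(function(df, key) {
      singles <- df |>
        mutate(
          scope = .data$target_id,
          p_mut = map_dbl(seq_len(n()), function(i) {
            if (is.na(df$q[i])) NA_real_ else p_mut(df$q[i])
          }),
          p_fs = map_dbl(seq_len(n()), function(i) {
            if (is.na(df$q[i])) NA_real_ else p_fs(df$q[i], df$im[i], df$nm[i])
          })
        ) |>
        select("scope", "p_mut", "p_fs")
      pooled <- tibble(
        scope = "pooled",
        p_mut = if (anyNA(df$q)) NA_real_ else p_mut(df$q),
        p_fs = if (anyNA(df$q) || anyNA(df$im) || anyNA(df$nm)) NA_real_ else
          p_fs(df$q, df$im, df$nm)
      )
      bind_rows(pooled, singles)
    }) |>
    ungroup()
  class(est) <- c("lof_estimate", class(est))
  est
}

#' Cohort medians of loss-of-function estimates
#'
#' Medians over animals per scope (each target and the pooled panel), using
#' the midpoint convention for even cohort sizes; animals with unavailable
#' estimates are excluded per scope. Percent columns are rounded to one
#' decimal, the convention used for reporting; full-precision proportions
#' are retained alongside.
#'
#' @param estimates A `lof_estimate` (or any tibble with `animal_id`,
#'   `scope`, `p_mut`, `p_fs`).
#' @return Tibble per scope: `n_animals`, `median_p_mut`, `median_p_fs`,
#'   `median_p_mut_pct`, `median_p_fs_pct`.
#' @export
cohort_lof_summary <- function(estimates) {
  if (!nrow(estimates)) abort("empty cohort")
  as_tibble(estimates) |>
    group_by(.data$scope) |>
    summarise(
      n_animals = sum(!is.na(.data$p_mut)),
      median_p_mut = median(.data$p_mut, na.rm = TRUE),
      median_p_fs = median(.data$p_fs, na.rm = TRUE),
      .groups = "drop"
    ) |>
    mutate(median_p_mut_pct = percent1(.data$median_p_mut),
           median_p_fs_pct = percent1(.data$median_p_fs))
}

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @importFrom generics glance
generics::glance

#' Tidy a loss-of-function estimate
#'
#' @param x A `lof_estimate`.
#' @param ... Unused.
#' @return The per-animal estimate tibble.
#' @exportS3Method generics::tidy
tidy.lof_estimate <- function(x, ...) {
  as_tibble(x)
}

#' One-row-per-scope summary of a loss-of-function estimate
#'
#' @param x A `lof_estimate`.
#' @param ... Unused.
#' @return Cohort medians per scope, see [cohort_lof_summary()].
#' @exportS3Method generics::glance
glance.lof_estimate <- function(x, ...) {
  cohort_lof_summary(x)
}

#' Plot per-animal loss-of-function estimates
#'
#' Jittered per-animal probabilities with the cohort median, per scope.
#'
#' @param object A `lof_estimate`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.lof_estimate <- function(object, ...) {
  long <- as_tibble(object) |>
    tidyr::pivot_longer(c("p_mut", "p_fs"), names_to = "measure",
                        values_to = "probability") |>
    filter(!is.na(.data$probability))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$scope, y = .data$probability)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.4, size = 0.8) +
    ggplot2::stat_summary(fun = median, geom = "crossbar",
                          width = 0.5, linewidth = 0.3, color = "#D55E00") +
    ggplot2::facet_wrap(~measure,
                        labeller = ggplot2::as_labeller(
                          c(p_mut = "P(M): mutation on each allele",
                            p_fs = "P(F): frameshift on each allele"))) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "probability") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
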