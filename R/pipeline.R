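#' Quantify a whole cohort from a sample sheet
#'
#' Runs alignment, event calling, classification and quantification for
#' every animal in a sample sheet, then derives per-animal loss-of-function
#' estimates and the cohort indel profile. Animals whose FASTQ cannot be
#' read are skipped with a warning rather than failing the cohort.
#'
#' @param sample_sheet Tibble with `animal_id`, `amplicon_id`, `fastq_path`
#'   (or an in-memory `reads` list-column of read tibbles).
#' @param amplicons Amplicon table.
#' @param targets Validated target table.
#' @param coding Coding interval table.
#' @param min_reads,min_identity,... Passed to [quantify_sample()].
#' @return A list of class `crispant_cohort`: `quant` (per animal/target
#'   fractions with nested size fractions), `lof` (a `lof_estimate`),
#'   `lof_summary` (cohort medians), `profile` (an `indel_profile`).
#' @export
quantify_cohort <- function(sample_sheet, amplicons, targets, coding,
                            min_reads = 100L, min_identity = 0.60, ...) {
  if (!nrow(sample_sheet)) abort("no samples in sample sheet")
  has_reads <- "reads" %in% names(sample_sheet)
  if (!has_reads && !"fastq_path" %in% names(sample_sheet)) {
    abort("sample sheet needs a fastq_path (or reads) column")
  }
  out <- vector("list", nrow(sample_sheet))
  for (i in seq_len(nrow(sample_sheet))) {
    row <- sample_sheet[i, ]
    amp <- amplicons |> filter(.data$amplicon_id == row$amplicon_id)
    if (!nrow(amp)) {
      abort(sprintf("sample sheet references unknown amplicon_id %s",
                    row$amplicon_id))
    }
    tg <- targets |> filter(.data$amplicon_id == row$amplicon_id)
    cod <- coding |> filter(.data$amplicon_id == row$amplicon_id)
    reads <- tryCatch(
      if (has_reads) row$reads[[1]] else read_fastq(row$fastq_path),
      error = function(e) {
        warn(sprintf("skipping %s / %s: %s", row$animal_id,
                     row$amplicon_id, conditionMessage(e)))
        NULL
      }
    )
    if (is.null(reads)) next
    out[[i]] <- quantify_sample(reads, amp, tg, cod,
                                min_reads = min_reads,
                                min_identity = min_identity, ...) |>
      mutate(animal_id = row$animal_id, amplicon_id = row$amplicon_id,
             .before = 1)
  }
  quant <- bind_rows(out)
  if (!nrow(quant)) abort("no sample could be quantified")
  lof <- estimate_lof(quant)
  res <- list(
    quant = quant,
    lof = lof,
    lof_summary = cohort_lof_summary(lof),
    profile = indel_profile(quant)
  )
  class(res) <- "crispant_cohort"
  res
}

#' Run the quantification pipeline from a configuration
#'
#' File-to-file entry point: reads the amplicon FASTA, target TSV, coding
#' BED and sample sheet named in `config`, quantifies the cohort and writes
#' per-animal fractions, loss-of-function estimates, cohort medians and
#' indel profiles as TSV, plus a JSON run-metadata file (parameters,
#' package version, input checksums).
#'
#' @param config Named list (or path to a YAML file) with entries
#'   `amplicons`, `targets`, `coding`, `sample_sheet` (input paths) and
#'   optionally `window_halfwidth`, `min_reads`, `min_identity`, alignment
#'   scores `match`, `mismatch`, `gap_open`, `gap_extend`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the `crispant_cohort`.
#' @export
run_quantify <- function(config, out_dir) {
  cfg <- load_config(config)
  for (f in c("amplicons", "targets", "coding", "sample_sheet")) {
    if (is.null(cfg[[f]])) abort(sprintf("config entry '%s' is required", f))
    if (!file.exists(cfg[[f]])) {
      abort(sprintf("input file for '%s' not found: %s", f, cfg[[f]]))
    }
  }
  amplicons <- read_amplicons(cfg$amplicons)
  coding <- read_coding_bed(cfg$coding, amplicons)
  targets <- validate_targets(read_targets(cfg$targets), amplicons,
                              window_halfwidth = cfg$window_halfwidth %||% 5L)
  sheet <- readr::read_tsv(cfg$sample_sheet, col_types = readr::cols())
  if (!nrow(sheet)) abort("no samples in sample sheet")
  cohort <- quantify_cohort(
    sheet, amplicons, targets, coding,
    min_reads = cfg$min_reads %||% 100L,
    min_identity = cfg$min_identity %||% 0.60,
    match = cfg$match %||% 2, mismatch = cfg$mismatch %||% -4,
    gap_open = cfg$gap_open %||% 10, gap_extend = cfg$gap_extend %||% 1
  )
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(
    cohort$quant |>
      select("animal_id", "target_id", "n_reads", "q", "mutation_rate",
             "fs", "im", "nm", "frameshift_of_mutated"),
    file.path(out_dir, "per_animal_fractions.tsv")
  )
  readr::write_tsv(tidy(cohort$lof), file.path(out_dir, "lof_estimates.tsv"))
  readr::write_tsv(cohort$lof_summary, file.path(out_dir, "lof_cohort_medians.tsv"))
  readr::write_tsv(
    as_tibble(cohort$profile) |>
      select("target_id", "size_frequencies") |>
      tidyr::unnest("size_frequencies"),
    file.path(out_dir, "indel_size_frequencies.tsv")
  )
  readr::write_tsv(
    as_tibble(cohort$profile) |>
      select("target_id", "deletion_fraction", "insertion_fraction",
             "top_indel_size", "top_indel_frequency"),
    file.path(out_dir, "indel_profile_summary.tsv")
  )
  write_run_metadata(cfg, out_dir,
                     inputs = unlist(cfg[c("amplicons", "targets", "coding",
                                           "sample_sheet")]))
  invisible(cohort)
}

#' Run the cohort simulator from a configuration
#'
#' @param config Named list (or YAML path) with `amplicons`, `targets`,
#'   `coding` input paths and optional [simulation_config()] fields under
#'   `simulation`.
#' @param out_dir Output directory for FASTQs, truth tables, sample sheet
#'   and echoed config.
#' @param seed Integer seed; identical seed and config give identical
#'   output files.
#' @return Invisibly, the `crispant_sim`.
#' @export
run_simulate <- function(config, out_dir, seed = 1L) {
  cfg <- load_config(config)
  for (f in c("amplicons", "targets", "coding")) {
    if (is.null(cfg[[f]])) abort(sprintf("config entry '%s' is required", f))
    if (!file.exists(cfg[[f]])) {
      abort(sprintf("input file for '%s' not found: %s", f, cfg[[f]]))
    }
  }
  amplicons <- read_amplicons(cfg$amplicons)
  coding <- read_coding_bed(cfg$coding, amplicons)
  targets <- validate_targets(read_targets(cfg$targets), amplicons,
                              window_halfwidth = cfg$window_halfwidth %||% 5L)
  sim_cfg <- do.call(simulation_config, cfg$simulation %||% list())
  sim <- simulate_cohort(amplicons, targets, coding, sim_cfg,
                         seed = seed, fastq_dir = out_dir)
  write_run_metadata(cfg, out_dir,
                     inputs = unlist(cfg[c("amplicons", "targets", "coding")]),
                     seed = seed)
  invisible(sim)
}

#' Loss-of-function model on a user-supplied fraction table
#'
#' Standalone entry point for the probability model: reads a fraction table
#' (TSV with `animal_id`, `target_id`, `q`, `im`, `nm`) and writes
#' per-animal estimates and cohort medians.
#'
#' @param fraction_table Path to a TSV, or a tibble.
#' @param out_dir Output directory (optional; when `NULL` nothing is
#'   written).
#' @return The `lof_estimate`, invisibly when writing.
#' @export
run_lof <- function(fraction_table, out_dir = NULL) {
  tbl <- if (is.data.frame(fraction_table)) {
    fraction_table
  } else {
    readr::read_tsv(fraction_table, col_types = readr::cols())
  }
  need <- c("animal_id", "target_id", "q", "im", "nm")
  miss <- setdiff(need, names(tbl))
  if (length(miss)) {
    abort(sprintf("fraction table missing column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  for (col in c("q", "im", "nm")) {
    bad <- which(!is.na(tbl[[col]]) & (tbl[[col]] < 0 | tbl[[col]] > 1))
    if (length(bad)) {
      abort(sprintf("column %s outside [0, 1] at row %d", col, bad[1]))
    }
  }
  est <- estimate_lof(tbl)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(tidy(est), file.path(out_dir, "lof_estimates.tsv"))
    readr::write_tsv(cohort_lof_summary(est),
                     file.path(out_dir, "lof_cohort_medians.tsv"))
    return(invisible(est))
  }
  est
}

#' Microcephaly index on a measurement CSV
#'
#' @param measurements Path to a CSV with `animal_id`, `group`,
#'   `head_diameter`, `body_length`, or a tibble.
#' @param control_group Control group used for normalization.
#' @param out_dir Output directory (optional).
#' @return Tibble with `mi` column; written with a per-group summary when
#'   `out_dir` is given.
#' @export
run_phenotype <- function(measurements, control_group, out_dir = NULL) {
  tbl <- if (is.data.frame(measurements)) {
    measurements
  } else {
    readr::read_csv(measurements, col_types = readr::cols())
  }
  rec <- microcephaly_index(tbl, control_group)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(rec, file.path(out_dir, "microcephaly_index.csv"))
    readr::write_csv(mi_group_summary(rec),
                     file.path(out_dir, "microcephaly_summary.csv"))
    return(invisible(rec))
  }
  rec
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    yaml::read_yaml(config)
  } else if (is.list(config)) {
    config
  } else {
    abort("config must be a named list or a YAML path")
  }
}

write_run_metadata <- function(cfg, out_dir, inputs, seed = NULL) {
  meta <- list(
    package = "crispant",
    version = as.character(packageVersion("crispant")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = seed,
    parameters = cfg[setdiff(names(cfg), c("amplicons", "targets", "coding",
                                           "sample_sheet"))],
    inputs = lapply(as.list(inputs), function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(meta)
}
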