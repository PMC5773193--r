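#' Configuration for a simulated mosaic F0 cohort
#'
#' Captures the generative model of a multi-sgRNA injected cohort:
#' per-animal editing rates with broad inter-animal spread, deletion-biased
#' indel spectra with a recurrent locus-specific (MMEJ-like) deletion of
#' highly variable per-animal weight, a small founder-allele pool per animal
#' (editing happens in the first cleavage stages, so few distinct alleles
#' arise) with Dirichlet frequencies, and substitution-only Illumina-like
#' sequencing errors.
#'
#' @param n_animals Animals in the cohort (default 96, one deep-sequencing
#'   plate).
#' @param reads_per_animal Reads simulated per animal per amplicon
#'   (default 2000).
#' @param editing_rate Per-target editing probability theta. Either a fixed
#'   number in `[0, 1]`, or a length-2 vector of Beta shape parameters from
#'   which theta is drawn per animal and target (default `c(5, 2)`, mean
#'   0.71 with wide spread, emulating observed 0-100% per-animal
#'   mutagenesis). May also be a named list keyed by `target_id`.
#' @param deletion_prob Probability an edit is a deletion (default 0.8,
#'   the ~4:1 deletion:insertion bias of Cas9 repair outcomes).
#' @param deletion_size_prob,deletion_size_max Truncated geometric deletion
#'   length distribution on `1..deletion_size_max` (defaults 0.2 and 30).
#' @param insertion_size_prob Geometric insertion length, mode 1
#'   (default 0.6).
#' @param recurrent_size Length of the privileged (microhomology-mediated)
#'   deletion per target (default 3); scalar or named vector by `target_id`.
#' @param recurrent_weight_shape,recurrent_weight_max Per-animal weight of
#'   the recurrent deletion among deletions:
#'   `recurrent_weight_max * Beta(shape[1], shape[2])`, spanning ~0-0.8
#'   (defaults `c(1, 2)` and 0.8).
#' @param n_founder_alleles Distinct founder alleles per animal per
#'   amplicon (default 4), with `Dirichlet(1, ..., 1)` frequencies.
#' @param substitution_error Per-base substitution error rate applied to
#'   reads (default 0.002); never introduces indels.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_animals = 96L,
                              reads_per_animal = 2000L,
                              editing_rate = c(5, 2),
                              deletion_prob = 0.8,
                              deletion_size_prob = 0.2,
                              deletion_size_max = 30L,
                              insertion_size_prob = 0.6,
                              recurrent_size = 3L,
                              recurrent_weight_shape = c(1, 2),
                              recurrent_weight_max = 0.8,
                              n_founder_alleles = 4L,
                              substitution_error = 0.002) {
  stopifnot(
    n_animals >= 1L, reads_per_animal >= 1L,
    deletion_prob >= 0, deletion_prob <= 1,
    deletion_size_prob > 0, deletion_size_prob <= 1,
    deletion_size_max >= 1L,
    insertion_size_prob > 0, insertion_size_prob <= 1,
    all(unlist(recurrent_size) >= 1L),
    length(recurrent_weight_shape) == 2L, all(recurrent_weight_shape > 0),
    recurrent_weight_max >= 0, recurrent_weight_max <= 1,
    n_founder_alleles >= 1L,
    substitution_error >= 0, substitution_error < 1
  )
  check_rate <- function(er) {
    if (is.numeric(er) && length(er) == 1L) {
      if (er < 0 || er > 1) abort("fixed editing rate must lie in [0, 1]")
    } else if (is.numeric(er) && length(er) == 2L) {
      if (any(er <= 0)) abort("Beta shape parameters must be positive")
    } else {
      abort("editing_rate must be a fixed rate or two Beta shape parameters")
    }
  }
  if (is.list(editing_rate)) lapply(editing_rate, check_rate) else check_rate(editing_rate)
  structure(
    list(
      n_animals = as.integer(n_animals),
      reads_per_animal = as.integer(reads_per_animal),
      editing_rate = editing_rate,
      deletion_prob = deletion_prob,
      deletion_size_prob = deletion_size_prob,
      deletion_size_max = as.integer(deletion_size_max),
      insertion_size_prob = insertion_size_prob,
      recurrent_size = recurrent_size,
      recurrent_weight_shape = recurrent_weight_shape,
      recurrent_weight_max = recurrent_weight_max,
      n_founder_alleles = as.integer(n_founder_alleles),
      substitution_error = substitution_error
    ),
    class = "simulation_config"
  )
}

per_target_param <- function(param, target_id) {
  if (is.list(param) || (length(param) > 1L && !is.null(names(param)))) {
    if (!target_id %in% names(param)) {
      abort(sprintf("no simulation parameter for target %s", target_id))
    }
    param[[target_id]]
  } else {
    param
  }
}

draw_theta <- function(editing_rate, target_id) {
  er <- per_target_param(editing_rate, target_id)
  if (length(er) == 1L) er else rbeta(1, er[1], er[2])
}

#' Simulate the founder allele pool of one animal
#'
#' Draws `n_founder_alleles` alleles: each target edits an allele with
#' probability `theta` (a deletion overlapping the cut with probability
#' `deletion_prob`, else an insertion anchored at the cut); deletion sizes
#' come from the recurrent MMEJ size with the animal's recurrent weight,
#' otherwise from a truncated geometric. Allele frequencies are
#' `Dirichlet(1, ..., 1)`. Exact per-target truth fractions are computed by
#' classifying each allele's (left-normalized) events with the same
#' window/coding rules the pipeline applies to reads.
#'
#' @param amplicon One-row amplicon table.
#' @param targets Validated targets on this amplicon.
#' @param coding Coding intervals for this amplicon.
#' @param config A [simulation_config()].
#' @param theta Named per-target editing rates for this animal (drawn by
#'   the caller so the truth is reportable).
#' @param recurrent_weight Named per-target recurrent-deletion weights.
#' @return List with `alleles` (tibble `allele_id`, `frequency`, `sequence`,
#'   nested `events`) and `truth` (tibble per target: `q`, `fs`, `im`,
#'   `nm`).
#' @export
simulate_allele_pool <- function(amplicon, targets, coding, config,
                                 theta, recurrent_weight) {
  K <- config$n_founder_alleles
  ref <- amplicon$sequence
  len <- nchar(ref)
  alleles <- vector("list", K)
  for (k in seq_len(K)) {
    events <- empty_events()
    for (t in seq_len(nrow(targets))) {
      tg <- targets[t, ]
      if (runif(1) >= theta[[tg$target_id]]) next
      ev <- draw_edit(tg, config, recurrent_weight[[tg$target_id]], len)
      if (overlaps_any(ev, events)) next  # keep events disjoint; rare
      events <- bind_rows(events, ev)
    }
    events <- left_align_events(events, ref)
    alleles[[k]] <- tibble(
      allele_id = sprintf("allele_%d", k),
      sequence = apply_events(ref, events),
      events = list(events)
    )
  }
  pool <- bind_rows(alleles)
  w <- rgamma(K, shape = 1)
  pool$frequency <- w / sum(w)

  truth <- map(seq_len(nrow(targets)), function(t) {
    tg <- targets[t, ]
    cls <- bind_rows(map(pool$events, classify_read_for_target,
                         window_start = tg$window_start,
                         window_end = tg$window_end, coding = coding))
    tibble(
      target_id = tg$target_id,
      q = sum(pool$frequency[cls$status == "unmodified"]),
      fs = sum(pool$frequency[cls$status == "mutated" &
                                cls$category == "frameshift"]),
      im = sum(pool$frequency[cls$status == "mutated" &
                                cls$category == "inframe"]),
      nm = sum(pool$frequency[cls$status == "mutated" &
                                cls$category == "noncoding"])
    )
  }) |> bind_rows()
  list(alleles = pool |> select("allele_id", "frequency", "sequence", "events"),
       truth = truth)
}

empty_events <- function() {
  tibble(kind = character(), ref_start = integer(),
         length = integer(), alt = character())
}

draw_edit <- function(tg, config, rec_weight, amplicon_length) {
  if (runif(1) < config$deletion_prob) {
    rec_size <- per_target_param(config$recurrent_size, tg$target_id)
    L <- if (runif(1) < rec_weight) {
      as.integer(rec_size)
    } else {
      trunc_geom(config$deletion_size_prob, config$deletion_size_max)
    }
    # deletion overlaps the cut: start in [cut - L, cut]
    st <- tg$cut_site - sample.int(L + 1L, 1L) + 1L
    st <- max(0L, min(st, amplicon_length - L))
    tibble(kind = "deletion", ref_start = as.integer(st),
           length = L, alt = "")
  } else {
    L <- 1L + rgeom(1, config$insertion_size_prob)
    tibble(kind = "insertion", ref_start = tg$cut_site, length = L,
           alt = paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                       collapse = ""))
  }
}

trunc_geom <- function(p, max_size) {
  repeat {
    L <- 1L + rgeom(1, p)
    if (L <= max_size) return(L)
  }
}

overlaps_any <- function(ev, events) {
  if (!nrow(events)) return(FALSE)
  s1 <- ev$ref_start
  e1 <- s1 + ifelse(ev$kind == "deletion", ev$length, 0L)
  s2 <- events$ref_start
  e2 <- s2 + ifelse(events$kind == "deletion", events$length, 0L)
  any(s1 <= e2 & s2 <= e1)
}

#' Simulate reads from an allele pool
#'
#' Each read samples an allele by frequency and applies i.i.d. substitution
#' errors at the configured per-base rate (never indels). Error-free copies
#' of the same allele are collapsed into one row with a `count`, which the
#' alignment layer understands.
#'
#' @param pool Allele tibble (`allele_id`, `frequency`, `sequence`).
#' @param n_reads Reads to draw.
#' @param error_rate Per-base substitution error rate.
#' @param id_prefix Prefix for generated read ids.
#' @return Read tibble `read_id`, `sequence`, `count`.
#' @export
simulate_reads <- function(pool, n_reads, error_rate = 0.002,
                           id_prefix = "read") {
  counts <- as.vector(rmultinom(1, n_reads, pool$frequency))
  out <- vector("list", nrow(pool))
  for (i in seq_len(nrow(pool))) {
    n_i <- counts[i]
    if (n_i == 0L) next
    seq_i <- pool$sequence[i]
    L <- nchar(seq_i)
    k_err <- if (error_rate > 0) rbinom(n_i, L, error_rate) else integer(n_i)
    rows <- list()
    n0 <- sum(k_err == 0L)
    if (n0 > 0L) {
      rows[[1]] <- tibble(
        read_id = sprintf("%s_%s_clean", id_prefix, pool$allele_id[i]),
        sequence = seq_i, count = n0
      )
    }
    errored <- which(k_err > 0L)
    if (length(errored)) {
      seqs <- character(length(errored))
      for (j in seq_along(errored)) {
        chars <- strsplit(seq_i, "", fixed = TRUE)[[1]]
        pos <- sample.int(L, k_err[errored[j]])
        for (pp in pos) {
          chars[pp] <- sample(setdiff(c("A", "C", "G", "T"), chars[pp]), 1L)
        }
        seqs[j] <- paste(chars, collapse = "")
      }
      rows[[length(rows) + 1L]] <- tibble(
        read_id = sprintf("%s_%s_e%04d", id_prefix, pool$allele_id[i],
                          seq_along(errored)),
        sequence = seqs, count = 1L
      )
    }
    out[[i]] <- bind_rows(rows)
  }
  res <- bind_rows(out)
  if (is.null(res) || !nrow(res)) {
    res <- tibble(read_id = character(), sequence = character(),
                  count = integer())
  }
  res
}

#' Simulate a mosaic F0 cohort with exact ground truth
#'
#' Full generative loop: per animal and amplicon, draw editing rates and
#' recurrent-deletion weights, build a founder allele pool, compute exact
#' expected fractions (`q`, `fs`, `im`, `nm`) and expected `P(M)`/`P(F)`,
#' and sample reads with sequencing errors. Identical `(config, seed)`
#' yield identical output.
#'
#' @param amplicons Amplicon table.
#' @param targets Validated target table ([validate_targets()]).
#' @param coding Coding interval table.
#' @param config A [simulation_config()].
#' @param seed Integer seed controlling every draw.
#' @param fastq_dir If non-`NULL`, write one gzipped FASTQ per animal and
#'   amplicon there, plus `sample_sheet.tsv`, `truth.tsv` and `config.yaml`.
#' @return An object of class `crispant_sim`: list with `truth` (per
#'   animal/target exact fractions, plus `theta` and `recurrent_weight`),
#'   `lof_truth` (exact per-animal `P(M)`/`P(F)`, pooled and single),
#'   `alleles`, `reads` (with `count`), `sample_sheet` (when writing
#'   FASTQs), `config` and `seed`.
#' @export
simulate_cohort <- function(amplicons, targets, coding, config = simulation_config(),
                            seed = 1L, fastq_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (!"cut_site" %in% names(targets)) {
    abort("targets must be validated first (validate_targets)")
  }
  set.seed(as.integer(seed))
  animal_ids <- sprintf("animal_%03d", seq_len(config$n_animals))
  truth <- list(); alleles <- list(); reads <- list()
  for (a in seq_along(animal_ids)) {
    aid <- animal_ids[a]
    for (amp_i in seq_len(nrow(amplicons))) {
      amp <- amplicons[amp_i, ]
      tg_amp <- targets |> filter(.data$amplicon_id == amp$amplicon_id)
      if (!nrow(tg_amp)) next
      cod_amp <- coding |> filter(.data$amplicon_id == amp$amplicon_id)
      theta <- setNames(
        map_dbl(tg_amp$target_id, ~ draw_theta(config$editing_rate, .x)),
        tg_amp$target_id
      )
      rw <- setNames(
        config$recurrent_weight_max *
          rbeta(nrow(tg_amp), config$recurrent_weight_shape[1],
                config$recurrent_weight_shape[2]),
        tg_amp$target_id
      )
      pool <- simulate_allele_pool(amp, tg_amp, cod_amp, config, theta, rw)
      truth[[length(truth) + 1L]] <- pool$truth |>
        mutate(animal_id = aid, amplicon_id = amp$amplicon_id,
               theta = theta[.data$target_id],
               recurrent_weight = rw[.data$target_id], .before = 1)
      alleles[[length(alleles) + 1L]] <- pool$alleles |>
        mutate(animal_id = aid, amplicon_id = amp$amplicon_id, .before = 1)
      rd <- simulate_reads(pool$alleles, config$reads_per_animal,
                           config$substitution_error,
                           id_prefix = sprintf("%s_%s", aid, amp$amplicon_id))
      reads[[length(reads) + 1L]] <- rd |>
        mutate(animal_id = aid, amplicon_id = amp$amplicon_id, .before = 1)
    }
  }
  truth <- bind_rows(truth)
  res <- list(
    truth = truth |>
      select("animal_id", "amplicon_id", "target_id", "theta",
             "recurrent_weight", "q", "fs", "im", "nm"),
    lof_truth = expected_lof(truth),
    alleles = bind_rows(alleles),
    reads = bind_rows(reads),
    config = config,
    seed = as.integer(seed)
  )
  if (!is.null(fastq_dir)) {
    res$sample_sheet <- write_sim_outputs(res, fastq_dir)
  }
  class(res) <- "crispant_sim"
  res
}

#' Exact expected loss-of-function probabilities from simulation truth
#'
#' Applies the closed-form [p_mut()]/[p_fs()] model to the exact truth
#' fractions, the oracle against which pipeline estimates are compared.
#'
#' @param truth Tibble with `animal_id`, `target_id`, `q`, `im`, `nm`.
#' @return Tibble `animal_id`, `scope`, `p_mut`, `p_fs` (pooled + singles).
#' @export
expected_lof <- function(truth) {
  as_tibble(estimate_lof(truth))
}

write_sim_outputs <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sheet <- sim$reads |>
    distinct(.data$animal_id, .data$amplicon_id) |>
    mutate(fastq_path = file.path(
      dir, sprintf("%s_%s.fastq.gz", .data$animal_id, .data$amplicon_id)
    ))
  for (i in seq_len(nrow(sheet))) {
    rd <- sim$reads |>
      filter(.data$animal_id == sheet$animal_id[i],
             .data$amplicon_id == sheet$amplicon_id[i])
    write_reads_fastq(rd, sheet$fastq_path[i])
  }
  readr::write_tsv(sheet, file.path(dir, "sample_sheet.tsv"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  readr::write_tsv(sim$lof_truth, file.path(dir, "lof_truth.tsv"))
  yaml::write_yaml(unclass(sim$config), file.path(dir, "config.yaml"))
  sheet
}

#' Write a read tibble as FASTQ
#'
#' Expands `count`s into individual records with constant qualities.
#'
#' @param reads Read tibble (`read_id`, `sequence`, optional `count`).
#' @param path Output path; `.gz` suffix enables compression.
#' @export
write_reads_fastq <- function(reads, path) {
  if (!"count" %in% names(reads)) reads$count <- 1L
  idx <- rep.int(seq_len(nrow(reads)), reads$count)
  seqs <- Biostrings::DNAStringSet(reads$sequence[idx])
  names(seqs) <- sprintf("%s/%d", reads$read_id[idx],
                         sequence_within(idx))
  quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(seqs)))
  Biostrings::writeXStringSet(seqs, path, format = "fastq",
                              qualities = quals,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

# 1,2,...,k within runs of equal values
sequence_within <- function(idx) {
  if (!length(idx)) return(integer())
  r <- rle(idx)
  unlist(lapply(r$lengths, seq_len), use.names = FALSE)
}
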