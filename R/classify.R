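#' Classify one read's events against one sgRNA target
#'
#' Core window/coding rule. A read is `mutated` for a target iff at least
#' one insertion/deletion event intersects the target's quantification
#' window (deletion: any deleted reference base in `[c-w, c+w)`; insertion:
#' between-base anchor in the closed range `[c-w, c+w]`). Substitutions are
#' typical Illumina/PCR errors and never change status. For mutated reads
#' the net coding shift sums, over in-window indels, `+length` for
#' insertions anchored strictly inside a coding interval and `-overlap` with
#' coding intervals for deletions; the category is `frameshift` when that
#' shift is not a multiple of 3, `inframe` when it is and at least one
#' in-window indel touches coding sequence, and `noncoding` otherwise.
#'
#' @param events Event tibble for one read (`kind`, `ref_start`, `length`,
#'   `alt`).
#' @param window_start,window_end Quantification window `[c-w, c+w)`.
#' @param coding Coding intervals for the read's amplicon: tibble with
#'   `start`, `end` (0-based half-open).
#' @param cov_start,cov_end Reference interval covered by the read's
#'   alignment; if it does not contain the window the status is
#'   `not_covering`.
#' @return A one-row tibble: `status` (`not_covering`/`unmodified`/
#'   `mutated`), `category` (`frameshift`/`inframe`/`noncoding` or `NA`),
#'   `net_coding_shift`.
#' @export
classify_read_for_target <- function(events, window_start, window_end, coding,
                                     cov_start = 0L, cov_end = Inf) {
  if (cov_start > window_start || cov_end < window_end) {
    return(tibble(status = "not_covering", category = NA_character_,
                  net_coding_shift = NA_integer_))
  }
  ev <- window_indels(events, window_start, window_end)
  if (!nrow(ev)) {
    return(tibble(status = "unmodified", category = NA_character_,
                  net_coding_shift = 0L))
  }
  shift <- 0L
  touches <- FALSE
  for (i in seq_len(nrow(ev))) {
    if (ev$kind[i] == "insertion") {
      inside <- any(coding$start < ev$ref_start[i] & ev$ref_start[i] < coding$end)
      if (inside) {
        shift <- shift + ev$length[i]
        touches <- TRUE
      }
    } else {
      ds <- ev$ref_start[i]
      de <- ds + ev$length[i]
      ov <- sum(pmax(0L, pmin(de, coding$end) - pmax(ds, coding$start)))
      if (ov > 0L) {
        shift <- shift - ov
        touches <- TRUE
      }
    }
  }
  category <- if (shift %% 3L != 0L) "frameshift" else if (touches) "inframe" else "noncoding"
  tibble(status = "mutated", category = category,
         net_coding_shift = as.integer(shift))
}

# indel events intersecting the quantification window
window_indels <- function(events, window_start, window_end) {
  if (!nrow(events)) return(events[0, ])
  is_del <- events$kind == "deletion"
  is_ins <- events$kind == "insertion"
  keep <- (is_del &
             events$ref_start < window_end &
             events$ref_start + events$length > window_start) |
          (is_ins &
             events$ref_start >= window_start &
             events$ref_start <= window_end)
  events[keep, ]
}

#' Classify aligned reads against every target on an amplicon
#'
#' @param aligned Output of [align_reads()] for one amplicon's reads.
#' @param targets Validated targets on that amplicon (rows of
#'   [validate_targets()] output).
#' @param coding Coding intervals for that amplicon (`start`, `end`).
#' @return Long tibble: one row per read x target with `read_id`, `count`,
#'   `target_id`, `status`, `category`, `net_coding_shift`. Unalignable
#'   reads are dropped (they belong to no denominator).
#' @export
classify_reads <- function(aligned, targets, coding) {
  usable <- aligned |> filter(.data$aligned)
  out <- vector("list", nrow(targets))
  for (t in seq_len(nrow(targets))) {
    tg <- targets[t, ]
    cls <- pmap(
      list(usable$events, usable$cov_start, usable$cov_end),
      function(ev, cs, ce) {
        classify_read_for_target(ev, tg$window_start, tg$window_end, coding,
                                 cov_start = cs, cov_end = ce)
      }
    )
    out[[t]] <- bind_rows(cls) |>
      mutate(read_id = usable$read_id, count = usable$count,
             target_id = tg$target_id, .before = 1)
  }
  bind_rows(out)
}

#' In-window indel events per read and target
#'
#' Event-level companion to [classify_reads()] used for indel-spectrum
#' profiling: every insertion/deletion event that intersects a target's
#' quantification window, with its signed size (negative = deletion).
#'
#' @inheritParams classify_reads
#' @return Tibble `read_id`, `count`, `target_id`, `kind`, `ref_start`,
#'   `size` (signed).
#' @export
window_indel_events <- function(aligned, targets, coding) {
  usable <- aligned |> filter(.data$aligned)
  out <- vector("list", nrow(targets))
  for (t in seq_len(nrow(targets))) {
    tg <- targets[t, ]
    evs <- map2(usable$events, seq_len(nrow(usable)), function(ev, i) {
      w <- window_indels(ev, tg$window_start, tg$window_end)
      if (!nrow(w)) return(NULL)
      tibble(
        read_id = usable$read_id[i], count = usable$count[i],
        kind = w$kind, ref_start = w$ref_start,
        size = ifelse(w$kind == "deletion", -w$length, w$length)
      )
    })
    ev_tbl <- bind_rows(evs)
    if (nrow(ev_tbl)) ev_tbl$target_id <- tg$target_id
    out[[t]] <- ev_tbl
  }
  res <- bind_rows(out)
  if (!nrow(res)) {
    return(tibble(read_id = character(), count = integer(),
                  target_id = character(), kind = character(),
                  ref_start = integer(), size = integer()))
  }
  res |> select("read_id", "count", "target_id", "kind", "ref_start", "size")
}

#' Per-target allele fractions for one animal
#'
#' Aggregates read classifications into the per-target fractions that feed
#' the loss-of-function model: `q` (unmodified), `fs` (frameshift), `im`
#' (in-frame) and `nm` (non-coding), all as fractions of reads covering the
#' target's window so that `q + fs + im + nm = 1`. Also reports
#' `mutation_rate = 1 - q` and `frameshift_of_mutated = fs / (1 - q)`.
#' Targets with fewer than `min_reads` covering reads are marked
#' insufficient (fractions `NA`) rather than divided to noise.
#'
#' @param classified Output of [classify_reads()].
#' @param min_reads Minimum covering reads per target (default 100).
#' @return Tibble per target: `target_id`, `n_reads`, `q`, `mutation_rate`,
#'   `fs`, `im`, `nm`, `frameshift_of_mutated`, `sufficient`.
#' @export
quantify_reads <- function(classified, min_reads = 100L) {
  classified |>
    group_by(.data$target_id) |>
    summarise(
      n_reads = sum(.data$count[.data$status != "not_covering"]),
      q = frac_of(.data$count, .data$status == "unmodified", .data$status != "not_covering"),
      fs = frac_of(.data$count, .data$status == "mutated" & .data$category == "frameshift",
                   .data$status != "not_covering"),
      im = frac_of(.data$count, .data$status == "mutated" & .data$category == "inframe",
                   .data$status != "not_covering"),
      nm = frac_of(.data$count, .data$status == "mutated" & .data$category == "noncoding",
                   .data$status != "not_covering"),
      .groups = "drop"
    ) |>
    mutate(
      sufficient = .data$n_reads >= min_reads,
      q = ifelse(.data$sufficient, .data$q, NA_real_),
      fs = ifelse(.data$sufficient, .data$fs, NA_real_),
      im = ifelse(.data$sufficient, .data$im, NA_real_),
      nm = ifelse(.data$sufficient, .data$nm, NA_real_),
      mutation_rate = 1 - .data$q,
      frameshift_of_mutated = ifelse(.data$mutation_rate > 0,
                                     .data$fs / .data$mutation_rate, NA_real_)
    ) |>
    select("target_id", "n_reads", "q", "mutation_rate", "fs", "im", "nm",
           "frameshift_of_mutated", "sufficient")
}

frac_of <- function(count, num, den) {
  d <- sum(count[den])
  if (d == 0) return(NA_real_)
  sum(count[num & den]) / d
}

#' Quantify one animal's reads for every target on an amplicon
#'
#' Convenience wrapper chaining [align_reads()], [classify_reads()],
#' [window_indel_events()], [quantify_reads()] and
#' [indel_size_fractions()] for a single animal/amplicon read set.
#'
#' @param reads Read tibble (`read_id`, `sequence`, optional `count`).
#' @param amplicon One-row amplicon table.
#' @param targets Validated targets on this amplicon.
#' @param coding Coding intervals for this amplicon.
#' @param min_reads,min_identity See [quantify_reads()], [align_reads()].
#' @param ... Passed to [align_reads()] (alignment scores).
#' @return Tibble per target as [quantify_reads()], plus nested list-columns
#'   `size_fractions` (per-size fraction of mutated reads) and event totals
#'   `n_del_events`, `n_ins_events`.
#' @export
quantify_sample <- function(reads, amplicon, targets, coding,
                            min_reads = 100L, min_identity = 0.60, ...) {
  aligned <- align_reads(reads, amplicon, min_identity = min_identity, ...)
  classified <- classify_reads(aligned, targets, coding)
  events <- window_indel_events(aligned, targets, coding)
  quant <- quantify_reads(classified, min_reads = min_reads)
  spec <- indel_size_fractions(events, classified)
  quant |>
    left_join(spec, by = "target_id") |>
    mutate(
      size_fractions = map(.data$size_fractions,
                           ~ .x %||% empty_size_fractions()),
      n_mutated_reads = ifelse(is.na(.data$n_mutated_reads), 0L,
                               .data$n_mutated_reads),
      n_del_events = ifelse(is.na(.data$n_del_events), 0L, .data$n_del_events),
      n_ins_events = ifelse(is.na(.data$n_ins_events), 0L, .data$n_ins_events)
    )
}

empty_size_fractions <- function() {
  tibble(size = integer(), n_reads_with = integer(), fraction = double())
}
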