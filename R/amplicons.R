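#' Read amplicon reference sequences from FASTA
#'
#' Loads the amplicon references that deep-sequencing reads will be aligned
#' against. Sequences are uppercased and validated: at least 50 nt and plain
#' A/C/G/T only (amplicons are short PCR products, not draft contigs).
#'
#' @param path Path to a FASTA file; one record per amplicon, the record name
#'   is used as `amplicon_id`.
#' @return A tibble with columns `amplicon_id`, `sequence` and `length`.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">amp1", strrep("ACGT", 20)), fa)
#' read_amplicons(fa)
read_amplicons <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  amplicon_table(names(ss), as.character(ss))
}

#' Build and validate an amplicon table
#'
#' @param amplicon_id Character vector of amplicon names.
#' @param sequence Character vector of reference sequences (A/C/G/T).
#' @return A tibble with columns `amplicon_id`, `sequence`, `length`.
#' @export
amplicon_table <- function(amplicon_id, sequence) {
  sequence <- toupper(sequence)
  if (anyDuplicated(amplicon_id)) {
    abort("duplicated amplicon_id in amplicon table")
  }
  bad_alpha <- grepl("[^ACGT]", sequence)
  if (any(bad_alpha)) {
    abort(sprintf(
      "amplicon sequence(s) contain non-ACGT characters: %s",
      paste(amplicon_id[bad_alpha], collapse = ", ")
    ))
  }
  too_short <- nchar(sequence) < 50L
  if (any(too_short)) {
    abort(sprintf(
      "amplicon(s) shorter than 50 nt: %s",
      paste(amplicon_id[too_short], collapse = ", ")
    ))
  }
  tibble(
    amplicon_id = as.character(amplicon_id),
    sequence = sequence,
    length = nchar(sequence)
  )
}

#' Read coding intervals from BED
#'
#' Coding sequence annotation on each amplicon, used to decide whether an
#' indel shifts the reading frame. BED input uses the amplicon id as the
#' chromosome name; intervals are returned 0-based half-open, per BED.
#'
#' @param path Path to a BED file (`chrom`, `chromStart`, `chromEnd`, ...).
#' @param amplicons Optional amplicon table for bounds checking.
#' @return A tibble with columns `amplicon_id`, `start`, `end` (0-based
#'   half-open), sorted and checked for pairwise disjointness per amplicon.
#' @export
read_coding_bed <- function(path, amplicons = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  coding_table(
    tibble(
      amplicon_id = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,   # back to BED 0-based
      end = GenomicRanges::end(gr)
    ),
    amplicons = amplicons
  )
}

#' Validate a coding-interval table
#'
#' @param coding Tibble with `amplicon_id`, `start`, `end` (0-based half-open).
#' @param amplicons Optional amplicon table for bounds checking.
#' @return The validated, sorted tibble.
#' @export
coding_table <- function(coding, amplicons = NULL) {
  stopifnot(all(c("amplicon_id", "start", "end") %in% names(coding)))
  coding <- coding |>
    mutate(start = as.integer(.data$start), end = as.integer(.data$end)) |>
    arrange(.data$amplicon_id, .data$start)
  if (any(coding$end <= coding$start)) {
    abort("coding intervals must be non-empty (end > start)")
  }
  if (any(coding$start < 0L)) abort("coding intervals must start at >= 0")
  overlap <- coding |>
    group_by(.data$amplicon_id) |>
    summarise(bad = any(.data$start[-1] < .data$end[-n()]), .groups = "drop")
  if (any(overlap$bad)) {
    abort(sprintf(
      "overlapping coding intervals on amplicon(s): %s",
      paste(overlap$amplicon_id[overlap$bad], collapse = ", ")
    ))
  }
  if (!is.null(amplicons)) {
    chk <- coding |> left_join(amplicons, by = "amplicon_id")
    if (any(is.na(chk$length))) {
      abort("coding intervals reference unknown amplicon_id")
    }
    if (any(chk$end > chk$length)) {
      abort("coding interval extends beyond its amplicon")
    }
  }
  coding |> select("amplicon_id", "start", "end")
}

#' Read an sgRNA target table
#'
#' @param path TSV with header columns `target_id`, `amplicon_id`,
#'   `protospacer` (20 nt, 5'->3' on the target strand), `strand` (`+`/`-`)
#'   and `pam_start` (0-based index of the first reference base of the PAM;
#'   for `-`-strand targets the PAM occupies the three reference bases whose
#'   reverse complement reads NGG).
#' @return A tibble of targets (not yet validated against amplicons; see
#'   [validate_targets()]).
#' @export
read_targets <- function(path) {
  tg <- readr::read_tsv(
    path,
    col_types = readr::cols(
      target_id = readr::col_character(),
      amplicon_id = readr::col_character(),
      protospacer = readr::col_character(),
      strand = readr::col_character(),
      pam_start = readr::col_integer(),
      .default = readr::col_guess()
    )
  )
  need <- c("target_id", "amplicon_id", "protospacer", "strand", "pam_start")
  miss <- setdiff(need, names(tg))
  if (length(miss)) {
    abort(sprintf("target table missing column(s): %s", paste(miss, collapse = ", ")))
  }
  tg
}

#' Predicted Cas9 cleavage site
#'
#' SpCas9 cuts between the third and fourth nucleotide upstream of the PAM.
#' With the protospacer occupying reference interval `[s, s + 20)` the cut is
#' the between-base coordinate `s + 17` on the `+` strand and `s + 3` on the
#' `-` strand (mirror image). Expressed via `pam_start`: `pam_start - 3`
#' (`+`) or `pam_start + 6` (`-`).
#'
#' @param pam_start 0-based index of the PAM's first reference base.
#' @param strand `"+"` or `"-"`, vectorized.
#' @return Integer vector of between-base cut coordinates: the cut lies
#'   between reference positions `c - 1` and `c`.
#' @export
#' @examples
#' cleavage_site(30, "+")  # protospacer at [10, 30) -> cut at 27
#' cleavage_site(7, "-")   # protospacer at [10, 30) -> cut at 13
cleavage_site <- function(pam_start, strand) {
  if (!all(strand %in% c("+", "-"))) abort('strand must be "+" or "-"')
  as.integer(ifelse(strand == "+", pam_start - 3L, pam_start + 6L))
}

#' Indel quantification window around a cut site
#'
#' The reference interval within which indels are attributed to CRISPR
#' activity: `[c - w, c + w)`, i.e. `w` bases on each side of the
#' between-base cut `c`. Insertion events are in-window if their between-base
#' anchor lies in the closed range `[c - w, c + w]`.
#'
#' @param cut_site Between-base cut coordinate(s), see [cleavage_site()].
#' @param halfwidth Window half-width `w` in nt (default 5).
#' @param amplicon_length Optional amplicon length(s); if given, a window
#'   extending beyond `[0, length)` is an error (amplicon too short).
#' @return A tibble with columns `window_start`, `window_end` (0-based
#'   half-open).
#' @export
quantification_window <- function(cut_site, halfwidth = 5L, amplicon_length = NULL) {
  halfwidth <- as.integer(halfwidth)
  if (any(halfwidth < 1L)) abort("window halfwidth must be >= 1")
  ws <- as.integer(cut_site) - halfwidth
  we <- as.integer(cut_site) + halfwidth
  if (!is.null(amplicon_length)) {
    bad <- ws < 0L | we > amplicon_length
    if (any(bad)) {
      abort(sprintf(
        "quantification window [%s) outside the amplicon; amplicon too short for this target",
        paste(ws[bad], we[bad], sep = ", ", collapse = "), [")
      ))
    }
  }
  tibble(window_start = ws, window_end = we)
}

#' Validate sgRNA targets against their amplicons
#'
#' Checks that each protospacer matches its amplicon at the location implied
#' by `pam_start` (reverse complement for `-`-strand targets), that the PAM
#' reads NGG on the target strand, and that the derived cut site and
#' quantification window lie within the amplicon. Adds the derived geometry.
#'
#' @param targets Target tibble (see [read_targets()]).
#' @param amplicons Amplicon table (see [read_amplicons()]).
#' @param window_halfwidth Default window half-width for targets that do not
#'   carry their own `window_halfwidth` column.
#' @return The target tibble augmented with `protospacer_start`, `cut_site`,
#'   `window_start`, `window_end` and `window_halfwidth`.
#' @export
validate_targets <- function(targets, amplicons, window_halfwidth = 5L) {
  if (!"window_halfwidth" %in% names(targets)) {
    targets$window_halfwidth <- as.integer(window_halfwidth)
  }
  targets <- targets |>
    mutate(pam_start = as.integer(.data$pam_start),
           protospacer = toupper(.data$protospacer),
           window_halfwidth = as.integer(.data$window_halfwidth))
  if (any(nchar(targets$protospacer) != 20L)) {
    abort("protospacer must be 20 nt")
  }
  tg <- targets |> left_join(amplicons, by = "amplicon_id")
  if (any(is.na(tg$sequence))) {
    abort(sprintf(
      "target(s) reference unknown amplicon_id: %s",
      paste(tg$target_id[is.na(tg$sequence)], collapse = ", ")
    ))
  }
  tg$protospacer_start <- NA_integer_
  for (i in seq_len(nrow(tg))) {
    row <- tg[i, ]
    seq <- row$sequence
    len <- row$length
    if (row$strand == "+") {
      s <- row$pam_start - 20L
      if (s < 0L || row$pam_start + 3L > len) {
        abort(sprintf("target %s: protospacer/PAM outside amplicon", row$target_id))
      }
      pam <- seq_slice(seq, row$pam_start, row$pam_start + 3L)
      if (substr(pam, 2, 3) != "GG") {
        abort(sprintf(
          "target %s: PAM at [%d, %d) reads %s, expected NGG",
          row$target_id, row$pam_start, row$pam_start + 3L, pam
        ))
      }
      obs <- seq_slice(seq, s, s + 20L)
      if (obs != row$protospacer) {
        abort(sprintf(
          "target %s: protospacer does not match amplicon at [%d, %d) (%s vs %s)",
          row$target_id, s, s + 20L, obs, row$protospacer
        ))
      }
    } else {
      s <- row$pam_start + 3L
      if (row$pam_start < 0L || s + 20L > len) {
        abort(sprintf("target %s: protospacer/PAM outside amplicon", row$target_id))
      }
      pam_ref <- seq_slice(seq, row$pam_start, row$pam_start + 3L)
      pam <- revcomp(pam_ref)
      if (substr(pam, 2, 3) != "GG") {
        abort(sprintf(
          "target %s: PAM at [%d, %d) reads %s on the target strand, expected NGG",
          row$target_id, row$pam_start, row$pam_start + 3L, pam
        ))
      }
      obs <- revcomp(seq_slice(seq, s, s + 20L))
      if (obs != row$protospacer) {
        abort(sprintf(
          "target %s: protospacer does not match amplicon at [%d, %d) (revcomp %s vs %s)",
          row$target_id, s, s + 20L, obs, row$protospacer
        ))
      }
    }
    tg$protospacer_start[i] <- s
  }
  tg$cut_site <- cleavage_site(tg$pam_start, tg$strand)
  win <- quantification_window(tg$cut_site, tg$window_halfwidth, tg$length)
  tg |>
    mutate(window_start = win$window_start, window_end = win$window_end) |>
    select(-"sequence", -"length")
}
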