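#' Read amplicon reads from FASTQ
#'
#' @param path FASTQ or gzipped FASTQ file.
#' @return Tibble with `read_id`, `sequence` and a `count` column of 1s
#'   (downstream functions aggregate identical sequences via `count`).
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble(
    read_id = sub(" .*$", "", names(ss)),
    sequence = unname(as.character(ss)),
    count = 1L
  )
}

#' Align reads globally to an amplicon and call mutation events
#'
#' Performs end-to-end (Needleman-Wunsch) alignment with affine gap
#' penalties, then extracts mutation events per read: maximal gap runs become
#' single insertion/deletion events, mismatch columns become length-1
#' substitution events, and indels are left-normalized so that equal-scoring
#' placements (e.g. within homopolymers) are reported at their leftmost
#' reference coordinate. Identical read sequences are dereplicated before
#' alignment and their `count`s summed, so deeply sequenced amplicons with
#' few distinct alleles align quickly.
#'
#' Terminal gap runs in the read (read shorter than the amplicon at either
#' end) are treated as lack of coverage, not as deletions: the covered
#' reference interval `[cov_start, cov_end)` spans the outermost reference
#' bases aligned to read bases.
#'
#' @param reads Tibble with `read_id`, `sequence` and optionally `count`
#'   (defaults to 1 per row).
#' @param amplicon_seq Reference sequence (single string) or a one-row
#'   amplicon table.
#' @param min_identity Minimum aligned identity (matches / alignment
#'   columns); reads below it are flagged `aligned = FALSE` and must be
#'   excluded from every denominator downstream.
#' @param match,mismatch Match score and mismatch penalty.
#' @param gap_open,gap_extend Affine gap penalties (positive numbers).
#' @return Tibble with one row per input read: `read_id`, `count`,
#'   `aligned`, `identity`, `cov_start`, `cov_end` and a nested `events`
#'   list-column of tibbles (`kind`, `ref_start`, `length`, `alt`).
#' @export
align_reads <- function(reads, amplicon_seq, min_identity = 0.60,
                        match = 2, mismatch = -4, gap_open = 10, gap_extend = 1) {
  if (is.data.frame(amplicon_seq)) {
    stopifnot(nrow(amplicon_seq) == 1L)
    amplicon_seq <- amplicon_seq$sequence
  }
  if (!nrow(reads)) {
    return(tibble(
      read_id = character(), count = integer(), aligned = logical(),
      identity = double(), cov_start = integer(), cov_end = integer(),
      events = list()
    ))
  }
  if (!"count" %in% names(reads)) reads$count <- 1L
  if (any(!nzchar(reads$sequence))) abort("empty read sequence")

  uniq <- reads |>
    group_by(sequence = toupper(.data$sequence)) |>
    summarise(u_count = sum(.data$count), .groups = "drop")

  sm <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE
  )
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(uniq$sequence),
    Biostrings::DNAString(amplicon_seq),
    type = "global", substitutionMatrix = sm,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  pat <- as.character(Biostrings::alignedPattern(aln))
  sub <- as.character(Biostrings::alignedSubject(aln))

  parsed <- map2(pat, sub, call_events, ref_seq = amplicon_seq)
  uniq$identity <- map_dbl(parsed, "identity")
  uniq$cov_start <- map_int(parsed, "cov_start")
  uniq$cov_end <- map_int(parsed, "cov_end")
  uniq$events <- map(parsed, "events")
  uniq$aligned <- uniq$identity >= min_identity

  reads |>
    mutate(sequence = toupper(.data$sequence)) |>
    left_join(uniq |> select(-"u_count"), by = "sequence") |>
    select("read_id", "count", "aligned", "identity",
           "cov_start", "cov_end", "events")
}

#' Call mutation events from one pairwise alignment
#'
#' Parses a pair of equal-length gapped strings (read and reference as
#' aligned) into mutation events. Maximal runs of read gaps become one
#' deletion, maximal runs of reference gaps one insertion (anchored at the
#' between-base coordinate of the preceding reference base boundary), and
#' each mismatch column a length-1 substitution; adjacent distinct events
#' are not merged. Indels are then left-normalized against `ref_seq` if
#' supplied. Terminal read-gap runs are reported as non-coverage rather than
#' deletion events.
#'
#' @param pattern_aln,subject_aln Aligned read and reference strings, equal
#'   length, `-` for gaps.
#' @param ref_seq Ungapped reference sequence for left-normalization
#'   (optional but recommended).
#' @return List with `events` (tibble `kind`, `ref_start`, `length`, `alt`),
#'   `identity`, `cov_start`, `cov_end`.
#' @export
call_events <- function(pattern_aln, subject_aln, ref_seq = NULL) {
  p <- strsplit(pattern_aln, "", fixed = TRUE)[[1]]
  s <- strsplit(subject_aln, "", fixed = TRUE)[[1]]
  if (length(p) != length(s)) abort("aligned strings differ in length")
  if (any(p == "-" & s == "-")) abort("double-gap alignment column")

  # 0-based ref coordinate of each column's reference base (NA in insertions)
  ref_pos <- cumsum(s != "-") - 1L
  ref_pos[s == "-"] <- NA_integer_
  # between-base anchor preceding each column
  anchor <- c(0L, cumsum(s != "-"))[seq_along(s)]

  state <- ifelse(p == "-", "D", ifelse(s == "-", "I", ifelse(p == s, "M", "S")))

  # terminal read-gap runs = the read does not reach the amplicon ends
  n <- length(state)
  lead <- 0L
  while (lead < n && state[lead + 1L] == "D") lead <- lead + 1L
  trail <- 0L
  while (trail < n - lead && state[n - trail] == "D") trail <- trail + 1L
  core <- if (n - lead - trail > 0L) (lead + 1L):(n - trail) else integer()

  cov_start <- lead
  cov_end <- sum(s != "-") - trail

  r <- rle(state[core])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ev <- vector("list", length(r$values))
  for (k in seq_along(r$values)) {
    cols <- core[starts[k]:ends[k]]
    val <- r$values[k]
    if (val == "M") next
    if (val == "D") {
      ev[[k]] <- tibble(
        kind = "deletion", ref_start = ref_pos[cols[1]],
        length = length(cols), alt = ""
      )
    } else if (val == "I") {
      ev[[k]] <- tibble(
        kind = "insertion", ref_start = anchor[cols[1]],
        length = length(cols), alt = paste(p[cols], collapse = "")
      )
    } else { # substitutions, one event per column
      ev[[k]] <- tibble(
        kind = "substitution", ref_start = ref_pos[cols],
        length = 1L, alt = p[cols]
      )
    }
  }
  events <- bind_rows(ev)
  if (!nrow(events)) {
    events <- tibble(kind = character(), ref_start = integer(),
                     length = integer(), alt = character())
  }
  events <- events |> mutate(ref_start = as.integer(.data$ref_start),
                             length = as.integer(.data$length))
  if (!is.null(ref_seq) && nrow(events)) {
    events <- left_align_events(events, ref_seq)
  }
  # identity over the covered region: terminal read-gap columns are lack of
  # coverage, they neither help nor hurt
  ncols <- length(core)
  list(
    events = events,
    identity = if (ncols) sum(state == "M") / ncols else 0,
    cov_start = as.integer(cov_start),
    cov_end = as.integer(cov_end)
  )
}

#' Left-normalize indel events
#'
#' Shifts each insertion/deletion to its leftmost equivalent reference
#' placement (VCF-style normalization): a deletion of `ref[s, s+L)` moves one
#' base left while `ref[s-1] == ref[s+L-1]`; an insertion at anchor `a` moves
#' left while `ref[a-1]` equals the last inserted base, rotating the inserted
#' sequence. Substitutions are untouched. Normalization preserves the edited
#' sequence exactly.
#'
#' @param events Event tibble (`kind`, `ref_start`, `length`, `alt`).
#' @param ref_seq Ungapped reference sequence.
#' @return The event tibble with normalized coordinates, sorted by
#'   `ref_start`.
#' @export
left_align_events <- function(events, ref_seq) {
  rc <- strsplit(ref_seq, "", fixed = TRUE)[[1]]
  for (i in seq_len(nrow(events))) {
    kind <- events$kind[i]
    if (kind == "deletion") {
      st <- events$ref_start[i]
      L <- events$length[i]
      while (st > 0L && rc[st] == rc[st + L]) st <- st - 1L  # rc is 1-based
      events$ref_start[i] <- st
    } else if (kind == "insertion") {
      a <- events$ref_start[i]
      alt <- strsplit(events$alt[i], "", fixed = TRUE)[[1]]
      L <- length(alt)
      while (a > 0L && rc[a] == alt[L]) {
        alt <- c(rc[a], alt[-L])
        a <- a - 1L
      }
      events$ref_start[i] <- a
      events$alt[i] <- paste(alt, collapse = "")
    }
  }
  events |> arrange(.data$ref_start, .data$kind)
}

#' Apply mutation events to a reference sequence
#'
#' Reconstructs the read (or allele) sequence implied by a set of events.
#' Used by the simulator to build allele sequences and by tests to check
#' that called events reproduce the read.
#'
#' @param ref_seq Reference sequence.
#' @param events Event tibble (`kind`, `ref_start`, `length`, `alt`).
#' @return The edited sequence (single string).
#' @export
apply_events <- function(ref_seq, events) {
  if (!nrow(events)) return(ref_seq)
  ev <- events |> arrange(dplyr::desc(.data$ref_start))
  out <- ref_seq
  for (i in seq_len(nrow(ev))) {
    st <- ev$ref_start[i]
    if (ev$kind[i] == "deletion") {
      out <- paste0(seq_slice(out, 0L, st), substr(out, st + ev$length[i] + 1L, nchar(out)))
    } else if (ev$kind[i] == "insertion") {
      out <- paste0(seq_slice(out, 0L, st), ev$alt[i], substr(out, st + 1L, nchar(out)))
    } else {
      substr(out, st + 1L, st + 1L) <- ev$alt[i]
    }
  }
  out
}
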