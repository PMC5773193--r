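# Fixtures are built in code: a random amplicon with a planted '+' target,
# a planted '-' target and one coding interval, plus small independent
# oracles used across test files.

# deterministic random DNA
random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc_chr <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "", fixed = TRUE)[[1]]),
                               collapse = ""))
}

# amplicon with '+' target (protospacer [80,100), PAM [100,103)) and
# '-' target (PAM [150,153) reading CCN on the reference), coding [60,200)
make_fixture <- function(seed = 1, len = 240L, coding_start = 60L,
                         coding_end = 200L) {
  seqv <- strsplit(random_dna(len, seed), "", fixed = TRUE)[[1]]
  seqv[101:103] <- c("T", "G", "G")   # 0-based [100,103) = TGG
  seqv[151:153] <- c("C", "C", "A")   # 0-based [150,153); revcomp = TGG
  seq <- paste(seqv, collapse = "")
  amp <- crispant::amplicon_table("amp1", seq)
  coding <- crispant::coding_table(
    tibble::tibble(amplicon_id = "amp1", start = coding_start,
                   end = coding_end), amp)
  targets <- tibble::tibble(
    target_id = c("sg_plus", "sg_minus"),
    amplicon_id = "amp1",
    protospacer = c(substr(seq, 81, 100), rc_chr(substr(seq, 154, 173))),
    strand = c("+", "-"),
    pam_start = c(100L, 150L)
  )
  list(
    amplicon = amp, sequence = seq, coding = coding,
    targets = crispant::validate_targets(targets, amp)
  )
}

# build a read by editing the reference with one tibble of events
read_from_events <- function(ref, events, read_id = "r1") {
  tibble::tibble(read_id = read_id,
                 sequence = crispant::apply_events(ref, events),
                 count = 1L)
}

ev <- function(kind, ref_start, length, alt = "") {
  tibble::tibble(kind = kind, ref_start = as.integer(ref_start),
                 length = as.integer(length), alt = alt)
}

# all deletion start positions of length L whose removal reproduces `read`
# (used to verify leftmost placement among equal-scoring alignments)
deletion_placements <- function(ref, read, L) {
  starts <- integer()
  for (s in 0:(nchar(ref) - L)) {
    cand <- paste0(substr(ref, 1, s), substr(ref, s + L + 1, nchar(ref)))
    if (cand == read) starts <- c(starts, s)
  }
  starts
}

# Independent brute-force classification oracle: a direct, unoptimized
# transcription of the window/coding rules, separate from the package's
# vectorized path.
naive_classify <- function(events, cut, w, coding_start, coding_end) {
  ws <- cut - w; we <- cut + w
  indels <- events[events$kind != "substitution", , drop = FALSE]
  in_win <- logical(nrow(indels))
  for (i in seq_len(nrow(indels))) {
    if (indels$kind[i] == "deletion") {
      del_bases <- indels$ref_start[i]:(indels$ref_start[i] + indels$length[i] - 1L)
      in_win[i] <- any(del_bases >= ws & del_bases < we)
    } else {
      in_win[i] <- indels$ref_start[i] >= ws && indels$ref_start[i] <= we
    }
  }
  if (!any(in_win)) return(list(status = "unmodified", category = NA))
  shift <- 0L; touches <- FALSE
  for (i in which(in_win)) {
    if (indels$kind[i] == "insertion") {
      if (indels$ref_start[i] > coding_start && indels$ref_start[i] < coding_end) {
        shift <- shift + indels$length[i]; touches <- TRUE
      }
    } else {
      del_bases <- indels$ref_start[i]:(indels$ref_start[i] + indels$length[i] - 1L)
      ov <- sum(del_bases >= coding_start & del_bases < coding_end)
      if (ov > 0) { shift <- shift - ov; touches <- TRUE }
    }
  }
  cat_ <- if (shift %% 3L != 0L) "frameshift" else if (touches) "inframe" else "noncoding"
  list(status = "mutated", category = cat_)
}

# write the fixture's amplicon FASTA, target TSV and coding BED into a dir
write_fixture_inputs <- function(fx, dir) {
  fa <- file.path(dir, "amplicons.fa")
  writeLines(c(">amp1", fx$sequence), fa)
  tsv <- file.path(dir, "targets.tsv")
  readr::write_tsv(
    fx$targets[, c("target_id", "amplicon_id", "protospacer", "strand",
                   "pam_start")], tsv)
  bed <- file.path(dir, "coding.bed")
  writeLines(sprintf("%s\t%d\t%d\tcds", fx$coding$amplicon_id,
                     fx$coding$start, fx$coding$end), bed)
  list(amplicons = fa, targets = tsv, coding = bed)
}
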