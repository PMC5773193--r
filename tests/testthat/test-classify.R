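# Window [92, 102) around cut 97 for sg_plus; coding [60, 200) in fixtures.

classify_one <- function(fx, events, target = "sg_plus") {
  tg <- fx$targets[fx$targets$target_id == target, ]
  classify_read_for_target(events, tg$window_start, tg$window_end, fx$coding,
                           cov_start = 0L, cov_end = nchar(fx$sequence))
}

test_that("event-free and substitution-only reads are unmodified", {
  fx <- make_fixture(seed = 51)
  expect_identical(classify_one(fx, ev("deletion", 0, 0)[0, ])$status,
                   "unmodified")
  # substitution inside the window never changes status (SNS rule)
  sns <- ev("substitution", 97, 1, alt = "A")
  expect_identical(classify_one(fx, sns)$status, "unmodified")
})

test_that("in-window indels are categorized by net coding shift", {
  fx <- make_fixture(seed = 52)
  # 1-nt insertion at the cut, inside coding: frameshift (+1)
  ins1 <- classify_one(fx, ev("insertion", 97, 1, alt = "G"))
  expect_identical(ins1$status, "mutated")
  expect_identical(ins1$category, "frameshift")
  expect_identical(ins1$net_coding_shift, 1L)
  # 3-nt deletion fully inside coding at the cut: in-frame
  del3 <- classify_one(fx, ev("deletion", 96, 3))
  expect_identical(del3$category, "inframe")
  expect_identical(del3$net_coding_shift, -3L)
  # 2-nt deletion: frameshift
  expect_identical(classify_one(fx, ev("deletion", 96, 2))$category,
                   "frameshift")
})

test_that("indels outside coding sequence are non-coding mutations", {
  # coding ends before the minus target's window: [151,161) vs coding [60,140)
  fx <- make_fixture(seed = 53, coding_end = 140L)
  del <- classify_one(fx, ev("deletion", 154, 2), target = "sg_minus")
  expect_identical(del$status, "mutated")
  expect_identical(del$category, "noncoding")
  expect_identical(del$net_coding_shift, 0L)
})

test_that("out-of-window indels never set mutated status", {
  fx <- make_fixture(seed = 54)
  far <- classify_one(fx, ev("deletion", 120, 3))
  expect_identical(far$status, "unmodified")
  # deletion ending exactly at window start is out; reaching in is in
  tg <- fx$targets[1, ]
  out_ev <- ev("deletion", tg$window_start - 2L, 2L)
  in_ev <- ev("deletion", tg$window_start - 1L, 2L)
  expect_identical(classify_one(fx, out_ev)$status, "unmodified")
  expect_identical(classify_one(fx, in_ev)$status, "mutated")
  # insertion anchors: the closed range [c-w, c+w] is in-window
  expect_identical(classify_one(fx, ev("insertion", tg$window_end, 1, "A"))$status,
                   "mutated")
  expect_identical(classify_one(fx, ev("insertion", tg$window_end + 1L, 1, "A"))$status,
                   "unmodified")
})

test_that("one large deletion spanning two targets counts as mutated for both", {
  fx <- make_fixture(seed = 55)
  # windows are [92,102) and [151,161): delete [95, 155)
  big <- ev("deletion", 95, 60)
  reads <- read_from_events(fx$sequence, big)
  aln <- align_reads(reads, fx$amplicon)
  cls <- classify_reads(aln, fx$targets, fx$coding)
  expect_identical(cls$status, c("mutated", "mutated"))
  # 60 deleted bases, all coding: net shift -60, in-frame for both targets
  expect_identical(cls$category, c("inframe", "inframe"))
})

test_that("reads not spanning a window are excluded from its denominator", {
  fx <- make_fixture(seed = 56)
  # read covering only the first 120 bases: covers sg_plus, not sg_minus
  short <- tibble::tibble(read_id = "s", sequence = substr(fx$sequence, 1, 120))
  aln <- align_reads(short, fx$amplicon)
  cls <- classify_reads(aln, fx$targets, fx$coding)
  expect_identical(cls$status[cls$target_id == "sg_plus"], "unmodified")
  expect_identical(cls$status[cls$target_id == "sg_minus"], "not_covering")
})

test_that("classification agrees with the brute-force oracle on short amplicons", {
  # <=60-nt core, <=2 events, exhaustive placements (acceptance property)
  set.seed(57)
  ref <- random_dna(60)
  cut <- 30L; w <- 5L
  cs <- 20L; ce <- 45L  # coding [20, 45)
  coding <- tibble::tibble(amplicon_id = "a", start = cs, end = ce)
  cases <- 0L
  for (kind1 in c("deletion", "insertion")) {
    for (st1 in seq(5L, 50L, by = 3L)) {
      for (L1 in c(1L, 2L, 3L)) {
        if (kind1 == "deletion" && st1 + L1 > 60L) next
        e1 <- ev(kind1, st1, L1,
                 alt = if (kind1 == "insertion") strrep("A", L1) else "")
        for (second in c(FALSE, TRUE)) {
          events <- if (second) {
            st2 <- ((st1 + 17L) %% 50L) + 5L
            kind2 <- if (kind1 == "deletion") "insertion" else "deletion"
            if (kind2 == "deletion" && st2 + 2L > 60L) next
            dplyr::bind_rows(e1, ev(kind2, st2, 2L,
                                    alt = if (kind2 == "insertion") "CC" else ""))
          } else e1
          got <- classify_read_for_target(events, cut - w, cut + w, coding)
          want <- naive_classify(events, cut, w, cs, ce)
          expect_identical(got$status, want$status)
          if (got$status == "mutated") {
            expect_identical(got$category, want$category)
          }
          cases <- cases + 1L
        }
      }
    }
  }
  expect_gt(cases, 100)
})

test_that("fractions conserve and match hand counts", {
  fx <- make_fixture(seed = 58)
  ref <- fx$sequence
  mk <- function(events, id, n) {
    read_from_events(ref, events, id) |> dplyr::mutate(count = as.integer(n))
  }
  reads <- dplyr::bind_rows(
    tibble::tibble(read_id = "wt", sequence = ref, count = 4L),
    mk(ev("insertion", 97, 1, "G"), "fs1", 3),   # frameshift
    mk(ev("deletion", 96, 3), "if1", 2),          # in-frame
    mk(ev("deletion", 95, 1), "fs2", 1)           # frameshift
  )
  quant <- quantify_sample(reads, fx$amplicon, fx$targets, fx$coding,
                           min_reads = 5)
  row <- quant[quant$target_id == "sg_plus", ]
  expect_equal(row$q, 0.4)
  expect_equal(row$fs, 0.4)
  expect_equal(row$im, 0.2)
  expect_equal(row$nm, 0.0)
  expect_equal(row$mutation_rate, 0.6)
  expect_equal(row$frameshift_of_mutated, 0.4 / 0.6)
  expect_equal(row$q + row$fs + row$im + row$nm, 1, tolerance = 1e-12)
})

test_that("adding substitution-only reads never changes any fraction", {
  fx <- make_fixture(seed = 59)
  ref <- fx$sequence
  base_reads <- dplyr::bind_rows(
    tibble::tibble(read_id = "wt", sequence = ref, count = 6L),
    read_from_events(ref, ev("deletion", 96, 2), "fs") |>
      dplyr::mutate(count = 4L)
  )
  q0 <- quantify_sample(base_reads, fx$amplicon, fx$targets, fx$coding,
                        min_reads = 5)
  # perturb the wildtype reads with scattered substitutions (incl. in-window)
  seqv <- strsplit(ref, "", fixed = TRUE)[[1]]
  for (pos in c(97L, 40L, 150L)) {
    seqv[pos + 1L] <- setdiff(c("A", "C", "G", "T"), seqv[pos + 1L])[1]
  }
  pert <- dplyr::bind_rows(
    tibble::tibble(read_id = "wt", sequence = ref, count = 3L),
    tibble::tibble(read_id = "wt_sns", sequence = paste(seqv, collapse = ""),
                   count = 3L),
    read_from_events(ref, ev("deletion", 96, 2), "fs") |>
      dplyr::mutate(count = 4L)
  )
  q1 <- quantify_sample(pert, fx$amplicon, fx$targets, fx$coding, min_reads = 5)
  expect_equal(q0$q, q1$q)
  expect_equal(q0$fs, q1$fs)
  expect_equal(q0$im, q1$im)
  expect_equal(q0$nm, q1$nm)
})

test_that("appending a frameshift read never decreases fs nor increases q", {
  fx <- make_fixture(seed = 60)
  ref <- fx$sequence
  reads <- dplyr::bind_rows(
    tibble::tibble(read_id = "wt", sequence = ref, count = 5L),
    read_from_events(ref, ev("deletion", 96, 3), "if") |>
      dplyr::mutate(count = 3L)
  )
  fs_read <- read_from_events(ref, ev("insertion", 97, 1, "T"), "fs")
  q0 <- quantify_sample(reads, fx$amplicon, fx$targets, fx$coding, min_reads = 2)
  for (k in 1:3) {
    reads <- dplyr::bind_rows(reads, fs_read |> dplyr::mutate(read_id = paste0("fs", k)))
    q1 <- quantify_sample(reads, fx$amplicon, fx$targets, fx$coding, min_reads = 2)
    expect_gte(q1$fs[1], q0$fs[1])
    expect_lte(q1$q[1], q0$q[1])
    q0 <- q1
  }
})

test_that("insufficient coverage is marked, never divided", {
  fx <- make_fixture(seed = 61)
  reads <- tibble::tibble(read_id = "only", sequence = fx$sequence, count = 3L)
  quant <- quantify_sample(reads, fx$amplicon, fx$targets, fx$coding,
                           min_reads = 100)
  expect_false(any(quant$sufficient))
  expect_true(all(is.na(quant$q)))
  # zero covering reads must not error
  none <- tibble::tibble(read_id = "short",
                         sequence = substr(fx$sequence, 1, 60), count = 1L)
  quant0 <- quantify_sample(none, fx$amplicon, fx$targets, fx$coding)
  expect_true(all(quant0$n_reads == 0L))
  expect_true(all(is.na(quant0$q)))
})
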