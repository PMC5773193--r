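test_that("simulation is deterministic under a fixed seed", {
  fx <- make_fixture(seed = 101)
  cfg <- simulation_config(n_animals = 3, reads_per_animal = 200)
  s1 <- simulate_cohort(fx$amplicon, fx$targets, fx$coding, cfg, seed = 5)
  s2 <- simulate_cohort(fx$amplicon, fx$targets, fx$coding, cfg, seed = 5)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$reads, s2$reads)
  s3 <- simulate_cohort(fx$amplicon, fx$targets, fx$coding, cfg, seed = 6)
  expect_false(identical(s1$reads, s3$reads))
})

test_that("zero editing rate gives a pure wildtype pool", {
  fx <- make_fixture(seed = 102)
  cfg <- simulation_config(n_animals = 2, reads_per_animal = 100,
                           editing_rate = 0, substitution_error = 0)
  sim <- simulate_cohort(fx$amplicon, fx$targets, fx$coding, cfg, seed = 7)
  expect_true(all(sim$truth$q == 1))
  expect_true(all(sim$reads$sequence == fx$sequence))
  lof <- sim$lof_truth
  expect_true(all(lof$p_mut == 0))
})

test_that("a forced in-frame deletion yields truth q=0, im=1", {
  fx <- make_fixture(seed = 103)
  # editing certain, all deletions recurrent of size 3, inside coding
  cfg <- simulation_config(
    n_animals = 2, reads_per_animal = 100, editing_rate = 1,
    deletion_prob = 1, recurrent_size = 3L,
    recurrent_weight_shape = c(1e6, 1e-6), recurrent_weight_max = 1,
    n_founder_alleles = 1L, substitution_error = 0
  )  # recurrent weight ~ Beta(1e6, 1e-6): every deletion is the -3 allele
  sim <- simulate_cohort(fx$amplicon, fx$targets, fx$coding, cfg, seed = 8)
  expect_true(all(sim$truth$q == 0))
  expect_true(all(sim$truth$im == 1))
  expect_true(all(sim$truth$fs == 0))
  expect_true(all(sim$lof_truth$p_mut == 1))
  expect_true(all(sim$lof_truth$p_fs == 0))
})

test_that("substitution errors appear at the configured rate, never as indels", {
  fx <- make_fixture(seed = 104)
  cfg <- simulation_config(n_animals = 1, reads_per_animal = 4000,
                           editing_rate = 0, substitution_error = 0.002)
  sim <- simulate_cohort(fx$amplicon, fx$targets, fx$coding, cfg, seed = 9)
  expect_true(all(nchar(sim$reads$sequence) == nchar(fx$sequence)))
  # observed mismatch rate within 10% of 0.002 over 4000 x 240 bases
  n_mm <- sum(purrr::map2_int(
    sim$reads$sequence, sim$reads$count,
    function(s, ct) {
      ct * sum(strsplit(s, "")[[1]] != strsplit(fx$sequence, "")[[1]])
    }
  ))
  rate <- n_mm / (4000 * nchar(fx$sequence))
  expect_lt(abs(rate - 0.002), 0.0002)
})

test_that("expected_lof evaluates the closed form on truth fractions", {
  truth <- tibble::tibble(
    animal_id = "a1", target_id = c("sg1", "sg2", "sg3"),
    q = c(0.5, 0.4, 0.2), im = 0, nm = 0
  )
  lof <- expected_lof(truth)
  expect_equal(lof$p_mut[lof$scope == "pooled"], 0.9216)
  all_wt <- tibble::tibble(animal_id = "a1", target_id = "sg1",
                           q = 1, im = 0, nm = 0)
  expect_true(all(expected_lof(all_wt)$p_mut == 0))
})

test_that("the pipeline recovers simulated truth fractions", {
  # full-loop parameter recovery at a fixed mid-range editing rate
  fx <- make_fixture(seed = 105)
  cfg <- simulation_config(
    n_animals = 1, reads_per_animal = 10000, editing_rate = 0.7,
    n_founder_alleles = 6L, substitution_error = 0
  )
  sim <- simulate_cohort(fx$amplicon, fx$targets, fx$coding, cfg, seed = 10)
  quant <- quantify_sample(
    sim$reads |> dplyr::select(read_id, sequence, count),
    fx$amplicon, fx$targets, fx$coding
  )
  cmp <- quant |>
    dplyr::select(target_id, q_est = q, fs_est = fs) |>
    dplyr::left_join(sim$truth, by = "target_id")
  expect_true(all(abs(cmp$q_est - cmp$q) <= 0.02))
  expect_true(all(abs(cmp$fs_est - cmp$fs) <= 0.02))
})

test_that("estimated q is unbiased across editing rates", {
  fx <- make_fixture(seed = 106)
  thetas <- seq(0.1, 0.9, length.out = 10)
  set.seed(11)
  biases <- purrr::map_dbl(seq_along(thetas), function(i) {
    cfg <- simulation_config(n_animals = 1, reads_per_animal = 5000,
                             editing_rate = thetas[i],
                             substitution_error = 0)
    sim <- simulate_cohort(fx$amplicon, fx$targets, fx$coding, cfg,
                           seed = 1000 + i)
    quant <- quantify_sample(
      sim$reads |> dplyr::select(read_id, sequence, count),
      fx$amplicon, fx$targets, fx$coding
    )
    cmp <- quant |>
      dplyr::select(target_id, q_est = q) |>
      dplyr::left_join(sim$truth, by = "target_id")
    mean(cmp$q_est - cmp$q)
  })
  expect_lt(abs(mean(biases)), 0.01)
})

test_that("raising the error rate leaves estimated mutation rates unchanged", {
  fx <- make_fixture(seed = 107)
  est_rate <- function(err, seed) {
    cfg <- simulation_config(n_animals = 1, reads_per_animal = 2000,
                             editing_rate = 0.5, substitution_error = err)
    sim <- simulate_cohort(fx$amplicon, fx$targets, fx$coding, cfg, seed = seed)
    quant <- dplyr::bind_rows(purrr::map(
      unique(sim$reads$animal_id),
      function(a) {
        quantify_sample(
          sim$reads |> dplyr::filter(animal_id == a) |>
            dplyr::select(read_id, sequence, count),
          fx$amplicon, fx$targets, fx$coding
        ) |> dplyr::mutate(animal_id = a)
      }
    ))
    quant |>
      dplyr::left_join(sim$truth |>
                         dplyr::select(animal_id, target_id, q_truth = q),
                       by = c("animal_id", "target_id"))
  }
  # same seed: identical allele pools, only the error layer differs
  clean <- est_rate(0, 12)
  noisy <- est_rate(0.005, 12)
  expect_true(all(abs(noisy$mutation_rate - clean$mutation_rate) < 0.01))
})

test_that("written FASTQ files round-trip and match the sample sheet", {
  fx <- make_fixture(seed = 108)
  cfg <- simulation_config(n_animals = 2, reads_per_animal = 50,
                           substitution_error = 0.002)
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(fx$amplicon, fx$targets, fx$coding, cfg,
                         seed = 13, fastq_dir = dir)
  expect_true(all(file.exists(sim$sample_sheet$fastq_path)))
  expect_true(file.exists(file.path(dir, "truth.tsv")))
  expect_true(file.exists(file.path(dir, "config.yaml")))
  rd <- read_fastq(sim$sample_sheet$fastq_path[1])
  expect_identical(sum(rd$count), 50L)
  in_mem <- sim$reads |>
    dplyr::filter(animal_id == sim$sample_sheet$animal_id[1])
  expect_identical(sort(rep(in_mem$sequence, in_mem$count)),
                   sort(rd$sequence))
})
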