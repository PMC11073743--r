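ref <- ra_reference_params()

test_that("i.i.d. state sampling matches its target distribution", {
  zero <- mem_params(rep(0, 7), matrix(0, 7, 7))
  n <- 128000
  draws <- sample_states_iid(zero, n, seed = 1)
  freq <- tabulate(draws, 128) / n
  se <- sqrt((1 / 128) * (127 / 128) / n)
  expect_lt(max(abs(freq - 1 / 128)), 4 * se)
  # moment matching against exact model moments at the reference parameters
  draws <- sample_states_iid(ref, 1e5, seed = 2)
  emp <- empirical_moments(all_states()[draws, ])
  mm <- model_moments(ref)
  expect_lt(max(abs(emp$first - mm$first)), 3.5 / sqrt(1e5))
  expect_identical(sample_states_iid(ref, 50, seed = 3),
                   sample_states_iid(ref, 50, seed = 3))
  expect_error(sample_states_iid(ref, 0), "positive")
})

test_that("i.i.d. moments converge at the root-n rate", {
  mm <- model_moments(ref)
  for (n in c(500, 8000)) {
    draws <- sample_states_iid(ref, n, seed = 4)
    emp <- empirical_moments(all_states()[draws, ])
    expect_lt(max(abs(emp$first - mm$first)), 4 / sqrt(n))
    expect_lt(max(abs(emp$second - mm$second)), 4 / sqrt(n))
  }
})

test_that("glauber dynamics freeze at zero sweeps and mix at many", {
  frozen <- sample_trajectory_glauber(ref, visits = 12, sweeps = 0, seed = 5)
  expect_equal(nrow(unique(frozen)), 1L)
  # long-run visit marginals approach the exact model moments
  long <- sample_trajectory_glauber(ref, visits = 4000, sweeps = 3, seed = 6)
  mm <- model_moments(ref)
  expect_lt(max(abs(colMeans(long) - mm$first)), 0.06)
})

test_that("the heat-bath conditional satisfies detailed balance", {
  set.seed(7)
  for (i in 1:20) {
    x <- sample(c(-1, 1), 7, TRUE)
    j <- sample.int(7, 1)
    x_up <- x; x_up[j] <- 1
    x_dn <- x; x_dn[j] <- -1
    p_up <- ralandscape:::glauber_p_up(ref, x, j)
    expect_equal(p_up / (1 - p_up),
                 exp(energy(x_dn, ref) - energy(x_up, ref)), tolerance = 1e-12)
  }
})

test_that("raw-value synthesis inverts binarization exactly", {
  set.seed(8)
  for (i in 1:200) {
    spins <- matrix(sample(c(-1L, 1L), 84, TRUE), 12, 7,
                    dimnames = list(NULL, ra_factors()))
    sex <- sample(c("male", "female"), 1)
    raw <- spins_to_raw(spins, sex = sex)
    raw$patient_id <- "P1"; raw$sex <- sex
    expect_equal(binarize_series(raw), spins, ignore_attr = TRUE)
  }
  spins <- matrix(1L, 12, 7, dimnames = list(NULL, ra_factors()))
  raw <- spins_to_raw(spins, sex = "female", seed = 9)
  expect_true(all(raw$STAGE %in% 3:4))
  expect_true(all(raw$RF > 15))
  rem <- spins_to_raw(-spins, sex = "female", seed = 10)
  expect_true(all(rem$RF <= 15 & rem$RF >= 0))
  expect_true(all(rem$SJC28 %in% 0:1))
})

test_that("synthesized HAQ tracks disease burden", {
  all_bad <- matrix(1L, 12, 7)
  all_good <- matrix(-1L, 12, 7)
  expect_equal(synthesize_haq(all_good, noise_sd = 0, increment = 0),
               rep(0.2, 12))
  expect_gt(mean(synthesize_haq(all_bad, seed = 11)),
            mean(synthesize_haq(all_good, seed = 11)))
  set.seed(12)
  spins <- decode_state(sample_states_iid(ref, 500))
  haq <- synthesize_haq(spins, noise_sd = 0.05)
  expect_gt(cor(haq, rowSums(spins == 1)), 0.8)
  expect_true(all(haq >= 0 & haq <= 3))
})

test_that("missingness injection spares the first visit and hits its rate", {
  s <- remission_series()
  expect_identical(inject_missingness(s, 0, 0), s)
  n_miss <- 0; n_cells <- 0
  for (i in 1:60) {
    out <- inject_missingness(s, missing_rate = 0.2, seed = 100 + i)
    expect_false(anyNA(out[1, ]))
    n_miss <- n_miss + sum(is.na(out[-1, ra_factors()]))
    n_cells <- n_cells + length(unlist(out[-1, ra_factors()]))
  }
  expect_lt(abs(n_miss / n_cells - 0.2), 0.02)
  trunc <- inject_missingness(s, truncation_prob = 0.5, seed = 13)
  expect_lt(nrow(trunc), 12L)
  expect_error(inject_missingness(s, missing_rate = 2), "rates")
})

test_that("imputation restores injected gaps at observed points", {
  s <- remission_series()
  s$RF <- seq(2, 24, 2)
  out <- inject_missingness(s, missing_rate = 0.3, truncation_prob = 0.1,
                            seed = 14)
  full <- impute_series(out)
  obs <- !is.na(out$RF)
  expect_equal(full$RF[out$visit[obs]], out$RF[obs])
  expect_equal(nrow(full), 12L)
})

test_that("generated cohorts are reproducible and well-formed", {
  c1 <- generate_cohort(20, mode = "iid", seed = 15, missing_rate = 0.1,
                        truncation_prob = 0.05)
  c2 <- generate_cohort(20, mode = "iid", seed = 15, missing_rate = 0.1,
                        truncation_prob = 0.05)
  expect_identical(c1$cohort, c2$cohort)
  expect_identical(c1$truth$states, c2$truth$states)
  expect_equal(length(unique(c1$cohort$patient_id)), 20L)
  expect_equal(dim(c1$truth$states), c(20L, 12L))
  # every retained raw row binarizes back to the latent state
  g <- generate_cohort(5, mode = "iid", seed = 16)
  for (i in 1:5) {
    id <- sprintf("P%04d", i)
    spins <- binarize_series(g$cohort[g$cohort$patient_id == id, ])
    expect_equal(unname(encode_state(spins)), unname(g$truth$states[i, ]))
  }
})

test_that("clustered cohorts carry their regime ground truth", {
  g <- generate_cohort(12, mode = "clustered", seed = 17)
  expect_equal(levels(g$truth$regime),
               c("toward_good", "toward_poor", "unstable"))
  expect_equal(length(g$truth$regime), 12L)
  ls <- energy_landscape(ref)
  # toward-good patients end in the good basin, toward-poor in the poor one
  final <- g$truth$states[, 12]
  expect_true(mean(ls$basin[final[g$truth$regime == "toward_good"]] == 81) > 0.7)
  expect_true(mean(ls$basin[final[g$truth$regime == "toward_poor"]] == 128) > 0.7)
})

test_that("cohort tables round-trip through the CSV format", {
  g <- generate_cohort(8, mode = "glauber", seed = 18, missing_rate = 0.1)
  path <- tempfile(fileext = ".csv")
  write_cohort(g$cohort, path)
  back <- read_cohort(path)
  expect_equal(back, g$cohort, tolerance = 1e-12)
})
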