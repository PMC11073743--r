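ref <- ra_reference_params()
ref_tab <- ra_reference_state_table()

test_that("parameter validation enforces the model structure", {
  w <- matrix(0, 7, 7); w[1, 2] <- 0.5
  expect_error(mem_params(rep(0, 7), w), "symmetric")
  w2 <- diag(0.1, 7)
  expect_error(mem_params(rep(0, 7), w2), "diagonal")
  expect_error(mem_params(rep(0, 6), matrix(0, 6, 6), factors = ra_factors()),
               "match")
  expect_error(mem_params(c(Inf, rep(0, 6)), matrix(0, 7, 7)), "finite")
})

test_that("energy evaluates the pairwise form", {
  zero <- mem_params(rep(0, 7), matrix(0, 7, 7))
  expect_equal(state_energies(zero), rep(0, 128))
  # independent explicit-loop oracle on random states and parameters
  p <- rand_params(3)
  set.seed(4)
  for (i in 1:20) {
    x <- sample(c(-1, 1), 7, TRUE)
    expect_equal(energy(x, p), oracle_energy(x, p$theta, p$w))
  }
})

test_that("energies from the reference parameters match the published table", {
  e <- state_energies(ref)
  expect_lt(max(abs(e - ref_tab$energy)), 1e-3)
})

test_that("partition function agrees with brute-force enumeration", {
  zero <- mem_params(rep(0, 7), matrix(0, 7, 7))
  expect_equal(partition_function(zero), 128)
  for (s in 1:3) {
    p <- rand_params(s)
    expect_equal(partition_function(p), oracle_partition_function(p),
                 tolerance = 1e-10)
  }
  p <- ref
  expect_gte(partition_function(p), exp(-min(state_energies(p))))
})

test_that("state probabilities are a Boltzmann distribution", {
  zero <- mem_params(rep(0, 7), matrix(0, 7, 7))
  expect_equal(state_probabilities(zero), rep(1 / 128, 128))
  for (s in 4:6) {
    p <- rand_params(s)
    pr <- state_probabilities(p)
    e <- state_energies(p)
    expect_equal(sum(pr), 1, tolerance = 1e-12)
    # consistency P(a)/P(b) = exp(Phi(b) - Phi(a)) on random pairs
    set.seed(s)
    ab <- matrix(sample.int(128, 20, TRUE), ncol = 2)
    expect_equal(pr[ab[, 1]] / pr[ab[, 2]],
                 exp(e[ab[, 2]] - e[ab[, 1]]), tolerance = 1e-10)
    # probabilities strictly decreasing in energy
    expect_true(all(diff(pr[order(e)]) <= 1e-15))
  }
  expect_equal(which.max(state_probabilities(ref)), 128L)
})

test_that("empirical moments summarise patient-visits", {
  one <- matrix(rep(1L, 7 * 12), ncol = 7)
  m <- empirical_moments(one)
  expect_equal(m$first, rep(1, 7))
  expect_equal(m$second, matrix(1, 7, 7))
  balanced <- rbind(matrix(1L, 5, 7), matrix(-1L, 5, 7))
  expect_equal(empirical_moments(balanced)$first, rep(0, 7))
  set.seed(7)
  rand <- matrix(sample(c(-1L, 1L), 35, TRUE), ncol = 7)
  expect_equal(diag(empirical_moments(rand)$second), rep(1, 7))
  expect_error(empirical_moments(matrix(integer(0), 0, 7)), "empty")
})

test_that("model moments match Monte-Carlo sampling estimates", {
  zero <- mem_params(rep(0, 7), matrix(0, 7, 7))
  mm0 <- model_moments(zero)
  expect_equal(unname(mm0$first), rep(0, 7))
  expect_equal(unname(mm0$second - diag(7)), matrix(0, 7, 7))
  mm <- model_moments(ref)
  n <- 1e6
  draws <- sample_states_iid(ref, n, seed = 42)
  emp <- empirical_moments(all_states()[draws, ])
  # spin means have SE <= 1/sqrt(n)
  expect_lt(max(abs(emp$first - mm$first)), 3.5 / sqrt(n))
  expect_lt(max(abs(emp$second - mm$second)), 3.5 / sqrt(n))
})

test_that("log-likelihood behaves like a likelihood", {
  zero <- mem_params(rep(0, 7), matrix(0, 7, 7))
  obs <- all_states()[c(1, 40, 128), ]
  expect_equal(log_likelihood(obs, zero, per_observation = TRUE), -log(128))
  p <- rand_params(9)
  ll <- log_likelihood(obs, p, per_observation = TRUE)
  expect_lte(ll, 0)
  expect_gte(ll, log(min(state_probabilities(p))))
})

test_that("a moment-matched initialisation is a fixed point of the fit", {
  # all 128 states once: empirical moments equal the uniform model's
  fit <- fit_mem(all_states(), trace_every = 0)
  expect_true(fit$converged)
  expect_equal(fit$iterations, 1L)
  expect_lt(max(abs(fit$params$theta)), 1e-6)
  expect_lt(max(abs(fit$params$w)), 1e-6)
})

test_that("gradient ascent matches empirical moments at convergence", {
  set.seed(11)
  draws <- sample_states_iid(rand_params(12), 3000)
  obs <- all_states()[draws, ]
  fit <- fit_mem(obs, trace_every = 0)
  expect_true(fit$converged)
  mm <- model_moments(fit$params)
  em <- empirical_moments(obs)
  expect_lt(max(abs(mm$first - em$first)), 1e-6)
  expect_lt(max(abs(mm$second - em$second)), 1e-6)
})

test_that("the log-likelihood trace is non-decreasing along the fit", {
  set.seed(13)
  obs <- all_states()[sample_states_iid(ref, 2000), ]
  fit <- fit_mem(obs, trace_every = 20)
  expect_gt(length(fit$loglik_trace), 3)
  expect_true(all(diff(fit$loglik_trace) > -1e-12))
  expect_gte(fit$loglik_trace[1], -log(128) - 1)  # sane scale
})

test_that("the fit rejects degenerate input", {
  expect_error(fit_mem(matrix(integer(0), 0, 7)), "empty")
  expect_error(fit_mem(all_states(), learning_rate = -1))
})
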