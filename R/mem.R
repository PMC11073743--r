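#' Pairwise maximum-entropy (Boltzmann machine) parameters
#'
#' Container for the bias vector theta and symmetric coupling matrix W of the
#' seven-node Boltzmann machine \eqn{P(X) \propto \exp(-\Phi(X))} with energy
#' \eqn{\Phi(X) = -\sum_i \theta_i x_i - \sum_{i<j} w_{ij} x_i x_j}.
#'
#' @param theta Numeric bias vector (one per factor, model order).
#' @param w Square symmetric coupling matrix with zero diagonal.
#' @param factors Factor names; defaults to [ra_factors()].
#'
#' @return Object of class `mem_params`: list with `theta`, `w`, `factors`.
#' @export
mem_params <- function(theta, w, factors = ra_factors()) {
  theta <- as.numeric(theta)
  w <- as.matrix(w)
  n <- length(theta)
  if (n != length(factors)) stop("theta length must match factor count")
  if (n > 20L) stop("exact enumeration is limited to 20 factors")
  if (!all(dim(w) == n)) stop("w must be ", n, " x ", n)
  if (!all(is.finite(theta)) || !all(is.finite(w))) stop("non-finite parameter")
  if (max(abs(w - t(w))) > 1e-8) stop("w must be symmetric")
  if (max(abs(diag(w))) > 1e-12) stop("w must have zero diagonal")
  w <- (w + t(w)) / 2
  diag(w) <- 0
  dimnames(w) <- list(factors, factors)
  structure(list(theta = setNames(theta, factors), w = w, factors = factors),
            class = "mem_params")
}

#' @export
print.mem_params <- function(x, ...) {
  cat("<mem_params>", length(x$factors), "factors:",
      paste(x$factors, collapse = ", "), "\n")
  cat("theta:", format(unname(x$theta), digits = 4), "\n")
  cat("coupling range: [", format(min(x$w[upper.tri(x$w)]), digits = 4), ",",
      format(max(x$w[upper.tri(x$w)]), digits = 4), "]\n")
  invisible(x)
}

as_spin_matrix <- function(spins) {
  m <- if (is.matrix(spins)) spins else matrix(spins, nrow = 1L)
  if (!all(m %in% c(-1, 1))) stop("spins must be -1 or +1")
  m
}

#' Energy of activity patterns
#'
#' Evaluates \eqn{\Phi(X) = -\sum_i \theta_i x_i - \sum_{i<j} w_{ij} x_i x_j}
#' (the pair sum runs over unordered pairs).
#'
#' @param spins A +-1 vector, or a matrix with one pattern per row.
#' @param params A [mem_params()].
#' @return Numeric energy, one value per pattern.
#' @export
#' @examples
#' p <- ra_reference_params()
#' energy(rep(1, 7), p)   # the poor-stability minimum, state 128
energy <- function(spins, params) {
  m <- as_spin_matrix(spins)
  stopifnot(ncol(m) == length(params$theta))
  # 0.5 * x' W x equals the unordered-pair sum because diag(W) = 0
  drop(-(m %*% params$theta) - 0.5 * rowSums((m %*% params$w) * m))
}

#' Energies of all states
#'
#' @param params A [mem_params()].
#' @return Numeric vector of length 2^N; entry `r` is the energy of state `r`.
#' @export
state_energies <- function(params) {
  energy(enumerate_states(length(params$theta)), params)
}

# All 2^n spin patterns, row r = state r (bit k of r-1 gives spin k).
enumerate_states <- function(n = 7L) {
  if (n == 7L) return(all_states())
  m <- t(vapply(seq_len(2^n) - 1L,
                function(i) ifelse(as.integer(intToBits(i))[seq_len(n)] == 1L, 1L, -1L),
                integer(n)))
  m
}

#' Partition function of the Boltzmann machine
#'
#' \eqn{Z = \sum_X \exp(-\Phi(X))} over all 2^N states, by exact enumeration
#' (computed on the log scale for stability).
#'
#' @param params A [mem_params()].
#' @param log If `TRUE` return log Z.
#' @return Scalar Z (or log Z).
#' @export
partition_function <- function(params, log = FALSE) {
  e <- -state_energies(params)
  m <- max(e)
  lz <- m + base::log(sum(exp(e - m)))
  if (log) lz else exp(lz)
}

#' Boltzmann probabilities of all states
#'
#' @param params A [mem_params()].
#' @return Probability vector over states (sums to 1), indexed by state number.
#' @export
state_probabilities <- function(params) {
  e <- -state_energies(params)
  p <- exp(e - max(e))
  p / sum(p)
}

#' Empirical spin moments of a dataset
#'
#' First and second moments over all patient-visits: `first[i]` is the mean of
#' spin i, `second[i, j]` the mean of the product of spins i and j (unit
#' diagonal).
#'
#' @param spins Matrix of +-1 with one observation (patient-visit) per row,
#'   columns in model order. Stack per-patient spin matrices with `rbind()`.
#' @return List with `first` (length-N vector) and `second` (N x N matrix).
#' @export
empirical_moments <- function(spins) {
  m <- as_spin_matrix(spins)
  if (nrow(m) == 0L) stop("empty dataset")
  list(first = colMeans(m), second = crossprod(m) / nrow(m))
}

#' Model spin moments by exact enumeration
#'
#' Expectations of spins and spin products under the Boltzmann distribution.
#'
#' @param params A [mem_params()].
#' @return List with `first` and `second`, as [empirical_moments()].
#' @export
model_moments <- function(params) {
  s <- enumerate_states(length(params$theta))
  p <- state_probabilities(params)
  list(first = drop(crossprod(s, p)), second = crossprod(s, s * p))
}

#' Log-likelihood of spin data under the model
#'
#' Sum over patient-visits of the log Boltzmann probability of the observed
#' state, treating observations as independent draws.
#'
#' @param spins Observation matrix as in [empirical_moments()].
#' @param params A [mem_params()].
#' @param per_observation If `TRUE`, divide by the number of observations.
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(spins, params, per_observation = FALSE) {
  m <- as_spin_matrix(spins)
  if (nrow(m) == 0L) stop("empty dataset")
  ll <- sum(-energy(m, params)) - nrow(m) * partition_function(params, log = TRUE)
  if (per_observation) ll / nrow(m) else ll
}

#' Fit the Boltzmann machine by exact gradient ascent
#'
#' Maximum-likelihood fit of theta and W by plain gradient ascent on the
#' log-likelihood, with expectations computed by exact enumeration of the
#' 2^N states. The updates are the moment-matching rule
#' `theta <- theta + eps * (empirical_first - model_first)` and likewise for
#' the couplings with second moments; at the optimum the model moments equal
#' the empirical moments, so the max-abs gradient doubles as a convergence
#' diagnostic.
#'
#' @param spins Observation matrix (+-1, one patient-visit per row), or a list
#'   of per-patient spin matrices which is row-bound.
#' @param learning_rate Step size epsilon (default 0.2).
#' @param max_iterations Iteration cap (default 5e6; convergence is normally
#'   reached within a few thousand iterations).
#' @param tolerance Stop when the max-abs gradient (moment mismatch) falls
#'   below this (default 1e-6).
#' @param init Optional `mem_params` starting point; default is the uniform
#'   model (theta = 0, W = 0).
#' @param trace_every Record the per-observation log-likelihood every this
#'   many iterations (0 disables the trace).
#'
#' @return Object of class `mem_fit`: list with `params` ([mem_params()]),
#'   `iterations`, `max_abs_gradient`, `converged`, and `loglik_trace`.
#' @export
fit_mem <- function(spins, learning_rate = 0.2, max_iterations = 5e6,
                    tolerance = 1e-6, init = NULL, trace_every = 100L) {
  if (is.list(spins) && !is.matrix(spins)) spins <- do.call(rbind, spins)
  m <- as_spin_matrix(spins)
  n_fac <- ncol(m)
  if (n_fac > 20L) stop("exact enumeration is limited to 20 factors")
  if (nrow(m) == 0L) stop("empty dataset")
  stopifnot(learning_rate > 0, max_iterations >= 1)

  s <- enumerate_states(n_fac)
  ut <- which(upper.tri(diag(n_fac)))
  pairs_all <- t(apply(s, 1L, function(x) tcrossprod(x)[ut]))   # 2^N x N(N-1)/2
  pairs_obs <- t(apply(m, 1L, function(x) tcrossprod(x)[ut]))
  emp1 <- colMeans(m)
  emp2 <- colMeans(pairs_obs)
  n_obs <- nrow(m)

  if (is.null(init)) {
    th <- numeric(n_fac); wu <- numeric(length(ut))
  } else {
    th <- unname(init$theta); wu <- init$w[ut]
  }

  trace <- numeric(0)
  it <- 0L
  g_max <- Inf
  while (it < max_iterations) {
    it <- it + 1L
    e <- s %*% th + pairs_all %*% wu         # minus energy of each state
    e <- e - max(e)
    q <- exp(e); lq <- sum(q); q <- q / lq
    g1 <- emp1 - drop(crossprod(s, q))
    g2 <- emp2 - drop(crossprod(pairs_all, q))
    if (!all(is.finite(g1)) || !all(is.finite(g2))) {
      stop("non-finite gradient: fit diverged (reduce learning_rate)")
    }
    th <- th + learning_rate * g1
    wu <- wu + learning_rate * g2
    g_max <- max(abs(c(g1, g2)))
    if (trace_every > 0 && it %% trace_every == 0L) {
      w_full <- matrix(0, n_fac, n_fac); w_full[ut] <- wu
      w_full <- w_full + t(w_full)
      trace <- c(trace, log_likelihood(m, mem_params(th, w_full,
                   factors = colnames(m) %||% paste0("f", seq_len(n_fac))),
                 per_observation = TRUE))
    }
    if (g_max < tolerance) break
  }
  w_full <- matrix(0, n_fac, n_fac); w_full[ut] <- wu
  w_full <- w_full + t(w_full)
  factors <- colnames(m) %||% paste0("f", seq_len(n_fac))
  structure(
    list(params = mem_params(th, w_full, factors = factors),
         iterations = it, max_abs_gradient = g_max,
         converged = g_max < tolerance, n_observations = n_obs,
         loglik_trace = trace),
    class = "mem_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mem_fit <- function(x, ...) {
  cat("<mem_fit>", x$n_observations, "observations;",
      x$iterations, "iterations;",
      if (x$converged) "converged" else "iteration cap reached",
      sprintf("(max-abs gradient %.2e)\n", x$max_abs_gradient))
  invisible(x)
}

#' Reference fitted parameters for the seven-factor model
#'
#' Loads the parameter set (theta, W) shipped with the package: a maximum-
#' likelihood fit of the seven-factor model to a treat-to-target rheumatoid
#' arthritis hospital registry. This is the default landscape used in
#' examples, simulations and the analysis scripts; its landscape has two
#' minima (states 81 and 128) separated by a saddle at about -1.48.
#'
#' @return A [mem_params()] object.
#' @export
#' @examples
#' find_minima(ra_reference_params())
ra_reference_params <- function() {
  read_params(system.file("extdata", "reference_mem_params.json",
                          package = "ralandscape", mustWork = TRUE))
}

#' Reference state table fixture
#'
#' The published 128-row state table for the reference parameter set: per-state
#' factor signs, energy, next transition state and basin minimum. Used as a
#' regression oracle for the landscape computations.
#'
#' @return Data frame with 128 rows: `state`, the seven factor sign columns,
#'   `energy`, `next_state`, `minimal_state`.
#' @export
ra_reference_state_table <- function() {
  read.csv(system.file("extdata", "reference_state_table.csv",
                       package = "ralandscape", mustWork = TRUE))
}
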