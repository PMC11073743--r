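#' Sample states i.i.d. from the Boltzmann distribution
#'
#' Exact categorical draws over the 2^N enumerated states (no MCMC needed at
#' N = 7).
#'
#' @param params A [mem_params()].
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return Integer vector of state numbers.
#' @export
sample_states_iid <- function(params, n, seed = NULL) {
  if (n <= 0) stop("n must be positive")
  if (!is.null(seed)) set.seed(seed)
  sample.int(2L^length(params$theta), n, replace = TRUE,
             prob = state_probabilities(params))
}

#' Sample a temporally correlated spin trajectory (Glauber dynamics)
#'
#' Heat-bath single-spin updates whose stationary law is the Boltzmann
#' distribution: a sweep visits every spin once in random order and redraws it
#' from its conditional, `P(x_i = +1 | rest) = 1 / (1 + exp(-2 h_i))` with
#' local field `h_i = theta_i + sum_j w_ij x_j`. Recording a visit every
#' `sweeps` sweeps yields autocorrelated series; `sweeps = 0` freezes the
#' initial state, and large `sweeps` recovers effectively independent
#' margins.
#'
#' @param params A [mem_params()].
#' @param visits Number of recorded visits (default 12).
#' @param sweeps Full update sweeps between recorded visits.
#' @param seed Optional integer seed.
#' @param init Initial state number; default a draw from the model.
#' @return `visits` x N spin matrix.
#' @export
sample_trajectory_glauber <- function(params, visits = 12L, sweeps = 1L,
                                      seed = NULL, init = NULL) {
  stopifnot(sweeps >= 0)
  if (!is.null(seed)) set.seed(seed)
  n_fac <- length(params$theta)
  x <- if (is.null(init)) {
    as.numeric(decode_state(sample_states_iid(params, 1L)))
  } else {
    as.numeric(decode_state(init))
  }
  out <- matrix(0L, visits, n_fac, dimnames = list(NULL, params$factors))
  for (t in seq_len(visits)) {
    if (t > 1L) {
      for (s in seq_len(sweeps)) {
        for (i in sample.int(n_fac)) {
          x[i] <- if (runif(1) < glauber_p_up(params, x, i)) 1 else -1
        }
      }
    }
    out[t, ] <- as.integer(x)
  }
  out
}

# Heat-bath conditional: P(x_i = +1 | x_{-i}) under the Boltzmann law.
# Satisfies detailed balance: p/(1-p) = exp(Phi(x_i=-1) - Phi(x_i=+1)).
glauber_p_up <- function(params, x, i) {
  h <- unname(params$theta[i]) + sum(params$w[i, ] * x)  # w_ii = 0: no self-coupling
  1 / (1 + exp(-2 * h))
}

# physiologic value ranges used when synthesising raw measurements
default_ranges <- function() {
  list(RF = c(0, 2200), ESR1h = c(0, 130), PtVAS = c(0, 100),
       DrVAS = c(0, 100), SJC28 = c(0, 28), TJC28 = c(0, 28))
}

#' Synthesize raw clinical values consistent with a spin matrix
#'
#' Inverse binarization: for each factor a raw value is drawn uniformly from
#' the remission side (spin -1) or nonremission side (+1) of its cutoff,
#' within physiologic ranges, so that `binarize_series()` recovers the spins
#' exactly. Joint counts are drawn as integers, STAGE from \{1,2\} or \{3,4\}.
#'
#' @param spins visits x 7 spin matrix (model order).
#' @param sex `"male"` or `"female"` (selects the ESR1h cutoff).
#' @param profile A [factor_profile()].
#' @param ranges Named list of value ranges, as [default_ranges()].
#' @param seed Optional integer seed.
#' @return Data frame with `visit` and the seven raw factor columns.
#' @export
spins_to_raw <- function(spins, sex, profile = factor_profile(),
                         ranges = default_ranges(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- as_spin_matrix(spins)
  n <- nrow(m)
  out <- data.frame(visit = seq_len(n))
  for (f in profile$factors) {
    s <- m[, f]
    if (f == "STAGE") {
      out[[f]] <- ifelse(s == -1, sample(1:2, n, TRUE), sample(3:4, n, TRUE))
      next
    }
    cut <- profile$thresholds[[f]]
    if (f == "ESR1h") cut <- unname(cut[sex])
    rng <- ranges[[f]]
    if (cut <= rng[1] || cut >= rng[2]) stop("empty range on one side of the ", f, " cutoff")
    if (f %in% c("SJC28", "TJC28")) {
      lo <- sample(seq(rng[1], cut), n, TRUE)              # 0..cut, remission
      hi <- sample(seq(cut + 1, rng[2]), n, TRUE)          # cut+1.., nonremission
      out[[f]] <- ifelse(s == -1, lo, hi)
    } else {
      out[[f]] <- ifelse(s == -1, runif(n, rng[1], cut), runif(n, cut, rng[2]))
    }
  }
  out
}

#' Synthesize HAQ scores from disease state
#'
#' A linear severity model: `haq(t) = clip(baseline + increment * k(t) +
#' noise, 0, 3)` where `k(t)` is the number of nonremission (+1) factors at
#' visit t. The defaults give HAQ around 0.2 in full remission and around 1.25
#' in the all-nonremission state, consistent with disability scores seen in
#' treat-to-target RA cohorts.
#'
#' @param spins visits x 7 spin matrix.
#' @param baseline Intercept (default 0.2).
#' @param increment Added per nonremission factor (default 0.15).
#' @param noise_sd Gaussian noise SD (default 0.2).
#' @param seed Optional integer seed.
#' @return Numeric HAQ vector in \[0, 3\].
#' @export
synthesize_haq <- function(spins, baseline = 0.2, increment = 0.15,
                           noise_sd = 0.2, seed = NULL) {
  stopifnot(noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  m <- as_spin_matrix(spins)
  k <- rowSums(m == 1)
  pmin(pmax(baseline + increment * k + rnorm(nrow(m), 0, noise_sd), 0), 3)
}

#' Delete observations to emulate registry missingness
#'
#' Two mechanisms: independent cell-level missingness at `missing_rate` for
#' every observation after the first visit, and early termination (all visits
#' after a geometric stopping point dropped) with per-visit probability
#' `truncation_prob`, emulating patients who leave follow-up or reach
#' remission early. The first visit is never deleted.
#'
#' @param series Per-patient data frame (12 rows, `visit` plus measurement
#'   columns).
#' @param missing_rate Probability a post-baseline cell is deleted.
#' @param truncation_prob Per-visit probability that the series ends.
#' @param seed Optional integer seed.
#' @return Data frame with truncated rows removed and deleted cells set `NA`.
#' @export
inject_missingness <- function(series, missing_rate = 0, truncation_prob = 0,
                               seed = NULL) {
  if (missing_rate < 0 || missing_rate > 1 || truncation_prob < 0 || truncation_prob > 1) {
    stop("rates must lie in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  series <- series[order(series$visit), , drop = FALSE]
  n <- nrow(series)
  last <- n
  if (truncation_prob > 0 && n > 1L) {
    stops <- which(rbinom(n - 1L, 1L, truncation_prob) == 1L)
    if (length(stops)) last <- stops[1L]
  }
  series <- series[seq_len(last), , drop = FALSE]
  cols <- intersect(c(ra_factors(), "HAQ"), names(series))
  if (missing_rate > 0 && nrow(series) > 1L) {
    for (f in cols) {
      drop_mask <- rbinom(nrow(series) - 1L, 1L, missing_rate) == 1L
      series[[f]][c(FALSE, drop_mask)] <- NA
    }
  }
  series
}

# conditional draw over a subset of states, renormalised
sample_states_conditional <- function(probs, allowed, n) {
  p <- probs[allowed]
  allowed[sample.int(length(allowed), n, replace = TRUE, prob = p / sum(p))]
}

#' Generate a synthetic cohort with known ground truth
#'
#' Builds a full cohort table in the long input format, plus the latent truth
#' that generated it, so that every pipeline stage can be validated
#' end-to-end. Three temporal modes:
#'
#' * `"iid"` — every visit is an independent Boltzmann draw (the sampling
#'   model the maximum-likelihood fit assumes);
#' * `"glauber"` — autocorrelated trajectories from heat-bath dynamics with
#'   the same stationary law;
#' * `"clustered"` — three latent regimes for cluster-recovery experiments:
#'   *toward-good* patients start in a transitional state of the good basin
#'   and relax along steepest descent to the good minimum, *toward-poor*
#'   patients likewise into the poor minimum, and *unstable* patients draw
#'   every visit from the transitional (at-or-above-threshold) states. A
#'   small per-visit excursion probability (`flip_noise`) knocks settled
#'   patients to a random neighbouring state.
#'
#' @param n_patients Cohort size.
#' @param params Generating [mem_params()] (default [ra_reference_params()]).
#' @param mode One of `"iid"`, `"glauber"`, `"clustered"`.
#' @param visits Visits per patient (default 12).
#' @param sweeps Glauber sweeps between visits (mode `"glauber"`).
#' @param flip_noise Excursion probability per settled visit (mode
#'   `"clustered"`, default 0.05).
#' @param female_share Proportion of female patients (default 0.8, typical of
#'   RA cohorts; only the ESR1h cutoff depends on it).
#' @param haq_baseline,haq_increment,haq_sd Passed to [synthesize_haq()].
#' @param missing_rate,truncation_prob Passed to [inject_missingness()].
#' @param seed Integer seed; all randomness flows from it.
#'
#' @return List with `cohort` (long data frame: `patient_id`, `sex`, `visit`,
#'   raw factor columns, `HAQ`) and `truth` (list: `params`, `states`
#'   (n x visits matrix of latent state numbers), `regime` (factor, clustered
#'   mode only), `haq` matrix, `seed`, `mode`).
#' @export
generate_cohort <- function(n_patients, params = ra_reference_params(),
                            mode = c("iid", "glauber", "clustered"),
                            visits = 12L, sweeps = 1L, flip_noise = 0.05,
                            female_share = 0.8,
                            haq_baseline = 0.2, haq_increment = 0.15,
                            haq_sd = 0.2, missing_rate = 0,
                            truncation_prob = 0, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_patients >= 1)
  if (!is.null(seed)) set.seed(seed)

  sex <- ifelse(runif(n_patients) < female_share, "female", "male")
  probs <- state_probabilities(params)
  states <- matrix(0L, n_patients, visits)
  regime <- NULL

  if (mode == "iid") {
    states[] <- sample_states_iid(params, n_patients * visits)
  } else if (mode == "glauber") {
    for (i in seq_len(n_patients)) {
      states[i, ] <- encode_state(sample_trajectory_glauber(params, visits, sweeps))
    }
  } else {
    ls <- energy_landscape(params)
    transitional <- which(ls$energies >= ls$threshold)
    good_min <- ls$good_minimum
    poor_min <- setdiff(ls$minima, good_min)[1L]
    pools <- list(
      toward_good = intersect(transitional, which(ls$basin == good_min)),
      toward_poor = intersect(transitional, which(ls$basin == poor_min))
    )
    regime <- factor(rep_len(c("toward_good", "toward_poor", "unstable"), n_patients),
                     levels = c("toward_good", "toward_poor", "unstable"))
    for (i in seq_len(n_patients)) {
      r <- as.character(regime[i])
      if (r == "unstable") {
        states[i, ] <- sample_states_conditional(probs, transitional, visits)
      } else {
        s <- sample_states_conditional(probs, pools[[r]], 1L)
        for (t in seq_len(visits)) {
          states[i, t] <- s
          s2 <- ls$next_state[s]
          if (s2 == s && runif(1) < flip_noise) {
            s2 <- sample(state_neighbors(s), 1L)   # brief excursion
          }
          s <- s2
        }
      }
    }
  }

  haq <- matrix(0, n_patients, visits)
  rows <- vector("list", n_patients)
  ids <- sprintf("P%04d", seq_len(n_patients))
  for (i in seq_len(n_patients)) {
    spins <- decode_state(states[i, ])
    haq[i, ] <- synthesize_haq(spins, haq_baseline, haq_increment, haq_sd)
    raw <- spins_to_raw(spins, sex = sex[i])
    raw <- data.frame(patient_id = ids[i], sex = sex[i], visit = raw$visit,
                      raw[ra_factors()], HAQ = haq[i, ])
    rows[[i]] <- inject_missingness(raw, missing_rate, truncation_prob)
  }
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL
  # input-format column order
  cohort <- cohort[, c("patient_id", "sex", "visit",
                       "RF", "ESR1h", "PtVAS", "DrVAS", "STAGE",
                       "SJC28", "TJC28", "HAQ")]
  list(
    cohort = cohort,
    truth = list(params = params, states = states, regime = regime,
                 haq = haq, sex = sex, mode = mode, seed = seed)
  )
}
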