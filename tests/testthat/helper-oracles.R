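# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: explicit loops, exhaustive enumeration
# and graph search instead of vectorised algebra, union-find or DP.

# Energy by the definition, written as explicit sums.
oracle_energy <- function(x, theta, w) {
  theta <- unname(theta)
  e <- 0
  for (i in seq_along(x)) e <- e - theta[i] * x[i]
  for (i in seq_along(x)) {
    for (j in seq_along(x)) {
      if (i < j) e <- e - w[i, j] * x[i] * x[j]
    }
  }
  e
}

# Partition function by enumerating spin assignments with expand.grid.
oracle_partition_function <- function(params) {
  grid <- as.matrix(expand.grid(rep(list(c(-1, 1)), length(params$theta))))
  sum(apply(grid, 1L, function(x) exp(-oracle_energy(x, params$theta, params$w))))
}

# DTW by recursive enumeration of every monotone alignment path.
oracle_dtw <- function(x, y) {
  x <- if (is.matrix(x)) x else matrix(x, ncol = 1L)
  y <- if (is.matrix(y)) y else matrix(y, ncol = 1L)
  n <- nrow(x); m <- nrow(y)
  cost <- function(i, j) sqrt(sum((x[i, ] - y[j, ])^2))
  rec <- function(i, j) {
    c0 <- cost(i, j)
    if (i == n && j == m) return(c0)
    branches <- c(
      if (i < n) rec(i + 1L, j),
      if (i < n && j < m) rec(i + 1L, j + 1L),
      if (j < m) rec(i, j + 1L)
    )
    c0 + min(branches)
  }
  rec(1L, 1L)
}

# Local minima by a direct scan over every state and neighbour.
oracle_minima <- function(params) {
  e <- state_energies(params)
  out <- integer(0)
  for (s in 1:128) {
    is_min <- TRUE
    for (k in 0:6) {
      nb <- bitwXor(s - 1L, bitwShiftL(1L, k)) + 1L
      if (e[nb] < e[s]) is_min <- FALSE
    }
    if (is_min) out <- c(out, s)
  }
  out
}

# Saddle level by bisection over candidate levels plus BFS connectivity.
oracle_saddle <- function(params, a, b) {
  e <- state_energies(params)
  connected_at <- function(level) {
    keep <- which(e <= level)
    if (!(a %in% keep && b %in% keep)) return(FALSE)
    seen <- c(a)
    frontier <- c(a)
    while (length(frontier)) {
      nxt <- integer(0)
      for (s in frontier) {
        for (k in 0:6) {
          nb <- bitwXor(s - 1L, bitwShiftL(1L, k)) + 1L
          if (nb %in% keep && !(nb %in% seen)) {
            seen <- c(seen, nb); nxt <- c(nxt, nb)
          }
        }
      }
      frontier <- nxt
    }
    b %in% seen
  }
  levels <- sort(unique(e))
  lo <- 1L; hi <- length(levels)
  while (lo < hi) {  # smallest level at which a and b connect
    mid <- (lo + hi) %/% 2L
    if (connected_at(levels[mid])) hi <- mid else lo <- mid + 1L
  }
  levels[lo]
}

# Random valid parameter draw.
rand_params <- function(seed, scale_theta = 0.5, scale_w = 0.4) {
  set.seed(seed)
  th <- rnorm(7, 0, scale_theta)
  w <- matrix(0, 7, 7)
  w[upper.tri(w)] <- rnorm(21, 0, scale_w)
  mem_params(th, w + t(w))
}

# Per-patient clinical series data frame on a partial visit grid.
make_series <- function(visits, values, patient_id = "P1", sex = "female") {
  df <- data.frame(patient_id = patient_id, sex = sex, visit = visits)
  for (nm in names(values)) df[[nm]] <- values[[nm]]
  df
}

# A complete series sitting exactly at every remission cutoff.
remission_series <- function(sex = "female") {
  make_series(1:12, list(RF = 15, ESR1h = if (sex == "male") 10 else 20,
                         PtVAS = 10, DrVAS = 10, STAGE = 2, SJC28 = 1,
                         TJC28 = 1, HAQ = 0.2), sex = sex)
}
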