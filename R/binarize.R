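#' Remission thresholds for the seven disease-activity factors
#'
#' Builds the factor profile used to binarize raw clinical values into
#' remission (-1) / nonremission (+1) spins. RF and ESR1h cutoffs follow blood
#' test reference values (ESR1h is sex-specific), PtVAS/DrVAS/SJC28/TJC28
#' follow Boolean remission criteria, and STAGE splits Steinbrocker stages
#' 1-2 (remission side) from 3-4.
#'
#' @param rf RF cutoff, IU/mL.
#' @param esr1h_male,esr1h_female ESR at 1 hour cutoffs, mm.
#' @param ptvas,drvas Patient / doctor VAS cutoffs, mm on a 100 mm scale.
#' @param sjc28,tjc28 Swollen / tender 28-joint count cutoffs.
#' @param stage_high First Steinbrocker stage counted as nonremission.
#' @param inclusive Logical; if `TRUE` (default) a value exactly at the cutoff
#'   is classified remission (`value <= cutoff`), if `FALSE` the boundary is
#'   exclusive.
#'
#' @return An object of class `factor_profile`: list with `factors`,
#'   `thresholds` (named list; `ESR1h` holds `c(male, female)`), `kind`
#'   (numeric/categorical per factor) and `inclusive`.
#' @export
#' @examples
#' p <- factor_profile()
#' p$thresholds$RF
factor_profile <- function(rf = 15, esr1h_male = 10, esr1h_female = 20,
                           ptvas = 10, drvas = 10, sjc28 = 1, tjc28 = 1,
                           stage_high = 3, inclusive = TRUE) {
  thr <- list(
    TJC28 = tjc28, SJC28 = sjc28, STAGE = stage_high, DrVAS = drvas,
    PtVAS = ptvas, ESR1h = c(male = esr1h_male, female = esr1h_female),
    RF = rf
  )
  stopifnot(all(unlist(thr) > 0))
  structure(
    list(
      factors = .OMEGA,
      thresholds = thr,
      kind = setNames(ifelse(.OMEGA == "STAGE", "categorical", "numeric"), .OMEGA),
      inclusive = isTRUE(inclusive)
    ),
    class = "factor_profile"
  )
}

#' Binarize a single clinical measurement
#'
#' Maps a raw factor value to a spin: -1 if the value satisfies the remission
#' criterion, +1 otherwise (nonremission / high activity). Numeric factors are
#' in remission when `value <= cutoff` (or `<` if the profile is exclusive);
#' STAGE is in remission for stages 1-2.
#'
#' @param factor One of [ra_factors()].
#' @param value Numeric measurement(s); non-negative.
#' @param sex `"male"` or `"female"`; required for ESR1h only.
#' @param profile A [factor_profile()].
#'
#' @return Integer vector of -1/+1, same length as `value`.
#' @export
#' @examples
#' binarize_value("RF", 100)           # +1, nonremission
#' binarize_value("ESR1h", 15, "male") # +1; the female cutoff is 20
binarize_value <- function(factor, value, sex = NULL,
                           profile = factor_profile()) {
  if (!factor %in% profile$factors) {
    stop("unknown factor: ", factor)
  }
  if (anyNA(value)) stop("missing value passed to binarize_value()")
  if (any(value < 0)) stop("negative measurement for ", factor)
  if (factor == "STAGE") {
    if (!all(value %in% 1:4)) stop("STAGE must be in 1..4")
    return(ifelse(value < profile$thresholds$STAGE, -1L, 1L))
  }
  cut <- profile$thresholds[[factor]]
  if (factor == "ESR1h") {
    if (is.null(sex) || !all(sex %in% c("male", "female"))) {
      stop("ESR1h requires sex = \"male\" or \"female\"")
    }
    cut <- unname(cut[sex])
  }
  remission <- if (profile$inclusive) value <= cut else value < cut
  ifelse(remission, -1L, 1L)
}

# Fill one factor's series onto the full visit grid. Numeric: linear
# interpolation between observed neighbours, flat extension at both ends
# (stats::approx rule = 2 gives the leading back-fill and the repeat-last-value
# extension for short series). Categorical (STAGE): carry the earlier observed
# value forward; leading gaps take the first observation.
impute_column <- function(x, kind = c("numeric", "categorical"), n_visits = 12L) {
  kind <- match.arg(kind)
  stopifnot(length(x) <= n_visits)
  x <- c(x, rep(NA_real_, n_visits - length(x)))
  obs <- which(!is.na(x))
  if (length(obs) == 0L) stop("factor entirely unobserved; cannot impute")
  if (length(obs) == n_visits) return(x)
  if (kind == "numeric") {
    if (length(obs) == 1L) return(rep(x[obs], n_visits))
    return(approx(obs, x[obs], xout = seq_len(n_visits), rule = 2)$y)
  }
  # categorical: index of the nearest observation at or before t, else first
  idx <- findInterval(seq_len(n_visits), obs)
  idx[idx == 0L] <- 1L
  x[obs[idx]]
}

#' Impute a patient's clinical series onto the 12-visit grid
#'
#' Applies the preprocessing rules: numeric factors (and HAQ) are linearly
#' interpolated between observed visits; STAGE, being categorical, takes the
#' adjacent observed value (earlier one when both neighbours exist); series
#' observed at fewer than 12 visits are extended by repeating the last
#' observation, and leading gaps are back-filled from the first one.
#' Observed values are preserved exactly, so the operation is idempotent.
#'
#' @param series Data frame with a `visit` column (integers in 1..12) and any
#'   of the factor columns plus `HAQ`; missing cells are `NA`. Non-measurement
#'   columns (`patient_id`, `sex`, ...) are carried through.
#' @param n_visits Length of the visit grid (12).
#'
#' @return Data frame with exactly `n_visits` rows, visits 1..12, all
#'   measurement cells populated.
#' @export
impute_series <- function(series, n_visits = 12L) {
  stopifnot(is.data.frame(series), "visit" %in% names(series))
  if (anyDuplicated(series$visit)) stop("duplicate visit in series")
  if (!all(series$visit %in% seq_len(n_visits))) stop("visit outside 1..", n_visits)
  series <- series[order(series$visit), , drop = FALSE]
  measure_cols <- intersect(c(.OMEGA, "HAQ"), names(series))
  meta_cols <- setdiff(names(series), c(measure_cols, "visit"))
  out <- data.frame(visit = seq_len(n_visits))
  for (m in meta_cols) {
    v <- series[[m]][!is.na(series[[m]])]
    out[[m]] <- if (length(v)) v[1L] else NA
  }
  for (m in measure_cols) {
    x <- rep(NA_real_, n_visits)
    x[series$visit] <- series[[m]]
    kind <- if (m == "STAGE") "categorical" else "numeric"
    out[[m]] <- impute_column(x, kind, n_visits)
  }
  out[, c("visit", meta_cols, measure_cols)]
}

#' Binarize a patient's series to a 12 x 7 spin matrix
#'
#' Imputes (if needed) and binarizes the seven factors, returning spins in
#' model (Omega) order.
#'
#' @param series Per-patient data frame as in [impute_series()]; must contain
#'   all seven factor columns and, for ESR1h, a `sex` column or `sex` argument.
#' @param profile A [factor_profile()].
#' @param sex Overrides the series' `sex` column if given.
#'
#' @return Integer matrix, 12 rows (visits) x 7 columns ([ra_factors()] order),
#'   entries -1/+1, with attribute `patient_id` when present in the input.
#' @export
binarize_series <- function(series, profile = factor_profile(), sex = NULL) {
  missing_factors <- setdiff(.OMEGA, names(series))
  if (length(missing_factors)) {
    stop("series lacks factor column(s): ", paste(missing_factors, collapse = ", "))
  }
  if (is.null(sex)) sex <- series$sex[1L]
  full <- if (nrow(series) == 12L && !anyNA(series[.OMEGA])) series else impute_series(series)
  spins <- vapply(
    .OMEGA,
    function(f) binarize_value(f, full[[f]], sex = sex, profile = profile),
    integer(12L)
  )
  dimnames(spins) <- list(NULL, .OMEGA)
  attr(spins, "patient_id") <- series$patient_id[1L]
  spins
}

#' Encode spin vectors as state numbers 1..128
#'
#' The state number is `1 + sum(b_k * 2^(k-1))` with `b_k = 1` iff factor `k`
#' is +1, factors indexed in model order (TJC28 = bit 1, ..., RF = bit 7).
#' State 1 is all-remission, state 128 all-nonremission.
#'
#' @param spins A +-1 vector of length 7, or a matrix with 7 columns (one
#'   state per row).
#' @return Integer state number(s) in 1..128.
#' @export
#' @examples
#' encode_state(rep(-1, 7))  # 1
#' encode_state(rep(1, 7))   # 128
encode_state <- function(spins) {
  if (is.matrix(spins)) {
    stopifnot(ncol(spins) == 7L)
    m <- spins
  } else {
    stopifnot(length(spins) == 7L)
    m <- matrix(spins, nrow = 1L)
  }
  if (!all(m %in% c(-1, 1))) stop("spins must be -1 or +1")
  code <- as.integer(1 + (m == 1) %*% 2^(0:6))
  if (is.matrix(spins)) code else code[1L]
}

#' Decode a state number to its spin vector
#'
#' Inverse of [encode_state()].
#'
#' @param code Integer state number(s) in 1..128.
#' @return For a single code, a named +-1 vector of length 7; for several, a
#'   matrix with one state per row (columns in [ra_factors()] order).
#' @export
#' @examples
#' decode_state(65)  # only RF = +1
decode_state <- function(code) {
  if (!all(code %in% 1:128)) stop("state code must be in 1..128")
  m <- t(vapply(
    as.integer(code),
    function(cc) ifelse(as.integer(intToBits(cc - 1L))[1:7] == 1L, 1L, -1L),
    integer(7L)
  ))
  colnames(m) <- .OMEGA
  if (length(code) == 1L) m[1L, ] else m
}

#' All 128 activity patterns as a spin matrix
#'
#' @return 128 x 7 integer matrix; row `r` is `decode_state(r)`.
#' @export
all_states <- function() decode_state(1:128)
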