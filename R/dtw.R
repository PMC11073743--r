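#' Dynamic time warping distance
#'
#' Least-cost monotone alignment distance between two multivariate series.
#' The local cost is the Euclidean distance between aligned points; the
#' recursion allows the three unit-weight steps (advance in either series or
#' both) with no window constraint, so series of different lengths are
#' comparable and aligned paths never cross.
#'
#' @param x,y Numeric matrices with one time point per row and matching
#'   column (channel) counts; plain vectors are treated as 1-D series.
#' @return Scalar alignment distance (non-negative, symmetric, zero on
#'   identical series).
#' @export
#' @examples
#' dtw_distance(c(0, 0, 1), c(0, 1))  # 0: the repeat aligns for free
#' dtw_distance(c(1, 2, 3), c(1, 3))  # 1
dtw_distance <- function(x, y) {
  x <- as_series(x); y <- as_series(y)
  if (ncol(x) != ncol(y)) stop("point dimensions differ")
  if (nrow(x) == 0L || nrow(y) == 0L) stop("empty sequence")
  dtw_cost_cpp(x, y)
}

as_series <- function(x) {
  if (is.matrix(x)) x * 1.0 else matrix(as.numeric(x), ncol = 1L)
}

#' Pairwise DTW distance matrix
#'
#' @param trajectories List of series (matrices with matching column counts).
#' @return Symmetric n x n matrix of DTW distances with zero diagonal.
#' @export
dtw_pairwise <- function(trajectories) {
  trajectories <- lapply(trajectories, as_series)
  d <- unique(vapply(trajectories, ncol, integer(1)))
  if (length(d) != 1L) stop("all series must share the point dimension")
  m <- dtw_pairwise_cpp(trajectories)
  dimnames(m) <- list(names(trajectories), names(trajectories))
  m
}
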