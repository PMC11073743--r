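#' Feature trajectory for clustering
#'
#' Builds the per-patient multivariate series used by the trajectory
#' clustering: at each visit the seven spins, the energy of the visit's state,
#' and the HAQ score (9 channels). Channels are used unscaled by default:
#' spins are +-1, energies of the reference landscape span roughly [-3.6, 3.8]
#' and HAQ lies in [0, 3], so the scales are commensurate.
#'
#' @param spins 12 x 7 spin matrix ([binarize_series()] output).
#' @param params A [mem_params()].
#' @param haq Numeric HAQ vector, one value per visit.
#' @return Numeric matrix, visits x 9, columns the factors plus `energy`,
#'   `HAQ`; `patient_id` attribute carried over from `spins`.
#' @export
build_features <- function(spins, params, haq) {
  m <- as_spin_matrix(spins)
  if (length(haq) != nrow(m)) stop("HAQ length must match the visit count")
  if (anyNA(haq)) stop("HAQ contains missing values; impute first")
  out <- cbind(m, energy = energy(m, params), HAQ = as.numeric(haq))
  attr(out, "patient_id") <- attr(spins, "patient_id")
  out
}

scale_trajectories <- function(trajectories) {
  stacked <- do.call(rbind, trajectories)
  mu <- colMeans(stacked)
  sdv <- apply(stacked, 2L, sd)
  sdv[sdv == 0] <- 1
  lapply(trajectories, function(x) sweep(sweep(x, 2L, mu), 2L, sdv, "/"))
}

#' k-means clustering under DTW distance
#'
#' Lloyd-style alternation: each trajectory is assigned to the nearest center
#' by DTW distance; centers are then updated as the visit-wise mean vector of
#' their members (all series share the same length, so the mean is
#' well-defined). Initial centers are trajectories drawn at random; the best
#' of `restarts` initialisations by within-cluster sum of squared DTW
#' distances (SSE) is kept. An emptied cluster is reseeded with the
#' trajectory farthest from its current center.
#'
#' @param trajectories List of equal-size numeric matrices (visits x
#'   channels), e.g. from [build_features()].
#' @param k Number of clusters.
#' @param max_iter Iteration cap per restart (default 50).
#' @param restarts Number of random initialisations (default 10).
#' @param seed Optional integer seed for reproducibility.
#' @param scale If `TRUE`, z-score each channel globally before clustering.
#'
#' @return Object of class `dtw_kmeans`: list with `k`, `centers` (list of k
#'   matrices), `assignment` (integer vector, named when trajectories are),
#'   `sse`, `iterations`, `converged`, `sse_trace` (per-iteration SSE of the
#'   winning restart), and `seed`.
#' @export
kmeans_dtw <- function(trajectories, k, max_iter = 50L, restarts = 10L,
                       seed = NULL, scale = FALSE) {
  n <- length(trajectories)
  if (k < 1L) stop("k must be >= 1")
  if (k > n) stop("k exceeds the number of trajectories")
  trajectories <- lapply(trajectories, as_series)
  work <- if (scale) scale_trajectories(trajectories) else trajectories
  if (!is.null(seed)) set.seed(seed)

  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- work[sample.int(n, k)]
    assign_old <- rep(0L, n)
    sse_trace <- numeric(0)
    iter <- 0L
    converged <- FALSE
    while (iter < max_iter) {
      iter <- iter + 1L
      d <- dtw_to_centers_cpp(work, centers)
      assign_new <- max.col(-d, ties.method = "first")
      # reseed empty clusters with the worst-fitted trajectory
      for (j in which(tabulate(assign_new, k) == 0L)) {
        far <- which.max(d[cbind(seq_len(n), assign_new)])
        assign_new[far] <- j
      }
      sse_trace <- c(sse_trace, sum(d[cbind(seq_len(n), assign_new)]^2))
      if (all(assign_new == assign_old)) { converged <- TRUE; break }
      assign_old <- assign_new
      centers <- lapply(seq_len(k), function(j) {
        members <- work[assign_new == j]
        Reduce(`+`, members) / length(members)
      })
    }
    d <- dtw_to_centers_cpp(work, centers)
    assign_fin <- max.col(-d, ties.method = "first")
    sse <- sum(d[cbind(seq_len(n), assign_fin)]^2)
    if (is.null(best) || sse < best$sse) {
      best <- list(k = k, centers = centers, assignment = assign_fin,
                   sse = sse, iterations = iter, converged = converged,
                   sse_trace = sse_trace)
    }
  }
  names(best$assignment) <- names(trajectories)
  best$seed <- seed
  best$scaled <- scale
  class(best) <- "dtw_kmeans"
  best
}

#' @export
print.dtw_kmeans <- function(x, ...) {
  cat("<dtw_kmeans> k =", x$k, "| SSE =", format(x$sse, digits = 6),
      "| sizes:", paste(tabulate(x$assignment, x$k), collapse = "/"), "\n")
  invisible(x)
}

#' Within-cluster sum of squared DTW distances
#'
#' Recomputes the SSE of a fitted model on a trajectory set: the sum over
#' patients of the squared DTW distance to their own cluster center.
#'
#' @param model A [kmeans_dtw()] fit.
#' @param trajectories The clustered trajectories (same order as at fit time).
#' @return Scalar SSE.
#' @export
cluster_sse <- function(model, trajectories) {
  trajectories <- lapply(trajectories, as_series)
  if (isTRUE(model$scaled)) trajectories <- scale_trajectories(trajectories)
  if (length(trajectories) != length(model$assignment)) stop("unassigned patient")
  sum(vapply(seq_along(trajectories), function(i) {
    dtw_cost_cpp(trajectories[[i]], model$centers[[model$assignment[i]]])^2
  }, numeric(1)))
}

#' Choose the number of clusters
#'
#' Runs [kmeans_dtw()] over a range of K and reports the elbow curve (SSE per
#' K) and the mean silhouette width per K, computed on the DTW distance
#' matrix. The silhouette-maximising K is recommended; the elbow curve is
#' returned for manual override.
#'
#' @param trajectories List of equal-size series.
#' @param k_range Candidate cluster counts (default 2:6).
#' @param max_iter,restarts,seed,scale Passed to [kmeans_dtw()].
#' @return List with `recommended_k`, `diagnostics` (data frame `k`, `sse`,
#'   `silhouette`), and `models` (the fitted `dtw_kmeans` per K).
#' @export
select_k <- function(trajectories, k_range = 2:6, max_iter = 50L,
                     restarts = 10L, seed = NULL, scale = FALSE) {
  n <- length(trajectories)
  if (any(k_range < 2L) || any(k_range > n - 1L)) {
    stop("k_range must lie within [2, n - 1] for silhouette analysis")
  }
  work <- lapply(trajectories, as_series)
  if (scale) work <- scale_trajectories(work)
  dmat <- dtw_pairwise(work)
  if (all(dmat == 0)) stop("all trajectories identical; clustering is degenerate")
  if (!is.null(seed)) set.seed(seed)
  models <- lapply(k_range, function(k) {
    kmeans_dtw(trajectories, k, max_iter = max_iter, restarts = restarts,
               seed = NULL, scale = scale)
  })
  sil <- vapply(seq_along(k_range), function(i) {
    s <- cluster::silhouette(models[[i]]$assignment, dmatrix = dmat)
    mean(s[, "sil_width"])
  }, numeric(1))
  diagnostics <- data.frame(
    k = k_range,
    sse = vapply(models, `[[`, numeric(1), "sse"),
    silhouette = sil
  )
  list(
    recommended_k = k_range[which.max(sil)],
    diagnostics = diagnostics,
    models = setNames(models, paste0("k", k_range))
  )
}
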