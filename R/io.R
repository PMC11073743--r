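# atomic file write: write to a temp file in the target directory, then rename
write_atomic <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not move temporary file to ", path)
  invisible(path)
}

.COHORT_COLS <- c("patient_id", "sex", "visit", "RF", "ESR1h", "PtVAS",
                  "DrVAS", "STAGE", "SJC28", "TJC28", "HAQ")

#' Read a long-format cohort CSV
#'
#' One row per patient-visit with columns `patient_id`, `sex`, `visit`, the
#' seven raw factor values and `HAQ`; empty fields are missing values. Unknown
#' columns are preserved. Validation covers the header, numeric types, visit
#' range, duplicate patient-visits, STAGE levels and the HAQ range.
#'
#' @param path CSV file.
#' @return Data frame of typed records.
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.COHORT_COLS, names(df))
  if (length(missing_cols)) {
    stop("cohort file lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  num_cols <- setdiff(.COHORT_COLS, c("patient_id", "sex"))
  for (cc in num_cols) {
    v <- df[[cc]]
    if (is.character(v)) {
      v_num <- suppressWarnings(as.numeric(ifelse(v == "", NA, v)))
      bad <- which(!is.na(v) & v != "" & is.na(v_num))
      if (length(bad)) stop("non-numeric value in ", cc, " at row ", bad[1L])
      v <- v_num
    }
    df[[cc]] <- as.numeric(v)
  }
  if (!all(df$sex %in% c("male", "female"))) stop("sex must be male/female")
  if (anyNA(df$visit) || !all(df$visit %in% 1:12)) stop("visit must be in 1..12")
  dup <- duplicated(df[c("patient_id", "visit")])
  if (any(dup)) {
    stop("duplicate (patient, visit) at row ", which(dup)[1L])
  }
  bad_stage <- which(!is.na(df$STAGE) & !df$STAGE %in% 1:4)
  if (length(bad_stage)) stop("STAGE outside 1..4 at row ", bad_stage[1L])
  bad_haq <- which(!is.na(df$HAQ) & (df$HAQ < 0 | df$HAQ > 3))
  if (length(bad_haq)) stop("HAQ outside [0, 3] at row ", bad_haq[1L])
  df
}

#' Write a cohort CSV
#'
#' @param cohort Data frame as produced by [generate_cohort()] or read by
#'   [read_cohort()].
#' @param path Output file (written atomically).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write_atomic(path, function(p) write.csv(cohort, p, row.names = FALSE, na = ""))
}

#' Read / write model parameters as JSON
#'
#' Parameters are serialised as `{"factors": [...], "theta": [...], "w":
#' [[...]]}`; reading validates symmetry and the zero diagonal.
#'
#' @param path JSON file.
#' @return `read_params()` returns a [mem_params()]; `write_params()` returns
#'   `path` invisibly.
#' @export
read_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!all(c("factors", "theta", "w") %in% names(x))) {
    stop("params JSON must contain factors, theta, w")
  }
  mem_params(x$theta, x$w, factors = x$factors)
}

#' @rdname read_params
#' @param params A [mem_params()].
#' @export
write_params <- function(params, path) {
  x <- list(factors = params$factors, theta = unname(params$theta),
            w = unname(params$w))
  write_atomic(path, function(p) {
    jsonlite::write_json(x, p, digits = NA, pretty = TRUE)
  })
}

#' Write the per-state summary table as CSV
#'
#' @param table A [state_table()] data frame.
#' @param path Output file (written atomically).
#' @return `path`, invisibly.
#' @export
write_state_table <- function(table, path) {
  stopifnot(is.data.frame(table), nrow(table) == 128L)
  write_atomic(path, function(p) write.csv(table, p, row.names = FALSE))
}

# stable hash of an R object (via its JSON serialisation)
config_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, digits = NA, auto_unbox = TRUE, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Chains the stages on a cohort table: binarize and impute, fit the model
#' (or use supplied parameters), derive the landscape, build feature
#' trajectories, and cluster them. Returns the fitted artifacts plus a
#' deterministic run report with the headline numbers.
#'
#' @param cohort Cohort data frame (see [read_cohort()]) or a path to one.
#' @param params Optional [mem_params()]; when supplied the fitting stage is
#'   skipped (e.g. [ra_reference_params()]).
#' @param k Cluster count, or `NULL` to select it via [select_k()].
#' @param k_range Candidate K values when `k` is `NULL`.
#' @param restarts,max_iter Clustering settings, see [kmeans_dtw()].
#' @param seed Integer seed governing fitting initialisation order and
#'   clustering restarts.
#' @param profile A [factor_profile()].
#' @param fit_control List of overrides for [fit_mem()] (`learning_rate`,
#'   `max_iterations`, `tolerance`).
#'
#' @return List with `params`, `landscape`, `spins` (list of per-patient spin
#'   matrices), `features`, `clusters` (a [kmeans_dtw()] fit), `selection`
#'   (when K was selected), and `report` — a plain list (seed, config hash,
#'   minima, threshold, transitional-state count, K, SSE, cluster sizes)
#'   identical across reruns with the same inputs.
#' @export
run_pipeline <- function(cohort, params = NULL, k = NULL, k_range = 2:6,
                         restarts = 10L, max_iter = 50L, seed = 1L,
                         profile = factor_profile(), fit_control = list()) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stage <- "binarize"
  res <- tryCatch({
    ids <- unique(cohort$patient_id)
    series <- lapply(ids, function(id) {
      impute_series(cohort[cohort$patient_id == id, , drop = FALSE])
    })
    spins <- lapply(series, binarize_series, profile = profile)
    names(spins) <- ids

    stage <- "fit"
    fit <- NULL
    if (is.null(params)) {
      fit <- do.call(fit_mem, c(list(spins = do.call(rbind, spins)), fit_control))
      params <- fit$params
    }

    stage <- "landscape"
    ls <- energy_landscape(params)

    stage <- "features"
    features <- lapply(ids, function(id) {
      i <- match(id, ids)
      build_features(spins[[i]], params, series[[i]]$HAQ)
    })
    names(features) <- ids

    stage <- "cluster"
    set.seed(seed)
    selection <- NULL
    if (is.null(k)) {
      selection <- select_k(features, k_range = k_range, restarts = restarts,
                            max_iter = max_iter)
      k <- selection$recommended_k
      clusters <- selection$models[[paste0("k", k)]]
    } else {
      clusters <- kmeans_dtw(features, k, restarts = restarts, max_iter = max_iter)
    }

    config <- list(n_patients = length(ids), k = k, k_range = k_range,
                   restarts = restarts, max_iter = max_iter, seed = seed,
                   fitted = is.null(fit), fit_control = fit_control)
    report <- list(
      seed = seed,
      config_hash = config_hash(config),
      n_patients = length(ids),
      fitted = !is.null(fit),
      fit_iterations = if (!is.null(fit)) fit$iterations else NA_integer_,
      minima = ls$minima,
      good_minimum = ls$good_minimum,
      threshold = ls$threshold,
      n_transitional = sum(ls$energies >= ls$threshold),
      k = k,
      sse = clusters$sse,
      cluster_sizes = tabulate(clusters$assignment, k)
    )
    list(params = params, fit = fit, landscape = ls, spins = spins,
         features = features, clusters = clusters, selection = selection,
         report = report)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  res
}
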