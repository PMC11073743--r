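#' Single-spin-flip neighbours of a state
#'
#' @param code State number(s) in 1..128.
#' @param n_factors Number of spins (7).
#' @return For one code, an integer vector of the 7 neighbouring state
#'   numbers (ascending); for several, a matrix with one row per code.
#' @export
#' @examples
#' state_neighbors(1)
state_neighbors <- function(code, n_factors = 7L) {
  n_states <- 2L^n_factors
  if (!all(code %in% seq_len(n_states))) stop("state code out of range")
  nb <- t(vapply(as.integer(code),
                 function(cc) sort(bitwXor(cc - 1L, bitwShiftL(1L, 0:(n_factors - 1L))) + 1L),
                 integer(n_factors)))
  if (length(code) == 1L) nb[1L, ] else nb
}

# next-state map for all states: strict steepest descent, ties to the
# smallest state number (neighbour rows are sorted ascending, max.col with
# ties.method = "first" picks it).
next_state_map <- function(energies, n_factors = 7L) {
  nb <- state_neighbors(seq_along(energies), n_factors)
  nb_e <- matrix(energies[nb], nrow = nrow(nb))
  j <- max.col(-nb_e, ties.method = "first")
  best <- nb[cbind(seq_along(energies), j)]
  ifelse(energies[best] < energies, best, seq_along(energies))
}

#' One steepest-descent step
#'
#' Moves to the minimum-energy single-flip neighbour if its energy is strictly
#' below the current state's; otherwise stays put. Ties go to the smallest
#' state number. This is the "next transition state" rule of the landscape.
#'
#' @param code State number(s).
#' @param params A [mem_params()].
#' @return State number(s) after one step.
#' @export
#' @examples
#' steepest_descent_step(1, ra_reference_params())  # 65
steepest_descent_step <- function(code, params) {
  nxt <- next_state_map(state_energies(params), length(params$theta))
  nxt[code]
}

#' Local minima of the energy landscape
#'
#' States all of whose single-flip neighbours have energy greater than or
#' equal to their own. (With the non-strict comparison a flat landscape is
#' degenerate: every state qualifies.)
#'
#' @param params A [mem_params()].
#' @return Integer vector of minimal state numbers.
#' @export
#' @examples
#' find_minima(ra_reference_params())  # 81 and 128
find_minima <- function(params) {
  e <- state_energies(params)
  nb <- state_neighbors(seq_along(e), length(params$theta))
  which(apply(matrix(e[nb], nrow = nrow(nb)) >= e, 1L, all))
}

#' Basin of attraction of every state
#'
#' Iterates [steepest_descent_step()] from each state to its fixed point.
#'
#' @param params A [mem_params()].
#' @return Integer vector: entry `r` is the minimal state reached from state
#'   `r`.
#' @export
basin_map <- function(params) {
  e <- state_energies(params)
  nxt <- next_state_map(e, length(params$theta))
  b <- seq_along(e)
  for (i in seq_along(e)) {  # path length is bounded by the state count
    b2 <- nxt[b]
    if (all(b2 == b)) break
    b <- b2
  }
  if (!all(nxt[b] == b)) stop("steepest descent failed to reach fixed points")
  b
}

# union-find with path halving
uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

# Level at which the sub-level sets of two states merge: add states in order
# of increasing energy, union edges to already-present neighbours, stop when
# a and b are connected. Returns the energy of the state whose addition
# connects them (the saddle level).
sublevel_merge_level <- function(energies, a, b, n_factors = 7L) {
  nb <- state_neighbors(seq_along(energies), n_factors)
  parent <- seq_along(energies)
  present <- logical(length(energies))
  for (s in order(energies)) {
    present[s] <- TRUE
    for (t in nb[s, ]) {
      if (present[t]) {
        ra <- uf_find(parent, s); rb <- uf_find(parent, t)
        if (ra != rb) parent[ra] <- rb
      }
    }
    if (uf_find(parent, a) == uf_find(parent, b)) return(energies[s])
  }
  stop("states never connect; landscape graph is broken")  # unreachable
}

#' Saddle level between two minima
#'
#' The minimax path level: the lowest energy `L` such that the two minima are
#' connected through states of energy at most `L` on the single-flip graph.
#' The energy barrier out of minimum `a` is `saddle - energy(a)`.
#'
#' @param params A [mem_params()].
#' @param min_a,min_b Two distinct local minima.
#' @return Scalar saddle energy.
#' @export
#' @examples
#' p <- ra_reference_params()
#' round(saddle_energy(p, 81, 128), 2)  # -1.48
saddle_energy <- function(params, min_a, min_b) {
  if (min_a == min_b) stop("minima must be distinct")
  minima <- find_minima(params)
  if (!all(c(min_a, min_b) %in% minima)) stop("arguments must be local minima")
  sublevel_merge_level(state_energies(params), min_a, min_b, length(params$theta))
}

#' Inter-pattern transition threshold
#'
#' For a two-minima landscape, the saddle energy between the minima: states at
#' or above this energy can pass between the two stable patterns. With more
#' than two minima the root merge level of the disconnectivity tree is
#' returned.
#'
#' @param params A [mem_params()].
#' @return Scalar threshold energy.
#' @export
transition_threshold <- function(params) {
  minima <- find_minima(params)
  if (length(minima) < 2L) {
    stop("transition threshold undefined: landscape has a single minimum")
  }
  if (length(minima) == 2L) {
    return(saddle_energy(params, minima[1L], minima[2L]))
  }
  build_disconnectivity(params)$root_level
}

#' Disconnectivity tree of the landscape
#'
#' Hierarchical merge structure over the local minima: leaves are minima at
#' their own energies; each internal node records the saddle level at which
#' two groups of basins become mutually reachable. Merges are found by
#' single-linkage agglomeration on the pairwise saddle levels.
#'
#' @param params A [mem_params()].
#' @return Object of class `disconnectivity_tree`: list with `minima`,
#'   `minima_energies`, `merges` (data frame `node_a`, `node_b`, `level`;
#'   negative node ids are leaves, positive ids earlier merges, as in
#'   [stats::hclust()]), and `root_level` (`NA` for a single leaf).
#' @export
build_disconnectivity <- function(params) {
  minima <- find_minima(params)
  e <- state_energies(params)
  k <- length(minima)
  merges <- data.frame(node_a = integer(0), node_b = integer(0), level = numeric(0))
  if (k >= 2L) {
    sad <- matrix(NA_real_, k, k)
    for (i in seq_len(k - 1L)) {
      for (j in seq((i + 1L), k)) {
        sad[i, j] <- sad[j, i] <-
          sublevel_merge_level(e, minima[i], minima[j], length(params$theta))
      }
    }
    active <- as.list(-seq_len(k))       # node id per current group
    members <- as.list(seq_len(k))       # leaf indices per group
    for (step in seq_len(k - 1L)) {
      # lowest pairwise saddle among active groups (single linkage)
      best <- c(NA, NA); best_lv <- Inf
      for (i in seq_along(active)[-1L]) {
        for (j in seq_len(i - 1L)) {
          lv <- min(sad[members[[i]], members[[j]]])
          if (lv < best_lv) { best_lv <- lv; best <- c(j, i) }
        }
      }
      merges <- rbind(merges, data.frame(
        node_a = active[[best[1L]]], node_b = active[[best[2L]]], level = best_lv))
      members[[best[1L]]] <- c(members[[best[1L]]], members[[best[2L]]])
      active[[best[1L]]] <- step
      members[[best[2L]]] <- NULL
      active[[best[2L]]] <- NULL
    }
  }
  structure(
    list(minima = minima, minima_energies = e[minima], merges = merges,
         root_level = if (nrow(merges)) merges$level[nrow(merges)] else NA_real_),
    class = "disconnectivity_tree"
  )
}

#' @export
print.disconnectivity_tree <- function(x, ...) {
  cat("<disconnectivity_tree>", length(x$minima), "minima:",
      paste0(x$minima, " (", format(x$minima_energies, digits = 4), ")",
             collapse = ", "), "\n")
  if (nrow(x$merges)) {
    cat("root merge level:", format(x$root_level, digits = 4), "\n")
  }
  invisible(x)
}

#' Write a disconnectivity tree as a DOT graph
#'
#' @param tree A [build_disconnectivity()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_disconnectivity_dot <- function(tree, path) {
  lines <- c("graph disconnectivity {", "  node [shape=box];")
  for (i in seq_along(tree$minima)) {
    lines <- c(lines, sprintf('  L%d [label="state %d\\nE=%.4f"];',
                              i, tree$minima[i], tree$minima_energies[i]))
  }
  node_name <- function(id) if (id < 0) sprintf("L%d", -id) else sprintf("M%d", id)
  for (r in seq_len(nrow(tree$merges))) {
    m <- tree$merges[r, ]
    lines <- c(lines,
      sprintf('  M%d [shape=point, xlabel="E=%.4f"];', r, m$level),
      sprintf("  M%d -- %s;", r, node_name(m$node_a)),
      sprintf("  M%d -- %s;", r, node_name(m$node_b)))
  }
  lines <- c(lines, "}")
  write_atomic(path, function(p) writeLines(lines, p))
  invisible(path)
}

#' Full energy-landscape summary
#'
#' Computes everything the landscape-level analyses need in one pass:
#' energies, next-state map, basins, minima, disconnectivity tree, transition
#' threshold, and the good-stability minimum used for quadrant labels.
#'
#' @param params A [mem_params()].
#' @param good_minimum State number of the minimum regarded as the
#'   good-stability (toward-remission) pattern. Default: the minimum whose
#'   pattern satisfies the most remission criteria (most -1 spins), ties
#'   broken by lower energy.
#' @return Object of class `energy_landscape`: list with `params`, `energies`,
#'   `next_state`, `basin`, `minima`, `tree`, `threshold`, `good_minimum`.
#' @export
#' @examples
#' ls <- energy_landscape(ra_reference_params())
#' ls$minima
energy_landscape <- function(params, good_minimum = NULL) {
  e <- state_energies(params)
  nxt <- next_state_map(e, length(params$theta))
  minima <- which(nxt == seq_along(e) &
                  apply(matrix(e[state_neighbors(seq_along(e), length(params$theta))],
                               nrow = length(e)) >= e, 1L, all))
  b <- basin_map(params)
  tree <- build_disconnectivity(params)
  thr <- if (length(minima) >= 2L) tree$root_level else NA_real_
  if (is.null(good_minimum)) {
    n_rem <- rowSums(decode_state(minima) == -1)
    good_minimum <- minima[order(-n_rem, e[minima])][1L]
  }
  if (!good_minimum %in% minima) stop("good_minimum must be a local minimum")
  structure(
    list(params = params, energies = e, next_state = nxt, basin = b,
         minima = minima, tree = tree, threshold = thr,
         good_minimum = good_minimum),
    class = "energy_landscape"
  )
}

#' @export
print.energy_landscape <- function(x, ...) {
  cat("<energy_landscape>", length(x$energies), "states;",
      length(x$minima), "minima:", paste(x$minima, collapse = ", "), "\n")
  cat("transition threshold:", format(x$threshold, digits = 4),
      "| good-stability minimum:", x$good_minimum, "\n")
  invisible(x)
}

#' Per-state summary table
#'
#' One row per state: the seven factor signs (reported in display order
#' RF ... TJC28), energy, next transition state, and basin minimum.
#'
#' @param params A [mem_params()].
#' @return Data frame with 128 rows.
#' @export
state_table <- function(params) {
  ls <- energy_landscape(params)
  spins <- all_states()
  data.frame(
    state = seq_along(ls$energies),
    spins[, rev(ra_factors()), drop = FALSE],
    energy = ls$energies,
    next_state = ls$next_state,
    minimal_state = ls$basin
  )
}

#' Quadrant label of states
#'
#' Cross-classifies states by basin and energy: `G` (good) if the basin is the
#' good-stability minimum, else `P` (poor); `L` (low, entrenched) if the
#' energy is strictly below the transition threshold, else `H` (high,
#' transitional; a state exactly at the saddle is transitional).
#'
#' @param code State number(s).
#' @param landscape An [energy_landscape()].
#' @return Character vector with values in `G-L`, `G-H`, `P-H`, `P-L`.
#' @export
#' @examples
#' ls <- energy_landscape(ra_reference_params())
#' quadrant(c(17, 40, 128), ls)
quadrant <- function(code, landscape) {
  if (is.na(landscape$threshold)) stop("quadrants undefined without a threshold")
  gp <- ifelse(landscape$basin[code] == landscape$good_minimum, "G", "P")
  lh <- ifelse(landscape$energies[code] < landscape$threshold, "L", "H")
  paste(gp, lh, sep = "-")
}

#' Quadrant occupancy of a cohort over visits
#'
#' Counts patients per quadrant at each visit, and the share of each
#' quadrant's patients in functional (HAQ) remission.
#'
#' @param states Integer matrix of state numbers, one patient per row, one
#'   column per visit.
#' @param landscape An [energy_landscape()].
#' @param haq Optional numeric matrix of HAQ scores, same shape as `states`.
#' @param haq_cutoff HAQ functional-remission cutoff (default 0.5).
#' @return List with `counts` (visits x 4) and, when `haq` is supplied,
#'   `haq_remission_share` (visits x 4, `NaN` for empty quadrants). Visit rows
#'   are labelled on the 0-based axis used for reporting.
#' @export
quadrant_occupancy <- function(states, landscape, haq = NULL, haq_cutoff = 0.5) {
  stopifnot(is.matrix(states))
  quads <- c("G-L", "G-H", "P-H", "P-L")
  n_visits <- ncol(states)
  counts <- matrix(0L, n_visits, 4L,
                   dimnames = list(paste0("t", seq_len(n_visits) - 1L), quads))
  share <- matrix(NaN, n_visits, 4L, dimnames = dimnames(counts))
  if (!is.null(haq)) {
    if (anyNA(haq)) stop("HAQ contains missing values; impute first")
    stopifnot(all(dim(haq) == dim(states)))
  }
  for (t in seq_len(n_visits)) {
    q <- factor(quadrant(states[, t], landscape), levels = quads)
    counts[t, ] <- tabulate(q, nbins = 4L)
    if (!is.null(haq)) {
      share[t, ] <- vapply(quads, function(qq) {
        sel <- q == qq
        if (!any(sel)) NaN else mean(haq[sel, t] <= haq_cutoff)
      }, numeric(1))
    }
  }
  out <- list(counts = counts)
  if (!is.null(haq)) out$haq_remission_share <- share
  out
}
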