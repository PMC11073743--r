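ref <- ra_reference_params()
ref_tab <- ra_reference_state_table()
ref_ls <- energy_landscape(ref)

test_that("every state has exactly seven symmetric single-flip neighbours", {
  expect_equal(state_neighbors(1), c(2L, 3L, 5L, 9L, 17L, 33L, 65L))
  nb <- state_neighbors(1:128)
  expect_equal(dim(nb), c(128L, 7L))
  for (s in 1:128) {
    expect_equal(length(unique(nb[s, ])), 7L)
    for (t in nb[s, ]) expect_true(s %in% nb[t, ])
  }
  expect_error(state_neighbors(0), "range")
})

test_that("steepest descent follows the published next-state column", {
  expect_equal(steepest_descent_step(1, ref), 65L)
  expect_equal(steepest_descent_step(81, ref), 81L)
  expect_equal(steepest_descent_step(40, ref), 39L)
  expect_equal(steepest_descent_step(1:128, ref), ref_tab$next_state)
})

test_that("steepest descent strictly decreases energy to a fixed point", {
  e <- state_energies(ref)
  for (s in c(1, 40, 64, 100, 128)) {
    path <- s
    repeat {
      nxt <- steepest_descent_step(path[length(path)], ref)
      if (nxt == path[length(path)]) break
      path <- c(path, nxt)
    }
    expect_lte(length(path), 128L)
    if (length(path) > 1) expect_true(all(diff(e[path]) < 0))
    expect_true(path[length(path)] %in% ref_ls$minima)
  }
})

test_that("local minima match a brute-force neighbourhood scan", {
  expect_equal(find_minima(ref), c(81L, 128L))
  for (s in c(1, 2, 5)) {
    p <- rand_params(s)
    expect_equal(find_minima(p), oracle_minima(p))
  }
  flat <- mem_params(rep(0, 7), matrix(0, 7, 7))
  expect_equal(find_minima(flat), 1:128)  # degenerate plateau
})

test_that("basins reproduce the published minimal-state column", {
  b <- basin_map(ref)
  expect_equal(b[64], 128L)
  expect_equal(b[17], 81L)
  expect_equal(b, ref_tab$minimal_state)
  # partition property: attractors are minima, minima map to themselves
  expect_true(all(b %in% ref_ls$minima))
  expect_equal(b[ref_ls$minima], ref_ls$minima)
})

test_that("saddle level is symmetric, dominates the minima, and matches the
           connectivity-bisection oracle", {
  s_ab <- saddle_energy(ref, 81, 128)
  expect_equal(s_ab, saddle_energy(ref, 128, 81))
  expect_gte(s_ab, max(state_energies(ref)[c(81, 128)]))
  expect_equal(s_ab, oracle_saddle(ref, 81, 128))
  for (s in c(2, 5)) {
    p <- rand_params(s)
    m <- find_minima(p)
    expect_equal(saddle_energy(p, m[1], m[2]), oracle_saddle(p, m[1], m[2]))
  }
  expect_error(saddle_energy(ref, 81, 81), "distinct")
  expect_error(saddle_energy(ref, 1, 128), "minima")
})

test_that("the transition threshold and transitional count match the
           published landscape", {
  thr <- transition_threshold(ref)
  expect_equal(round(thr, 2), -1.48)
  expect_equal(sum(state_energies(ref) >= thr), 109L)
})

test_that("scaling the parameters scales barriers monotonically", {
  # energy is linear in (theta, W), so doubling both doubles every barrier
  p2 <- mem_params(2 * ref$theta, 2 * ref$w)
  b1 <- saddle_energy(ref, 81, 128) - state_energies(ref)[81]
  b2 <- saddle_energy(p2, 81, 128) - state_energies(p2)[81]
  expect_gt(b2, b1)
  expect_equal(b2, 2 * b1, tolerance = 1e-12)
})

test_that("a single-minimum landscape has no threshold", {
  p <- mem_params(rep(2, 7), matrix(0, 7, 7))  # strong field, unique minimum
  expect_equal(find_minima(p), 128L)
  expect_error(transition_threshold(p), "single minimum")
  tree <- build_disconnectivity(p)
  expect_equal(nrow(tree$merges), 0L)
  expect_true(is.na(tree$root_level))
})

test_that("the disconnectivity tree merges basins at saddle levels", {
  tree <- ref_ls$tree
  expect_equal(tree$minima, c(81L, 128L))
  expect_equal(nrow(tree$merges), 1L)
  expect_equal(tree$root_level, saddle_energy(ref, 81, 128))
  expect_true(all(tree$merges$level >= max(tree$minima_energies)))
  # three-minima landscape: merges are ordered and dominate the leaves
  p3 <- rand_params(1)
  m3 <- find_minima(p3)
  expect_gte(length(m3), 3L)
  t3 <- build_disconnectivity(p3)
  expect_equal(nrow(t3$merges), length(m3) - 1L)
  expect_true(all(diff(t3$merges$level) >= 0))
  expect_true(all(t3$merges$level >= min(t3$minima_energies)))
  expect_equal(t3$root_level, max(t3$merges$level))
})

test_that("the disconnectivity tree exports to DOT", {
  path <- tempfile(fileext = ".dot")
  write_disconnectivity_dot(ref_ls$tree, path)
  lines <- readLines(path)
  expect_match(lines[1], "graph disconnectivity")
  expect_true(any(grepl("state 81", lines)))
  expect_true(any(grepl("state 128", lines)))
})

test_that("the state table reproduces the published rows", {
  st <- state_table(ref)
  expect_equal(nrow(st), 128L)
  expect_equal(st$state, 1:128)
  expect_equal(unlist(st[1, c("RF", "ESR1h", "PtVAS", "DrVAS", "STAGE",
                              "SJC28", "TJC28")], use.names = FALSE), rep(-1L, 7))
  expect_equal(st$next_state[1], 65L)
  expect_equal(st$minimal_state[128], 128L)
  expect_lt(max(abs(st$energy - ref_tab$energy)), 1e-3)
})

test_that("quadrant labels cross-classify basin and energy", {
  expect_equal(quadrant(17, ref_ls), "G-L")
  expect_equal(quadrant(40, ref_ls), "G-H")
  expect_equal(quadrant(128, ref_ls), "P-L")
  q <- quadrant(1:128, ref_ls)
  expect_true(all(q %in% c("G-L", "G-H", "P-H", "P-L")))
  expect_equal(sum(table(q)), 128L)  # labels partition the states
  # the good minimum carries the remission-richest pattern
  expect_equal(ref_ls$good_minimum, 81L)
  pat <- decode_state(81)
  expect_equal(names(pat[pat == 1]), c("PtVAS", "RF"))
})

test_that("quadrant occupancy counts partition the cohort at every visit", {
  states <- matrix(128L, 1, 12)
  occ <- quadrant_occupancy(states, ref_ls, haq = matrix(2, 1, 12))
  expect_equal(unname(occ$counts[, "P-L"]), rep(1L, 12))
  expect_equal(unname(occ$haq_remission_share[, "P-L"]), rep(0, 12))
  set.seed(21)
  states <- matrix(sample.int(128, 60, TRUE), 5, 12)
  occ <- quadrant_occupancy(states, ref_ls)
  expect_true(all(rowSums(occ$counts) == 5L))
})

test_that("a constructed drift trajectory migrates G-H to G-L", {
  states <- matrix(rep(c(rep(40L, 4), rep(81L, 8)), 3), nrow = 3, byrow = TRUE)
  occ <- quadrant_occupancy(states, ref_ls)
  expect_equal(unname(occ$counts[1, "G-H"]), 3L)
  expect_equal(unname(occ$counts[12, "G-L"]), 3L)
})
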