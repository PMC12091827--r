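make_flat_grids <- function(nr = 20, nc = 20) {
  list(
    a = simulate_env_grid(nr, nc, gradient = list(direction = "ns", range = c(0, 19))),
    b = simulate_env_grid(nr, nc, gradient = list(direction = "we", range = c(0, 19)))
  )
}

test_that("suitability is 1 at the centroid, monotone in Mahalanobis distance, truncated", {
  grids <- make_flat_grids()
  occ <- sample_occurrences(grids, list(a = c(6, 14), b = c(6, 14)), k = 30,
                            species = "sp", seed = 3)
  surf <- fit_suitability(occ, grids)
  env <- cbind(as.vector(grids$a$values), as.vector(grids$b$values))
  occ_env <- cbind(grid_values_at(grids$a, occ$longitude, occ$latitude),
                   grid_values_at(grids$b, occ$longitude, occ$latitude))
  mu <- colMeans(occ_env); S <- cov(occ_env)
  d2 <- stats::mahalanobis(env, mu, S)
  s <- as.vector(surf$values)
  # zero beyond the chi-square truncation
  expect_true(all(s[d2 > qchisq(0.95, 2)] == 0))
  # monotone: smaller distance => suitability at least as large
  ord <- order(d2)
  expect_true(all(diff(s[ord]) <= 1e-12))
  expect_equal(max(s), 1)
})

test_that("a one-variable envelope zeroes exactly the cells beyond the chi-square cut", {
  # occurrences {10, 12, 14}: mean 12, sample variance 4
  g <- simulate_env_grid(21, 3, gradient = list(direction = "ns", range = c(0, 20)))
  cc <- cell_centers(g)
  occ <- data.frame(species = "sp",
                    longitude = cc$lon[c(1, 2, 3)],
                    latitude = cc$lat[c(11, 13, 15)])  # row r holds value r - 1
  vals <- grid_values_at(g, occ$longitude, occ$latitude)
  expect_equal(sort(vals), c(10, 12, 14))
  surf <- fit_suitability(occ, list(v = g), truncation_q = 0.95, min_records = 3)
  zero <- surf$values == 0
  expected_zero <- (g$values - 12)^2 / 4 > qchisq(0.95, 1)
  expect_identical(zero, expected_zero)
})

test_that("degenerate covariance falls back to diagonal with a warning", {
  grids <- make_flat_grids()
  # all occurrences on one row: variable `a` has zero variance
  cc <- cell_centers(grids$a)
  occ <- data.frame(species = "flat", longitude = cc$lon[3:9], latitude = cc$lat[10])
  expect_warning(surf <- fit_suitability(occ, grids), "diagonal")
  expect_true(all(surf$values >= 0 & surf$values <= 1))
})

test_that("low-record species are rejected by the envelope fit", {
  grids <- make_flat_grids()
  occ <- sample_occurrences(grids, list(a = c(6, 14), b = c(6, 14)), k = 2,
                            species = "rare", seed = 1)
  expect_error(fit_suitability(occ, grids), "low-record")
})

test_that("disperser counts follow the interval rule", {
  expect_equal(dispersers_from_cell(0.6, 2), 2L)   # s > 0.5 -> two dispersers
  expect_equal(dispersers_from_cell(0.5, 2), 1L)   # s <= 0.5 -> one
  expect_equal(dispersers_from_cell(0.3, 4), 2L)   # (0.25, 0.5] is interval 2 of 4
  expect_equal(dispersers_from_cell(0, 2), 0L)
  expect_equal(dispersers_from_cell(1, 3), 3L)
  expect_error(dispersers_from_cell(1.2, 2), "\\[0, 1\\]")
  # generalized rule matches brute-force interval search
  for (m in 1:6) {
    for (s in seq(0.01, 1, by = 0.01)) {
      edges <- seq(0, 1, length.out = m + 1)
      idx <- max(which(s > edges[-length(edges)]))   # upper-closed intervals
      expect_equal(dispersers_from_cell(s, m), as.integer(idx))
    }
  }
})

test_that("M simulation: zero-event identity, monotone growth, determinism", {
  grids <- make_flat_grids()
  occ <- sample_occurrences(grids, list(a = c(4, 16), b = c(4, 16)), k = 25,
                            species = "sp", seed = 8)
  surf <- fit_suitability(occ, grids)

  m0 <- simulate_m(surf, occ, dispersal_config(n_events = 0, seed = 1))
  rc <- point_to_cell(grids$a, occ$longitude, occ$latitude)
  occupied <- matrix(FALSE, 20, 20); occupied[cbind(rc$row, rc$col)] <- TRUE
  expect_identical(m0$mask, occupied)

  prev <- m0$mask
  for (ne in c(5, 15, 35)) {
    mk <- simulate_m(surf, occ, dispersal_config(n_events = ne, seed = 77))
    expect_true(all(prev <= mk$mask))   # monotone colonization
    prev <- mk$mask
  }

  a <- simulate_m(surf, occ, dispersal_config(seed = 42))
  b <- simulate_m(surf, occ, dispersal_config(seed = 42))
  expect_identical(a$mask, b$mask)
  expect_true(all(a$mask[occupied]))    # M contains occupied cells
})

test_that("M never colonizes nodata cells", {
  nd <- cbind(rep(5, 20), 1:20)
  g1 <- simulate_env_grid(20, 20, gradient = list(direction = "ns", range = c(0, 19)),
                          nodata_cells = nd)
  g2 <- simulate_env_grid(20, 20, gradient = list(direction = "we", range = c(0, 19)))
  grids <- list(a = g1, b = g2)
  occ <- sample_occurrences(grids, list(a = c(6, 16), b = c(2, 18)), k = 25,
                            species = "sp", seed = 2)
  surf <- fit_suitability(occ, grids)
  m <- simulate_m(surf, occ, dispersal_config(seed = 5))
  expect_true(all(!m$mask[nd]))
})

test_that("fallback yields occurrence-only areas exactly for low-record species", {
  grids <- make_flat_grids()
  counts <- c(30, 30, 2, 3, 30, 4, 30, 30)
  areas <- list()
  for (i in seq_along(counts)) {
    sp <- sprintf("sp%02d", i)
    occ <- sample_occurrences(grids, list(a = c(4, 16), b = c(4, 16)),
                              k = counts[i], species = sp, seed = i)
    areas[[sp]] <- build_m_or_fallback(occ, grids, dispersal_config(seed = i))
  }
  status <- vapply(areas, `[[`, character(1), "status")
  expect_equal(unname(status == "occurrence_only"), counts < 5)
  # occurrence-only masks cover exactly the occupied cells
  occ3 <- sample_occurrences(grids, list(a = c(4, 16), b = c(4, 16)),
                             k = 2, species = "sp03", seed = 3)
  rc <- point_to_cell(grids$a, occ3$longitude, occ3$latitude)
  expect_equal(sum(areas$sp03$mask), nrow(unique(rc)))
  expect_true(all(areas$sp03$mask[cbind(rc$row, rc$col)]))
})
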