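test_that("noise-free gradient grids are exact and seeded grids reproduce", {
  g <- simulate_env_grid(11, 7, gradient = list(direction = "ns", range = c(0, 10)))
  expect_equal(rowMeans(g$values), as.numeric(0:10))
  expect_true(all(apply(g$values, 1, function(r) length(unique(r)) == 1)))

  gw <- simulate_env_grid(5, 11, gradient = list(direction = "we", range = c(0, 10)))
  expect_equal(colMeans(gw$values), as.numeric(0:10))

  a <- simulate_env_grid(30, 30, noise_sd = 0.7, seed = 99)
  b <- simulate_env_grid(30, 30, noise_sd = 0.7, seed = 99)
  expect_identical(a$values, b$values)
  c2 <- simulate_env_grid(30, 30, noise_sd = 0.7, seed = 100)
  expect_false(identical(a$values, c2$values))

  expect_error(simulate_env_grid(11, 5, gradient = list(direction = "ns", range = c(0, Inf))),
               "finite")
  expect_error(simulate_env_grid(1, 5), "n_rows")
})

test_that("detrended noise field has the requested standard deviation", {
  g <- simulate_env_grid(100, 100, gradient = list(direction = "ns", range = c(0, 10)),
                         noise_sd = 0.5, seed = 1)
  base <- matrix(seq(0, 10, length.out = 100), 100, 100)
  detrended <- g$values - base
  expect_lt(abs(sd(as.vector(detrended)) - 0.5) / 0.5, 0.2)
})

test_that("nodata cells appear only where requested", {
  nd <- cbind(c(1, 3), c(2, 4))
  g <- simulate_env_grid(5, 5, noise_sd = 0.1, seed = 2, nodata_cells = nd)
  expect_true(all(is.na(g$values[nd])))
  expect_equal(sum(is.na(g$values)), 2)
})

test_that("Yule trees are rooted, binary, ultrametric, at the requested depth", {
  t2 <- simulate_yule_tree(2, depth = 5, seed = 1)
  expect_equal(ape::Ntip(t2), 2)
  expect_equal(t2$Nnode, 1)
  expect_equal(max(ape::node.depth.edgelength(t2)), 5)

  for (seed in 1:5) {
    tr <- simulate_yule_tree(12, depth = 6.12, seed = seed)
    expect_true(ape::is.binary(tr))
    expect_true(ape::is.rooted(tr))
    depths <- ape::node.depth.edgelength(tr)[1:12]
    expect_lt(var(depths), 1e-9)          # ultrametric
    expect_equal(tr$Nnode, 11)            # n - 1 internal nodes
    expect_equal(anyDuplicated(tr$tip.label), 0)
  }
  expect_error(simulate_yule_tree(1), "n_tips")
})

test_that("niche evolution without events copies the root interval everywhere", {
  tree <- simulate_yule_tree(8, seed = 4)
  truth <- evolve_true_niches(tree, list(temperature = c(10, 20)),
                              list(temperature = c(0, 30)),
                              event_rate = 0, seed = 1)
  expect_equal(nrow(truth$events), 0)
  expect_true(all(truth$niches$low == 10))
  expect_true(all(truth$niches$high == 20))
  expect_error(
    evolve_true_niches(tree, list(temperature = c(-5, 20)),
                       list(temperature = c(0, 30)), event_rate = 0),
    "outside the grid range")
})

test_that("events modify intervals by their recorded magnitude and truth replays", {
  tree <- simulate_yule_tree(10, seed = 7)
  truth <- evolve_true_niches(tree, list(temperature = c(10, 20)),
                              list(temperature = c(0, 30)),
                              event_rate = 0.5, step_sd = 2, seed = 11)
  expect_gt(nrow(truth$events), 0)
  check_truth_consistency(truth, tree)
  ev <- truth$events[!truth$events$clamped, ]
  for (i in seq_len(min(nrow(ev), 10))) {
    par <- truth$niches[truth$niches$node == ev$parent[i], ]
    ch <- truth$niches[truth$niches$node == ev$child[i], ]
    delta <- switch(ev$event[i],
      expansion_high = ch$high - par$high,
      retraction_high = par$high - ch$high,
      expansion_low = par$low - ch$low,
      retraction_low = ch$low - par$low)
    expect_equal(delta, ev$magnitude_applied[i], tolerance = 1e-12)
  }
})

test_that("per-branch event frequency matches the configured rate", {
  tree <- simulate_yule_tree(12, seed = 2)
  n_branches <- nrow(tree$edge)
  rate <- 0.3
  reps <- 120
  hits <- 0
  for (s in seq_len(reps)) {
    tr <- evolve_true_niches(tree, list(v = c(10, 20)), list(v = c(0, 30)),
                             event_rate = rate, step_sd = 0.5, seed = s)
    hits <- hits + nrow(tr$events)
  }
  n <- reps * n_branches
  se <- sqrt(rate * (1 - rate) / n)
  expect_lt(abs(hits / n - rate), 3 * se)
})

test_that("occurrence sampling respects true intervals, counts and nodata", {
  g1 <- simulate_env_grid(20, 20, gradient = list(direction = "ns", range = c(0, 19)),
                          nodata_cells = cbind(10, 1:20))
  g2 <- simulate_env_grid(20, 20, gradient = list(direction = "we", range = c(0, 19)))
  grids <- list(a = g1, b = g2)
  niche <- list(a = c(5, 12), b = c(3, 15))
  occ <- sample_occurrences(grids, niche, k = 54, species = "big", seed = 5)
  expect_equal(nrow(occ), 54)
  va <- grid_values_at(g1, occ$longitude, occ$latitude)
  vb <- grid_values_at(g2, occ$longitude, occ$latitude)
  expect_true(all(va >= 5 & va <= 12))     # inside every true interval
  expect_true(all(vb >= 3 & vb <= 15))
  expect_false(anyNA(va))                  # never on nodata cells

  occ2 <- sample_occurrences(grids, niche, k = 2, species = "small", seed = 5)
  expect_equal(nrow(occ2), 2)

  expect_error(sample_occurrences(grids, list(a = c(100, 101), b = c(3, 15)),
                                  k = 1, species = "ghost"),
               "no suitable habitat.*ghost")
  tiny <- list(a = c(0, 0.4), b = c(0, 19))   # exactly one suitable row? -> few cells
  n_cells <- sum(g1$values >= 0 & g1$values <= 0.4 & !is.na(g1$values) &
                   g2$values >= 0, na.rm = TRUE)
  expect_error(sample_occurrences(grids, tiny, k = n_cells + 3, species = "tiny"),
               "suitable cells")
})
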