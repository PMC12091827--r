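test_that("ESRI ASCII grids round-trip field-by-field", {
  g <- simulate_env_grid(9, 7, gradient = list(direction = "we", range = c(-3, 14)),
                         noise_sd = 1.3, seed = 21, nodata_cells = cbind(2, 3),
                         xll = -64.5, yll = -33.25, cellsize = 0.0416667,
                         variable = "bio1")
  f <- withr::local_tempfile(fileext = ".asc")
  write_env_grid(g, f)
  h <- read_env_grid(f, variable = "bio1")
  expect_equal(h$values, g$values)
  expect_equal(h$xll, g$xll)
  expect_equal(h$yll, g$yll)
  expect_equal(h$cellsize, g$cellsize)
  expect_identical(is.na(h$values), is.na(g$values))
})

test_that("nodata sentinel cells are masked on read and headers are validated", {
  f <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "NODATA_value -9999",
               "1 -9999", "3 4"), f)
  g <- read_env_grid(f)
  expect_true(is.na(g$values[1, 2]))
  expect_equal(g$values[2, ], c(3, 4))

  bad <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 3", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "NODATA_value -9999", "1 2", "3 4"), bad)
  expect_error(read_env_grid(bad), "expected 3 data rows")
  bad2 <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "xllcorner 0", "yllcorner 0", "cellsize 1",
               "1 2"), bad2)
  expect_error(read_env_grid(bad2), "header")
})

test_that("cell centers and point-to-cell mapping follow the half-open convention", {
  g <- env_grid(matrix(1:4, 2, 2), xll = 10, yll = 20, cellsize = 0.0416667)
  cc <- cell_centers(g)
  expect_equal(cc$lon, 10 + 0.0416667 * c(0.5, 1.5))
  expect_equal(cc$lat, 20 + 0.0416667 * c(1.5, 0.5))  # row 1 is north

  g2 <- env_grid(matrix(0, 4, 4), xll = 0, yll = 0, cellsize = 1)
  rc <- point_to_cell(g2, c(0, 0.5, 3.999, 4, 4.5), c(0, 0.5, 3.999, 4, 2))
  expect_equal(rc$col, c(1L, 1L, 4L, 4L, NA))  # right boundary -> last cell
  expect_equal(rc$row, c(4L, 4L, 1L, 1L, NA))  # top boundary -> first row
})

test_that("occurrence validation drops out-of-extent and nodata points with reasons", {
  vals <- matrix(1, 4, 4); vals[2, 2] <- NA
  g <- env_grid(vals, xll = 0, yll = 0, cellsize = 1)
  cc <- cell_centers(g)
  occ <- data.frame(
    species = "sp",
    longitude = c(cc$lon[1], cc$lon[2], cc$lon[3], 9, cc$lon[4], -1, cc$lon[1]),
    latitude = c(cc$lat[1], cc$lat[2], cc$lat[3], 1, cc$lat[4], 1, cc$lat[3]))
  out <- validate_occurrences(occ, g)
  expect_equal(nrow(out), 4)
  dropped <- attr(out, "dropped")
  expect_setequal(dropped$reason, c("nodata", "out-of-extent"))
  expect_equal(sum(dropped$reason == "nodata"), 1)
  expect_equal(sum(dropped$reason == "out-of-extent"), 2)
  allbad <- occ[c(4, 6), ]
  expect_error(validate_occurrences(allbad, g), "invalid")
})

test_that("thinning enforces the pairwise distance floor and is idempotent", {
  one <- data.frame(species = "s", longitude = 0, latitude = 0)
  expect_equal(nrow(thin_occurrences(one)), 1)

  # two points ~3 km apart (1 deg lat ~ 111 km)
  two <- data.frame(species = "s", longitude = c(0, 0), latitude = c(0, 0.027))
  th <- thin_occurrences(two, min_dist_km = 5.2)
  expect_equal(nrow(th), 1)

  set.seed(31)
  cloud <- data.frame(species = "s",
                      longitude = runif(40, 0, 0.3),
                      latitude = runif(40, 0, 0.3))
  th <- thin_occurrences(cloud, min_dist_km = 5.2)
  d <- geosphere::distm(cbind(th$longitude, th$latitude),
                        fun = function(a, b) geosphere::distHaversine(a, b, r = 6371.0088))
  expect_true(all(d[upper.tri(d)] >= 5.2))
  th2 <- thin_occurrences(th, min_dist_km = 5.2)
  expect_equal(th2, th)
})

test_that("thinning a 1-km-spaced line retains the exhaustive-search optimum", {
  lat <- (0:9) * (1 / 111.1949266)   # ~1 km spacing along a meridian
  line <- data.frame(species = "s", longitude = 0, latitude = lat)
  th <- thin_occurrences(line, min_dist_km = 5.2)
  expect_equal(nrow(th), oracle_max_retained(line$longitude, line$latitude, 5.2))
})

test_that("interactive bioclim variables are excluded and others untouched", {
  vs <- exclude_interactive_variables(paste0("bio", 1:19))
  expect_equal(length(vs$names), 15)
  expect_setequal(vs$excluded, c("bio8", "bio9", "bio18", "bio19"))
  expect_equal(exclude_interactive_variables(c("bio1", "bio12")),
               list(names = c("bio1", "bio12"), excluded = character(0)))
  expect_equal(exclude_interactive_variables(character(0)),
               list(names = character(0), excluded = character(0)))
})

test_that("Newick round-trip preserves topology, lengths and derived node ages", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", f)
  tr <- read_dated_tree(f)
  ages <- node_ages(tr)
  labs <- node_labels(tr)
  expect_equal(unname(ages[labs == "A"]), 0)
  root_id <- ape::Ntip(tr) + 1
  expect_equal(ages[root_id], 2)
  internal <- setdiff(unique(tr$edge[, 1]), root_id)
  expect_equal(unname(ages[internal]), 1)

  yule <- simulate_yule_tree(40, seed = 9)
  f2 <- withr::local_tempfile(fileext = ".nwk")
  write_dated_tree(yule, f2)
  back <- read_dated_tree(f2)
  expect_equal(ape::Ntip(back), 40)
  expect_equal(length(internal_postorder(back)), 39)
  expect_true(ape::all.equal.phylo(yule, back, use.edge.length = FALSE))
  o1 <- ape::node.depth.edgelength(yule)
  o2 <- ape::node.depth.edgelength(back)
  expect_equal(max(abs(sort(o1) - sort(o2))), 0, tolerance = 1e-9)
})
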