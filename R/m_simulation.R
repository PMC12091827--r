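#' Fit an environmental-suitability surface from occurrences
#'
#' Truncated Mahalanobis-ellipsoid envelope: suitability declines linearly
#' with squared Mahalanobis distance from the occurrence centroid in
#' environment space, reaching 0 at the chi-square quantile
#' `truncation_q` (df = number of variables), and is rescaled so the best
#' data cell scores 1. A singular occurrence covariance falls back to the
#' diagonal covariance with a warning.
#'
#' @param occ occurrence data.frame for one species.
#' @param grids named list of [env_grid()]s sharing one frame.
#' @param truncation_q chi-square truncation quantile (default 0.95).
#' @param min_records minimum number of records required (default 5).
#' @return list of class `suitability_surface`: `species`, `values`
#'   (matrix in [0, 1], `NA` on nodata), and the frame fields of the grids.
#' @export
fit_suitability <- function(occ, grids, truncation_q = 0.95, min_records = 5) {
  assert_shared_frame(grids)
  check_number(truncation_q, "truncation_q")
  if (truncation_q <= 0 || truncation_q >= 1) {
    stop_invalid("`truncation_q` must be in (0, 1)")
  }
  if (nrow(occ) < min_records) {
    stop_invalid("low-record species '%s': %d records < min_records = %d",
                 occ$species[1], nrow(occ), min_records)
  }
  env <- vapply(grids, function(g) grid_values_at(g, occ$longitude, occ$latitude),
                numeric(nrow(occ)))
  env <- matrix(env, nrow = nrow(occ))
  if (anyNA(env)) stop_invalid("occurrences of '%s' fall on nodata cells; validate first",
                               occ$species[1])
  mu <- colMeans(env)
  S <- stats::cov(env)
  if (length(grids) == 1) S <- matrix(S, 1, 1)
  ok <- is.finite(determinant(S)$modulus) && rcond_ok(S)
  if (!ok) {
    warning(sprintf("singular environmental covariance for '%s'; using diagonal covariance",
                    occ$species[1]))
    S <- diag(pmax(diag(S), 1e-12), nrow = length(mu))
  }
  cut <- stats::qchisq(truncation_q, df = length(mu))
  cellvals <- vapply(grids, function(g) as.vector(g$values),
                     numeric(length(grids[[1]]$values)))
  cellvals <- matrix(cellvals, ncol = length(grids))
  d2 <- rep(NA_real_, nrow(cellvals))
  data_ok <- stats::complete.cases(cellvals)
  d2[data_ok] <- stats::mahalanobis(cellvals[data_ok, , drop = FALSE], mu, S)
  s <- pmax(0, 1 - d2 / cut)
  mx <- max(s, na.rm = TRUE)
  if (mx > 0) s <- s / mx
  g1 <- grids[[1]]
  structure(
    list(species = occ$species[1],
         values = matrix(s, n_rows(g1), n_cols(g1)),
         xll = g1$xll, yll = g1$yll, cellsize = g1$cellsize,
         nodata_value = g1$nodata_value),
    class = "suitability_surface")
}

rcond_ok <- function(S, tol = 1e-12) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  min(ev) > tol * max(abs(ev))
}

#' Dispersers emitted by a colonized cell
#'
#' The suitability range (0, 1] is split into `max_dispersers` equal
#' intervals; a cell emits as many dispersers as the 1-based index of the
#' interval containing its suitability (upper-closed), i.e.
#' `ceiling(s * m)` clamped to `[1, m]` for `s > 0`, and 0 for `s = 0`.
#' With the default `m = 2`: two dispersers when s > 0.5, one when
#' 0 < s <= 0.5.
#'
#' @param suitability numeric vector in [0, 1].
#' @param max_dispersers maximum dispersers per cell per event (>= 1).
#' @return integer vector of disperser counts.
#' @export
dispersers_from_cell <- function(suitability, max_dispersers = 2) {
  m <- check_count(max_dispersers, "max_dispersers", min = 1L)
  if (any(!is.finite(suitability)) || any(suitability < 0 | suitability > 1)) {
    stop_invalid("suitability values must lie in [0, 1]")
  }
  n <- pmin(pmax(ceiling(suitability * m), 1L), m)
  n[suitability == 0] <- 0L
  as.integer(n)
}

#' Dispersal configuration for M simulation
#'
#' @param n_events number of dispersal events (default 35, about one event
#'   per year over the span of the climate reference period).
#' @param max_dispersers maximum dispersers leaving a cell per event
#'   (default 2).
#' @param kernel_sd sdlog of the log-normal dispersal kernel (distance in
#'   cell widths, median fixed at 1 cell); screened candidates are 0.25,
#'   0.50 and 0.75, default 0.50.
#' @param seed integer seed.
#' @return list of class `dispersal_config`.
#' @export
dispersal_config <- function(n_events = 35, max_dispersers = 2,
                             kernel_sd = 0.50, seed = 1) {
  check_count(n_events, "n_events", min = 0L)
  check_count(max_dispersers, "max_dispersers", min = 1L)
  check_number(kernel_sd, "kernel_sd")
  if (kernel_sd <= 0) stop_invalid("`kernel_sd` must be > 0")
  structure(list(n_events = as.integer(n_events),
                 max_dispersers = as.integer(max_dispersers),
                 kernel_sd = kernel_sd, seed = seed),
            class = "dispersal_config")
}

#' Simulate a species' accessible area (M) by iterated dispersal
#'
#' Starting from the occupied cells, each dispersal event lets every
#' colonized cell with positive suitability emit
#' [dispersers_from_cell()] dispersers; each disperser lands at a
#' displacement with log-normal distance (median 1 cell width,
#' `sdlog = kernel_sd`) and uniform direction, rounded to the nearest
#' cell. Landing cells with positive suitability become colonized;
#' displacements leaving the grid are discarded (absorbing boundary).
#' The colonized set is monotone non-decreasing over events and the
#' result is a deterministic function of inputs and seed.
#'
#' @param surface a `suitability_surface` from [fit_suitability()].
#' @param occ occurrence data.frame for the species (same frame).
#' @param cfg a [dispersal_config()].
#' @return list of class `accessible_area`: `species`, `mask` (logical
#'   matrix; `NA`-free), `status = "simulated"`.
#' @export
simulate_m <- function(surface, occ, cfg = dispersal_config()) {
  nr <- nrow(surface$values); nc <- ncol(surface$values)
  rc <- point_to_cell(surface, occ$longitude, occ$latitude)
  if (anyNA(rc$row)) stop_invalid("occurrences of '%s' fall outside the grid",
                                  occ$species[1])
  suit <- surface$values
  suit[is.na(suit)] <- 0            # nodata cells never colonizable
  colonized <- matrix(FALSE, nr, nc)
  colonized[cbind(rc$row, rc$col)] <- TRUE
  if (all(suit[colonized] == 0)) {
    warning(sprintf("'%s': no occupied cell has positive suitability; M = occupied cells",
                    occ$species[1]))
    return(structure(list(species = occ$species[1], mask = colonized,
                          status = "simulated"), class = "accessible_area"))
  }
  with_seed(cfg$seed, {
    for (ev in seq_len(cfg$n_events)) {
      src <- which(colonized & suit > 0)
      if (!length(src)) break
      counts <- dispersers_from_cell(suit[src], cfg$max_dispersers)
      src <- rep(src, counts)
      n <- length(src)
      if (!n) next
      dist <- stats::rlnorm(n, meanlog = 0, sdlog = cfg$kernel_sd)
      ang <- stats::runif(n, 0, 2 * pi)
      sr <- ((src - 1) %% nr) + 1
      sc <- ((src - 1) %/% nr) + 1
      dr <- round(sr + dist * sin(ang))
      dc <- round(sc + dist * cos(ang))
      ok <- dr >= 1 & dr <= nr & dc >= 1 & dc <= nc
      if (any(ok)) {
        dest <- cbind(dr[ok], dc[ok])
        land <- suit[dest] > 0
        if (any(land)) colonized[dest[land, , drop = FALSE]] <- TRUE
      }
    }
  })
  structure(list(species = occ$species[1], mask = colonized,
                 status = "simulated"), class = "accessible_area")
}

#' Build an accessible area, falling back to occurrence cells
#'
#' Runs [fit_suitability()] + [simulate_m()]; species with fewer than
#' `min_records` records (or a failed suitability fit) get
#' `status = "occurrence_only"` with a mask covering exactly the occupied
#' cells, mirroring species for which M simulation is not possible.
#'
#' @inheritParams fit_suitability
#' @param cfg a [dispersal_config()].
#' @return an `accessible_area` with `status` `"simulated"` or
#'   `"occurrence_only"` (the fallback reason is attached as attribute
#'   `reason`).
#' @export
build_m_or_fallback <- function(occ, grids, cfg = dispersal_config(),
                                truncation_q = 0.95, min_records = 5) {
  res <- tryCatch({
    surf <- fit_suitability(occ, grids, truncation_q = truncation_q,
                            min_records = min_records)
    simulate_m(surf, occ, cfg)
  }, error = function(e) e)
  if (inherits(res, "error")) {
    g1 <- grids[[1]]
    rc <- point_to_cell(g1, occ$longitude, occ$latitude)
    mask <- matrix(FALSE, n_rows(g1), n_cols(g1))
    keep <- !is.na(rc$row)
    mask[cbind(rc$row[keep], rc$col[keep])] <- TRUE
    out <- structure(list(species = occ$species[1], mask = mask,
                          status = "occurrence_only"), class = "accessible_area")
    attr(out, "reason") <- conditionMessage(res)
    return(out)
  }
  res
}

#' @export
print.accessible_area <- function(x, ...) {
  cat(sprintf("<accessible_area> %s (%s): %d colonized cells\n",
              x$species, x$status, sum(x$mask)))
  invisible(x)
}

#' Values of an environmental grid inside an accessible area
#'
#' @param grid an [env_grid()].
#' @param area an `accessible_area` on the same frame.
#' @return numeric vector of in-M environmental values (nodata dropped).
#' @export
m_values <- function(grid, area) {
  v <- grid$values[area$mask]
  v[!is.na(v)]
}
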