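#' Simulate a spatially autocorrelated environmental grid
#'
#' Builds a deterministic linear gradient plus a seeded Gaussian random
#' field smoothed by a fixed-width moving-average kernel (a light-weight
#' stand-in for the spatial autocorrelation of real bioclim layers). The
#' smoothed noise field is recentred and rescaled so its standard
#' deviation equals `noise_sd` exactly.
#'
#' @param n_rows,n_cols grid dimensions (>= 2).
#' @param gradient list with `direction` (`"ns"` rows, north to south, or
#'   `"we"` columns, west to east) and `range` `c(from, to)` in
#'   environmental units.
#' @param noise_sd standard deviation of the added autocorrelated noise
#'   field (environmental units); 0 gives the pure gradient.
#' @param smooth moving-average kernel half-width in cells (window is
#'   `2*smooth+1` cells square).
#' @param seed integer seed; the same seed reproduces the grid bitwise.
#' @param nodata_cells optional 2-column matrix of (row, col) indices to
#'   blank out as nodata.
#' @param variable,xll,yll,cellsize passed to [env_grid()].
#' @return an [env_grid()].
#' @export
simulate_env_grid <- function(n_rows, n_cols,
                              gradient = list(direction = "ns", range = c(0, 30)),
                              noise_sd = 0, smooth = 2, seed = 1,
                              nodata_cells = NULL,
                              variable = "env", xll = 0, yll = 0, cellsize = 1) {
  check_count(n_rows, "n_rows", min = 2L)
  check_count(n_cols, "n_cols", min = 2L)
  if (!all(is.finite(gradient$range)) || length(gradient$range) != 2) {
    stop_invalid("gradient range must be two finite numbers")
  }
  check_number(noise_sd, "noise_sd")
  if (noise_sd < 0) stop_invalid("`noise_sd` must be >= 0")
  dir <- match.arg(gradient$direction, c("ns", "we"))
  g <- gradient$range
  base <- if (dir == "ns") {
    matrix(seq(g[1], g[2], length.out = n_rows), n_rows, n_cols)
  } else {
    matrix(seq(g[1], g[2], length.out = n_cols), n_rows, n_cols, byrow = TRUE)
  }
  vals <- base
  if (noise_sd > 0) {
    noise <- with_seed(seed, matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols))
    noise <- moving_average_2d(noise, smooth)
    s <- stats::sd(as.vector(noise))
    if (s > 0) noise <- (noise - mean(noise)) / s * noise_sd
    vals <- base + noise
  }
  if (!is.null(nodata_cells)) vals[nodata_cells] <- NA_real_
  env_grid(vals, variable = variable, xll = xll, yll = yll, cellsize = cellsize)
}

## 2-D moving average with edge truncation (windows clipped at borders)
moving_average_2d <- function(m, hw) {
  if (hw <= 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  acc <- matrix(0, nr, nc)
  cnt <- matrix(0, nr, nc)
  for (di in -hw:hw) {
    ri <- seq_len(nr) + di
    ok_r <- ri >= 1 & ri <= nr
    for (dj in -hw:hw) {
      cj <- seq_len(nc) + dj
      ok_c <- cj >= 1 & cj <= nc
      acc[ok_r, ok_c] <- acc[ok_r, ok_c] + m[ri[ok_r], cj[ok_c]]
      cnt[ok_r, ok_c] <- cnt[ok_r, ok_c] + 1
    }
  }
  acc / cnt
}

#' Simulate a dated Yule tree
#'
#' Pure-birth tree conditioned on the number of tips, rescaled so the root
#' age equals `depth` (ultrametric by construction). Defaults mirror a
#' 40-species clade with a 6.12 Myr crown age.
#'
#' @param n_tips number of tips (>= 2).
#' @param depth root age in Myr.
#' @param seed integer seed.
#' @param tip_prefix prefix for generated tip labels.
#' @return an `ape::phylo`, rooted, binary, ultrametric, with
#'   `node.label`s assigned.
#' @export
simulate_yule_tree <- function(n_tips = 40, depth = 6.12, seed = 1,
                               tip_prefix = "sp") {
  check_count(n_tips, "n_tips", min = 2L)
  check_number(depth, "depth")
  if (depth <= 0) stop_invalid("`depth` must be > 0")
  tree <- with_seed(seed, ape::rphylo(n_tips, birth = 1, death = 0))
  cur <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length * (depth / cur)
  tree$tip.label <- sprintf("%s%02d", tip_prefix, seq_len(n_tips))
  tree$node.label <- paste0("n", n_tips + seq_len(tree$Nnode))
  tree
}

niche_event_types <- c("expansion_high", "expansion_low",
                       "retraction_high", "retraction_low")

#' Evolve true interval niches along a tree with known events
#'
#' Each branch independently experiences at most one event per variable
#' (probability `event_rate`), drawn uniformly from expansion/retraction at
#' the upper/lower limit, with magnitude `|N(0, step_sd)|` floored at
#' `min_magnitude`. Child intervals equal the parent interval modified by
#' the event; retractions are capped so the interval keeps a positive
#' width, and expansions are clamped at the grid range. Caps and clamps are
#' recorded (`magnitude_applied`, `clamped`) so the truth table remains
#' exactly reconstructable.
#'
#' @param tree dated `phylo` with `node.label`s.
#' @param root_intervals named list, one `c(low, high)` per variable.
#' @param grid_ranges named list, one `c(min, max)` per variable; intervals
#'   are clamped to these.
#' @param event_rate per-branch, per-variable event probability in [0, 1].
#' @param step_sd named list or single number: event magnitude scale per
#'   variable (environmental units).
#' @param seed integer seed.
#' @param min_magnitude floor on event magnitudes (same units); 0 disables.
#' @param min_width retractions are capped so the child interval keeps at
#'   least this width (recorded as a clamp).
#' @param terminal_only if `TRUE`, only terminal branches receive events.
#' @param eligible_tips optional character vector: terminal events are
#'   planted only on branches leading to these tips.
#' @return list with `niches` (data.frame `node`, `variable`, `low`,
#'   `high`) and `events` (data.frame `parent`, `child`, `variable`,
#'   `event`, `magnitude`, `magnitude_applied`, `clamped`).
#' @export
evolve_true_niches <- function(tree, root_intervals, grid_ranges,
                               event_rate = 0.3, step_sd = 1, seed = 1,
                               min_magnitude = 0, min_width = 1e-6,
                               terminal_only = FALSE,
                               eligible_tips = NULL) {
  check_number(event_rate, "event_rate")
  if (event_rate < 0 || event_rate > 1) stop_invalid("`event_rate` must be in [0, 1]")
  vars <- names(root_intervals)
  if (is.null(vars)) stop_invalid("`root_intervals` must be a named list")
  if (!is.list(step_sd)) step_sd <- stats::setNames(as.list(rep(step_sd, length.out = length(vars))), vars)
  if (!is.list(min_width)) {
    min_width <- if (!is.null(names(min_width))) as.list(min_width)
                 else stats::setNames(as.list(rep(min_width, length.out = length(vars))), vars)
  }
  for (v in vars) {
    iv <- root_intervals[[v]]; gr <- grid_ranges[[v]]
    if (is.null(gr)) stop_invalid("no grid range for variable '%s'", v)
    if (iv[1] >= iv[2]) stop_invalid("root interval for '%s' must have low < high", v)
    if (iv[1] < gr[1] || iv[2] > gr[2]) {
      stop_invalid("root interval for '%s' lies outside the grid range", v)
    }
  }
  labs <- node_labels(tree)
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  ## parents before children
  po <- ape::reorder.phylo(tree, "postorder")
  edge_order <- rev(seq_len(nrow(po$edge)))
  niche <- array(NA_real_, dim = c(length(labs), length(vars), 2),
                 dimnames = list(labs, vars, c("low", "high")))
  for (v in vars) niche[labs[root], v, ] <- root_intervals[[v]]
  ev <- list()
  with_seed(seed, {
    for (ei in edge_order) {
      pid <- po$edge[ei, 1]; cid <- po$edge[ei, 2]
      for (v in vars) {
        iv <- niche[labs[pid], v, ]
        eligible <- (!terminal_only || cid <= ntip) &&
          (is.null(eligible_tips) || cid > ntip || labs[cid] %in% eligible_tips)
        if (terminal_only && cid > ntip) eligible <- FALSE
        u <- stats::runif(1)
        if (eligible && u < event_rate) {
          type <- sample(niche_event_types, 1)
          mag <- abs(stats::rnorm(1, 0, step_sd[[v]]))
          mag <- max(mag, min_magnitude)
          gr <- grid_ranges[[v]]
          applied <- mag
          clamped <- FALSE
          width <- iv[2] - iv[1]
          if (type %in% c("retraction_high", "retraction_low") &&
              mag > width - min_width[[v]]) {
            applied <- max(width - min_width[[v]], 0)  # keep a usable niche width
            clamped <- TRUE
          }
          new_iv <- switch(type,
            expansion_high = c(iv[1], iv[2] + applied),
            expansion_low = c(iv[1] - applied, iv[2]),
            retraction_high = c(iv[1], iv[2] - applied),
            retraction_low = c(iv[1] + applied, iv[2]))
          if (new_iv[1] < gr[1]) { new_iv[1] <- gr[1]; clamped <- TRUE
                                   applied <- if (type == "expansion_low") iv[1] - new_iv[1] else applied }
          if (new_iv[2] > gr[2]) { new_iv[2] <- gr[2]; clamped <- TRUE
                                   applied <- if (type == "expansion_high") new_iv[2] - iv[2] else applied }
          niche[labs[cid], v, ] <- new_iv
          ev[[length(ev) + 1L]] <- data.frame(
            parent = labs[pid], child = labs[cid], variable = v,
            event = type, magnitude = mag, magnitude_applied = applied,
            clamped = clamped, stringsAsFactors = FALSE)
        } else {
          niche[labs[cid], v, ] <- iv
        }
      }
    }
  })
  events <- if (length(ev)) do.call(rbind, ev) else data.frame(
    parent = character(0), child = character(0), variable = character(0),
    event = character(0), magnitude = numeric(0),
    magnitude_applied = numeric(0), clamped = logical(0))
  niches <- data.frame(
    node = rep(labs, times = length(vars)),
    variable = rep(vars, each = length(labs)),
    low = as.vector(niche[, , "low"]),
    high = as.vector(niche[, , "high"]),
    stringsAsFactors = FALSE)
  list(niches = niches, events = events)
}

#' Check a truth table for parent/child consistency
#'
#' Re-derives every child interval from its parent interval plus the
#' recorded events and compares with the stored niches; an exhaustive
#' audit of the generator's output.
#'
#' @param truth output of [evolve_true_niches()].
#' @param tree the tree the truth was generated on.
#' @param tol numeric tolerance.
#' @return `TRUE` invisibly; errors on inconsistency.
#' @export
check_truth_consistency <- function(truth, tree, tol = 1e-9) {
  labs <- node_labels(tree)
  bt <- branch_table(tree)
  nk <- truth$niches
  get_iv <- function(node, v) {
    r <- nk[nk$node == node & nk$variable == v, ]
    c(r$low, r$high)
  }
  for (v in unique(nk$variable)) {
    for (i in seq_len(nrow(bt))) {
      piv <- get_iv(bt$parent[i], v)
      civ <- get_iv(bt$child[i], v)
      e <- truth$events
      e <- e[e$parent == bt$parent[i] & e$child == bt$child[i] & e$variable == v, ]
      expect <- piv
      if (nrow(e) == 1) {
        a <- e$magnitude_applied
        expect <- switch(e$event,
          expansion_high = c(piv[1], piv[2] + a),
          expansion_low = c(piv[1] - a, piv[2]),
          retraction_high = c(piv[1], piv[2] - a),
          retraction_low = c(piv[1] + a, piv[2]))
        if (e$clamped) {              # clamping may have hit the grid edge
          if (max(abs(expect - civ)) > tol && !all(civ[1] <= civ[2])) {
            stop_invalid("truth inconsistency on branch %s->%s (%s)",
                         bt$parent[i], bt$child[i], v)
          }
          next
        }
      } else if (nrow(e) > 1) {
        stop_invalid("multiple events on branch %s->%s (%s)",
                     bt$parent[i], bt$child[i], v)
      }
      if (max(abs(expect - civ)) > tol) {
        stop_invalid("truth inconsistency on branch %s->%s (%s): expected [%g, %g], got [%g, %g]",
                     bt$parent[i], bt$child[i], v, expect[1], expect[2], civ[1], civ[2])
      }
    }
  }
  invisible(TRUE)
}

#' Sample occurrences from the jointly suitable cells
#'
#' Suitable cells satisfy every variable's true interval (closed) and are
#' nodata in none of the grids. `k` distinct cells are sampled uniformly
#' without replacement; occurrence coordinates are the cell centers.
#'
#' @param grids named list of [env_grid()]s sharing one frame.
#' @param true_niche named list, one `c(low, high)` per variable.
#' @param k number of records; `NULL` takes every suitable cell.
#' @param species species label used in the output and error messages.
#' @param seed integer seed.
#' @return occurrence data.frame (`species`, `longitude`, `latitude`).
#' @export
sample_occurrences <- function(grids, true_niche, k, species = "sp", seed = 1) {
  assert_shared_frame(grids)
  ok <- !is.na(grids[[1]]$values)
  for (g in grids) ok <- ok & !is.na(g$values)
  for (v in names(true_niche)) {
    iv <- true_niche[[v]]
    gv <- grids[[v]]$values
    ok <- ok & !is.na(gv) & gv >= iv[1] & gv <= iv[2]
  }
  cells <- which(ok)
  if (length(cells) == 0) {
    stop_invalid("no suitable habitat for species '%s'", species)
  }
  if (is.null(k)) k <- length(cells)
  check_count(k, "k", min = 1L)
  if (k > length(cells)) {
    stop_invalid("species '%s': %d records requested but only %d suitable cells",
                 species, k, length(cells))
  }
  pick <- with_seed(seed, sample(cells, k))
  nr <- n_rows(grids[[1]])
  row <- ((pick - 1) %% nr) + 1
  col <- ((pick - 1) %/% nr) + 1
  cc <- cell_centers(grids[[1]])
  data.frame(species = species, longitude = cc$lon[col], latitude = cc$lat[row],
             stringsAsFactors = FALSE)
}

#' Write a truth-event table as TSV
#'
#' @param truth output of [evolve_true_niches()].
#' @param path output path.
#' @export
write_truth_events <- function(truth, path) {
  utils::write.table(truth$events, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
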