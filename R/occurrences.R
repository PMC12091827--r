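#' Read / write occurrence tables
#'
#' Occurrence tables are plain CSV with header
#' `species,longitude,latitude[,source]`.
#'
#' @param path file path.
#' @return data.frame with columns `species`, `longitude`, `latitude` and
#'   optionally `source`.
#' @export
read_occurrences <- function(path) {
  occ <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "longitude", "latitude")
  if (!all(need %in% names(occ))) {
    stop_invalid("'%s': occurrence CSV must have columns %s", path,
                 paste(need, collapse = ", "))
  }
  occ
}

#' @rdname read_occurrences
#' @param occ occurrence data.frame.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(occ, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate occurrences against a grid frame
#'
#' Drops points outside the grid extent and points that fall on nodata
#' cells; every dropped point is reported in the `dropped` attribute with a
#' reason (`"out-of-extent"` or `"nodata"`).
#'
#' @param occ occurrence data.frame (`species`, `longitude`, `latitude`).
#' @param frame an [env_grid()] defining the shared spatial frame.
#' @return the retained subset, with attribute `dropped` (a data.frame with
#'   a `reason` column).
#' @export
validate_occurrences <- function(occ, frame) {
  rc <- point_to_cell(frame, occ$longitude, occ$latitude)
  reason <- rep(NA_character_, nrow(occ))
  reason[is.na(rc$row)] <- "out-of-extent"
  idx <- which(!is.na(rc$row))
  if (length(idx)) {
    bad <- idx[is.na(frame$values[cbind(rc$row[idx], rc$col[idx])])]
    reason[bad] <- "nodata"
  }
  keep <- is.na(reason)
  if (!any(keep)) {
    stop_invalid("all occurrence points invalid for species set {%s}",
                 paste(unique(occ$species), collapse = ", "))
  }
  out <- occ[keep, , drop = FALSE]
  rownames(out) <- NULL
  dropped <- occ[!keep, , drop = FALSE]
  dropped$reason <- reason[!keep]
  attr(out, "dropped") <- dropped
  out
}

## pairwise great-circle distance matrix in km
haversine_matrix <- function(lon, lat) {
  p <- cbind(lon, lat)
  geosphere::distm(p, fun = function(a, b) {
    geosphere::distHaversine(a, b, r = 6371.0088)
  })
}

## Exact maximum independent set on an adjacency matrix, deterministic.
## Branch on the lowest-index vertex of highest degree; returns the largest
## set, ties broken by lexicographically smallest sorted index vector.
mis_exact <- function(adj) {
  n <- nrow(adj)
  best <- integer(0)
  better <- function(a, b) {
    if (length(a) != length(b)) return(length(a) > length(b))
    a <- sort(a); b <- sort(b)
    d <- which(a != b)
    length(d) > 0 && a[d[1]] < b[d[1]]
  }
  rec <- function(remaining, chosen) {
    if (length(remaining) == 0) {
      if (better(chosen, best)) best <<- chosen
      return(invisible(NULL))
    }
    # bound: cannot beat best even taking all remaining
    if (length(chosen) + length(remaining) < length(best)) return(invisible(NULL))
    deg <- vapply(remaining, function(v) sum(adj[v, remaining]), numeric(1))
    if (all(deg == 0)) {
      cand <- sort(c(chosen, remaining))
      if (better(cand, best)) best <<- cand
      return(invisible(NULL))
    }
    v <- remaining[which.max(deg)]
    # include v
    rec(setdiff(remaining, c(v, which(adj[v, ] & seq_len(n) %in% remaining))),
        c(chosen, v))
    # exclude v
    rec(setdiff(remaining, v), chosen)
  }
  rec(seq_len(n), integer(0))
  sort(best)
}

## Greedy fallback for large conflict components: iteratively drop the point
## with the most neighbours inside the threshold, ties to the lowest index.
mis_greedy <- function(adj) {
  alive <- rep(TRUE, nrow(adj))
  repeat {
    deg <- colSums(adj[alive, alive, drop = FALSE])
    if (!length(deg) || all(deg == 0)) break
    drop_local <- which.max(deg)
    idx <- which(alive)[drop_local]
    alive[idx] <- FALSE
  }
  which(alive)
}

connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0
  for (s in seq_len(n)) {
    if (comp[s] == 0) {
      cur <- cur + 1
      stack <- s
      while (length(stack)) {
        v <- stack[length(stack)]; stack <- stack[-length(stack)]
        if (comp[v] == 0) {
          comp[v] <- cur
          stack <- c(stack, which(adj[v, ] & comp == 0))
        }
      }
    }
  }
  comp
}

#' Spatial thinning of occurrence records
#'
#' Retains a maximum-size subset of points whose pairwise great-circle
#' distances are all at least `min_dist_km` (haversine, Earth radius
#' 6371.0088 km). Points closer than the threshold form a conflict graph;
#' within each connected component an exact maximum independent set is
#' computed by branch-and-bound (deterministic, lexicographic tie-break)
#' for components up to `exact_limit` points, with a greedy
#' most-neighbours-removed fallback above that. The result is idempotent:
#' re-thinning a thinned set changes nothing. Multi-species tables are
#' thinned per species.
#'
#' @param occ occurrence data.frame.
#' @param min_dist_km minimum pairwise distance to enforce, km. Default
#'   5.2 km (one point per 2.5-arcmin pixel).
#' @param frame optional [env_grid()]; when given, points are first
#'   de-duplicated per grid cell (keeping the first).
#' @param exact_limit component size above which the greedy fallback is used.
#' @return thinned occurrence data.frame (subset of the input rows).
#' @export
thin_occurrences <- function(occ, min_dist_km = 5.2, frame = NULL,
                             exact_limit = 24) {
  check_number(min_dist_km, "min_dist_km")
  if (min_dist_km <= 0) stop_invalid("`min_dist_km` must be > 0")
  if (length(unique(occ$species)) > 1) {
    parts <- split(seq_len(nrow(occ)), occ$species)
    keep <- sort(unlist(lapply(parts, function(ix) {
      ix[thin_indices(occ[ix, , drop = FALSE], min_dist_km, frame, exact_limit)]
    }), use.names = FALSE))
    out <- occ[keep, , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  out <- occ[thin_indices(occ, min_dist_km, frame, exact_limit), , drop = FALSE]
  rownames(out) <- NULL
  out
}

thin_indices <- function(occ, min_dist_km, frame, exact_limit) {
  n <- nrow(occ)
  if (n <= 1) return(seq_len(n))
  keep0 <- seq_len(n)
  if (!is.null(frame)) {            # per-cell dedup before distance thinning
    rc <- point_to_cell(frame, occ$longitude, occ$latitude)
    cellkey <- paste(rc$row, rc$col)
    keep0 <- keep0[!duplicated(cellkey)]
  }
  if (length(keep0) == 1) return(keep0)
  d <- haversine_matrix(occ$longitude[keep0], occ$latitude[keep0])
  adj <- d < min_dist_km
  diag(adj) <- FALSE
  if (!any(adj)) return(keep0)
  comp <- connected_components(adj)
  kept <- unlist(lapply(unique(comp), function(cc) {
    vs <- which(comp == cc)
    if (length(vs) == 1) return(vs)
    sub <- adj[vs, vs, drop = FALSE]
    if (length(vs) <= exact_limit) vs[mis_exact(sub)] else vs[mis_greedy(sub)]
  }), use.names = FALSE)
  keep0[sort(kept)]
}

#' Exclude temperature/precipitation interaction variables
#'
#' Removes the four bioclim variables that mix temperature and
#' precipitation measurements (bio8, bio9, bio18, bio19), which carry known
#' spatial anomalies, from the retained variable set.
#'
#' @param vars character vector of variable names, or a list with elements
#'   `names` and `excluded`.
#' @return list with `names` (retained) and `excluded`.
#' @export
exclude_interactive_variables <- function(vars) {
  interactive_vars <- c("bio8", "bio9", "bio18", "bio19")
  if (is.list(vars)) {
    prior_excluded <- vars$excluded
    vars <- vars$names
  } else {
    prior_excluded <- character(0)
  }
  hit <- intersect(vars, interactive_vars)
  list(names = setdiff(vars, hit),
       excluded = union(prior_excluded, hit))
}
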