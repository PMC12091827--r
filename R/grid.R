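#' Environmental grid
#'
#' A georeferenced lattice of one climatic variable's values on a regular
#' lon/lat grid (WGS84, lower-left-corner registered), with missing cells
#' stored as `NA`. All grids entering one analysis must share the same
#' spatial frame (origin, cell size, shape); see [same_frame()].
#'
#' @param values numeric matrix, row 1 = northernmost row (as serialized in
#'   the ESRI ASCII dialect); `NA` marks nodata cells.
#' @param variable variable name, e.g. `"bio1"`.
#' @param xll,yll longitude/latitude of the lower-left corner of the grid,
#'   in decimal degrees.
#' @param cellsize cell width in degrees (square cells).
#' @param nodata_value sentinel used when the grid is serialized.
#' @return An object of class `env_grid`.
#' @export
env_grid <- function(values, variable = "env", xll = 0, yll = 0,
                     cellsize = 1, nodata_value = -9999) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_invalid("`values` must be a numeric matrix")
  }
  check_number(xll, "xll"); check_number(yll, "yll")
  check_number(cellsize, "cellsize")
  if (cellsize <= 0) stop_invalid("`cellsize` must be > 0")
  if (any(!is.finite(values) & !is.na(values))) {
    stop_invalid("grid values must be finite or NA")
  }
  structure(
    list(values = values, variable = as.character(variable),
         xll = xll, yll = yll, cellsize = cellsize,
         nodata_value = nodata_value),
    class = "env_grid"
  )
}

#' @export
print.env_grid <- function(x, ...) {
  cat(sprintf("<env_grid> %s: %d x %d cells, cellsize %g deg, origin (%g, %g), %d nodata\n",
              x$variable, nrow(x$values), ncol(x$values), x$cellsize,
              x$xll, x$yll, sum(is.na(x$values))))
  invisible(x)
}

#' @rdname env_grid
#' @param x an `env_grid`.
#' @export
n_rows <- function(x) nrow(x$values)

#' @rdname env_grid
#' @export
n_cols <- function(x) ncol(x$values)

#' Do two grids share one spatial frame?
#'
#' @param a,b `env_grid` objects (or accessible-area masks carrying a frame).
#' @param tol numeric tolerance on origin and cell size.
#' @return logical.
#' @export
same_frame <- function(a, b, tol = 1e-9) {
  nrow(a$values) == nrow(b$values) && ncol(a$values) == ncol(b$values) &&
    abs(a$xll - b$xll) < tol && abs(a$yll - b$yll) < tol &&
    abs(a$cellsize - b$cellsize) < tol
}

assert_shared_frame <- function(grids) {
  if (length(grids) > 1) {
    for (i in 2:length(grids)) {
      if (!same_frame(grids[[1]], grids[[i]])) {
        stop_invalid("grids '%s' and '%s' do not share a spatial frame",
                     grids[[1]]$variable, grids[[i]]$variable)
      }
    }
  }
  invisible(TRUE)
}

#' Cell centers of a grid
#'
#' @param grid an `env_grid`.
#' @return list with `lon` (length `n_cols`) and `lat` (length `n_rows`,
#'   ordered north to south to match matrix rows).
#' @export
cell_centers <- function(grid) {
  nr <- n_rows(grid); nc <- n_cols(grid)
  list(
    lon = grid$xll + (seq_len(nc) - 0.5) * grid$cellsize,
    lat = grid$yll + (nr - seq_len(nr) + 0.5) * grid$cellsize
  )
}

#' Map points to grid cells
#'
#' Cells are half-open, `[x, x + cellsize) x [y, y + cellsize)`; points on
#' the extreme top/right boundary of the grid map to the last cell. Points
#' outside the extent yield `NA` row/col.
#'
#' @param grid an `env_grid`.
#' @param lon,lat numeric vectors of point coordinates (degrees).
#' @return data.frame with integer columns `row` (1 = north) and `col`.
#' @export
point_to_cell <- function(grid, lon, lat) {
  nr <- n_rows(grid); nc <- n_cols(grid)
  xmax <- grid$xll + nc * grid$cellsize
  ymax <- grid$yll + nr * grid$cellsize
  col <- floor((lon - grid$xll) / grid$cellsize) + 1
  row_from_bottom <- floor((lat - grid$yll) / grid$cellsize) + 1
  col[lon == xmax] <- nc           # top/right boundary convention
  row_from_bottom[lat == ymax] <- nr
  out <- lon < grid$xll | lon > xmax | lat < grid$yll | lat > ymax
  col[out] <- NA_integer_
  row_from_bottom[out] <- NA_integer_
  data.frame(row = as.integer(nr - row_from_bottom + 1), col = as.integer(col))
}

#' Extract grid values at point locations
#'
#' @inheritParams point_to_cell
#' @return numeric vector; `NA` for points outside the extent or on nodata.
#' @export
grid_values_at <- function(grid, lon, lat) {
  rc <- point_to_cell(grid, lon, lat)
  vals <- rep(NA_real_, nrow(rc))
  ok <- !is.na(rc$row)
  vals[ok] <- grid$values[cbind(rc$row[ok], rc$col[ok])]
  vals
}

#' Read an ESRI ASCII grid
#'
#' Parses the `ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value` header
#' dialect; cells equal to the nodata sentinel become `NA`.
#'
#' @param path file path.
#' @param variable variable name to attach (defaults to the file stem).
#' @return an [env_grid()].
#' @export
read_env_grid <- function(path, variable = NULL) {
  lines <- readLines(path)
  if (length(lines) < 6) stop_invalid("'%s': incomplete ESRI ASCII header", path)
  hdr <- list()
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  i <- 1
  while (i <= length(lines)) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (!(key %in% c(need, "nodata_value"))) break
    if (length(parts) != 2 || is.na(suppressWarnings(as.numeric(parts[2])))) {
      stop_invalid("'%s': malformed header at line %d: '%s'", path, i, lines[i])
    }
    hdr[[key]] <- as.numeric(parts[2])
    i <- i + 1
  }
  missing <- setdiff(need, names(hdr))
  if (length(missing)) {
    stop_invalid("'%s': header missing field(s): %s", path,
                 paste(missing, collapse = ", "))
  }
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  body <- lines[i:length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != nr) {
    stop_invalid("'%s': expected %d data rows, found %d (format error at line %d)",
                 path, nr, length(body), i + length(body))
  }
  vals <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    row <- suppressWarnings(as.numeric(strsplit(trimws(body[r]), "\\s+")[[1]]))
    if (length(row) != nc || anyNA(row)) {
      stop_invalid("'%s': row %d has %d values, expected %d (line %d)",
                   path, r, length(row), nc, i + r - 1)
    }
    vals[r, ] <- row
  }
  vals[vals == nodata] <- NA_real_
  if (is.null(variable)) {
    variable <- sub("\\.[^.]*$", "", basename(path))
  }
  env_grid(vals, variable = variable, xll = hdr$xllcorner, yll = hdr$yllcorner,
           cellsize = hdr$cellsize, nodata_value = nodata)
}

#' Write an ESRI ASCII grid
#'
#' Round-trips bit-exactly with [read_env_grid()] for values written at
#' full precision.
#'
#' @param grid an [env_grid()].
#' @param path output file path.
#' @export
write_env_grid <- function(grid, path) {
  vals <- grid$values
  vals[is.na(vals)] <- grid$nodata_value
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(vals)),
    sprintf("nrows %d", nrow(vals)),
    sprintf("xllcorner %s", format(grid$xll, digits = 17)),
    sprintf("yllcorner %s", format(grid$yll, digits = 17)),
    sprintf("cellsize %s", format(grid$cellsize, digits = 17)),
    sprintf("NODATA_value %s", format(grid$nodata_value, digits = 17))
  ), con)
  writeLines(apply(vals, 1, function(r) {
    paste(format(r, digits = 17, trim = TRUE, scientific = FALSE), collapse = " ")
  }), con)
  invisible(path)
}
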