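#' Project ancestral/current niche states into geographic space
#'
#' Paints each cell of a species' accessible area with a category derived
#' from the bin its environmental value falls in: `both` (present in
#' ancestor and descendant), `ancestral_only` (retraction zone),
#' `current_only` (expansion zone), `neither`, or `indeterminate` when
#' either state is uncertain or the value falls outside the bin scheme.
#' Cells outside M are `outside_M`.
#'
#' @param area the species' `accessible_area`.
#' @param grid the variable's [env_grid()] (same frame).
#' @param scheme the variable's `bin_scheme`.
#' @param A,D ancestor and descendant bin-state vectors over
#'   `{"1", "0", "?"}` aligned to `scheme`.
#' @param species species label.
#' @return list of class `projection_grid`: `species`, `variable`,
#'   `categories` (integer matrix coded by `projection_legend()`), frame
#'   fields, and `n_outside_scheme` (warning count).
#' @export
project_change <- function(area, grid, scheme, A, D, species = area$species) {
  if (length(A) != scheme$n_bins || length(D) != scheme$n_bins) {
    stop_invalid("state vectors are not aligned to the bin scheme")
  }
  legend <- projection_legend()
  cat_codes <- matrix(legend[["outside_M"]], n_rows(grid), n_cols(grid))
  idx <- which(area$mask)
  vals <- grid$values[idx]
  b <- bin_index(vals, scheme)
  cell_cat <- integer(length(idx))
  out_scheme <- is.na(b)
  cell_cat[out_scheme] <- legend[["indeterminate"]]
  ok <- !out_scheme
  a <- A[b[ok]]; d <- D[b[ok]]
  cc <- ifelse(a == "?" | d == "?", legend[["indeterminate"]],
        ifelse(a == "1" & d == "1", legend[["both"]],
        ifelse(a == "1" & d == "0", legend[["ancestral_only"]],
        ifelse(a == "0" & d == "1", legend[["current_only"]],
               legend[["neither"]]))))
  cell_cat[ok] <- cc
  cat_codes[idx] <- cell_cat
  n_out <- sum(out_scheme)
  if (n_out > 0) {
    warning(sprintf("'%s': %d M cells have values outside the bin scheme; coded indeterminate",
                    species, n_out))
  }
  structure(list(species = species, variable = scheme$variable,
                 categories = cat_codes,
                 xll = grid$xll, yll = grid$yll, cellsize = grid$cellsize,
                 nodata_value = grid$nodata_value,
                 n_outside_scheme = n_out,
                 occurrence_only = identical(area$status, "occurrence_only")),
            class = "projection_grid")
}

#' Category legend for projection grids
#'
#' @return named integer vector mapping category names to grid codes.
#' @export
projection_legend <- function() {
  c(outside_M = 0L, both = 1L, ancestral_only = 2L, current_only = 3L,
    neither = 4L, indeterminate = 5L)
}

#' Export a projection grid as an integer-coded ASCII raster plus legend
#'
#' @param proj a `projection_grid`.
#' @param path output raster path; a `<path>.legend.txt` sidecar lists the
#'   category codes.
#' @export
export_category_grid <- function(proj, path) {
  g <- env_grid(proj$categories + 0, variable = proj$variable,
                xll = proj$xll, yll = proj$yll, cellsize = proj$cellsize,
                nodata_value = -1)
  write_env_grid(g, path)
  legend <- projection_legend()
  writeLines(sprintf("%d\t%s", unname(legend), names(legend)),
             paste0(path, ".legend.txt"))
  invisible(path)
}

#' Read back an exported category grid
#'
#' @param path raster path written by [export_category_grid()].
#' @return integer matrix of category codes.
#' @export
read_category_grid <- function(path) {
  g <- read_env_grid(path)
  m <- g$values
  storage.mode(m) <- "integer"
  m
}
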