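#' Union of accessible-area masks
#'
#' @param areas list of `accessible_area` objects on one frame.
#' @return logical matrix, `TRUE` where at least one mask is `TRUE`.
#' @export
union_mask <- function(areas) {
  if (!length(areas)) stop_invalid("`areas` must contain at least one accessible area")
  out <- areas[[1]]$mask
  for (a in areas[-1]) {
    if (!all(dim(a$mask) == dim(out))) stop_invalid("masks differ in shape")
    out <- out | a$mask
  }
  out
}

#' Niche summary statistics
#'
#' Mean, sample standard deviation (n - 1), median, minimum, maximum and
#' quartiles (linear-interpolation, type 7) of a set of environmental
#' values, as used to characterize each species' realized and accessible
#' niche per variable.
#'
#' @param values numeric vector of environmental values.
#' @param species,variable,source labels carried into the output.
#' @return one-row data.frame with columns `species`, `variable`,
#'   `source`, `mean`, `sd`, `median`, `min`, `max`, `q1`, `q3`, `range`.
#' @export
niche_summary <- function(values, species = NA_character_,
                          variable = NA_character_, source = "occurrences") {
  values <- values[is.finite(values)]
  if (!length(values)) stop_invalid("`values` must contain at least one finite value")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  data.frame(
    species = species, variable = variable, source = source,
    mean = mean(values),
    sd = if (length(values) > 1) stats::sd(values) else 0,
    median = q[2], min = min(values), max = max(values),
    q1 = q[1], q3 = q[3], range = max(values) - min(values),
    stringsAsFactors = FALSE)
}

#' Build an equal-width bin scheme for one variable
#'
#' The global niche range is the min/max of the grid values over the union
#' of all accessible areas. The range is parsed into
#' `max(1, round(range / target_width))` bins of exactly equal width
#' (hence widths approximate the target, e.g. ~1 degree C or ~100 mm).
#' Bins are half-open `[edge_i, edge_{i+1})`, the last bin closed.
#'
#' @param grid an [env_grid()].
#' @param union logical matrix from [union_mask()] (or `NULL` to use all
#'   data cells).
#' @param target_width target bin width in environmental units.
#' @return list of class `bin_scheme`: `variable`, `edges`, `width`,
#'   `global_min`, `global_max`, `n_bins`.
#' @export
build_bin_scheme <- function(grid, union = NULL, target_width) {
  check_number(target_width, "target_width")
  if (target_width <= 0) stop_invalid("`target_width` must be > 0")
  vals <- if (is.null(union)) grid$values else grid$values[union]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop_invalid("union of accessible areas covers no data cell")
  lo <- min(vals); hi <- max(vals)
  if (hi - lo <= 0) {
    warning("zero environmental range over the union; single degenerate bin")
    return(structure(list(variable = grid$variable,
                          edges = c(lo, lo + target_width),
                          width = target_width,
                          global_min = lo, global_max = hi, n_bins = 1L),
                     class = "bin_scheme"))
  }
  n_bins <- max(1L, as.integer(round((hi - lo) / target_width)))
  width <- (hi - lo) / n_bins
  structure(list(variable = grid$variable,
                 edges = seq(lo, hi, length.out = n_bins + 1L),
                 width = width, global_min = lo, global_max = hi,
                 n_bins = n_bins),
            class = "bin_scheme")
}

#' @export
print.bin_scheme <- function(x, ...) {
  cat(sprintf("<bin_scheme> %s: %d bins of width %.4g over [%.4g, %.4g]\n",
              x$variable, x$n_bins, x$width, x$global_min, x$global_max))
  invisible(x)
}

#' Midpoints of a bin scheme
#' @param scheme a `bin_scheme`.
#' @return numeric vector of bin midpoints.
#' @export
bin_midpoints <- function(scheme) {
  (scheme$edges[-1] + scheme$edges[-length(scheme$edges)]) / 2
}

#' Bin index of environmental values
#'
#' Half-open bins, last bin closed at `global_max`; values outside the
#' scheme range give `NA`.
#'
#' @param values numeric vector.
#' @param scheme a `bin_scheme`.
#' @return integer vector of 1-based bin indices.
#' @export
bin_index <- function(values, scheme) {
  idx <- findInterval(values, scheme$edges, rightmost.closed = TRUE)
  idx[idx < 1 | idx > scheme$n_bins] <- NA_integer_
  idx[is.na(values)] <- NA_integer_
  as.integer(idx)
}

## bins whose half-open interval has non-empty overlap with [lo, hi] (closed)
bins_overlapping_closed <- function(scheme, lo, hi) {
  e <- scheme$edges
  n <- scheme$n_bins
  left <- e[-length(e)]; right <- e[-1]
  ov <- left <= hi & right > lo
  ov[n] <- ov[n] | (left[n] <= hi & right[n] >= lo)   # last bin closed
  which(ov)
}

## bins overlapping the open interval (lo, hi)
bins_overlapping_open <- function(scheme, lo, hi) {
  e <- scheme$edges
  left <- e[-length(e)]; right <- e[-1]
  which(left < hi & right > lo)
}

#' Code a species' binned-range (BR) character vector
#'
#' Applies the BR coding rules: (1) every bin overlapping the closed
#' occupied range `[min(occ), max(occ)]` is present (`"1"`); (2) bins
#' within the accessible (M) environmental range but outside the occupied
#' range are absent (`"0"`); (3) bins beyond the M range are uncertain
#' (`"?"`) — environment the species could not sample. For species
#' without a simulated M (`m_vals = NULL`), every bin outside the
#' occupied range is uncertain.
#'
#' @param occ_vals environmental values at the species' occurrences.
#' @param m_vals environmental values over the species' M, or `NULL` for
#'   occurrence-only species.
#' @param scheme a `bin_scheme`.
#' @return character vector over `{"1", "0", "?"}`, one entry per bin.
#' @export
code_br <- function(occ_vals, m_vals, scheme) {
  occ_vals <- occ_vals[is.finite(occ_vals)]
  if (!length(occ_vals)) stop_invalid("no finite occurrence values to code")
  o_lo <- min(occ_vals); o_hi <- max(occ_vals)
  if (o_hi < scheme$global_min || o_lo > scheme$global_max) {
    stop_invalid("occupied range [%g, %g] lies outside the bin scheme range [%g, %g]",
                 o_lo, o_hi, scheme$global_min, scheme$global_max)
  }
  out <- rep("?", scheme$n_bins)
  if (!is.null(m_vals)) {
    m_vals <- m_vals[is.finite(m_vals)]
    if (!length(m_vals)) stop_invalid("no finite M values to code against")
    m_lo <- min(min(m_vals), o_lo)     # M range must contain the occupied range
    m_hi <- max(max(m_vals), o_hi)
    out[bins_overlapping_open(scheme, m_lo, m_hi)] <- "0"
  }
  out[bins_overlapping_closed(scheme, o_lo, o_hi)] <- "1"
  out
}

#' Build the species-by-bin BR matrix for one variable
#'
#' @param codings named list (species -> BR character vector) all coded
#'   against `scheme`.
#' @param tree dated tree; rows are ordered to match `tree$tip.label`.
#' @param scheme the `bin_scheme` used.
#' @return character matrix of class `br_matrix` (rows = species in tip
#'   order, columns named by bin midpoints), with attributes `scheme` and
#'   `variable`.
#' @export
build_br_matrix <- function(codings, tree, scheme) {
  tips <- tree$tip.label
  missing <- setdiff(tips, names(codings))
  extra <- setdiff(names(codings), tips)
  if (length(missing) || length(extra)) {
    stop_invalid("species/tree mismatch; missing from codings: {%s}; not in tree: {%s}",
                 paste(missing, collapse = ", "), paste(extra, collapse = ", "))
  }
  m <- do.call(rbind, codings[tips])
  rownames(m) <- tips
  colnames(m) <- format(bin_midpoints(scheme), digits = 10, trim = TRUE)
  ## tip invariant: at least one present bin forming a contiguous run
  for (sp in tips) {
    pres <- which(m[sp, ] == "1")
    if (!length(pres)) stop_invalid("species '%s' has no present bin", sp)
    if (any(diff(pres) != 1)) {
      stop_invalid("species '%s': present bins are not contiguous", sp)
    }
  }
  structure(m, class = c("br_matrix", class(m)), scheme = scheme,
            variable = scheme$variable)
}

#' Write / read a BR matrix as TSV
#'
#' @param br a `br_matrix`.
#' @param path file path.
#' @export
write_br_matrix <- function(br, path) {
  utils::write.table(unclass(br), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' @rdname write_br_matrix
#' @export
read_br_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE,
                                   colClasses = "character"))
  m
}
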