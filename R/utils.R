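#' @keywords internal
"_PACKAGE"

## Run expr with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

## scalar checks used across modules
check_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (finite && !is.finite(x))) {
    stop_invalid("`%s` must be a single finite number", name)
  }
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  check_number(x, name)
  if (x < min || x != floor(x)) {
    stop_invalid("`%s` must be an integer >= %d", name, min)
  }
  invisible(as.integer(x))
}
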