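#' Round for reporting (half away from zero)
#'
#' Monetary figures are stored at full floating precision throughout the
#' package; rounding to whole currency units happens only when a value is
#' presented in a report. Ties round away from zero (so 0.5 -> 1, -0.5 -> -1),
#' matching the usual convention of financial tables rather than base R's
#' banker's rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places to keep (default 0).
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' report_round(c(0.5, 1.5, -0.5, 2.4))
report_round <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# scalar checks used by the constructors; stop with the offending field name
.check_nonneg <- function(x, field) {
  if (any(!is.finite(x) | x < 0)) {
    stop(sprintf("field '%s' must be finite and >= 0", field), call. = FALSE)
  }
  invisible(x)
}

.check_prob <- function(x, field) {
  if (any(!is.finite(x) | x < 0 | x > 1)) {
    stop(sprintf("field '%s' must lie in [0, 1]", field), call. = FALSE)
  }
  invisible(x)
}

.check_enum <- function(x, values, field) {
  if (any(!x %in% values)) {
    stop(sprintf("field '%s' must be one of: %s", field,
                 paste(values, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

.check_count <- function(x, field) {
  if (any(!is.finite(x) | x < 0 | x != floor(x))) {
    stop(sprintf("field '%s' must be a nonnegative integer count", field),
         call. = FALSE)
  }
  invisible(x)
}

# lossless, deterministic numeric formatting for the CSV writers: 17
# significant digits round-trips any double through read.csv exactly
.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else formatC(v, digits = 17, format = "g")
  }, character(1))
  out
}

# run an expression with a locally-seeded RNG, restoring global RNG state
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop("'seed' must be a single finite number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
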