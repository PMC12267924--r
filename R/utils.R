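#' Round half away from zero
#'
#' Reporting-style rounding: exact .5 cases go up, unlike [base::round()]'s
#' banker's rounding. Used only for "reported" percentage fields; all internal
#' arithmetic stays at full precision.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(27.25, 1) # 27.3
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Deterministic 32-bit sub-seed for a named random stream. One user-facing
# seed fans out into independent per-table streams so partial regeneration is
# reproducible.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 1009) %% 2147483587) + 1L
}

with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derive_seed(seed, stream))
  expr
}

# sample() without the scalar-x surprise: safe_sample(5L, 1) draws 5, not 1:5
safe_sample <- function(x, size, ...) {
  if (length(x) == 1) {
    if (size >= 1) x else x[0]
  } else {
    sample(x, size, ...)
  }
}

assert_columns <- function(df, cols, what = "input table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")),
          class = "natparadox_input_error")
  }
  invisible(df)
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < min || x > max) {
    abort(sprintf("configuration field `%s` must be a single finite number in [%s, %s]",
                  name, format(min), format(max)),
          class = "natparadox_config_error")
  }
  invisible(x)
}
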