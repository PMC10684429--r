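#' @keywords internal
"_PACKAGE"

# Classed conditions so callers can distinguish validation, parse, I/O,
# numerical and degenerate-input failures programmatically.
gp_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "goodph_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

gp_validation_error <- function(msg) gp_stop(msg, "goodph_validation_error")
gp_parse_error      <- function(msg) gp_stop(msg, "goodph_parse_error")
gp_io_error         <- function(msg) gp_stop(msg, "goodph_io_error")
gp_numeric_error    <- function(msg) gp_stop(msg, "goodph_numeric_error")
gp_degenerate_error <- function(msg) gp_stop(msg, "goodph_degenerate_error")
gp_range_error      <- function(msg) gp_stop(msg, "goodph_range_error")

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    gp_validation_error(sprintf("'%s' must be a number, got NULL", name))
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    gp_validation_error(sprintf("'%s' must be a single finite number", name))
  }
  if (x < lower || x > upper) {
    gp_validation_error(sprintf("'%s' = %g outside [%g, %g]", name, x, lower, upper))
  }
  invisible(x)
}

# Kelvin range shared by every temperature-accepting entry point.
assert_temperature <- function(temperature, name = "temperature") {
  assert_scalar_number(temperature, name, lower = 273.15, upper = 373.15)
}

# Evaluate `expr` under a deterministic RNG state without disturbing the
# caller's stream (the synthetic module promises seed-reproducibility).
with_seed <- function(seed, expr) {
  if (is.null(seed)) gp_validation_error("a seed must be set explicitly")
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
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a base seed and an index
#'
#' Deterministic mixing used by the simulators so that every spectrum in a
#' series gets its own reproducible random stream. Always below 2^31.
#'
#' @param seed Base integer seed.
#' @param index Integer stream index.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + as.double(index) * 104729) %% 2147483629)
}
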