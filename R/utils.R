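# Internal helpers shared across modules.

# Validate a single numeric parameter lies in [lo, hi]; name the offender.
check_param <- function(x, name, lo = -Inf, hi = Inf, lo_open = FALSE,
                        hi_open = FALSE, integer = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "ddmosaic_parameter_error")
  }
  bad_lo <- if (lo_open) x <= lo else x < lo
  bad_hi <- if (hi_open) x >= hi else x > hi
  if (bad_lo || bad_hi) {
    abort(sprintf("`%s` = %g is outside its valid range %s%g, %g%s.",
                  name, x, if (lo_open) "(" else "[", lo, hi,
                  if (hi_open) ")" else "]"),
          class = "ddmosaic_parameter_error")
  }
  if (integer && x != round(x)) {
    abort(sprintf("`%s` must be a whole number.", name),
          class = "ddmosaic_parameter_error")
  }
  invisible(x)
}

#' Round half away from zero
#'
#' Printed cohort percentages use commercial ("half-up") rounding, which
#' differs from R's bankers rounding at exact .5 ties.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @examples
#' round_half_up(c(0.125, 96.774, 87.875), 1)
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Convert between fraction and percent scales
#'
#' MAFs are fractions in `[0, 1]` internally; all tabular I/O uses percent
#' with two decimals. These helpers centralise the conversion.
#'
#' @param x numeric vector.
#' @return numeric vector on the other scale.
#' @export
frac_to_pct <- function(x) 100 * x

#' @rdname frac_to_pct
#' @export
pct_to_frac <- function(x) x / 100

# Derive a stream-specific 32-bit seed from a base seed without touching
# global RNG state outside withr-free local evaluation.
derive_seed <- function(seed, offset = 0L) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
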