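# broom-style tidiers for fitted objects.

#' Tidy a MAF concordance fit
#'
#' @param x a `maf_concordance` object.
#' @param ... unused.
#' @return tibble with one row per OLS coefficient (`term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`).
#' @method tidy maf_concordance
#' @export
tidy.maf_concordance <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble(term = rownames(sm), estimate = unname(sm[, 1]),
         std.error = unname(sm[, 2]), statistic = unname(sm[, 3]),
         p.value = unname(sm[, 4]))
}

#' Glance at a MAF concordance fit
#'
#' @param x a `maf_concordance` object.
#' @param ... unused.
#' @return one-row tibble: `r.squared`, `slope`, `intercept`, `n.pairs`.
#' @method glance maf_concordance
#' @export
glance.maf_concordance <- function(x, ...) {
  tibble(r.squared = x$r_squared, slope = x$slope,
         intercept = x$intercept, n.pairs = x$n_pairs)
}

#' Tidy a report bundle's family classifications
#'
#' @param x a `report_bundle` from [run_pipeline()].
#' @param ... unused.
#' @return the family classification tibble.
#' @method tidy report_bundle
#' @export
tidy.report_bundle <- function(x, ...) x$families

#' Glance at a report bundle
#'
#' @param x a `report_bundle` from [run_pipeline()].
#' @param ... unused.
#' @return the one-row cohort summary tibble.
#' @method glance report_bundle
#' @export
glance.report_bundle <- function(x, ...) x$summary
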