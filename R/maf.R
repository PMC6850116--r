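# Statistical core: exact binomial CIs for MAFs, the CI-based
# positive-detection rule, negative-control error-rate pooling,
# detection-limit curves, and cross-platform concordance.

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval for a binomial proportion, obtained by
#' inverting the binomial tail tests; computed through the beta-quantile
#' closed form. The lower bound is exactly 0 when `k = 0` and the upper
#' bound exactly 1 when `k = n`; for `k = 0` the upper bound equals
#' `1 - (alpha/2)^(1/n)`.
#'
#' Exact intervals are conservative (coverage at least the nominal level),
#' which is the appropriate behaviour when calling rare alleles against a
#' detection cutoff.
#'
#' @param k mutant (success) count(s), `0 <= k <= n`.
#' @param n denominator(s), `>= 1`. Vectorised; recycled against `k`.
#' @param alpha two-sided level (default 0.05 for 95% intervals).
#' @return tibble with columns `lower`, `upper` (fractions).
#' @examples
#' binomial_ci(5, 10000)
#' binomial_ci(0, 30000)$upper  # = 1 - 0.025^(1/30000)
#' @export
binomial_ci <- function(k, n, alpha = 0.05) {
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be a single number in (0, 1).",
          class = "ddmosaic_domain_error")
  }
  if (any(!is.finite(k)) || any(!is.finite(n))) {
    abort("`k` and `n` must be finite.", class = "ddmosaic_domain_error")
  }
  m <- vctrs_recycle(k, n)
  k <- m[[1]]; n <- m[[2]]
  if (any(n < 1)) {
    abort("`n` must be >= 1.", class = "ddmosaic_domain_error")
  }
  if (any(k < 0) || any(k > n)) {
    abort("`k` must satisfy 0 <= k <= n.", class = "ddmosaic_domain_error")
  }
  lower <- ifelse(k == 0, 0, qbeta(alpha / 2, k, n - k + 1))
  upper <- ifelse(k == n, 1, qbeta(1 - alpha / 2, k + 1, n - k))
  tibble(lower = lower, upper = upper)
}

# Minimal common-length recycling for two numeric vectors.
vctrs_recycle <- function(a, b) {
  len <- max(length(a), length(b))
  if ((len %% length(a)) != 0 || (len %% length(b)) != 0) {
    abort("Incompatible lengths.", class = "ddmosaic_domain_error")
  }
  list(rep_len(a, len), rep_len(b, len))
}

#' Estimate MAF with exact confidence interval
#'
#' Data-frame-first MAF estimation. Accepts droplet count rows (`mu` and
#' `wt` or `informative`) or amplicon rows (`alt_reads` and `depth`), and
#' appends `maf`, `ci_low`, `ci_high`, `k`, `n` columns (fractions).
#' Non-informative (`na`) droplets never enter the denominator.
#'
#' @param counts data frame of count rows.
#' @param alpha two-sided CI level.
#' @param platform optional platform tag recorded in the output when the
#'   input has no `platform` column.
#' @return the input tibble with estimate columns appended.
#' @examples
#' estimate_maf(tibble::tibble(mu = 50, wt = 9950))
#' @export
estimate_maf <- function(counts, alpha = 0.05, platform = NULL) {
  stopifnot(is.data.frame(counts))
  counts <- as_tibble(counts)
  has_droplets <- all(c("mu", "wt") %in% names(counts)) ||
    all(c("mu", "informative") %in% names(counts))
  has_reads <- all(c("alt_reads", "depth") %in% names(counts))
  if (!has_droplets && !has_reads) {
    abort("Need droplet counts (`mu`, `wt`) or read counts (`alt_reads`, `depth`).",
          class = "ddmosaic_estimation_error")
  }
  if (has_droplets) {
    k <- counts$mu
    n <- if ("informative" %in% names(counts) &&
             !all(is.na(counts$informative))) {
      counts$informative
    } else counts$mu + counts$wt
  } else {
    k <- counts$alt_reads
    n <- counts$depth
  }
  if (any(is.na(n)) || any(n < 1)) {
    abort("Zero or missing informative denominator; MAF is undefined (not 0).",
          class = "ddmosaic_estimation_error")
  }
  ci <- binomial_ci(k, n, alpha)
  out <- mutate(counts, maf = .env$k / .env$n, ci_low = ci$lower,
                ci_high = ci$upper, k = .env$k, n = .env$n,
                alpha = .env$alpha)
  if (!"platform" %in% names(out) && !is.null(platform)) {
    out$platform <- platform
  }
  out
}

#' Call samples with the CI-based positive-detection rule
#'
#' A sample is called `mosaic` when the lower bound of its MAF confidence
#' interval strictly exceeds `lower_cut` (the noise-derived detection
#' cutoff) and the upper bound is strictly below `upper_cut` (the
#' constitutional-heterozygote expectation); `het_consistent` when the
#' upper bound reaches `upper_cut`; otherwise `negative`. Comparisons are
#' performed at the precision of the supplied bounds: printed two-decimal
#' percent tables are compared as printed on the percent scale
#' (`unit = "percent"`, cutoffs 0.01 and 50.00), so a printed lower bound
#' of exactly 0.01 is negative.
#'
#' @param data data frame with CI bound columns.
#' @param lower_cut,upper_cut detection cutoffs in the unit of the bounds.
#'   Defaults: 0.0001 / 0.50 for fractions, 0.01 / 50.00 for percents.
#' @param unit `"fraction"` (columns `ci_low`, `ci_high`) or `"percent"`
#'   (columns `ci_low_pct`, `ci_high_pct`).
#' @return input tibble with a `call` column (`negative`, `mosaic`,
#'   `het_consistent`); rows with missing bounds get `NA` calls.
#' @examples
#' load_cohort_fixture("table1_blood") |>
#'   dplyr::filter(platform == "mDDPCR") |>
#'   classify_sample(unit = "percent")
#' @export
classify_sample <- function(data, lower_cut = NULL, upper_cut = NULL,
                            unit = c("fraction", "percent")) {
  unit <- match.arg(unit)
  stopifnot(is.data.frame(data))
  lo_col <- if (unit == "fraction") "ci_low" else "ci_low_pct"
  hi_col <- if (unit == "fraction") "ci_high" else "ci_high_pct"
  if (!all(c(lo_col, hi_col) %in% names(data))) {
    abort(sprintf("Need columns `%s` and `%s`.", lo_col, hi_col),
          class = "ddmosaic_domain_error")
  }
  lower_cut <- lower_cut %||% if (unit == "fraction") 0.0001 else 0.01
  upper_cut <- upper_cut %||% if (unit == "fraction") 0.50 else 50.00
  lo <- data[[lo_col]]
  hi <- data[[hi_col]]
  call <- dplyr::case_when(
    is.na(lo) | is.na(hi) ~ NA_character_,
    lo > lower_cut & hi < upper_cut ~ "mosaic",
    hi >= upper_cut ~ "het_consistent",
    TRUE ~ "negative"
  )
  mutate(as_tibble(data), call = call)
}

#' Pool negative-control droplet counts into an assay error rate
#'
#' The empirical false-mutant-call rate is the total mutant droplet count
#' over the total informative droplet count across all negative controls,
#' with an exact binomial CI on the pooled counts.
#'
#' @param controls data frame of negative-control count rows (`mu` plus
#'   `wt` or `informative`).
#' @param alpha CI level.
#' @return one-row tibble: `pooled_rate`, `total_mu`, `total_informative`,
#'   `ci_low`, `ci_high`.
#' @examples
#' pool_error_rate(tibble::tibble(mu = c(1, 0), wt = c(49999, 50000)))
#' @export
pool_error_rate <- function(controls, alpha = 0.05) {
  stopifnot(is.data.frame(controls))
  if (nrow(controls) == 0) {
    abort("No negative controls supplied.", class = "ddmosaic_domain_error")
  }
  informative <- if ("informative" %in% names(controls)) {
    controls$informative
  } else controls$mu + controls$wt
  total_n <- sum(informative)
  if (!is.finite(total_n) || total_n < 1) {
    abort("Negative controls contain no informative droplets.",
          class = "ddmosaic_domain_error")
  }
  total_mu <- sum(controls$mu)
  ci <- binomial_ci(total_mu, total_n, alpha)
  tibble(pooled_rate = total_mu / total_n, total_mu = total_mu,
         total_informative = total_n, ci_low = ci$lower, ci_high = ci$upper)
}

#' Detection-limit curve from an assay error rate
#'
#' For each candidate number of informative droplets `n`, computes the
#' expected false-mutant count `expected_k` under the pooled error rate,
#' the upper bound of the exact CI at that count, and whether that upper
#' bound falls below the detection cutoff. The smallest `n` in the grid
#' whose upper bound clears the cutoff is reported as the
#' `min_informative` attribute. `k_rule = "zero"` uses `k = 0` instead of
#' the expected count, giving the floor `1 - (alpha/2)^(1/n)` that a
#' clean assay can reach.
#'
#' @param error_rate per-droplet false-mutant-call probability.
#' @param n_grid increasing vector of informative-droplet counts.
#' @param alpha CI level.
#' @param cutoff detection cutoff as a fraction (default 0.0001 = 0.01%).
#' @param k_rule `"expected"` (`k = round(error_rate * n)`) or `"zero"`.
#' @return tibble of class `lod_curve` with columns `n`, `expected_k`,
#'   `upper_bound`, `below_cutoff`.
#' @examples
#' detection_limit_curve(2.15664e-05, c(1e3, 1e4, 1e5, 1e6))
#' @export
detection_limit_curve <- function(error_rate, n_grid, alpha = 0.05,
                                  cutoff = 0.0001,
                                  k_rule = c("expected", "zero")) {
  k_rule <- match.arg(k_rule)
  check_param(error_rate, "error_rate", lo = 0, hi = 1, hi_open = TRUE)
  check_param(cutoff, "cutoff", lo = 0, hi = 1)
  if (length(n_grid) == 0 || any(n_grid < 1) || is.unsorted(n_grid)) {
    abort("`n_grid` must be a non-empty increasing vector of counts >= 1.",
          class = "ddmosaic_parameter_error")
  }
  n_grid <- as.numeric(n_grid)
  expected_k <- if (k_rule == "expected") round(error_rate * n_grid) else
    rep(0, length(n_grid))
  ci <- binomial_ci(expected_k, n_grid, alpha)
  out <- tibble(n = n_grid, expected_k = expected_k,
                upper_bound = ci$upper,
                below_cutoff = ci$upper < cutoff)
  attr(out, "min_informative") <- if (any(out$below_cutoff)) {
    min(out$n[out$below_cutoff])
  } else NA_real_
  attr(out, "cutoff") <- cutoff
  class(out) <- c("lod_curve", class(out))
  out
}

#' Cross-platform MAF concordance
#'
#' Ordinary least squares of amplicon-sequencing MAFs on droplet-PCR MAFs
#' over paired samples, summarising agreement between the two platforms.
#'
#' @param pairs data frame with columns `maf_mddpcr`, `maf_pasm` (any
#'   consistent unit); rows with missing values are rejected.
#' @return object of class `maf_concordance`: list with `r_squared`,
#'   `slope`, `intercept`, `n_pairs`, the underlying `lm` fit, and the
#'   input pairs. Has [tidy()], [glance()] and [autoplot()] methods.
#' @examples
#' concordance(tibble::tibble(maf_mddpcr = c(1, 2, 3),
#'                            maf_pasm = c(1.1, 1.9, 3.2)))
#' @export
concordance <- function(pairs) {
  stopifnot(is.data.frame(pairs))
  if (!all(c("maf_mddpcr", "maf_pasm") %in% names(pairs))) {
    abort("Need columns `maf_mddpcr` and `maf_pasm`.",
          class = "ddmosaic_domain_error")
  }
  if (nrow(pairs) < 2) {
    abort("Concordance needs at least 2 pairs.",
          class = "ddmosaic_domain_error")
  }
  if (anyNA(pairs$maf_mddpcr) || anyNA(pairs$maf_pasm)) {
    abort("Concordance input contains missing values.",
          class = "ddmosaic_domain_error")
  }
  if (stats::var(pairs$maf_mddpcr) == 0) {
    abort("Zero variance in the droplet-PCR MAFs.",
          class = "ddmosaic_domain_error")
  }
  fit <- lm(maf_pasm ~ maf_mddpcr, data = pairs)
  # computed directly so an exactly collinear input stays warning-free
  tss <- sum((pairs$maf_pasm - mean(pairs$maf_pasm))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(stats::residuals(fit)^2) / tss
  structure(
    list(r_squared = r2, slope = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]), n_pairs = nrow(pairs),
         fit = fit, pairs = as_tibble(pairs)),
    class = "maf_concordance"
  )
}

#' @export
print.maf_concordance <- function(x, ...) {
  cat(sprintf(
    "MAF concordance (OLS, n = %d pairs)\n  R^2 = %.4f  slope = %.4f  intercept = %.4f\n",
    x$n_pairs, x$r_squared, x$slope, x$intercept))
  invisible(x)
}
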