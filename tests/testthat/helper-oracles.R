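# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: the CI oracle inverts binomial tail
# probabilities by bisection on pbinom, and the OLS oracle uses the
# closed-form covariance arithmetic.

# Vectorised bisection solver: finds p where `pred(p)` flips from FALSE
# to TRUE (pred monotone non-decreasing in p).
bisect_p <- function(pred, len, iters = 60) {
  lo <- rep(0, len)
  hi <- rep(1, len)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    flip <- pred(mid)
    lo <- ifelse(flip, mid, lo)
    hi <- ifelse(flip, hi, mid)
  }
  (lo + hi) / 2
}

# Exact two-sided binomial interval by direct tail inversion:
# lower solves P(X >= k | p) = alpha/2, upper solves P(X <= k | p) = alpha/2.
cp_oracle <- function(k, n, alpha = 0.05) {
  len <- max(length(k), length(n))
  k <- rep_len(k, len)
  n <- rep_len(n, len)
  lower <- bisect_p(function(p) 1 - pbinom(k - 1, n, p) < alpha / 2, len)
  lower[k == 0] <- 0
  upper <- bisect_p(function(p) pbinom(k, n, p) >= alpha / 2, len)
  upper[k == n] <- 1
  list(lower = lower, upper = upper)
}

# Closed-form OLS of y on x.
ols_oracle <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  yhat <- a + b * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(slope = b, intercept = a, r_squared = r2)
}

# Classify vectors of (k, n) droplet counts through the package rule.
call_counts <- function(k, n, alpha = 0.05, lower_cut = 0.0001,
                        upper_cut = 0.50) {
  ci <- binomial_ci(k, n, alpha)
  d <- tibble::tibble(ci_low = ci$lower, ci_high = ci$upper)
  classify_sample(d, lower_cut, upper_cut, unit = "fraction")$call
}

# The printed mDDPCR/PASM MAF pairs of the blood-screen table.
printed_concordance_pairs <- function() {
  tibble::tibble(
    sample = c("A012 proband", "A052 mother", "A052 proband", "A066 father",
               "A066 proband", "A067 mother", "A067 proband", "A112 father",
               "A112 proband"),
    maf_mddpcr = c(44.19, 18.82, 49.98, 7.53, 50.00, 7.65, 50.41, 17.05, 49.93),
    maf_pasm = c(32.5, 17.1, 50.9, 4.5, 44.3, 6.4, 49.2, 18.8, 52.6)
  )
}

# Standard five-scenario synthetic cohort used in recovery tests.
recovery_scenarios <- function(n_per_kind) {
  kinds <- c("de_novo", "inherited_het", "parental_somatic_mosaic",
             "parental_germline_only_mosaic", "proband_mosaic")
  scenarios <- list()
  for (kind in kinds) {
    for (i in seq_len(n_per_kind)) {
      sc <- switch(kind,
        de_novo = family_scenario("de_novo"),
        inherited_het = family_scenario(
          "inherited_het",
          parent_of_origin = if (i %% 2 == 0) "paternal" else "maternal"),
        parental_somatic_mosaic = family_scenario(
          "parental_somatic_mosaic",
          parent_of_origin = if (i %% 2 == 0) "paternal" else "maternal",
          parent_maf = c(0.02, 0.05, 0.1, 0.2)[1 + (i %% 4)]),
        parental_germline_only_mosaic = family_scenario(
          "parental_germline_only_mosaic",
          sperm_maf = c(0.01, 0.05, 0.12, 0.33)[1 + (i %% 4)]),
        proband_mosaic = family_scenario("proband_mosaic",
                                         proband_maf = 0.3))
      scenarios[[paste0(kind, "_", i)]] <- sc
    }
  }
  scenarios
}
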