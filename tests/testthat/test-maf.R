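# Statistical core: exact CIs, MAF estimation, the detection rule,
# error-rate pooling, detection limits, concordance.

test_that("exact CI boundary cases hit their closed forms", {
  ci <- binomial_ci(0, 1000)
  expect_equal(ci$lower, 0)
  expect_equal(binomial_ci(0, 30000)$upper, 1 - 0.025^(1 / 30000),
               tolerance = 1e-12)
  expect_equal(binomial_ci(30000, 30000)$upper, 1)
  # k = 0 closed form across a grid, against the tail-inversion oracle
  for (n in c(10, 100, 10000)) {
    o <- cp_oracle(0, n)
    expect_equal(binomial_ci(0, n)$upper, 1 - 0.025^(1 / n),
                 tolerance = 1e-10)
    expect_equal(binomial_ci(0, n)$upper, o$upper, tolerance = 1e-9)
  }
})

test_that("exact CI matches brute-force tail inversion", {
  cases <- tibble::tibble(k = c(5, 1, 50, 117, 0, 9999),
                          n = c(10000, 30000, 9950, 500, 77, 10000))
  got <- binomial_ci(cases$k, cases$n)
  want <- cp_oracle(cases$k, cases$n)
  expect_equal(got$lower, want$lower, tolerance = 1e-6)
  expect_equal(got$upper, want$upper, tolerance = 1e-6)
})

test_that("CI domain errors are raised", {
  expect_error(binomial_ci(5, 4), class = "ddmosaic_domain_error")
  expect_error(binomial_ci(0, 0), class = "ddmosaic_domain_error")
  expect_error(binomial_ci(-1, 10), class = "ddmosaic_domain_error")
  expect_error(binomial_ci(1, 10, alpha = 0), class = "ddmosaic_domain_error")
})

test_that("empirical CI coverage stays in the conservative band", {
  n <- 20000
  for (p in c(0.0005, 0.005, 0.05, 0.5)) {
    k <- withr::with_seed(31, rbinom(5000, n, p))
    ci <- binomial_ci(k, n)
    coverage <- mean(ci$lower <= p & p <= ci$upper)
    expect_gte(coverage, 0.93)
    expect_lte(coverage, 0.98)
  }
})

test_that("MAF estimation uses only informative denominators", {
  est <- estimate_maf(tibble::tibble(mu = 0, wt = 10000, na = 40000))
  expect_equal(est$maf, 0)
  expect_equal(est$ci_low, 0)
  expect_equal(est$n, 10000)

  est2 <- estimate_maf(tibble::tibble(mu = 50, wt = 9950))
  expect_equal(est2$maf, 0.005)
  o <- cp_oracle(50, 10000)
  expect_equal(est2$ci_low, o$lower, tolerance = 1e-6)
  expect_equal(est2$ci_high, o$upper, tolerance = 1e-6)

  # amplicon counts give the printed point estimate of 32.5%
  est3 <- estimate_maf(tibble::tibble(alt_reads = 3250, ref_reads = 6750,
                                      depth = 10000))
  expect_equal(frac_to_pct(est3$maf), 32.5)

  expect_error(estimate_maf(tibble::tibble(mu = 0, wt = 0)),
               class = "ddmosaic_estimation_error")
  expect_error(estimate_maf(tibble::tibble(x = 1)),
               class = "ddmosaic_estimation_error")
})

test_that("the detection rule reproduces printed sample calls", {
  printed <- tibble::tibble(
    label = c("A052 mother", "A052 proband", "A012 mother", "exact cutoff"),
    maf_pct = c(18.82, 49.98, 0.01, 0.02),
    ci_low_pct = c(18.51, 49.60, 0.00, 0.01),
    ci_high_pct = c(19.14, 50.35, 0.03, 0.04))
  calls <- classify_sample(printed, unit = "percent")
  expect_equal(calls$call,
               c("mosaic", "het_consistent", "negative", "negative"))
})

test_that("call is a pure function of the CI bounds and cutoffs", {
  d <- tibble::tibble(ci_low = c(0.002, 0.0001, 0, 0.4),
                      ci_high = c(0.01, 0.002, 0.00005, 0.55))
  expect_equal(classify_sample(d)$call,
               c("mosaic", "negative", "negative", "het_consistent"))
  # strictness at the lower cutoff
  expect_equal(classify_sample(tibble::tibble(ci_low = 0.0001,
                                              ci_high = 0.3))$call,
               "negative")
  # missing bounds propagate NA
  expect_true(is.na(classify_sample(tibble::tibble(ci_low = NA_real_,
                                                   ci_high = NA_real_))$call))
})

test_that("a zero mutant count can never be called mosaic", {
  for (n in c(1, 10, 1000, 50000, 2000000)) {
    expect_false(call_counts(0, n) == "mosaic")
  }
})

test_that("error-rate pooling aggregates counts exactly", {
  expect_equal(pool_error_rate(tibble::tibble(mu = 0, wt = 50000))$pooled_rate,
               0)
  one <- pool_error_rate(tibble::tibble(mu = 1, wt = 49999))
  expect_equal(one$pooled_rate, 2e-05)
  expect_equal(one$total_informative, 50000)
  several <- pool_error_rate(tibble::tibble(mu = c(2, 1, 0),
                                            wt = c(49998, 49999, 50000)))
  expect_equal(several$pooled_rate, 3 / 150000)
  expect_equal(several$ci_low, cp_oracle(3, 150000)$lower, tolerance = 1e-9)
  expect_error(pool_error_rate(tibble::tibble(mu = integer(), wt = integer())),
               class = "ddmosaic_domain_error")
  expect_error(pool_error_rate(tibble::tibble(mu = 0, wt = 0)),
               class = "ddmosaic_domain_error")
})

test_that("detection-limit curve matches the CI oracle on both k rules", {
  grid <- c(1e3, 1e4, 1e5, 1e6)
  zero <- detection_limit_curve(0, grid)
  expect_equal(zero$expected_k, rep(0, 4))
  expect_equal(zero$upper_bound, 1 - 0.025^(1 / grid), tolerance = 1e-10)
  expect_true(all(diff(zero$upper_bound) < 0))

  rate <- 2.15664e-05
  curve <- detection_limit_curve(rate, grid)
  o <- cp_oracle(curve$expected_k, curve$n)
  expect_equal(curve$upper_bound, o$upper, tolerance = 1e-6)
  expect_equal(curve$below_cutoff, curve$upper_bound < 0.0001)

  floor_curve <- detection_limit_curve(rate, grid, k_rule = "zero")
  expect_equal(floor_curve$expected_k, rep(0, 4))
  expect_true(is.na(attr(floor_curve, "min_informative")) ||
                attr(floor_curve, "min_informative") %in% grid)
  expect_error(detection_limit_curve(rate, numeric()),
               class = "ddmosaic_parameter_error")
  expect_error(detection_limit_curve(rate, c(100, 50)),
               class = "ddmosaic_parameter_error")
})

test_that("mosaic calling has high power and controlled false positives", {
  n <- 20000
  fcr <- 2.15664e-05
  reps <- 500
  # power at 5% true MAF
  k_pos <- withr::with_seed(33, rbinom(reps, n, 0.05 + 0.95 * fcr))
  expect_gte(mean(call_counts(k_pos, n) == "mosaic"), 0.99)
  # specificity at zero true MAF
  k_neg <- withr::with_seed(34, rbinom(reps, n, fcr))
  expect_lte(mean(call_counts(k_neg, n) == "mosaic"), 0.05)
  # heterozygote behaviour at 50% MAF
  k_het <- withr::with_seed(35, rbinom(reps, 50000, 0.5))
  het_calls <- call_counts(k_het, 50000)
  expect_gte(mean(het_calls == "het_consistent"), 0.90)
  expect_lte(mean(het_calls == "negative"), 0.10)
})

test_that("concordance matches the closed-form OLS oracle", {
  ident <- concordance(tibble::tibble(maf_mddpcr = c(1, 5, 20),
                                      maf_pasm = c(1, 5, 20)))
  expect_equal(ident$r_squared, 1)
  expect_equal(ident$slope, 1)
  expect_equal(ident$intercept, 0)

  two <- concordance(tibble::tibble(maf_mddpcr = c(1, 2),
                                    maf_pasm = c(3, 7)))
  expect_equal(two$r_squared, 1)

  pairs <- printed_concordance_pairs()
  fit <- concordance(pairs)
  o <- ols_oracle(pairs$maf_mddpcr, pairs$maf_pasm)
  expect_equal(fit$r_squared, o$r_squared, tolerance = 1e-10)
  expect_equal(fit$slope, o$slope, tolerance = 1e-10)
  expect_equal(fit$intercept, o$intercept, tolerance = 1e-10)
  expect_equal(fit$n_pairs, 9)

  expect_error(concordance(pairs[1, ]), class = "ddmosaic_domain_error")
  expect_error(concordance(tibble::tibble(maf_mddpcr = c(1, 1),
                                          maf_pasm = c(1, 2))),
               class = "ddmosaic_domain_error")
  expect_error(concordance(tibble::tibble(maf_mddpcr = c(1, NA),
                                          maf_pasm = c(1, 2))),
               class = "ddmosaic_domain_error")
})

test_that("concordance tidiers expose the fit in broom form", {
  fit <- concordance(printed_concordance_pairs())
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", "maf_mddpcr"))
  expect_equal(td$estimate[2], fit$slope)
  gl <- glance(fit)
  expect_equal(gl$r.squared, fit$r_squared)
  expect_equal(gl$n.pairs, 9)
})
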