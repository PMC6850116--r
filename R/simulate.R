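# Synthetic assay generators: droplet-level mDDPCR, count-level mDDPCR,
# and amplicon (PASM-style) read counts.

# Default two-channel prototype cluster centers (arbitrary fluorescence
# units): NA (empty / non-target) low on both channels, WT high on channel
# 1, MU high on channel 2. Matches the layout of mDDPCR scatter plots.
default_droplet_centers <- function() {
  matrix(c(1000, 1000,
           8000, 1200,
           1200, 8000),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("NA", "WT", "MU"), c("ch1", "ch2")))
}

#' Simulate a raw two-channel droplet assay
#'
#' Generates per-droplet fluorescence intensities with latent class labels,
#' the ground truth for gating. Each droplet is independently non-informative
#' (class `"NA"`, no target template) with probability `1 - occupancy_rate`.
#' Informative droplets carry a mutant template with probability `true_maf`;
#' a wild-type-template droplet is additionally miscalled mutant with
#' probability `false_call_rate` (the assay's false-positive channel
#' crosstalk). Intensities are drawn from three well-separated cluster
#' centers plus isotropic Gaussian noise whose standard deviation is
#' `noise_sd` times the smallest center separation.
#'
#' Droplets are modeled as carrying at most one template molecule; the MAF
#' of a sample is therefore the mutant fraction among informative droplets,
#' with no Poisson multi-occupancy correction.
#'
#' @param n_droplets number of droplets to generate (>= 1).
#' @param occupancy_rate expected fraction of template-containing droplets,
#'   in `[0, 1]`.
#' @param true_maf true mutant allele fraction in `[0, 1]`.
#' @param false_call_rate per-informative-droplet probability that a
#'   wild-type droplet is miscalled mutant, in `[0, 1)`.
#' @param noise_sd intensity noise, as a fraction of the smallest distance
#'   between cluster centers.
#' @param seed integer seed; identical seeds give identical output.
#' @param centers optional 3 x 2 matrix of cluster centers with rownames
#'   `NA`, `WT`, `MU`.
#' @return a tibble of class `raw_droplets` with columns `droplet_id`,
#'   `ch1`, `ch2`, `true_class`, and a `meta` attribute recording the
#'   generating parameters.
#' @examples
#' d <- simulate_droplet_assay(2000, 0.3, 0.05, 0, 0.05, seed = 1)
#' table(d$true_class)
#' @export
simulate_droplet_assay <- function(n_droplets, occupancy_rate, true_maf,
                                   false_call_rate = 0, noise_sd = 0.05,
                                   seed, centers = default_droplet_centers()) {
  check_param(n_droplets, "n_droplets", lo = 1, integer = TRUE)
  check_param(occupancy_rate, "occupancy_rate", lo = 0, hi = 1)
  check_param(true_maf, "true_maf", lo = 0, hi = 1)
  check_param(false_call_rate, "false_call_rate", lo = 0, hi = 1, hi_open = TRUE)
  check_param(noise_sd, "noise_sd", lo = 0)
  check_param(seed, "seed", integer = TRUE)
  stopifnot(is.matrix(centers), nrow(centers) == 3, ncol(centers) == 2)

  sep <- min(dist(centers))
  sd_units <- noise_sd * sep
  cls <- with_seed(derive_seed(seed, 11L), {
    informative <- runif(n_droplets) < occupancy_rate
    mutant <- informative & (runif(n_droplets) < true_maf)
    miscall <- informative & !mutant & (runif(n_droplets) < false_call_rate)
    cl <- ifelse(!informative, "NA", ifelse(mutant | miscall, "MU", "WT"))
    noise <- matrix(rnorm(2L * n_droplets, sd = sd_units), ncol = 2)
    list(cl = cl, noise = noise)
  })
  idx <- match(cls$cl, rownames(centers))
  out <- tibble(
    droplet_id = seq_len(n_droplets),
    ch1 = unname(centers[idx, 1]) + cls$noise[, 1],
    ch2 = unname(centers[idx, 2]) + cls$noise[, 2],
    true_class = cls$cl
  )
  attr(out, "meta") <- list(
    n_droplets = n_droplets, occupancy_rate = occupancy_rate,
    true_maf = true_maf, false_call_rate = false_call_rate,
    noise_sd = noise_sd, seed = seed, centers = centers
  )
  class(out) <- c("raw_droplets", class(out))
  out
}

#' Simulate droplet class counts directly
#'
#' The count-level marginal of [simulate_droplet_assay()]: draws the number
#' of informative droplets and the mutant count from the same binomial
#' model without materialising per-droplet intensities. Used for large
#' cohort simulations where only the count triple matters.
#'
#' @inheritParams simulate_droplet_assay
#' @return one-row tibble with columns `mu`, `wt`, `na`, `informative`.
#' @export
simulate_droplet_counts <- function(n_droplets, occupancy_rate, true_maf,
                                    false_call_rate = 0, seed) {
  check_param(n_droplets, "n_droplets", lo = 1, integer = TRUE)
  check_param(occupancy_rate, "occupancy_rate", lo = 0, hi = 1)
  check_param(true_maf, "true_maf", lo = 0, hi = 1)
  check_param(false_call_rate, "false_call_rate", lo = 0, hi = 1, hi_open = TRUE)
  check_param(seed, "seed", integer = TRUE)
  p_mu <- true_maf + (1 - true_maf) * false_call_rate
  with_seed(derive_seed(seed, 13L), {
    informative <- rbinom(1L, n_droplets, occupancy_rate)
    mu <- rbinom(1L, informative, p_mu)
    tibble(mu = mu, wt = informative - mu,
           na = n_droplets - informative, informative = informative)
  })
}

#' Simulate deep-amplicon allele counts
#'
#' Draws the alternate-allele read count at a site sequenced to `depth`
#' from `alt ~ Binomial(depth, q)` with
#' `q = true_maf (1 - base_error_rate) + (1 - true_maf) base_error_rate`:
#' a true mutant read survives unless miscalled, and a reference read is
#' miscalled as mutant at the per-base error rate.
#'
#' @param depth total filtered read depth (>= 1).
#' @param true_maf true mutant allele fraction in `[0, 1]`.
#' @param base_error_rate per-base miscall probability in `[0, 1)`.
#' @param seed integer seed.
#' @return one-row tibble with `alt_reads`, `ref_reads`, `depth`,
#'   `platform` (`"PASM"`).
#' @examples
#' simulate_amplicon_reads(10000, 0.01, 1e-4, seed = 2)
#' @export
simulate_amplicon_reads <- function(depth, true_maf, base_error_rate = 0,
                                    seed) {
  check_param(depth, "depth", lo = 1, integer = TRUE)
  check_param(true_maf, "true_maf", lo = 0, hi = 1)
  check_param(base_error_rate, "base_error_rate", lo = 0, hi = 1,
              hi_open = TRUE)
  check_param(seed, "seed", integer = TRUE)
  q <- true_maf * (1 - base_error_rate) + (1 - true_maf) * base_error_rate
  alt <- with_seed(derive_seed(seed, 17L), rbinom(1L, depth, q))
  tibble(alt_reads = alt, ref_reads = depth - alt, depth = depth,
         platform = "PASM")
}

#' Write a raw droplet set to CSV
#'
#' @param droplets a `raw_droplets` tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_droplet_csv <- function(droplets, path) {
  readr::write_csv(as_tibble(droplets), path)
  invisible(path)
}

#' Read a raw droplet CSV
#'
#' @param path file with columns `droplet_id`, `ch1`, `ch2` and optionally
#'   `true_class`.
#' @return tibble of droplets.
#' @details The literal string `NA` in `true_class` is the non-template
#'   droplet class, not a missing value.
#' @export
read_droplet_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, na = character())
}
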