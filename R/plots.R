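# ggplot2 visualisations for the main result types.

#' Plot a raw droplet set
#'
#' Two-channel scatter plot of droplet intensities, coloured by latent
#' class when present - the standard mDDPCR cluster view.
#'
#' @param object a `raw_droplets` tibble.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot raw_droplets
#' @export
autoplot.raw_droplets <- function(object, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$ch1, y = .data$ch2))
  if ("true_class" %in% names(object)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$true_class),
                                 alpha = 0.4, size = 0.6)
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.4, size = 0.6)
  }
  p + ggplot2::labs(x = "Channel 1 intensity", y = "Channel 2 intensity",
                    colour = "class")
}

#' Plot cross-platform concordance
#'
#' Paired MAFs with the OLS fit and the identity line.
#'
#' @param object a `maf_concordance` object.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot maf_concordance
#' @export
autoplot.maf_concordance <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$maf_mddpcr, y = .data$maf_pasm)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "MAF (droplet digital PCR)", y = "MAF (deep amplicon sequencing)",
      title = sprintf("Platform concordance, R² = %.4f (n = %d)",
                      object$r_squared, object$n_pairs))
}

#' Plot a detection-limit curve
#'
#' Upper CI bound of the false-call MAF against the number of informative
#' droplets, with the detection cutoff as a horizontal reference.
#'
#' @param object an `lod_curve` from [detection_limit_curve()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot lod_curve
#' @export
autoplot.lod_curve <- function(object, ...) {
  cutoff <- attr(object, "cutoff")
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$n, y = .data$upper_bound)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$below_cutoff)) +
    ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed",
                        colour = "blue") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "informative droplets",
                  y = "upper 95% CI bound of MAF",
                  colour = sprintf("below %.2f%%", 100 * cutoff))
}

#' Plot per-sample MAF estimates with confidence intervals
#'
#' @param calls classified sample tibble with `maf_pct`, `ci_low_pct`,
#'   `ci_high_pct` (or fraction-scale equivalents) and `call`.
#' @return a ggplot.
#' @export
plot_maf_calls <- function(calls) {
  d <- as_tibble(calls)
  if (!"maf_pct" %in% names(d) && "maf" %in% names(d)) {
    d <- mutate(d, maf_pct = frac_to_pct(.data$maf),
                ci_low_pct = frac_to_pct(.data$ci_low),
                ci_high_pct = frac_to_pct(.data$ci_high))
  }
  d <- filter(d, !is.na(.data$maf_pct))
  d <- mutate(d, sample_id = paste(.data$family_id, .data$member_role,
                                   .data$tissue, sep = ":"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$maf_pct,
                                  y = stats::reorder(.data$sample_id,
                                                     .data$maf_pct),
                                  colour = .data$call)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low_pct,
                                         xmax = .data$ci_high_pct),
                            height = 0.3) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "MAF (%)", y = NULL, colour = "call")
}
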