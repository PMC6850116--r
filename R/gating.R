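# Droplet gating: convert two-channel intensities into MU/WT/NA counts.
# Default is explicit rectangular thresholds, mirroring manual gating of
# scatter plots; a nearest-center method (k-means from configured
# prototypes) is provided for automation.

#' Fit a gate model for two-channel droplet data
#'
#' @param droplets data frame with numeric columns `ch1`, `ch2` (>= 10
#'   rows).
#' @param method `"thresholds"` (default) for rectangular per-class
#'   regions, or `"nearest_center"` for assignment to the nearest of three
#'   fitted cluster centers.
#' @param params for `"thresholds"`: optionally `regions`, a named list of
#'   `c(ch1_min, ch1_max, ch2_min, ch2_max)` per class (`NA`, `WT`, `MU`);
#'   if absent, boundaries are derived from `centers` midpoints. For
#'   `"nearest_center"`: optionally `centers`, a 3 x 2 prototype matrix
#'   used to initialise the iterative center update (defaults to the
#'   simulator's prototypes).
#' @return list of class `gate_model` with `method` and either `regions`
#'   or fitted `centers` (rows `NA`/`WT`/`MU`).
#' @details Rectangular regions use half-open `[min, max)` intervals and
#'   must be disjoint; droplets falling in no region are counted `NA`
#'   (conservative for rare-allele calling). With `nearest_center` the
#'   three centers are fitted by Lloyd-type iteration (`stats::kmeans`)
#'   initialised at the prototypes, and each fitted center inherits the
#'   label of its nearest prototype.
#' @examples
#' d <- simulate_droplet_assay(5000, 0.3, 0.02, 0, 0.03, seed = 1)
#' g <- fit_gates(d, "nearest_center")
#' count_droplets(d, g)
#' @export
fit_gates <- function(droplets, method = c("thresholds", "nearest_center"),
                      params = list()) {
  method <- match.arg(method)
  stopifnot(is.data.frame(droplets),
            all(c("ch1", "ch2") %in% names(droplets)))
  if (nrow(droplets) < 10) {
    abort("Gating needs at least 10 droplets.", class = "ddmosaic_gating_error")
  }
  if (!all(is.finite(droplets$ch1)) || !all(is.finite(droplets$ch2))) {
    abort("Droplet intensities must be finite.",
          class = "ddmosaic_gating_error")
  }
  if (diff(range(droplets$ch1)) == 0 && diff(range(droplets$ch2)) == 0) {
    abort("Degenerate input: all intensities identical.",
          class = "ddmosaic_gating_error")
  }
  centers <- params$centers %||% attr(droplets, "meta")$centers %||%
    default_droplet_centers()

  if (method == "thresholds") {
    regions <- params$regions %||% {
      # Midpoint boundaries between the NA corner and the WT/MU arms.
      mid1 <- (centers["NA", 1] + centers["WT", 1]) / 2
      mid2 <- (centers["NA", 2] + centers["MU", 2]) / 2
      list(
        `NA` = c(ch1_min = -Inf, ch1_max = mid1, ch2_min = -Inf, ch2_max = mid2),
        WT = c(ch1_min = mid1, ch1_max = Inf, ch2_min = -Inf, ch2_max = mid2),
        MU = c(ch1_min = -Inf, ch1_max = mid1, ch2_min = mid2, ch2_max = Inf)
      )
    }
    stopifnot(all(c("NA", "WT", "MU") %in% names(regions)))
    check_regions_disjoint(regions)
    structure(list(method = "thresholds", regions = regions),
              class = "gate_model")
  } else {
    km <- with_seed(1L, kmeans(cbind(droplets$ch1, droplets$ch2),
                               centers = centers, algorithm = "Lloyd",
                               iter.max = 100))
    fitted <- km$centers
    # Label each fitted center by its nearest prototype.
    lab <- rownames(centers)[apply(fitted, 1, function(ct) {
      which.min(colSums((t(centers) - ct)^2))
    })]
    if (anyDuplicated(lab)) {
      abort("Cluster centers collapsed onto the same prototype; cannot label classes.",
            class = "ddmosaic_gating_error")
    }
    rownames(fitted) <- lab
    colnames(fitted) <- c("ch1", "ch2")
    structure(list(method = "nearest_center",
                   centers = fitted[c("NA", "WT", "MU"), , drop = FALSE]),
              class = "gate_model")
  }
}

check_regions_disjoint <- function(regions) {
  cls <- names(regions)
  for (i in seq_along(cls)) {
    for (j in seq_along(cls)) {
      if (j <= i) next
      a <- regions[[i]]; b <- regions[[j]]
      overlap1 <- min(a["ch1_max"], b["ch1_max"]) > max(a["ch1_min"], b["ch1_min"])
      overlap2 <- min(a["ch2_max"], b["ch2_max"]) > max(a["ch2_min"], b["ch2_min"])
      if (overlap1 && overlap2) {
        abort(sprintf("Gate regions '%s' and '%s' overlap.", cls[i], cls[j]),
              class = "ddmosaic_gating_error")
      }
    }
  }
  invisible(regions)
}

# Assign a class label to every droplet under a gate model.
assign_droplet_classes <- function(droplets, gates) {
  stopifnot(inherits(gates, "gate_model"))
  ch1 <- droplets$ch1
  ch2 <- droplets$ch2
  if (gates$method == "thresholds") {
    lab <- rep("NA", length(ch1))
    n_ungated <- length(ch1)
    for (cls in c("WT", "MU", "NA")) {
      r <- gates$regions[[cls]]
      inside <- ch1 >= r["ch1_min"] & ch1 < r["ch1_max"] &
        ch2 >= r["ch2_min"] & ch2 < r["ch2_max"]
      lab[inside] <- cls
      n_ungated <- n_ungated - sum(inside)
    }
    if (n_ungated > 0) {
      message(sprintf("%d droplet(s) fell outside all gate regions; counted as NA.",
                      n_ungated))
    }
    lab
  } else {
    ct <- gates$centers
    d2 <- sapply(seq_len(nrow(ct)), function(k) {
      (ch1 - ct[k, 1])^2 + (ch2 - ct[k, 2])^2
    })
    rownames(ct)[max.col(-d2, ties.method = "first")]
  }
}

#' Count droplets per gated class
#'
#' Assigns every droplet exactly one label under the gate model and
#' returns the MU/WT/NA count triple, the sufficient statistic for MAF
#' inference. Droplets outside all threshold regions are counted `NA` and
#' reported via a message, never dropped.
#'
#' @param droplets data frame with `ch1`, `ch2`.
#' @param gates a `gate_model` from [fit_gates()].
#' @return one-row tibble with `mu`, `wt`, `na`, `informative`
#'   (`= mu + wt`).
#' @export
count_droplets <- function(droplets, gates) {
  lab <- assign_droplet_classes(droplets, gates)
  mu <- sum(lab == "MU")
  wt <- sum(lab == "WT")
  tibble(mu = mu, wt = wt, na = sum(lab == "NA"), informative = mu + wt)
}
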