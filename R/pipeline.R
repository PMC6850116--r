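# End-to-end runner: load fixtures or simulate a cohort, estimate MAFs,
# call samples, classify families, summarise, cluster, write a bundle.

#' Build family records from a classified sample table
#'
#' Turns a long per-sample table (one row per family member, tissue and
#' platform, with `call` already assigned) into the per-family record
#' structure consumed by [classify_family()]. Proband Sanger status is
#' inferred from the proband call (`het_detected` for het-consistent
#' probands); parents are taken as unaffected with negative Sanger unless
#' `members` information is supplied on the records afterwards.
#'
#' @param samples classified sample tibble with `family_id`,
#'   `member_role`, `tissue`, `platform`, `call`, and optionally `origin`
#'   (ASPCR parent-of-origin).
#' @return named list of `family_record` objects.
#' @export
as_family_records <- function(samples) {
  stopifnot(is.data.frame(samples), "call" %in% names(samples))
  split(as_tibble(samples), samples$family_id) |>
    purrr::imap(function(s, fid) {
      pb <- filter(s, .data$member_role == "proband")
      # Families in these tables are variant-positive by construction: a
      # record with no proband rows still represents a proband whose
      # heterozygous variant was established upstream (Sanger/NGS).
      pb_sanger <- if (nrow(pb) == 0) {
        "het_detected"
      } else if (any(pb$call == "het_consistent", na.rm = TRUE)) {
        "het_detected"
      } else if (any(pb$call == "mosaic", na.rm = TRUE)) {
        "weak_signal"
      } else "not_detected"
      members <- tibble(
        member_role = c("father", "mother", "proband"),
        affected = c(FALSE, FALSE, TRUE),
        sanger_status = c("not_detected", "not_detected", pb_sanger)
      )
      origin <- if ("origin" %in% names(s)) s$origin[1] else "uninformative"
      structure(
        list(family_id = fid, members = members, samples = s,
             aspcr_origin = if (identical(origin, "proband"))
               "uninformative" else origin),
        class = "family_record")
    })
}

default_pipeline_config <- function() {
  list(mode = "fixtures", seed = 1L, alpha = 0.05,
       lower_cut_pct = 0.01, upper_cut_pct = 50.00,
       linkage = "average", na_policy = "drop_feature",
       scenarios = NULL, assay_params = list())
}

#' Run the full mosaicism-detection pipeline
#'
#' Executes load/simulate, MAF estimation, sample calling, family
#' classification, cohort summary and multi-tissue clustering, and
#' (optionally) writes the result bundle: `calls.tsv`, `families.tsv`,
#' `summary.json`, `dendrogram.nwk` and `run.log`. Identical config and
#' seed give identical outputs. Any stage failure aborts with a
#' stage-named message and removes partial outputs.
#'
#' @param config list merged over the defaults: `mode` (`"fixtures"` uses
#'   the bundled reference tables; `"simulate"` generates a cohort from
#'   `scenarios`, a list of [family_scenario()] objects), `seed`, `alpha`,
#'   `lower_cut_pct`, `upper_cut_pct`, `linkage`, `na_policy`,
#'   `assay_params`.
#' @param out_dir output directory, or `NULL` to skip writing files.
#' @return invisible list (`report_bundle`): `calls`, `families`,
#'   `summary`, `newick`, `log`.
#' @examples
#' bundle <- run_pipeline(list(mode = "fixtures"))
#' bundle$summary$parental_mosaic_pct
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  cfg <- utils::modifyList(default_pipeline_config(), config)
  out_files <- if (!is.null(out_dir)) {
    file.path(out_dir, c("calls.tsv", "families.tsv", "summary.json",
                         "dendrogram.nwk", "run.log"))
  } else character()

  stage <- "setup"
  bundle <- tryCatch({
    if (cfg$mode == "fixtures") {
      stage <- "load"
      samples <- bind_rows(load_cohort_fixture("table1_blood"),
                           load_cohort_fixture("table3_tissues"))
      samples <- filter(samples, .data$platform == "mDDPCR")
      stage <- "call"
      calls <- classify_sample(samples, cfg$lower_cut_pct,
                               cfg$upper_cut_pct, unit = "percent")
      tallies <- load_cohort_fixture("cohort_tallies")
      cluster_values <- mutate(calls, maf = pct_to_frac(.data$maf_pct))
    } else if (cfg$mode == "simulate") {
      stage <- "simulate"
      if (is.null(cfg$scenarios)) {
        abort("simulate mode needs `scenarios`.",
              class = "ddmosaic_config_error")
      }
      cohort <- simulate_cohort(cfg$scenarios, cfg$assay_params,
                                seed = cfg$seed)
      samples <- purrr::map_dfr(cohort, "samples")
      samples <- filter(samples, .data$platform == "mDDPCR")
      stage <- "estimate"
      est <- estimate_maf(samples, alpha = cfg$alpha)
      stage <- "call"
      calls <- classify_sample(est, pct_to_frac(cfg$lower_cut_pct),
                               pct_to_frac(cfg$upper_cut_pct),
                               unit = "fraction")
      calls <- mutate(calls, maf_pct = frac_to_pct(.data$maf))
      tallies <- NULL
      cluster_values <- calls
      # carry calls back onto the records for classification
      cohort <- purrr::map(cohort, function(f) {
        f$samples <- filter(calls, .data$family_id == f$family_id)
        f
      })
    } else {
      abort(sprintf("Unknown mode '%s'.", cfg$mode),
            class = "ddmosaic_config_error")
    }

    stage <- "classify_families"
    records <- if (cfg$mode == "fixtures") as_family_records(calls) else cohort
    families <- classify_families(records)

    stage <- "summarize"
    summary <- summarize_cohort(calls, tallies)

    stage <- "cluster"
    parental <- filter(cluster_values,
                       .data$member_role %in% c("father", "mother", "control"),
                       !is.na(.data$maf))
    newick <- if (nrow(parental) >= 2) {
      parental <- mutate(parental, sample_id = paste(.data$family_id,
                                                     .data$member_role,
                                                     .data$tissue, sep = ":"),
                         feature = "maf")
      m <- build_maf_matrix(parental, row = .data$sample_id,
                            col = .data$feature, value = .data$maf,
                            na_policy = cfg$na_policy)
      h <- hierarchical_cluster(sqrt_euclidean_distances(m),
                                linkage = cfg$linkage)
      dendrogram_to_newick(h)
    } else NA_character_

    log_lines <- c(
      sprintf("ddmosaic pipeline run, mode=%s seed=%d", cfg$mode, cfg$seed),
      sprintf("config: alpha=%g lower_cut_pct=%g upper_cut_pct=%g linkage=%s na_policy=%s",
              cfg$alpha, cfg$lower_cut_pct, cfg$upper_cut_pct, cfg$linkage,
              cfg$na_policy),
      sprintf("samples called: %d; families classified: %d",
              nrow(calls), nrow(families))
    )
    list(calls = calls, families = families, summary = summary,
         newick = newick, log = log_lines)
  }, error = function(e) {
    unlink(out_files)
    abort(sprintf("Pipeline failed at stage '%s': %s", stage,
                  conditionMessage(e)),
          class = "ddmosaic_pipeline_error", parent = e)
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(bundle$calls, out_files[1])
    readr::write_tsv(bundle$families, out_files[2])
    jsonlite::write_json(as.list(bundle$summary), out_files[3],
                         auto_unbox = TRUE, digits = NA, na = "null")
    writeLines(bundle$newick %||% "", out_files[4])
    writeLines(bundle$log, out_files[5])
  }
  class(bundle) <- "report_bundle"
  invisible(bundle)
}
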