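# Bundled reference tables: verbatim transcriptions of the published
# ATP1A3/AHC mosaicism screen (blood-screen table, multi-tissue table,
# phenotype table, and the cohort tallies). MAF and CI values are percent
# with the printed number of decimals; NA cells are preserved as missing
# and never imputed.

fixture_names <- function() {
  c("table1_blood", "table3_tissues", "cohort_tallies", "table2_phenotypes")
}

#' Load a bundled reference cohort table
#'
#' Returns the transcription of one of the reference screen's printed
#' tables. `"table1_blood"` holds the blood-sample MAFs (mDDPCR and PASM,
#' with 95% CIs) for the five positive mosaic families plus controls;
#' `"table3_tissues"` the multi-tissue MAFs (father sperm plus six somatic
#' tissues of the mosaic parent); `"cohort_tallies"` the cohort-level
#' counts (probands enrolled, variant-positive, trios tested, de novo,
#' inherited, droplet-screened families, sperm donors, and
#' parent-of-origin tallies); `"table2_phenotypes"` the descriptive
#' phenotype table.
#'
#' MAF columns are percent values as printed; missing cells are `NA`.
#'
#' @param name one of `"table1_blood"`, `"table3_tissues"`,
#'   `"cohort_tallies"`, `"table2_phenotypes"`.
#' @return a tibble; for `"cohort_tallies"` a two-column key/value tibble.
#' @examples
#' load_cohort_fixture("table1_blood")
#' @export
load_cohort_fixture <- function(name) {
  if (length(name) != 1L || !name %in% fixture_names()) {
    abort(sprintf("Unknown fixture name '%s'. Available: %s.",
                  paste(name, collapse = ","),
                  paste(fixture_names(), collapse = ", ")),
          class = "ddmosaic_fixture_error")
  }
  path <- system.file("extdata", paste0(name, ".tsv"), package = "ddmosaic",
                      mustWork = TRUE)
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         na = "NA")
  if (name %in% c("table1_blood", "table3_tissues")) {
    tab <- mutate(tab, across(c("maf_pct", "ci_low_pct", "ci_high_pct"),
                              as.numeric))
    stopifnot(!anyNA(tab$family_id), !anyNA(tab$member_role))
  }
  if (name == "cohort_tallies") {
    tab <- mutate(tab, value = as.integer(.data$value))
  }
  tab
}

# Tallies as a named list for arithmetic convenience.
tallies_as_list <- function(tallies = load_cohort_fixture("cohort_tallies")) {
  as.list(setNames(tallies$value, tallies$key))
}
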