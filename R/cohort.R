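# Family-level inheritance classification and cohort summaries.

inheritance_categories <- function() {
  c("inherited_affected_parent", "parental_somatic_mosaic",
    "parental_germline_only_mosaic", "proband_postzygotic_mosaic",
    "de_novo_unresolved", "needs_review")
}

# Ensure a family record's samples carry calls; compute them from counts
# if needed (fraction scale, droplet rule cutoffs).
called_samples <- function(f, lower_cut = 0.0001, upper_cut = 0.50,
                           alpha = 0.05) {
  s <- f$samples
  if (!"call" %in% names(s)) {
    s <- filter(s, .data$platform == "mDDPCR")
    s <- estimate_maf(s, alpha = alpha)
    s <- classify_sample(s, lower_cut, upper_cut, unit = "fraction")
  }
  s
}

#' Classify a family's inheritance configuration
#'
#' Applies the decision cascade to one family record: (1) an affected
#' parent with a heterozygous Sanger result transmits as an inherited
#' variant; (2) otherwise any parental somatic-tissue sample (blood,
#' buccal, saliva, hair, urine, skin) called mosaic makes the family a
#' parental somatic/gonosomal mosaic with that parent as origin; (3)
#' otherwise a mosaic paternal sperm sample makes it germline-only
#' (necessarily paternal - female germ cells are not collectable); (4)
#' otherwise a proband blood sample called mosaic (not het-consistent) is
#' a postzygotic proband mosaic; (5) otherwise the variant remains de novo
#' with unresolved mechanism, with parent-of-origin taken from
#' allele-specific PCR when informative. Somatic evidence outranks
#' germline-only evidence because a somatic-positive parent is screened
#' first in blood.
#'
#' Families where both parents show mosaicism for the same variant are
#' flagged `needs_review`, never silently classified.
#'
#' @param f a `family_record` (from [simulate_mosaic_family()] or built
#'   from real sample sheets) with elements `members`, `samples`,
#'   `aspcr_origin`.
#' @param lower_cut,upper_cut,alpha detection-rule parameters used when
#'   sample calls are not yet present (fraction scale).
#' @return one-row tibble: `family_id`, `category`, `origin`, `note`.
#' @export
classify_family <- function(f, lower_cut = 0.0001, upper_cut = 0.50,
                            alpha = 0.05) {
  stopifnot(is.list(f), !is.null(f$samples), !is.null(f$members))
  s <- called_samples(f, lower_cut, upper_cut, alpha)
  members <- f$members
  res <- function(category, origin, note = NA_character_) {
    tibble(family_id = f$family_id %||% NA_character_,
           category = category, origin = origin, note = note)
  }

  proband_calls <- s$call[s$member_role == "proband"]
  proband_sanger <- members$sanger_status[members$member_role == "proband"]
  if (!any(proband_calls %in% c("mosaic", "het_consistent")) &&
      !any(proband_sanger == "het_detected")) {
    return(res("needs_review", "unknown",
               "proband carries no detectable variant"))
  }

  # (1) inherited from an affected heterozygous parent
  parent_rows <- filter(members, .data$member_role %in% c("father", "mother"))
  inh <- filter(parent_rows, .data$sanger_status == "het_detected",
                .data$affected)
  if (nrow(inh) > 0) {
    origin <- if (inh$member_role[1] == "father") "paternal" else "maternal"
    return(res("inherited_affected_parent", origin))
  }

  # (2) parental somatic (gonosomal) mosaicism
  som <- filter(s, .data$member_role %in% c("father", "mother"),
                .data$tissue %in% somatic_tissues(),
                !is.na(.data$call), .data$call == "mosaic")
  som_parents <- unique(som$member_role)
  if (length(som_parents) > 1) {
    return(res("needs_review", "unknown",
               "both parents mosaic for the same variant"))
  }
  if (length(som_parents) == 1) {
    origin <- if (som_parents == "father") "paternal" else "maternal"
    return(res("parental_somatic_mosaic", origin))
  }

  # (3) germline-only mosaicism, observable in sperm
  sperm <- filter(s, .data$member_role == "father", .data$tissue == "sperm",
                  !is.na(.data$call), .data$call == "mosaic")
  if (nrow(sperm) > 0) {
    return(res("parental_germline_only_mosaic", "paternal"))
  }

  # (4) postzygotic mosaicism in the proband
  pb <- filter(s, .data$member_role == "proband", .data$tissue == "blood",
               !is.na(.data$call), .data$call == "mosaic")
  if (nrow(pb) > 0) {
    return(res("proband_postzygotic_mosaic", "unknown"))
  }

  # (5) unresolved de novo; origin from ASPCR when informative
  origin <- switch(f$aspcr_origin %||% "uninformative",
                   paternal = "paternal", maternal = "maternal", "unknown")
  res("de_novo_unresolved", origin)
}

#' Classify every family in a cohort
#'
#' @param cohort list of `family_record` objects.
#' @inheritParams classify_family
#' @return tibble with one row per family (`family_id`, `category`,
#'   `origin`, `note`).
#' @export
classify_families <- function(cohort, lower_cut = 0.0001, upper_cut = 0.50,
                              alpha = 0.05) {
  purrr::map_dfr(cohort, classify_family, lower_cut = lower_cut,
                 upper_cut = upper_cut, alpha = alpha)
}

#' Summarise a cohort's headline fractions
#'
#' Computes the cohort-level quantities from classified sample calls and
#' the cohort tallies: variant detection rate, de novo rate,
#' parent-of-origin percentages, parental mosaic counts (blood-positive,
#' sperm-only, total) and rate over the droplet-screened families, the
#' number of mosaic probands, and the MAF range over mosaic-called
#' parental samples. Percentages are recomputed from counts and rounded
#' half-up to one decimal. Undefined ratios (zero denominators) are `NA`,
#' never errors.
#'
#' @param samples classified sample table: columns `family_id`,
#'   `member_role`, `tissue`, `platform`, `maf_pct`, `call` (percent-scale
#'   calls from [classify_sample()]). Typically the combined blood-screen
#'   and multi-tissue fixtures, or a simulated cohort's samples.
#' @param tallies the `cohort_tallies` fixture (key/value tibble), a named
#'   list, or `NULL` (tally-derived fields become `NA`).
#' @return one-row tibble of cohort summary fields.
#' @examples
#' samples <- dplyr::bind_rows(load_cohort_fixture("table1_blood"),
#'                             load_cohort_fixture("table3_tissues")) |>
#'   dplyr::filter(platform == "mDDPCR") |>
#'   classify_sample(unit = "percent")
#' summarize_cohort(samples, load_cohort_fixture("cohort_tallies"))
#' @export
summarize_cohort <- function(samples, tallies = NULL) {
  stopifnot(is.data.frame(samples))
  if (nrow(samples) == 0) {
    abort("Empty cohort.", class = "ddmosaic_domain_error")
  }
  if (!"call" %in% names(samples)) {
    abort("`samples` must carry a `call` column; run classify_sample() first.",
          class = "ddmosaic_domain_error")
  }
  tl <- if (is.null(tallies)) list() else if (is.data.frame(tallies)) {
    tallies_as_list(tallies)
  } else as.list(tallies)
  g <- function(key) if (is.null(tl[[key]])) NA_integer_ else tl[[key]]
  pct <- function(num, den) {
    if (is.na(num) || is.na(den) || den == 0) NA_real_
    else round_half_up(100 * num / den, 1)
  }

  dd <- filter(samples, .data$platform == "mDDPCR")
  parental <- filter(dd, .data$member_role %in% c("father", "mother"))
  som_mosaic <- filter(parental, .data$tissue %in% somatic_tissues(),
                       !is.na(.data$call), .data$call == "mosaic")
  blood_mosaic <- filter(som_mosaic, .data$tissue == "blood")
  sperm_mosaic <- filter(parental, .data$tissue == "sperm",
                         !is.na(.data$call), .data$call == "mosaic")
  som_fams <- unique(som_mosaic$family_id)
  sperm_only_fams <- setdiff(unique(sperm_mosaic$family_id), som_fams)
  mosaic_fams <- union(som_fams, sperm_only_fams)

  par_mosaic_samples <- bind_rows(som_mosaic, sperm_mosaic)
  # Parent-of-origin among the mosaic families (father vs mother carrier).
  carrier_roles <- distinct(par_mosaic_samples, .data$family_id,
                            .data$member_role)
  n_pat <- sum(carrier_roles$member_role == "father")
  n_mat <- sum(carrier_roles$member_role == "mother")

  proband_mosaic <- filter(dd, .data$member_role == "proband",
                           !is.na(.data$call), .data$call == "mosaic")

  n_screened <- g("n_screened_families")
  tibble(
    n_probands = g("n_probands"),
    n_variant_positive = g("n_variant_positive"),
    detection_rate_pct = pct(g("n_variant_positive"), g("n_probands")),
    n_trios_tested = g("n_trios_tested"),
    n_de_novo = g("n_de_novo"),
    de_novo_pct = pct(g("n_de_novo"), g("n_trios_tested")),
    n_inherited = g("n_inherited"),
    n_screened_mosaic = n_screened,
    n_sperm_donors = g("n_sperm_donors"),
    n_parental_mosaic_blood = length(unique(blood_mosaic$family_id)),
    n_parental_mosaic_sperm_only = length(sperm_only_fams),
    n_parental_mosaic_total = length(mosaic_fams),
    parental_mosaic_pct = pct(length(mosaic_fams), n_screened),
    sperm_only_rate_pct = pct(length(sperm_only_fams), g("n_sperm_donors")),
    n_parental_mosaic_paternal = n_pat,
    n_parental_mosaic_maternal = n_mat,
    n_proband_mosaic = length(unique(proband_mosaic$family_id)),
    n_aspcr_informative = g("n_aspcr_informative"),
    origin_paternal_pct = pct(g("n_aspcr_paternal"), g("n_aspcr_informative")),
    origin_maternal_pct = pct(g("n_aspcr_maternal"), g("n_aspcr_informative")),
    maf_min_pct = if (nrow(par_mosaic_samples)) {
      min(par_mosaic_samples$maf_pct)
    } else NA_real_,
    maf_max_pct = if (nrow(par_mosaic_samples)) {
      max(par_mosaic_samples$maf_pct)
    } else NA_real_
  )
}
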