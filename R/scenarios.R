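# Family scenario generator: whole-family, multi-tissue synthetic assays
# with germ-layer-correlated MAFs.

#' Germ-layer grouping of sampled tissues
#'
#' Fixed modeling table used to correlate tissue MAFs within an individual:
#' blood and saliva are mesoderm-dominant, buccal/hair/skin contain
#' ectoderm-derived epithelium, urine forms its own group, and sperm is the
#' germline compartment. Tissues in the same group share a group-level MAF
#' draw, so their simulated MAFs are more similar than across groups -
#' emulating variants arising in early embryonic progenitors.
#'
#' @return tibble with columns `tissue`, `germ_layer`.
#' @export
tissue_germ_layers <- function() {
  tibble(
    tissue = c("blood", "saliva", "buccal", "hair", "skin", "urine", "sperm"),
    germ_layer = c("mesoderm", "mesoderm", "ectoderm", "ectoderm",
                   "ectoderm", "urine", "germline")
  )
}

somatic_tissues <- function() c("blood", "buccal", "saliva", "hair", "urine", "skin")

#' Describe a family mosaicism scenario
#'
#' Builds the ground-truth description consumed by
#' [simulate_mosaic_family()]. Five scenario kinds cover the inheritance
#' configurations the classifier distinguishes:
#' \describe{
#'   \item{de_novo}{both parents variant-free, proband constitutional
#'     heterozygote (MAF 0.5).}
#'   \item{inherited_het}{one parent is an affected heterozygote.}
#'   \item{parental_somatic_mosaic}{one parent carries the variant in a
#'     fraction of somatic cells (and, for fathers, sperm).}
#'   \item{parental_germline_only_mosaic}{the father carries the variant in
#'     sperm only; all his somatic tissues are variant-free.}
#'   \item{proband_mosaic}{a postzygotic variant in the proband
#'     (blood MAF below 0.5); parents variant-free.}
#' }
#'
#' Platform sensitivities are carried as scenario fields: Sanger
#' sequencing resolves mosaicism only above `sanger_lod` (default 10%
#' MAF), while the droplet and amplicon assays have limits of detection of
#' 0.01% and 0.5% respectively.
#'
#' @param kind one of the five scenario kinds above.
#' @param parent_of_origin `"paternal"`, `"maternal"`, or `"unknown"`.
#'   Germline-only scenarios are always paternal (only sperm is
#'   collectable).
#' @param parent_maf carrier parent's mean somatic MAF (mosaic scenarios).
#' @param sperm_maf father's sperm MAF; defaults to `parent_maf` for
#'   paternal somatic mosaics.
#' @param proband_maf proband blood MAF; 0.5 except `proband_mosaic`.
#' @param tissues somatic tissues sampled on the carrier parent.
#' @param sanger_lod Sanger sequencing detection threshold (fraction).
#' @param mddpcr_lod,pasm_lod platform limits of detection (fractions).
#' @return list of class `family_scenario`.
#' @examples
#' family_scenario("parental_germline_only_mosaic", sperm_maf = 0.12)
#' @export
family_scenario <- function(kind = c("de_novo", "inherited_het",
                                     "parental_somatic_mosaic",
                                     "parental_germline_only_mosaic",
                                     "proband_mosaic"),
                            parent_of_origin = NULL,
                            parent_maf = 0.1,
                            sperm_maf = NULL,
                            proband_maf = NULL,
                            tissues = somatic_tissues(),
                            sanger_lod = 0.10,
                            mddpcr_lod = 0.0001,
                            pasm_lod = 0.005) {
  kind <- match.arg(kind)
  unknown <- setdiff(tissues, somatic_tissues())
  if (length(unknown) > 0) {
    abort(sprintf("Unknown tissue name(s): %s.",
                  paste(unknown, collapse = ", ")),
          class = "ddmosaic_config_error")
  }
  parent_of_origin <- parent_of_origin %||% switch(
    kind,
    de_novo = "unknown",
    inherited_het = "maternal",
    parental_somatic_mosaic = "maternal",
    parental_germline_only_mosaic = "paternal",
    proband_mosaic = "unknown"
  )
  if (kind == "parental_germline_only_mosaic" &&
      parent_of_origin != "paternal") {
    abort("Germline-only mosaicism is observable only in sperm; set parent_of_origin = 'paternal'.",
          class = "ddmosaic_config_error")
  }
  check_param(parent_maf, "parent_maf", lo = 0, hi = 1)
  check_param(sanger_lod, "sanger_lod", lo = 0, hi = 1)
  proband_maf <- proband_maf %||% if (kind == "proband_mosaic") 0.3 else 0.5
  check_param(proband_maf, "proband_maf", lo = 0, hi = 1)
  sperm_maf <- sperm_maf %||% switch(
    kind,
    parental_somatic_mosaic =
      if (parent_of_origin == "paternal") parent_maf else 0,
    parental_germline_only_mosaic = 0.12,
    0
  )
  check_param(sperm_maf, "sperm_maf", lo = 0, hi = 1)
  structure(
    list(kind = kind, parent_of_origin = parent_of_origin,
         parent_maf = parent_maf, sperm_maf = sperm_maf,
         proband_maf = proband_maf, tissues = tissues,
         sanger_lod = sanger_lod, mddpcr_lod = mddpcr_lod,
         pasm_lod = pasm_lod),
    class = "family_scenario"
  )
}

#' Default droplet assay parameters for cohort simulation
#'
#' About 150,000 droplets at 1/3 occupancy give ~50,000 informative
#' (template-containing) droplets per assay, which makes simulated CI
#' widths comparable to the published tables. The default false-call rate
#' is the pooled negative-control error rate of the reference screen.
#'
#' @return named list of assay parameters.
#' @export
default_assay_params <- function() {
  list(n_droplets = 150000L, occupancy_rate = 1 / 3,
       false_call_rate = 2.15664e-05,
       sd_between = 0.25, sd_within = 0.08,
       pasm_depth = 10000L, pasm_base_error = 1e-04, with_pasm = FALSE)
}

# Draw per-tissue true MAFs around a member-level somatic mean, with a
# shared lognormal group effect per germ layer (smaller dispersion within
# a group than between groups). A mean of zero stays exactly zero.
draw_tissue_mafs <- function(mean_maf, tissues, sd_between, sd_within) {
  if (mean_maf == 0) {
    return(setNames(rep(0, length(tissues)), tissues))
  }
  layers <- tissue_germ_layers()
  grp <- layers$germ_layer[match(tissues, layers$tissue)]
  ug <- unique(grp)
  grp_mult <- setNames(exp(rnorm(length(ug), 0, sd_between)), ug)
  vals <- mean_maf * grp_mult[grp] * exp(rnorm(length(tissues), 0, sd_within))
  setNames(pmin(pmax(vals, 0), 1), tissues)
}

sanger_status_for <- function(true_blood_maf, sanger_lod) {
  if (true_blood_maf >= 0.35) "het_detected"
  else if (true_blood_maf > sanger_lod) "weak_signal"
  else "not_detected"
}

#' Simulate a whole mosaic family
#'
#' Generates per-member, per-tissue droplet counts (and optionally
#' amplicon allele counts) under a [family_scenario()] ground truth. The
#' carrier parent's somatic tissue MAFs are drawn around the member mean
#' with smaller dispersion within the same germ-layer group (see
#' [tissue_germ_layers()]). Both parents contribute a blood sample, the
#' father a sperm sample, the proband a blood sample. Simulated Sanger
#' trio status is a hard threshold on true blood MAF at `sanger_lod`.
#'
#' @param scenario a [family_scenario()].
#' @param assay_params named list as from [default_assay_params()]; set
#'   `with_pasm = TRUE` to also simulate amplicon reads for each sample.
#' @param seed integer seed.
#' @param family_id identifier for the simulated family.
#' @return list of class `family_record` with elements `family_id`,
#'   `scenario_kind`, `aspcr_origin`, `members` (role, affected,
#'   sanger_status, true blood MAF) and `samples` (member_role, tissue,
#'   platform, count columns, `true_maf`).
#' @examples
#' fam <- simulate_mosaic_family(
#'   family_scenario("parental_somatic_mosaic", parent_maf = 0.1),
#'   seed = 4)
#' fam$samples
#' @export
simulate_mosaic_family <- function(scenario,
                                   assay_params = default_assay_params(),
                                   seed, family_id = "SIM001") {
  stopifnot(inherits(scenario, "family_scenario"))
  if (length(scenario$tissues) == 0) {
    abort("Scenario must sample at least one tissue.",
          class = "ddmosaic_config_error")
  }
  check_param(seed, "seed", integer = TRUE)
  ap <- utils::modifyList(default_assay_params(), assay_params)

  truth <- with_seed(derive_seed(seed, 19L), {
    kind <- scenario$kind
    origin <- scenario$parent_of_origin
    carrier <- switch(origin, paternal = "father", maternal = "mother", NA)
    father <- list(somatic = setNames(rep(0, length(scenario$tissues)),
                                      scenario$tissues),
                   sperm = 0)
    mother <- list(somatic = father$somatic)
    if (kind == "inherited_het" && !is.na(carrier)) {
      if (carrier == "father") {
        father$somatic[] <- 0.5; father$sperm <- 0.5
      } else mother$somatic[] <- 0.5
    }
    if (kind == "parental_somatic_mosaic" && !is.na(carrier)) {
      mafs <- draw_tissue_mafs(scenario$parent_maf, scenario$tissues,
                               ap$sd_between, ap$sd_within)
      if (carrier == "father") {
        father$somatic <- mafs; father$sperm <- scenario$sperm_maf
      } else mother$somatic <- mafs
    }
    if (kind == "parental_germline_only_mosaic") {
      father$sperm <- scenario$sperm_maf
    }
    proband_blood <- scenario$proband_maf
    list(father = father, mother = mother, proband_blood = proband_blood)
  })

  sample_grid <- bind_rows(
    tibble(member_role = "father",
           tissue = c(scenario$tissues, "sperm"),
           true_maf = unname(c(truth$father$somatic[scenario$tissues],
                               truth$father$sperm))),
    tibble(member_role = "mother", tissue = scenario$tissues,
           true_maf = unname(truth$mother$somatic[scenario$tissues])),
    tibble(member_role = "proband", tissue = "blood",
           true_maf = truth$proband_blood)
  )

  counts <- purrr::map_dfr(seq_len(nrow(sample_grid)), function(i) {
    simulate_droplet_counts(
      ap$n_droplets, ap$occupancy_rate, sample_grid$true_maf[i],
      ap$false_call_rate, seed = derive_seed(seed, 100L + i)
    )
  })
  samples <- bind_rows(
    mutate(bind_cols(sample_grid, counts), platform = "mDDPCR",
           alt_reads = NA_integer_, depth = NA_integer_)
  )
  if (isTRUE(ap$with_pasm)) {
    pasm <- purrr::map_dfr(seq_len(nrow(sample_grid)), function(i) {
      rd <- simulate_amplicon_reads(ap$pasm_depth, sample_grid$true_maf[i],
                                    ap$pasm_base_error,
                                    seed = derive_seed(seed, 500L + i))
      bind_cols(sample_grid[i, ], rd[, c("alt_reads", "depth")])
    })
    pasm <- mutate(pasm, platform = "PASM", mu = NA_integer_,
                   wt = NA_integer_, na = NA_integer_,
                   informative = NA_integer_)
    samples <- bind_rows(samples, pasm)
  }
  samples <- mutate(samples, family_id = family_id, .before = 1)

  blood_maf <- function(role) {
    v <- samples$true_maf[samples$member_role == role &
                            samples$tissue == "blood" &
                            samples$platform == "mDDPCR"]
    if (length(v)) v[1] else 0
  }
  members <- tibble(
    member_role = c("father", "mother", "proband"),
    affected = c(
      scenario$kind == "inherited_het" &
        scenario$parent_of_origin == "paternal",
      scenario$kind == "inherited_het" &
        scenario$parent_of_origin == "maternal",
      TRUE),
    true_blood_maf = c(blood_maf("father"), blood_maf("mother"),
                       blood_maf("proband")),
    sanger_status = c(
      sanger_status_for(blood_maf("father"), scenario$sanger_lod),
      sanger_status_for(blood_maf("mother"), scenario$sanger_lod),
      sanger_status_for(blood_maf("proband"), scenario$sanger_lod))
  )

  structure(
    list(family_id = family_id, scenario_kind = scenario$kind,
         aspcr_origin = if (scenario$parent_of_origin == "unknown")
           "uninformative" else scenario$parent_of_origin,
         members = members, samples = samples, seed = seed),
    class = "family_record"
  )
}

#' Simulate a cohort of families
#'
#' @param scenarios list of [family_scenario()] objects, one per family.
#' @param assay_params see [simulate_mosaic_family()].
#' @param seed integer seed; each family gets a derived sub-seed.
#' @return list of `family_record` objects, named by family id.
#' @export
simulate_cohort <- function(scenarios, assay_params = default_assay_params(),
                            seed) {
  check_param(seed, "seed", integer = TRUE)
  purrr::imap(scenarios, function(sc, i) {
    idx <- if (is.character(i)) match(i, names(scenarios)) else as.integer(i)
    id <- if (is.character(i) && nzchar(i)) i else sprintf("SIM%03d", idx)
    simulate_mosaic_family(sc, assay_params,
                           seed = derive_seed(seed, 1000L + idx),
                           family_id = id)
  })
}
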