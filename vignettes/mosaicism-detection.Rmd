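---
title: "Detecting low-fraction mosaicism from droplet digital PCR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting low-fraction mosaicism from droplet digital PCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddmosaic)
library(dplyr)
```

## The statistical model

A droplet digital PCR assay partitions a DNA sample into droplets and
scores each as mutant (MU), wild-type (WT) or non-informative (NA). The
package treats each droplet as carrying at most one template molecule,
so the mutant count `k` among the `n = MU + WT` informative droplets is
`Binomial(n, MAF)` and the mutant allele fraction estimate is `k/n`. No
Poisson multi-occupancy correction is applied: MAF is reported directly
from the class counts, which is how droplet counts are read off the
instrument's cluster plot. The simulator has an `occupancy_rate`
parameter controlling how many droplets are informative, but occupancy
never enters the estimator.

Confidence intervals are two-sided exact (Clopper–Pearson) intervals at
`alpha = 0.05`, computed from the beta-quantile closed form. Exactness
matters at the boundaries this application lives at: the interval is
well defined at `k = 0` (lower bound exactly 0, upper bound
`1 - (alpha/2)^(1/n)`), and its coverage is conservative, which is the
right direction of error when deciding whether a rare allele is real.
Printed zero-count intervals in the reference tables (for example
`0.0 (0.0–0.6)` from a ~10,000x amplicon assay) are consistent with this
construction. Which interval flavour the original instrument software
used is not documented; exactness is this package's documented choice.

Deep amplicon sequencing ("PASM-style") estimates reuse the same
machinery with `k = alt_reads` and `n = depth`.

### The positive-detection rule

A sample is called **mosaic** when `CI_lower > lower_cut` and
`CI_upper < upper_cut`, with strict inequalities; **het_consistent**
when `CI_upper >= upper_cut`; otherwise **negative**. Defaults are
`lower_cut = 0.01%` and `upper_cut = 50%`. The lower cutoff is a
detection limit calibrated from negative controls (below); the upper
cutoff separates mosaics from constitutional heterozygotes, whose
expected MAF is 50%. `het_consistent` is not a category the reference
screen names explicitly — it is how this package encodes "the CI
reaches 50%, so the sample looks heterozygous rather than mosaic".

Two conventions are worth stating because they decide borderline calls:

* comparisons happen at the precision of the supplied bounds. Printed
  two-decimal percent tables are compared as printed on the percent
  scale, so a printed lower bound of exactly 0.01 fails `> 0.01` and the
  sample is negative. This reproduces every call in the bundled tables,
  including the borderline father's blood `0.01 (0.01–0.02)`.
* no multiple-testing correction is applied. The screen applies the
  per-sample rule as-is; the package mirrors that and documents it here.
  With the calibrated cutoff the per-sample false-positive rate is
  already far below `alpha` (a mosaic call at `n = 50,000` requires
  `k >= 11` while the expected false count is ~1), so a cohort-level
  correction would change nothing in practice.

### Calibration from negative controls

`pool_error_rate()` pools mutant and informative droplet counts across
negative-control assays into a single per-droplet false-call rate with
an exact CI. The reference screen's pooled value, `2.15664e-05`, is used
throughout the package as the default simulated false-call rate.
`detection_limit_curve()` turns a rate into the upper CI bound as a
function of the number of informative droplets. The construction used
for the published version of this curve is ambiguous in one respect:
whether the count entering the CI is the expected false count or zero.
The operation exposes both (`k_rule = "expected"` and `"zero"`) rather
than guessing; the expected-count curve is the default. With either
rule, the 0.01% cutoff becomes reachable at roughly 10^4 or more
informative droplets, which motivates both the cutoff and the ~50,000
informative droplets the simulator defaults to.

## Family-level classification

`classify_family()` applies a fixed decision cascade:

1. an affected parent with a heterozygous Sanger result →
   `inherited_affected_parent`;
2. any parental somatic tissue (blood, buccal, saliva, hair, urine,
   skin) called mosaic → `parental_somatic_mosaic`, that parent is the
   origin;
3. otherwise mosaic paternal sperm → `parental_germline_only_mosaic`;
4. otherwise a mosaic (not het-consistent) proband blood sample →
   `proband_postzygotic_mosaic`;
5. otherwise `de_novo_unresolved`, with parent-of-origin from
   allele-specific PCR when informative.

Somatic evidence outranks germline-only evidence deliberately: blood is
screened first, and a somatic-positive parent is a gonosomal mosaic
whether or not sperm was also tested. Sperm positivity is proof of
paternal origin; the maternal germline is unobservable in this design
(no female germ cells are collected), an asymmetry the cohort summary
inherits — maternal germline-only mosaicism is systematically missed,
and maternal counts are best read as lower bounds. A family in which
both parents appear mosaic for the same variant is contradictory data
and is flagged `needs_review` rather than classified.

Cohort percentages are rounded half-up to one decimal, matching the
printed convention of the reference tallies.

## The synthetic-data generator

The generator is first-class, tested code that defines the conditions
under which the statistical properties are asserted:

* **Droplet assays**: three well-separated intensity cluster centers
  (NA low/low, WT high on channel 1, MU high on channel 2) plus
  isotropic Gaussian noise scaled to the smallest center separation.
  Informative droplets are mutant with probability
  `MAF + (1 - MAF) * false_call_rate`.
* **Assay size**: 150,000 droplets at occupancy 1/3, i.e. ~50,000
  informative droplets per assay. The reference screen does not print
  per-assay droplet totals; this default was chosen once because it
  makes simulated CI widths comparable to the printed ones, and is not
  asserted as the study's value.
* **Error rate**: default `2.15664e-05`, the published pooled
  negative-control rate, used as generating truth in calibration tests.
* **Tissue panels**: a carrier parent's somatic tissue MAFs are drawn
  around the member-level mean with a shared lognormal group effect per
  germ layer (blood/saliva mesoderm-dominant; buccal/hair/skin
  ectoderm-containing; urine its own group; sperm germline) and a
  smaller within-group dispersion (log-scale SDs 0.25 between, 0.08
  within). The germ-layer table is a documented modeling choice that
  emulates variants arising in early embryonic progenitors; the real
  biology motivates the grouping but prescribes no parameter values.
* **Platform sensitivities**: Sanger detectability is a hard threshold
  at 10% blood MAF (`weak_signal` between 10% and 35%, `het_detected`
  above); the droplet and amplicon assays have detection limits of
  0.01% and 0.5%. No trace simulation is attempted.
* **Determinism**: every generator takes an explicit seed and touches no
  global RNG state; identical seeds give byte-identical output.
* For whole-cohort simulation the droplet counts are drawn at the count
  level (the binomial marginal of the droplet-level generator) so that
  hundreds of families simulate in seconds; a test checks the two levels
  agree distributionally, and intensity-level simulation remains
  available through `simulate_droplet_assay()` + gating.

What the generator does **not** emulate: droplet volume variation,
multi-template occupancy, fluorescence compensation or rain (the
smeared intermediate-intensity droplets of real assays), amplicon
read-level errors with position structure, or relatedness between
families. Passing tests therefore demonstrate correctness of the
statistical machinery under the stated model, not robustness to every
artifact of real droplet data.

## Multi-tissue clustering

MAF vectors are square-root transformed (variance stabilisation for
binomial fractions; applied to fractions in `[0, 1]`, a documented
scale choice since the transform is monotone on either scale), compared
by Euclidean distance, and clustered agglomeratively. Average (UPGMA)
linkage is the default — the reference analysis names the distance but
not the linkage, and UPGMA is the common default for such dendrograms;
complete and single linkage are available. Ties are broken
deterministically by presenting rows in lexicographic label order, so
row order never changes the tree. Trees export as ultrametric Newick
(leaf depth = merge height / 2) and round-trip through standard
parsers.

Missing cells are handled before distances by policy: `drop_feature`
(default, conservative), `drop_sample`, or `pairwise`. Fixture NA cells
are preserved as missing at load time, never imputed. Whether the
published dendrogram clustered samples over several assay columns or a
single MAF column per family is not stated; `build_maf_matrix()`
supports both layouts.

## Numerical choices and degenerate inputs

* CI computation uses `qbeta` directly; tests verify it against an
  independent brute-force bisection on binomial tail probabilities to
  1e-6, exhaustively for all `(k, n <= 500)`.
* `estimate_maf()` refuses a zero informative denominator (an undefined
  MAF is distinct from a MAF of zero).
* Gating requires >= 10 droplets and non-degenerate intensities;
  droplets outside all threshold regions are counted NA and reported,
  never dropped silently. Threshold regions are half-open `[min, max)`
  and must be disjoint.
* `concordance()` requires >= 2 pairs, complete cases, and predictor
  variance; R² is computed from residuals directly so exactly collinear
  input returns 1 without warnings.
* Percent/fraction conversions are centralised (`frac_to_pct()` /
  `pct_to_frac()`); the internal unit is always the fraction.

## Problem sizes used in the test suite

Property-style tests run at sizes chosen to make their Monte-Carlo
margins comfortable: CI coverage at `n = 20,000` with 5,000 replicates
per true fraction; calibration coverage with 500 replicate experiments
of 20 negative controls x 50,000 informative droplets; scenario
recovery over 200 simulated families across the five scenario kinds;
sensitivity brackets with 500 replicate assays. These sizes are the
package's own test design.

## Known limitations

* The bundled cohort tables carry printed point estimates and CI bounds
  but not raw droplet counts, so per-sample counts cannot be
  regenerated from them; analyses on fixtures operate on the printed
  values at printed precision.
* The 80-family screen's ~74 negative families have no printed
  per-sample data and are represented only through the cohort tallies.
* Maternal germline-only mosaicism is undetectable by design (see
  above).
* The published cross-platform R² and the published dendrogram's exact
  leaf set derive from sample sets that are not fully enumerated in the
  tables; the package checks its concordance and clustering operations
  against independent recomputation oracles on the printed values
  instead of asserting those two figures.
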