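---
title: "Triple-tracer PET lesion phenotyping: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triple-tracer PET lesion phenotyping: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tripet)
```

## The problem

In metastatic castration-resistant prostate cancer (mCRPC), different
metastases within one patient can express different biology: some lesions
are PSMA-avid adenocarcinoma, some are glycolytic (FDG-avid) but have lost
PSMA expression, and a minority express somatostatin receptors (DOTATATE-avid),
suggesting neuroendocrine differentiation. This *intrapatient
intermetastatic heterogeneity* (IIH) matters clinically because
radiopharmaceutical therapy (RPT) only treats lesions that express its
target: a patient with even one FDG-positive/PSMA-negative lesion has
hypermetabolic disease that PSMA RPT cannot reach.

`tripet` implements a complete, reproducible analysis chain for
multi-tracer PET phenotyping studies of this design: image quantitation
from co-registered SUV volumes, per-lesion phenotype classification,
patient-level endpoints (IIH, suspected neuroendocrine differentiation,
RPT eligibility), cohort prevalence statistics with exact binomial
intervals, and phenotype-stratified survival analysis. Because real
triple-tracer cohorts are rare and individual patient data are typically
unpublished, the package ships synthetic generators — a voxel phantom and
a lesion-table replica cohort — that exercise every stage end to end.

## The quantitation model

All measurements are expressed as SUV (standardized uptake value) ratios
against the patient's own liver, which removes most inter-scan calibration
differences:

1. **Liver reference.** The liver SUVmean is measured in a 3-cm-diameter
   spherical volume of interest (`measure_liver_reference()`), per tracer.
2. **Segmentation.** Voxels with SUV at or above 1.5 × liver SUVmean are
   grouped into connected components (`segment_vois()`), one VOI per
   component. "Contiguous uptake" is interpreted as 26-connectivity
   (faces, edges and corners); 6- and 18-connectivity are available.
3. **Volume filter.** VOIs strictly smaller than 1 cm³ are discarded
   (`filter_small_vois()`); exactly 1.00 cm³ is kept.
4. **Physiologic exclusion.** VOIs overlapping a supplied
   physiologic-uptake mask by more than 50% are dropped
   (`exclude_physiologic()`). In the clinical workflow this step is expert
   consensus; a mask with an overlap cutoff is the automatable analogue.
5. **Cross-tracer merging.** VOIs from different tracers that share at
   least one voxel (transitively) are one lesion (`merge_lesions()`). Every
   tracer is then measured on the *union* footprint, which is what makes a
   discordant phenotype such as FDG+/PSMA− measurable: the PSMA ratio of an
   FDG-detected lesion is evaluated on the same voxels and found
   sub-threshold.
6. **SUVpeak.** The peak is PERCIST-style (`measure_suv_peak()`): the
   maximum over 1-cm³ spheres centered on each lesion voxel of the mean SUV
   of all in-grid voxels inside the sphere. The sphere is not restricted to
   lesion voxels, so small hot lesions are averaged down — the standard
   partial-volume-like behaviour of SUVpeak. For lesions near the grid edge
   the sphere is clipped to the grid, which also covers lesions smaller
   than the sphere support.
7. **Capping.** Within each compartment (nodes, bones, liver, other) ×
   dual-tracer phenotype (FDG+/PSMA−, FDG+/PSMA+, FDG−/PSMA+) cell, the 10
   hottest lesions are recorded (`cap_lesions()`), a budget of up to 120
   lesions per patient. "Hottest" is not defined in the source protocols;
   we use the maximum SUVpeak ratio over the tracers positive for the
   lesion, falling back to the maximum over all measured tracers, with ties
   broken by larger volume then smaller lesion id so the selection is
   deterministic. DOTATATE status does not create extra capping cells.

Voxel indices are 1-based inside R; the world coordinate of voxel
$(i,j,k)$ is $((i,j,k)-1) \cdot \text{spacing}$, and sphere membership is
decided by voxel-center distance. All geometric operations are exact under
this convention and are tested against brute-force voxel enumeration.

## Phenotypes and endpoints

A lesion is **positive** for a tracer when its SUVpeak ratio is at least
1.5 — inclusive, so a ratio of exactly 1.5 is positive
(`classify_lesion()`). Patient-level endpoints follow directly:

* **DOTATATE trigger** — at least one FDG+/PSMA− lesion. In the study
  design this gates the third scan; in the pipeline it is data
  (`dotatate_scanned`), so cohorts where not every trigger-positive patient
  was scanned are representable.
* **IIH** — at least two lesions with different phenotype labels.
* **Suspected neuroendocrine differentiation (NED)** — at least one
  DOTATATE+ lesion, defined only in the scanned subcohort.
* **PSMA-RPT eligibility** — at least one PSMA+ lesion and no FDG+/PSMA−
  lesion.
* **DOTATATE-RPT eligibility** — at least one DOTATATE+ lesion and no
  FDG+/DOTATATE− lesion (scanned subcohort only).

Two label conventions required a decision:

* **All-negative lesions** (every measured ratio below 1.5) carry no
  phenotype: they never contribute to a combination or to IIH. A patient
  whose every lesion is all-negative forms the *all-negative class*; such
  patients stay in prevalence denominators but are excluded from
  IIH-stratified group comparisons and survival contrasts, whose grouping
  is undefined for them.
* **DOTATATE-negative lesions keep their dual FDG/PSMA label**, and `/D+`
  is appended only for DOTATATE-positive lesions. This places scanned and
  unscanned patients in a single combination space (a scanned patient whose
  lesions are all DOTATATE-negative has the same combination as the
  equivalent unscanned patient), which is what makes a single cohort-wide
  count of distinct combinations meaningful. Within a patient the mapping
  preserves label distinctness, so IIH is identical under full
  FDG/PSMA/DOTATATE labels.

With these conventions the combination space is the 7 non-empty subsets of
{FDG+/PSMA−, FDG+/PSMA+, FDG−/PSMA+} plus DOTATATE-split variants, and
`count_phenotype_combinations()` counts distinct combinations over
patients with at least one phenotype-positive lesion.

## Cohort statistics

Prevalences are reported with Clopper–Pearson exact binomial intervals,
computed from the beta-quantile characterization of the binomial tail
inversion (`clopper_pearson()`), in percent. Group comparisons
(`two_group_tests()`) dispatch to the standard two-sided tests: Pearson
χ² *with Yates continuity correction* and Fisher's exact test for 2×2
tables, and t / Mann–Whitney for continuous variables. Continuity
correction is deliberate: it is the common clinical-statistics default and
reproduces the published table p-values this package is validated against
(the uncorrected χ² does not).

The protocol sample-size rule (`sample_size_for_proportion()`) is the
normal-approximation precision formula
$n = \lceil z^2\,p(1-p)/d^2 \rceil$ for half-width $d$; it returns 81 at
$p=0.30,\ d=0.10$ and 97 at $p=0.50$, and is maximal at $p=0.5$.

## Survival analysis

Overall survival runs from the first PET scan to death of any cause, with
administrative censoring at 13 months. `km_fit()`, `logrank_test()` and
`cox_binary()` are typed wrappers over the `survival` package: product-limit
estimation with log-log median CIs, the 1-df log-rank test, and a
single-binary-covariate Cox model with **Efron** tie handling (ties are
guaranteed by month-resolution data and by the censoring horizon) and a
Wald CI on the log hazard scale. A fit with no events, or with complete
separation (divergent estimate), is flagged non-estimable rather than
returned as a spurious number. The test suite verifies these wrappers
against hand-computed product-limit curves, risk-set log-rank tallies and a
grid-search maximizer of the Efron partial likelihood, and checks the
score-test/log-rank identity on tie-free data.

`survival_contrast()` runs the three study stratifications: IIH vs no IIH
and FDG+/PSMA− carriage vs not (both excluding the all-negative class, so
n = 97 in the replica) and DOTATATE positivity within the scanned
subcohort (n = 37).

## The synthetic generators

### Voxel phantom

`generate_phantom()` renders per-tracer SUV volumes from a uniform
background, a spherical liver at a configurable SUV (the ratio
denominator), and planted spherical lesions carrying per-tracer SUVs
(additive where spheres overlap), with optional additive Gaussian noise
clamped at zero. The phantom emulates exactly what the thresholding logic
consumes — contrast against a liver reference on a voxel grid. It does
*not* emulate PET physics: no scatter, no reconstruction point-spread, no
Poisson count statistics, no partial-volume blur. Passing phantom tests
therefore validates the segmentation/measurement chain, not robustness to
scanner noise characteristics.

### Replica cohort

`generate_replica_cohort()` produces a 98-patient lesion-table cohort whose
patient-level marginals equal the published counts on every seed: 81/98
with IIH, 45/98 with ≥1 FDG+/PSMA− lesion, one all-negative patient, 52/98
PSMA-RPT eligible, and a 37-patient DOTATATE subcohort with 6 DOTATATE+
patients, 31 with IIH and none DOTATATE-RPT eligible, across 12 distinct
phenotype combinations including one 5-phenotype patient. The roster of
combinations is fixed — the marginals are construction invariants, not
sampling outcomes — while the seed drives ratios (positives uniform on
[1.55, 6], negatives on [0.30, 1.40]), volumes (1–25 cm³), compartments,
duplicate-lesion counts and survival draws. Per-combination patient counts
beyond the stated marginals are not published as text and were chosen
freely subject to those constraints; analyses that depend on the detailed
combination distribution should not treat the replica as ground truth.

### Survival generator

`simulate_survival()` draws exponential event times per group
(rate $\ln 2 / \text{median}$), accrual at time 0, censored at the horizon.
The replica attaches survival by phenotype group with medians 3.0 months
(DOTATATE-positive), 5.6 months (other FDG+/PSMA− carriers; the published
median of that stratum) and 15.12 months (= 5.6 × 2.7, all others), so the
FDG+/PSMA− contrast has true hazard ratio 2.7 against an arm whose median
lies beyond the censoring horizon ("not reached"). The generator
conditions on FDG/PSMA and DOTATATE status only; it does not separately
force the IIH contrast, whose published patient-level times are
unavailable, so the replica's IIH hazard ratio is attenuated relative to
the published one — a known, documented limitation rather than a target.

## Numerical and performance choices

* Connected components are computed by a vectorized 3D adjacency scan fed
  to a union–find (`igraph::components()`); the suite checks equality with
  an explicit flood-fill oracle on 1,000 random grids up to 16³.
* All generators are bit-reproducible for a fixed seed; the pipeline uses
  stable sorts and deterministic tie-breaks throughout, so re-running with
  identical inputs is bit-identical.
* Simulation-based checks use 500 replicates of the 97-patient two-group
  design (seconds on one CPU); the Cox recovery property is asserted on
  the mean estimate within 10%, which absorbs the small upward
  transformation bias of averaging hazard ratios on the natural scale
  (about +4% at these event counts).
* Degenerate inputs are first-class: empty cohorts fail validation before
  any stage runs; patients missing a required tracer are routed to an
  exclusions report; no-event or separated survival strata are flagged
  non-estimable; an all-background volume segments to an empty VOI list.

## Known limitations

* The phantom's noise model is additive Gaussian; real PET noise is
  neither Gaussian nor stationary.
* Compartment assignment expects a label map (majority vote over the
  lesion footprint); organ segmentation is out of scope.
* Physiologic exclusion is mask-driven, a proxy for expert consensus
  reading.
* Only single-binary-covariate survival models are provided — matching the
  analyses the package reproduces — not multivariable Cox or competing
  risks.
* The replica cohort reproduces marginals, not joint distributions; its
  published-value agreement validates endpoint logic, not biology.
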