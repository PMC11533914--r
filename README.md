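# tripet

Multi-tracer PET lesion phenotyping and intermetastatic-heterogeneity
analysis for metastatic castration-resistant prostate cancer (mCRPC)
imaging studies.

## What it does, and for whom

In mCRPC, metastases within one patient can diverge biologically:
PSMA-expressing adenocarcinoma, PSMA-negative but glycolytic (FDG-avid)
disease, and somatostatin-receptor-positive (DOTATATE-avid) lesions
suggestive of neuroendocrine differentiation. Radiopharmaceutical therapy
(RPT) only reaches lesions expressing its target, so *intrapatient
intermetastatic heterogeneity* (IIH) — one patient harbouring lesions with
different multi-tracer phenotypes — directly determines treatment
eligibility.

`tripet` is for imaging scientists and trialists running
FDG / PSMA / DOTATATE PET phenotyping analyses. It implements the full
chain:

* **Quantitation** — liver-referenced threshold segmentation of SUV
  volumes (threshold = 1.5 × liver SUVmean from a 3-cm sphere),
  26-connected VOI delineation, discarding of VOIs < 1 cm³, mask-based
  physiologic exclusion, cross-tracer lesion merging, PERCIST-style 1-cm³
  SUVpeak, and capping at the 10 hottest lesions per compartment ×
  phenotype cell (≤ 120 lesions/patient).
* **Phenotyping** — a lesion is positive for a tracer when its SUVpeak
  ratio (SUVpeak ÷ liver SUVmean) is ≥ 1.5. Patient endpoints: phenotype
  combination, IIH (≥ 2 lesions with different phenotypes), suspected
  neuroendocrine differentiation (≥ 1 DOTATATE+ lesion), PSMA-RPT
  eligibility (≥ 1 PSMA+ and no FDG+/PSMA− lesion) and DOTATATE-RPT
  eligibility (≥ 1 DOTATATE+ and no FDG+/DOTATATE− lesion).
* **Cohort statistics** — Clopper–Pearson exact binomial prevalence CIs,
  χ² (with continuity correction) / Fisher / t / Mann–Whitney group
  comparisons, and the precision-based sample-size rule
  n = ⌈z² p(1−p)/d²⌉.
* **Survival** — Kaplan–Meier medians, log-rank tests and binary-covariate
  Cox hazard ratios (Efron ties, Wald CIs), censored at 13 months.
* **Synthetic data** — a voxel phantom with planted spherical lesions and
  a 98-patient replica cohort whose endpoint marginals match the published
  study counts on every seed, so the whole pipeline is testable without
  patient data.

## Worked example

```r
library(tripet)

cohort <- generate_replica_cohort(seed = 1)
result <- run_pipeline(cohort = cohort)
print(result)
```

```
<tripet_result> 98 patients, 12 phenotype combinations
              endpoint  k  n proportion    ci_low   ci_high
                   iih 81 98   82.65306 73.685031 89.557568
      fdg_pos_psma_neg 45 98   45.91837 35.803815 56.286202
                   ned  6 37   16.21622  6.192572 32.013708
     psma_rpt_eligible 52 98   53.06122 42.710955 63.221549
 dotatate_rpt_eligible  0 37    0.00000  0.000000  9.489059
  iih: HR 1.01 (0.53-1.94), log-rank p 0.9694
  fdg_pos_psma_neg: HR 2.62 (1.59-4.30), log-rank p 8.634e-05
  dotatate_pos: HR 3.71 (1.39-9.86), log-rank p 0.004951
```

Reading this: 81/98 patients (82.7%, exact 95% CI 73.7–89.6%) show IIH;
45/98 harbour at least one FDG+/PSMA− lesion, which makes them ineligible
for PSMA RPT (52/98 remain eligible; the one all-negative patient is also
ineligible). Of the 37 DOTATATE-scanned patients, 6 have a DOTATATE+
lesion and none qualifies for DOTATATE RPT. The survival lines are Cox
hazard ratios with 95% CIs for each phenotype stratification of the
simulated survival data; carriers of FDG+/PSMA− lesions (generated with
true hazard ratio 2.7) and DOTATATE+ patients die faster, while the
replica's IIH contrast is attenuated by design (see the methods
vignette).

The voxel path works the same way from images:

```r
spec <- phantom_spec(
  grid_shape = c(48, 48, 48), voxel_spacing = 4, liver_suv = 2,
  liver_center = c(60, 60, 60), liver_radius = 20,
  lesions = list(lesion_spec(c(120, 120, 120), radius = 10,
                             suv_by_tracer = c(FDG = 4, PSMA = 1))))
vols <- generate_phantom(spec)
quantify_patient(vols, liver_center = c(60, 60, 60))
#>   patient_id lesion_id compartment volume_cm3 ratio_fdg ratio_psma ratio_dotatate
#> 1         P1         1       other      5.184         2        0.5             NA
```

One lesion, FDG ratio 2.0 (positive), PSMA ratio 0.5 (negative): an
FDG+/PSMA− lesion, the phenotype that triggers DOTATATE scanning and
blocks PSMA-RPT eligibility.

A thin CLI covering the generators and the table pipeline ships in
`inst/exec/tripet` (`replica`, `phantom`, `pipeline` subcommands).

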