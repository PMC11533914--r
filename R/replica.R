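#' Generate the replica study cohort
#'
#' Builds a 98-patient lesion-table cohort whose patient-level marginals
#' reproduce the study's printed counts on every seed:
#'
#' * 81/98 patients with intrapatient intermetastatic heterogeneity (IIH);
#' * 45/98 patients with at least one FDG+/PSMA- lesion;
#' * exactly 1 patient with no tracer-positive lesion (all-negative class);
#' * 52/98 patients eligible for PSMA radiopharmaceutical therapy;
#' * a flagged 37-patient DOTATATE subcohort (all harbouring an FDG+/PSMA-
#'   lesion) containing exactly 6 patients with a DOTATATE+ lesion, 31 with
#'   IIH, and 0 eligible for DOTATATE RPT;
#' * exactly 12 distinct phenotype combinations, one patient carrying 5
#'   distinct lesion phenotypes.
#'
#' The roster of phenotype combinations is fixed (the marginals hold
#' structurally); the seed only drives the sampled SUVpeak ratios, lesion
#' volumes, compartments, extra duplicate lesions, and the
#' phenotype-dependent survival draws.  Positive phenotype assignments
#' sample ratios >= 1.5, negative ones < 1.5.  Survival is exponential with
#' group medians 3.0 months (DOTATATE+ patients), 5.6 months (other
#' FDG+/PSMA- patients) and 15.12 months (all others), censored at 13
#' months.
#'
#' @param seed integer seed.
#' @return List of class `tripet_cohort` with elements `patients`
#'   (`patient_id`, `dotatate_scanned`, `os_months`, `event`) and `lesions`
#'   (`patient_id`, `lesion_id`, `compartment`, `volume_cm3`, `ratio_fdg`,
#'   `ratio_psma`, `ratio_dotatate`).
#' @export
generate_replica_cohort <- function(seed = 1L) {
  combos <- replica_roster()
  set.seed(as.integer(seed))

  lesion_rows <- list()
  patient_rows <- list()
  for (i in seq_along(combos)) {
    pid <- sprintf("P%03d", i)
    combo <- combos[[i]]
    labels <- combo$labels
    # duplicate some phenotypes so lesion count exceeds phenotype count
    n_extra <- sample(0:3, 1)
    labels <- c(labels, sample(labels, n_extra, replace = TRUE))
    les <- replica_lesions(pid, labels, combo$scanned)
    lesion_rows[[i]] <- les
    patient_rows[[i]] <- data.frame(patient_id = pid,
                                    dotatate_scanned = combo$scanned,
                                    survival_group = combo$surv_group,
                                    stringsAsFactors = FALSE)
  }
  lesions <- do.call(rbind, lesion_rows)
  patients <- do.call(rbind, patient_rows)
  rownames(lesions) <- rownames(patients) <- NULL

  scen <- survival_scenario(
    stats::setNames(patients$survival_group, patients$patient_id),
    c(dot_pos = 3.0, fp_neg = 5.6, other = 5.6 * 2.7),
    censor_horizon = 13,
    seed = (as.integer(seed) + 7919L) %% .Machine$integer.max
  )
  surv <- simulate_survival(scen)
  patients$os_months <- surv$os_months[match(patients$patient_id, surv$patient_id)]
  patients$event <- surv$event[match(patients$patient_id, surv$patient_id)]
  patients$survival_group <- NULL

  cohort <- structure(list(patients = patients, lesions = lesions),
                      class = "tripet_cohort")
  validate_replica(cohort)
  cohort
}

# Fixed combination roster: 98 patients, each a set of canonical phenotype
# labels ("neg" = all-negative lesion), a DOTATATE-scanned flag, and a
# survival group.  Label vocabulary: F+/P-, F+/P+, F-/P+ and the
# DOTATATE-split variants F+/P-/D+, F+/P+/D+, F-/P+/D+.
replica_roster <- function() {
  combo <- function(labels, scanned, surv_group)
    list(labels = labels, scanned = scanned, surv_group = surv_group)
  rep_combo <- function(n, ...) rep(list(combo(...)), n)

  c(
    # 1 all-negative patient (two sub-threshold lesions)
    list(combo(c("neg", "neg"), FALSE, "other")),
    # 52 PSMA-RPT-eligible patients (no F+/P- lesion, >=1 PSMA+)
    rep_combo(5,  "F+/P+", FALSE, "other"),
    rep_combo(5,  "F-/P+", FALSE, "other"),
    rep_combo(42, c("F+/P+", "F-/P+"), FALSE, "other"),
    # 8 unscanned F+/P- patients, all with dual-tracer IIH
    rep_combo(4, c("F+/P-", "F+/P+"), FALSE, "fp_neg"),
    rep_combo(2, c("F+/P-", "F-/P+"), FALSE, "fp_neg"),
    rep_combo(2, c("F+/P-", "F+/P+", "F-/P+"), FALSE, "fp_neg"),
    # 37-patient DOTATATE subcohort (every patient has >=1 F+/P- lesion):
    #   6 without IIH (single phenotype, DOTATATE-negative throughout)
    rep_combo(6, "F+/P-", TRUE, "fp_neg"),
    #   25 with dual-tracer IIH, DOTATATE-negative
    rep_combo(10, c("F+/P-", "F+/P+"), TRUE, "fp_neg"),
    rep_combo(7,  c("F+/P-", "F-/P+"), TRUE, "fp_neg"),
    rep_combo(8,  c("F+/P-", "F+/P+", "F-/P+"), TRUE, "fp_neg"),
    #   6 with >=1 DOTATATE+ lesion, covering the 5 DOTATATE-split
    #   combinations (the last is the 5-phenotype patient)
    rep_combo(2, c("F+/P-", "F+/P-/D+"), TRUE, "dot_pos"),
    rep_combo(1, c("F+/P-", "F+/P+", "F+/P-/D+"), TRUE, "dot_pos"),
    rep_combo(1, c("F+/P-", "F-/P+", "F-/P+/D+"), TRUE, "dot_pos"),
    rep_combo(1, c("F+/P-", "F+/P+", "F-/P+", "F+/P-/D+"), TRUE, "dot_pos"),
    rep_combo(1, c("F+/P-", "F+/P+", "F-/P+", "F+/P-/D+", "F+/P+/D+"),
              TRUE, "dot_pos")
  )
}

# Sample one patient's lesion rows consistent with the assigned labels.
replica_lesions <- function(pid, labels, scanned) {
  n <- length(labels)
  pos_ratio <- function(k) stats::runif(k, 1.55, 6.0)
  neg_ratio <- function(k) stats::runif(k, 0.30, 1.40)
  f <- grepl("F+", labels, fixed = TRUE)
  p <- grepl("P+", labels, fixed = TRUE)
  d <- grepl("D+", labels, fixed = TRUE)
  neg <- labels == "neg"
  data.frame(
    patient_id = rep(pid, n),
    lesion_id = seq_len(n),
    compartment = sample(c("nodes", "bones", "liver", "other"), n, replace = TRUE),
    volume_cm3 = round(stats::runif(n, 1.0, 25.0), 2),
    ratio_fdg = ifelse(f & !neg, pos_ratio(n), neg_ratio(n)),
    ratio_psma = ifelse(p & !neg, pos_ratio(n), neg_ratio(n)),
    ratio_dotatate = if (scanned) ifelse(d, pos_ratio(n), neg_ratio(n))
                     else NA_real_,
    stringsAsFactors = FALSE
  )
}

# Hard check that the construction meets every marginal; a failure here is
# a programming error, not a data property.
validate_replica <- function(cohort) {
  prof <- build_profiles(cohort$lesions, cohort$patients)
  sub <- prof[prof$dotatate_scanned, ]
  ok <- nrow(prof) == 98L &&
    sum(prof$iih) == 81L &&
    sum(prof$has_fdg_pos_psma_neg) == 45L &&
    sum(prof$combination == "all-negative") == 1L &&
    sum(prof$psma_rpt_eligible) == 52L &&
    nrow(sub) == 37L &&
    all(sub$has_fdg_pos_psma_neg) &&
    sum(sub$ned) == 6L &&
    sum(sub$iih) == 31L &&
    sum(sub$dotatate_rpt_eligible) == 0L &&
    count_phenotype_combinations(prof) == 12L &&
    max(prof$n_phenotypes) == 5L
  if (!ok) stop("internal error: replica cohort violates a marginal constraint")
  invisible(cohort)
}

#' @export
print.tripet_cohort <- function(x, ...) {
  cat(sprintf("<tripet_cohort> %d patients, %d lesions (%d DOTATATE-scanned)\n",
              nrow(x$patients), nrow(x$lesions), sum(x$patients$dotatate_scanned)))
  invisible(x)
}

#' Write / read a cohort as CSV files
#'
#' The on-disk form is two plain CSVs, `lesions.csv` and `patients.csv`,
#' in the schema of [generate_replica_cohort()].  An unmeasured DOTATATE
#' ratio is an empty field.
#'
#' @param cohort a `tripet_cohort` (or any list with `patients` and
#'   `lesions` data.frames).
#' @param dir directory to write to / read from.
#' @return `write_cohort` returns the paths invisibly; `read_cohort`
#'   returns a `tripet_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lp <- file.path(dir, "lesions.csv")
  pp <- file.path(dir, "patients.csv")
  utils::write.csv(cohort$lesions, lp, row.names = FALSE, na = "")
  utils::write.csv(cohort$patients, pp, row.names = FALSE, na = "")
  invisible(c(lesions = lp, patients = pp))
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  lesions <- utils::read.csv(file.path(dir, "lesions.csv"),
                             stringsAsFactors = FALSE)
  patients <- utils::read.csv(file.path(dir, "patients.csv"),
                              stringsAsFactors = FALSE)
  patients$dotatate_scanned <- as.logical(patients$dotatate_scanned)
  structure(list(patients = patients, lesions = lesions),
            class = "tripet_cohort")
}
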