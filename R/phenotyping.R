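#' Classify a lesion's imaging phenotype
#'
#' A lesion is positive for a tracer when its SUVpeak ratio (lesion SUVpeak
#' divided by that tracer's liver SUVmean) is at least `threshold` --
#' inclusive, so a ratio of exactly 1.5 is positive.  Tracers the patient
#' was not scanned with are `unmeasured`; a measured tracer with a missing
#' ratio is an error.
#'
#' @param ratios named numeric vector of SUVpeak ratios, e.g.
#'   `c(FDG = 2.1, PSMA = 0.8)` or with a `DOTATATE` entry.
#' @param scanned_tracers character vector of tracers the patient was
#'   scanned with (default: the names of `ratios` that are non-missing).
#' @param threshold positivity cutoff (default 1.5).
#' @return List with `status` (named character,
#'   `"positive"`/`"negative"`/`"unmeasured"`) and `label` (e.g.
#'   `"F+/P-"`, `"F+/P+/D-"`).
#' @export
classify_lesion <- function(ratios, scanned_tracers = NULL, threshold = 1.5) {
  all_tracers <- c("FDG", "PSMA", "DOTATATE")
  if (is.null(scanned_tracers))
    scanned_tracers <- names(ratios)[!is.na(ratios)]
  scanned_tracers <- intersect(all_tracers, scanned_tracers)
  if (length(scanned_tracers) == 0L) stop("at least one tracer must be scanned")
  missing_r <- setdiff(scanned_tracers, names(ratios)[!is.na(ratios)])
  if (length(missing_r))
    stop("missing ratio for scanned tracer(s): ", paste(missing_r, collapse = ", "))
  status <- stats::setNames(rep("unmeasured", 3L), all_tracers)
  for (tr in scanned_tracers)
    status[tr] <- if (ratios[tr] >= threshold) "positive" else "negative"
  abbr <- c(FDG = "F", PSMA = "P", DOTATATE = "D")
  parts <- vapply(all_tracers[status != "unmeasured"], function(tr)
    paste0(abbr[tr], if (status[tr] == "positive") "+" else "-"), character(1))
  list(status = status, label = paste(parts, collapse = "/"))
}

# Vectorized positivity columns for a lesion table.  dotatate_scanned:
# logical, recycled over rows.  Ratios for unscanned DOTATATE are ignored
# even if present.
lesion_positivity <- function(lesions, dotatate_scanned, threshold = 1.5) {
  n <- nrow(lesions)
  if (any(is.na(lesions$ratio_fdg)) || any(is.na(lesions$ratio_psma)))
    stop("FDG and PSMA ratios are required for every lesion")
  ds <- rep_len(dotatate_scanned, n)
  if (any(ds & is.na(lesions$ratio_dotatate)))
    stop("missing DOTATATE ratio for a DOTATATE-scanned patient's lesion")
  data.frame(
    fdg_pos = lesions$ratio_fdg >= threshold,
    psma_pos = lesions$ratio_psma >= threshold,
    dot_pos = ifelse(ds, lesions$ratio_dotatate >= threshold, NA)
  )
}

# Canonical per-lesion phenotype label used for combinations and IIH.
# DOTATATE-negative (or unmeasured) lesions keep their dual F/P label;
# "/D+" is appended only when DOTATATE-positive, so scanned and unscanned
# patients' combinations live in one label space.  All-negative lesions
# (no positive measured tracer) get the sentinel "neg" and never contribute
# a phenotype.
phenotype_labels <- function(pos) {
  lab <- paste0(ifelse(pos$fdg_pos, "F+", "F-"), "/",
                ifelse(pos$psma_pos, "P+", "P-"))
  dplus <- !is.na(pos$dot_pos) & pos$dot_pos
  lab[dplus] <- paste0(lab[dplus], "/D+")
  allneg <- !pos$fdg_pos & !pos$psma_pos & !dplus
  lab[allneg] <- "neg"
  lab
}

#' Patient-level endpoint predicates
#'
#' Boolean endpoints evaluated on one patient's (capped) lesion table:
#'
#' * `needs_dotatate()`: at least one FDG+/PSMA- lesion -- the trigger for
#'   the third, DOTATATE, scan.
#' * `flag_iih()`: intrapatient intermetastatic heterogeneity -- at least
#'   2 lesions with different phenotype labels.  All-negative lesions carry
#'   no phenotype and are ignored.
#' * `flag_ned()`: suspected neuroendocrine differentiation -- at least one
#'   DOTATATE+ lesion (defined only for DOTATATE-scanned patients).
#' * `psma_rpt_eligible()`: at least one PSMA+ lesion and no FDG+/PSMA-
#'   lesion.
#' * `dotatate_rpt_eligible()`: at least one DOTATATE+ lesion and no
#'   FDG+/DOTATATE- lesion (DOTATATE-scanned patients only).
#'
#' @param lesions lesion table for a single patient (see [lesion_table()]).
#' @param dotatate_scanned logical, was the patient DOTATATE-scanned.
#' @param threshold positivity cutoff (default 1.5).
#' @return Logical scalar.
#' @name patient-flags
NULL

#' @rdname patient-flags
#' @export
needs_dotatate <- function(lesions, threshold = 1.5) {
  if (nrow(lesions) == 0L) return(FALSE)
  pos <- lesion_positivity(lesions, FALSE, threshold)
  any(pos$fdg_pos & !pos$psma_pos)
}

#' @rdname patient-flags
#' @export
flag_iih <- function(lesions, dotatate_scanned = FALSE, threshold = 1.5) {
  if (nrow(lesions) < 2L) return(FALSE)
  pos <- lesion_positivity(lesions, dotatate_scanned, threshold)
  lab <- phenotype_labels(pos)
  length(unique(lab[lab != "neg"])) >= 2L
}

#' @rdname patient-flags
#' @export
flag_ned <- function(lesions, dotatate_scanned, threshold = 1.5) {
  if (!isTRUE(dotatate_scanned))
    stop("NED is defined only for DOTATATE-scanned patients")
  if (nrow(lesions) == 0L) return(FALSE)
  pos <- lesion_positivity(lesions, TRUE, threshold)
  any(pos$dot_pos)
}

#' @rdname patient-flags
#' @export
psma_rpt_eligible <- function(lesions, threshold = 1.5) {
  if (nrow(lesions) == 0L) return(FALSE)
  pos <- lesion_positivity(lesions, FALSE, threshold)
  any(pos$psma_pos) && !any(pos$fdg_pos & !pos$psma_pos)
}

#' @rdname patient-flags
#' @export
dotatate_rpt_eligible <- function(lesions, dotatate_scanned, threshold = 1.5) {
  if (!isTRUE(dotatate_scanned))
    stop("DOTATATE-RPT eligibility is defined only for DOTATATE-scanned patients")
  if (nrow(lesions) == 0L) return(FALSE)
  pos <- lesion_positivity(lesions, TRUE, threshold)
  any(pos$dot_pos) && !any(pos$fdg_pos & !pos$dot_pos)
}

#' Canonical phenotype-combination identifier
#'
#' The patient's combination is the sorted set of distinct phenotype labels
#' among their lesions; all-negative lesions contribute nothing.  A patient
#' whose every lesion is all-negative belongs to the `"all-negative"`
#' class, which is not counted as a phenotype combination.
#'
#' @inheritParams patient-flags
#' @return Character scalar, e.g. `"F+/P-|F+/P+"` or `"all-negative"`.
#' @export
combination_label <- function(lesions, dotatate_scanned = FALSE, threshold = 1.5) {
  if (nrow(lesions) == 0L) return("all-negative")
  pos <- lesion_positivity(lesions, dotatate_scanned, threshold)
  lab <- unique(phenotype_labels(pos))
  lab <- sort(lab[lab != "neg"])
  if (length(lab) == 0L) "all-negative" else paste(lab, collapse = "|")
}

#' Build per-patient phenotype profiles
#'
#' Runs the full patient-level phenotyping over a cohort's lesion and
#' patient tables: per-lesion positivity, combination label, IIH, NED,
#' DOTATATE-scan trigger, and both RPT-eligibility flags.  NED and
#' DOTATATE-RPT eligibility are `NA` for patients who were not
#' DOTATATE-scanned; patients with no lesions above threshold are the
#' `"all-negative"` class.
#'
#' @param lesions cohort lesion table (`patient_id`, `lesion_id`,
#'   `compartment`, `volume_cm3`, `ratio_fdg`, `ratio_psma`,
#'   `ratio_dotatate`).
#' @param patients cohort patient table (`patient_id`, `dotatate_scanned`,
#'   and optionally `os_months`, `event`).
#' @param threshold positivity cutoff (default 1.5).
#' @return data.frame with one row per patient: `patient_id`,
#'   `dotatate_scanned`, `n_lesions`, `combination`, `n_phenotypes`,
#'   `has_fdg_pos_psma_neg`, `iih`, `ned`, `psma_rpt_eligible`,
#'   `dotatate_rpt_eligible`, plus survival columns when present.
#' @export
build_profiles <- function(lesions, patients, threshold = 1.5) {
  stopifnot(all(c("patient_id", "dotatate_scanned") %in% names(patients)))
  if (nrow(patients) == 0L) stop("empty cohort: no patients")
  les_split <- split(lesions, factor(lesions$patient_id, levels = patients$patient_id))
  rows <- lapply(seq_len(nrow(patients)), function(i) {
    pid <- patients$patient_id[i]
    ds <- isTRUE(patients$dotatate_scanned[i])
    les <- les_split[[pid]]
    if (is.null(les)) les <- lesions[0, , drop = FALSE]
    combo <- combination_label(les, ds, threshold)
    data.frame(
      patient_id = pid,
      dotatate_scanned = ds,
      n_lesions = nrow(les),
      combination = combo,
      n_phenotypes = if (combo == "all-negative") 0L
                     else length(strsplit(combo, "|", fixed = TRUE)[[1]]),
      has_fdg_pos_psma_neg = needs_dotatate(les, threshold),
      iih = flag_iih(les, ds, threshold),
      ned = if (ds) flag_ned(les, TRUE, threshold) else NA,
      psma_rpt_eligible = psma_rpt_eligible(les, threshold),
      dotatate_rpt_eligible = if (ds) dotatate_rpt_eligible(les, TRUE, threshold) else NA,
      stringsAsFactors = FALSE
    )
  })
  profiles <- do.call(rbind, rows)
  for (col in c("os_months", "event"))
    if (col %in% names(patients))
      profiles[[col]] <- patients[[col]][match(profiles$patient_id, patients$patient_id)]
  profiles
}

#' Count distinct phenotype combinations in a cohort
#'
#' Number of distinct patient-level combinations among patients with at
#' least one phenotype-positive lesion (the all-negative class is not a
#' combination).
#'
#' @param profiles output of [build_profiles()].
#' @return Integer count.
#' @export
count_phenotype_combinations <- function(profiles) {
  length(unique(profiles$combination[profiles$combination != "all-negative"]))
}
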