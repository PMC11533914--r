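#' Pipeline configuration
#'
#' Bundles every tunable parameter of the analysis chain.  The defaults are
#' the study's stated parameters: 1.5x liver-SUVmean threshold, 1 cm^3
#' minimum lesion volume, 3 cm liver reference sphere, 1 cm^3 SUVpeak
#' sphere, 26-connectivity, up to 10 lesions per compartment-by-phenotype
#' cell, 95% confidence level, and a 13-month censoring horizon.
#'
#' @param threshold_multiplier segmentation threshold as a multiple of the
#'   liver SUVmean; also the positivity cutoff on the SUVpeak ratio.
#' @param min_volume_cm3 minimum retained VOI volume.
#' @param liver_sphere_diameter_mm liver reference sphere diameter.
#' @param peak_sphere_volume_cm3 SUVpeak sphere volume.
#' @param connectivity voxel connectivity (6, 18 or 26).
#' @param overlap_cutoff maximum tolerated physiologic-mask overlap.
#' @param cap_per_cell lesion cap per compartment x phenotype cell.
#' @param conf_level confidence level for all intervals.
#' @param censor_horizon_months administrative censoring horizon.
#' @param seed integer seed echoed in outputs.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(threshold_multiplier = 1.5,
                            min_volume_cm3 = 1.0,
                            liver_sphere_diameter_mm = 30,
                            peak_sphere_volume_cm3 = 1.0,
                            connectivity = 26,
                            overlap_cutoff = 0.5,
                            cap_per_cell = 10,
                            conf_level = 0.95,
                            censor_horizon_months = 13,
                            seed = 1L) {
  structure(list(
    threshold_multiplier = threshold_multiplier,
    min_volume_cm3 = min_volume_cm3,
    liver_sphere_diameter_mm = liver_sphere_diameter_mm,
    peak_sphere_volume_cm3 = peak_sphere_volume_cm3,
    connectivity = connectivity,
    overlap_cutoff = overlap_cutoff,
    cap_per_cell = cap_per_cell,
    conf_level = conf_level,
    censor_horizon_months = censor_horizon_months,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Quantify one patient's multi-tracer volumes into a lesion table
#'
#' Runs the full image-quantitation chain on co-registered SUV volumes:
#' per-tracer liver reference, threshold segmentation into connected VOIs,
#' sub-centimeter filtering, physiologic-mask exclusion, cross-tracer
#' merging into lesions with per-tracer SUVpeak ratios, and per-cell lesion
#' capping.
#'
#' @param volumes named list of [tracer_volume()] objects (FDG and PSMA
#'   required; DOTATATE optional).
#' @param liver_center liver reference sphere center, mm.
#' @param patient_id patient identifier for the output table.
#' @param exclusion_mask optional logical array of physiologic uptake.
#' @param compartment_map optional character array of compartment labels.
#' @param config a [pipeline_config()].
#' @return Lesion table (see [lesion_table()]); zero rows when nothing
#'   survives filtering.
#' @export
quantify_patient <- function(volumes, liver_center, patient_id = "P1",
                             exclusion_mask = NULL, compartment_map = NULL,
                             config = pipeline_config()) {
  if (!all(c("FDG", "PSMA") %in% names(volumes)))
    stop("patient ", patient_id, " is missing a required tracer volume (FDG, PSMA)")
  liver <- vapply(volumes, measure_liver_reference, numeric(1),
                  center = liver_center,
                  diameter_mm = config$liver_sphere_diameter_mm)
  vois <- lapply(names(volumes), function(tr) {
    v <- segment_vois(volumes[[tr]], liver[tr],
                      threshold_multiplier = config$threshold_multiplier,
                      connectivity = config$connectivity)
    v <- filter_small_vois(v, config$min_volume_cm3)
    if (!is.null(exclusion_mask))
      v <- exclude_physiologic(v, exclusion_mask,
                               dims = dim(volumes[[tr]]$suv),
                               overlap_cutoff = config$overlap_cutoff)
    v
  })
  names(vois) <- names(volumes)
  lesions <- merge_lesions(vois, volumes, compartment_map,
                           liver_suv_means = liver,
                           sphere_volume_cm3 = config$peak_sphere_volume_cm3)
  lesions <- lesions[vapply(lesions, function(l)
    l$volume_cm3 >= config$min_volume_cm3, logical(1))]
  tab <- lesion_table(lesions, patient_id)
  cap_lesions(tab, cap = config$cap_per_cell,
              threshold = config$threshold_multiplier)
}

#' Run the end-to-end cohort analysis
#'
#' Mirrors the study's stepwise design on a cohort given either as lesion
#' tables (`cohort`) or as per-patient volume inputs (`volume_inputs`):
#' quantitation (volume path only), conditional DOTATATE gating (DOTATATE
#' ratios are interpreted only for scanned patients), per-patient
#' phenotyping, endpoint prevalences with exact CIs, and the three
#' phenotype-stratified survival contrasts.  Patients missing a required
#' tracer are collected in an exclusions report rather than crashing the
#' run.
#'
#' @param cohort a `tripet_cohort` (lists `patients` and `lesions`), e.g.
#'   from [generate_replica_cohort()] or [read_cohort()].
#' @param volume_inputs alternatively, a named list (by patient id) of
#'   lists with elements `volumes`, `liver_center`, and optionally
#'   `exclusion_mask`, `compartment_map`, `dotatate_scanned`; requires
#'   `survival_records` for the survival stage.
#' @param survival_records optional data.frame (`patient_id`, `os_months`,
#'   `event`) overriding/supplying survival data.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, `profiles.csv`,
#'   `endpoints.csv`, `endpoints.json`, `survival.json` and per-group KM
#'   curve CSVs are written there.
#' @return List of class `tripet_result` with `profiles`, `endpoints`,
#'   `n_combinations`, `survival` (per-contrast results), `exclusions`,
#'   `config`.
#' @export
run_pipeline <- function(cohort = NULL, volume_inputs = NULL,
                         survival_records = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  exclusions <- data.frame(patient_id = character(0), reason = character(0),
                           stringsAsFactors = FALSE)
  if (is.null(cohort) && is.null(volume_inputs))
    stop("either 'cohort' or 'volume_inputs' must be supplied")

  if (!is.null(volume_inputs)) {
    if (length(volume_inputs) == 0L) stop("empty cohort: no volume inputs")
    tabs <- list()
    pats <- list()
    for (pid in names(volume_inputs)) {
      vi <- volume_inputs[[pid]]
      tab <- tryCatch(
        quantify_patient(vi$volumes, vi$liver_center, pid,
                         vi$exclusion_mask, vi$compartment_map, config),
        error = function(e) e)
      if (inherits(tab, "error")) {
        exclusions <- rbind(exclusions,
                            data.frame(patient_id = pid,
                                       reason = conditionMessage(tab)))
        next
      }
      tabs[[pid]] <- tab
      pats[[pid]] <- data.frame(
        patient_id = pid,
        dotatate_scanned = isTRUE(vi$dotatate_scanned) ||
          "DOTATATE" %in% names(vi$volumes),
        stringsAsFactors = FALSE)
    }
    if (length(tabs) == 0L) stop("no patient could be quantified")
    cohort <- list(patients = do.call(rbind, pats),
                   lesions = do.call(rbind, tabs))
  }

  if (nrow(cohort$patients) == 0L) stop("empty cohort: no patients")
  patients <- cohort$patients
  lesions <- cohort$lesions

  # lesion-table path: a patient whose rows lack a required ratio is
  # excluded, mirroring the study's attrition accounting
  bad <- unique(lesions$patient_id[is.na(lesions$ratio_fdg) |
                                     is.na(lesions$ratio_psma)])
  scanned_ids <- patients$patient_id[patients$dotatate_scanned]
  bad_d <- unique(lesions$patient_id[lesions$patient_id %in% scanned_ids &
                                       is.na(lesions$ratio_dotatate)])
  bad <- union(bad, bad_d)
  if (length(bad)) {
    exclusions <- rbind(exclusions,
                        data.frame(patient_id = bad,
                                   reason = "missing ratio for a required tracer"))
    patients <- patients[!patients$patient_id %in% bad, , drop = FALSE]
    lesions <- lesions[!lesions$patient_id %in% bad, , drop = FALSE]
    if (nrow(patients) == 0L) stop("all patients excluded")
  }

  if (!is.null(survival_records)) {
    patients$os_months <- survival_records$os_months[
      match(patients$patient_id, survival_records$patient_id)]
    patients$event <- survival_records$event[
      match(patients$patient_id, survival_records$patient_id)]
  }

  # conditional-DOTATATE gating: ratios are interpreted only for scanned
  # patients (build_profiles enforces this); a scanned flag without the
  # trigger lesion is tolerated as data
  lesions$ratio_dotatate[!(lesions$patient_id %in% scanned_ids)] <- NA_real_

  profiles <- build_profiles(lesions, patients,
                             threshold = config$threshold_multiplier)
  endpoints <- endpoint_summary(profiles, level = config$conf_level)
  n_comb <- count_phenotype_combinations(profiles)

  surv <- NULL
  if (all(c("os_months", "event") %in% names(profiles)) &&
      !anyNA(profiles$os_months)) {
    surv <- list()
    for (s in c("iih", "fdg_pos_psma_neg", "dotatate_pos")) {
      res <- tryCatch(survival_contrast(profiles, s), error = function(e) NULL)
      if (!is.null(res)) surv[[s]] <- res
    }
  }

  result <- structure(
    list(profiles = profiles, endpoints = endpoints, n_combinations = n_comb,
         survival = surv, exclusions = exclusions, config = config),
    class = "tripet_result")
  if (!is.null(out_dir)) write_result(result, out_dir)
  result
}

#' @export
print.tripet_result <- function(x, ...) {
  cat(sprintf("<tripet_result> %d patients, %d phenotype combinations\n",
              nrow(x$profiles), x$n_combinations))
  print(x$endpoints, row.names = FALSE)
  if (!is.null(x$survival)) {
    for (s in names(x$survival)) {
      r <- x$survival[[s]]
      cat(sprintf("  %s: HR %.2f (%.2f-%.2f), log-rank p %.4g\n",
                  s, r$hr, r$hr_ci[1], r$hr_ci[2], r$logrank_p))
    }
  }
  if (nrow(x$exclusions))
    cat(sprintf("  %d patient(s) excluded\n", nrow(x$exclusions)))
  invisible(x)
}

# Write all pipeline artifacts to a directory.
write_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$profiles, file.path(out_dir, "profiles.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(result$endpoints, file.path(out_dir, "endpoints.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(endpoints = result$endpoints,
         n_combinations = result$n_combinations,
         config = unclass(result$config)),
    file.path(out_dir, "endpoints.json"),
    auto_unbox = TRUE, digits = NA)
  if (!is.null(result$survival)) {
    jsonlite::write_json(
      lapply(result$survival, function(r)
        list(stratify = r$stratify, n = r$n, groups = r$groups,
             median = as.list(r$median),
             logrank_p = r$logrank_p, hr = r$hr,
             hr_ci = r$hr_ci, estimable = r$estimable)),
      file.path(out_dir, "survival.json"),
      auto_unbox = TRUE, digits = NA, na = "null")
  }
  if (nrow(result$exclusions))
    utils::write.csv(result$exclusions, file.path(out_dir, "exclusions.csv"),
                     row.names = FALSE)
  invisible(out_dir)
}
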