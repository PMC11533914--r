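#' Measure the liver reference SUVmean
#'
#' Mean SUV over the voxels whose centers lie within a spherical volume of
#' interest (3 cm diameter by default) placed in healthy liver.  The result
#' is the per-tracer denominator of every SUVpeak ratio and, multiplied by
#' the threshold factor (1.5), the segmentation threshold.
#'
#' @param volume a [tracer_volume()].
#' @param center sphere center in mm (world coordinates).
#' @param diameter_mm sphere diameter in mm (default 30).
#' @return SUVmean (dimensionless scalar).
#' @export
measure_liver_reference <- function(volume, center, diameter_mm = 30) {
  stopifnot(inherits(volume, "tracer_volume"))
  dims <- dim(volume$suv)
  r <- diameter_mm / 2
  extent <- (dims - 1) * volume$voxel_spacing
  if (any(center - r < 0) || any(center + r > extent))
    stop("liver reference sphere extends outside the grid")
  idx <- sphere_voxels(center, r, dims, volume$voxel_spacing)
  if (nrow(idx) == 0L) stop("liver reference sphere contains no voxel centers")
  mean(volume$suv[linear_index(idx, dims)])
}

# Label 3D connected components of a logical mask.  Foreground voxels become
# graph vertices; edges join voxels adjacent under the requested
# connectivity (6 faces, 18 faces+edges, 26 faces+edges+corners).  Returns
# an integer vector of component labels parallel to which(mask).
label_components <- function(mask, connectivity = 26) {
  stopifnot(connectivity %in% c(6, 18, 26))
  dims <- dim(mask)
  fg <- which(mask)
  n <- length(fg)
  if (n == 0L) return(list(voxels = fg, labels = integer(0)))
  id <- array(0L, dims)
  id[fg] <- seq_len(n)

  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ord <- apply(offs, 1, function(o) sum(o * c(1, 3, 9)))  # keep one of each +/- pair
  offs <- offs[ord > 0, , drop = FALSE]
  nz <- rowSums(abs(offs))
  offs <- switch(as.character(connectivity),
                 "6"  = offs[nz == 1, , drop = FALSE],
                 "18" = offs[nz <= 2, , drop = FALSE],
                 "26" = offs)

  rng <- function(d, o) if (o >= 0) seq_len(d - o) else seq(1 - o, d)
  edges <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    o <- offs[k, ]
    a <- id[rng(dims[1], o[1]), rng(dims[2], o[2]), rng(dims[3], o[3]), drop = FALSE]
    b <- id[rng(dims[1], -o[1]), rng(dims[2], -o[2]), rng(dims[3], -o[3]), drop = FALSE]
    keep <- a > 0L & b > 0L
    edges[[k]] <- rbind(a[keep], b[keep])
  }
  em <- do.call(cbind, edges)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(em)) g <- igraph::add_edges(g, as.vector(em))
  list(voxels = fg, labels = igraph::components(g)$membership)
}

#' Segment volumes of interest by liver-referenced thresholding
#'
#' Applies the study threshold (`threshold_multiplier` times the liver
#' SUVmean, default 1.5x) to the SUV volume and groups supra-threshold
#' voxels (SUV >= threshold) into connected components, one VOI per
#' component.  26-connectivity ("contiguous uptake" including diagonal
#' touches) is the default.
#'
#' @param volume a [tracer_volume()].
#' @param liver_suv_mean liver reference SUVmean, > 0.
#' @param threshold_multiplier threshold factor (default 1.5).
#' @param connectivity 6, 18 or 26 (default 26).
#' @return List of VOIs; each is a list with `tracer`, `voxels`
#'   (n x 3 matrix of 1-based indices), `volume_cm3`.
#' @export
segment_vois <- function(volume, liver_suv_mean, threshold_multiplier = 1.5,
                         connectivity = 26) {
  stopifnot(inherits(volume, "tracer_volume"))
  if (!is.finite(liver_suv_mean) || liver_suv_mean <= 0)
    stop("liver_suv_mean must be > 0")
  thr <- threshold_multiplier * liver_suv_mean
  dims <- dim(volume$suv)
  lab <- label_components(volume$suv >= thr, connectivity)
  if (length(lab$labels) == 0L) return(list())
  vv <- voxel_volume_cm3(volume$voxel_spacing)
  comp <- split(lab$voxels, lab$labels)
  lapply(unname(comp), function(lin) {
    list(tracer = volume$tracer,
         voxels = array_index(lin, dims),
         volume_cm3 = length(lin) * vv)
  })
}

#' Discard sub-centimeter VOIs
#'
#' VOIs smaller than `min_volume_cm3` (strictly; exactly 1.00 cm^3 is kept)
#' are removed from the analysis.
#'
#' @param vois list of VOIs from [segment_vois()].
#' @param min_volume_cm3 minimum retained volume (default 1).
#' @return Filtered VOI list.
#' @export
filter_small_vois <- function(vois, min_volume_cm3 = 1.0) {
  keep <- vapply(vois, function(v) v$volume_cm3 >= min_volume_cm3, logical(1))
  vois[keep]
}

#' Exclude physiologic-uptake VOIs by mask overlap
#'
#' Drops any VOI whose fractional overlap with a physiologic/benign-uptake
#' exclusion mask exceeds `overlap_cutoff` (a VOI exactly at the cutoff is
#' retained).
#'
#' @param vois list of VOIs.
#' @param exclusion_mask logical 3D array on the same grid.
#' @param dims grid dimensions the VOIs were segmented on.
#' @param overlap_cutoff maximum tolerated overlap fraction (default 0.5).
#' @return Filtered VOI list.
#' @export
exclude_physiologic <- function(vois, exclusion_mask, dims = dim(exclusion_mask),
                                overlap_cutoff = 0.5) {
  if (!identical(as.integer(dim(exclusion_mask)), as.integer(dims)))
    stop("exclusion mask grid does not match the volume grid")
  keep <- vapply(vois, function(v) {
    frac <- mean(exclusion_mask[linear_index(v$voxels, dims)])
    frac <= overlap_cutoff
  }, logical(1))
  vois[keep]
}

#' Measure SUVpeak over a voxel set
#'
#' PERCIST-style peak: the maximum, over spheres of `sphere_volume_cm3`
#' (default 1 cm^3, radius ~6.2 mm) centered on each voxel of the set, of
#' the mean SUV of all in-grid voxels whose centers fall inside the sphere.
#' Background voxels inside the sphere contribute to the mean, so the peak
#' of a small hot lesion is pulled below its hottest voxel.
#'
#' @param volume a [tracer_volume()].
#' @param voxels n x 3 matrix of 1-based voxel indices (the lesion).
#' @param sphere_volume_cm3 sphere volume (default 1).
#' @return SUVpeak (dimensionless scalar).
#' @export
measure_suv_peak <- function(volume, voxels, sphere_volume_cm3 = 1.0) {
  stopifnot(inherits(volume, "tracer_volume"))
  voxels <- matrix(as.integer(voxels), ncol = 3)
  if (nrow(voxels) == 0L) stop("lesion voxel set is empty")
  dims <- dim(volume$suv)
  r <- sphere_radius_mm(sphere_volume_cm3)
  offs <- sphere_offsets(r, volume$voxel_spacing)
  n <- nrow(voxels)
  acc <- numeric(n)
  cnt <- numeric(n)
  for (k in seq_len(nrow(offs))) {
    idx <- sweep(voxels, 2L, offs[k, ], "+")
    ok <- in_grid(idx, dims)
    if (!any(ok)) next
    acc[ok] <- acc[ok] + volume$suv[linear_index(idx[ok, , drop = FALSE], dims)]
    cnt[ok] <- cnt[ok] + 1
  }
  max(acc / cnt)
}

#' Merge per-tracer VOIs into multi-tracer lesions
#'
#' VOIs from different tracers whose voxel sets share at least one voxel
#' (transitively closed across tracers) are merged into a single lesion
#' whose footprint is the voxel union.  Each tracer's SUVpeak is then
#' measured on that union, so a lesion seen on one tracer still gets a
#' (typically sub-threshold) measurement on the others -- the basis of
#' discordant phenotypes such as FDG+/PSMA-.  The compartment is assigned
#' by majority vote of the union voxels over `compartment_map` (ties broken
#' alphabetically; voxels labelled `"none"` are ignored when any labelled
#' voxel exists).
#'
#' @param vois_by_tracer named list, tracer -> list of VOIs (all on one grid).
#' @param volumes named list of [tracer_volume()] objects, one per tracer to
#'   measure (may include tracers with no VOIs).
#' @param compartment_map character 3D array of compartment labels, or
#'   `NULL` for all-`"other"`.
#' @param liver_suv_means named numeric, tracer -> liver SUVmean; when
#'   supplied, SUVpeak ratios are computed.
#' @param sphere_volume_cm3 SUVpeak sphere volume (default 1).
#' @return List of lesions; each has `lesion_id`, `compartment`, `voxels`,
#'   `volume_cm3`, `suv_peak_by_tracer`, `ratio_by_tracer`.
#' @export
merge_lesions <- function(vois_by_tracer, volumes, compartment_map = NULL,
                          liver_suv_means = NULL, sphere_volume_cm3 = 1.0) {
  flat <- list()
  for (tr in names(vois_by_tracer))
    flat <- c(flat, vois_by_tracer[[tr]])
  if (length(flat) == 0L) return(list())
  dims <- dim(volumes[[1]]$suv)
  spacing <- volumes[[1]]$voxel_spacing

  lins <- lapply(flat, function(v) linear_index(v$voxels, dims))
  # edges between VOIs sharing a voxel
  memb <- data.frame(vox = unlist(lins),
                     voi = rep.int(seq_along(flat), lengths(lins)))
  g <- igraph::make_empty_graph(n = length(flat), directed = FALSE)
  shared <- memb[memb$vox %in% memb$vox[duplicated(memb$vox)], ]
  if (nrow(shared)) {
    edges <- do.call(rbind, lapply(split(shared$voi, shared$vox), function(v) {
      v <- sort(unique(v))
      if (length(v) < 2) NULL else cbind(v[1], v[-1])
    }))
    if (!is.null(edges) && nrow(edges))
      g <- igraph::add_edges(g, as.vector(t(edges)))
  }
  groups <- igraph::components(g)$membership

  tracers <- names(volumes)
  lesions <- lapply(sort(unique(groups)), function(grp) {
    lin <- sort(unique(unlist(lins[groups == grp])))
    vox <- array_index(lin, dims)
    comp <- "other"
    if (!is.null(compartment_map)) {
      labs <- compartment_map[lin]
      labs <- labs[labs != "none"]
      if (length(labs)) {
        tab <- table(labs)
        comp <- sort(names(tab)[tab == max(tab)])[1]
      }
    }
    peaks <- vapply(tracers, function(tr)
      measure_suv_peak(volumes[[tr]], vox, sphere_volume_cm3), numeric(1))
    ratios <- if (is.null(liver_suv_means)) NULL else peaks / liver_suv_means[tracers]
    list(lesion_id = grp, compartment = comp, voxels = vox,
         volume_cm3 = length(lin) * voxel_volume_cm3(spacing),
         suv_peak_by_tracer = peaks, ratio_by_tracer = ratios)
  })
  # stable ids ordered by first voxel
  ord <- order(vapply(lesions, function(l) linear_index(l$voxels, dims)[1], numeric(1)))
  lesions <- lesions[ord]
  for (i in seq_along(lesions)) lesions[[i]]$lesion_id <- i
  lesions
}

#' Tabulate merged lesions
#'
#' Flattens the lesion list produced by [merge_lesions()] into the standard
#' lesion table used by the phenotyping stage (one row per lesion, one ratio
#' column per tracer).
#'
#' @param lesions list from [merge_lesions()] (ratios present).
#' @param patient_id patient identifier to attach.
#' @return data.frame with columns `patient_id`, `lesion_id`, `compartment`,
#'   `volume_cm3`, `ratio_fdg`, `ratio_psma`, `ratio_dotatate`.
#' @export
lesion_table <- function(lesions, patient_id = "P1") {
  get_ratio <- function(l, tr) {
    r <- l$ratio_by_tracer
    if (is.null(r) || !(tr %in% names(r))) NA_real_ else unname(r[tr])
  }
  data.frame(
    patient_id = rep(patient_id, length(lesions)),
    lesion_id = vapply(lesions, function(l) l$lesion_id, numeric(1)),
    compartment = vapply(lesions, function(l) l$compartment, character(1)),
    volume_cm3 = vapply(lesions, function(l) l$volume_cm3, numeric(1)),
    ratio_fdg = vapply(lesions, get_ratio, numeric(1), tr = "FDG"),
    ratio_psma = vapply(lesions, get_ratio, numeric(1), tr = "PSMA"),
    ratio_dotatate = vapply(lesions, get_ratio, numeric(1), tr = "DOTATATE"),
    stringsAsFactors = FALSE
  )
}

#' Cap recorded lesions per compartment and dual-tracer phenotype
#'
#' Within each (compartment x FDG/PSMA phenotype) cell, at most `cap`
#' lesions are recorded, keeping the hottest ones.  With 4 compartments and
#' the 3 positive dual-tracer phenotypes (FDG+/PSMA-, FDG+/PSMA+,
#' FDG-/PSMA+) this yields the study budget of up to 120 lesions per
#' patient.  Hotness is the maximum SUVpeak ratio over the tracers positive
#' for the lesion (falling back to the maximum ratio over all measured
#' tracers for all-negative lesions); ties break toward the larger volume,
#' then the smaller lesion id.  Operates per patient when a `patient_id`
#' column is present.  Idempotent.
#'
#' @param lesions lesion table (see [lesion_table()]).
#' @param cap maximum lesions per cell (default 10).
#' @param threshold positivity threshold on the SUVpeak ratio (default 1.5).
#' @return The capped lesion table, original row order preserved.
#' @export
cap_lesions <- function(lesions, cap = 10, threshold = 1.5) {
  if (nrow(lesions) == 0L) return(lesions)
  fpos <- !is.na(lesions$ratio_fdg) & lesions$ratio_fdg >= threshold
  ppos <- !is.na(lesions$ratio_psma) & lesions$ratio_psma >= threshold
  fp_label <- paste0(ifelse(fpos, "F+", "F-"), ifelse(ppos, "P+", "P-"))
  rat <- as.matrix(lesions[, c("ratio_fdg", "ratio_psma", "ratio_dotatate")])
  pos <- !is.na(rat) & rat >= threshold
  hot <- vapply(seq_len(nrow(rat)), function(i) {
    r <- rat[i, ]
    if (any(pos[i, ])) max(r[pos[i, ]]) else max(r, na.rm = TRUE)
  }, numeric(1))
  pid <- if ("patient_id" %in% names(lesions)) lesions$patient_id else ""
  cell <- paste(pid, lesions$compartment, fp_label, sep = "\r")
  ord <- order(cell, -hot, -lesions$volume_cm3, lesions$lesion_id)
  rank_in_cell <- stats::ave(seq_along(ord), cell[ord], FUN = seq_along)
  keep_rows <- ord[rank_in_cell <= cap]
  lesions[sort(keep_rows), , drop = FALSE]
}
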