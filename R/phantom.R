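#' Specify a synthetic lesion
#'
#' Describes one spherical lesion to plant in a phantom: its position and
#' size in mm, the anatomical compartment it belongs to, and the SUV it
#' carries on each tracer.  The intended phenotype (sign per tracer) is
#' carried along for ground-truth bookkeeping; it is not used to render the
#' volume.
#'
#' @param center numeric length-3, lesion center in mm (world coordinates).
#' @param radius sphere radius in mm, > 0.
#' @param suv_by_tracer named numeric vector, tracer -> SUV inside the
#'   sphere (e.g. `c(FDG = 4, PSMA = 1)`).
#' @param compartment one of `"nodes"`, `"bones"`, `"liver"`, `"other"`.
#' @param intended_phenotype optional named logical vector of intended
#'   per-tracer positivity, for bookkeeping.
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(center, radius, suv_by_tracer,
                        compartment = c("other", "nodes", "bones", "liver"),
                        intended_phenotype = NULL) {
  compartment <- match.arg(compartment)
  if (radius <= 0) stop("lesion radius must be > 0")
  if (is.null(names(suv_by_tracer)) || any(!nzchar(names(suv_by_tracer))))
    stop("suv_by_tracer must be a named vector (tracer -> SUV)")
  structure(
    list(center = as.numeric(center), radius = radius,
         suv_by_tracer = suv_by_tracer, compartment = compartment,
         intended_phenotype = intended_phenotype),
    class = "lesion_spec"
  )
}

#' Specify a multi-tracer phantom
#'
#' A phantom is a uniform background with a spherical liver reference region
#' and a list of planted spherical lesions, optionally degraded with
#' additive Gaussian noise.  The liver sphere supplies the liver SUVmean
#' denominator used throughout quantitation.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param voxel_spacing numeric length-3 (or scalar), mm per axis.
#' @param background_suv background SUV (dimensionless).
#' @param liver_center liver sphere center, mm.
#' @param liver_radius liver sphere radius, mm.
#' @param liver_suv SUV inside the liver sphere.
#' @param lesions list of [lesion_spec()] objects.
#' @param noise_sd standard deviation of additive Gaussian noise, in SUV
#'   units; 0 disables noise.
#' @param seed integer seed making the noise reproducible.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(48, 48, 48), voxel_spacing = 4,
                         background_suv = 0.5,
                         liver_center = NULL, liver_radius = 25,
                         liver_suv = 2.0, lesions = list(),
                         noise_sd = 0, seed = 1L) {
  grid_shape <- as.integer(rep_len(grid_shape, 3L))
  voxel_spacing <- rep_len(as.numeric(voxel_spacing), 3L)
  if (any(voxel_spacing <= 0)) stop("voxel_spacing must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  extent <- (grid_shape - 1) * voxel_spacing
  if (is.null(liver_center)) liver_center <- extent / 2
  liver_center <- as.numeric(liver_center)
  if (any(liver_center - liver_radius < 0) ||
      any(liver_center + liver_radius > extent))
    stop("liver sphere must lie fully inside the grid")
  for (i in seq_along(lesions)) {
    ls <- lesions[[i]]
    if (!inherits(ls, "lesion_spec")) stop("lesions must be lesion_spec objects")
    if (any(ls$center - ls$radius < 0) || any(ls$center + ls$radius > extent))
      stop(sprintf("lesion %d extends outside the grid", i))
  }
  structure(
    list(grid_shape = grid_shape, voxel_spacing = voxel_spacing,
         background_suv = background_suv, liver_center = liver_center,
         liver_radius = liver_radius, liver_suv = liver_suv,
         lesions = lesions, noise_sd = noise_sd, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Generate a multi-tracer SUV phantom
#'
#' Renders one [tracer_volume()] per tracer named in any lesion's
#' `suv_by_tracer` (at minimum FDG and PSMA).  Voxels whose centers fall
#' inside a lesion sphere carry that lesion's SUV for that tracer, summed
#' over overlapping lesions; the liver sphere carries `liver_suv`; all other
#' voxels carry `background_suv`.  When `noise_sd > 0`, independent Gaussian
#' noise is added and the result clamped at zero (SUV cannot be negative).
#' Fully deterministic for a fixed `seed`.
#'
#' @param spec a [phantom_spec()].
#' @param tracers tracer names to render; defaults to the union of FDG,
#'   PSMA and every tracer named by a lesion.
#' @return Named list of [tracer_volume()] objects, plus attributes
#'   `compartment_map` (character array of compartment labels, `"none"`
#'   outside lesions) and `liver_center`.
#' @export
generate_phantom <- function(spec, tracers = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$grid_shape
  sp <- spec$voxel_spacing
  if (is.null(tracers)) {
    tracers <- unique(c("FDG", "PSMA",
                        unlist(lapply(spec$lesions, function(l) names(l$suv_by_tracer)))))
  }
  liver_idx <- sphere_voxels(spec$liver_center, spec$liver_radius, dims, sp)
  liver_lin <- linear_index(liver_idx, dims)

  lesion_lin <- lapply(spec$lesions, function(l)
    linear_index(sphere_voxels(l$center, l$radius, dims, sp), dims))

  compartment_map <- array("none", dims)
  compartment_map[liver_lin] <- "liver"
  for (i in seq_along(spec$lesions))
    compartment_map[lesion_lin[[i]]] <- spec$lesions[[i]]$compartment

  set.seed(spec$seed)
  vols <- lapply(tracers, function(tr) {
    suv <- array(spec$background_suv, dims)
    suv[liver_lin] <- spec$liver_suv
    contrib <- array(0, dims)
    for (i in seq_along(spec$lesions)) {
      val <- spec$lesions[[i]]$suv_by_tracer[tr]
      if (!is.na(val))
        contrib[lesion_lin[[i]]] <- contrib[lesion_lin[[i]]] + val
    }
    suv[contrib > 0] <- contrib[contrib > 0]
    if (spec$noise_sd > 0)
      suv <- pmax(suv + stats::rnorm(length(suv), sd = spec$noise_sd), 0)
    tracer_volume(suv, sp, tr)
  })
  names(vols) <- tracers
  attr(vols, "compartment_map") <- compartment_map
  attr(vols, "liver_center") <- spec$liver_center
  vols
}

#' Write phantom volumes to a directory as NIfTI files
#'
#' @param vols result of [generate_phantom()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_phantom <- function(vols, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(vols), function(tr) {
    p <- file.path(dir, paste0(tolower(tr), ".nii.gz"))
    write_tracer_volume(vols[[tr]], p)
    p
  }, character(1))
  invisible(paths)
}
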