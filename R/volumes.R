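#' Tracer SUV volume
#'
#' A `tracer_volume` holds one tracer's 3D standardized-uptake-value (SUV)
#' image together with its voxel geometry.  Voxel indices are 1-based in R;
#' the world coordinate (mm) of voxel `(i, j, k)` is
#' `(c(i, j, k) - 1) * voxel_spacing`, i.e. the first voxel center sits at
#' the origin.  All SUV values must be non-negative and spacing strictly
#' positive.
#'
#' @param suv 3D numeric array of SUV values (dimensionless).
#' @param voxel_spacing numeric length-3, voxel edge lengths in mm.
#' @param tracer tracer label, one of `"FDG"`, `"PSMA"`, `"DOTATATE"`.
#' @return An object of class `tracer_volume`.
#' @export
tracer_volume <- function(suv, voxel_spacing, tracer = c("FDG", "PSMA", "DOTATATE")) {
  tracer <- match.arg(tracer)
  suv <- as.array(suv)
  if (length(dim(suv)) != 3L)
    stop("'suv' must be a 3D array")
  if (anyNA(suv) || any(suv < 0))
    stop("SUV values must be non-negative and non-missing")
  voxel_spacing <- rep_len(as.numeric(voxel_spacing), 3L)
  if (any(voxel_spacing <= 0))
    stop("voxel_spacing must be > 0")
  structure(
    list(tracer = tracer, suv = suv, voxel_spacing = voxel_spacing),
    class = "tracer_volume"
  )
}

#' @export
print.tracer_volume <- function(x, ...) {
  cat(sprintf("<tracer_volume> %s  %s voxels @ %s mm  SUV range [%.2f, %.2f]\n",
              x$tracer, paste(dim(x$suv), collapse = "x"),
              paste(format(x$voxel_spacing), collapse = "x"),
              min(x$suv), max(x$suv)))
  invisible(x)
}

# voxel volume in cm^3 (spacing is mm)
voxel_volume_cm3 <- function(voxel_spacing) prod(voxel_spacing) / 1000

# integer offsets (n x 3) whose voxel-center displacement lies within
# radius_mm of the center voxel
sphere_offsets <- function(radius_mm, voxel_spacing) {
  r <- ceiling(radius_mm / voxel_spacing)
  g <- expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3])
  d2 <- (g$dx * voxel_spacing[1])^2 + (g$dy * voxel_spacing[2])^2 +
    (g$dz * voxel_spacing[3])^2
  as.matrix(g[d2 <= radius_mm^2 + 1e-9, , drop = FALSE])
}

# radius (mm) of a sphere with the given volume in cm^3
sphere_radius_mm <- function(volume_cm3) 10 * (3 * volume_cm3 / (4 * pi))^(1 / 3)

# logical: are the 1-based voxel indices (n x 3 matrix) inside the grid?
in_grid <- function(idx, dims) {
  idx[, 1] >= 1L & idx[, 1] <= dims[1] &
    idx[, 2] >= 1L & idx[, 2] <= dims[2] &
    idx[, 3] >= 1L & idx[, 3] <= dims[3]
}

# 1-based voxel indices (n x 3) of voxels whose centers lie within
# radius_mm of a world-coordinate center (mm)
sphere_voxels <- function(center_mm, radius_mm, dims, voxel_spacing) {
  ctr_idx <- round(center_mm / voxel_spacing) + 1
  off <- sphere_offsets(radius_mm + max(voxel_spacing), voxel_spacing)
  idx <- sweep(off, 2L, ctr_idx, "+")
  idx <- idx[in_grid(idx, dims), , drop = FALSE]
  pos <- sweep(idx - 1, 2L, voxel_spacing, "*")
  d2 <- (pos[, 1] - center_mm[1])^2 + (pos[, 2] - center_mm[2])^2 +
    (pos[, 3] - center_mm[3])^2
  idx[d2 <= radius_mm^2 + 1e-9, , drop = FALSE]
}

# convert n x 3 index matrix to linear indices for an array of dims
linear_index <- function(idx, dims) {
  (idx[, 3] - 1L) * dims[1] * dims[2] + (idx[, 2] - 1L) * dims[1] + idx[, 1]
}

# inverse of linear_index
array_index <- function(lin, dims) {
  lin0 <- lin - 1L
  cbind(lin0 %% dims[1] + 1L,
        (lin0 %/% dims[1]) %% dims[2] + 1L,
        lin0 %/% (dims[1] * dims[2]) + 1L)
}

#' Read and write tracer volumes as NIfTI
#'
#' Volumes are stored as SUV-valued NIfTI images whose affine is diagonal in
#' the voxel spacing (no rotation; co-registered inputs are assumed).
#'
#' @param x a [tracer_volume()].
#' @param path file path (`.nii` or `.nii.gz`).
#' @param tracer tracer label to attach on reading.
#' @return `write_tracer_volume` returns `path` invisibly;
#'   `read_tracer_volume` returns a [tracer_volume()].
#' @export
write_tracer_volume <- function(x, path) {
  stopifnot(inherits(x, "tracer_volume"))
  img <- RNifti::asNifti(x$suv)
  RNifti::pixdim(img) <- x$voxel_spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_tracer_volume
#' @export
read_tracer_volume <- function(path, tracer) {
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[seq_len(3)]
  tracer_volume(as.array(img), spacing, tracer)
}
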