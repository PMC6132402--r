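#' @useDynLib needlefinder, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang abort warn .data
#' @importFrom stats median quantile rbinom rnorm runif sd setNames
#' @importFrom utils head tail
NULL

# Axis convention used throughout: array dimension 1 = lateral, 2 = axial
# (beam/depth direction), 3 = elevational. "Coronal" planes are
# lateral-elevational planes (perpendicular to the axial axis). Voxel
# indexing is 1-based in R; the physical center of voxel (i, j, k) is
# origin_mm + (c(i, j, k) - 0.5) * voxel_size_mm.

US_AXES <- c("lateral", "axial", "elevational")

#' 3D ultrasound volume
#'
#' A scalar 3D intensity grid with isotropic voxel size. Array dimensions are
#' ordered (lateral, axial, elevational); the axial axis is the beam/depth
#' direction and coronal planes are lateral-elevational planes.
#'
#' @param intensities 3D numeric array, finite, non-negative.
#' @param voxel_size_mm Positive scalar, edge length of a voxel in mm.
#' @param origin_mm Physical position of the volume corner (mm); the center
#'   of voxel (1,1,1) sits at `origin_mm + 0.5 * voxel_size_mm`.
#' @return An object of class `us_volume`.
#' @export
us_volume <- function(intensities, voxel_size_mm, origin_mm = c(0, 0, 0)) {
  intensities <- unclass(intensities)
  if (length(dim(intensities)) != 3L)
    abort("`intensities` must be a 3D array")
  if (any(dim(intensities) < 1L)) abort("all three dimensions must be >= 1")
  if (!all(is.finite(intensities))) abort("intensities must be finite")
  if (!is.numeric(voxel_size_mm) || length(voxel_size_mm) != 1L ||
      voxel_size_mm <= 0)
    abort("`voxel_size_mm` must be a positive scalar")
  structure(
    list(intensities = intensities, voxel_size_mm = voxel_size_mm,
         origin_mm = as.numeric(origin_mm), axes = US_AXES),
    class = "us_volume")
}

#' Binary label volume aligned to a source volume
#'
#' @param labels 3D array with values in \{0, 1\}.
#' @inheritParams us_volume
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, voxel_size_mm, origin_mm = c(0, 0, 0)) {
  labels <- unclass(labels)
  if (length(dim(labels)) != 3L) abort("`labels` must be a 3D array")
  if (!all(labels %in% c(0, 1))) abort("labels must be 0 or 1")
  storage.mode(labels) <- "integer"
  structure(
    list(labels = labels, voxel_size_mm = voxel_size_mm,
         origin_mm = as.numeric(origin_mm), axes = US_AXES),
    class = "label_volume")
}

#' Per-voxel probability volume aligned to a source volume
#'
#' @param probabilities 3D array with values in \[0, 1\].
#' @inheritParams us_volume
#' @return An object of class `prob_volume`.
#' @export
prob_volume <- function(probabilities, voxel_size_mm, origin_mm = c(0, 0, 0)) {
  probabilities <- unclass(probabilities)
  if (length(dim(probabilities)) != 3L)
    abort("`probabilities` must be a 3D array")
  if (any(probabilities < 0 | probabilities > 1, na.rm = TRUE) ||
      anyNA(probabilities))
    abort("probabilities must lie in [0, 1]")
  structure(
    list(probabilities = probabilities, voxel_size_mm = voxel_size_mm,
         origin_mm = as.numeric(origin_mm), axes = US_AXES),
    class = "prob_volume")
}

#' @export
print.us_volume <- function(x, ...) {
  cat(sprintf("<us_volume> %s voxels (lat x ax x elev), %.3g mm/voxel\n",
              paste(dim(x$intensities), collapse = " x "), x$voxel_size_mm))
  cat(sprintf("  intensity range [%.3g, %.3g]\n",
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> %s voxels, %d positive (%.4g%%)\n",
              paste(dim(x$labels), collapse = " x "), sum(x$labels),
              100 * mean(x$labels)))
  invisible(x)
}

#' @export
print.prob_volume <- function(x, ...) {
  cat(sprintf("<prob_volume> %s voxels, mean p = %.3g\n",
              paste(dim(x$probabilities), collapse = " x "),
              mean(x$probabilities)))
  invisible(x)
}

# Grid payload regardless of volume flavour.
vol_data <- function(v) {
  if (inherits(v, "us_volume")) return(v$intensities)
  if (inherits(v, "label_volume")) return(v$labels)
  if (inherits(v, "prob_volume")) return(v$probabilities)
  abort("not a volume object")
}

#' @export
dim.us_volume <- function(x) dim(x$intensities)
#' @export
dim.label_volume <- function(x) dim(x$labels)
#' @export
dim.prob_volume <- function(x) dim(x$probabilities)

#' @export
as.array.us_volume <- function(x, ...) x$intensities
#' @export
as.array.label_volume <- function(x, ...) x$labels
#' @export
as.array.prob_volume <- function(x, ...) x$probabilities

stop_if_geometry_differs <- function(a, b) {
  if (!identical(dim(vol_data(a)), dim(vol_data(b))))
    abort("volume shapes differ")
  if (abs(a$voxel_size_mm - b$voxel_size_mm) > 1e-9)
    abort("voxel sizes differ")
  invisible(TRUE)
}

#' Physical voxel-center coordinates (mm) of 1-based voxel indices
#'
#' @param v A volume object.
#' @param idx Integer matrix (n x 3) of 1-based voxel indices.
#' @return n x 3 matrix of mm coordinates.
#' @export
voxel_centers_mm <- function(v, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  sweep((idx - 0.5) * v$voxel_size_mm, 2, v$origin_mm, "+")
}

# mm coordinates -> continuous 0-based index coordinates for interpolation.
mm_to_index0 <- function(v, pts_mm) {
  sweep(pts_mm, 2, v$origin_mm, "-") / v$voxel_size_mm - 0.5
}
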