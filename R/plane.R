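#' Oriented plane in volume physical (mm) space
#'
#' @param point_mm 3-vector on the plane (mm).
#' @param normal 3-vector; must have unit norm to within 1e-6 (not
#'   normalized silently, so degenerate specs are caught).
#' @param in_plane_axes Optional 2-row matrix of orthonormal in-plane basis
#'   vectors; constructed automatically when omitted.
#' @return A `plane_spec` object.
#' @export
plane_spec <- function(point_mm, normal, in_plane_axes = NULL) {
  point_mm <- as.numeric(point_mm)
  normal <- as.numeric(normal)
  if (length(point_mm) != 3L || length(normal) != 3L)
    abort("`point_mm` and `normal` must be 3-vectors")
  if (abs(sqrt(sum(normal^2)) - 1) > 1e-6)
    abort("`normal` must be a unit vector")
  if (is.null(in_plane_axes)) {
    seed <- if (abs(normal[2]) < 0.9) c(0, 1, 0) else c(1, 0, 0)
    u <- seed - sum(seed * normal) * normal
    u <- u / sqrt(sum(u^2))
    w <- cross3(normal, u)
    in_plane_axes <- rbind(u, w)
  } else {
    in_plane_axes <- matrix(as.numeric(in_plane_axes), nrow = 2, byrow = FALSE)
    if (!isTRUE(all.equal(dim(in_plane_axes), c(2L, 3L))))
      abort("`in_plane_axes` must be a 2 x 3 matrix")
    g <- in_plane_axes %*% t(in_plane_axes)
    if (max(abs(g - diag(2))) > 1e-6)
      abort("`in_plane_axes` must be orthonormal")
    if (max(abs(in_plane_axes %*% normal)) > 1e-6)
      abort("`in_plane_axes` must be orthogonal to the normal")
  }
  structure(list(point_mm = point_mm, normal = normal,
                 in_plane_axes = in_plane_axes),
            class = "plane_spec")
}

#' @export
print.plane_spec <- function(x, ...) {
  cat(sprintf("<plane_spec> point (%s) mm, normal (%s)\n",
              paste(signif(x$point_mm, 4), collapse = ", "),
              paste(signif(x$normal, 4), collapse = ", ")))
  invisible(x)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Resample a volume on an arbitrary plane
#'
#' Samples the volume on the plane's orthonormal grid, centered on
#' `plane$point_mm`. Out-of-volume samples are zero. Interpolation is
#' trilinear; use `"nearest"` for label volumes.
#'
#' @param v A volume object.
#' @param plane A [plane_spec].
#' @param extent_mm Length-2 vector, physical extent (mm) along the two
#'   in-plane axes.
#' @param sample_step_mm Grid step (mm); defaults to the voxel size.
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @return Numeric matrix with attributes `axes_mm` (row/column sample
#'   positions, mm offsets from the plane point) and `plane`.
#' @export
extract_plane <- function(v, plane, extent_mm,
                          sample_step_mm = v$voxel_size_mm,
                          interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (!inherits(plane, "plane_spec")) abort("`plane` must be a plane_spec")
  extent_mm <- rep_len(as.numeric(extent_mm), 2L)
  # symmetric grid including u = w = 0, so the plane point is a sample
  half_n <- floor(extent_mm / 2 / sample_step_mm)
  u_pos <- seq(-half_n[1], half_n[1]) * sample_step_mm
  w_pos <- seq(-half_n[2], half_n[2]) * sample_step_mm
  grid <- expand.grid(u = u_pos, w = w_pos)
  pts_mm <- outer(grid$u, plane$in_plane_axes[1, ]) +
    outer(grid$w, plane$in_plane_axes[2, ])
  pts_mm <- sweep(pts_mm, 2, plane$point_mm, "+")
  vals <- nn_trilinear_sample(vol_data(v), mm_to_index0(v, pts_mm), 0,
                              interpolation == "nearest")
  img <- matrix(vals, nrow = length(u_pos), ncol = length(w_pos))
  attr(img, "axes_mm") <- list(u = u_pos, w = w_pos)
  attr(img, "plane") <- plane
  img
}
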