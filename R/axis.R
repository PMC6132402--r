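# Needle-axis estimation: RANSAC fitting of a fixed-diameter cylinder
# (default ~2 mm, covering the experimented needle diameters) to the
# detected voxels, tip designation from the inlier extent, and extraction
# of the in-plane needle view -- the plane containing the whole axis that
# is perpendicular to the coronal (lateral-elevational) planes.

#' RANSAC configuration for cylinder fitting
#'
#' @param cylinder_diameter_mm Cylinder model diameter, mm (default 2.0).
#' @param n_iterations Number of 2-point hypotheses (fixed, for
#'   determinism).
#' @param min_inliers Minimum consensus for a valid needle.
#' @param seed Integer seed.
#' @param refine Re-estimate the line as the principal axis of the inlier
#'   centers (total-least-squares) and recount inliers.
#' @return A `ransac_config` object.
#' @export
ransac_config <- function(cylinder_diameter_mm = 2.0, n_iterations = 1000L,
                          min_inliers = 5L, seed = 1L, refine = TRUE) {
  if (cylinder_diameter_mm <= 0) abort("diameter must be > 0")
  if (n_iterations < 1) abort("`n_iterations` must be >= 1")
  structure(as.list(environment()), class = "ransac_config")
}

# Distances of points (n x 3) to the infinite line through p0 along dir.
point_line_distance <- function(pts, p0, dir) {
  rel <- sweep(pts, 2, p0, "-")
  t_ax <- as.numeric(rel %*% dir)
  sqrt(pmax(rowSums(rel^2) - t_ax^2, 0))
}

#' Fit the needle axis to detected voxels with RANSAC
#'
#' Repeats `n_iterations` times: sample two distinct detected voxel
#' centers, form the candidate axis line, count detected voxels within
#' `cylinder_diameter_mm / 2` of it; the maximum-consensus model wins (ties
#' broken by first occurrence). With `refine = TRUE` the line is
#' re-estimated as the principal axis of the inlier centers and inliers are
#' recounted. The inlier distance is point-to-infinite-line; the finite
#' segment enters only at tip designation.
#'
#' @param detected A [label_volume] of detected voxels, or an n x 3 matrix
#'   of point coordinates in mm.
#' @param cfg A [ransac_config].
#' @param entry_hint Passed to [designate_tip()] to orient the axis.
#' @return A `needle_axis` (point_mm, direction, inlier mask, tip_mm,
#'   length_mm, n_inliers) or a `needle_not_found` result when fewer than
#'   `min_inliers` voxels support the best model (check with
#'   [is_needle_found()]).
#' @export
ransac_fit <- function(detected, cfg = ransac_config(), entry_hint = "auto") {
  if (inherits(detected, "label_volume")) {
    idx <- which(detected$labels == 1L, arr.ind = TRUE)
    pts <- voxel_centers_mm(detected, idx)
    bbox <- rbind(detected$origin_mm,
                  detected$origin_mm + dim(detected$labels) *
                    detected$voxel_size_mm)
  } else {
    pts <- matrix(as.numeric(detected), ncol = 3)
    idx <- NULL
    bbox <- rbind(apply(pts, 2, min), apply(pts, 2, max))
  }
  n <- nrow(pts)
  if (n < 2L || n < cfg$min_inliers)
    return(structure(list(reason = sprintf("only %d detected voxels", n),
                          n_points = n), class = "needle_not_found"))
  r <- cfg$cylinder_diameter_mm / 2
  best_count <- -1L
  best <- NULL
  with_seed_local(cfg$seed, {
    for (it in seq_len(cfg$n_iterations)) {
      s <- sample.int(n, 2L)
      dir <- pts[s[2], ] - pts[s[1], ]
      nd <- sqrt(sum(dir^2))
      if (nd < 1e-9) next
      dir <- dir / nd
      cnt <- sum(point_line_distance(pts, pts[s[1], ], dir) <= r)
      if (cnt > best_count) {
        best_count <- cnt
        best <- list(p0 = pts[s[1], ], dir = dir)
      }
    }
  })
  if (is.null(best) || best_count < cfg$min_inliers)
    return(structure(list(reason = sprintf(
      "best consensus %d below min_inliers %d", max(best_count, 0L),
      cfg$min_inliers), n_points = n), class = "needle_not_found"))
  inl <- point_line_distance(pts, best$p0, best$dir) <= r
  if (cfg$refine && sum(inl) >= 2L) {
    ip <- pts[inl, , drop = FALSE]
    ctr <- colMeans(ip)
    sv <- svd(sweep(ip, 2, ctr, "-"))
    dir2 <- sv$v[, 1]
    inl2 <- point_line_distance(pts, ctr, dir2) <= r
    if (sum(inl2) >= cfg$min_inliers) {
      best <- list(p0 = ctr, dir = dir2)
      inl <- inl2
    }
  }
  axis <- structure(list(point_mm = as.numeric(best$p0),
                         direction = as.numeric(best$dir),
                         inlier_mask = inl,
                         inlier_points_mm = pts[inl, , drop = FALSE],
                         inlier_indices = if (!is.null(idx))
                           idx[inl, , drop = FALSE] else NULL,
                         n_inliers = sum(inl), bbox_mm = bbox,
                         tip_mm = NULL, length_mm = NULL),
                    class = "needle_axis")
  designate_tip(axis, entry_hint)
}

#' @rdname ransac_fit
#' @param x Object returned by [ransac_fit()].
#' @export
is_needle_found <- function(x) inherits(x, "needle_axis")

#' @export
print.needle_axis <- function(x, ...) {
  cat(sprintf(
    "<needle_axis> %d inliers, direction (%s), tip (%s) mm, length %.2f mm\n",
    x$n_inliers, paste(signif(x$direction, 3), collapse = ", "),
    paste(signif(x$tip_mm, 4), collapse = ", "), x$length_mm))
  invisible(x)
}

#' @export
print.needle_not_found <- function(x, ...) {
  cat("<needle_not_found>", x$reason, "\n")
  invisible(x)
}

#' Designate the needle tip from the inlier extent
#'
#' Projects the inlier centers onto the axis; the endpoints are the extreme
#' projections. The tip is the endpoint farther from the entry face
#' (`"auto"`: the lateral/elevational volume face closest to either
#' endpoint is taken as the entry); the direction is re-oriented
#' entry-to-tip and the length is the endpoint distance.
#'
#' @param axis A `needle_axis` with >= 2 inliers.
#' @param entry_hint One of `"auto"`, `"lateral_min"`, `"lateral_max"`,
#'   `"elevational_min"`, `"elevational_max"`.
#' @return The axis with `tip_mm`, `entry_mm`, `length_mm` and an oriented
#'   `direction`.
#' @export
designate_tip <- function(axis, entry_hint = c("auto", "lateral_min",
                                               "lateral_max",
                                               "elevational_min",
                                               "elevational_max")) {
  entry_hint <- match.arg(entry_hint)
  stopifnot(inherits(axis, "needle_axis"), axis$n_inliers >= 2L)
  pts <- axis$inlier_points_mm
  t_ax <- as.numeric(sweep(pts, 2, axis$point_mm, "-") %*% axis$direction)
  e1 <- axis$point_mm + min(t_ax) * axis$direction
  e2 <- axis$point_mm + max(t_ax) * axis$direction
  ends <- rbind(e1, e2)
  face_dist <- function(p, face) {
    switch(face,
      lateral_min = p[1] - axis$bbox_mm[1, 1],
      lateral_max = axis$bbox_mm[2, 1] - p[1],
      elevational_min = p[3] - axis$bbox_mm[1, 3],
      elevational_max = axis$bbox_mm[2, 3] - p[3])
  }
  faces <- c("lateral_min", "lateral_max", "elevational_min",
             "elevational_max")
  if (entry_hint == "auto") {
    dmat <- vapply(faces, function(f)
      c(face_dist(e1, f), face_dist(e2, f)), numeric(2))
    entry_hint <- faces[which.min(apply(dmat, 2, min))]
  }
  d_ends <- c(face_dist(e1, entry_hint), face_dist(e2, entry_hint))
  entry <- ends[which.min(d_ends), ]
  tip <- ends[which.max(d_ends), ]
  L <- sqrt(sum((tip - entry)^2))
  dir <- if (L > 1e-12) (tip - entry) / L else axis$direction
  axis$entry_mm <- as.numeric(entry)
  axis$tip_mm <- as.numeric(tip)
  axis$length_mm <- L
  axis$direction <- as.numeric(dir)
  axis$entry_face <- entry_hint
  axis
}

#' The coronal-perpendicular plane containing the needle axis
#'
#' Constructs the plane through `axis$point_mm` spanned by the axis
#' direction and the axial unit vector; its normal is
#' `normalize(axial x direction)`. By construction the plane contains the
#' whole axis and is perpendicular to every coronal plane. When the axis is
#' within 1e-6 rad of the axial direction the construction is degenerate
#' and the lateral-axial plane through the point is returned, flagged with
#' attribute `degenerate = TRUE`.
#'
#' @param axis A `needle_axis`.
#' @return A [plane_spec].
#' @export
needle_plane <- function(axis) {
  stopifnot(inherits(axis, "needle_axis"))
  axial <- c(0, 1, 0)
  d <- axis$direction
  s <- cross3(axial, d)
  ns <- sqrt(sum(s^2))
  if (ns < 1e-6) {
    pl <- plane_spec(axis$point_mm, c(0, 0, 1),
                     rbind(c(1, 0, 0), c(0, 1, 0)))
    attr(pl, "degenerate") <- TRUE
    return(pl)
  }
  normal <- s / ns
  u <- d - sum(d * axial) * axial
  u <- u / sqrt(sum(u^2))
  plane_spec(axis$point_mm, normal, rbind(u, axial))
}

#' Render the in-plane needle view
#'
#' Extracts the needle plane over the full volume footprint and returns it
#' with the axis endpoints as a sidecar overlay (never burned into the
#' intensities).
#'
#' @param v An [us_volume].
#' @param axis A `needle_axis`.
#' @param sample_step_mm Sampling step of the rendered image, mm.
#' @return An `inplane_view`: list with `image` (matrix), `overlay` (entry
#'   and tip in image (u, w) mm coordinates), `plane`, and `degenerate`
#'   flag.
#' @export
render_inplane_view <- function(v, axis, sample_step_mm = v$voxel_size_mm) {
  pl <- needle_plane(axis)
  ext <- dim(vol_data(v)) * v$voxel_size_mm
  ctr <- v$origin_mm + ext / 2
  # re-center the plane point on the volume center projected onto the plane
  p0 <- ctr - sum((ctr - pl$point_mm) * pl$normal) * pl$normal
  pl2 <- plane_spec(p0, pl$normal, pl$in_plane_axes)
  diag_mm <- sqrt(sum(ext^2))
  img <- extract_plane(v, pl2, c(diag_mm, diag_mm), sample_step_mm)
  to_uw <- function(p) {
    rel <- p - pl2$point_mm
    c(u = sum(rel * pl2$in_plane_axes[1, ]),
      w = sum(rel * pl2$in_plane_axes[2, ]))
  }
  entry <- axis$tip_mm - axis$length_mm * axis$direction
  structure(list(image = img, plane = pl2,
                 overlay = list(entry_uw = to_uw(entry),
                                tip_uw = to_uw(axis$tip_mm)),
                 degenerate = isTRUE(attr(pl, "degenerate")),
                 sample_step_mm = sample_step_mm),
            class = "inplane_view")
}

#' @export
print.inplane_view <- function(x, ...) {
  cat(sprintf("<inplane_view> %d x %d samples at %.3g mm%s\n",
              nrow(x$image), ncol(x$image), x$sample_step_mm,
              if (x$degenerate) " (degenerate fallback plane)" else ""))
  invisible(x)
}
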