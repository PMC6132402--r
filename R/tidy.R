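#' @importFrom generics tidy glance
#' @export
generics::tidy
#' @export
generics::glance

#' Tidy and glance methods
#'
#' `tidy()` returns the per-round / per-epoch / per-fold report of a fit;
#' `glance()` a one-row summary.
#'
#' @param x A `patch_fit`, `fcn_fit`, `crossval_result` or `needle_axis`.
#' @param ... Unused.
#' @name needlefinder-tidiers
NULL

#' @rdname needlefinder-tidiers
#' @export
tidy.patch_fit <- function(x, ...) x$report

#' @rdname needlefinder-tidiers
#' @export
glance.patch_fit <- function(x, ...) {
  dplyr::slice_tail(x$report, n = 1) |>
    dplyr::select("precision", "recall", "f1", "val_loss") |>
    dplyr::mutate(rounds = max(x$report$round))
}

#' @rdname needlefinder-tidiers
#' @export
tidy.fcn_fit <- function(x, ...) x$report

#' @rdname needlefinder-tidiers
#' @export
glance.fcn_fit <- function(x, ...) {
  dplyr::slice_tail(x$report, n = 1) |>
    dplyr::select("loss", "val_slice_f1") |>
    dplyr::mutate(epochs = nrow(x$report),
                  width_scale = x$cfg$width_scale,
                  gap_d_mm = x$tcfg$gap_d_mm)
}

#' @rdname needlefinder-tidiers
#' @export
tidy.crossval_result <- function(x, ...) x$per_fold

#' @rdname needlefinder-tidiers
#' @export
glance.crossval_result <- function(x, ...) x$pooled

#' @rdname needlefinder-tidiers
#' @export
tidy.needle_axis <- function(x, ...) {
  tibble::tibble(
    point_lat_mm = x$point_mm[1], point_ax_mm = x$point_mm[2],
    point_elev_mm = x$point_mm[3],
    dir_lat = x$direction[1], dir_ax = x$direction[2],
    dir_elev = x$direction[3],
    tip_lat_mm = x$tip_mm[1], tip_ax_mm = x$tip_mm[2],
    tip_elev_mm = x$tip_mm[3],
    length_mm = x$length_mm, n_inliers = x$n_inliers)
}

#' Plot length-stratified error curves
#'
#' Mean tip and orientation error versus needle length with standard-error
#' ribbons, in the style of a length-sweep accuracy figure.
#'
#' @param tbl Tibble from [length_stratified_errors()].
#' @return A ggplot object.
#' @export
plot_length_errors <- function(tbl) {
  long <- dplyr::bind_rows(
    dplyr::transmute(tbl, length_mm = .data$length_mm,
                     metric = "tip error (mm)",
                     mean = .data$eps_t_mean, se = .data$eps_t_se),
    dplyr::transmute(tbl, length_mm = .data$length_mm,
                     metric = "orientation error (deg)",
                     mean = .data$eps_v_mean, se = .data$eps_v_se))
  ggplot2::ggplot(long, ggplot2::aes(.data$length_mm, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         alpha = 0.25) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "needle length (mm)", y = NULL)
}

#' Plot a gap-d sweep
#'
#' @param tbl Tibble from [gap_sweep()].
#' @return A ggplot object of voxel F1 versus thick-slice gap d.
#' @export
plot_gap_sweep <- function(tbl) {
  ggplot2::ggplot(tbl, ggplot2::aes(factor(.data$d_mm), .data$f1)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "thick-slice gap d (mm)", y = "voxel F1")
}

#' @rdname plot_length_errors
#' @param object An `inplane_view`.
#' @param ... Unused.
#' @export
autoplot.inplane_view <- function(object, ...) {
  img <- object$image
  ax <- attr(img, "axes_mm")
  df <- expand.grid(u = ax$u, w = ax$w)
  df$value <- as.vector(img)
  ov <- dplyr::bind_rows(
    tibble::tibble(u = object$overlay$entry_uw[1],
                   w = object$overlay$entry_uw[2], what = "entry"),
    tibble::tibble(u = object$overlay$tip_uw[1],
                   w = object$overlay$tip_uw[2], what = "tip"))
  ggplot2::ggplot(df, ggplot2::aes(.data$u, .data$w)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::geom_line(data = ov, colour = "red") +
    ggplot2::geom_point(data = ov, ggplot2::aes(shape = .data$what),
                        colour = "red", size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "in-plane u (mm)", y = "in-plane w (mm)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
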