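# Evaluation: voxel-level classification metrics (recall, precision,
# specificity, F1 as the harmonic mean of recall and precision), geometric
# accuracy (tip error = point-plane distance from the ground-truth tip to
# the detected needle plane; orientation error = angle between detected and
# ground-truth axes, undirected), length-stratified error curves, and the
# k-fold cross-validation harness.

#' Voxel-level classification metrics
#'
#' Recall = detected needle voxels / needle voxels; precision = detected
#' needle voxels / all detected voxels; specificity = correctly rejected
#' background / background; F1 = harmonic mean of recall and precision.
#' Precision (and hence F1) is reported as `NA` -- undefined, not zero --
#' when no voxel is predicted positive.
#'
#' @param pred,truth [label_volume]s of identical geometry.
#' @return One-row tibble: recall, precision, specificity, f1, tp, fp, tn,
#'   fn.
#' @export
voxel_metrics <- function(pred, truth) {
  stop_if_geometry_differs(pred, truth)
  p <- pred$labels; t0 <- truth$labels
  tp <- sum(p == 1L & t0 == 1L)
  fp <- sum(p == 1L & t0 == 0L)
  fn <- sum(p == 0L & t0 == 1L)
  tn <- sum(p == 0L & t0 == 0L)
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  specificity <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  f1 <- if (is.na(precision) || is.na(recall)) NA_real_
    else if (precision + recall == 0) 0
    else 2 * precision * recall / (precision + recall)
  tibble::tibble(recall = recall, precision = precision,
                 specificity = specificity, f1 = f1,
                 tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Tip error: point-plane distance (mm)
#'
#' Distance from the ground-truth needle tip to the detected needle plane,
#' `|(tip - plane$point_mm) . plane$normal|`.
#'
#' @param truth_tip_mm Ground-truth tip, mm.
#' @param plane A [plane_spec].
#' @return Non-negative scalar, mm.
#' @export
tip_error <- function(truth_tip_mm, plane) {
  stopifnot(inherits(plane, "plane_spec"))
  abs(sum((as.numeric(truth_tip_mm) - plane$point_mm) * plane$normal))
}

#' Orientation error: angle between two needle axes (degrees)
#'
#' Axes are undirected: the angle is `acos(|a . b|)`, invariant to flipping
#' either direction, in \[0, 90\] degrees.
#'
#' @param dir_a,dir_b Unit 3-vectors.
#' @return Angle in degrees.
#' @export
orientation_error <- function(dir_a, dir_b) {
  a <- as.numeric(dir_a); b <- as.numeric(dir_b)
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  acos(pmin(1, abs(sum(a * b)))) * 180 / pi
}

#' Tip and orientation errors as a function of needle length
#'
#' Generates phantom replicates with the needle length swept over
#' `lengths_mm` (all other settings from `base_cfg`), runs the detector on
#' each volume, fits the axis, and reports mean and standard error of the
#' tip error and orientation error per length. Detector or fit failures are
#' recorded as missing, not silently dropped.
#'
#' @param detector Function `us_volume -> label_volume` of detected voxels.
#' @param lengths_mm Needle lengths to sweep, mm.
#' @param base_cfg A [phantom_config] providing all other settings.
#' @param n_replicates Phantom replicates per length.
#' @param ransac_cfg A [ransac_config].
#' @param seed Integer seed; replicate seeds are derived from it.
#' @return Tidy tibble: length_mm, n, n_failed, eps_t_mean, eps_t_se,
#'   eps_v_mean, eps_v_se.
#' @export
length_stratified_errors <- function(detector, lengths_mm,
                                     base_cfg = phantom_config(),
                                     n_replicates = 5L,
                                     ransac_cfg = ransac_config(),
                                     seed = 1L) {
  rows <- purrr::imap(as.numeric(lengths_mm), function(L, li) {
    errs <- purrr::map(seq_len(n_replicates), function(r) {
      cfg <- base_cfg
      cfg$needle_length_mm <- L
      cfg$seed <- as.integer(seed + 1000L * li + r)
      ph <- generate_phantom(cfg)
      det <- detector(ph$volume)
      ax <- ransac_fit(det, ransac_cfg)
      if (!is_needle_found(ax))
        return(tibble::tibble(eps_t = NA_real_, eps_v = NA_real_))
      tibble::tibble(
        eps_t = tip_error(ph$truth$tip_mm, needle_plane(ax)),
        eps_v = orientation_error(ax$direction, ph$truth$axis_direction))
    }) |> dplyr::bind_rows()
    se <- function(x) if (sum(!is.na(x)) > 1) sd(x, na.rm = TRUE) /
      sqrt(sum(!is.na(x))) else NA_real_
    tibble::tibble(
      length_mm = L, n = n_replicates, n_failed = sum(is.na(errs$eps_t)),
      eps_t_mean = mean(errs$eps_t, na.rm = TRUE), eps_t_se = se(errs$eps_t),
      eps_v_mean = mean(errs$eps_v, na.rm = TRUE), eps_v_se = se(errs$eps_v))
  })
  dplyr::bind_rows(rows)
}

#' k-fold cross-validation of a detection method
#'
#' Uses the manifest's volume-disjoint fold assignment: trains on k-1
#' folds, evaluates full-volume voxel metrics on the held-out fold, and
#' reports per-fold metrics plus their mean and standard deviation. Folds
#' that predict no positive voxel have undefined precision; they are
#' excluded from the precision/F1 averages and counted in
#' `n_undefined_precision`.
#'
#' @param manifest Tibble from [make_dataset()] / [read_manifest()].
#' @param method `"patch"` or `"fcn"`.
#' @param k Number of folds; must match the manifest's folds.
#' @param patch_model_cfg,patch_train_cfg Patch-method configurations.
#' @param fcn_cfg,fcn_train_cfg FCN-method configurations.
#' @param stride Voxel stride for patch-method full-volume classification.
#' @param gap_d_mm Thick-slice gap for the FCN method.
#' @return A `crossval_result`: list with `per_fold` (tibble, one row per
#'   fold) and `pooled` (one row: mean and sd across folds).
#' @export
crossval <- function(manifest, method = c("patch", "fcn"), k = 5L,
                     patch_model_cfg = patch_model_config(),
                     patch_train_cfg = patch_train_config(),
                     fcn_cfg = fcn_config(), fcn_train_cfg = fcn_train_config(),
                     stride = 1L, gap_d_mm = 2.0) {
  method <- match.arg(method)
  folds <- sort(unique(manifest$fold))
  if (length(folds) != k)
    abort(sprintf("manifest defines %d folds but k = %d", length(folds), k))
  dup <- manifest |>
    dplyr::distinct(.data$volume, .data$fold) |>
    dplyr::count(.data$volume) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0)
    abort("fold leakage: a volume is assigned to more than one fold")
  per_fold <- purrr::map(folds, function(f) {
    train_rows <- manifest[manifest$fold != f, ]
    test_rows <- manifest[manifest$fold == f, ]
    if (any(test_rows$volume %in% train_rows$volume))
      abort("fold leakage: same volume in train and test")
    train_pairs <- load_pairs(train_rows)
    test_pairs <- load_pairs(test_rows)
    detect <- if (method == "patch") {
      fit <- train_patch_classifier(train_pairs, patch_model_cfg,
                                    patch_train_cfg)
      function(v) classify_volume_patchwise(fit$model, v, stride)$labels
    } else {
      fit <- train_fcn(train_pairs, fcn_cfg, fcn_train_cfg)
      function(v) segment_volume(fit$model, v, gap_d_mm)$labels
    }
    mets <- purrr::map(test_pairs, function(pair)
      voxel_metrics(detect(pair$volume), pair$mask)) |>
      dplyr::bind_rows()
    dplyr::summarise(mets,
      recall = mean(.data$recall, na.rm = TRUE),
      precision = mean(.data$precision, na.rm = TRUE),
      specificity = mean(.data$specificity, na.rm = TRUE),
      f1 = mean(.data$f1, na.rm = TRUE),
      n_volumes = dplyr::n(),
      n_undefined_precision = sum(is.na(.data$precision))) |>
      dplyr::mutate(fold = f, .before = 1)
  }) |> dplyr::bind_rows()
  pooled <- tibble::tibble(
    recall_mean = mean(per_fold$recall), recall_sd = sd(per_fold$recall),
    precision_mean = mean(per_fold$precision, na.rm = TRUE),
    precision_sd = sd(per_fold$precision, na.rm = TRUE),
    f1_mean = mean(per_fold$f1, na.rm = TRUE),
    f1_sd = sd(per_fold$f1, na.rm = TRUE),
    n_undefined_precision = sum(per_fold$n_undefined_precision))
  structure(list(per_fold = per_fold, pooled = pooled, method = method),
            class = "crossval_result")
}

#' @export
print.crossval_result <- function(x, ...) {
  cat(sprintf("<crossval_result> method = %s\n", x$method))
  print(x$per_fold)
  cat("pooled (mean +/- sd across folds):\n")
  print(x$pooled)
  invisible(x)
}
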