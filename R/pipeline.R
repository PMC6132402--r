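# End-to-end pipeline: voxel detection (patch or FCN method, a config
# switch over a shared detector interface) -> RANSAC axis estimation ->
# needle-plane extraction and rendering, per volume, with provenance
# stamping (config hash + seed) on every artifact.

#' Pipeline run configuration
#'
#' @param volumes Character vector of volume paths, or a list of
#'   [us_volume] objects.
#' @param method `"patch"` or `"fcn"`.
#' @param model A trained model object, a `*_fit`, or a checkpoint path.
#' @param out_dir Output directory.
#' @param ransac A [ransac_config].
#' @param gap_d_mm Thick-slice gap for the FCN detector, mm.
#' @param stride Voxel stride for the patch detector.
#' @param threshold Probability threshold for the label volume.
#' @param seed Global seed; per-stage seeds derive from it
#'   deterministically.
#' @return A `run_config` object.
#' @export
run_config <- function(volumes, method = c("fcn", "patch"), model,
                       out_dir = "needlefinder_out",
                       ransac = ransac_config(), gap_d_mm = 2.0,
                       stride = 1L, threshold = 0.5, seed = 1L) {
  method <- match.arg(method)
  structure(as.list(environment()), class = "run_config")
}

#' Run the three-stage detection pipeline
#'
#' For every input volume: per-voxel needle detection by the configured
#' method, RANSAC cylinder fitting, tip designation, needle-plane
#' extraction and in-plane rendering. Writes the probability and label
#' volumes (NRRD), the axis as JSON and the rendered view; every artifact
#' is stamped with the configuration hash and seed. A stage failure yields
#' a partial-results row with the failed stage's diagnostics rather than
#' aborting the run.
#'
#' @param cfg A [run_config].
#' @return Tibble run report: one row per volume with stage status and
#'   artifact paths.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  model <- cfg$model
  if (is.character(model)) model <- load_model(model)
  if (inherits(model, c("patch_fit", "fcn_fit"))) model <- model$model
  if (cfg$method == "fcn" && !inherits(model, "fcn_model"))
    abort("method 'fcn' needs an fcn_model")
  if (cfg$method == "patch" && !inherits(model, "patch_model"))
    abort("method 'patch' needs a patch_model")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  # hash the scientific configuration only: the output location must not
  # change the recorded provenance of identical reruns
  stamp <- list(config_hash = config_hash(cfg[setdiff(names(cfg),
                                                      c("model", "out_dir",
                                                        "volumes"))]),
                seed = cfg$seed)
  vols <- cfg$volumes
  rows <- purrr::imap(vols, function(vsrc, i) {
    name <- if (is.character(vsrc))
      sub("\\.[^.]*$", "", basename(vsrc)) else sprintf("volume_%03d", i)
    row <- tibble::tibble(volume = name, status = "ok", failed_stage = NA_character_,
                          message = NA_character_, axis_json = NA_character_,
                          render = NA_character_, n_inliers = NA_integer_)
    stage <- "load"
    result <- tryCatch({
      v <- if (is.character(vsrc)) read_volume(vsrc) else vsrc
      stage <- "detect"
      det <- if (cfg$method == "fcn") {
        segment_volume(model, v, cfg$gap_d_mm, cfg$threshold)
      } else {
        cl <- classify_volume_patchwise(model, v, cfg$stride)
        list(prob = cl$prob, labels = cl$labels)
      }
      write_volume(det$prob, file.path(cfg$out_dir, paste0(name, "_prob.nrrd")))
      write_volume(det$labels, file.path(cfg$out_dir, paste0(name, "_label.nrrd")))
      stage <- "ransac"
      rc <- cfg$ransac
      rc$seed <- cfg$seed + 7919L * i
      ax <- ransac_fit(det$labels, rc)
      if (!is_needle_found(ax))
        stop("no needle found: ", ax$reason, call. = FALSE)
      stage <- "visualize"
      view <- render_inplane_view(v, ax)
      axis_json <- file.path(cfg$out_dir, paste0(name, "_axis.json"))
      jsonlite::write_json(list(
        point_mm = ax$point_mm, direction = ax$direction,
        tip_mm = ax$tip_mm, entry_mm = ax$entry_mm,
        length_mm = ax$length_mm, n_inliers = ax$n_inliers,
        provenance = stamp), axis_json, auto_unbox = TRUE, digits = NA)
      render_path <- file.path(cfg$out_dir, paste0(name, "_view.json"))
      img <- view$image
      jsonlite::write_json(list(
        n_rows = nrow(img), n_cols = ncol(img),
        intensity_range = range(img),
        overlay = view$overlay, degenerate = view$degenerate,
        provenance = stamp), render_path, auto_unbox = TRUE, digits = NA)
      write_volume(us_volume(array(img, c(dim(img), 1L)), view$sample_step_mm),
                   file.path(cfg$out_dir, paste0(name, "_view.nrrd")))
      if (requireNamespace("png", quietly = TRUE)) {
        rng <- range(img)
        norm <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
        png::writePNG(t(norm),
                      file.path(cfg$out_dir, paste0(name, "_view.png")))
      }
      list(axis_json = axis_json, render = render_path,
           n_inliers = ax$n_inliers, stage = stage)
    }, error = function(e) {
      list(error = conditionMessage(e), stage = stage)
    })
    if (!is.null(result$error)) {
      row$status <- "failed"
      row$failed_stage <- result$stage
      row$message <- result$error
    } else {
      row$axis_json <- result$axis_json
      row$render <- result$render
      row$n_inliers <- result$n_inliers
    }
    row
  })
  report <- dplyr::bind_rows(rows)
  jsonlite::write_json(
    c(stamp, list(n_volumes = nrow(report),
                  n_ok = sum(report$status == "ok"))),
    file.path(cfg$out_dir, "run_report.json"), auto_unbox = TRUE, digits = NA)
  report
}
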