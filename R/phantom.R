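# Synthetic needle-phantom generator. Background is a smooth low-frequency
# echogenicity field times Rayleigh-distributed multiplicative speckle with a
# light Gaussian blur (the standard envelope-statistics approximation).
# Bright curvilinear/blob distractors with gains overlapping the needle's
# make the detection problem non-separable on intensity alone. The needle is
# a voxelized straight cylinder, brightened multiplicatively, with optional
# contiguous dropout runs (partial invisibility, as under steered beams) and
# an axial acoustic shadow beneath the shaft.

#' Phantom configuration
#'
#' Defaults emulate a motorized linear-array acquisition: ~174 x 189 x 188
#' voxels at 0.2 mm/voxel with a 17 G (1.47 mm) needle of up to 30 mm and a
#' steepness angle in the 10-30 degree range. Pass a smaller `shape` for
#' quick experiments.
#'
#' @param shape Volume shape, 3 positive integers (lateral, axial,
#'   elevational).
#' @param voxel_size_mm Isotropic voxel size, mm.
#' @param needle_diameter_mm Needle outer diameter, mm (17 G = 1.47,
#'   22 G = 0.72).
#' @param needle_length_mm Inserted needle length, mm.
#' @param entry_face Face the needle enters through: `"lateral"` or
#'   `"elevational"`.
#' @param steepness_angle_deg Insertion angle relative to the coronal
#'   (lateral-elevational) plane, degrees.
#' @param horizontal_angle_deg In-coronal-plane angle away from the entry
#'   axis, degrees.
#' @param needle_intensity_gain Multiplicative brightening of needle voxels
#'   (> 1).
#' @param dropout_fraction Fraction of the shaft rendered invisible, in
#'   contiguous runs; must be < 1.
#' @param shadow_enabled Attenuate intensities below the needle along the
#'   axial (beam) direction.
#' @param shadow_attenuation Multiplicative attenuation factor in \[0, 1\].
#' @param n_distractors Number of bright distractor tubes/ellipsoids.
#' @param speckle_scale Rayleigh scale of the multiplicative speckle.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A `phantom_config` object.
#' @export
phantom_config <- function(shape = c(174, 189, 188),
                           voxel_size_mm = 0.2,
                           needle_diameter_mm = 1.47,
                           needle_length_mm = 30,
                           entry_face = c("lateral", "elevational"),
                           steepness_angle_deg = 20,
                           horizontal_angle_deg = 0,
                           needle_intensity_gain = 3,
                           dropout_fraction = 0,
                           shadow_enabled = TRUE,
                           shadow_attenuation = 0.6,
                           n_distractors = 8,
                           speckle_scale = 1,
                           seed = 1L) {
  entry_face <- match.arg(entry_face)
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) abort("`shape` must be 3 positive integers")
  if (needle_diameter_mm < 0.2) abort("needle diameter too small")
  if (dropout_fraction < 0 || dropout_fraction >= 1)
    abort("`dropout_fraction` must be in [0, 1)")
  if (needle_intensity_gain <= 1) abort("`needle_intensity_gain` must be > 1")
  if (shadow_attenuation < 0 || shadow_attenuation > 1)
    abort("`shadow_attenuation` must be in [0, 1]")
  structure(list(
    shape = shape, voxel_size_mm = voxel_size_mm,
    needle_diameter_mm = needle_diameter_mm,
    needle_length_mm = needle_length_mm, entry_face = entry_face,
    steepness_angle_deg = steepness_angle_deg,
    horizontal_angle_deg = horizontal_angle_deg,
    needle_intensity_gain = needle_intensity_gain,
    dropout_fraction = dropout_fraction, shadow_enabled = shadow_enabled,
    shadow_attenuation = shadow_attenuation, n_distractors = n_distractors,
    speckle_scale = speckle_scale, seed = as.integer(seed)),
    class = "phantom_config")
}

# Evaluate expr under a fixed RNG state without disturbing the caller's.
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

needle_direction <- function(cfg) {
  a <- cfg$steepness_angle_deg * pi / 180
  b <- cfg$horizontal_angle_deg * pi / 180
  if (cfg$entry_face == "lateral") {
    d <- c(cos(a) * cos(b), sin(a), cos(a) * sin(b))
  } else {
    d <- c(cos(a) * sin(b), sin(a), cos(a) * cos(b))
  }
  d / sqrt(sum(d^2))
}

#' Voxelize a cylinder around a finite 3D segment
#'
#' A voxel belongs to the mask iff its physical center lies within
#' `diameter_mm / 2` of the segment from `entry_mm` to
#' `entry_mm + length_mm * direction`.
#'
#' @param entry_mm Segment start, mm.
#' @param direction Unit 3-vector.
#' @param length_mm Segment length (> 0), mm.
#' @param diameter_mm Cylinder diameter (> 0), mm.
#' @param grid A volume object supplying geometry (shape, voxel size,
#'   origin).
#' @return A [label_volume].
#' @export
rasterize_cylinder <- function(entry_mm, direction, length_mm, diameter_mm,
                               grid) {
  direction <- as.numeric(direction)
  if (abs(sqrt(sum(direction^2)) - 1) > 1e-6)
    abort("`direction` must be a unit vector")
  if (length_mm <= 0) abort("`length_mm` must be > 0")
  if (diameter_mm <= 0) abort("`diameter_mm` must be > 0")
  shp <- dim(vol_data(grid))
  vx <- grid$voxel_size_mm
  r <- diameter_mm / 2
  p0 <- as.numeric(entry_mm)
  p1 <- p0 + length_mm * direction
  # limit the distance test to the segment's bounding box plus the radius
  lo <- pmax(1L, floor((pmin(p0, p1) - r - grid$origin_mm) / vx + 0.5) - 1L)
  hi <- pmin(shp, ceiling((pmax(p0, p1) + r - grid$origin_mm) / vx + 0.5) + 1L)
  mask <- array(0L, shp)
  if (any(lo > hi)) return(label_volume(mask, vx, grid$origin_mm))
  ijk <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2],
                               k = lo[3]:hi[3]))
  ctr <- voxel_centers_mm(grid, ijk)
  rel <- sweep(ctr, 2, p0, "-")
  t_ax <- pmin(pmax(rel %*% direction, 0), length_mm)
  perp <- rel - t_ax %*% t(direction)
  inside <- rowSums(perp^2) <= r^2
  mask[ijk[inside, , drop = FALSE]] <- 1L
  label_volume(mask, vx, grid$origin_mm)
}

# Axis position (mm along the shaft) of each mask voxel, for dropout runs.
shaft_position_mm <- function(grid, ijk, entry_mm, direction, length_mm) {
  rel <- sweep(voxel_centers_mm(grid, ijk), 2, entry_mm, "-")
  pmin(pmax(as.numeric(rel %*% direction), 0), length_mm)
}

smooth_field <- function(shape, coarse = 8) {
  # low-frequency echogenicity: coarse Gaussian grid, trilinearly upsampled
  cdim <- pmax(2L, ceiling(shape / coarse) + 1L)
  coarse_grid <- array(rnorm(prod(cdim)), cdim)
  idx <- as.matrix(expand.grid(
    i = seq(0, cdim[1] - 1, length.out = shape[1]),
    j = seq(0, cdim[2] - 1, length.out = shape[2]),
    k = seq(0, cdim[3] - 1, length.out = shape[3])))
  f <- nn_trilinear_sample(coarse_grid, idx, 0, FALSE)
  array(f, shape)
}

gaussian_kernel1d <- function(sigma) {
  r <- max(1L, ceiling(2.5 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

random_unit3 <- function() {
  repeat {
    u <- rnorm(3)
    n <- sqrt(sum(u^2))
    if (n > 1e-8) return(u / n)
  }
}

#' Generate a synthetic needle phantom with ground truth
#'
#' @param cfg A [phantom_config].
#' @return A list with elements `volume` (an [us_volume]) and `truth`, a
#'   `phantom_truth` list carrying `mask` (a [label_volume] that includes
#'   dropped-out, invisible needle voxels, as manual annotation would),
#'   `axis_entry_mm`, `axis_direction`, `tip_mm` and `length_mm`.
#' @export
generate_phantom <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  with_seed_local(cfg$seed, {
    shp <- cfg$shape
    vx <- cfg$voxel_size_mm
    ext <- shp * vx
    dir <- needle_direction(cfg)
    L <- cfg$needle_length_mm
    r <- cfg$needle_diameter_mm / 2
    # entry position: uniform over the part of the entry face from which the
    # whole segment (plus radius) stays inside the volume
    margin <- r + vx
    lo <- rep(margin, 3)
    hi <- ext - margin
    span <- L * dir
    e_lo <- pmax(lo, lo - span)
    e_hi <- pmin(hi, hi - span)
    if (any(e_lo > e_hi))
      abort("needle does not fit inside the volume for this configuration")
    entry <- e_lo + runif(3) * (e_hi - e_lo)
    entry_axis <- if (cfg$entry_face == "lateral") 1L else 3L
    entry[entry_axis] <- e_lo[entry_axis]
    tip <- entry + L * dir

    grid <- us_volume(array(0, shp), vx)
    mask <- rasterize_cylinder(entry, dir, L, cfg$needle_diameter_mm, grid)

    # background: smooth echogenicity x Rayleigh speckle, lightly blurred
    echo <- 1 + 0.35 * smooth_field(shp)
    echo <- pmax(echo, 0.1)
    speckle <- cfg$speckle_scale * sqrt(-2 * log(runif(prod(shp))))
    intens <- echo * array(speckle, shp)
    intens <- nn_sepconv3(intens, gaussian_kernel1d(0.8))

    # distractors: bright random tubes and ellipsoids, gains overlapping the
    # needle's so intensity alone cannot separate the classes
    if (cfg$n_distractors > 0) {
      for (d in seq_len(cfg$n_distractors)) {
        gain_d <- runif(1, 0.6, 1.1) * cfg$needle_intensity_gain
        if (runif(1) < 0.6) {  # tube
          len_d <- runif(1, 0.15, 0.5) * min(ext)
          dia_d <- runif(1, 0.5, 2.5)
          dir_d <- random_unit3()
          ctr_d <- lo + runif(3) * (hi - lo)
          m_d <- rasterize_cylinder(ctr_d - dir_d * len_d / 2, dir_d, len_d,
                                    dia_d, grid)$labels
        } else {  # ellipsoid blob
          ctr_d <- lo + runif(3) * (hi - lo)
          semi <- runif(3, 0.5, 2.5)
          box <- ceiling(semi / vx) + 1L
          c_idx <- round(ctr_d / vx + 0.5)
          lo_i <- pmax(1L, c_idx - box)
          hi_i <- pmin(shp, c_idx + box)
          m_d <- array(0L, shp)
          if (all(lo_i <= hi_i)) {
            ijk <- as.matrix(expand.grid(i = lo_i[1]:hi_i[1],
                                         j = lo_i[2]:hi_i[2],
                                         k = lo_i[3]:hi_i[3]))
            rel <- sweep(voxel_centers_mm(grid, ijk), 2, ctr_d, "-")
            inside <- rowSums(sweep(rel, 2, semi, "/")^2) <= 1
            m_d[ijk[inside, , drop = FALSE]] <- 1L
          }
        }
        sel <- m_d == 1L
        intens[sel] <- intens[sel] * gain_d
      }
    }

    # needle: multiplicative gain on visible shaft voxels; dropout removes
    # contiguous runs along the shaft (beam-angle-dependent invisibility)
    needle_idx <- which(mask$labels == 1L, arr.ind = TRUE)
    visible <- rep(TRUE, nrow(needle_idx))
    if (cfg$dropout_fraction > 0 && nrow(needle_idx) > 0) {
      tpos <- shaft_position_mm(grid, needle_idx, entry, dir, L)
      total_drop <- cfg$dropout_fraction * L
      n_runs <- sample(1:3, 1)
      run_len <- rep(total_drop / n_runs, n_runs)
      starts <- sort(runif(n_runs, 0, L - total_drop / n_runs))
      for (s in seq_len(n_runs)) {
        visible <- visible & !(tpos >= starts[s] & tpos < starts[s] + run_len[s])
      }
    }
    vis_idx <- needle_idx[visible, , drop = FALSE]
    intens[vis_idx] <- intens[vis_idx] * cfg$needle_intensity_gain

    # acoustic shadow: attenuate below the shaft along the axial direction
    if (cfg$shadow_enabled && nrow(needle_idx) > 0 &&
        cfg$shadow_attenuation < 1) {
      cols <- needle_idx[, c(1, 3), drop = FALSE]
      deepest <- tapply(needle_idx[, 2],
                        interaction(cols[, 1], cols[, 2], drop = TRUE), max)
      keys <- strsplit(names(deepest), ".", fixed = TRUE)
      for (q in seq_along(deepest)) {
        i <- as.integer(keys[[q]][1]); k <- as.integer(keys[[q]][2])
        j0 <- deepest[[q]] + 1L
        if (j0 <= shp[2])
          intens[i, j0:shp[2], k] <- intens[i, j0:shp[2], k] *
            cfg$shadow_attenuation
      }
    }

    truth <- structure(list(mask = mask, axis_entry_mm = entry,
                            axis_direction = dir, tip_mm = tip,
                            length_mm = L), class = "phantom_truth")
    list(volume = us_volume(intens, vx), truth = truth)
  })
}

#' Generate a phantom dataset on disk with fold assignments
#'
#' Writes each phantom's volume and ground-truth mask as NRRD files plus a
#' JSON manifest assigning volume-disjoint cross-validation folds
#' round-robin.
#'
#' @param cfgs List of [phantom_config] objects (>= `n_folds` for k-fold
#'   use).
#' @param dir Output directory (created if missing).
#' @param n_folds Number of folds (default 5).
#' @return The manifest as a tibble (also written to
#'   `file.path(dir, "manifest.json")`), one row per volume: id, paths,
#'   seed, fold and the truth axis parameters.
#' @export
make_dataset <- function(cfgs, dir, n_folds = 5L) {
  n_folds <- as.integer(n_folds)
  if (length(cfgs) < n_folds)
    abort(sprintf("need >= %d volumes for %d-fold use", n_folds, n_folds))
  seeds <- vapply(cfgs, function(cc) cc$seed, integer(1))
  if (anyDuplicated(seeds))
    warn("duplicate seeds in phantom configurations")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- purrr::imap(cfgs, function(cfg, i) {
    ph <- generate_phantom(cfg)
    vol_path <- file.path(dir, sprintf("vol_%03d.nrrd", i))
    mask_path <- file.path(dir, sprintf("mask_%03d.nrrd", i))
    write_volume(ph$volume, vol_path)
    write_volume(ph$truth$mask, mask_path)
    tibble::tibble(
      id = i, volume = vol_path, mask = mask_path, seed = cfg$seed,
      fold = ((i - 1L) %% n_folds) + 1L,
      voxel_size_mm = cfg$voxel_size_mm,
      entry_mm = list(ph$truth$axis_entry_mm),
      direction = list(ph$truth$axis_direction),
      tip_mm = list(ph$truth$tip_mm),
      length_mm = ph$truth$length_mm)
  })
  manifest <- dplyr::bind_rows(rows)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       digits = NA, auto_unbox = FALSE)
  manifest
}

#' @rdname make_dataset
#' @param path Path to a `manifest.json` written by [make_dataset()].
#' @export
read_manifest <- function(path) {
  m <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  tibble::as_tibble(m) |>
    dplyr::mutate(dplyr::across(c("entry_mm", "direction", "tip_mm"),
                                ~ purrr::map(.x, as.numeric)))
}
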