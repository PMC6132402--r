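# Thick-slice (2.5D) data representation and ShareFCN training. A thick
# slice stacks the processing cross-section with its two parallel
# neighbours at a gap of d mm (default 2.0 mm) into a 3-channel input;
# cross-sections are taken perpendicular to the lateral and the elevational
# axis at a step of one voxel, and one shared network serves both views.

#' Extract the ordered thick slices of a volume along one direction
#'
#' One `thick_slice` per index along the chosen axis; the previous/next
#' channels sit at +/- `round(gap_d_mm / voxel_size_mm)` voxels, clamped to
#' the volume boundary (border replication), so the channel count is always
#' three. A gap of 0 yields three identical channels.
#'
#' @param v An [us_volume] (or [label_volume] for label maps).
#' @param direction `"lateral"` or `"elevational"`.
#' @param gap_d_mm Inter-channel gap in mm (>= 0).
#' @return List of `thick_slice` objects: `channels` (H, W, 3),
#'   `gap_d_mm`, `position_index`, `direction`.
#' @export
extract_thick_slices <- function(v, direction = c("lateral", "elevational"),
                                 gap_d_mm = 2.0) {
  direction <- match.arg(direction)
  arr <- vol_data(v)
  ax <- if (direction == "lateral") 1L else 3L
  n <- dim(arr)[ax]
  g <- as.integer(round(gap_d_mm / v$voxel_size_mm))
  if (g < 0) abort("`gap_d_mm` must be >= 0")
  if (g >= n) abort("gap exceeds the volume extent along this direction")
  get_slice <- function(i) {
    if (ax == 1L) arr[i, , ] else arr[, , i]
  }
  lapply(seq_len(n), function(i) {
    idx <- pmin(pmax(c(i - g, i, i + g), 1L), n)
    ch <- array(0, c(dim(arr)[-ax], 3L))
    for (s in 1:3) ch[, , s] <- get_slice(idx[s])
    structure(list(channels = ch, gap_d_mm = gap_d_mm, position_index = i,
                   direction = direction),
              class = "thick_slice")
  })
}

# Label map of the processing (middle) plane of a thick slice.
mask_slice <- function(mask, direction, i) {
  if (direction == "lateral") mask$labels[i, , ] else mask$labels[, , i]
}

#' Rotate a volume around the axial axis
#'
#' Coronal (lateral-elevational) planes rotate in-plane about the volume
#' center; every axial level rotates identically. Used for training-set
#' augmentation.
#'
#' @param v A volume object.
#' @param angle_deg Rotation angle, degrees.
#' @param nearest Use nearest-neighbour interpolation (for label volumes).
#' @return A volume of the same class and geometry.
#' @export
rotate_volume_axial <- function(v, angle_deg, nearest = inherits(v, "label_volume")) {
  arr <- vol_data(v)
  d <- dim(arr)
  a <- angle_deg * pi / 180
  ctr <- (d[c(1, 3)] - 1) / 2
  g <- expand.grid(i = seq_len(d[1]) - 1, k = seq_len(d[3]) - 1)
  di <- g$i - ctr[1]; dk <- g$k - ctr[2]
  src_i <- ctr[1] + cos(a) * di - sin(a) * dk
  src_k <- ctr[2] + sin(a) * di + cos(a) * dk
  out <- array(0, d)
  for (j in seq_len(d[2])) {
    pts <- cbind(src_i, j - 1, src_k)
    out[, j, ] <- nn_trilinear_sample(arr, pts, 0, nearest)
  }
  if (inherits(v, "label_volume"))
    label_volume(array(as.integer(out > 0.5), d), v$voxel_size_mm, v$origin_mm)
  else if (inherits(v, "prob_volume"))
    prob_volume(pmin(pmax(out, 0), 1), v$voxel_size_mm, v$origin_mm)
  else us_volume(out, v$voxel_size_mm, v$origin_mm)
}

#' FCN training configuration
#'
#' @param lr Initial Adam learning rate.
#' @param gap_d_mm Thick-slice gap, mm (2.0 is the reference optimum).
#' @param n_rotations Number of arbitrary-angle axial rotations augmenting
#'   each training volume (the reference uses 10); 0 disables augmentation.
#' @param epochs Training epochs over the balanced slice set.
#' @param max_slices_per_class Optional cap on needle-containing slices kept
#'   per volume and direction (background slices are matched); `Inf` keeps
#'   all.
#' @param crop_size Optional training-window side (pixels). When set, each
#'   training sample is a fixed-size window cropped from the thick slice --
#'   centered near the needle for needle-containing sections, random for
#'   background ones. The network is fully convolutional, so inference
#'   still runs on full cross-sections; cropping only reduces the
#'   per-update cost and improves the pixel class balance. `NULL` trains on
#'   full slices.
#' @param val_fraction Fraction of slices held out for the per-epoch report.
#' @param seed Integer seed.
#' @return An `fcn_train_config`. Batch size is fixed at one sample.
#' @export
fcn_train_config <- function(lr = 1e-4, gap_d_mm = 2.0, n_rotations = 10L,
                             epochs = 1L, max_slices_per_class = Inf,
                             crop_size = NULL, val_fraction = 0.1, seed = 1L) {
  if (gap_d_mm < 0) abort("`gap_d_mm` must be >= 0")
  if (!is.null(crop_size) && crop_size %% 32L != 0L)
    abort("`crop_size` must be a multiple of 32")
  structure(c(as.list(environment()), list(batch_size = 1L)),
            class = "fcn_train_config")
}

# Crop a (H, W, 3) slice and its label map to a window of side `cs`,
# centered near a needle pixel for positive sections (with jitter), random
# for background ones.
crop_slice <- function(x, y, cs, has_needle) {
  d <- dim(x)
  if (d[1] <= cs && d[2] <= cs) return(list(x = x, y = y))
  pick_center <- function() {
    if (has_needle) {
      px <- which(y == 1L, arr.ind = TRUE)
      ctr <- px[sample.int(nrow(px), 1L), ]
      ctr + sample(seq(-cs %/% 4, cs %/% 4), 2L, replace = TRUE)
    } else {
      c(sample.int(d[1], 1L), sample.int(d[2], 1L))
    }
  }
  ctr <- pick_center()
  lo <- pmin(pmax(ctr - cs %/% 2L, 1L), pmax(d[1:2] - cs + 1L, 1L))
  hi <- pmin(lo + cs - 1L, d[1:2])
  list(x = x[lo[1]:hi[1], lo[2]:hi[2], , drop = FALSE],
       y = y[lo[1]:hi[1], lo[2]:hi[2], drop = FALSE])
}

# Build the balanced training slice list from volume/mask pairs.
build_slice_set <- function(dataset, gap_d_mm, n_rotations,
                            max_slices_per_class, crop_size = NULL) {
  slices <- list()
  for (d in dataset) {
    copies <- list(list(v = d$volume, m = d$mask))
    if (n_rotations > 0) {
      angles <- runif(n_rotations, 0, 360)
      for (a in angles)
        copies[[length(copies) + 1L]] <-
          list(v = rotate_volume_axial(d$volume, a),
               m = rotate_volume_axial(d$mask, a))
    }
    for (cp in copies) {
      for (dir in c("lateral", "elevational")) {
        th <- extract_thick_slices(cp$v, dir, gap_d_mm)
        pos_i <- which(vapply(seq_along(th), function(i)
          any(mask_slice(cp$m, dir, i) == 1L), logical(1)))
        neg_i <- setdiff(seq_along(th), pos_i)
        if (!length(pos_i)) next
        if (is.finite(max_slices_per_class) &&
            length(pos_i) > max_slices_per_class)
          pos_i <- sort(sample(pos_i, max_slices_per_class))
        neg_take <- sample(neg_i, min(length(neg_i), length(pos_i)))
        add_one <- function(i, has_needle) {
          x <- th[[i]]$channels
          y <- mask_slice(cp$m, dir, i)
          if (!is.null(crop_size)) {
            cr <- crop_slice(x, y, crop_size, has_needle)
            x <- cr$x; y <- cr$y
          }
          slices[[length(slices) + 1L]] <<-
            list(x = x, y = y, has_needle = has_needle)
        }
        for (i in pos_i) add_one(i, TRUE)
        for (i in neg_take) add_one(i, FALSE)
      }
    }
  }
  slices
}

slice_loss_and_grads <- function(model, sl, training = TRUE) {
  fw <- fcn_forward(model, sl$x, training = training, keep_cache = training)
  hp <- fw$hp; wp <- fw$wp
  y <- matrix(0L, hp, wp)
  y[seq_len(fw$h), seq_len(fw$w)] <- sl$y
  wts <- matrix(0, hp, wp)
  wts[seq_len(fw$h), seq_len(fw$w)] <- 1
  y1 <- cbind(1 - as.vector(y), as.vector(y))
  lo <- ce_loss_rows(fw$prob_full, y1, as.vector(wts))
  out <- list(loss = lo$loss, prob = fw$prob)
  if (training) out$grads <- fcn_backward(model, fw, lo$dlogits)
  out
}

slice_f1 <- function(prob, y, thr = 0.5) {
  pred <- prob > thr
  tp <- sum(pred & y == 1L); fp <- sum(pred & y == 0L)
  fn <- sum(!pred & y == 1L)
  if (tp == 0) return(0)
  p <- tp / (tp + fp); r <- tp / (tp + fn)
  2 * p * r / (p + r)
}

#' Train the thick-slice FCN
#'
#' Trains one shared network on balanced slice sets from both the lateral
#' and elevational directions (SGD, batch size one, Adam, softmax
#' cross-entropy). Slice label maps are the truth mask's intersection with
#' each processing plane. Needle-free cross-sections are downsampled to
#' match the needle-containing ones.
#'
#' @param dataset List of `list(volume, mask)` pairs with truth masks.
#' @param cfg An [fcn_config].
#' @param tcfg An [fcn_train_config].
#' @return An `fcn_fit`: list with `model`, `report` (tibble: epoch, mean
#'   training loss, held-out slice-level F1) and the configs.
#' @export
train_fcn <- function(dataset, cfg = fcn_config(), tcfg = fcn_train_config()) {
  check_patch_dataset(dataset)
  model <- build_fcn(cfg, tcfg$seed)
  with_seed_local(tcfg$seed + 1L, {
    slices <- build_slice_set(dataset, tcfg$gap_d_mm, tcfg$n_rotations,
                              tcfg$max_slices_per_class, tcfg$crop_size)
    if (!length(slices)) abort("no needle-containing slices in the dataset")
    n <- length(slices)
    n_val <- max(1L, floor(tcfg$val_fraction * n))
    perm <- sample.int(n)
    val_i <- perm[seq_len(n_val)]
    tr_i <- perm[-seq_len(n_val)]
    if (!length(tr_i)) { tr_i <- val_i }
    opt <- opt_init(fcn_trainables(model), "adam")
    report <- list()
    for (ep in seq_len(tcfg$epochs)) {
      ord <- tr_i[sample.int(length(tr_i))]
      ep_loss <- 0
      for (s in ord) {
        res <- slice_loss_and_grads(model, slices[[s]], training = TRUE)
        if (!is.finite(res$loss)) abort("FCN training diverged: non-finite loss")
        st <- opt_step(fcn_trainables(model), res$grads, opt, tcfg$lr)
        model <- set_fcn_trainables(model, st$params)
        opt <- st$state
        ep_loss <- ep_loss + res$loss
      }
      f1s <- vapply(val_i, function(s) {
        pr <- fcn_forward(model, slices[[s]]$x)$prob
        slice_f1(pr, slices[[s]]$y)
      }, numeric(1))
      report[[ep]] <- tibble::tibble(
        epoch = ep, loss = ep_loss / length(ord),
        val_slice_f1 = mean(f1s), n_train = length(ord), n_val = n_val)
    }
    structure(list(model = model, report = dplyr::bind_rows(report),
                   cfg = cfg, tcfg = tcfg), class = "fcn_fit")
  })
}

#' @export
print.fcn_fit <- function(x, ...) {
  cat("<fcn_fit>\n")
  print(x$report)
  invisible(x)
}

#' Dense segmentation of a volume along one direction
#'
#' Applies the FCN to every thick slice along the direction and maps each
#' per-slice probability map back onto its position in 3D.
#'
#' @param model An `fcn_model`.
#' @param v An [us_volume].
#' @param direction `"lateral"` or `"elevational"`.
#' @param gap_d_mm Thick-slice gap, mm.
#' @return A [prob_volume] aligned with `v`.
#' @export
segment_direction <- function(model, v, direction = c("lateral", "elevational"),
                              gap_d_mm = 2.0) {
  direction <- match.arg(direction)
  th <- extract_thick_slices(v, direction, gap_d_mm)
  d <- dim(vol_data(v))
  out <- array(0, d)
  for (i in seq_along(th)) {
    pm <- fcn_forward(model, th[[i]]$channels)$prob
    if (direction == "lateral") out[i, , ] <- pm else out[, , i] <- pm
  }
  prob_volume(pmin(pmax(out, 0), 1), v$voxel_size_mm, v$origin_mm)
}

#' Multiplicative fusion of two probability volumes
#'
#' Voxelwise geometric mean `sqrt(p_lat * p_elev)` (the multiplicative
#' analogue of averaging; threshold-equivalent to the raw product, which is
#' available via `method = "product"`). Commutative, bounded in \[0, 1\],
#' idempotent on equal inputs and dominated by either zero.
#'
#' @param p_lat,p_elev [prob_volume]s of identical geometry.
#' @param method `"geometric"` (default) or `"product"`.
#' @return A fused [prob_volume].
#' @export
fuse_multiplicative <- function(p_lat, p_elev,
                                method = c("geometric", "product")) {
  method <- match.arg(method)
  stop_if_geometry_differs(p_lat, p_elev)
  prod <- p_lat$probabilities * p_elev$probabilities
  fused <- if (method == "geometric") sqrt(prod) else prod
  prob_volume(fused, p_lat$voxel_size_mm, p_lat$origin_mm)
}

#' Threshold a probability volume into a label volume
#'
#' @param p A [prob_volume].
#' @param threshold Decision threshold, strictly inside (0, 1).
#' @return A [label_volume] with `label = p > threshold`.
#' @export
binarize <- function(p, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1)
    abort("`threshold` must be strictly inside (0, 1)")
  label_volume(array(as.integer(p$probabilities > threshold), dim(p$probabilities)),
               p$voxel_size_mm, p$origin_mm)
}

#' Segment a volume with both views and fuse
#'
#' Convenience wrapper: lateral + elevational dense segmentation,
#' multiplicative fusion, thresholding.
#'
#' @inheritParams segment_direction
#' @param threshold Decision threshold on the fused probabilities.
#' @return List with `prob` (fused [prob_volume]) and `labels`
#'   (a [label_volume]).
#' @export
segment_volume <- function(model, v, gap_d_mm = 2.0, threshold = 0.5) {
  p_lat <- segment_direction(model, v, "lateral", gap_d_mm)
  p_elev <- segment_direction(model, v, "elevational", gap_d_mm)
  fused <- fuse_multiplicative(p_lat, p_elev)
  list(prob = fused, labels = binarize(fused, threshold))
}

#' Gap-d sweep: thick-slice spacing versus segmentation quality
#'
#' Trains one FCN per candidate gap `d` (including `d = 0`, the
#' single-slice condition: three identical channels) on the training pairs
#' and measures the fused voxel-level F1 on held-out pairs.
#'
#' @param train_pairs,test_pairs Lists of `list(volume, mask)` pairs.
#' @param d_values_mm Gaps to evaluate, mm (reference sweep:
#'   0.5, 1.3, 2.0, 2.7).
#' @param cfg An [fcn_config].
#' @param tcfg An [fcn_train_config]; its `gap_d_mm` is overridden.
#' @return Tibble: `d_mm`, voxel `f1`, `recall`, `precision`, and
#'   `f1_gain` over the `d = 0` condition (NA when 0 is not in the sweep).
#' @export
gap_sweep <- function(train_pairs, test_pairs,
                      d_values_mm = c(0, 0.5, 1.3, 2.0, 2.7),
                      cfg = fcn_config(), tcfg = fcn_train_config()) {
  rows <- purrr::map(d_values_mm, function(d) {
    tc <- tcfg
    tc$gap_d_mm <- d
    fit <- train_fcn(train_pairs, cfg, tc)
    mets <- purrr::map(test_pairs, function(pair) {
      seg <- segment_volume(fit$model, pair$volume, gap_d_mm = d)
      voxel_metrics(seg$labels, pair$mask)
    })
    tibble::tibble(d_mm = d,
                   f1 = mean(vapply(mets, function(m) m$f1, numeric(1))),
                   recall = mean(vapply(mets, function(m) m$recall, numeric(1))),
                   precision = mean(vapply(mets, function(m) m$precision,
                                           numeric(1))))
  })
  out <- dplyr::bind_rows(rows)
  f1_0 <- out$f1[out$d_mm == 0]
  out$f1_gain <- if (length(f1_0)) out$f1 - f1_0[1] else NA_real_
  out
}
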