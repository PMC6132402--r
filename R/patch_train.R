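# Training machinery for the triplanar patch classifier: balanced sampling
# of the ~1:3000-imbalanced voxel population, 90-degree axial-rotation
# augmentation, bootstrap harvesting of hard negatives ("most aggressive"
# non-needle voxels), and the two-phase train/update schedule
# (lr 1e-4 then 1e-5, RMSProp, categorical cross-entropy).

#' Patch-classifier training configuration
#'
#' @param lr_train Initial learning rate for the first (balanced) training
#'   phase.
#' @param lr_update Learning rate for bootstrap update phases; must be
#'   smaller than `lr_train`.
#' @param bootstrap_rounds Number of hard-negative resampling rounds
#'   (>= 0; 0 = plain balanced training).
#' @param per_class_n Patches per class in each balanced set.
#' @param batch_size Minibatch size.
#' @param max_epochs,patience Epoch cap and early-stopping patience on
#'   held-out loss (a 10% split of the balanced set).
#' @param augment Apply random 0/90/180/270 degree rotations around the
#'   axial axis.
#' @param harvest_scan Background voxels scanned per harvesting pass.
#' @param eval_pos_cap,eval_neg_per_pos Size of the per-round evaluation
#'   sample on the held-out volume: up to `eval_pos_cap` needle voxels plus
#'   `eval_neg_per_pos` background voxels per needle voxel.
#' @param seed Integer seed; sampling, initialization and dropout are
#'   deterministic given it.
#' @return A `patch_train_config` object.
#' @export
patch_train_config <- function(lr_train = 1e-4, lr_update = 1e-5,
                               bootstrap_rounds = 1L, per_class_n = 500L,
                               batch_size = 128L, max_epochs = 100L,
                               patience = 5L, augment = TRUE,
                               harvest_scan = 20000L,
                               eval_pos_cap = 2000L, eval_neg_per_pos = 25L,
                               seed = 1L) {
  if (lr_update >= lr_train) abort("`lr_update` must be < `lr_train`")
  if (bootstrap_rounds < 0) abort("`bootstrap_rounds` must be >= 0")
  structure(as.list(environment()), class = "patch_train_config")
}

# dataset: list of list(volume = us_volume, mask = label_volume).
check_patch_dataset <- function(dataset) {
  if (!length(dataset)) abort("empty dataset")
  for (d in dataset) {
    if (!inherits(d$volume, "us_volume") || !inherits(d$mask, "label_volume"))
      abort("dataset entries must be list(volume = us_volume, mask = label_volume)")
    stop_if_geometry_differs(d$volume, d$mask)
  }
  invisible(TRUE)
}

# Load volume/mask pairs referenced by a make_dataset() manifest.
#' Load the volume/mask pairs of a dataset manifest
#'
#' @param manifest Tibble from [make_dataset()] or [read_manifest()].
#' @return List of `list(volume, mask)` pairs in manifest order.
#' @export
load_pairs <- function(manifest) {
  purrr::pmap(list(manifest$volume, manifest$mask), function(vp, mp)
    list(volume = read_volume(vp), mask = as_label_volume(read_volume(mp))))
}

sample_background_centers <- function(dataset, n) {
  vols <- sample.int(length(dataset), n, replace = TRUE)
  centers <- matrix(0L, n, 3)
  for (q in seq_len(n)) {
    m <- dataset[[vols[q]]]$mask$labels
    d <- dim(m)
    repeat {
      c0 <- c(sample.int(d[1], 1), sample.int(d[2], 1), sample.int(d[3], 1))
      if (m[c0[1], c0[2], c0[3]] == 0L) break
    }
    centers[q, ] <- c0
  }
  list(volume_id = vols, centers = centers)
}

positive_index <- function(dataset) {
  purrr::imap(dataset, function(d, i) {
    idx <- which(d$mask$labels == 1L, arr.ind = TRUE)
    if (nrow(idx)) cbind(vol = i, idx) else NULL
  }) |> do.call(what = rbind)
}

#' Sample a balanced, augmented patch training set
#'
#' Draws `per_class_n` needle patches and `per_class_n` uniformly sampled
#' background patches; each patch is optionally rotated by a random multiple
#' of 90 degrees around the axial axis.
#'
#' @param dataset List of `list(volume, mask)` pairs.
#' @param per_class_n Patches per class.
#' @param seed Integer seed (sampling is deterministic given it).
#' @param half_size Patch half-size.
#' @param augment Apply rotation augmentation.
#' @return List with `patches` (side, side, 3, 2n), `labels` (1 = needle),
#'   `volume_id`, `centers`.
#' @export
sample_balanced_training_set <- function(dataset, per_class_n, seed = 1L,
                                         half_size = 10L, augment = TRUE) {
  check_patch_dataset(dataset)
  with_seed_local(seed, {
    pos <- positive_index(dataset)
    if (is.null(pos) || nrow(pos) < per_class_n)
      abort(sprintf("need %d needle voxels but only %d available",
                    per_class_n, if (is.null(pos)) 0L else nrow(pos)))
    sel <- pos[sample.int(nrow(pos), per_class_n), , drop = FALSE]
    neg <- sample_background_centers(dataset, per_class_n)
    vol_id <- c(sel[, 1], neg$volume_id)
    centers <- rbind(sel[, 2:4, drop = FALSE], neg$centers)
    labels <- rep(c(1L, 0L), each = per_class_n)
    side <- 2L * half_size + 1L
    patches <- array(0, c(side, side, 3L, 2L * per_class_n))
    for (q in seq_len(2L * per_class_n)) {
      pl <- extract_triplanar_planes(vol_data(dataset[[vol_id[q]]]$volume),
                                     as.integer(centers[q, ]), half_size)
      if (augment) pl <- rotate_triplanar_90(pl, sample.int(4L, 1) - 1L)
      patches[, , , q] <- pl
    }
    list(patches = patches, labels = labels, volume_id = vol_id,
         centers = centers)
  })
}

#' Harvest hard negatives: background voxels classified as needle
#'
#' Scans a seeded random subsample of background voxels in the training
#' volumes, keeps those the current model calls needle (p > 0.5), ranks
#' them by predicted needle probability and truncates to `limit`.
#'
#' @param model A trained patch model.
#' @param dataset List of `list(volume, mask)` pairs.
#' @param limit Maximum number of hard negatives returned.
#' @param n_scan Background voxels to scan.
#' @param seed Integer seed.
#' @return List with `patches`, `centers`, `volume_id`, `prob` (sorted
#'   decreasing); all empty when the model makes no false positives.
#' @export
harvest_hard_negatives <- function(model, dataset, limit, n_scan = 20000L,
                                   seed = 1L) {
  check_patch_dataset(dataset)
  hs <- model$cfg$half_size
  with_seed_local(seed, {
    cand <- sample_background_centers(dataset, n_scan)
    side <- 2L * hs + 1L
    prob <- numeric(n_scan)
    bs <- 1024L
    for (s in seq(1L, n_scan, by = bs)) {
      e <- min(n_scan, s + bs - 1L)
      batch <- array(0, c(side, side, 3L, e - s + 1L))
      for (q in s:e)
        batch[, , , q - s + 1L] <- extract_triplanar_planes(
          vol_data(dataset[[cand$volume_id[q]]]$volume),
          as.integer(cand$centers[q, ]), hs)
      prob[s:e] <- patch_predict(model, batch)
    }
    hard <- which(prob > 0.5)
    hard <- hard[order(prob[hard], decreasing = TRUE)]
    hard <- head(hard, limit)
    if (!length(hard))
      return(list(patches = array(0, c(side, side, 3L, 0L)),
                  centers = matrix(0L, 0, 3), volume_id = integer(0),
                  prob = numeric(0)))
    patches <- array(0, c(side, side, 3L, length(hard)))
    for (q in seq_along(hard))
      patches[, , , q] <- extract_triplanar_planes(
        vol_data(dataset[[cand$volume_id[hard[q]]]]$volume),
        as.integer(cand$centers[hard[q], ]), hs)
    list(patches = patches, centers = cand$centers[hard, , drop = FALSE],
         volume_id = cand$volume_id[hard], prob = prob[hard])
  })
}

# Minibatch training on a labeled patch set with early stopping on a 10%
# held-out split. Mutates and returns the model.
fit_patch_set <- function(model, patches, labels, lr, batch_size, max_epochs,
                          patience) {
  n <- length(labels)
  n_val <- max(1L, floor(0.1 * n))
  perm <- sample.int(n)
  val_i <- perm[seq_len(n_val)]
  tr_i <- perm[-seq_len(n_val)]
  y1 <- cbind(1 - labels, labels)  # columns: background, needle
  opt <- opt_init(patch_trainables(model), "rmsprop")
  best <- Inf; best_tr <- patch_trainables(model); stall <- 0L
  losses <- numeric(0)
  for (ep in seq_len(max_epochs)) {
    ord <- tr_i[sample.int(length(tr_i))]
    ep_loss <- 0; nb <- 0L
    for (s in seq(1L, length(ord), by = batch_size)) {
      e <- min(length(ord), s + batch_size - 1L)
      sel <- ord[s:e]
      fw <- patch_forward(model, patches[, , , sel, drop = FALSE],
                          training = TRUE, keep_cache = TRUE)
      lo <- ce_loss_rows(fw$probs, y1[sel, , drop = FALSE])
      if (!is.finite(lo$loss))
        abort("patch training diverged: non-finite loss")
      grads <- patch_backward(model, fw$cache, lo$dlogits)
      st <- opt_step(patch_trainables(model), grads, opt, lr)
      model <- set_patch_trainables(model, st$params)
      opt <- st$state
      ep_loss <- ep_loss + lo$loss; nb <- nb + 1L
    }
    pv <- patch_forward(model, patches[, , , val_i, drop = FALSE])$probs
    vl <- ce_loss_rows(pv, y1[val_i, , drop = FALSE])$loss
    losses <- c(losses, vl)
    if (vl < best - 1e-6) {
      best <- vl; best_tr <- patch_trainables(model); stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }
  model <- set_patch_trainables(model, best_tr)
  attr(model, "val_loss") <- best
  model
}

# Precision/recall of the model on a sampled voxel set of one held-out pair.
eval_patch_on_pair <- function(model, pair, eval_pos_cap, eval_neg_per_pos,
                               seed) {
  hs <- model$cfg$half_size
  with_seed_local(seed, {
    pos <- which(pair$mask$labels == 1L, arr.ind = TRUE)
    if (nrow(pos) > eval_pos_cap)
      pos <- pos[sample.int(nrow(pos), eval_pos_cap), , drop = FALSE]
    n_neg <- nrow(pos) * eval_neg_per_pos
    neg <- sample_background_centers(list(pair), n_neg)$centers
    centers <- rbind(pos, neg)
    truth <- rep(c(1L, 0L), c(nrow(pos), nrow(neg)))
    prob <- patch_predict(model,
                          extract_triplanar_batch(pair$volume, centers, hs))
    pred <- as.integer(prob > 0.5)
    tp <- sum(pred == 1L & truth == 1L)
    fp <- sum(pred == 1L & truth == 0L)
    fn <- sum(pred == 0L & truth == 1L)
    tibble::tibble(
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      recall = tp / (tp + fn),
      f1 = if (tp + fp > 0 && tp > 0)
        2 * (tp / (tp + fp)) * (tp / (tp + fn)) /
          ((tp / (tp + fp)) + (tp / (tp + fn))) else 0)
  })
}

#' Train the triplanar patch classifier with bootstrap resampling
#'
#' Performs balanced training at `lr_train`, then `bootstrap_rounds` rounds
#' of: harvest hard negatives with the current model, rebuild a balanced set
#' (fresh positives plus harvested negatives topped up with random ones),
#' and continue training the same weights at `lr_update`. Per-round
#' precision/recall are measured on a held-out volume.
#'
#' @param dataset List of `list(volume, mask)` pairs; the last pair is held
#'   out for reporting (when more than one pair is given).
#' @param model_cfg A [patch_model_config].
#' @param train_cfg A [patch_train_config].
#' @return A `patch_fit`: list with `model` and `report` (tibble with one
#'   row per round: round, phase, val_loss, precision, recall, f1, n_hard).
#' @export
train_patch_classifier <- function(dataset, model_cfg,
                                   train_cfg = patch_train_config()) {
  check_patch_dataset(dataset)
  tc <- train_cfg
  if (length(dataset) >= 2L) {
    report_pair <- dataset[[length(dataset)]]
    train_set <- dataset[-length(dataset)]
  } else {
    report_pair <- dataset[[1L]]
    train_set <- dataset
  }
  model <- build_patch_model(model_cfg, tc$seed)
  ts <- sample_balanced_training_set(train_set, tc$per_class_n, tc$seed,
                                     model_cfg$half_size, tc$augment)
  model <- with_seed_local(tc$seed + 1L,
    fit_patch_set(model, ts$patches, ts$labels, tc$lr_train, tc$batch_size,
                  tc$max_epochs, tc$patience))
  rows <- list(dplyr::bind_cols(
    tibble::tibble(round = 0L, phase = "train",
                   val_loss = attr(model, "val_loss"), n_hard = NA_integer_),
    eval_patch_on_pair(model, report_pair, tc$eval_pos_cap,
                       tc$eval_neg_per_pos, tc$seed + 90L)))
  if (tc$bootstrap_rounds > 0) {
    for (r in seq_len(tc$bootstrap_rounds)) {
      hard <- harvest_hard_negatives(model, train_set, tc$per_class_n,
                                     tc$harvest_scan, tc$seed + 10L * r)
      n_hard <- length(hard$volume_id)
      ts2 <- sample_balanced_training_set(train_set, tc$per_class_n,
                                          tc$seed + 10L * r + 1L,
                                          model_cfg$half_size, tc$augment)
      # replace random negatives by the harvested hard ones
      if (n_hard > 0) {
        neg_slots <- tc$per_class_n + seq_len(min(n_hard, tc$per_class_n))
        ts2$patches[, , , neg_slots] <-
          hard$patches[, , , seq_along(neg_slots), drop = FALSE]
      }
      model <- with_seed_local(tc$seed + 10L * r + 2L,
        fit_patch_set(model, ts2$patches, ts2$labels, tc$lr_update,
                      tc$batch_size, tc$max_epochs, tc$patience))
      rows[[r + 1L]] <- dplyr::bind_cols(
        tibble::tibble(round = r, phase = "update",
                       val_loss = attr(model, "val_loss"), n_hard = n_hard),
        eval_patch_on_pair(model, report_pair, tc$eval_pos_cap,
                           tc$eval_neg_per_pos, tc$seed + 90L))
    }
  }
  structure(list(model = model, report = dplyr::bind_rows(rows),
                 train_cfg = tc), class = "patch_fit")
}

#' @export
print.patch_fit <- function(x, ...) {
  cat("<patch_fit>\n")
  print(x$report)
  invisible(x)
}

#' Classify every voxel of a volume with the patch model
#'
#' Scans the voxel grid at the given stride; unvisited voxels get
#' probability 0. The label volume thresholds the probabilities at 0.5.
#'
#' @param model A trained patch model.
#' @param v An [us_volume].
#' @param stride Positive integer step between scanned voxels.
#' @param batch_size Patches per forward batch.
#' @return List with `prob` (a [prob_volume]) and `labels` (a
#'   [label_volume]).
#' @export
classify_volume_patchwise <- function(model, v, stride = 1L,
                                      batch_size = 1024L) {
  d <- dim(vol_data(v))
  hs <- model$cfg$half_size
  grid <- as.matrix(expand.grid(i = seq(1L, d[1], by = stride),
                                j = seq(1L, d[2], by = stride),
                                k = seq(1L, d[3], by = stride)))
  prob <- array(0, d)
  for (s in seq(1L, nrow(grid), by = batch_size)) {
    e <- min(nrow(grid), s + batch_size - 1L)
    batch <- extract_triplanar_batch(v, grid[s:e, , drop = FALSE], hs)
    prob[grid[s:e, , drop = FALSE]] <- patch_predict(model, batch)
  }
  list(prob = prob_volume(prob, v$voxel_size_mm, v$origin_mm),
       labels = label_volume(array(as.integer(prob > 0.5), d),
                             v$voxel_size_mm, v$origin_mm))
}
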