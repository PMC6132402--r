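test_that("voxel metrics match hand-computed confusion arithmetic", {
  mk <- function(vals) label_volume(array(vals, c(10, 10, 1)), 0.2)
  truth <- array(0L, c(10, 10, 1)); truth[1:5, 1, 1] <- 1L
  pred <- array(0L, c(10, 10, 1)); pred[1:3, 1, 1] <- 1L; pred[6, 1, 1] <- 1L
  m <- voxel_metrics(mk(pred), mk(truth))
  # tp = 3, fp = 1, fn = 2, tn = 94
  expect_equal(m$tp, 3); expect_equal(m$fp, 1)
  expect_equal(m$fn, 2); expect_equal(m$tn, 94)
  expect_equal(m$recall, 0.6)
  expect_equal(m$precision, 0.75)
  expect_equal(m$specificity, 94 / 95)
  expect_equal(m$f1, 2 * 0.75 * 0.6 / (0.75 + 0.6), tolerance = 1e-12)
  expect_equal(m$tp + m$fp + m$tn + m$fn, 100)
  # identity case
  mi <- voxel_metrics(mk(truth), mk(truth))
  expect_equal(unlist(mi[, c("recall", "precision", "specificity", "f1")]),
               c(recall = 1, precision = 1, specificity = 1, f1 = 1))
  # degenerate: nothing predicted -> precision missing, recall 0
  m0 <- voxel_metrics(mk(array(0L, c(10, 10, 1))), mk(truth))
  expect_equal(m0$recall, 0)
  expect_true(is.na(m0$precision))
  expect_true(is.na(m0$f1))
  expect_error(voxel_metrics(mk(truth),
                             label_volume(array(0L, c(5, 5, 1)), 0.2)),
               "shape")
})

test_that("voxel metrics agree with a naive per-voxel loop oracle", {
  set.seed(41)
  d <- c(6, 7, 5)
  t0 <- array(rbinom(prod(d), 1, 0.2), d)
  p0 <- array(rbinom(prod(d), 1, 0.3), d)
  m <- voxel_metrics(label_volume(p0, 0.2), label_volume(t0, 0.2))
  tp <- fp <- tn <- fn <- 0
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    if (p0[i, j, k] == 1 && t0[i, j, k] == 1) tp <- tp + 1
    if (p0[i, j, k] == 1 && t0[i, j, k] == 0) fp <- fp + 1
    if (p0[i, j, k] == 0 && t0[i, j, k] == 0) tn <- tn + 1
    if (p0[i, j, k] == 0 && t0[i, j, k] == 1) fn <- fn + 1
  }
  expect_equal(unlist(m[, c("tp", "fp", "tn", "fn")]),
               c(tp = tp, fp = fp, tn = tn, fn = fn))
  expect_equal(m$recall, tp / (tp + fn))
  expect_equal(m$precision, tp / (tp + fp))
})

test_that("tip error is the point-plane distance", {
  pl <- plane_spec(c(0, 0, 0), c(1, 0, 0))
  expect_equal(tip_error(c(3, 5, -2), pl), 3)
  expect_equal(tip_error(c(0, 7, 1), pl), 0)
  # random plane versus dense-sampling nearest-point oracle
  set.seed(42)
  for (q in 1:5) {
    n <- rnorm(3); n <- n / sqrt(sum(n^2))
    p0 <- rnorm(3)
    pl_q <- plane_spec(p0, n)
    tip <- rnorm(3, sd = 3)
    grid <- as.matrix(expand.grid(u = seq(-15, 15, by = 0.05),
                                  w = seq(-15, 15, by = 0.05)))
    pts <- sweep(grid[, 1] %o% pl_q$in_plane_axes[1, ] +
                   grid[, 2] %o% pl_q$in_plane_axes[2, ], 2, p0, "+")
    oracle <- min(sqrt(rowSums(sweep(pts, 2, tip, "-")^2)))
    expect_equal(tip_error(tip, pl_q), oracle, tolerance = 0.01)
  }
})

test_that("orientation error is symmetric, sign-invariant and bounded", {
  a <- c(1, 0, 0)
  b <- c(0, 1, 0)
  expect_equal(orientation_error(a, a), 0)
  expect_equal(orientation_error(a, -a), 0)
  expect_equal(orientation_error(a, b), 90)
  set.seed(43)
  for (q in 1:20) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    v <- rnorm(3); v <- v / sqrt(sum(v^2))
    e <- orientation_error(u, v)
    expect_equal(e, orientation_error(v, u), tolerance = 1e-12)
    expect_equal(e, orientation_error(-u, v), tolerance = 1e-12)
    expect_gte(e, 0); expect_lte(e, 90)
  }
})

test_that("length-stratified errors produce a tidy table; an oracle detector is exact", {
  base <- phantom_config(shape = c(48, 48, 48), steepness_angle_deg = 12,
                         needle_length_mm = 5, n_distractors = 0,
                         needle_intensity_gain = 10, dropout_fraction = 0,
                         shadow_enabled = FALSE, seed = 1)
  lengths <- c(3, 5, 7)
  # run with a detector that thresholds the bright needle directly
  detector <- function(v) {
    thr <- quantile(v$intensities, 0.999)
    label_volume(array(as.integer(v$intensities > thr), dim(v$intensities)),
                 v$voxel_size_mm, v$origin_mm)
  }
  tbl <- length_stratified_errors(detector, lengths, base,
                                  n_replicates = 2,
                                  ransac_cfg = ransac_config(seed = 5),
                                  seed = 7)
  expect_equal(nrow(tbl), 3L)
  expect_named(tbl, c("length_mm", "n", "n_failed", "eps_t_mean",
                      "eps_t_se", "eps_v_mean", "eps_v_se"))
  ok <- tbl$n_failed < tbl$n
  expect_true(any(ok))
  expect_true(all(tbl$eps_t_mean[ok] < 1))   # bright-needle detector is accurate
  expect_true(all(tbl$eps_v_mean[ok] < 10))
  # a detector that always fails is recorded as missing, not dropped
  none <- function(v) label_volume(array(0L, dim(v$intensities)),
                                   v$voxel_size_mm)
  tbl0 <- length_stratified_errors(none, c(4), base, n_replicates = 2,
                                   seed = 7)
  expect_equal(tbl0$n_failed, 2)
  expect_true(is.nan(tbl0$eps_t_mean) || is.na(tbl0$eps_t_mean))
})

test_that("crossval guards fold structure and averages fold metrics", {
  dir <- tempfile("cv")
  cfgs <- lapply(1:4, function(i)
    phantom_config(shape = c(32, 32, 32), needle_length_mm = 4.4,
                   steepness_angle_deg = 8 + 2 * i,
                   needle_intensity_gain = 10, n_distractors = 0,
                   dropout_fraction = 0, shadow_enabled = FALSE,
                   seed = 60 + i))
  man <- make_dataset(cfgs, dir, n_folds = 2)
  res <- crossval(
    man, method = "patch", k = 2,
    patch_model_cfg = patch_model_config("ShareCNN",
                                         conv_filters = c(3, 4, 6, 8),
                                         fc_sizes = c(16, 8, 2)),
    patch_train_cfg = patch_train_config(lr_train = 1e-3, lr_update = 1e-4,
                                         per_class_n = 120L, max_epochs = 4L,
                                         patience = 2L, bootstrap_rounds = 0L,
                                         seed = 2),
    stride = 3L)
  expect_s3_class(res, "crossval_result")
  expect_equal(nrow(res$per_fold), 2L)
  expect_equal(res$per_fold$n_volumes, c(2L, 2L))
  # pooled means are the arithmetic means of the fold metrics
  expect_equal(res$pooled$recall_mean, mean(res$per_fold$recall),
               tolerance = 1e-12)
  expect_equal(res$pooled$f1_mean, mean(res$per_fold$f1, na.rm = TRUE),
               tolerance = 1e-12)
  expect_s3_class(tidy(res), "tbl_df")
  expect_equal(nrow(glance(res)), 1L)
  # leakage injection must raise a hard error
  man_bad <- man
  man_bad$fold[2] <- man_bad$fold[1]
  man_bad$volume[2] <- man_bad$volume[1]
  man_bad$fold[3] <- 2L
  man_bad$volume[3] <- man_bad$volume[1]
  expect_error(crossval(man_bad, "patch", k = 2), "leakage")
  expect_error(crossval(man, "patch", k = 5), "folds")
})
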