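nf <- asNamespace("needlefinder")

test_that("conv parameter counting follows the bank convention", {
  share <- patch_model_config("ShareCNN")
  indep <- patch_model_config("IndepCNN")
  expect_identical(count_conv_parameters(share), 2160L)
  expect_identical(count_conv_parameters(indep), 6480L)
  one <- patch_model_config("ShareCNN", conv_filters = 1, fc_sizes = c(4, 2))
  expect_identical(count_conv_parameters(one), 9L)
  # conventional weight count includes input depth
  expect_identical(count_conv_weights(one), 9L)
  expect_identical(
    count_conv_weights(share),
    as.integer(9 * (1 * 32 + 32 * 48 + 48 * 64 + 64 * 96)))
  expect_identical(count_conv_weights(indep), 3L * count_conv_weights(share))
})

test_that("triplanar extraction matches a brute-force indexing oracle", {
  set.seed(11)
  arr <- array(rnorm(10 * 11 * 12), c(10, 11, 12))
  v <- us_volume(arr - min(arr), 0.2)
  hs <- 3L
  side <- 2L * hs + 1L
  oracle <- function(center) {
    planes <- array(0, c(side, side, 3))
    for (a in seq_len(side)) for (b in seq_len(side)) {
      i <- center[1] + a - hs - 1L
      j <- center[2] + b - hs - 1L
      k <- center[3] + b - hs - 1L
      jj <- center[2] + a - hs - 1L
      d <- dim(v$intensities)
      inb <- function(ii, dd) ii >= 1 && ii <= dd
      if (inb(i, d[1]) && inb(j, d[2]) && inb(center[3], d[3]))
        planes[a, b, 1] <- v$intensities[i, j, center[3]]
      if (inb(i, d[1]) && inb(center[2], d[2]) && inb(k, d[3]))
        planes[a, b, 2] <- v$intensities[i, center[2], k]
      if (inb(jj, d[2]) && inb(k, d[3]) && inb(center[1], d[1]))
        planes[a, b, 3] <- v$intensities[center[1], jj, k]
    }
    planes
  }
  centers <- rbind(c(5, 6, 7),      # interior
                   c(1, 1, 1),      # corner: zero-padded
                   c(10, 11, 12),   # far corner
                   c(2, 6, 11))
  for (q in seq_len(nrow(centers))) {
    p <- extract_triplanar(v, centers[q, ], hs)
    expect_equal(p$planes, oracle(centers[q, ]), tolerance = 1e-12)
    # center pixel of every tile is the center voxel's value
    expect_equal(unname(p$planes[hs + 1, hs + 1, ]),
                 rep(v$intensities[centers[q, 1], centers[q, 2],
                                   centers[q, 3]], 3))
  }
  # constant volume -> three constant tiles
  vc <- us_volume(array(2.5, c(9, 9, 9)), 0.2)
  pc <- extract_triplanar(vc, c(5, 5, 5), hs)
  expect_true(all(pc$planes == 2.5))
  # ramp volume v[i,j,k] = i: lateral-axial tile rows constant,
  # axial-elevational tile constant at the center's lateral value
  vr <- ramp_volume(9, 0.2)
  pr <- extract_triplanar(vr, c(5, 5, 5), hs)
  expect_true(all(apply(pr$planes[, , 1], 1, sd) == 0))
  expect_true(all(pr$planes[, , 3] == 5))
})

test_that("patch models are softmax-normalized, seeded, and bank-share as claimed", {
  cfg <- patch_model_config("ShareCNN", conv_filters = c(3, 4),
                            fc_sizes = c(8, 6, 2), half_size = 3L)
  m1 <- build_patch_model(cfg, seed = 5)
  m2 <- build_patch_model(cfg, seed = 5)
  m3 <- build_patch_model(cfg, seed = 6)
  patches <- array(rnorm(7 * 7 * 3 * 4), c(7, 7, 3, 4))
  p1 <- nf$patch_forward(m1, patches)$probs
  expect_equal(rowSums(p1), rep(1, 4), tolerance = 1e-12)
  expect_identical(p1, nf$patch_forward(m2, patches)$probs)
  expect_false(identical(p1, nf$patch_forward(m3, patches)$probs))

  # ShareCNN: identical planes give identical pre-concatenation features;
  # IndepCNN does not share banks, so its output reacts to plane order
  same <- array(rep(rnorm(49), 3), c(7, 7, 3, 1))
  fs <- nf$patch_forward(m1, same)$plane_features
  expect_equal(fs[[1]], fs[[2]], tolerance = 1e-12)
  expect_equal(fs[[1]], fs[[3]], tolerance = 1e-12)
  mi <- build_patch_model(
    patch_model_config("IndepCNN", conv_filters = c(3, 4),
                       fc_sizes = c(8, 6, 2), half_size = 3L), seed = 5)
  fi <- nf$patch_forward(mi, same)$plane_features
  expect_false(isTRUE(all.equal(fi[[1]], fi[[2]], tolerance = 1e-8)))
  perm <- patches[, , c(2, 3, 1), , drop = FALSE]
  expect_false(identical(nf$patch_forward(mi, patches)$probs,
                         nf$patch_forward(mi, perm)$probs))
})

test_that("balanced sampling yields equal classes, deterministically", {
  pairs <- list(easy_pair(401), easy_pair(402))
  ts1 <- sample_balanced_training_set(pairs, 50, seed = 3)
  ts2 <- sample_balanced_training_set(pairs, 50, seed = 3)
  ts3 <- sample_balanced_training_set(pairs, 50, seed = 4)
  expect_equal(sum(ts1$labels == 1), 50)
  expect_equal(sum(ts1$labels == 0), 50)
  expect_identical(ts1$centers, ts2$centers)
  expect_identical(ts1$patches, ts2$patches)
  expect_false(identical(ts1$centers, ts3$centers))
  # sampled positives really are needle voxels, negatives background
  for (q in seq_along(ts1$labels)) {
    m <- pairs[[ts1$volume_id[q]]]$mask$labels
    expect_equal(m[ts1$centers[q, 1], ts1$centers[q, 2], ts1$centers[q, 3]],
                 ts1$labels[q])
  }
  expect_error(sample_balanced_training_set(pairs, 1e6, seed = 1),
               "available")
})

test_that("hard-negative harvesting returns only confident false positives", {
  pairs <- list(easy_pair(405))
  cfg <- patch_model_config("ShareCNN", conv_filters = c(2, 3),
                            fc_sizes = c(6, 4, 2), half_size = 3L)
  model <- build_patch_model(cfg, seed = 2)
  h <- harvest_hard_negatives(model, pairs, limit = 40, n_scan = 300,
                              seed = 9)
  if (length(h$prob)) {
    expect_true(all(h$prob > 0.5))
    expect_true(all(diff(h$prob) <= 1e-12))  # ranked decreasing
    expect_lte(length(h$prob), 40)
    for (q in seq_along(h$prob))
      expect_equal(pairs[[h$volume_id[q]]]$mask$labels[
        h$centers[q, 1], h$centers[q, 2], h$centers[q, 3]], 0L)
  }
  # a model forced to predict background everywhere harvests nothing
  model0 <- model
  model0$fc[[3]]$W[] <- 0
  model0$fc[[3]]$b <- c(50, -50)
  h0 <- harvest_hard_negatives(model0, pairs, limit = 40, n_scan = 200,
                               seed = 9)
  expect_length(h0$prob, 0)
  # a model predicting needle everywhere returns the scan limit
  model1 <- model
  model1$fc[[3]]$W[] <- 0
  model1$fc[[3]]$b <- c(-50, 50)
  h1 <- harvest_hard_negatives(model1, pairs, limit = 40, n_scan = 200,
                               seed = 9)
  expect_length(h1$prob, 40)
})

test_that("classify_volume_patchwise visits the stride grid and stays in [0,1]", {
  cfg <- patch_model_config("ShareCNN", conv_filters = c(2, 3),
                            fc_sizes = c(6, 4, 2), half_size = 3L)
  model <- build_patch_model(cfg, seed = 2)
  v <- us_volume(array(abs(rnorm(12^3)), c(12, 12, 12)), 0.2)
  out <- classify_volume_patchwise(model, v, stride = 3L)
  visited <- out$prob$probabilities[seq(1, 12, 3), seq(1, 12, 3), seq(1, 12, 3)]
  expect_true(all(visited > 0 & visited < 1))
  unvisited_mask <- array(TRUE, c(12, 12, 12))
  unvisited_mask[seq(1, 12, 3), seq(1, 12, 3), seq(1, 12, 3)] <- FALSE
  expect_true(all(out$prob$probabilities[unvisited_mask] == 0))
  expect_identical(out$labels$labels,
                   array(as.integer(out$prob$probabilities > 0.5),
                         c(12, 12, 12)))
})

test_that("a trained classifier detects the needle in an easy high-gain phantom", {
  fit <- patch_smoke_fit()
  # training report: one row per round, precision/recall present
  expect_equal(fit$report$round, c(0L, 1L))
  expect_true(all(is.finite(fit$report$recall)))
  held_out <- easy_pair(777, 4.5, 12)
  cl <- classify_volume_patchwise(fit$model, held_out$volume, stride = 1L)
  m <- voxel_metrics(cl$labels, held_out$mask)
  expect_gt(m$f1, 0.5)
  ax <- ransac_fit(cl$labels, ransac_config(seed = 2))
  expect_true(is_needle_found(ax))
  expect_lt(tip_error(held_out$truth$tip_mm, needle_plane(ax)), 1)
  expect_lt(orientation_error(ax$direction, held_out$truth$axis_direction),
            10)
})

test_that("rotation augmentation permutes tiles consistently", {
  set.seed(12)
  planes <- array(rnorm(7 * 7 * 3), c(7, 7, 3))
  r4 <- nf$rotate_triplanar_90(nf$rotate_triplanar_90(planes, 2), 2)
  expect_equal(r4, planes, tolerance = 1e-12)
  r0 <- nf$rotate_triplanar_90(planes, 0)
  expect_identical(r0, planes)
  r1 <- nf$rotate_triplanar_90(planes, 1)
  expect_equal(r1[, , 1], t(planes[, , 3]), tolerance = 1e-12)
})
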