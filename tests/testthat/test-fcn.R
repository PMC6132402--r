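nf <- asNamespace("needlefinder")

test_that("thick-slice extraction clamps neighbours and honours the gap", {
  v <- ramp_volume(12, 0.2)
  th <- extract_thick_slices(v, "lateral", gap_d_mm = 0)
  expect_length(th, 12L)
  for (sl in th[c(1, 6, 12)]) {
    expect_equal(sl$channels[, , 1], sl$channels[, , 2])
    expect_equal(sl$channels[, , 2], sl$channels[, , 3])
  }
  # gap 2.0 mm at 0.2 mm/voxel -> neighbour offset 10 voxels; on the
  # lateral ramp the channel values identify the source slice index
  th2 <- extract_thick_slices(v, "lateral", gap_d_mm = 2.0)
  sl <- th2[[11]]
  expect_true(all(sl$channels[, , 1] == 1))   # 11 - 10
  expect_true(all(sl$channels[, , 2] == 11))
  expect_true(all(sl$channels[, , 3] == 12))  # 21 clamped to 12
  expect_equal(sl$position_index, 11L)
  # elevational direction slices have (lateral x axial) shape
  the <- extract_thick_slices(v, "elevational", gap_d_mm = 0.4)
  expect_equal(dim(the[[5]]$channels), c(12, 12, 3))
  expect_equal(the[[5]]$channels[, , 2], v$intensities[, , 5])
  expect_error(extract_thick_slices(v, "lateral", gap_d_mm = 5), "extent")
})

test_that("the FCN maps inputs to same-size normalized probability maps", {
  cfg <- fcn_config(width_scale = 0.05, dropout_p = 0, normalize = "none")
  expect_equal(prod(cfg$unpool_factors), 32)
  m <- build_fcn(cfg, seed = 1)
  m2 <- build_fcn(cfg, seed = 1)
  x <- array(abs(rnorm(64 * 32 * 3)), c(64, 32, 3))
  fw <- nf$fcn_forward(m, x)
  expect_equal(dim(fw$prob), c(64, 32))
  expect_true(all(fw$prob >= 0 & fw$prob <= 1))
  expect_equal(rowSums(fw$prob_full), rep(1, nrow(fw$prob_full)),
               tolerance = 1e-12)
  expect_identical(fw$prob, nf$fcn_forward(m2, x)$prob)
  # non-multiples of 32 are padded and cropped internally
  x2 <- array(abs(rnorm(24 * 40 * 3)), c(24, 40, 3))
  expect_equal(dim(nf$fcn_forward(m, x2)$prob), c(24, 40))
  # the nearest x8 decoder alternative also preserves shape
  mn <- build_fcn(fcn_config(width_scale = 0.05, dropout_p = 0,
                             final_upsample = "nearest",
                             normalize = "none"), seed = 1)
  expect_equal(dim(nf$fcn_forward(mn, x2)$prob), c(24, 40))
})

test_that("segment_direction is exactly slice-consistent", {
  cfg <- fcn_config(width_scale = 0.05, dropout_p = 0)
  m <- build_fcn(cfg, seed = 2)
  v <- us_volume(array(abs(rnorm(32 * 32 * 8)), c(32, 32, 8)), 0.2)
  p <- segment_direction(m, v, "elevational", gap_d_mm = 0.4)
  expect_identical(dim(p$probabilities), dim(v$intensities))
  th <- extract_thick_slices(v, "elevational", 0.4)
  for (k in c(1L, 4L, 8L))
    expect_equal(p$probabilities[, , k],
                 nf$fcn_forward(m, th[[k]]$channels)$prob,
                 tolerance = 1e-12)
  p2 <- segment_direction(m, v, "lateral", gap_d_mm = 0.4)
  th2 <- extract_thick_slices(v, "lateral", 0.4)
  expect_equal(p2$probabilities[5, , ],
               nf$fcn_forward(m, th2[[5]]$channels)$prob, tolerance = 1e-12)
})

test_that("multiplicative fusion has the geometric-mean properties", {
  set.seed(13)
  mk <- function(a) prob_volume(array(a, c(4, 4, 4)), 0.2)
  p <- array(runif(64), c(4, 4, 4))
  q <- array(runif(64), c(4, 4, 4))
  pa <- mk(p); qa <- mk(q)
  fused <- fuse_multiplicative(pa, qa)
  expect_equal(fused$probabilities, sqrt(p * q), tolerance = 1e-12)
  # commutative, idempotent, zero-dominated, bounded
  expect_equal(fuse_multiplicative(qa, pa)$probabilities,
               fused$probabilities, tolerance = 1e-12)
  expect_equal(fuse_multiplicative(pa, pa)$probabilities, p,
               tolerance = 1e-12)
  z <- mk(0)
  expect_true(all(fuse_multiplicative(pa, z)$probabilities == 0))
  expect_true(all(fused$probabilities >= 0 & fused$probabilities <= 1))
  half <- mk(0.5)
  expect_equal(fuse_multiplicative(half, half)$probabilities[1], 0.5)
  # product alternative is threshold-equivalent through a square
  expect_equal(fuse_multiplicative(pa, qa, "product")$probabilities,
               fused$probabilities^2, tolerance = 1e-12)
  expect_error(fuse_multiplicative(pa, prob_volume(array(0.5, c(3, 3, 3)),
                                                   0.2)), "shape")
})

test_that("binarize validates its threshold and is monotone", {
  set.seed(14)
  p <- prob_volume(array(runif(125), c(5, 5, 5)), 0.2)
  expect_error(binarize(p, 0), "strictly")
  expect_error(binarize(p, 1), "strictly")
  expect_true(all(binarize(prob_volume(array(0.4, c(3, 3, 3)), 0.2),
                           0.5)$labels == 0))
  thrs <- sort(runif(5, 0.05, 0.95))
  counts <- vapply(thrs, function(t) sum(binarize(p, t)$labels), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("axial rotation preserves geometry and rotates coronal planes", {
  v <- ramp_volume(16, 0.2)
  r90 <- rotate_volume_axial(v, 90)
  expect_identical(dim(r90), dim(v))
  # rotating a lateral ramp by 90 degrees makes it an elevational ramp:
  # constant across the lateral index within the rotated interior
  inner <- 5:12
  expect_lt(max(apply(r90$intensities[inner, 1, inner], 2, sd)), 1e-6)
  r0 <- rotate_volume_axial(v, 0)
  expect_equal(r0$intensities[inner, , inner],
               v$intensities[inner, , inner], tolerance = 1e-9)
  # label volumes stay binary
  lab <- label_volume(array(rbinom(16^3, 1, 0.1), c(16, 16, 16)), 0.2)
  rl <- rotate_volume_axial(lab, 37)
  expect_true(all(rl$labels %in% c(0L, 1L)))
})

test_that("train_fcn balances slice classes and reports per epoch", {
  # short needles in larger volumes, so background slices are plentiful
  pairs <- list(phantom_pair(501, shape = c(48, 48, 48), length_mm = 3,
                             dropout = 0, distractors = 0, gain = 10),
                phantom_pair(502, shape = c(48, 48, 48), length_mm = 3,
                             steep = 18, dropout = 0, distractors = 0,
                             gain = 10))
  nfcfg <- fcn_config(width_scale = 0.05, dropout_p = 0)
  slices <- local({
    set.seed(99)
    nf$build_slice_set(pairs, gap_d_mm = 0.4, n_rotations = 0,
                       max_slices_per_class = Inf)
  })
  n_pos <- sum(vapply(slices, function(s) s$has_needle, logical(1)))
  n_neg <- sum(!vapply(slices, function(s) s$has_needle, logical(1)))
  expect_equal(n_pos, n_neg)
  # rotation augmentation multiplies the volume copies
  slices_aug <- local({
    set.seed(99)
    nf$build_slice_set(pairs[1], gap_d_mm = 0.4, n_rotations = 2,
                       max_slices_per_class = 4)
  })
  expect_gt(length(slices_aug), length(local({
    set.seed(99)
    nf$build_slice_set(pairs[1], gap_d_mm = 0.4, n_rotations = 0,
                       max_slices_per_class = 4)
  })))
  fit <- train_fcn(pairs, nfcfg,
                   fcn_train_config(lr = 3e-4, epochs = 2, n_rotations = 0,
                                    max_slices_per_class = 3,
                                    crop_size = 32L, seed = 1))
  expect_equal(nrow(fit$report), 2L)
  expect_true(all(is.finite(fit$report$loss)))
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(glance(fit)), 1L)
  # a dataset with no needle-containing slices errors
  empty <- list(list(volume = pairs[[1]]$volume,
                     mask = label_volume(array(0L, dim(pairs[[1]]$mask$labels)),
                                         0.2)))
  expect_error(train_fcn(empty, nfcfg, fcn_train_config(epochs = 1)),
               "needle")
})
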