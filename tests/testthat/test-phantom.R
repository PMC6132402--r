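test_that("rasterize_cylinder matches a brute-force distance scan", {
  grid <- us_volume(array(0, c(20, 20, 20)), 0.5)
  entry <- c(1.2, 2.1, 3.3)
  dirn <- c(2, 1, 0.5)
  dirn <- dirn / sqrt(sum(dirn^2))
  L <- 6
  dia <- 1.6
  mask <- rasterize_cylinder(entry, dirn, L, dia, grid)
  # exhaustive oracle over every voxel center
  idx <- as.matrix(expand.grid(i = 1:20, j = 1:20, k = 1:20))
  ctr <- voxel_centers_mm(grid, idx)
  rel <- sweep(ctr, 2, entry, "-")
  t_ax <- pmin(pmax(rel %*% dirn, 0), L)
  d <- sqrt(rowSums((rel - t_ax %*% t(dirn))^2))
  oracle <- array(0L, c(20, 20, 20))
  oracle[idx[d <= dia / 2, , drop = FALSE]] <- 1L
  expect_identical(mask$labels, oracle)
  expect_gt(sum(mask$labels), 0)
})

test_that("rasterize_cylinder handles axis-aligned and degenerate cases", {
  grid <- us_volume(array(0, c(12, 12, 12)), 0.2)
  # radius = half voxel, axis through a row of voxel centers
  m <- rasterize_cylinder(c(0.1, 1.1, 1.1), c(1, 0, 0), 1.6, 0.2, grid)
  pos <- which(m$labels == 1L, arr.ind = TRUE)
  expect_true(all(pos[, 2] == 6L & pos[, 3] == 6L))
  expect_equal(nrow(pos), 9L)  # centers at t = 0, 0.2, ..., 1.6
  expect_error(rasterize_cylinder(c(0, 0, 0), c(1, 0, 0), 0, 1, grid),
               "length")
  expect_error(rasterize_cylinder(c(0, 0, 0), c(2, 0, 0), 1, 1, grid),
               "unit")
})

test_that("phantom generation is deterministic and leaves RNG untouched", {
  cfg <- phantom_config(shape = c(24, 24, 24), needle_length_mm = 3,
                        steepness_angle_deg = 15, seed = 4)
  set.seed(123)
  ph1 <- generate_phantom(cfg)
  after1 <- runif(1)
  set.seed(123)
  ph2 <- generate_phantom(cfg)
  after2 <- runif(1)
  expect_identical(ph1$volume$intensities, ph2$volume$intensities)
  expect_identical(ph1$truth$mask$labels, ph2$truth$mask$labels)
  expect_identical(after1, after2)
})

test_that("phantom truth is self-consistent (mask within cylinder, tip identity)", {
  cfg <- phantom_config(shape = c(40, 40, 40), needle_length_mm = 5,
                        steepness_angle_deg = 25, horizontal_angle_deg = 10,
                        dropout_fraction = 0.3, seed = 8)
  ph <- generate_phantom(cfg)
  tr <- ph$truth
  expect_equal(tr$tip_mm, tr$axis_entry_mm + tr$length_mm * tr$axis_direction,
               tolerance = 1e-9)
  idx <- which(tr$mask$labels == 1L, arr.ind = TRUE)
  ctr <- voxel_centers_mm(tr$mask, idx)
  rel <- sweep(ctr, 2, tr$axis_entry_mm, "-")
  t_ax <- pmin(pmax(rel %*% tr$axis_direction, 0), tr$length_mm)
  d <- sqrt(rowSums((rel - t_ax %*% t(tr$axis_direction))^2))
  expect_true(all(d <= cfg$needle_diameter_mm / 2 + 1e-9))
})

test_that("high-gain needle voxels exceed the background's 99th percentile", {
  cfg <- phantom_config(shape = c(40, 40, 40), needle_length_mm = 5,
                        steepness_angle_deg = 12,
                        needle_intensity_gain = 10, n_distractors = 0,
                        dropout_fraction = 0, shadow_enabled = FALSE,
                        seed = 3)
  ph <- generate_phantom(cfg)
  bg <- ph$volume$intensities[ph$truth$mask$labels == 0]
  nd <- ph$volume$intensities[ph$truth$mask$labels == 1]
  expect_gt(min(nd), quantile(bg, 0.99))
})

test_that("dropout hides shaft voxels and shadow darkens below the needle", {
  base <- phantom_config(shape = c(48, 48, 48), needle_length_mm = 7,
                         steepness_angle_deg = 10, n_distractors = 0,
                         needle_intensity_gain = 10, shadow_enabled = FALSE,
                         seed = 21)
  drop_cfg <- base
  drop_cfg$dropout_fraction <- 0.5
  ph0 <- generate_phantom(base)
  ph1 <- generate_phantom(drop_cfg)
  # masks identical (annotation covers invisible parts too)
  expect_identical(ph0$truth$mask$labels, ph1$truth$mask$labels)
  on_needle0 <- ph0$volume$intensities[ph0$truth$mask$labels == 1]
  on_needle1 <- ph1$volume$intensities[ph1$truth$mask$labels == 1]
  # with 50% contiguous dropout, a good fraction of shaft voxels are dim
  frac_bright0 <- mean(on_needle0 > quantile(ph0$volume$intensities, 0.95))
  frac_bright1 <- mean(on_needle1 > quantile(ph1$volume$intensities, 0.95))
  expect_lt(frac_bright1, frac_bright0 - 0.2)

  shadow_cfg <- base
  shadow_cfg$shadow_enabled <- TRUE
  shadow_cfg$shadow_attenuation <- 0.3
  ph2 <- generate_phantom(shadow_cfg)
  mask <- ph2$truth$mask$labels
  cols <- which(apply(mask, c(1, 3), sum) > 0, arr.ind = TRUE)
  below0 <- below2 <- numeric(0)
  for (q in seq_len(nrow(cols))) {
    i <- cols[q, 1]; k <- cols[q, 2]
    j_max <- max(which(mask[i, , k] == 1L))
    if (j_max < 48) {
      below0 <- c(below0, ph0$volume$intensities[i, (j_max + 1):48, k])
      below2 <- c(below2, ph2$volume$intensities[i, (j_max + 1):48, k])
    }
  }
  expect_lt(mean(below2), 0.6 * mean(below0))
})

test_that("background speckle is right-skewed and decorrelates within 10 voxels", {
  cfg <- phantom_config(shape = c(48, 48, 48), needle_length_mm = 5,
                        steepness_angle_deg = 10, n_distractors = 0,
                        shadow_enabled = FALSE, seed = 5)
  ph <- generate_phantom(cfg)
  bg <- ph$volume$intensities[ph$truth$mask$labels == 0]
  skew <- mean((bg - mean(bg))^3) / sd(bg)^3
  expect_gt(skew, 0)
  # correlation measured on a needle-free elevational slab, so the bright
  # shaft does not leak into the texture statistics
  free_k <- which(apply(ph$truth$mask$labels, 3, sum) == 0)
  slab <- ph$volume$intensities[, , free_k]
  lag1 <- cor(as.vector(slab[1:47, , ]), as.vector(slab[2:48, , ]))
  lag10 <- cor(as.vector(slab[1:38, , ]), as.vector(slab[11:48, , ]))
  expect_gt(lag1, 0.3)          # speckle has finite grain
  expect_lt(lag10, 0.3)         # but decorrelates within 10 voxels
  expect_lt(lag10, lag1 / 2)
})

test_that("full-size phantoms reproduce the ~1:3000 needle:background imbalance", {
  # average over the two needle gauges at maximum insertion, as the
  # imbalance is quoted as a dataset-wide average
  ratios <- vapply(c(1.47, 0.72), function(dia) {
    ph <- generate_phantom(phantom_config(
      shape = c(174, 189, 188), voxel_size_mm = 0.2,
      needle_diameter_mm = dia, needle_length_mm = 30,
      steepness_angle_deg = 20, n_distractors = 0, seed = 61))
    mean(ph$truth$mask$labels)
  }, numeric(1))
  avg <- mean(ratios)
  expect_gt(avg, 1 / 3000 / 3)
  expect_lt(avg, 3 / 3000)
})

test_that("an unfittable needle raises a configuration error", {
  cfg <- phantom_config(shape = c(16, 16, 16), needle_length_mm = 50,
                        seed = 1)
  expect_error(generate_phantom(cfg), "fit")
})

test_that("make_dataset writes volume-disjoint folds and reloads identically", {
  dir <- tempfile("ds")
  cfgs <- lapply(1:5, function(i)
    phantom_config(shape = c(20, 20, 20), voxel_size_mm = 0.4,
                   needle_length_mm = 2.5,
                   steepness_angle_deg = 10, n_distractors = 1,
                   seed = 10 + i))
  man <- make_dataset(cfgs, dir, n_folds = 5)
  expect_equal(nrow(man), 5L)
  expect_equal(sort(unique(man$fold)), 1:5)
  expect_equal(as.integer(table(man$fold)), rep(1L, 5))
  expect_true(all(file.exists(man$volume)))
  reload <- read_manifest(file.path(dir, "manifest.json"))
  expect_identical(reload$fold, man$fold)
  expect_identical(reload$volume, man$volume)

  # 10 volumes over 5 folds -> folds of size 2, volume-disjoint
  cfgs10 <- lapply(1:10, function(i)
    phantom_config(shape = c(20, 20, 20), voxel_size_mm = 0.4,
                   needle_length_mm = 2.5,
                   steepness_angle_deg = 10, n_distractors = 1,
                   seed = 100 + i))
  man10 <- make_dataset(cfgs10, tempfile("ds"), n_folds = 5)
  expect_equal(as.integer(table(man10$fold)), rep(2L, 5))
  expect_false(any(duplicated(man10$volume)))

  expect_error(make_dataset(cfgs[1:3], tempfile("ds"), n_folds = 5), ">= 5")
  expect_warning(make_dataset(c(cfgs, cfgs[1]), tempfile("ds"), n_folds = 5),
                 "duplicate")
})
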