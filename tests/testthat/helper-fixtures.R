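# Shared fixtures. Heavy trained models are built lazily once per test run
# and cached in this environment so that several tests can share them.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# Small deterministic ramp volume: v[i, j, k] = i.
ramp_volume <- function(n = 8L, voxel = 0.5) {
  arr <- array(0, c(n, n, n))
  for (i in seq_len(n)) arr[i, , ] <- i
  us_volume(arr, voxel)
}

# Moderate-difficulty phantom pair (17 G, distractors), used by the
# training suites.
phantom_pair <- function(seed, shape = c(64, 64, 64), length_mm = 10.4,
                         steep = 14, horiz = 0, dropout = 0.1,
                         distractors = 4, diameter = 1.47, gain = 3,
                         voxel = 0.2) {
  cfg <- phantom_config(
    shape = shape, voxel_size_mm = voxel, needle_diameter_mm = diameter,
    needle_length_mm = length_mm, steepness_angle_deg = steep,
    horizontal_angle_deg = horiz, needle_intensity_gain = gain,
    dropout_fraction = dropout, n_distractors = distractors, seed = seed)
  ph <- generate_phantom(cfg)
  list(volume = ph$volume, mask = ph$truth$mask, truth = ph$truth)
}

# Suite used by the FCN learning tests: ~10 small 17 G phantoms with mixed
# angles and mild dropout at 0.2 mm voxels (needle lengths >= 10 mm).
fcn_suite <- function(seed0, n = 8L) {
  lapply(seq_len(n), function(i) phantom_pair(
    seed = seed0 + i, length_mm = 10 + (i %% 3) * 0.4,
    steep = 8 + (i * 5) %% 13, horiz = -12 + (i * 9) %% 25,
    dropout = 0.1, distractors = 4))
}

fcn_smoke_fit <- function(seed) {
  fixture(paste0("fcn_fit_", seed), function() {
    train_pairs <- fcn_suite(100 + seed)
    fit <- train_fcn(
      train_pairs,
      fcn_config(width_scale = 0.125, dropout_p = 0),
      fcn_train_config(lr = 3e-4, epochs = 15L, n_rotations = 0L,
                       max_slices_per_class = 10L, crop_size = 32L,
                       seed = seed))
    test_pairs <- lapply(1:2, function(i) phantom_pair(
      seed = 900 + seed + i, length_mm = 10 + (i %% 3) * 0.4,
      steep = 8 + (i * 5) %% 13, horiz = -12 + (i * 9) %% 25,
      dropout = 0.1, distractors = 4))
    evals <- lapply(test_pairs, function(pair) {
      seg <- segment_volume(fit$model, pair$volume)
      ax <- ransac_fit(seg$labels, ransac_config(seed = 1))
      list(metrics = voxel_metrics(seg$labels, pair$mask),
           eps_t = if (is_needle_found(ax))
             tip_error(pair$truth$tip_mm, needle_plane(ax)) else NA_real_,
           eps_v = if (is_needle_found(ax))
             orientation_error(ax$direction, pair$truth$axis_direction)
           else NA_real_)
    })
    list(fit = fit, evals = evals)
  })
}

# Easy high-gain suite for the patch classifier: small volumes, bright
# needle, no distractors.
easy_pair <- function(seed, length_mm = 4.5, steep = 12) {
  phantom_pair(seed, shape = c(32, 32, 32), length_mm = length_mm,
               steep = steep, dropout = 0, distractors = 0, gain = 10)
}

patch_smoke_fit <- function() {
  fixture("patch_fit_easy", function() {
    pairs <- list(easy_pair(301, 4.2, 8), easy_pair(302, 4.4, 14),
                  easy_pair(303, 4.6, 11))
    train_patch_classifier(
      pairs,
      patch_model_config("ShareCNN", conv_filters = c(4, 6, 8, 12),
                         fc_sizes = c(32, 16, 2)),
      patch_train_config(lr_train = 1e-3, lr_update = 1e-4,
                         per_class_n = 250L, max_epochs = 10L,
                         patience = 3L, bootstrap_rounds = 1L,
                         harvest_scan = 4000L, seed = 1L))
  })
}

# Bootstrap suite: moderate phantoms with distractors (48^3, 17 G).
bootstrap_fit <- function(seed) {
  fixture(paste0("bootstrap_fit_", seed), function() {
    pairs <- lapply(1:3, function(i) phantom_pair(
      seed = 200 + seed + i, shape = c(48, 48, 48),
      length_mm = 7 + (i %% 3) * 0.4, steep = 8 + (i * 5) %% 13,
      horiz = -12 + (i * 9) %% 25, dropout = 0, distractors = 4))
    train_patch_classifier(
      pairs,
      patch_model_config("ShareCNN", conv_filters = c(4, 6, 8, 12),
                         fc_sizes = c(32, 16, 2)),
      patch_train_config(lr_train = 1e-3, lr_update = 1e-4,
                         per_class_n = 250L, max_epochs = 6L, patience = 2L,
                         bootstrap_rounds = 1L, harvest_scan = 4000L,
                         eval_pos_cap = 300L, eval_neg_per_pos = 25L,
                         seed = seed))
  })
}
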