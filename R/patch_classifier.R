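# Triplanar orthogonal-patch voxel classifier. Each voxel is described by
# three orthogonal 21 x 21 cross-sections centered on it (lateral-axial,
# lateral-elevational, axial-elevational). ShareCNN convolves all three
# planes with one shared filter bank; IndepCNN trains three independent
# banks. Feature maps are concatenated before the fully connected stages.
# No pooling: four valid 3x3 convolutions take 21 -> 19 -> 17 -> 15 -> 13.

#' Patch-model architecture configuration
#'
#' Defaults follow the reference architecture: four convolutional layers of
#' 32, 48, 64 and 96 filters with 3 x 3 kernels, fully connected stages of
#' 128, 64 and 2 neurons, ReLU activations, dropout 0.5 on the first two
#' fully connected stages, softmax output.
#'
#' @param variant `"ShareCNN"` (one shared filter bank) or `"IndepCNN"`
#'   (three independent banks, one per plane).
#' @param conv_filters Filter counts of the convolutional layers.
#' @param kernel Convolution kernel side (square).
#' @param fc_sizes Fully connected layer sizes; last entry must be 2.
#' @param dropout_p Dropout probability on the first two FC stages.
#' @param half_size Patch half-size; tiles are `2 * half_size + 1` square.
#' @return A `patch_model_config` object.
#' @export
patch_model_config <- function(variant = c("ShareCNN", "IndepCNN"),
                               conv_filters = c(32, 48, 64, 96),
                               kernel = 3L,
                               fc_sizes = c(128, 64, 2),
                               dropout_p = 0.5,
                               half_size = 10L) {
  variant <- match.arg(variant)
  if (tail(fc_sizes, 1) != 2) abort("final FC stage must have 2 neurons")
  side <- 2L * half_size + 1L
  final_side <- side - length(conv_filters) * (kernel - 1L)
  if (final_side < 1L) abort("too many valid convolutions for this patch size")
  structure(list(variant = variant, conv_filters = as.integer(conv_filters),
                 kernel = as.integer(kernel), fc_sizes = as.integer(fc_sizes),
                 dropout_p = dropout_p, half_size = as.integer(half_size),
                 final_side = as.integer(final_side)),
            class = "patch_model_config")
}

#' Convolutional-layer parameter counts of a patch architecture
#'
#' `count_conv_parameters()` uses the input-depth-independent convention:
#' the sum over convolutional layers of filters x kernel area, multiplied by
#' the number of filter banks (1 for ShareCNN, 3 for IndepCNN); biases and
#' input depth are excluded. Under this convention the default ShareCNN and
#' IndepCNN architectures count 2160 and 6480 parameters.
#' `count_conv_weights()` is the conventional weight count
#' (kernel area x input channels x filters, summed, times banks).
#'
#' @param cfg A [patch_model_config].
#' @return Integer parameter count.
#' @export
count_conv_parameters <- function(cfg) {
  stopifnot(inherits(cfg, "patch_model_config"))
  banks <- if (cfg$variant == "IndepCNN") 3L else 1L
  as.integer(banks * sum(cfg$conv_filters * cfg$kernel^2))
}

#' @rdname count_conv_parameters
#' @export
count_conv_weights <- function(cfg) {
  stopifnot(inherits(cfg, "patch_model_config"))
  banks <- if (cfg$variant == "IndepCNN") 3L else 1L
  cin <- c(1L, head(cfg$conv_filters, -1))
  as.integer(banks * sum(cfg$kernel^2 * cin * cfg$conv_filters))
}

#' Extract the three orthogonal patches centered on a voxel
#'
#' Tiles are `2 * half_size + 1` square; samples falling outside the volume
#' are zero-padded, so any center index (even at a corner) is valid. Tile 1
#' is the lateral-axial plane, tile 2 lateral-elevational, tile 3
#' axial-elevational; the center voxel's value appears at the center pixel
#' of every tile.
#'
#' @param v An [us_volume].
#' @param center Integer 3-vector, 1-based voxel index.
#' @param half_size Patch half-size (default 10, i.e. 21 x 21 tiles).
#' @return A `triplanar_patch`: list with `planes` (side x side x 3 array),
#'   `center_index`, and optional `label`.
#' @export
extract_triplanar <- function(v, center, half_size = 10L) {
  planes <- extract_triplanar_planes(vol_data(v), as.integer(center),
                                     as.integer(half_size))
  structure(list(planes = planes, center_index = as.integer(center),
                 label = NULL),
            class = "triplanar_patch")
}

# Core tile extraction on a raw array; shared by single and batch paths.
extract_triplanar_planes <- function(arr, center, half_size) {
  side <- 2L * half_size + 1L
  d <- dim(arr)
  rng <- lapply(1:3, function(a) (center[a] - half_size):(center[a] + half_size))
  ok <- lapply(1:3, function(a) rng[[a]] >= 1L & rng[[a]] <= d[a])
  cl <- lapply(1:3, function(a) rng[[a]][ok[[a]]])
  planes <- array(0, c(side, side, 3))
  # tile 1: lateral-axial at fixed elevational index
  if (center[3] >= 1L && center[3] <= d[3])
    planes[ok[[1]], ok[[2]], 1] <- arr[cl[[1]], cl[[2]], center[3]]
  # tile 2: lateral-elevational at fixed axial index
  if (center[2] >= 1L && center[2] <= d[2])
    planes[ok[[1]], ok[[3]], 2] <- arr[cl[[1]], center[2], cl[[3]]]
  # tile 3: axial-elevational at fixed lateral index
  if (center[1] >= 1L && center[1] <= d[1])
    planes[ok[[2]], ok[[3]], 3] <- arr[center[1], cl[[2]], cl[[3]]]
  planes
}

# Batch of triplanar patches: (side, side, 3, N) array.
extract_triplanar_batch <- function(v, centers, half_size = 10L) {
  arr <- vol_data(v)
  side <- 2L * half_size + 1L
  n <- nrow(centers)
  out <- array(0, c(side, side, 3L, n))
  for (q in seq_len(n))
    out[, , , q] <- extract_triplanar_planes(arr, as.integer(centers[q, ]),
                                             half_size)
  out
}

# Rotate a triplanar patch by r * 90 degrees around the axial axis.
# Under lat -> elev, elev -> -lat: the coronal tile rotates in-plane, and
# the two axial-containing tiles exchange (with the matching flip).
rotate_triplanar_90 <- function(planes, r) {
  r <- r %% 4L
  if (r == 0L) return(planes)
  side <- dim(planes)[1]
  rot90 <- function(m) t(m)[side:1, , drop = FALSE]
  for (s in seq_len(r)) {
    p1 <- planes[, , 1]; p2 <- planes[, , 2]; p3 <- planes[, , 3]
    planes[, , 1] <- t(p3)              # new lat-ax from old ax-elev
    planes[, , 2] <- rot90(p2)          # coronal tile rotates in-plane
    planes[, , 3] <- t(p1)[, side:1]    # new ax-elev from old lat-ax, flipped
  }
  planes
}

#' Build a trainable triplanar patch model
#'
#' Weight initialization is He-normal and deterministic given `seed`.
#'
#' @param cfg A [patch_model_config].
#' @param seed Integer seed for weight initialization.
#' @return A `patch_model` object.
#' @export
build_patch_model <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "patch_model_config"))
  with_seed_local(seed, {
    n_banks <- if (cfg$variant == "IndepCNN") 3L else 1L
    cin <- c(1L, head(cfg$conv_filters, -1))
    banks <- lapply(seq_len(n_banks), function(b)
      lapply(seq_along(cfg$conv_filters), function(l)
        he_conv(cfg$kernel, cin[l], cfg$conv_filters[l])))
    feat_dim <- 3L * cfg$final_side^2 * tail(cfg$conv_filters, 1)
    fc_in <- c(feat_dim, head(cfg$fc_sizes, -1))
    fc <- lapply(seq_along(cfg$fc_sizes), function(l)
      he_fc(fc_in[l], cfg$fc_sizes[l]))
    structure(list(cfg = cfg, banks = banks, fc = fc, seed = seed),
              class = "patch_model")
  })
}

#' @export
print.patch_model <- function(x, ...) {
  cat(sprintf("<patch_model> %s: conv %s (3x3, %d bank%s), fc %s\n",
              x$cfg$variant, paste(x$cfg$conv_filters, collapse = "-"),
              length(x$banks), if (length(x$banks) > 1) "s" else "",
              paste(x$cfg$fc_sizes, collapse = "-")))
  invisible(x)
}

# Forward pass. patches: (side, side, 3, N). Returns probs (N x 2) and,
# when keep_cache, everything needed for the backward pass. The
# pre-concatenation per-plane feature maps are exposed for inspection.
patch_forward <- function(model, patches, training = FALSE,
                          keep_cache = FALSE) {
  cfg <- model$cfg
  n <- dim(patches)[4]
  side <- dim(patches)[1]
  fs <- cfg$final_side
  f_last <- tail(cfg$conv_filters, 1)
  plane_feats <- vector("list", 3)
  conv_caches <- vector("list", 3)
  for (p in 1:3) {
    bank <- model$banks[[min(p, length(model$banks))]]
    x <- array(patches[, , p, ], c(side, side, n))  # Cin = 1
    caches <- vector("list", length(bank))
    for (l in seq_along(bank)) {
      caches[[l]] <- conv_forward(x, bank[[l]], n, pad = 0L, relu = TRUE)
      x <- caches[[l]]$y
    }
    plane_feats[[p]] <- x                 # (fs, fs, n * f_last)
    conv_caches[[p]] <- caches
  }
  feat <- matrix(0, n, 3L * fs * fs * f_last)
  blk <- fs * fs * f_last
  # slices are sample-major (q-1)*C + c, so a straight reshape gives the
  # (features x samples) block for each plane
  for (p in 1:3)
    feat[, ((p - 1L) * blk + 1L):(p * blk)] <-
      t(matrix(plane_feats[[p]], blk, n))
  fc_caches <- vector("list", length(model$fc))
  x <- feat
  n_fc <- length(model$fc)
  for (l in seq_len(n_fc)) {
    last <- l == n_fc
    fc_caches[[l]] <- fc_forward(
      x, model$fc[[l]], relu = !last,
      dropout_p = if (l <= 2 && !last) cfg$dropout_p else 0,
      training = training)
    x <- fc_caches[[l]]$y
  }
  probs <- softmax_rows(x)
  out <- list(probs = probs, plane_features = plane_feats)
  if (keep_cache)
    out$cache <- list(conv = conv_caches, fc = fc_caches, n = n, feat = feat)
  out
}

# Backward pass from dlogits; returns gradients shaped like
# patch_trainables(model).
patch_backward <- function(model, cache, dlogits) {
  cfg <- model$cfg
  n <- cache$n
  fs <- cfg$final_side
  f_last <- tail(cfg$conv_filters, 1)
  dg_fc <- vector("list", length(model$fc))
  dy <- dlogits
  for (l in rev(seq_along(model$fc))) {
    g <- fc_backward(cache$fc[[l]], model$fc[[l]], dy)
    dg_fc[[l]] <- list(W = g$dW, b = g$db)
    dy <- g$dx
  }
  blk <- fs * fs * f_last
  n_banks <- length(model$banks)
  dg_banks <- lapply(model$banks, function(bank)
    lapply(bank, function(l) list(W = l$W * 0, b = l$b * 0)))
  for (p in 1:3) {
    dfeat <- array(t(dy[, ((p - 1L) * blk + 1L):(p * blk), drop = FALSE]),
                   c(fs, fs, n * f_last))
    b_idx <- min(p, n_banks)
    bank <- model$banks[[b_idx]]
    dcur <- dfeat
    for (l in rev(seq_along(bank))) {
      g <- conv_backward(cache$conv[[p]][[l]], bank[[l]], dcur, n, pad = 0L)
      dg_banks[[b_idx]][[l]]$W <- dg_banks[[b_idx]][[l]]$W + g$dW
      dg_banks[[b_idx]][[l]]$b <- dg_banks[[b_idx]][[l]]$b + g$db
      dcur <- g$dx
    }
  }
  list(banks = dg_banks, fc = dg_fc)
}

patch_trainables <- function(model) {
  list(banks = lapply(model$banks, function(bank)
    lapply(bank, conv_trainables)),
    fc = lapply(model$fc, function(l) list(W = l$W, b = l$b)))
}

set_patch_trainables <- function(model, tr) {
  for (b in seq_along(model$banks))
    for (l in seq_along(model$banks[[b]]))
      model$banks[[b]][[l]] <- set_conv_trainables(model$banks[[b]][[l]],
                                                   tr$banks[[b]][[l]])
  for (l in seq_along(model$fc)) {
    model$fc[[l]]$W <- tr$fc[[l]]$W
    model$fc[[l]]$b <- tr$fc[[l]]$b
  }
  model
}

#' Predict needle probabilities for a batch of triplanar patches
#'
#' @param model A trained [build_patch_model()] model.
#' @param patches Array (side, side, 3, N).
#' @return Numeric vector of needle probabilities (class 2).
#' @export
patch_predict <- function(model, patches) {
  if (length(dim(patches)) == 3L) dim(patches) <- c(dim(patches), 1L)
  n <- dim(patches)[4]
  out <- numeric(n)
  bs <- 512L
  for (s in seq(1L, n, by = bs)) {
    e <- min(n, s + bs - 1L)
    out[s:e] <- patch_forward(model, patches[, , , s:e, drop = FALSE])$probs[, 2]
  }
  out
}
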