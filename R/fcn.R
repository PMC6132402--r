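# 2.5D thick-slice fully convolutional segmenter (ShareFCN). Encoder is a
# VGG-19-style convolutional stack (stages of 2,2,4,4,4 3x3 convolutions
# with 64,128,256,512,512 filters, five 2x max-pools recording argmax
# indices). Decoder: index unpooling by 2 (pool-5 indices) -> 512-filter
# conv, unpooling by 2 (pool-4 indices) -> 256-filter conv, unpooling by 8
# -> 2-filter conv and per-pixel softmax. Skip connections tap the encoder
# before the 4th and 5th pools and are fused by addition after a 1x1
# channel-matching convolution. One shared network serves the lateral and
# elevational views. A width_scale knob shrinks all channel counts for
# CPU-scale training; defaults reproduce the reference architecture.

FCN_BASE_CHANNELS <- c(64, 128, 256, 512, 512)
FCN_CONVS_PER_STAGE <- c(2L, 2L, 4L, 4L, 4L)

#' FCN architecture configuration
#'
#' @param width_scale Multiplier in (0, 1] on all channel counts;
#'   `width_scale = 1` is the full VGG-19-style architecture.
#' @param dropout_p Dropout probability applied at the two deepest encoder
#'   convolution stages (the reference uses 0.85).
#' @param final_upsample `"index"`: the x8 unpooling starts with an
#'   index unpool using the pool-3 indices (the deepest stage whose channel
#'   count matches the decoder map) followed by nearest x4; `"nearest"`:
#'   plain nearest-neighbour x8.
#' @param normalize Input normalization applied to every thick slice before
#'   the first convolution: `"log"` (log-compression `log1p` followed by
#'   per-slice standardization -- the usual conditioning for envelope
#'   ultrasound data) or `"none"` (raw intensities).
#' @return An `fcn_config` object.
#' @export
fcn_config <- function(width_scale = 1, dropout_p = 0.85,
                       final_upsample = c("index", "nearest"),
                       normalize = c("log", "none")) {
  final_upsample <- match.arg(final_upsample)
  normalize <- match.arg(normalize)
  if (width_scale <= 0 || width_scale > 1)
    abort("`width_scale` must be in (0, 1]")
  ch <- pmax(2L, as.integer(round(FCN_BASE_CHANNELS * width_scale)))
  structure(list(width_scale = width_scale, dropout_p = dropout_p,
                 final_upsample = final_upsample, normalize = normalize,
                 channels = ch,
                 convs_per_stage = FCN_CONVS_PER_STAGE,
                 dec_channels = c(ch[5], ch[3], 2L),
                 unpool_factors = c(2L, 2L, 8L)),
            class = "fcn_config")
}

#' Build a trainable thick-slice FCN
#'
#' @param cfg An [fcn_config].
#' @param seed Integer seed; He-normal initialization is deterministic
#'   given it.
#' @return An `fcn_model` object mapping a 3-channel 2D input to a
#'   per-pixel 2-class softmax map of identical spatial size (inputs whose
#'   sides are not multiples of 32 are padded and cropped internally).
#' @export
build_fcn <- function(cfg = fcn_config(), seed = 1L) {
  stopifnot(inherits(cfg, "fcn_config"))
  with_seed_local(seed, {
    ch <- cfg$channels
    enc <- vector("list", 5L)
    cin <- 3L
    for (st in 1:5) {
      enc[[st]] <- lapply(seq_len(cfg$convs_per_stage[st]), function(l) {
        layer <- he_conv(3L, if (l == 1L) cin else ch[st], ch[st])
        layer
      })
      cin <- ch[st]
    }
    skipA <- he_conv(1L, ch[5], ch[5])   # tap before pool 5
    skipB <- he_conv(1L, ch[4], ch[5])   # tap before pool 4
    dec <- list(he_conv(3L, ch[5], cfg$dec_channels[1]),
                he_conv(3L, cfg$dec_channels[1], cfg$dec_channels[2]),
                he_conv(3L, cfg$dec_channels[2], 2L))
    structure(list(cfg = cfg, enc = enc, skipA = skipA, skipB = skipB,
                   dec = dec, seed = seed),
              class = "fcn_model")
  })
}

#' @export
print.fcn_model <- function(x, ...) {
  cat(sprintf(
    "<fcn_model> ShareFCN, width_scale %.3g, channels %s, decoder %s\n",
    x$cfg$width_scale, paste(x$cfg$channels, collapse = "-"),
    paste(x$cfg$dec_channels, collapse = "-")))
  invisible(x)
}

fcn_trainables <- function(model) {
  list(enc = lapply(model$enc, function(st) lapply(st, conv_trainables)),
       skipA = conv_trainables(model$skipA),
       skipB = conv_trainables(model$skipB),
       dec = lapply(model$dec, conv_trainables))
}

set_fcn_trainables <- function(model, tr) {
  for (st in 1:5)
    for (l in seq_along(model$enc[[st]]))
      model$enc[[st]][[l]] <- set_conv_trainables(model$enc[[st]][[l]],
                                                  tr$enc[[st]][[l]])
  model$skipA <- set_conv_trainables(model$skipA, tr$skipA)
  model$skipB <- set_conv_trainables(model$skipB, tr$skipB)
  for (l in 1:3) model$dec[[l]] <- set_conv_trainables(model$dec[[l]],
                                                       tr$dec[[l]])
  model
}

pad_to_multiple <- function(x, m = 32L) {
  d <- dim(x)
  hp <- ceiling(d[1] / m) * m
  wp <- ceiling(d[2] / m) * m
  if (hp == d[1] && wp == d[2]) return(list(x = x, h = d[1], w = d[2]))
  out <- array(0, c(hp, wp, d[3]))
  out[seq_len(d[1]), seq_len(d[2]), ] <- x
  list(x = out, h = d[1], w = d[2])
}

# Forward pass on one 3-channel slice (H, W, 3). Returns the needle
# probability map (original H x W) and, optionally, the full cache.
fcn_forward <- function(model, x, training = FALSE, keep_cache = FALSE) {
  cfg <- model$cfg
  if (identical(cfg$normalize, "log")) {
    x <- log1p(pmax(x, 0))
    s <- sd(x)
    x <- (x - mean(x)) / if (s > 1e-8) s else 1
  }
  pd <- pad_to_multiple(x)
  cur <- pd$x
  ch <- cfg$channels
  enc_caches <- vector("list", 5L)
  pool_idx <- vector("list", 5L)
  stage_out <- vector("list", 5L)
  drop_masks <- list()
  for (st in 1:5) {
    caches <- vector("list", length(model$enc[[st]]))
    n_l <- length(model$enc[[st]])
    for (l in seq_len(n_l)) {
      caches[[l]] <- conv_forward(cur, model$enc[[st]][[l]], 1L, pad = 1L,
                                  relu = TRUE)
      cur <- caches[[l]]$y
      # heavy regularization at the two deepest encoder conv stages
      if (training && cfg$dropout_p > 0 && st == 5L && l >= n_l - 1L) {
        mask <- array(rbinom(length(cur), 1, 1 - cfg$dropout_p) /
                        (1 - cfg$dropout_p), dim(cur))
        cur <- cur * mask
        drop_masks[[paste0("s5l", l)]] <- mask
      }
    }
    enc_caches[[st]] <- caches
    stage_out[[st]] <- cur
    mp <- nn_maxpool2_forward(cur)
    pool_idx[[st]] <- mp$idx
    cur <- mp$y
  }
  # decoder stage 1: x2 index unpool (pool-5), skip from before pool 5
  u1 <- nn_unpool2(cur, pool_idx[[5]])
  sA <- conv_forward(stage_out[[5]], model$skipA, 1L, pad = 0L, relu = FALSE)
  a1 <- u1 + sA$y
  d1 <- conv_forward(a1, model$dec[[1]], 1L, pad = 1L, relu = TRUE)
  # decoder stage 2: x2 index unpool (pool-4), skip from before pool 4
  u2 <- nn_unpool2(d1$y, pool_idx[[4]])
  sB <- conv_forward(stage_out[[4]], model$skipB, 1L, pad = 0L, relu = FALSE)
  a2 <- u2 + sB$y
  d2 <- conv_forward(a2, model$dec[[2]], 1L, pad = 1L, relu = TRUE)
  # decoder stage 3: x8 upsampling then the 2-filter conv + softmax
  if (cfg$final_upsample == "index") {
    u3 <- nn_upsample_nearest(nn_unpool2(d2$y, pool_idx[[3]]), 4L)
  } else {
    u3 <- nn_upsample_nearest(d2$y, 8L)
  }
  d3 <- conv_forward(u3, model$dec[[3]], 1L, pad = 1L, relu = FALSE)
  logits <- d3$y                       # (Hp, Wp, 2)
  hp <- dim(logits)[1]; wp <- dim(logits)[2]
  lmat <- cbind(as.vector(logits[, , 1]), as.vector(logits[, , 2]))
  pmat <- softmax_rows(lmat)
  prob_full <- matrix(pmat[, 2], hp, wp)
  prob <- prob_full[seq_len(pd$h), seq_len(pd$w), drop = FALSE]
  out <- list(prob = prob, prob_full = pmat, h = pd$h, w = pd$w,
              hp = hp, wp = wp)
  if (keep_cache)
    out$cache <- list(enc = enc_caches, pool_idx = pool_idx,
                      stage_out = stage_out, drop = drop_masks,
                      sA = sA, sB = sB, a1 = a1, d1 = d1, a2 = a2, d2 = d2,
                      u3 = u3, d3 = d3)
  out
}

# Backward pass from per-pixel dlogits (rows matching prob_full). Returns
# gradients shaped like fcn_trainables(model).
fcn_backward <- function(model, fw, dlogit_rows) {
  cfg <- model$cfg
  cache <- fw$cache
  hp <- fw$hp; wp <- fw$wp
  dlogits <- array(c(dlogit_rows[, 1], dlogit_rows[, 2]), c(hp, wp, 2))
  g3 <- conv_backward(cache$d3, model$dec[[3]], dlogits, 1L, pad = 1L)
  if (cfg$final_upsample == "index") {
    du3 <- nn_downsample_sum(g3$dx, 4L)
    dd2y <- nn_pool_gather(du3, cache$pool_idx[[3]])
  } else {
    dd2y <- nn_downsample_sum(g3$dx, 8L)
  }
  g2 <- conv_backward(cache$d2, model$dec[[2]], dd2y, 1L, pad = 1L)
  gB <- conv_backward(cache$sB, model$skipB, g2$dx, 1L, pad = 0L)
  dd1y <- nn_pool_gather(g2$dx, cache$pool_idx[[4]])
  g1 <- conv_backward(cache$d1, model$dec[[1]], dd1y, 1L, pad = 1L)
  gA <- conv_backward(cache$sA, model$skipA, g1$dx, 1L, pad = 0L)
  dp5 <- nn_pool_gather(g1$dx, cache$pool_idx[[5]])

  denc <- lapply(model$enc, function(st) lapply(st, function(l)
    list(W = l$W * 0, b = l$b * 0)))
  dcur <- NULL
  for (st in 5:1) {
    # gradient entering the stage output: max-pool backward (+ skip taps)
    dpool <- nn_unpool2(if (st == 5L) dp5 else dcur, cache$pool_idx[[st]])
    if (st == 5L) dpool <- dpool + gA$dx
    if (st == 4L) dpool <- dpool + gB$dx
    dy <- dpool
    n_l <- length(model$enc[[st]])
    for (l in rev(seq_len(n_l))) {
      if (st == 5L && l >= n_l - 1L) {
        key <- paste0("s5l", l)
        if (!is.null(cache$drop[[key]])) dy <- dy * cache$drop[[key]]
      }
      g <- conv_backward(cache$enc[[st]][[l]], model$enc[[st]][[l]], dy, 1L,
                         pad = 1L)
      denc[[st]][[l]] <- list(W = g$dW, b = g$db)
      dy <- g$dx
    }
    dcur <- dy
  }
  list(enc = denc, skipA = list(W = gA$dW, b = gA$db),
       skipB = list(W = gB$dW, b = gB$db),
       dec = list(list(W = g1$dW, b = g1$db), list(W = g2$dW, b = g2$db),
                  list(W = g3$dW, b = g3$db)))
}

#' Predict the needle-probability map of one thick slice
#'
#' @param model An [build_fcn()] model.
#' @param slice A `thick_slice` or a (H, W, 3) array.
#' @return Numeric H x W matrix of needle probabilities.
#' @export
fcn_predict_slice <- function(model, slice) {
  x <- if (inherits(slice, "thick_slice")) slice$channels else slice
  fcn_forward(model, x)$prob
}
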