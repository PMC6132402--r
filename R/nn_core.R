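# Layer orchestration for the two networks. Heavy kernels (batched im2col
# convolution, pooling, unpooling, resampling) live in src/; this file keeps
# the parameter containers, He initialization, ReLU/dropout/softmax pieces
# and the RMSProp/Adam updates. Batches of N images with C channels travel
# as arrays of dim (H, W, N*C), sample-major (slice n*C + c), matching the
# C++ layout.

he_conv <- function(k, cin, cout) {
  list(W = matrix(rnorm(k * k * cin * cout) * sqrt(2 / (k * k * cin)),
                  nrow = k * k * cin, ncol = cout),
       b = numeric(cout), k = k, cin = cin, cout = cout)
}

he_fc <- function(din, dout) {
  list(W = matrix(rnorm(din * dout) * sqrt(2 / din), nrow = din, ncol = dout),
       b = numeric(dout))
}

conv_forward <- function(x, layer, n_batch, pad, relu = TRUE) {
  y <- nn_conv2d_forward(x, layer$W, layer$b, n_batch, layer$k, pad)
  mask <- NULL
  if (relu) {
    mask <- y > 0
    y <- y * mask
  }
  list(y = y, x = x, mask = mask)
}

conv_backward <- function(cache, layer, dy, n_batch, pad) {
  if (!is.null(cache$mask)) dy <- dy * cache$mask
  g <- nn_conv2d_backward(cache$x, layer$W, dy, n_batch, layer$k, pad)
  list(dx = g$dx, dW = g$dw, db = as.numeric(g$db))
}

fc_forward <- function(x, layer, relu = TRUE, dropout_p = 0, training = FALSE) {
  z <- sweep(x %*% layer$W, 2, layer$b, "+")
  mask <- NULL
  if (relu) {
    mask <- z > 0
    z <- z * mask
  }
  dmask <- NULL
  if (training && dropout_p > 0) {
    dmask <- matrix(rbinom(length(z), 1, 1 - dropout_p) / (1 - dropout_p),
                    nrow = nrow(z))
    z <- z * dmask
  }
  list(y = z, x = x, mask = mask, dmask = dmask)
}

fc_backward <- function(cache, layer, dy) {
  if (!is.null(cache$dmask)) dy <- dy * cache$dmask
  if (!is.null(cache$mask)) dy <- dy * cache$mask
  list(dx = dy %*% t(layer$W), dW = t(cache$x) %*% dy, db = colSums(dy))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Cross-entropy over one-hot rows; returns loss and dlogits (already /N).
ce_loss_rows <- function(p, y_onehot, weights = NULL) {
  n <- nrow(p)
  if (is.null(weights)) weights <- rep(1, n)
  wsum <- sum(weights)
  if (wsum == 0) return(list(loss = 0, dlogits = 0 * p))
  loss <- -sum(weights * log(pmax(rowSums(p * y_onehot), 1e-12))) / wsum
  dlogits <- (p - y_onehot) * (weights / wsum)
  list(loss = loss, dlogits = dlogits)
}

## ---- nested parameter utilities -------------------------------------

is_param_leaf <- function(x) is.numeric(x)

nested_map <- function(f, a) {
  if (is_param_leaf(a)) return(f(a))
  out <- lapply(a, function(el) nested_map(f, el))
  out
}

nested_map2 <- function(f, a, b) {
  if (is_param_leaf(a)) return(f(a, b))
  out <- mapply(function(x, y) nested_map2(f, x, y), a, b, SIMPLIFY = FALSE)
  out
}

## ---- optimizers ------------------------------------------------------

opt_init <- function(params, method = c("rmsprop", "adam")) {
  method <- match.arg(method)
  st <- list(method = method, t = 0L)
  st$v <- nested_map(function(p) p * 0, params)
  if (method == "adam") st$m <- nested_map(function(p) p * 0, params)
  st
}

# One optimizer step; returns list(params, state). `grads` mirrors `params`
# (non-numeric bookkeeping entries like kernel sizes are passed through).
opt_step <- function(params, grads, state, lr) {
  eps <- 1e-8
  if (state$method == "rmsprop") {
    state$v <- nested_map2(function(v, g) 0.9 * v + 0.1 * g * g,
                           state$v, grads)
    upd <- nested_map2(function(g, v) lr * g / (sqrt(v) + eps),
                       grads, state$v)
    params <- nested_map2(function(p, u) p - u, params, upd)
  } else {
    state$t <- state$t + 1L
    b1 <- 0.9; b2 <- 0.999
    state$m <- nested_map2(function(m, g) b1 * m + (1 - b1) * g,
                           state$m, grads)
    state$v <- nested_map2(function(v, g) b2 * v + (1 - b2) * g * g,
                           state$v, grads)
    bc1 <- 1 - b1^state$t
    bc2 <- 1 - b2^state$t
    upd <- nested_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                       state$m, state$v)
    params <- nested_map2(function(p, u) p - u, params, upd)
  }
  list(params = params, state = state)
}

# Strip bookkeeping so params/grads share a shape for the optimizer.
conv_trainables <- function(layer) list(W = layer$W, b = layer$b)
set_conv_trainables <- function(layer, tr) {
  layer$W <- tr$W; layer$b <- tr$b; layer
}
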