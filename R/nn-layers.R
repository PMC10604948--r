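# Layer-level forward/backward building blocks for the stacked FCN.
#
# All feature maps are arrays dim (H, W, C, B); convolution weights are
# (k, k, Cin, Cout). Convolutions/pools are C++ (see src/ops.cpp); batch
# norm, activations, softmax and attention live here. Every *_bwd function
# is the exact adjoint of its *_fwd, verified by finite differences in the
# test suite.

# Single- vs double-precision convolution GEMM; the double path exists for
# finite-difference verification and costs about twice the time.
conv_double <- function() isTRUE(getOption("cephmark.conv_double"))

BN_EPS <- 1e-3
BN_MOMENTUM <- 0.9

he_uniform <- function(k, cin, cout) {
  lim <- sqrt(6 / (k * k * cin))
  array(runif(k * k * cin * cout, -lim, lim), dim = c(k, k, cin, cout))
}

conv_params <- function(k, cin, cout, bn = TRUE) {
  p <- list(w = he_uniform(k, cin, cout), b = numeric(cout))
  if (bn) { p$gamma <- rep(1, cout); p$beta <- numeric(cout) }
  p
}

convt_params <- function(cin, cout) {
  lim <- sqrt(6 / (4 * cin))
  list(w = array(runif(4 * cin * cout, -lim, lim), dim = c(2, 2, cin, cout)),
       b = numeric(cout))
}

# conv (3x3, same padding) -> batch norm -> ReLU. Batch statistics are per
# channel over (H, W, B); running statistics (momentum 0.9) are used at
# inference time.
conv_block_fwd <- function(p, rs, x, dilation = 1L, train = FALSE) {
  z <- .cm_conv2d_fwd(x, p$w, p$b, as.integer(dilation), conv_double())
  if (train) {
    st <- .cm_bn_stats(z)
    mu <- st$mean; v <- st$var
    rs$mean <- BN_MOMENTUM * rs$mean + (1 - BN_MOMENTUM) * mu
    rs$var <- BN_MOMENTUM * rs$var + (1 - BN_MOMENTUM) * v
  } else {
    mu <- rs$mean; v <- rs$var
  }
  inv_sd <- 1 / sqrt(v + BN_EPS)
  sc <- p$gamma * inv_sd
  y <- .cm_scale_shift(z, sc, p$beta - mu * sc, TRUE)
  list(y = y, rs = rs,
       cache = if (train) list(x = x, z = z, y = y, mu = mu,
                               inv_sd = inv_sd, dilation = dilation))
}

conv_block_bwd <- function(p, cache, gy) {
  xhat <- .cm_normalize(cache$z, cache$mu, cache$inv_sd)
  r1 <- .cm_bn_relu_bwd1(gy, cache$y, xhat, TRUE)
  d <- dim(gy); m <- d[1] * d[2] * d[4]
  gxbn <- .cm_bn_bwd2(r1$g, xhat, p$gamma * cache$inv_sd,
                      r1$dbeta / m, r1$dgamma / m)
  cv <- .cm_conv2d_bwd(cache$x, p$w, gxbn, as.integer(cache$dilation),
                       conv_double())
  list(gx = cv$gx,
       grads = list(w = cv$gw, b = cv$gb, gamma = r1$dgamma,
                    beta = r1$dbeta))
}

# Per-pixel softmax over the channel axis.
softmax_channels <- function(z) .cm_softmax_channels(z)

# Gradient of CEL(y, softmax(z)) w.r.t. z; p = softmax(z).
# dL/dp = -(1/N) (y/p - (1-y)/(1-p)) with p clipped; then the softmax
# Jacobian: dz_c = p_c (g_c - sum_k g_k p_k).
softmax_cel_grad <- function(y, p, eps = 1e-7) .cm_softmax_cel_grad(y, p, eps)

col_softmax <- function(S) {
  S <- sweep(S, 2, apply(S, 2, max), "-")
  E <- exp(S)
  sweep(E, 2, colSums(E), "/")
}

col_softmax_bwd <- function(P, gP) {
  P * sweep(gP, 2, colSums(P * gP), "-")
}

# ---- spatial (position) attention -----------------------------------------
# Per sample: G (N x C) pixel-major features. Projections F0 = G W0 + b0,
# F1 = G W1 + b1 (N x Cp), F2 = G W2 + b2 (N x C). Scores S = F0 F1^T;
# column-softmax P (weights over source positions i for each output j).
# Output O = gamma * P^T F2 + G.
sam_fwd_one <- function(G, p) {
  F0 <- sweep(G %*% p$w0, 2, p$b0, "+")
  F1 <- sweep(G %*% p$w1, 2, p$b1, "+")
  F2 <- sweep(G %*% p$w2, 2, p$b2, "+")
  S <- F0 %*% t(F1)
  P <- col_softmax(S)
  agg <- crossprod(P, F2)
  O <- p$gamma * agg + G
  list(O = O, cache = list(G = G, F0 = F0, F1 = F1, F2 = F2, P = P,
                           agg = agg))
}

sam_bwd_one <- function(gO, cache, p) {
  G <- cache$G; P <- cache$P
  gG <- gO
  ggamma <- sum(gO * cache$agg)
  gF2 <- p$gamma * (P %*% gO)
  gP <- p$gamma * tcrossprod(gO, cache$F2)   # grad w.r.t. t(P): N x N
  gP <- t(gP)
  gS <- col_softmax_bwd(P, gP)
  gF0 <- gS %*% cache$F1
  gF1 <- crossprod(gS, cache$F0)
  gw0 <- crossprod(G, gF0); gb0 <- colSums(gF0)
  gw1 <- crossprod(G, gF1); gb1 <- colSums(gF1)
  gw2 <- crossprod(G, gF2); gb2 <- colSums(gF2)
  gG <- gG + tcrossprod(gF0, p$w0) + tcrossprod(gF1, p$w1) +
    tcrossprod(gF2, p$w2)
  list(gG = gG, grads = list(w0 = gw0, b0 = gb0, w1 = gw1, b1 = gb1,
                             w2 = gw2, b2 = gb2, gamma = ggamma))
}

# ---- channel attention -----------------------------------------------------
# S = G^T G (C x C), column-softmax A; O = gamma * G A + G.
cam_fwd_one <- function(G, gamma) {
  S <- crossprod(G)
  A <- col_softmax(S)
  agg <- G %*% A
  O <- gamma * agg + G
  list(O = O, cache = list(G = G, A = A, agg = agg))
}

cam_bwd_one <- function(gO, cache, gamma) {
  G <- cache$G; A <- cache$A
  gG <- gO
  ggamma <- sum(gO * cache$agg)
  gA <- gamma * crossprod(G, gO)
  gG <- gG + gamma * tcrossprod(gO, A)
  gS <- col_softmax_bwd(A, gA)
  gG <- gG + G %*% (gS + t(gS))
  list(gG = gG, grads = list(gamma = ggamma))
}

as_pixel_matrix <- function(slice) {
  d <- dim(slice)
  matrix(slice, nrow = d[1] * d[2])
}

# Batched wrappers: x (H, W, C, B) -> same shape; caches kept per sample.
sam_fwd <- function(x, p, max_n = 4096) {
  d <- dim(x); N <- d[1] * d[2]
  if (N > max_n)
    stop(sprintf(paste0("spatial attention needs an %d x %d map; over the ",
                        "memory budget - use a smaller bridge resolution"),
                 N, N))
  y <- x; caches <- vector("list", d[4])
  for (b in seq_len(d[4])) {
    r <- sam_fwd_one(as_pixel_matrix(x[, , , b, drop = FALSE]), p)
    y[, , , b] <- array(r$O, dim = d[1:3])
    caches[[b]] <- r$cache
  }
  list(y = y, caches = caches)
}

sam_bwd <- function(gy, caches, p) {
  d <- dim(gy)
  gx <- gy
  acc <- NULL
  for (b in seq_len(d[4])) {
    r <- sam_bwd_one(as_pixel_matrix(gy[, , , b, drop = FALSE]),
                     caches[[b]], p)
    gx[, , , b] <- array(r$gG, dim = d[1:3])
    acc <- if (is.null(acc)) r$grads else
      mapply(`+`, acc, r$grads, SIMPLIFY = FALSE)
  }
  list(gx = gx, grads = acc)
}

cam_fwd <- function(x, gamma) {
  d <- dim(x)
  y <- x; caches <- vector("list", d[4])
  for (b in seq_len(d[4])) {
    r <- cam_fwd_one(as_pixel_matrix(x[, , , b, drop = FALSE]), gamma)
    y[, , , b] <- array(r$O, dim = d[1:3])
    caches[[b]] <- r$cache
  }
  list(y = y, caches = caches)
}

cam_bwd <- function(gy, caches, gamma) {
  d <- dim(gy)
  gx <- gy
  ggamma <- 0
  for (b in seq_len(d[4])) {
    r <- cam_bwd_one(as_pixel_matrix(gy[, , , b, drop = FALSE]),
                     caches[[b]], gamma)
    gx[, , , b] <- array(r$gG, dim = d[1:3])
    ggamma <- ggamma + r$grads$gamma
  }
  list(gx = gx, grads = list(gamma = ggamma))
}

#' Spatial (position) attention over a feature map
#'
#' Computes position-pair similarity scores from two pointwise projections
#' of the input, normalises them with a softmax into an `N x N` map
#' (`N = H * W`, rows sum to 1), aggregates a third projection with those
#' weights, and adds the result back scaled by the learnable gain `gamma`.
#' With `gamma = 0` the module is the identity, which is how it is
#' initialised during training.
#'
#' @param f Feature map, `H x W x C` array (single sample).
#' @param gamma Scalar gain.
#' @param w0,w1,w2 Pointwise projection matrices (`C x Cp`, `C x Cp`,
#'   `C x C`); identity by default, which is the form used by the
#'   transcription oracles.
#' @param b0,b1,b2 Projection biases (default 0).
#' @param return_map Also return the row-stochastic attention map.
#' @return Array shaped like `f`; if `return_map`, a list with elements
#'   `output` and `map`.
#' @export
spatial_attention <- function(f, gamma = 0, w0 = NULL, w1 = NULL, w2 = NULL,
                              b0 = NULL, b1 = NULL, b2 = NULL,
                              return_map = FALSE) {
  stopifnot(length(dim(f)) == 3L, all(is.finite(f)))
  C <- dim(f)[3]
  p <- list(w0 = if (is.null(w0)) diag(C) else w0,
            w1 = if (is.null(w1)) diag(C) else w1,
            w2 = if (is.null(w2)) diag(C) else w2,
            gamma = gamma)
  p$b0 <- if (is.null(b0)) numeric(ncol(p$w0)) else b0
  p$b1 <- if (is.null(b1)) numeric(ncol(p$w1)) else b1
  p$b2 <- if (is.null(b2)) numeric(ncol(p$w2)) else b2
  r <- sam_fwd_one(as_pixel_matrix(f), p)
  out <- array(r$O, dim = dim(f))
  if (return_map) list(output = out, map = t(r$cache$P)) else out
}

#' Channel attention over a feature map
#'
#' Computes channel-pair similarity scores directly from the input (no
#' learned projections), softmax-normalises them into a `C x C` map (rows
#' sum to 1), aggregates the channels with those weights, and adds the
#' result back scaled by the learnable gain `gamma` (identity at
#' `gamma = 0`).
#'
#' @inheritParams spatial_attention
#' @return Array shaped like `f`; if `return_map`, a list with `output`
#'   and `map`.
#' @export
channel_attention <- function(f, gamma = 0, return_map = FALSE) {
  stopifnot(length(dim(f)) == 3L, all(is.finite(f)))
  r <- cam_fwd_one(as_pixel_matrix(f), gamma)
  out <- array(r$O, dim = dim(f))
  if (return_map) list(output = out, map = t(r$cache$A)) else out
}

#' Dual attention: both branches on the same feature map
#'
#' Applies [spatial_attention()] and [channel_attention()] to the same
#' input, as done at the bridge of the first FCN stage; both branch outputs
#' are retained so later stages can concatenate them.
#'
#' @inheritParams spatial_attention
#' @param gamma_s,gamma_c Gains of the spatial and channel branch.
#' @param use_sam,use_cam Branch toggles (ablation wiring).
#' @return Named list with the enabled branches (`spatial`, `channel`).
#' @export
dual_attention <- function(f, gamma_s = 0, gamma_c = 0, use_sam = TRUE,
                           use_cam = TRUE, ...) {
  out <- list()
  if (use_sam) out$spatial <- spatial_attention(f, gamma = gamma_s, ...)
  if (use_cam) out$channel <- channel_attention(f, gamma = gamma_c)
  out
}

#' Multi-scale input pyramid
#'
#' Average-pools the input image by factors 2, 4, ..., matching the
#' resolutions of the encoder levels it is fused into.
#'
#' @param image `H x W` matrix or `H x W x 1 x B` array.
#' @param levels Number of pyramid levels (default 3: 1/2, 1/4, 1/8).
#' @return List of pooled arrays.
#' @export
multi_scale_inputs <- function(image, levels = 3L) {
  x <- as_batch(image)
  d <- dim(x)
  if (d[1] %% 2^levels || d[2] %% 2^levels)
    stop("image dimensions must be divisible by 2^levels")
  lapply(seq_len(levels), function(k) .cm_avgpool_fwd(x, as.integer(2^k)))
}

# Promote H x W or H x W x C to (H, W, C, 1).
as_batch <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected a matrix or array")
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

concat_channels <- function(...) .cm_concat_channels(list(...))

split_channels <- function(g, sizes) .cm_split_channels(g, as.integer(sizes))
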