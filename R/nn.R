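# Internal neural-network engine for the dual-input convolutional model.
#
# No deep-learning backend is assumed: convolution is im2col + BLAS
# matmul, with hand-written backward passes for conv, spatial batch
# norm, 2x2/stride-1 max pooling, dense, ReLU, dropout and
# MSE-on-softmax, optimized with Adagrad.
#
# Batch layout convention: a batch of feature maps of height H, width W
# and C channels is a matrix of n rows by H*W*C columns, where entry
# (h, w, c) sits at column h + (w-1)*H + (c-1)*H*W (column-major within
# a channel, channels outermost). `as.vector()` of an encoder's H x W
# matrix produces exactly one such row for C = 1.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.99
ADAGRAD_EPS <- 1e-7
ADAGRAD_INIT <- 0.1

# ---- layer geometry ---------------------------------------------------

conv_spec <- function(in_h, in_w, in_c, kh, kw, filters) {
  out_h <- in_h - kh + 1L
  out_w <- in_w - kw + 1L
  if (out_h < 1L || out_w < 1L) {
    stop(sprintf("conv kernel %dx%d does not fit input %dx%d", kh, kw, in_h, in_w),
         call. = FALSE)
  }
  P <- out_h * out_w
  K <- kh * kw * in_c
  oh <- rep(seq_len(out_h), times = out_w)
  ow <- rep(seq_len(out_w), each = out_h)
  idx <- matrix(0L, P, K)
  k <- 0L
  for (c in seq_len(in_c)) {
    for (dw in seq_len(kw)) {
      for (dh in seq_len(kh)) {
        k <- k + 1L
        idx[, k] <- (oh + dh - 1L) + (ow + dw - 2L) * in_h + (c - 1L) * in_h * in_w
      }
    }
  }
  list(in_h = in_h, in_w = in_w, in_c = in_c, kh = kh, kw = kw,
       filters = filters, out_h = out_h, out_w = out_w, P = P, K = K,
       idx0 = idx - 1L, in_size = in_h * in_w * in_c, out_size = P * filters)
}

pool_spec <- function(in_h, in_w, in_c, size = 2L, stride = 1L) {
  stopifnot(size == 2L, stride == 1L)  # the only pooling the model uses
  out_h <- in_h - 1L
  out_w <- in_w - 1L
  P <- out_h * out_w
  oh <- rep(seq_len(out_h), times = out_w)
  ow <- rep(seq_len(out_w), each = out_h)
  chan <- rep(seq_len(in_c), each = P)
  base_h <- rep(oh, in_c)
  base_w <- rep(ow, in_c)
  mk <- function(dh, dw) {
    as.integer((base_h + dh) + (base_w + dw - 1L) * in_h + (chan - 1L) * in_h * in_w)
  }
  idx4 <- cbind(mk(0L, 0L), mk(1L, 0L), mk(0L, 1L), mk(1L, 1L)) - 1L
  list(in_h = in_h, in_w = in_w, in_c = in_c, out_h = out_h, out_w = out_w,
       P = P, idx4 = idx4,
       in_size = in_h * in_w * in_c, out_size = P * in_c)
}

# ---- layer forward/backward ------------------------------------------
# Thin wrappers over the compiled kernels in src/layers.cpp.

conv_forward <- function(X, W, b, spec) {
  cpp_conv_forward(X, W, b, spec$idx0)
}

conv_backward <- function(dY, cache, W, spec) {
  out <- cpp_conv_backward(dY, cache$cols, W, spec$idx0, spec$in_size)
  out$db <- as.numeric(out$db)
  out
}

pool_forward <- function(X, spec) {
  cpp_pool_forward(X, spec$idx4)
}

pool_backward <- function(dY, cache, spec) {
  cpp_pool_backward(dY, cache$arg, spec$idx4, spec$in_size)
}

# Spatial batch norm over channels: x is n x (P*C); statistics pool the
# batch and spatial dimensions per channel, as in image backends.
bn_forward <- function(X, gamma, beta, run_mean, run_var, training) {
  out <- cpp_bn_forward(X, gamma, beta, run_mean, run_var, training,
                        BN_EPS, BN_MOMENTUM)
  if (training) {
    list(out = out$out,
         cache = list(xhat = out$xhat, inv = as.numeric(out$inv)),
         run_mean = as.numeric(out$new_mean),
         run_var = as.numeric(out$new_var))
  } else {
    list(out = out$out)
  }
}

bn_backward <- function(dY, cache, gamma) {
  out <- cpp_bn_backward(dY, cache$xhat, cache$inv, gamma)
  out$dgamma <- as.numeric(out$dgamma)
  out$dbeta <- as.numeric(out$dbeta)
  out
}

relu_forward <- function(X) {
  mask <- X > 0
  list(out = X * mask, mask = mask)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

glorot_uniform <- function(fan_in, fan_out, dims) {
  limit <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(prod(dims), -limit, limit), dims[1], dims[2])
}

# ---- network ----------------------------------------------------------

# Builds layer geometry + initialized parameters for the dual-input
# architecture. Shapes are derived from the config; the defaults
# reproduce the published geometry (module 1: 32x20 -> conv16(3x2) ->
# BN -> ReLU -> conv32(6x4) -> pool(2,1) -> BN -> ReLU -> dense;
# module 2: 20x20 -> conv16(1x2) -> pool(2,1) -> BN -> ReLU -> dense;
# concat -> dense 256 -> dense 128 (both L2) -> dropout -> dense 2
# softmax; valid conv padding throughout).
nn_init <- function(config) {
  s <- list()
  s$c1 <- conv_spec(config$input1[1], config$input1[2], 1L,
                    config$m1_conv1$kernel[1], config$m1_conv1$kernel[2],
                    config$m1_conv1$filters)
  s$c2 <- conv_spec(s$c1$out_h, s$c1$out_w, s$c1$filters,
                    config$m1_conv2$kernel[1], config$m1_conv2$kernel[2],
                    config$m1_conv2$filters)
  s$p1 <- pool_spec(s$c2$out_h, s$c2$out_w, s$c2$filters,
                    config$pool$size, config$pool$stride)
  s$c3 <- conv_spec(config$input2[1], config$input2[2], 1L,
                    config$m2_conv$kernel[1], config$m2_conv$kernel[2],
                    config$m2_conv$filters)
  s$p2 <- pool_spec(s$c3$out_h, s$c3$out_w, s$c3$filters,
                    config$pool$size, config$pool$stride)
  dw <- config$module_dense
  f1 <- config$fusion_dense[1]
  f2 <- config$fusion_dense[2]

  params <- with_seed(config$seed, {
    p <- list()
    cw <- function(spec) glorot_uniform(spec$K, spec$kh * spec$kw * spec$filters,
                                        c(spec$K, spec$filters))
    dn <- function(n_in, n_out) glorot_uniform(n_in, n_out, c(n_in, n_out))
    p$c1_W <- cw(s$c1); p$c1_b <- numeric(s$c1$filters)
    p$c2_W <- cw(s$c2); p$c2_b <- numeric(s$c2$filters)
    p$c3_W <- cw(s$c3); p$c3_b <- numeric(s$c3$filters)
    p$d1_W <- dn(s$p1$out_size, dw); p$d1_b <- numeric(dw)
    p$d2_W <- dn(s$p2$out_size, dw); p$d2_b <- numeric(dw)
    p$f1_W <- dn(2L * dw, f1); p$f1_b <- numeric(f1)
    p$f2_W <- dn(f1, f2); p$f2_b <- numeric(f2)
    p$out_W <- dn(f2, 2L); p$out_b <- numeric(2L)
    for (bn in c("bn1", "bn2", "bn3")) {
      C <- switch(bn, bn1 = s$c1$filters, bn2 = s$c2$filters, bn3 = s$c3$filters)
      p[[paste0(bn, "_gamma")]] <- rep(1, C)
      p[[paste0(bn, "_beta")]] <- numeric(C)
    }
    p
  })
  buffers <- list(
    bn1_mean = numeric(s$c1$filters), bn1_var = rep(1, s$c1$filters),
    bn2_mean = numeric(s$c2$filters), bn2_var = rep(1, s$c2$filters),
    bn3_mean = numeric(s$c3$filters), bn3_var = rep(1, s$c3$filters))
  list(spec = s, params = params, buffers = buffers, config = config)
}

# Forward pass. X1: n x prod(input1); X2: n x prod(input2).
# In training mode returns caches for the backward pass and updated BN
# buffers; in inference mode uses running BN statistics and no dropout,
# so the output of a sample does not depend on its batch.
nn_forward <- function(net, X1, X2, training = FALSE) {
  p <- net$params; s <- net$spec; b <- net$buffers
  cache <- list()

  c1 <- conv_forward(X1, p$c1_W, p$c1_b, s$c1)
  bn1 <- bn_forward(c1$out, p$bn1_gamma, p$bn1_beta, b$bn1_mean, b$bn1_var, training)
  r1 <- relu_forward(bn1$out)
  c2 <- conv_forward(r1$out, p$c2_W, p$c2_b, s$c2)
  p1 <- pool_forward(c2$out, s$p1)
  bn2 <- bn_forward(p1$out, p$bn2_gamma, p$bn2_beta, b$bn2_mean, b$bn2_var, training)
  r2 <- relu_forward(bn2$out)
  h1 <- relu_forward(r2$out %*% p$d1_W + rep(p$d1_b, each = nrow(X1)))

  c3 <- conv_forward(X2, p$c3_W, p$c3_b, s$c3)
  p2 <- pool_forward(c3$out, s$p2)
  bn3 <- bn_forward(p2$out, p$bn3_gamma, p$bn3_beta, b$bn3_mean, b$bn3_var, training)
  r3 <- relu_forward(bn3$out)
  h2 <- relu_forward(r3$out %*% p$d2_W + rep(p$d2_b, each = nrow(X2)))

  H <- cbind(h1$out, h2$out)
  a1 <- relu_forward(H %*% p$f1_W + rep(p$f1_b, each = nrow(H)))
  a2 <- relu_forward(a1$out %*% p$f2_W + rep(p$f2_b, each = nrow(H)))
  if (training && net$config$dropout > 0) {
    keep <- 1 - net$config$dropout
    mask <- matrix(stats::runif(length(a2$out)) < keep, nrow(a2$out), ncol(a2$out)) / keep
    dropped <- a2$out * mask
  } else {
    mask <- NULL
    dropped <- a2$out
  }
  Z <- dropped %*% p$out_W + rep(p$out_b, each = nrow(H))
  prob <- softmax_rows(Z)

  out <- list(prob = prob)
  if (training) {
    out$cache <- list(X1 = X1, X2 = X2, c1 = c1, bn1 = bn1, r1 = r1, c2 = c2,
                      p1 = p1, bn2 = bn2, r2 = r2, h1 = h1, c3 = c3, p2 = p2,
                      bn3 = bn3, r3 = r3, h2 = h2, H = H, a1 = a1, a2 = a2,
                      mask = mask, dropped = dropped, prob = prob)
    out$buffers <- list(
      bn1_mean = bn1$run_mean, bn1_var = bn1$run_var,
      bn2_mean = bn2$run_mean, bn2_var = bn2$run_var,
      bn3_mean = bn3$run_mean, bn3_var = bn3$run_var)
  }
  out
}

# Backward pass from MSE-on-softmax against one-hot targets Y (n x 2).
# Returns gradients for every parameter (L2 terms added for the two
# fusion dense kernels).
nn_backward <- function(net, cache, Y) {
  p <- net$params; s <- net$spec
  n <- nrow(Y)
  g <- list()

  prob <- cache$prob
  dprob <- 2 * (prob - Y) / length(Y)          # mean over all entries
  dZ <- prob * (dprob - rowSums(dprob * prob)) # softmax jacobian

  g$out_W <- crossprod(cache$dropped, dZ)
  g$out_b <- colSums(dZ)
  dDrop <- tcrossprod(dZ, p$out_W)
  dA2 <- if (is.null(cache$mask)) dDrop else dDrop * cache$mask
  dA2 <- dA2 * cache$a2$mask
  g$f2_W <- crossprod(cache$a1$out, dA2) + 2 * net$config$l2 * p$f2_W
  g$f2_b <- colSums(dA2)
  dA1 <- tcrossprod(dA2, p$f2_W) * cache$a1$mask
  g$f1_W <- crossprod(cache$H, dA1) + 2 * net$config$l2 * p$f1_W
  g$f1_b <- colSums(dA1)
  dH <- tcrossprod(dA1, p$f1_W)
  dw <- net$config$module_dense
  dh1 <- dH[, seq_len(dw), drop = FALSE] * cache$h1$mask
  dh2 <- dH[, dw + seq_len(dw), drop = FALSE] * cache$h2$mask

  # module 1
  g$d1_W <- crossprod(cache$r2$out, dh1)
  g$d1_b <- colSums(dh1)
  dr2 <- tcrossprod(dh1, p$d1_W) * cache$r2$mask
  bb2 <- bn_backward(dr2, cache$bn2$cache, p$bn2_gamma)
  g$bn2_gamma <- bb2$dgamma; g$bn2_beta <- bb2$dbeta
  dp1 <- pool_backward(bb2$dX, cache$p1, s$p1)
  cb2 <- conv_backward(dp1, cache$c2, p$c2_W, s$c2)
  g$c2_W <- cb2$dW; g$c2_b <- cb2$db
  dr1 <- cb2$dX * cache$r1$mask
  bb1 <- bn_backward(dr1, cache$bn1$cache, p$bn1_gamma)
  g$bn1_gamma <- bb1$dgamma; g$bn1_beta <- bb1$dbeta
  cb1 <- conv_backward(bb1$dX, cache$c1, p$c1_W, s$c1)
  g$c1_W <- cb1$dW; g$c1_b <- cb1$db

  # module 2
  g$d2_W <- crossprod(cache$r3$out, dh2)
  g$d2_b <- colSums(dh2)
  dr3 <- tcrossprod(dh2, p$d2_W) * cache$r3$mask
  bb3 <- bn_backward(dr3, cache$bn3$cache, p$bn3_gamma)
  g$bn3_gamma <- bb3$dgamma; g$bn3_beta <- bb3$dbeta
  dp2 <- pool_backward(bb3$dX, cache$p2, s$p2)
  cb3 <- conv_backward(dp2, cache$c3, p$c3_W, s$c3)
  g$c3_W <- cb3$dW; g$c3_b <- cb3$db

  g
}

nn_loss <- function(net, prob, Y) {
  mse <- mean((prob - Y)^2)
  reg <- net$config$l2 * (sum(net$params$f1_W^2) + sum(net$params$f2_W^2))
  mse + reg
}

adagrad_init <- function(params) {
  lapply(params, function(w) array(ADAGRAD_INIT, dim = if (is.matrix(w)) dim(w)
                                   else length(w)))
}

adagrad_step <- function(params, grads, acc, lr) {
  cpp_adagrad_step(params, grads, acc, lr, ADAGRAD_EPS)
}
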