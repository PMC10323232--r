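# Layer primitives for the window classifier, implemented on BLAS-backed
# base-R matrix operations. Activation arrays use the layout (H, W, N, C)
# with N = batch * time; convolution is im2col + GEMM so that a flattened
# (H, W, N, Cin) slice indexes rows of the column matrix directly.
# Every *_fw returns list(out, cache); every *_bw consumes that cache.

# no bias: batch normalisation follows immediately and absorbs it.
# The inner loops live in src/conv3x3.cpp; the backward pass recomputes the
# input patches from the cached activations instead of storing an im2col
# matrix, trading a little compute for a 9x smaller cache.
conv_fw <- function(A, Wm, keep_cache = TRUE) {
  Y <- cpp_conv3x3_fw(A, dim(A), Wm)
  list(out = Y,
       cache = if (keep_cache) list(A = A, dimA = dim(A), Wm = Wm) else NULL)
}

conv_bw <- function(dY, cache, need_dx = TRUE) {
  r <- cpp_conv3x3_bw(cache$A, cache$dimA, dY, cache$Wm, need_dx)
  list(dX = r$dX, dW = r$dW)
}

# batch normalisation with an optionally fused ReLU (the conv blocks always
# use the fused form; the mask gates the backward pass)
bn_fw <- function(A, gamma, beta, run_mean, run_var, training,
                  momentum = 0.9, eps = 1e-5, relu = TRUE) {
  d <- dim(A); C <- d[4]
  n <- prod(d[1:3])
  if (training) {
    r <- cpp_bn_fw_train(A, n, C, gamma, beta, eps, relu)
    run_mean <- momentum * run_mean + (1 - momentum) * r$mu
    run_var <- momentum * run_var + (1 - momentum) * r$var
    Y <- r$Y
    dim(Y) <- d
    return(list(out = Y,
                cache = list(xhat = r$xhat, invstd = r$invstd, gamma = gamma,
                             mask = if (relu) r$mask else NULL, dimA = d),
                run_mean = run_mean, run_var = run_var))
  }
  invstd <- 1 / sqrt(run_var + eps)
  scale <- gamma * invstd
  Y <- cpp_bn_fw_infer(A, n, C, scale, beta - run_mean * scale, relu)
  dim(Y) <- d
  list(out = Y, cache = NULL, run_mean = run_mean, run_var = run_var)
}

bn_bw <- function(dY, cache) {
  d <- cache$dimA; C <- d[4]
  n <- prod(d[1:3])
  r <- cpp_bn_bw(dY, cache$xhat, n, C, cache$gamma, cache$invstd, cache$mask)
  dX <- r$dX
  dim(dX) <- d
  list(dX = dX, dgamma = r$dgamma, dbeta = r$dbeta)
}

relu_fw <- function(A, keep_cache = TRUE) {
  mask <- A > 0
  list(out = A * mask, cache = if (keep_cache) mask else NULL)
}

relu_bw <- function(dY, mask) {
  dY[!mask] <- 0
  dY
}

pool_fw <- function(A, keep_cache = TRUE) {
  d <- dim(A)
  r <- cpp_maxpool_fw(A, d, keep_cache)
  list(out = r$Y,
       cache = if (keep_cache) list(argmax = r$argmax, dimA = d) else NULL)
}

pool_bw <- function(dY, cache) {
  cpp_maxpool_bw(dY, cache$argmax, cache$dimA)
}

gpool_fw <- function(A, keep_cache = TRUE) {
  d <- dim(A)  # (h, w, N, C)
  r <- cpp_gpool_fw(A, d, keep_cache)
  list(out = r$F,
       cache = if (keep_cache) list(argmax = r$argmax, dimA = d) else NULL)
}

gpool_bw <- function(dF, cache) {
  cpp_gpool_bw(dF, cache$argmax, cache$dimA)
}

sigm <- function(x) 1 / (1 + exp(-x))

gru_fw <- function(Xseq, p) {
  # Xseq: (T, B, D); p: list Wz,Wr,Wh (DxU), Uz,Ur,Uh (UxU), bz,br,bh (U)
  Tn <- dim(Xseq)[1]; B <- dim(Xseq)[2]; D <- dim(Xseq)[3]
  U <- length(p$bz)
  h <- matrix(0, B, U)
  steps <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    xt <- matrix(Xseq[t, , ], B, D)
    z <- sigm(sweep(xt %*% p$Wz + h %*% p$Uz, 2L, p$bz, "+"))
    r <- sigm(sweep(xt %*% p$Wr + h %*% p$Ur, 2L, p$br, "+"))
    rh <- r * h
    hh <- tanh(sweep(xt %*% p$Wh + rh %*% p$Uh, 2L, p$bh, "+"))
    hn <- z * h + (1 - z) * hh
    steps[[t]] <- list(xt = xt, hprev = h, z = z, r = r, hh = hh, rh = rh)
    h <- hn
  }
  list(out = h, cache = list(steps = steps, p = p, dims = c(Tn, B, D, U)))
}

gru_bw <- function(dh, cache) {
  p <- cache$p
  dims <- cache$dims
  Tn <- dims[1]; B <- dims[2]; D <- dims[3]; U <- dims[4]
  g <- list(Wz = 0 * p$Wz, Wr = 0 * p$Wr, Wh = 0 * p$Wh,
            Uz = 0 * p$Uz, Ur = 0 * p$Ur, Uh = 0 * p$Uh,
            bz = 0 * p$bz, br = 0 * p$br, bh = 0 * p$bh)
  dX <- array(0, c(Tn, B, D))
  for (t in rev(seq_len(Tn))) {
    s <- cache$steps[[t]]
    dz <- dh * (s$hprev - s$hh)
    dhh <- dh * (1 - s$z)
    dhprev <- dh * s$z
    dhh_pre <- dhh * (1 - s$hh^2)
    dxt <- tcrossprod(dhh_pre, p$Wh)
    drh <- tcrossprod(dhh_pre, p$Uh)
    dr <- drh * s$hprev
    dhprev <- dhprev + drh * s$r
    dz_pre <- dz * s$z * (1 - s$z)
    dr_pre <- dr * s$r * (1 - s$r)
    dxt <- dxt + tcrossprod(dz_pre, p$Wz) + tcrossprod(dr_pre, p$Wr)
    dhprev <- dhprev + tcrossprod(dz_pre, p$Uz) + tcrossprod(dr_pre, p$Ur)
    g$Wz <- g$Wz + crossprod(s$xt, dz_pre)
    g$Wr <- g$Wr + crossprod(s$xt, dr_pre)
    g$Wh <- g$Wh + crossprod(s$xt, dhh_pre)
    g$Uz <- g$Uz + crossprod(s$hprev, dz_pre)
    g$Ur <- g$Ur + crossprod(s$hprev, dr_pre)
    g$Uh <- g$Uh + crossprod(s$rh, dhh_pre)
    g$bz <- g$bz + colSums(dz_pre)
    g$br <- g$br + colSums(dr_pre)
    g$bh <- g$bh + colSums(dhh_pre)
    dX[t, , ] <- dxt
    dh <- dhprev
  }
  list(dX = dX, grads = g)
}

softmax_rows <- function(L) {
  L <- L - apply(L, 1L, max)
  E <- exp(L)
  E / rowSums(E)
}
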