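## Minimal neural-network engine for 3D volumes.
##
## Tensors are plain R arrays laid out (H, W, D, C). Convolution is im2col +
## matrix multiply with the gather indices precomputed per configuration;
## transposed convolution is implemented as the exact adjoint of convolution,
## reusing the same index machinery. All backward passes are hand-derived and
## guarded by finite-difference tests.

.conv_cache <- new.env(parent = emptyenv())

## Gather-index matrix for im2col: rows = output sites (column-major over the
## output grid), cols = kernel offsets x input channels (column-major,
## matching the flattening of a (kh,kw,kd,cin,cout) weight array).
conv_idx <- function(dims, cin, kernel, stride, pad) {
  key <- paste(c(dims, cin, kernel, stride, pad), collapse = ",")
  hit <- .conv_cache[[key]]
  if (!is.null(hit)) return(hit)
  dp <- dims + 2L * pad
  oh <- (dp - kernel) %/% stride + 1L
  stopifnot(all(oh >= 1L))
  base <- as.vector(outer(outer((0:(oh[1] - 1)) * stride[1],
                                dp[1] * (0:(oh[2] - 1)) * stride[2], `+`),
                          dp[1] * dp[2] * (0:(oh[3] - 1)) * stride[3], `+`))
  off_grid <- expand.grid(a = 0:(kernel[1] - 1), b = 0:(kernel[2] - 1),
                          c = 0:(kernel[3] - 1), ci = 0:(cin - 1))
  offs <- off_grid$a + dp[1] * off_grid$b + dp[1] * dp[2] * off_grid$c +
    dp[1] * dp[2] * dp[3] * off_grid$ci
  idx <- outer(base, offs, `+`) + 1L
  out <- list(idx = idx, out_dims = oh, padded_dims = dp)
  .conv_cache[[key]] <- out
  out
}

pad3 <- function(x, pad) {
  if (all(pad == 0L)) return(x)
  d <- dim(x)
  dp <- d
  dp[1:3] <- d[1:3] + 2L * pad
  out <- array(0, dp)
  out[pad[1] + seq_len(d[1]), pad[2] + seq_len(d[2]),
      pad[3] + seq_len(d[3]), ] <- x
  out
}

unpad3 <- function(x, pad, dims) {
  if (all(pad == 0L)) return(x)
  x[pad[1] + seq_len(dims[1]), pad[2] + seq_len(dims[2]),
    pad[3] + seq_len(dims[3]), , drop = FALSE]
}

conv3d_fwd <- function(x, W, b, stride = c(1L, 1L, 1L), pad = NULL) {
  kd <- dim(W)
  d <- dim(x)
  if (is.null(pad)) pad <- (kd[1:3] - 1L) %/% 2L
  stopifnot(d[4] == kd[4])
  ci <- conv_idx(d[1:3], d[4], kd[1:3], as.integer(stride), as.integer(pad))
  xp <- pad3(x, pad)
  P <- matrix(xp[ci$idx], nrow = nrow(ci$idx))
  Wm <- matrix(W, ncol = kd[5])
  Y <- P %*% Wm
  Y <- sweep(Y, 2, b, `+`)
  y <- array(Y, c(ci$out_dims, kd[5]))
  list(y = y, cache = list(P = P, ci = ci, Wm = Wm, kdim = kd,
                           in_dims = d, pad = pad))
}

conv3d_bwd <- function(cache, dY) {
  kd <- cache$kdim
  dYm <- matrix(dY, ncol = kd[5])
  dW <- array(crossprod(cache$P, dYm), kd)
  db <- colSums(dYm)
  dP <- dYm %*% t(cache$Wm)
  dp_dims <- c(cache$ci$padded_dims, cache$in_dims[4])
  dxp <- numeric(prod(dp_dims))
  idx <- cache$ci$idx
  for (j in seq_len(ncol(idx)))
    dxp[idx[, j]] <- dxp[idx[, j]] + dP[, j]
  dxp <- array(dxp, dp_dims)
  dx <- unpad3(dxp, cache$pad, cache$in_dims[1:3])
  list(dx = dx, dW = dW, db = db)
}

## Transposed convolution: weight array (kh,kw,kd,cout,cin); for input with
## extent n the output extent is stride*(n-1) + kernel - 2*pad. Forward is
## the adjoint (scatter) of the matching convolution; backward reuses the
## convolution forward.
tconv3d_fwd <- function(x, W, b, stride = c(2L, 2L, 2L), pad = NULL) {
  kd <- dim(W)                      # (kh,kw,kd,cout,cin)
  d <- dim(x)
  stopifnot(d[4] == kd[5])
  if (is.null(pad)) pad <- pmax((kd[1:3] - as.integer(stride)) %/% 2L, 0L)
  out_dims <- as.integer(stride) * (d[1:3] - 1L) + kd[1:3] - 2L * as.integer(pad)
  ci <- conv_idx(out_dims, kd[4], kd[1:3], as.integer(stride),
                 as.integer(pad))
  stopifnot(all(ci$out_dims == d[1:3]))
  Wm <- matrix(W, ncol = kd[5])     # rows: kernel x cout, cols: cin
  xm <- matrix(x, ncol = d[4])
  dP <- xm %*% t(Wm)
  dp_dims <- c(ci$padded_dims, kd[4])
  yp <- numeric(prod(dp_dims))
  idx <- ci$idx
  for (j in seq_len(ncol(idx)))
    yp[idx[, j]] <- yp[idx[, j]] + dP[, j]
  yp <- array(yp, dp_dims)
  y <- unpad3(yp, pad, out_dims)
  y <- sweep(y, 4, b, `+`)
  list(y = y, cache = list(ci = ci, Wm = Wm, kdim = kd, xm = xm,
                           in_dims = d, out_dims = out_dims, pad = pad))
}

tconv3d_bwd <- function(cache, dY) {
  kd <- cache$kdim
  gp <- pad3(dY, cache$pad)
  P <- matrix(gp[cache$ci$idx], nrow = nrow(cache$ci$idx))
  dx <- array(P %*% cache$Wm, cache$in_dims)
  dW <- array(crossprod(P, cache$xm), kd)
  db <- apply(dY, 4, sum)
  list(dx = dx, dW = dW, db = db)
}

## Activations -----------------------------------------------------------

act_fwd <- function(x, kind) {
  y <- switch(kind,
              silu = x * (1 / (1 + exp(-x))),
              lrelu = ifelse(x > 0, x, 0.2 * x),
              tanh = tanh(x),
              identity = x,
              stop("unknown activation ", kind))
  list(y = y, cache = list(x = x, y = y, kind = kind))
}

act_bwd <- function(cache, dy) {
  x <- cache$x
  g <- switch(cache$kind,
              silu = { s <- 1 / (1 + exp(-x)); s * (1 + x * (1 - s)) },
              lrelu = ifelse(x > 0, 1, 0.2),
              tanh = 1 - cache$y^2,
              identity = array(1, dim(x)))
  dy * g
}

dense_fwd <- function(x, W, b) {
  y <- x %*% W
  y <- sweep(y, 2, b, `+`)
  list(y = y, cache = list(x = x, W = W))
}

dense_bwd <- function(cache, dy) {
  list(dx = dy %*% t(cache$W), dW = crossprod(cache$x, dy), db = colSums(dy))
}

## Initialization --------------------------------------------------------

he_conv <- function(kernel, cin, cout, gain = 1) {
  fan_in <- prod(kernel) * cin
  array(stats::rnorm(prod(kernel) * cin * cout, sd = gain * sqrt(2 / fan_in)),
        c(kernel, cin, cout))
}

he_tconv <- function(kernel, cin, cout, gain = 1) {
  fan_in <- prod(kernel) * cin
  array(stats::rnorm(prod(kernel) * cout * cin, sd = gain * sqrt(2 / fan_in)),
        c(kernel, cout, cin))
}

he_dense <- function(nin, nout, gain = 1) {
  matrix(stats::rnorm(nin * nout, sd = gain * sqrt(2 / nin)), nin, nout)
}

## Single-head scaled dot-product self-attention over a (B, L, C) stack:
## each of the B independent sequences of length L attends over itself.
attn_seq_fwd <- function(X, Wq, Wk, Wv, Wo) {
  d <- dim(X)
  B <- d[1]; L <- d[2]; C <- d[3]
  sc <- 1 / sqrt(C)
  O <- array(0, d)
  cache <- vector("list", B)
  for (b in seq_len(B)) {
    Xb <- matrix(X[b, , ], L, C)
    Q <- Xb %*% Wq; K <- Xb %*% Wk; V <- Xb %*% Wv
    S <- (Q %*% t(K)) * sc
    S <- S - apply(S, 1, max)
    A <- exp(S); A <- A / rowSums(A)
    Hd <- A %*% V
    O[b, , ] <- Hd %*% Wo
    cache[[b]] <- list(Xb = Xb, Q = Q, K = K, V = V, A = A, Hd = Hd)
  }
  list(y = O, cache = list(per = cache, Wq = Wq, Wk = Wk, Wv = Wv, Wo = Wo,
                           sc = sc, dims = d))
}

attn_seq_bwd <- function(cache, dO) {
  d <- cache$dims
  B <- d[1]; L <- d[2]; C <- d[3]
  sc <- cache$sc
  dX <- array(0, d)
  dWq <- matrix(0, C, C); dWk <- dWq; dWv <- dWq; dWo <- dWq
  for (b in seq_len(B)) {
    cb <- cache$per[[b]]
    dOb <- matrix(dO[b, , ], L, C)
    dWo <- dWo + crossprod(cb$Hd, dOb)
    dH <- dOb %*% t(cache$Wo)
    dA <- dH %*% t(cb$V)
    dV <- crossprod(cb$A, dH)
    # softmax rows: dS = A * (dA - rowSums(dA * A))
    dS <- cb$A * (dA - rowSums(dA * cb$A))
    dQ <- (dS %*% cb$K) * sc
    dK <- (t(dS) %*% cb$Q) * sc
    dWq <- dWq + crossprod(cb$Xb, dQ)
    dWk <- dWk + crossprod(cb$Xb, dK)
    dWv <- dWv + crossprod(cb$Xb, dV)
    dX[b, , ] <- dQ %*% t(cache$Wq) + dK %*% t(cache$Wk) + dV %*% t(cache$Wv)
  }
  list(dX = dX, dWq = dWq, dWk = dWk, dWv = dWv, dWo = dWo)
}

## Reshape helpers between a (H,W,D,C) feature map and a (B,L,C) stack.
## spatial: sequences are the H*W in-plane positions, one per depth slice.
## depth:   sequences are the D depth positions, one per in-plane site.
to_seq <- function(x, mode) {
  d <- dim(x)
  m <- matrix(x, prod(d[1:3]), d[4])          # rows ordered i fastest, then j, k
  if (mode == "spatial") {
    out <- array(0, c(d[3], d[1] * d[2], d[4]))
    for (k in seq_len(d[3]))
      out[k, , ] <- m[(k - 1) * d[1] * d[2] + seq_len(d[1] * d[2]), ]
  } else {
    out <- array(0, c(d[1] * d[2], d[3], d[4]))
    for (k in seq_len(d[3]))
      out[, k, ] <- m[(k - 1) * d[1] * d[2] + seq_len(d[1] * d[2]), ]
  }
  out
}

from_seq <- function(s, dims, mode) {
  m <- matrix(0, prod(dims[1:3]), dims[4])
  if (mode == "spatial") {
    for (k in seq_len(dims[3]))
      m[(k - 1) * dims[1] * dims[2] + seq_len(dims[1] * dims[2]), ] <- s[k, , ]
  } else {
    for (k in seq_len(dims[3]))
      m[(k - 1) * dims[1] * dims[2] + seq_len(dims[1] * dims[2]), ] <- s[, k, ]
  }
  array(m, dims)
}

attn3d_fwd <- function(x, p, mode) {
  s <- to_seq(x, mode)
  af <- attn_seq_fwd(s, p$Wq, p$Wk, p$Wv, p$Wo)
  y <- x + from_seq(af$y, dim(x), mode)       # residual connection
  list(y = y, cache = list(att = af$cache, mode = mode, dims = dim(x)))
}

attn3d_bwd <- function(cache, dy) {
  ds <- to_seq(dy, cache$mode)
  ab <- attn_seq_bwd(cache$att, ds)
  dx <- dy + from_seq(ab$dX, cache$dims, cache$mode)
  list(dx = dx, dWq = ab$dWq, dWk = ab$dWk, dWv = ab$dWv, dWo = ab$dWo)
}

#' Spatial self-attention over a 3D feature map
#'
#' Scaled dot-product self-attention among the in-plane (row, column)
#' positions of a feature map, applied independently per depth slice — the
#' depth axis is treated as an extension of the batch axis — followed by a
#' residual connection. Output shape equals input shape.
#'
#' @param features 4D array (H, W, D, C).
#' @param params Optional list with C x C matrices `Wq`, `Wk`, `Wv`, `Wo`;
#'   defaults to identity-query random projections drawn from the current RNG
#'   state when omitted.
#' @return 4D array of the same shape.
#' @export
spatial_attention <- function(features, params = NULL) {
  stopifnot(length(dim(features)) == 4L)
  if (is.null(params)) params <- attn_params(dim(features)[4])
  attn3d_fwd(features, params, "spatial")$y
}

#' Depth self-attention over a 3D feature map
#'
#' Scaled dot-product self-attention among the depth positions of a feature
#' map, applied independently per in-plane site — the high-resolution plane
#' axes are treated as batch axes — followed by a residual connection. This
#' lets every in-plane feature vector attend across slices, giving the model
#' its through-plane consistency.
#'
#' @inheritParams spatial_attention
#' @return 4D array of the same shape.
#' @export
depth_attention <- function(features, params = NULL) {
  stopifnot(length(dim(features)) == 4L)
  if (is.null(params)) params <- attn_params(dim(features)[4])
  attn3d_fwd(features, params, "depth")$y
}

attn_params <- function(C, gain = 0.5) {
  list(Wq = he_dense(C, C, gain), Wk = he_dense(C, C, gain),
       Wv = he_dense(C, C, gain), Wo = he_dense(C, C, gain))
}

## Adam / AdamW over a flat named list of arrays -------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    if (weight_decay > 0)
      params[[nm]] <- params[[nm]] - lr * weight_decay * params[[nm]]
    params[[nm]] <- params[[nm]] - lr * upd
  }
  list(params = params, state = state)
}

## Flatten/unflatten nested parameter lists so Adam can treat a whole model
## as one flat collection.
flatten_params <- function(x, prefix = "") {
  out <- list()
  for (nm in names(x)) {
    key <- if (prefix == "") nm else paste0(prefix, ".", nm)
    if (is.list(x[[nm]])) out <- c(out, flatten_params(x[[nm]], key))
    else out[[key]] <- x[[nm]]
  }
  out
}

unflatten_params <- function(flat) {
  out <- list()
  for (key in names(flat)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    out <- assign_path(out, parts, flat[[key]])
  }
  out
}

assign_path <- function(lst, parts, value) {
  if (length(parts) == 1L) { lst[[parts]] <- value; return(lst) }
  head <- parts[1]
  if (is.null(lst[[head]])) lst[[head]] <- list()
  lst[[head]] <- assign_path(lst[[head]], parts[-1], value)
  lst
}

## Accumulate grads (same structure) across a batch.
acc_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}

scale_grads <- function(g, s) lapply(g, function(x) x * s)

## Per-channel instance normalization with learned scale/shift; normalizes
## over the spatial axes of a (H,W,D,C) map. Stabilizes the deeper
## encoder/decoder stacks against constant-output collapse.
inorm_fwd <- function(x, g, b, eps = 1e-5) {
  d <- dim(x)
  n <- prod(d[1:3])
  xm <- matrix(x, n, d[4])
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  v <- colMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xh <- sweep(xc, 2, istd, `*`)
  y <- sweep(sweep(xh, 2, g, `*`), 2, b, `+`)
  list(y = array(y, d), cache = list(xh = xh, istd = istd, g = g, dims = d))
}

inorm_bwd <- function(cache, dy) {
  d <- cache$dims
  n <- prod(d[1:3])
  dym <- matrix(dy, n, d[4])
  dg <- colSums(dym * cache$xh)
  db <- colSums(dym)
  dxh <- sweep(dym, 2, cache$g, `*`)
  # d x = istd * (dxh - mean(dxh) - xh * mean(dxh * xh)) per channel
  m1 <- colMeans(dxh)
  m2 <- colMeans(dxh * cache$xh)
  dx <- sweep(dxh, 2, m1) - sweep(cache$xh, 2, m2, `*`)
  dx <- sweep(dx, 2, cache$istd, `*`)
  list(dx = array(dx, d), dg = dg, db = db)
}
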