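#' Latent grid shape under a compression factor
#'
#' The encoder reduces every axis of an (H, W, D) volume by the compression
#' factor `s`, so a 256 x 256 x 32 volume maps to a 64 x 64 x 8 latent grid
#' at s = 4 and 32 x 32 x 4 at s = 8.
#'
#' @param input_shape Integer length-3 extents (H, W, D).
#' @param s Compression factor (1, 2, 4, 8, ...).
#' @return Integer length-3 latent extents.
#' @export
latent_shape <- function(input_shape, s) {
  input_shape <- as.integer(input_shape)
  s <- as.integer(s)
  if (s < 1L || bitwAnd(s, s - 1L) != 0L)
    stop("latent_shape: s must be a power of two >= 1", call. = FALSE)
  if (any(input_shape %% s != 0L))
    stop("latent_shape: extents ", paste(input_shape, collapse = "x"),
         " not divisible by s = ", s, call. = FALSE)
  input_shape %/% s
}

#' Vector-quantization codebook
#'
#' `n` learnable `k`-dimensional vectors with exponential-moving-average
#' accumulators. Codebook vectors are optimized not by gradient descent but
#' by maintaining an EMA over the latent vectors assigned to each entry
#' (see [codebook_ema_update()]).
#'
#' @param n Number of entries, >= 2.
#' @param k Vector dimension (latent channels).
#' @param decay EMA decay in \[0, 1).
#' @param eps Numerical floor for the usage counts.
#' @param init Optional n x k matrix of initial vectors; defaults to
#'   Normal(0, 0.5) draws from the current RNG state.
#' @return An object of class `codebook`.
#' @export
codebook <- function(n, k, decay = 0.99, eps = 1e-5, init = NULL) {
  n <- as.integer(n); k <- as.integer(k)
  if (n < 2L) stop("codebook: need at least 2 entries", call. = FALSE)
  if (decay < 0 || decay >= 1) stop("codebook: decay must be in [0, 1)",
                                    call. = FALSE)
  vectors <- if (is.null(init)) matrix(stats::rnorm(n * k, sd = 0.5), n, k)
             else { stopifnot(all(dim(init) == c(n, k))); init }
  structure(list(vectors = vectors,
                 ema_counts = rep(1, n),
                 ema_sums = vectors,
                 decay = decay, eps = eps, n = n, k = k),
            class = "codebook")
}

#' @export
print.codebook <- function(x, ...) {
  cat(sprintf("<codebook> %d entries of dimension %d, EMA decay %g\n",
              x$n, x$k, x$decay))
  invisible(x)
}

#' Quantize a latent grid against a codebook
#'
#' Replaces the latent vector at each grid site with its nearest codebook
#' entry in Euclidean distance; ties are broken toward the lowest index.
#'
#' @param z 4D array (h, w, d, k) of continuous latents, or a matrix with k
#'   columns.
#' @param cb A [codebook()] with matching dimension `k`.
#' @return A list with `z_q` (quantized grid, same shape as `z`) and
#'   `indices` (integer array of codebook indices, shape h x w x d).
#' @export
quantize_latents <- function(z, cb) {
  stopifnot(inherits(cb, "codebook"))
  dims <- dim(z)
  k <- dims[length(dims)]
  if (k != cb$k)
    stop("quantize_latents: channel count ", k, " != codebook dimension ",
         cb$k, call. = FALSE)
  zm <- matrix(z, ncol = k)
  E <- cb$vectors
  # squared distances: ||z||^2 - 2 z.e + ||e||^2 (||z||^2 constant per row)
  D <- -2 * zm %*% t(E)
  D <- sweep(D, 2, rowSums(E^2), `+`)
  idx <- max.col(-D, ties.method = "first")
  zq <- E[idx, , drop = FALSE]
  out_idx <- if (length(dims) > 2L) array(idx, dims[-length(dims)]) else idx
  list(z_q = array(zq, dims), indices = out_idx)
}

#' Straight-through estimator
#'
#' Forward value equals the quantized grid `z_q`; in backpropagation the
#' gradient of any downstream scalar with respect to the continuous latents
#' `z_e` is taken to equal its gradient with respect to this op's output
#' (identity backward), which lets the encoder learn through the
#' non-differentiable quantization step. voxgen's training loops implement
#' the backward rule explicitly; this function documents and supplies the
#' forward value.
#'
#' @param z_e Continuous latent grid.
#' @param z_q Quantized latent grid of the same shape.
#' @return `z_q` (the forward value).
#' @export
straight_through <- function(z_e, z_q) {
  if (!identical(dim(z_e), dim(z_q)))
    stop("straight_through: shapes differ", call. = FALSE)
  z_q
}

#' Commitment loss
#'
#' Mean squared error between the continuous latents and their assigned
#' codebook vectors, averaged over all sites and channels. During training
#' only the continuous latents receive gradients (the quantized side is
#' detached), pulling the encoder toward the codebook.
#'
#' @inheritParams straight_through
#' @return Scalar loss >= 0.
#' @export
commitment_loss <- function(z_e, z_q) {
  if (!identical(dim(z_e), dim(z_q)))
    stop("commitment_loss: shapes differ", call. = FALSE)
  mean((z_e - z_q)^2)
}

#' EMA update of a codebook
#'
#' Updates the per-entry usage counts and vector sums by exponential moving
#' average over the batch of latents assigned to each entry, then sets each
#' vector to its running mean `ema_sums / max(ema_counts, eps)`. With
#' decay 0 an entry jumps exactly to the mean of the vectors assigned to it
#' this step; with a fixed assignment set the vectors converge geometrically
#' (error shrinking by the decay factor per step) to that set's mean.
#'
#' @param cb A [codebook()].
#' @param z Latents as a 4D array (h, w, d, k) or matrix with k columns.
#' @param indices Assignment indices from [quantize_latents()] on `z`.
#' @return The updated [codebook()].
#' @export
codebook_ema_update <- function(cb, z, indices) {
  zm <- matrix(z, ncol = cb$k)
  idx <- as.integer(indices)
  counts <- tabulate(idx, nbins = cb$n)
  sums <- matrix(0, cb$n, cb$k)
  present <- sort(unique(idx))
  if (length(present))
    sums[present, ] <- rowsum(zm, idx)[as.character(present), , drop = FALSE]
  d <- cb$decay
  cb$ema_counts <- d * cb$ema_counts + (1 - d) * counts
  cb$ema_sums <- d * cb$ema_sums + (1 - d) * sums
  cb$vectors <- cb$ema_sums / pmax(cb$ema_counts, cb$eps)
  cb
}

#' Reconstruction loss between a volume and its reconstruction
#'
#' Two modes. `"l1_msssim"` (the default, self-contained) is the mean
#' absolute error plus one minus the multiscale structural similarity; it is
#' symmetric, non-negative, and zero exactly for identical inputs.
#' `"perceptual"` computes a mean slice-wise feature-space distance and
#' requires an externally supplied 2D feature extractor (a function mapping
#' an H x W matrix to a numeric feature vector); no pretrained extractor
#' ships with the package.
#'
#' @param x,xhat [volume3d()] objects or arrays of equal shape.
#' @param mode `"l1_msssim"` or `"perceptual"`.
#' @param extractor Feature-extractor function for perceptual mode.
#' @return Scalar loss >= 0.
#' @export
reconstruction_loss <- function(x, xhat, mode = c("l1_msssim", "perceptual"),
                                extractor = NULL) {
  mode <- match.arg(mode)
  xv <- as_vox(x); yv <- as_vox(xhat)
  if (!identical(dim(xv), dim(yv)))
    stop("reconstruction_loss: shapes differ", call. = FALSE)
  if (mode == "l1_msssim")
    return(mean(abs(xv - yv)) + (1 - ms_ssim(xv, yv)))
  if (is.null(extractor))
    stop("reconstruction_loss: perceptual mode requires a feature extractor",
         call. = FALSE)
  d <- dim(xv)
  mean(vapply(seq_len(d[3]), function(s) {
    fa <- extractor(xv[, , s]); fb <- extractor(yv[, , s])
    mean((fa - fb)^2)
  }, numeric(1)))
}

## Encoder / decoder / discriminators ------------------------------------

vqgan_arch <- function(s, k, base_width, width_cap = 32L) {
  n_levels <- as.integer(round(log2(s)))
  widths <- pmin(base_width * 2^(seq_len(max(n_levels, 1L)) - 1L), width_cap)
  list(n_levels = n_levels, widths = widths, k = k, base_width = base_width)
}

## Each encoder/decoder stage is conv (or transposed conv) -> instance norm
## -> SiLU; the two output convolutions are norm-free. The normalization is
## needed for trainability of the deeper (s >= 4) stacks, which otherwise
## collapse onto a constant cohort-mean reconstruction.
vqgan_init_params <- function(arch) {
  nl <- arch$n_levels
  w <- arch$widths
  normed <- function(W, cout) list(W = W, b = rep(0, cout),
                                   g = rep(1, cout), nb = rep(0, cout))
  enc <- list()
  cin <- 1L
  if (nl == 0L) {
    enc$c1 <- normed(he_conv(c(3, 3, 3), 1L, arch$base_width),
                     arch$base_width)
    cin <- arch$base_width
  } else {
    for (l in seq_len(nl)) {
      enc[[paste0("d", l)]] <- normed(he_conv(c(4, 4, 4), cin, w[l]), w[l])
      cin <- w[l]
    }
  }
  enc$out <- list(W = he_conv(c(3, 3, 3), cin, arch$k), b = rep(0, arch$k))
  dec <- list()
  top <- if (nl == 0L) arch$base_width else w[nl]
  dec$inp <- normed(he_conv(c(3, 3, 3), arch$k, top), top)
  cin <- top
  if (nl > 0L) {
    for (l in rev(seq_len(nl))) {
      cout <- if (l > 1L) w[l - 1L] else arch$base_width
      dec[[paste0("u", l)]] <- normed(he_tconv(c(4, 4, 4), cin, cout), cout)
      cin <- cout
    }
  }
  dec$out <- list(W = he_conv(c(3, 3, 3), cin, 1L), b = 0)
  list(enc = enc, dec = dec)
}

## conv/tconv -> instance norm -> silu stage helpers
stage_fwd <- function(x, p, kind = "conv", stride = c(1L, 1L, 1L),
                      pad = NULL) {
  cv <- if (kind == "conv") conv3d_fwd(x, p$W, p$b, stride, pad)
        else tconv3d_fwd(x, p$W, p$b, stride, pad)
  nr <- inorm_fwd(cv$y, p$g, p$nb)
  ac <- act_fwd(nr$y, "silu")
  list(y = ac$y, cache = list(conv = cv$cache, norm = nr$cache,
                              act = ac$cache, kind = kind))
}

stage_bwd <- function(cache, dy) {
  da <- act_bwd(cache$act, dy)
  nb <- inorm_bwd(cache$norm, da)
  bw <- if (cache$kind == "conv") conv3d_bwd(cache$conv, nb$dx)
        else tconv3d_bwd(cache$conv, nb$dx)
  list(dx = bw$dx, grads = list(W = bw$dW, b = bw$db, g = nb$dg,
                                nb = nb$db))
}

vqgan_encode_fwd <- function(params, arch, x) {
  caches <- list()
  h <- array(x, c(dim(x), 1L))
  if (arch$n_levels == 0L) {
    st <- stage_fwd(h, params$enc$c1)
    caches$c1 <- st$cache
    h <- st$y
  } else {
    for (l in seq_len(arch$n_levels)) {
      nm <- paste0("d", l)
      st <- stage_fwd(h, params$enc[[nm]], "conv", stride = c(2L, 2L, 2L),
                      pad = c(1L, 1L, 1L))
      caches[[nm]] <- st$cache
      h <- st$y
    }
  }
  cv <- conv3d_fwd(h, params$enc$out$W, params$enc$out$b)
  caches$out <- list(conv = cv$cache)
  list(z_e = cv$y, caches = caches)
}

vqgan_encode_bwd <- function(params, arch, caches, dz) {
  grads <- list()
  bw <- conv3d_bwd(caches$out$conv, dz)
  grads$out <- list(W = bw$dW, b = bw$db)
  dh <- bw$dx
  if (arch$n_levels == 0L) {
    sb <- stage_bwd(caches$c1, dh)
    grads$c1 <- sb$grads
  } else {
    for (l in rev(seq_len(arch$n_levels))) {
      nm <- paste0("d", l)
      sb <- stage_bwd(caches[[nm]], dh)
      grads[[nm]] <- sb$grads
      dh <- sb$dx
    }
  }
  grads
}

vqgan_decode_fwd <- function(params, arch, zq) {
  caches <- list()
  st <- stage_fwd(zq, params$dec$inp)
  caches$inp <- st$cache
  h <- st$y
  if (arch$n_levels > 0L) {
    for (l in rev(seq_len(arch$n_levels))) {
      nm <- paste0("u", l)
      st <- stage_fwd(h, params$dec[[nm]], "tconv", stride = c(2L, 2L, 2L),
                      pad = c(1L, 1L, 1L))
      caches[[nm]] <- st$cache
      h <- st$y
    }
  }
  cv <- conv3d_fwd(h, params$dec$out$W, params$dec$out$b)
  tn <- act_fwd(cv$y, "tanh")
  caches$out <- list(conv = cv$cache, act = tn$cache)
  list(xhat = array(tn$y, dim(tn$y)[1:3]), caches = caches)
}

vqgan_decode_bwd <- function(params, arch, caches, dxhat) {
  grads <- list()
  dh <- act_bwd(caches$out$act, array(dxhat, c(dim(dxhat), 1L)))
  bw <- conv3d_bwd(caches$out$conv, dh)
  grads$out <- list(W = bw$dW, b = bw$db)
  dh <- bw$dx
  if (arch$n_levels > 0L) {
    for (l in seq_len(arch$n_levels)) {
      nm <- paste0("u", l)
      sb <- stage_bwd(caches[[nm]], dh)
      grads[[nm]] <- sb$grads
      dh <- sb$dx
    }
  }
  sb <- stage_bwd(caches$inp, dh)
  grads$inp <- sb$grads
  list(grads = grads, dz = sb$dx)
}

## Patch discriminators: `slice` operates on one random depth slice (2D
## kernels), `vol` on the whole volume (3D kernels). Both return the final
## patch score map plus hidden features for the feature-matching loss.
disc_init_params <- function(kind, width = 12L) {
  kern <- if (kind == "slice") c(4L, 4L, 1L) else c(4L, 4L, 4L)
  k2 <- if (kind == "slice") c(3L, 3L, 1L) else c(3L, 3L, 3L)
  list(c1 = list(W = he_conv(kern, 1L, width), b = rep(0, width)),
       c2 = list(W = he_conv(kern, width, 2L * width), b = rep(0, 2L * width)),
       c3 = list(W = he_conv(k2, 2L * width, 1L), b = 0))
}

disc_stride <- function(kind) if (kind == "slice") c(2L, 2L, 1L) else c(2L, 2L, 2L)

disc_fwd <- function(params, kind, x) {
  st <- disc_stride(kind)
  h <- array(x, c(dim(x), 1L))
  c1 <- conv3d_fwd(h, params$c1$W, params$c1$b, stride = st, pad = c(1L, 1L, if (kind == "slice") 0L else 1L))
  a1 <- act_fwd(c1$y, "lrelu")
  c2 <- conv3d_fwd(a1$y, params$c2$W, params$c2$b, stride = st, pad = c(1L, 1L, if (kind == "slice") 0L else 1L))
  a2 <- act_fwd(c2$y, "lrelu")
  c3 <- conv3d_fwd(a2$y, params$c3$W, params$c3$b)
  list(map = c3$y, feats = list(a1$y, a2$y),
       caches = list(c1 = c1$cache, a1 = a1$cache, c2 = c2$cache,
                     a2 = a2$cache, c3 = c3$cache))
}

disc_bwd <- function(caches, dmap, dfeats = NULL) {
  grads <- list()
  bw3 <- conv3d_bwd(caches$c3, dmap)
  grads$c3 <- list(W = bw3$dW, b = bw3$db)
  dh <- bw3$dx
  if (!is.null(dfeats) && !is.null(dfeats[[2]])) dh <- dh + dfeats[[2]]
  da <- act_bwd(caches$a2, dh)
  bw2 <- conv3d_bwd(caches$c2, da)
  grads$c2 <- list(W = bw2$dW, b = bw2$db)
  dh <- bw2$dx
  if (!is.null(dfeats) && !is.null(dfeats[[1]])) dh <- dh + dfeats[[1]]
  da <- act_bwd(caches$a1, dh)
  bw1 <- conv3d_bwd(caches$c1, da)
  grads$c1 <- list(W = bw1$dW, b = bw1$db)
  list(grads = grads, dx = array(bw1$dx, dim(bw1$dx)[1:3]))
}

#' Adversarial losses for a real/reconstruction pair
#'
#' Hinge-formulation GAN losses over the two discriminators of the 3D
#' VQ-GAN: a slice-wise discriminator scoring one random depth slice and a
#' volumetric discriminator scoring the whole volume. Also returns the
#' feature-matching loss (mean L1 distance between per-layer discriminator
#' features of real and fake), used to stabilize training.
#'
#' @param real,fake 3D arrays or [volume3d()] of equal shape.
#' @param disc_s,disc_v Discriminator parameter lists (see [fit_vqgan()]);
#'   fresh random discriminators are drawn when omitted.
#' @param slice_index Depth slice scored by the slice discriminator; random
#'   when `NULL`.
#' @return List with `d_loss`, `g_loss`, `fm_loss`.
#' @export
adversarial_losses <- function(real, fake, disc_s = NULL, disc_v = NULL,
                               slice_index = NULL) {
  real <- as_vox(real); fake <- as_vox(fake)
  stopifnot(identical(dim(real), dim(fake)))
  if (is.null(disc_s)) disc_s <- disc_init_params("slice")
  if (is.null(disc_v)) disc_v <- disc_init_params("vol")
  if (is.null(slice_index)) slice_index <- sample.int(dim(real)[3], 1L)
  rs <- real[, , slice_index, drop = FALSE]
  fs <- fake[, , slice_index, drop = FALSE]
  fr_s <- disc_fwd(disc_s, "slice", rs); ff_s <- disc_fwd(disc_s, "slice", fs)
  fr_v <- disc_fwd(disc_v, "vol", real); ff_v <- disc_fwd(disc_v, "vol", fake)
  hinge_d <- function(r, f) mean(pmax(1 - r, 0)) + mean(pmax(1 + f, 0))
  d_loss <- hinge_d(fr_s$map, ff_s$map) + hinge_d(fr_v$map, ff_v$map)
  g_loss <- -(mean(ff_s$map) + mean(ff_v$map))
  fm <- function(fr, ff)
    mean(vapply(seq_along(fr), function(i) mean(abs(fr[[i]] - ff[[i]])),
                numeric(1)))
  fm_loss <- (fm(fr_s$feats, ff_s$feats) + fm(fr_v$feats, ff_v$feats)) / 2
  list(d_loss = d_loss, g_loss = g_loss, fm_loss = fm_loss)
}

#' Fit a 3D VQ-GAN to a cohort of volumes
#'
#' Trains the vector-quantized adversarial autoencoder: an encoder
#' compresses each volume by the factor `s` per axis into `k` latent
#' channels, the latents are snapped to the nearest codebook vectors, and a
#' decoder reconstructs the volume. The generator objective is
#' `lambda_rec * L_rec + lambda_commit * L_commit + lambda_gan * L_g +
#' lambda_fm * L_fm`; the codebook itself is optimized by EMA over the
#' latents assigned to each entry (replacing an explicit codebook loss
#' term), and the straight-through estimator carries gradients through the
#' quantization step. A slice-wise and a volumetric patch discriminator are
#' trained alongside with the hinge loss; the adversarial weight is held at
#' zero for a warm-up fraction of the steps.
#'
#' @param cohort List of [volume3d()] (values in \[-1, 1\]) or of
#'   `list(volume=, mask=)` pairs as returned by [generate_cohort()].
#' @param s Per-axis compression factor (power of two); every volume extent
#'   must be divisible by it.
#' @param k Latent channels.
#' @param codebook_size Number of codebook entries.
#' @param base_width Encoder/decoder channels at the first level.
#' @param steps Optimizer steps.
#' @param batch_size Volumes per step.
#' @param lr Adam learning rate.
#' @param lambda_rec,lambda_commit,lambda_gan,lambda_fm Loss weights.
#' @param gan_warmup Fraction of steps with the adversarial weight at zero.
#' @param flip_p Probability of a vertical-flip augmentation per batch item.
#' @param seed Seed controlling initialization, batching and augmentation.
#' @param verbose Print progress every 50 steps.
#' @return An object of class `vqgan` with the learned parameters, codebook,
#'   architecture and loss history.
#' @seealso [predict.vqgan()], [fit_latent_ddpm()]
#' @export
fit_vqgan <- function(cohort, s = 2L, k = 8L, codebook_size = 64L,
                      base_width = 16L, steps = 200L, batch_size = 4L,
                      lr = 2e-3, lambda_rec = 1, lambda_commit = 0.25,
                      lambda_gan = 0.2, lambda_fm = 1, gan_warmup = 0.25,
                      flip_p = 0, seed = 1L, verbose = FALSE) {
  vols <- lapply(cohort, function(it) as_vox(if (is.list(it) && !inherits(it, "volume3d")) it$volume else it))
  stopifnot(length(vols) >= 1L)
  shp <- dim(vols[[1]])
  lat <- latent_shape(shp, s)   # validates divisibility
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  arch <- vqgan_arch(s, k, base_width)
  params <- vqgan_init_params(arch)
  cb <- codebook(codebook_size, k)
  dsc <- list(s = disc_init_params("slice"), v = disc_init_params("vol"))
  gen_flat <- flatten_params(params)
  dsc_flat <- flatten_params(dsc)
  opt_g <- adam_init(gen_flat)
  opt_d <- adam_init(dsc_flat)
  history <- data.frame(step = integer(), rec = numeric(), commit = numeric(),
                        g = numeric(), fm = numeric(), d = numeric())
  n <- length(vols)
  for (step in seq_len(steps)) {
    idx <- sample.int(n, min(batch_size, n), replace = n < batch_size)
    use_gan <- lambda_gan > 0 && step > gan_warmup * steps
    g_acc <- NULL; d_acc <- NULL
    losses <- c(rec = 0, commit = 0, g = 0, fm = 0, d = 0)
    for (ii in idx) {
      x <- vols[[ii]]
      if (flip_p > 0 && stats::runif(1) < flip_p)
        x <- x[rev(seq_len(dim(x)[1])), , , drop = FALSE]
      ef <- vqgan_encode_fwd(params, arch, x)
      qz <- quantize_latents(ef$z_e, cb)
      df <- vqgan_decode_fwd(params, arch, qz$z_q)
      rec <- l1_msssim_grad(x, df$xhat)
      comm <- commitment_loss(ef$z_e, qz$z_q)
      dxhat <- lambda_rec * rec$grad_y
      sl <- sample.int(dim(x)[3], 1L)
      if (lambda_gan > 0) {
        rs <- x[, , sl, drop = FALSE]; fs <- df$xhat[, , sl, drop = FALSE]
        fr_s <- disc_fwd(dsc$s, "slice", rs); ff_s <- disc_fwd(dsc$s, "slice", fs)
        fr_v <- disc_fwd(dsc$v, "vol", x);   ff_v <- disc_fwd(dsc$v, "vol", df$xhat)
        g_loss <- -(mean(ff_s$map) + mean(ff_v$map))
        fm_loss <- (mean(abs(fr_s$feats[[1]] - ff_s$feats[[1]])) +
                      mean(abs(fr_s$feats[[2]] - ff_s$feats[[2]])) +
                      mean(abs(fr_v$feats[[1]] - ff_v$feats[[1]])) +
                      mean(abs(fr_v$feats[[2]] - ff_v$feats[[2]]))) / 4
        d_loss <- mean(pmax(1 - fr_s$map, 0)) + mean(pmax(1 + ff_s$map, 0)) +
          mean(pmax(1 - fr_v$map, 0)) + mean(pmax(1 + ff_v$map, 0))
        if (use_gan) {
          # generator gradient through both discriminators (+ feature match)
          dmap_s <- array(-1 / length(ff_s$map), dim(ff_s$map))
          dfe_s <- lapply(1:2, function(i)
            lambda_fm * sign(ff_s$feats[[i]] - fr_s$feats[[i]]) /
              (4 * length(ff_s$feats[[i]])))
          bs <- disc_bwd(ff_s$caches, dmap_s, dfe_s)
          dmap_v <- array(-1 / length(ff_v$map), dim(ff_v$map))
          dfe_v <- lapply(1:2, function(i)
            lambda_fm * sign(ff_v$feats[[i]] - fr_v$feats[[i]]) /
              (4 * length(ff_v$feats[[i]])))
          bv <- disc_bwd(ff_v$caches, dmap_v, dfe_v)
          adv <- bv$dx
          adv[, , sl] <- adv[, , sl] + array(bs$dx, dim(x)[1:2])
          # adaptive balancing (VQ-GAN lineage): scale the adversarial
          # gradient so its norm is lambda_gan times the reconstruction
          # gradient norm at the decoder output
          nr <- sqrt(sum(dxhat^2)); na <- sqrt(sum(adv^2))
          if (na > 0) dxhat <- dxhat + adv * (lambda_gan * nr / na)
        }
        # discriminator step gradients (fake detached)
        dr_s <- array(-(fr_s$map < 1) / length(fr_s$map), dim(fr_s$map))
        df_s <- array((ff_s$map > -1) / length(ff_s$map), dim(ff_s$map))
        dr_v <- array(-(fr_v$map < 1) / length(fr_v$map), dim(fr_v$map))
        df_v <- array((ff_v$map > -1) / length(ff_v$map), dim(ff_v$map))
        gd <- list(
          s = acc_grads(flatten_params(disc_bwd(fr_s$caches, dr_s)$grads),
                        flatten_params(disc_bwd(ff_s$caches, df_s)$grads)),
          v = acc_grads(flatten_params(disc_bwd(fr_v$caches, dr_v)$grads),
                        flatten_params(disc_bwd(ff_v$caches, df_v)$grads)))
        d_acc <- acc_grads(d_acc, flatten_params(gd))
      } else { g_loss <- 0; fm_loss <- 0; d_loss <- 0 }
      db <- vqgan_decode_bwd(params, arch, df$caches, dxhat)
      # straight-through: decoder-input gradient flows to z_e unchanged,
      # plus the commitment pull toward the (detached) codebook vectors
      dz_e <- db$dz + lambda_commit * 2 * (ef$z_e - qz$z_q) / length(ef$z_e)
      ge <- vqgan_encode_bwd(params, arch, ef$caches, dz_e)
      g_acc <- acc_grads(g_acc, flatten_params(list(enc = ge, dec = db$grads)))
      cb <- codebook_ema_update(cb, ef$z_e, qz$indices)
      losses <- losses + c(rec$value, comm, g_loss, fm_loss, d_loss)
    }
    nb <- length(idx)
    losses <- losses / nb
    if (any(!is.finite(losses)))
      stop("fit_vqgan: non-finite loss at step ", step, ": ",
           paste(names(losses), round(losses, 3), collapse = " "),
           call. = FALSE)
    upd <- adam_step(gen_flat, scale_grads(g_acc, 1 / nb), opt_g, lr)
    gen_flat <- upd$params; opt_g <- upd$state
    params <- unflatten_params(gen_flat)
    if (!is.null(d_acc)) {
      upd <- adam_step(dsc_flat, scale_grads(d_acc, 1 / nb), opt_d, lr)
      dsc_flat <- upd$params; opt_d <- upd$state
      dsc <- unflatten_params(dsc_flat)
    }
    history <- rbind(history, data.frame(step = step, rec = losses["rec"],
                                         commit = losses["commit"],
                                         g = losses["g"], fm = losses["fm"],
                                         d = losses["d"]))
    if (verbose && step %% 50L == 0L)
      message(sprintf("step %d: rec %.4f commit %.4f d %.3f", step,
                      losses["rec"], losses["commit"], losses["d"]))
  }
  rownames(history) <- NULL
  structure(list(params = params, arch = arch, codebook = cb, disc = dsc,
                 s = as.integer(s), k = as.integer(k),
                 input_shape = shp, latent_dims = lat,
                 history = history, steps = as.integer(steps),
                 seed = as.integer(seed),
                 call = match.call()),
            class = "vqgan")
}

#' @export
print.vqgan <- function(x, ...) {
  cat(sprintf("<vqgan> compression s=%d, k=%d latent channels, %d codebook entries\n",
              x$s, x$k, x$codebook$n))
  cat(sprintf("  input %s -> latent %s; trained %d steps (seed %d)\n",
              paste(x$input_shape, collapse = "x"),
              paste(x$latent_dims, collapse = "x"), x$steps, x$seed))
  if (nrow(x$history))
    cat(sprintf("  final reconstruction loss %.4f\n",
                tail(x$history$rec, 1)))
  invisible(x)
}

#' @export
summary.vqgan <- function(object, ...) {
  h <- object$history
  used <- length(unique(as.integer(codebook_usage(object))))
  cat("3D vector-quantized adversarial autoencoder\n")
  print(object)
  cat(sprintf("  reconstruction loss: first %.4f -> last %.4f\n",
              h$rec[1], tail(h$rec, 1)))
  cat(sprintf("  codebook entries in active use (EMA count > 1e-3): %d of %d\n",
              sum(object$codebook$ema_counts > 1e-3), object$codebook$n))
  invisible(object)
}

codebook_usage <- function(object) {
  which(object$codebook$ema_counts > 1e-3)
}

#' Encode, quantize or reconstruct volumes with a fitted VQ-GAN
#'
#' @param object A fitted [fit_vqgan()] model.
#' @param newdata A [volume3d()], 3D array, or list of either.
#' @param type `"reconstruction"` (decode the quantized latents),
#'   `"latent"` (continuous encoder output z_e), `"quantized"` (z_q), or
#'   `"indices"` (codebook index grid).
#' @param ... Unused.
#' @return For a single input, an array (or [volume3d()] for
#'   reconstructions); for a list input, a list of the same.
#' @export
predict.vqgan <- function(object, newdata,
                          type = c("reconstruction", "latent", "quantized",
                                   "indices"), ...) {
  type <- match.arg(type)
  single <- inherits(newdata, "volume3d") ||
    (is.array(newdata) && length(dim(newdata)) == 3L)
  items <- if (single) list(newdata) else newdata
  out <- lapply(items, function(it) {
    x <- as_vox(if (is.list(it) && !inherits(it, "volume3d")) it$volume else it)
    if (!identical(dim(x), as.integer(object$input_shape)) &&
        !identical(as.integer(dim(x)), as.integer(object$input_shape)))
      stop("predict.vqgan: input shape ", paste(dim(x), collapse = "x"),
           " does not match model input ",
           paste(object$input_shape, collapse = "x"), call. = FALSE)
    ze <- vqgan_encode_fwd(object$params, object$arch, x)$z_e
    if (type == "latent") return(ze)
    qz <- quantize_latents(ze, object$codebook)
    if (type == "quantized") return(qz$z_q)
    if (type == "indices") return(qz$indices)
    volume3d(vqgan_decode_fwd(object$params, object$arch, qz$z_q)$xhat,
             modality = "synthetic")
  })
  if (single) out[[1]] else out
}

#' Decode a quantized latent grid to a volume
#'
#' @param object A fitted [fit_vqgan()] model.
#' @param z_q Quantized latent grid (h, w, d, k).
#' @return A [volume3d()] with values in \[-1, 1\].
#' @export
decode_latents <- function(object, z_q) {
  stopifnot(inherits(object, "vqgan"))
  volume3d(vqgan_decode_fwd(object$params, object$arch, z_q)$xhat,
           modality = "synthetic")
}

#' @export
plot.vqgan <- function(x, ...) {
  h <- x$history
  graphics::plot(h$step, h$rec, type = "l", xlab = "step",
                 ylab = "reconstruction loss (L1 + 1-MS-SSIM)",
                 main = "VQ-GAN training", ...)
  invisible(x)
}

#' Residual volumes of a fitted VQ-GAN
#'
#' @param object A fitted [fit_vqgan()] model.
#' @param newdata Volumes to reconstruct (defaults to nothing; required).
#' @param ... Unused.
#' @return List of arrays `x - reconstruction`.
#' @export
residuals.vqgan <- function(object, newdata, ...) {
  rec <- predict(object, newdata, type = "reconstruction")
  single <- inherits(newdata, "volume3d") ||
    (is.array(newdata) && length(dim(newdata)) == 3L)
  items <- if (single) list(newdata) else newdata
  recs <- if (single) list(rec) else rec
  out <- Map(function(it, r) {
    x <- as_vox(if (is.list(it) && !inherits(it, "volume3d")) it$volume else it)
    x - as_vox(r)
  }, items, recs)
  if (single) out[[1]] else out
}
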