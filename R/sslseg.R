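#' Patch-masking specification for inpainting pretraining
#'
#' @param patch_size Integer length-3 patch extents in voxels.
#' @param mask_ratio Target masked-voxel fraction in \[0, 1).
#' @param fill_value Value written into masked voxels (0, the midpoint of
#'   the \[-1, 1\] intensity range, by default).
#' @return An object of class `masking_spec`.
#' @export
masking_spec <- function(patch_size = c(4L, 4L, 2L), mask_ratio = 0.3,
                         fill_value = 0) {
  patch_size <- as.integer(patch_size)
  if (length(patch_size) != 3L || any(patch_size < 1L))
    stop("masking_spec: patch_size must be 3 extents >= 1", call. = FALSE)
  if (mask_ratio < 0 || mask_ratio >= 1)
    stop("masking_spec: mask_ratio must be in [0, 1)", call. = FALSE)
  structure(list(patch_size = patch_size, mask_ratio = mask_ratio,
                 fill_value = fill_value), class = "masking_spec")
}

#' Mask random patches of a volume (inpainting pretext task)
#'
#' Draws axis-aligned patches at uniformly random corners (overlap allowed)
#' until the masked fraction reaches `mask_ratio`, sets the masked voxels to
#' the fill value, then applies random horizontal/vertical flips (p = 0.5
#' each) identically to the masked volume, the mask, and the reconstruction
#' target.
#'
#' @param vol A [volume3d()] or 3D array.
#' @param spec A [masking_spec()]; patches must fit inside the volume.
#' @param flip_p Probability of each of the two flips.
#' @return List with `masked` (volume with patches overwritten), `mask`
#'   ([label_mask()] marking masked voxels) and `target` (the original
#'   volume under the same flips).
#' @export
mask_random_patches <- function(vol, spec, flip_p = 0.5) {
  stopifnot(inherits(spec, "masking_spec"))
  x <- as_vox(vol)
  d <- dim(x)
  if (any(spec$patch_size > d))
    stop("mask_random_patches: patch larger than volume", call. = FALSE)
  m <- array(0, d)
  ps <- spec$patch_size
  total <- prod(d)
  if (spec$mask_ratio > 0) {
    repeat {
      corner <- vapply(1:3, function(a) sample.int(d[a] - ps[a] + 1L, 1L),
                       integer(1))
      m[corner[1] + seq_len(ps[1]) - 1L, corner[2] + seq_len(ps[2]) - 1L,
        corner[3] + seq_len(ps[3]) - 1L] <- 1
      if (sum(m) / total >= spec$mask_ratio) break
    }
  }
  masked <- x
  masked[m == 1] <- spec$fill_value
  target <- x
  for (axis in 1:2) {
    if (flip_p > 0 && stats::runif(1) < flip_p) {
      idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
      idx[[axis]] <- rev(idx[[axis]])
      masked <- masked[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
      m <- m[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
      target <- target[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
      dim(masked) <- d; dim(m) <- d; dim(target) <- d
    }
  }
  list(masked = volume3d(masked, modality = "synthetic"),
       mask = label_mask(m), target = volume3d(target, modality = "synthetic"))
}

#' Inpainting reconstruction loss
#'
#' Weighted combination of the mean absolute error and one minus the
#' multiscale structural similarity between prediction and target — the
#' pretext objective of the self-supervised pretraining stage.
#'
#' @param pred,target [volume3d()] or arrays of equal shape.
#' @param w_l1,w_msssim Non-negative weights.
#' @return Scalar loss >= 0, zero iff the inputs are identical.
#' @export
inpaint_loss <- function(pred, target, w_l1 = 0.5, w_msssim = 0.5) {
  p <- as_vox(pred); x <- as_vox(target)
  if (!identical(dim(p), dim(x)))
    stop("inpaint_loss: shapes differ", call. = FALSE)
  w_l1 * mean(abs(p - x)) + w_msssim * (1 - ms_ssim(x, p))
}

#' Segmentation loss: cross-entropy plus soft Dice
#'
#' `scores` are per-voxel class scores (logits) for background/foreground;
#' they are softmax-normalized, the voxelwise cross-entropy against the
#' binary truth is averaged, and a soft Dice computed from the foreground
#' probabilities supplies the second term.
#'
#' @param scores 4D array (H, W, D, 2) of class scores.
#' @param truth A [label_mask()] or binary array (H, W, D).
#' @param w_ce,w_dice Non-negative weights.
#' @return Scalar loss >= 0.
#' @export
seg_loss <- function(scores, truth, w_ce = 0.5, w_dice = 0.5) {
  seg_loss_grad(scores, as_vox(truth), w_ce, w_dice)$value
}

seg_loss_grad <- function(scores, truth, w_ce = 0.5, w_dice = 0.5,
                          eps = 1e-7) {
  d <- dim(scores)
  if (length(d) != 4L || d[4] != 2L)
    stop("seg_loss: scores must be (H, W, D, 2)", call. = FALSE)
  if (!identical(d[1:3], dim(truth)))
    stop("seg_loss: truth shape differs from scores grid", call. = FALSE)
  n <- prod(d[1:3])
  s0 <- scores[, , , 1]; s1 <- scores[, , , 2]
  mx <- pmax(s0, s1)
  e0 <- exp(s0 - mx); e1 <- exp(s1 - mx)
  z <- e0 + e1
  p1 <- e1 / z; p0 <- e0 / z
  ce <- -mean(truth * log(p1 + eps) + (1 - truth) * log(p0 + eps))
  inter <- sum(p1 * truth)
  denom <- sum(p1) + sum(truth) + eps
  dice_soft <- 2 * inter / denom
  value <- w_ce * ce + w_dice * (1 - dice_soft)
  # gradients wrt the logits
  dce_ds1 <- (p1 - truth) / n
  ddice_dp1 <- 2 * (truth * denom - inter) / denom^2
  dd_ds1 <- -w_dice * ddice_dp1 * p1 * p0
  g1 <- w_ce * dce_ds1 + dd_ds1
  g <- array(0, d)
  g[, , , 2] <- g1
  g[, , , 1] <- -g1     # two-class softmax: logit gradients are opposite
  list(value = value, grad = g, ce = ce, dice_soft = dice_soft)
}

#' Augmentation configuration
#'
#' Probabilities and magnitudes for the supervised-training augmentations,
#' applied in the order: flips, affine, ghosting, Gaussian noise, blurring,
#' bias field, gamma. Spatial transforms (flip, affine) are applied
#' identically to the paired mask with nearest-neighbour interpolation;
#' intensity transforms touch the volume only.
#'
#' @param flip_p,affine_p,ghost_p,noise_p,blur_p,bias_p,gamma_p Per-transform
#'   probabilities in \[0, 1\].
#' @param affine_scale Max relative zoom deviation.
#' @param affine_shift Max translation in voxels.
#' @param ghost_strength Amplitude of the periodic slice-intensity
#'   modulation (the MR ghosting analog).
#' @param noise_sd Additive noise standard deviation.
#' @param blur_sigma Gaussian blur sigma in voxels.
#' @param bias_amplitude Multiplicative bias-field amplitude.
#' @param gamma_range Range of the gamma exponent.
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(flip_p = 0.5, affine_p = 0.3, ghost_p = 0.1,
                           noise_p = 0.3, blur_p = 0.2, bias_p = 0.2,
                           gamma_p = 0.3, affine_scale = 0.05,
                           affine_shift = 2, ghost_strength = 0.1,
                           noise_sd = 0.05, blur_sigma = 0.7,
                           bias_amplitude = 0.15, gamma_range = c(0.8, 1.25)) {
  p <- c(flip_p, affine_p, ghost_p, noise_p, blur_p, bias_p, gamma_p)
  if (any(p < 0 | p > 1))
    stop("augment_config: probabilities must be in [0, 1]", call. = FALSE)
  structure(list(flip_p = flip_p, affine_p = affine_p, ghost_p = ghost_p,
                 noise_p = noise_p, blur_p = blur_p, bias_p = bias_p,
                 gamma_p = gamma_p, affine_scale = affine_scale,
                 affine_shift = affine_shift, ghost_strength = ghost_strength,
                 noise_sd = noise_sd, blur_sigma = blur_sigma,
                 bias_amplitude = bias_amplitude, gamma_range = gamma_range),
            class = "augment_config")
}

#' Augment a volume (and optionally its mask)
#'
#' @param vol A [volume3d()] or 3D array.
#' @param mask Optional paired [label_mask()].
#' @param config An [augment_config()].
#' @return List with `volume` and (if supplied) `mask`.
#' @export
augment <- function(vol, mask = NULL, config = augment_config()) {
  x <- as_vox(vol)
  m <- if (!is.null(mask)) as_vox(mask)
  d <- dim(x)
  # flips (one vertical, one horizontal draw)
  for (axis in 1:2) {
    if (stats::runif(1) < config$flip_p) {
      idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
      idx[[axis]] <- rev(idx[[axis]])
      x <- x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]; dim(x) <- d
      if (!is.null(m)) { m <- m[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]; dim(m) <- d }
    }
  }
  # affine: random zoom + translation, trilinear for the image,
  # nearest-neighbour for the mask
  if (stats::runif(1) < config$affine_p) {
    sc <- 1 + stats::runif(3, -config$affine_scale, config$affine_scale)
    sh <- stats::runif(3, -config$affine_shift, config$affine_shift)
    ctr <- (d - 1) / 2
    src <- lapply(1:3, function(a)
      (seq_len(d[a]) - 1 - ctr[a]) / sc[a] + ctr[a] + sh[a])
    g <- expand.grid(i = src[[1]], j = src[[2]], k = src[[3]])
    x <- array(trilinear_at(x, g$i, g$j, g$k), d)
    if (!is.null(m)) {
      gi <- pmin(pmax(round(g$i), 0), d[1] - 1)
      gj <- pmin(pmax(round(g$j), 0), d[2] - 1)
      gk <- pmin(pmax(round(g$k), 0), d[3] - 1)
      m <- array(m[1 + gi + d[1] * (gj + d[2] * gk)], d)
    }
  }
  # ghosting: periodic intensity modulation along the slice axis
  if (stats::runif(1) < config$ghost_p) {
    period <- sample(2:4, 1)
    phase <- stats::runif(1, 0, 2 * pi)
    mod <- 1 + config$ghost_strength * sin(2 * pi * (seq_len(d[3]) - 1) / period + phase)
    x <- sweep(x, 3, mod, `*`)
  }
  if (stats::runif(1) < config$noise_p)
    x <- x + stats::rnorm(length(x), sd = config$noise_sd)
  if (stats::runif(1) < config$blur_p)
    x <- gauss_filter3(x, gauss_kernel(5L, config$blur_sigma))
  if (stats::runif(1) < config$bias_p)
    x <- x * (1 + bias_field(d, config$bias_amplitude))
  if (stats::runif(1) < config$gamma_p) {
    gam <- stats::runif(1, config$gamma_range[1], config$gamma_range[2])
    u <- (pmin(pmax(x, -1), 1) + 1) / 2
    x <- 2 * u^gam - 1
  }
  out <- list(volume = volume3d(x, modality = "synthetic"))
  if (!is.null(m)) out$mask <- label_mask(m)
  out
}

## Segmentation / inpainting backbone: a small 3-level 3D encoder-decoder
## with one skip connection; the trunk is shared between the inpainting
## head (1 channel, tanh) and the segmentation head (2-channel logits), so
## pretrained trunk weights transfer to fine-tuning.

unet_init <- function(c1 = 12L, head = c("recon", "seg")) {
  head <- match.arg(head)
  c2 <- 2L * c1
  p <- list(
    e1 = list(W = he_conv(c(3, 3, 3), 1L, c1), b = rep(0, c1)),
    e2 = list(W = he_conv(c(3, 3, 3), c1, c1), b = rep(0, c1)),
    down = list(W = he_conv(c(4, 4, 4), c1, c2), b = rep(0, c2)),
    mid = list(W = he_conv(c(3, 3, 3), c2, c2), b = rep(0, c2)),
    up = list(W = he_tconv(c(4, 4, 4), c2, c1), b = rep(0, c1)),
    d1 = list(W = he_conv(c(3, 3, 3), 2L * c1, c1), b = rep(0, c1)))
  nout <- if (head == "recon") 1L else 2L
  p$head <- list(W = he_conv(c(3, 3, 3), c1, nout, gain = 0.5),
                 b = rep(0, nout))
  p
}

unet_fwd <- function(p, x, head) {
  ca <- list()
  h <- array(x, c(dim(x), 1L))
  v <- conv3d_fwd(h, p$e1$W, p$e1$b); a1 <- act_fwd(v$y, "silu")
  ca$e1 <- list(conv = v$cache, act = a1$cache)
  v <- conv3d_fwd(a1$y, p$e2$W, p$e2$b); a2 <- act_fwd(v$y, "silu")
  ca$e2 <- list(conv = v$cache, act = a2$cache)
  v <- conv3d_fwd(a2$y, p$down$W, p$down$b, stride = c(2L, 2L, 2L),
                  pad = c(1L, 1L, 1L))
  a3 <- act_fwd(v$y, "silu")
  ca$down <- list(conv = v$cache, act = a3$cache)
  v <- conv3d_fwd(a3$y, p$mid$W, p$mid$b); a4 <- act_fwd(v$y, "silu")
  ca$mid <- list(conv = v$cache, act = a4$cache)
  v <- tconv3d_fwd(a4$y, p$up$W, p$up$b, stride = c(2L, 2L, 2L),
                   pad = c(1L, 1L, 1L))
  a5 <- act_fwd(v$y, "silu")
  ca$up <- list(conv = v$cache, act = a5$cache)
  cu <- dim(a5$y)[4]
  cat_ <- array(0, c(dim(a5$y)[1:3], cu + dim(a2$y)[4]))
  cat_[, , , seq_len(cu)] <- a5$y
  cat_[, , , cu + seq_len(dim(a2$y)[4])] <- a2$y
  v <- conv3d_fwd(cat_, p$d1$W, p$d1$b); a6 <- act_fwd(v$y, "silu")
  ca$d1 <- list(conv = v$cache, act = a6$cache, cu = cu)
  v <- conv3d_fwd(a6$y, p$head$W, p$head$b)
  if (head == "recon") {
    tn <- act_fwd(v$y, "tanh")
    ca$head <- list(conv = v$cache, act = tn$cache)
    list(out = array(tn$y, dim(tn$y)[1:3]), caches = ca)
  } else {
    ca$head <- list(conv = v$cache)
    list(out = v$y, caches = ca)
  }
}

unet_bwd <- function(p, ca, dout, head) {
  g <- list()
  if (head == "recon") {
    dh <- act_bwd(ca$head$act, array(dout, c(dim(dout), 1L)))
  } else dh <- dout
  bw <- conv3d_bwd(ca$head$conv, dh); g$head <- list(W = bw$dW, b = bw$db)
  dh <- act_bwd(ca$d1$act, bw$dx)
  bw <- conv3d_bwd(ca$d1$conv, dh); g$d1 <- list(W = bw$dW, b = bw$db)
  cu <- ca$d1$cu
  dup <- bw$dx[, , , seq_len(cu), drop = FALSE]
  dskip <- bw$dx[, , , cu + seq_len(dim(bw$dx)[4] - cu), drop = FALSE]
  dh <- act_bwd(ca$up$act, dup)
  bw <- tconv3d_bwd(ca$up$conv, dh); g$up <- list(W = bw$dW, b = bw$db)
  dh <- act_bwd(ca$mid$act, bw$dx)
  bw <- conv3d_bwd(ca$mid$conv, dh); g$mid <- list(W = bw$dW, b = bw$db)
  dh <- act_bwd(ca$down$act, bw$dx)
  bw <- conv3d_bwd(ca$down$conv, dh); g$down <- list(W = bw$dW, b = bw$db)
  dh <- act_bwd(ca$e2$act, bw$dx + dskip)
  bw <- conv3d_bwd(ca$e2$conv, dh); g$e2 <- list(W = bw$dW, b = bw$db)
  dh <- act_bwd(ca$e1$act, bw$dx)
  bw <- conv3d_bwd(ca$e1$conv, dh); g$e1 <- list(W = bw$dW, b = bw$db)
  g
}

#' Self-supervised inpainting pretraining
#'
#' Masks random patches of each training volume and trains the backbone to
#' reconstruct the original, with the L1 + (1 - MS-SSIM) objective and the
#' AdamW optimizer (learning rate 1e-3, weight decay 0.01). The returned
#' trunk weights can seed [finetune_segmenter()] / [finetune_fractions()].
#'
#' @param volumes List of [volume3d()] (or phantom pairs); typically
#'   synthetic volumes from [simulate.latent_ddpm()] or a phantom cohort.
#' @param spec A [masking_spec()].
#' @param steps Optimizer steps.
#' @param batch_size Volumes per step.
#' @param width Backbone channels at the first level.
#' @param lr,weight_decay AdamW settings.
#' @param seed Seed for initialization, masking and batching.
#' @param verbose Print progress every 25 steps.
#' @return An object of class `inpainter` with the trained parameters and
#'   loss history.
#' @export
pretrain_inpainter <- function(volumes, spec = masking_spec(), steps = 100L,
                               batch_size = 4L, width = 12L, lr = 1e-3,
                               weight_decay = 0.01, seed = 1L,
                               verbose = FALSE) {
  vols <- lapply(volumes, function(it)
    as_vox(if (is.list(it) && !inherits(it, "volume3d")) it$volume else it))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  params <- unet_init(width, "recon")
  flat <- flatten_params(params)
  opt <- adam_init(flat)
  n <- length(vols)
  history <- numeric(steps)
  for (step in seq_len(steps)) {
    if (lr == 0) { history[step] <- NA; next }
    idx <- sample.int(n, min(batch_size, n), replace = n < batch_size)
    acc <- NULL; lsum <- 0
    for (ii in idx) {
      mp <- mask_random_patches(vols[[ii]], spec)
      fw <- unet_fwd(params, mp$masked$voxels, "recon")
      lg <- l1_msssim_grad(mp$target$voxels, fw$out)
      lsum <- lsum + lg$value
      acc <- acc_grads(acc, flatten_params(
        unet_bwd(params, fw$caches, lg$grad_y, "recon")))
    }
    nb <- length(idx)
    if (!is.finite(lsum))
      stop("pretrain_inpainter: non-finite loss at step ", step,
           call. = FALSE)
    upd <- adam_step(flat, scale_grads(acc, 1 / nb), opt, lr,
                     weight_decay = weight_decay)
    flat <- upd$params; opt <- upd$state
    params <- unflatten_params(flat)
    history[step] <- lsum / nb
    if (verbose && step %% 25L == 0L)
      message(sprintf("pretrain step %d: loss %.4f", step, history[step]))
  }
  structure(list(params = params, width = as.integer(width), spec = spec,
                 history = history, seed = as.integer(seed)),
            class = "inpainter")
}

#' @export
print.inpainter <- function(x, ...) {
  h <- x$history[!is.na(x$history)]
  cat(sprintf("<inpainter> width %d backbone, %d pretraining steps", x$width,
              length(x$history)))
  if (length(h)) cat(sprintf("; loss %.4f -> %.4f", h[1], tail(h, 1)))
  cat("\n")
  invisible(x)
}

#' Fine-tune a segmentation model on labeled pairs
#'
#' Trains the two-class segmentation head (cross-entropy + soft Dice) on
#' volume/mask pairs, optionally starting from a pretrained inpainting
#' trunk, with AdamW and train-time augmentation.
#'
#' @param pairs List of `list(volume=, mask=)` training pairs.
#' @param pretrained Optional [pretrain_inpainter()] result; its trunk
#'   weights initialize the backbone.
#' @param steps Optimizer steps.
#' @param batch_size Pairs per step.
#' @param width Backbone width (must match `pretrained` if given).
#' @param lr,weight_decay AdamW settings.
#' @param config An [augment_config()] (or `NULL` for no augmentation).
#' @param seed Seed.
#' @return An object of class `segmenter`.
#' @export
finetune_segmenter <- function(pairs, pretrained = NULL, steps = 60L,
                               batch_size = 2L, width = 12L, lr = 1e-3,
                               weight_decay = 0.01,
                               config = augment_config(), seed = 1L) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  params <- unet_init(width, "seg")
  if (!is.null(pretrained)) {
    stopifnot(inherits(pretrained, "inpainter"))
    if (pretrained$width != width)
      stop("finetune_segmenter: width mismatch with pretrained trunk",
           call. = FALSE)
    for (nm in setdiff(names(pretrained$params), "head"))
      params[[nm]] <- pretrained$params[[nm]]
  }
  flat <- flatten_params(params)
  opt <- adam_init(flat)
  n <- length(pairs)
  history <- numeric(steps)
  for (step in seq_len(steps)) {
    idx <- sample.int(n, min(batch_size, n), replace = n < batch_size)
    acc <- NULL; lsum <- 0
    for (ii in idx) {
      v <- as_vox(pairs[[ii]]$volume); m <- as_vox(pairs[[ii]]$mask)
      if (!is.null(config)) {
        au <- augment(v, m, config)
        v <- au$volume$voxels; m <- au$mask$voxels
      }
      fw <- unet_fwd(params, v, "seg")
      sl <- seg_loss_grad(fw$out, m)
      lsum <- lsum + sl$value
      acc <- acc_grads(acc, flatten_params(
        unet_bwd(params, fw$caches, sl$grad, "seg")))
    }
    nb <- length(idx)
    if (!is.finite(lsum))
      stop("finetune_segmenter: non-finite loss at step ", step,
           call. = FALSE)
    upd <- adam_step(flat, scale_grads(acc, 1 / nb), opt, lr,
                     weight_decay = weight_decay)
    flat <- upd$params; opt <- upd$state
    params <- unflatten_params(flat)
    history[step] <- lsum / nb
  }
  structure(list(params = params, width = as.integer(width),
                 history = history, pretrained = !is.null(pretrained),
                 seed = as.integer(seed)),
            class = "segmenter")
}

#' Predict a segmentation mask
#'
#' @param object A [finetune_segmenter()] model.
#' @param newdata A [volume3d()]/array or list of them.
#' @param type `"mask"` for the argmax [label_mask()], `"prob"` for the
#'   foreground-probability array.
#' @param ... Unused.
#' @export
predict.segmenter <- function(object, newdata, type = c("mask", "prob"),
                              ...) {
  type <- match.arg(type)
  single <- inherits(newdata, "volume3d") ||
    (is.array(newdata) && length(dim(newdata)) == 3L)
  items <- if (single) list(newdata) else newdata
  out <- lapply(items, function(it) {
    x <- as_vox(if (is.list(it) && !inherits(it, "volume3d")) it$volume else it)
    sc <- unet_fwd(object$params, x, "seg")$out
    if (type == "prob") {
      e1 <- exp(sc[, , , 2] - pmax(sc[, , , 1], sc[, , , 2]))
      e0 <- exp(sc[, , , 1] - pmax(sc[, , , 1], sc[, , , 2]))
      return(e1 / (e0 + e1))
    }
    label_mask(array(as.numeric(sc[, , , 2] > sc[, , , 1]), dim(x)))
  })
  if (single) out[[1]] else out
}

#' @export
print.segmenter <- function(x, ...) {
  cat(sprintf("<segmenter> width %d backbone (%s pretraining), %d steps, final loss %.4f\n",
              x$width, if (x$pretrained) "with" else "no",
              length(x$history), tail(x$history, 1)))
  invisible(x)
}

#' Label-fraction fine-tuning experiment
#'
#' The limited-data experiment: the cohort is split into a fixed held-out
#' test set and a training pool; for each label fraction a nested seeded
#' subset of the pool (5% within 10% within 20% ...) is used to fine-tune a
#' segmenter — optionally initialized from an inpainting-pretrained trunk —
#' and mean test Dice with its bootstrap standard deviation is recorded.
#'
#' @param cohort List of `list(volume=, mask=)` pairs.
#' @param fractions Percentages in (0, 100].
#' @param pretrained Optional [pretrain_inpainter()] result.
#' @param seed Seed controlling the split, subset order and training.
#' @param test_frac Fraction of the cohort held out for testing.
#' @param steps,width,lr,config Passed to [finetune_segmenter()].
#' @param n_boot Bootstrap resamples for the Dice standard deviation.
#' @return An object of class `fraction_experiment`: a data frame of
#'   per-fraction results plus metadata.
#' @export
finetune_fractions <- function(cohort, fractions = c(5, 10, 20, 40, 80, 100),
                               pretrained = NULL, seed = 1L,
                               test_frac = 0.25, steps = 60L, width = 12L,
                               lr = 1e-3, config = augment_config(),
                               n_boot = 1000L) {
  stopifnot(all(fractions > 0 & fractions <= 100))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  n <- length(cohort)
  n_test <- max(1L, round(test_frac * n))
  perm <- sample.int(n)
  test_idx <- perm[seq_len(n_test)]
  pool <- perm[-seq_len(n_test)]      # already shuffled: nested prefixes
  res <- data.frame(fraction = sort(fractions), n_train = NA_integer_,
                    dice = NA_real_, dice_sd = NA_real_)
  for (r in seq_len(nrow(res))) {
    f <- res$fraction[r]
    n_use <- ceiling(f / 100 * length(pool))
    if (n_use < 1L)
      stop("finetune_fractions: fraction ", f, "% yields zero samples",
           call. = FALSE)
    train <- cohort[pool[seq_len(n_use)]]
    model <- finetune_segmenter(train, pretrained = pretrained,
                                steps = steps, width = width, lr = lr,
                                config = config, seed = seed + r)
    dices <- vapply(cohort[test_idx], function(p)
      dice(predict(model, p$volume), p$mask), numeric(1))
    res$n_train[r] <- n_use
    res$dice[r] <- mean(dices)
    res$dice_sd[r] <- bootstrap_sd(dices, n_boot = n_boot, seed = seed)
  }
  structure(list(results = res, pretrain = !is.null(pretrained),
                 seed = as.integer(seed), n_test = n_test),
            class = "fraction_experiment")
}

#' @export
print.fraction_experiment <- function(x, ...) {
  cat(sprintf("<fraction_experiment> %s pretraining, %d test volumes, seed %d\n",
              if (x$pretrain) "with" else "no", x$n_test, x$seed))
  print(x$results, row.names = FALSE)
  invisible(x)
}

#' @export
plot.fraction_experiment <- function(x, ...) {
  r <- x$results
  graphics::plot(r$fraction, r$dice, type = "b", ylim = c(0, 1),
                 xlab = "label fraction (%)", ylab = "mean test Dice",
                 main = sprintf("Segmentation vs label fraction (%s pretraining)",
                                if (x$pretrain) "with" else "no"), ...)
  graphics::arrows(r$fraction, r$dice - r$dice_sd, r$fraction,
                   r$dice + r$dice_sd, angle = 90, code = 3, length = 0.04)
  invisible(x)
}
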