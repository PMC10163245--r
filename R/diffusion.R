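#' Diffusion noise schedule
#'
#' The Markov chain that gradually corrupts a clean latent x_0 with Gaussian
#' noise over `T` steps: per-step variances beta_t, alpha_t = 1 - beta_t and
#' the cumulative products alpha_bar_t that give the closed-form marginal
#' used by [q_sample()].
#'
#' @param T_steps Number of diffusion steps, >= 1.
#' @param kind Schedule family; `"linear"` interpolates beta from
#'   `beta_start` to `beta_end`.
#' @param beta_start,beta_end Bounds with `0 < beta_start <= beta_end < 1`.
#' @return An object of class `noise_schedule` with fields `T`, `beta`,
#'   `alpha`, `alpha_bar`.
#' @examples
#' sch <- make_noise_schedule(1000)
#' sch$alpha_bar[1000] < 1e-4
#' @export
make_noise_schedule <- function(T_steps, kind = c("linear"),
                                beta_start = 1e-4, beta_end = 0.02) {
  kind <- match.arg(kind)
  T_steps <- as.integer(T_steps)
  if (T_steps < 1L) stop("make_noise_schedule: T must be >= 1", call. = FALSE)
  if (!(beta_start > 0 && beta_start <= beta_end && beta_end < 1))
    stop("make_noise_schedule: need 0 < beta_start <= beta_end < 1",
         call. = FALSE)
  beta <- if (T_steps == 1L) beta_start else
    seq(beta_start, beta_end, length.out = T_steps)
  alpha <- 1 - beta
  structure(list(T = T_steps, beta = beta, alpha = alpha,
                 alpha_bar = cumprod(alpha), kind = kind),
            class = "noise_schedule")
}

#' @export
print.noise_schedule <- function(x, ...) {
  cat(sprintf("<noise_schedule> %s, T = %d, beta in [%g, %g], alpha_bar_T = %.3g\n",
              x$kind, x$T, x$beta[1], x$beta[x$T], x$alpha_bar[x$T]))
  invisible(x)
}

check_t <- function(t, sched) {
  if (any(t < 1L) || any(t > sched$T))
    stop("timestep t out of [1, ", sched$T, "]", call. = FALSE)
  as.integer(t)
}

#' Closed-form forward diffusion sample
#'
#' Draws x_t directly from the marginal of the noising chain:
#' `x_t = sqrt(alpha_bar_t) x_0 + sqrt(1 - alpha_bar_t) eps`.
#'
#' @param x0 Clean latent (any numeric array).
#' @param t Timestep in `[1, T]`.
#' @param eps Standard-normal draw, same shape as `x0`.
#' @param sched A [make_noise_schedule()].
#' @return Noised latent of the same shape.
#' @export
q_sample <- function(x0, t, eps, sched) {
  t <- check_t(t, sched)
  ab <- sched$alpha_bar[t]
  sqrt(ab) * x0 + sqrt(1 - ab) * eps
}

#' Noise-prediction training loss
#'
#' Draws a uniform timestep and a fresh noise realization per batch item,
#' forms x_t with [q_sample()], and returns the mean squared error between
#' the true noise and the model's prediction — the standard epsilon-
#' prediction objective.
#'
#' @param model A noise-prediction model: either a function `f(xt, t)`
#'   returning an array shaped like `xt`, or a fitted denoiser.
#' @param x0_batch List of clean latents (arrays), normalized to about
#'   \[-1, 1\].
#' @param sched A [make_noise_schedule()].
#' @return Scalar loss >= 0.
#' @export
denoise_loss <- function(model, x0_batch, sched) {
  if (!is.list(x0_batch)) x0_batch <- list(x0_batch)
  tot <- 0; n <- 0
  for (x0 in x0_batch) {
    t <- sample.int(sched$T, 1L)
    eps <- array(stats::rnorm(length(x0)), dim(x0) %||% length(x0))
    xt <- q_sample(x0, t, eps, sched)
    pred <- noise_predict(model, xt, t)
    tot <- tot + sum((pred - eps)^2)
    n <- n + length(x0)
  }
  tot / n
}

noise_predict <- function(model, xt, t) {
  if (is.function(model)) return(model(xt, t))
  if (inherits(model, "latent_ddpm"))
    return(denoiser_fwd(model$params, model$spec, xt, t)$out)
  stop("noise_predict: unsupported model", call. = FALSE)
}

#' One reverse-diffusion step
#'
#' Computes the reverse-process mean from the model's noise prediction,
#' `mean = (xt - beta_t / sqrt(1 - alpha_bar_t) * eps_hat) / sqrt(alpha_t)`,
#' and adds sigma_t * z for t > 1 (no noise is injected at the final step).
#' `sigma_mode = "beta"` uses sigma_t^2 = beta_t; `"posterior"` uses the
#' posterior variance `beta_t (1 - alpha_bar_{t-1}) / (1 - alpha_bar_t)`.
#'
#' @param model Noise-prediction model (see [denoise_loss()]).
#' @param xt Current latent at timestep `t`.
#' @param t Timestep in `[1, T]`.
#' @param sched A [make_noise_schedule()].
#' @param sigma_mode `"beta"` (default) or `"posterior"`.
#' @return The latent at timestep `t - 1`.
#' @export
p_sample_step <- function(model, xt, t, sched,
                          sigma_mode = c("beta", "posterior")) {
  sigma_mode <- match.arg(sigma_mode)
  t <- check_t(t, sched)
  eps_hat <- noise_predict(model, xt, t)
  a <- sched$alpha[t]; b <- sched$beta[t]; ab <- sched$alpha_bar[t]
  mean_ <- (xt - (b / sqrt(1 - ab)) * eps_hat) / sqrt(a)
  if (t == 1L) return(mean_)
  sig2 <- if (sigma_mode == "beta") b else {
    ab_prev <- sched$alpha_bar[t - 1L]
    b * (1 - ab_prev) / (1 - ab)
  }
  mean_ + sqrt(sig2) * array(stats::rnorm(length(xt)),
                             dim(xt) %||% length(xt))
}

#' Sample a latent grid from the reverse diffusion chain
#'
#' Starts from x_T ~ N(0, I) of the requested shape and applies
#' [p_sample_step()] for t = T .. 1.
#'
#' @param model Noise-prediction model.
#' @param shape Integer extents of the latent (e.g. `c(h, w, d, k)`).
#' @param sched A [make_noise_schedule()].
#' @param seed Optional seed making the trajectory reproducible.
#' @inheritParams p_sample_step
#' @return Array of the requested shape (the x_0 estimate).
#' @export
sample_latent <- function(model, shape, sched, seed = NULL,
                          sigma_mode = "beta") {
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  x <- array(stats::rnorm(prod(shape)), shape)
  for (t in rev(seq_len(sched$T)))
    x <- p_sample_step(model, x, t, sched, sigma_mode = sigma_mode)
  x
}

#' Latent min-max normalizer derived from a codebook
#'
#' The diffusion model expects inputs in about \[-1, 1\]. Because
#' quantization keeps the continuous latents close to the codebook vectors,
#' the minimum and maximum over all codebook components approximate the
#' range of the unquantized latents; min-max normalizing with these two
#' scalars maps the latents near \[-1, 1\].
#'
#' @param cb A [codebook()] (or a fitted `vqgan`, whose codebook is used).
#' @return An object of class `latent_normalizer` with `cb_min`, `cb_max`.
#' @export
latent_normalizer <- function(cb) {
  if (inherits(cb, "vqgan")) cb <- cb$codebook
  stopifnot(inherits(cb, "codebook"))
  lo <- min(cb$vectors); hi <- max(cb$vectors)
  if (!(lo < hi)) stop("latent_normalizer: degenerate codebook range",
                       call. = FALSE)
  structure(list(cb_min = lo, cb_max = hi), class = "latent_normalizer")
}

#' Normalize latents to about \[-1, 1\] using the codebook range
#'
#' `y = 2 (z - cb_min) / (cb_max - cb_min) - 1`. Values outside the codebook
#' range map outside \[-1, 1\] and are not clipped here.
#'
#' @param z Numeric array of latents.
#' @param norm A [latent_normalizer()].
#' @return Array of the same shape.
#' @export
latent_normalize <- function(z, norm) {
  stopifnot(inherits(norm, "latent_normalizer"))
  2 * (z - norm$cb_min) / (norm$cb_max - norm$cb_min) - 1
}

#' @rdname latent_normalize
#' @param y Normalized latents.
#' @export
latent_denormalize <- function(y, norm) {
  stopifnot(inherits(norm, "latent_normalizer"))
  (y + 1) / 2 * (norm$cb_max - norm$cb_min) + norm$cb_min
}

## Denoiser U-Net --------------------------------------------------------
##
## Two resolution levels over the latent grid. Convolutions use 3x3x1
## kernels and downsampling/upsampling acts only on the high-resolution
## plane (stride (2,2,1)), so shallow latent depths survive; each level-2
## block is followed by spatial attention then depth attention with residual
## connections; upsampling is a transposed convolution and the skip
## connection is concatenated.

sin_embed <- function(t, dim) {
  half <- dim %/% 2
  freqs <- exp(-log(10000) * (seq_len(half) - 1) / half)
  c(sin(t * freqs), cos(t * freqs))
}

denoiser_spec <- function(k, base_ch = 24L, t_dim = 16L, latent_dims = NULL) {
  list(k = as.integer(k), c1 = as.integer(base_ch),
       c2 = 2L * as.integer(base_ch), t_dim = as.integer(t_dim),
       latent_dims = latent_dims)
}

denoiser_init <- function(spec) {
  c1 <- spec$c1; c2 <- spec$c2; k <- spec$k; td <- spec$t_dim
  list(
    te1 = list(W = he_dense(td, c2), b = rep(0, c2)),
    te2 = list(W = he_dense(c2, c2), b = rep(0, c2)),
    tp1 = list(W = he_dense(c2, c1), b = rep(0, c1)),
    tp2 = list(W = he_dense(c2, c2), b = rep(0, c2)),
    b1c1 = list(W = he_conv(c(3, 3, 1), k, c1), b = rep(0, c1)),
    b1c2 = list(W = he_conv(c(3, 3, 1), c1, c1), b = rep(0, c1)),
    down = list(W = he_conv(c(4, 4, 1), c1, c2), b = rep(0, c2)),
    b2c1 = list(W = he_conv(c(3, 3, 1), c2, c2), b = rep(0, c2)),
    b2c2 = list(W = he_conv(c(3, 3, 1), c2, c2), b = rep(0, c2)),
    attn_s = attn_params(c2, gain = 0.3),
    attn_d = attn_params(c2, gain = 0.3),
    up = list(W = he_tconv(c(4, 4, 1), c2, c1), b = rep(0, c1)),
    b3c1 = list(W = he_conv(c(3, 3, 1), 2L * c1, c1), b = rep(0, c1)),
    b3c2 = list(W = he_conv(c(3, 3, 1), c1, c1), b = rep(0, c1)),
    out = list(W = he_conv(c(3, 3, 1), c1, k, gain = 0.1), b = rep(0, k)))
}

add_chan <- function(x, v) sweep(x, 4, v, `+`)

denoiser_fwd <- function(p, spec, x, t) {
  ca <- list()
  emb <- matrix(sin_embed(t, spec$t_dim), 1)
  e1 <- dense_fwd(emb, p$te1$W, p$te1$b); a1 <- act_fwd(e1$y, "silu")
  e2 <- dense_fwd(a1$y, p$te2$W, p$te2$b); a2 <- act_fwd(e2$y, "silu")
  tp1 <- dense_fwd(a2$y, p$tp1$W, p$tp1$b)
  tp2 <- dense_fwd(a2$y, p$tp2$W, p$tp2$b)
  ca$t <- list(e1 = e1$cache, a1 = a1$cache, e2 = e2$cache, a2 = a2$cache,
               tp1 = tp1$cache, tp2 = tp2$cache)
  v11 <- conv3d_fwd(x, p$b1c1$W, p$b1c1$b)
  s11 <- act_fwd(add_chan(v11$y, as.vector(tp1$y)), "silu")
  v12 <- conv3d_fwd(s11$y, p$b1c2$W, p$b1c2$b)
  s12 <- act_fwd(v12$y, "silu")
  ca$b1 <- list(v11 = v11$cache, s11 = s11$cache, v12 = v12$cache,
                s12 = s12$cache)
  dn <- conv3d_fwd(s12$y, p$down$W, p$down$b, stride = c(2L, 2L, 1L),
                   pad = c(1L, 1L, 0L))
  sdn <- act_fwd(dn$y, "silu")
  ca$dn <- list(conv = dn$cache, act = sdn$cache)
  v21 <- conv3d_fwd(sdn$y, p$b2c1$W, p$b2c1$b)
  s21 <- act_fwd(add_chan(v21$y, as.vector(tp2$y)), "silu")
  v22 <- conv3d_fwd(s21$y, p$b2c2$W, p$b2c2$b)
  s22 <- act_fwd(v22$y, "silu")
  at_s <- attn3d_fwd(s22$y, p$attn_s, "spatial")
  at_d <- attn3d_fwd(at_s$y, p$attn_d, "depth")
  ca$b2 <- list(v21 = v21$cache, s21 = s21$cache, v22 = v22$cache,
                s22 = s22$cache, at_s = at_s$cache, at_d = at_d$cache)
  upv <- tconv3d_fwd(at_d$y, p$up$W, p$up$b, stride = c(2L, 2L, 1L),
                     pad = c(1L, 1L, 0L))
  sup <- act_fwd(upv$y, "silu")
  ca$up <- list(conv = upv$cache, act = sup$cache)
  cat_ <- array(0, c(dim(sup$y)[1:3], dim(sup$y)[4] + dim(s12$y)[4]))
  cat_[, , , seq_len(dim(sup$y)[4])] <- sup$y
  cat_[, , , dim(sup$y)[4] + seq_len(dim(s12$y)[4])] <- s12$y
  v31 <- conv3d_fwd(cat_, p$b3c1$W, p$b3c1$b)
  s31 <- act_fwd(v31$y, "silu")
  v32 <- conv3d_fwd(s31$y, p$b3c2$W, p$b3c2$b)
  s32 <- act_fwd(v32$y, "silu")
  vo <- conv3d_fwd(s32$y, p$out$W, p$out$b)
  ca$b3 <- list(v31 = v31$cache, s31 = s31$cache, v32 = v32$cache,
                s32 = s32$cache, vo = vo$cache, c_up = dim(sup$y)[4])
  list(out = vo$y, caches = ca)
}

denoiser_bwd <- function(p, spec, ca, dout) {
  g <- list()
  bw <- conv3d_bwd(ca$b3$vo, dout); g$out <- list(W = bw$dW, b = bw$db)
  dh <- act_bwd(ca$b3$s32, bw$dx)
  bw <- conv3d_bwd(ca$b3$v32, dh); g$b3c2 <- list(W = bw$dW, b = bw$db)
  dh <- act_bwd(ca$b3$s31, bw$dx)
  bw <- conv3d_bwd(ca$b3$v31, dh); g$b3c1 <- list(W = bw$dW, b = bw$db)
  cu <- ca$b3$c_up
  dcat <- bw$dx
  dsup <- dcat[, , , seq_len(cu), drop = FALSE]
  dskip <- dcat[, , , cu + seq_len(dim(dcat)[4] - cu), drop = FALSE]
  dh <- act_bwd(ca$up$act, dsup)
  bw <- tconv3d_bwd(ca$up$conv, dh); g$up <- list(W = bw$dW, b = bw$db)
  ad <- attn3d_bwd(ca$b2$at_d, bw$dx)
  g$attn_d <- list(Wq = ad$dWq, Wk = ad$dWk, Wv = ad$dWv, Wo = ad$dWo)
  as_ <- attn3d_bwd(ca$b2$at_s, ad$dx)
  g$attn_s <- list(Wq = as_$dWq, Wk = as_$dWk, Wv = as_$dWv, Wo = as_$dWo)
  dh <- act_bwd(ca$b2$s22, as_$dx)
  bw <- conv3d_bwd(ca$b2$v22, dh); g$b2c2 <- list(W = bw$dW, b = bw$db)
  dh <- act_bwd(ca$b2$s21, bw$dx)
  dtp2 <- matrix(apply(dh, 4, sum), 1)
  bw <- conv3d_bwd(ca$b2$v21, dh); g$b2c1 <- list(W = bw$dW, b = bw$db)
  dh <- act_bwd(ca$dn$act, bw$dx)
  bw <- conv3d_bwd(ca$dn$conv, dh); g$down <- list(W = bw$dW, b = bw$db)
  # the level-1 activation feeds both the down path and the skip concat
  dh <- act_bwd(ca$b1$s12, bw$dx + dskip)
  bw <- conv3d_bwd(ca$b1$v12, dh); g$b1c2 <- list(W = bw$dW, b = bw$db)
  dh <- act_bwd(ca$b1$s11, bw$dx)
  dtp1 <- matrix(apply(dh, 4, sum), 1)
  bw <- conv3d_bwd(ca$b1$v11, dh); g$b1c1 <- list(W = bw$dW, b = bw$db)
  dx <- bw$dx
  # timestep-embedding path
  bt1 <- dense_bwd(ca$t$tp1, dtp1); g$tp1 <- list(W = bt1$dW, b = bt1$db)
  bt2 <- dense_bwd(ca$t$tp2, dtp2); g$tp2 <- list(W = bt2$dW, b = bt2$db)
  da2 <- act_bwd(ca$t$a2, bt1$dx + bt2$dx)
  be2 <- dense_bwd(ca$t$e2, da2); g$te2 <- list(W = be2$dW, b = be2$db)
  da1 <- act_bwd(ca$t$a1, be2$dx)
  be1 <- dense_bwd(ca$t$e1, da1); g$te1 <- list(W = be1$dW, b = be1$db)
  list(grads = g, dx = dx)
}

#' Fit a latent diffusion model on a trained VQ-GAN's latent space
#'
#' Encodes every cohort volume with the VQ-GAN encoder, min-max normalizes
#' the continuous latents using the codebook range (see
#' [latent_normalizer()]), and trains a small U-Net denoiser with the
#' epsilon-prediction objective over a linear noise schedule. The denoiser
#' uses 3x3x1 convolutions, downsampling only on the high-resolution plane,
#' transposed-convolution upsampling, and spatial followed by depth
#' attention at the coarse level.
#'
#' @param vqgan A fitted [fit_vqgan()] model.
#' @param cohort Training volumes (list of [volume3d()] or phantom pairs).
#' @param T_steps Diffusion steps (desk-scale default 100).
#' @param steps Optimizer steps.
#' @param batch_size Latents per step.
#' @param base_ch Denoiser channels at the fine level.
#' @param lr Adam learning rate.
#' @param beta_start,beta_end Linear schedule bounds.
#' @param seed Seed for initialization, batching, timesteps and noise.
#' @param verbose Print progress every 50 steps.
#' @return An object of class `latent_ddpm` holding the denoiser, schedule,
#'   normalizer and a reference to the paired VQ-GAN.
#' @seealso [simulate.latent_ddpm()], [generate_volume()]
#' @export
fit_latent_ddpm <- function(vqgan, cohort, T_steps = 100L, steps = 300L,
                            batch_size = 4L, base_ch = 24L, lr = 2e-3,
                            beta_start = 1e-4, beta_end = 0.02, seed = 1L,
                            verbose = FALSE) {
  stopifnot(inherits(vqgan, "vqgan"))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  norm <- latent_normalizer(vqgan)
  lats <- lapply(cohort, function(it) {
    x <- as_vox(if (is.list(it) && !inherits(it, "volume3d")) it$volume else it)
    latent_normalize(vqgan_encode_fwd(vqgan$params, vqgan$arch, x)$z_e, norm)
  })
  sched <- make_noise_schedule(T_steps, beta_start = beta_start,
                               beta_end = beta_end)
  spec <- denoiser_spec(vqgan$k, base_ch, latent_dims = dim(lats[[1]]))
  params <- denoiser_init(spec)
  flat <- flatten_params(params)
  opt <- adam_init(flat)
  n <- length(lats)
  history <- numeric(steps)
  for (step in seq_len(steps)) {
    idx <- sample.int(n, min(batch_size, n), replace = n < batch_size)
    acc <- NULL; lsum <- 0
    for (ii in idx) {
      x0 <- lats[[ii]]
      t <- sample.int(sched$T, 1L)
      eps <- array(stats::rnorm(length(x0)), dim(x0))
      xt <- q_sample(x0, t, eps, sched)
      fw <- denoiser_fwd(params, spec, xt, t)
      diffr <- fw$out - eps
      lsum <- lsum + mean(diffr^2)
      bw <- denoiser_bwd(params, spec, fw$caches, 2 * diffr / length(diffr))
      acc <- acc_grads(acc, flatten_params(bw$grads))
    }
    nb <- length(idx)
    if (!is.finite(lsum))
      stop("fit_latent_ddpm: non-finite loss at step ", step, call. = FALSE)
    upd <- adam_step(flat, scale_grads(acc, 1 / nb), opt, lr)
    flat <- upd$params; opt <- upd$state
    params <- unflatten_params(flat)
    history[step] <- lsum / nb
    if (verbose && step %% 50L == 0L)
      message(sprintf("step %d: denoise loss %.4f", step, history[step]))
  }
  structure(list(params = params, spec = spec, sched = sched, norm = norm,
                 vqgan = vqgan, history = history, seed = as.integer(seed),
                 latent_dims = dim(lats[[1]]), call = match.call()),
            class = "latent_ddpm")
}

#' @export
print.latent_ddpm <- function(x, ...) {
  cat(sprintf("<latent_ddpm> T = %d over %s latents (k = %d); %d training steps\n",
              x$sched$T, paste(x$latent_dims[1:3], collapse = "x"),
              x$spec$k, length(x$history)))
  cat(sprintf("  denoise loss: first %.3f -> last %.3f; codebook range [%.3f, %.3f]\n",
              x$history[1], tail(x$history, 1), x$norm$cb_min, x$norm$cb_max))
  invisible(x)
}

#' @export
summary.latent_ddpm <- function(object, ...) {
  print(object)
  print(object$sched)
  invisible(object)
}

#' @export
plot.latent_ddpm <- function(x, ...) {
  graphics::plot(seq_along(x$history), x$history, type = "l", xlab = "step",
                 ylab = "noise-prediction MSE", main = "Latent DDPM training",
                 ...)
  invisible(x)
}

#' Generate synthetic volumes from a fitted latent diffusion model
#'
#' Runs the reverse chain from pure noise, clips the sampled latents to
#' \[-1, 1\], undoes the codebook min-max normalization, quantizes against
#' the VQ-GAN codebook, and decodes — the full two-stage generation path.
#'
#' @param object A fitted [fit_latent_ddpm()] model.
#' @param nsim Number of volumes.
#' @param seed Seed; sample `i` uses `seed + i - 1`.
#' @param clip Clip sampled latents to \[-1, 1\] before denormalizing.
#' @param ... Unused.
#' @return A list of `nsim` [volume3d()] objects.
#' @export
simulate.latent_ddpm <- function(object, nsim = 1, seed = 1L, clip = TRUE,
                                 ...) {
  lapply(seq_len(nsim), function(i)
    generate_volume(object$vqgan, object, seed = seed + i - 1L, clip = clip))
}

#' Generate one volume from a trained VQ-GAN / diffusion pair
#'
#' @param vqgan A fitted [fit_vqgan()] model.
#' @param ddpm A fitted [fit_latent_ddpm()] model trained on its latents.
#' @param seed Seed for the reverse trajectory.
#' @param clip Clip sampled latents to \[-1, 1\].
#' @return A [volume3d()] with values in \[-1, 1\].
#' @export
generate_volume <- function(vqgan, ddpm, seed = 1L, clip = TRUE) {
  stopifnot(inherits(vqgan, "vqgan"), inherits(ddpm, "latent_ddpm"))
  if (!identical(as.integer(ddpm$latent_dims),
                 as.integer(c(vqgan$latent_dims, vqgan$k))))
    stop("generate_volume: latent shapes of the two models disagree",
         call. = FALSE)
  y <- sample_latent(ddpm, ddpm$latent_dims, ddpm$sched, seed = seed)
  if (clip) y <- pmin(pmax(y, -1), 1)
  z <- latent_denormalize(y, ddpm$norm)
  qz <- quantize_latents(z, vqgan$codebook)
  decode_latents(vqgan, qz$z_q)
}
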