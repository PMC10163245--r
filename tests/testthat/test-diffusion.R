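test_that("noise schedules satisfy their invariants", {
  s1 <- make_noise_schedule(1L, beta_start = 0.5, beta_end = 0.5)
  expect_equal(s1$alpha_bar, 0.5)
  s <- make_noise_schedule(50L, beta_start = 1e-3, beta_end = 0.1)
  expect_true(all(diff(s$alpha_bar) < 0))
  expect_true(all(s$beta > 0 & s$beta < 1))
  expect_equal(s$alpha, 1 - s$beta)
  full <- make_noise_schedule(1000L)
  expect_lt(full$alpha_bar[1000], 1e-4)
  expect_error(make_noise_schedule(10L, beta_start = 0), "beta")
  expect_error(make_noise_schedule(0L), "T")
})

test_that("q_sample is the closed-form marginal", {
  # beta -> 0 limit: alpha_bar ~ 1, so x_t ~ x_0 (noise term O(sqrt(T beta)))
  sched <- make_noise_schedule(10L, beta_start = 1e-9, beta_end = 1e-9)
  x0 <- array(rnorm(24), c(2, 3, 4))
  eps <- array(rnorm(24), c(2, 3, 4))
  expect_lt(max(abs(q_sample(x0, 10L, eps, sched) - x0)), 1e-3)
  s2 <- make_noise_schedule(10L)
  expect_equal(q_sample(array(0, c(2, 2)), 5L, eps[1:4], s2),
               sqrt(1 - s2$alpha_bar[5]) * eps[1:4], ignore_attr = TRUE)
  expect_error(q_sample(x0, 11L, eps, sched), "out of")
  # Monte-Carlo variance at alpha_bar = 0.64: var(xt) = 0.36
  s3 <- make_noise_schedule(1L, beta_start = 0.36, beta_end = 0.36)
  set.seed(10)
  draws <- q_sample(rep(0.5, 10000), 1L, rnorm(10000), s3)
  se <- sqrt(2 / (10000 - 1)) * 0.36     # SE of a normal variance estimate
  expect_lt(abs(var(draws) - 0.36), 3 * se)
  expect_lt(abs(mean(draws) - 0.8 * 0.5), 3 * 0.6 / sqrt(10000))
})

test_that("q_sample moments match Monte Carlo for random (x0, t)", {
  sched <- make_noise_schedule(40L, beta_start = 5e-3, beta_end = 0.08)
  set.seed(21)
  for (i in 1:5) {
    x0 <- runif(1, -1, 1)
    t <- sample.int(40L, 1L)
    draws <- q_sample(rep(x0, 10000), t, rnorm(10000), sched)
    ab <- sched$alpha_bar[t]
    expect_lt(abs(mean(draws) - sqrt(ab) * x0),
              3 * sqrt((1 - ab) / 10000))
    expect_lt(abs(var(draws) - (1 - ab)),
              3 * sqrt(2 / (10000 - 1)) * (1 - ab))
  }
})

test_that("chained per-step noising matches the closed-form marginal", {
  # applying x_t = sqrt(alpha_t) x_{t-1} + sqrt(beta_t) eps_t for t = 1..T
  # must reproduce the q_sample moments
  sched <- make_noise_schedule(8L, beta_start = 0.02, beta_end = 0.3)
  x0 <- 0.7
  set.seed(31)
  n <- 10000
  x <- rep(x0, n)
  for (t in 1:8)
    x <- sqrt(sched$alpha[t]) * x + sqrt(sched$beta[t]) * rnorm(n)
  ab <- sched$alpha_bar[8]
  expect_lt(abs(mean(x) - sqrt(ab) * x0), 3 * sqrt((1 - ab) / n))
  expect_lt(abs(var(x) - (1 - ab)), 3 * sqrt(2 / (n - 1)) * (1 - ab))
})

test_that("denoise loss is zero for an oracle and about 1 for a zero model", {
  sched <- make_noise_schedule(20L)
  x0 <- array(runif(8 * 8 * 4, -1, 1), c(8, 8, 4))
  # oracle: capture the drawn eps via the closed form
  oracle <- function(xt, t)
    (xt - sqrt(sched$alpha_bar[t]) * x0) / sqrt(1 - sched$alpha_bar[t])
  set.seed(41)
  expect_equal(denoise_loss(oracle, list(x0), sched), 0, tolerance = 1e-12)
  zero_model <- function(xt, t) array(0, dim(xt))
  set.seed(42)
  ls <- replicate(40, denoise_loss(zero_model, list(x0), sched))
  # E[eps^2] = 1 per element; 40 x 256 elements
  expect_lt(abs(mean(ls) - 1), 3 * sd(ls) / sqrt(40))
  expect_true(all(ls >= 0))
})

test_that("the reverse step follows the DDPM mean formula", {
  sched <- make_noise_schedule(1L, beta_start = 0.19, beta_end = 0.19)
  model <- function(xt, t) array(0.5, dim(xt))
  xt <- array(1.0, c(1, 1, 1, 1))
  out <- p_sample_step(model, xt, 1L, sched)
  expect_equal(as.numeric(out),
               (1 / sqrt(0.81)) * (1 - (0.19 / sqrt(0.19)) * 0.5),
               tolerance = 1e-12)           # t = 1: no injected noise
  s2 <- make_noise_schedule(5L, beta_start = 0.05, beta_end = 0.2)
  set.seed(5); a <- p_sample_step(model, xt, 3L, s2)
  set.seed(5); b <- p_sample_step(model, xt, 3L, s2)
  expect_identical(a, b)
  set.seed(6); c2 <- p_sample_step(model, xt, 3L, s2, "posterior")
  expect_true(is.finite(c2))
  expect_error(p_sample_step(model, xt, 9L, s2), "out of")
})

test_that("an oracle denoiser contracts the distance to x_0", {
  # with a perfect noise oracle the noiseless reverse mean can be written
  # mean - x0 = (sqrt(ab_{t-1}) - 1) x0 + c_t sqrt(1 - ab_t) eps with both
  # coefficients strictly smaller in magnitude than in x_t - x0, so the
  # distance to x0 contracts on average (individual draws where the two
  # terms cancel in x_t can move slightly away)
  sched <- make_noise_schedule(10L, beta_start = 0.01, beta_end = 0.2)
  set.seed(51)
  d_before <- d_after <- numeric(200)
  for (i in 1:200) {
    x0 <- runif(1, -1, 1)
    t <- sample(2:10, 1)
    eps <- rnorm(1)
    xt <- q_sample(x0, t, eps, sched)
    a <- sched$alpha[t]; b <- sched$beta[t]; ab <- sched$alpha_bar[t]
    mean_ <- (xt - (b / sqrt(1 - ab)) * eps) / sqrt(a)  # sigma = 0
    d_before[i] <- abs(xt - x0)
    d_after[i] <- abs(mean_ - x0)
  }
  expect_lt(mean(d_after), mean(d_before))
  expect_gt(mean(d_after < d_before + 1e-12), 0.85)
  # coefficient contraction, checked exactly at one timestep
  t <- 6L
  abp <- sched$alpha_bar[t - 1L]; ab <- sched$alpha_bar[t]
  expect_lt(1 - sqrt(abp), 1 - sqrt(ab))
  ct <- (sqrt(1 - ab) - sched$beta[t] / sqrt(1 - ab)) / sqrt(sched$alpha[t])
  expect_lt(abs(ct), sqrt(1 - ab))
})

test_that("sampling honours shape, seed and the model interface", {
  sched <- make_noise_schedule(10L)
  model <- function(xt, t) 0.1 * xt
  a <- sample_latent(model, c(4L, 4L, 2L, 3L), sched, seed = 7L)
  expect_equal(dim(a), c(4L, 4L, 2L, 3L))
  b <- sample_latent(model, c(4L, 4L, 2L, 3L), sched, seed = 7L)
  expect_identical(a, b)
  c2 <- sample_latent(model, c(4L, 4L, 2L, 3L), sched, seed = 8L)
  expect_false(identical(a, c2))
})

test_that("a toy denoiser recovers the modes of a two-point distribution", {
  # scalar latents at -0.5 / +0.5; a tiny MLP trained with the package's
  # dense layers and the epsilon-prediction objective
  sched <- make_noise_schedule(50L, beta_start = 1e-3, beta_end = 0.15)
  set.seed(61)
  H <- 48L
  params <- list(W1 = voxgen:::he_dense(3L, H), b1 = rep(0, H),
                 W2 = voxgen:::he_dense(H, H), b2 = rep(0, H),
                 W3 = voxgen:::he_dense(H, 1L, gain = 0.1), b3 = 0)
  opt <- voxgen:::adam_init(params)
  lin <- function(x, W, b) sweep(x %*% W, 2, as.numeric(b), `+`)
  feats <- function(xt, t) cbind(xt, sqrt(sched$alpha_bar[t]),
                                 sqrt(1 - sched$alpha_bar[t]))
  fwd <- function(inp, p) {
    h1 <- voxgen:::act_fwd(lin(inp, p$W1, p$b1), "silu")
    h2 <- voxgen:::act_fwd(lin(h1$y, p$W2, p$b2), "silu")
    list(out = lin(h2$y, p$W3, p$b3), h1 = h1, h2 = h2)
  }
  nb <- 32L
  for (step in 1:4000) {
    x0 <- sample(c(-0.5, 0.5), nb, replace = TRUE)
    t <- sample.int(50L, nb, replace = TRUE)
    eps <- rnorm(nb)
    xt <- q_sample(x0, t, eps, sched)
    inp <- feats(xt, t)
    f <- fwd(inp, params)
    dpred <- 2 * (f$out - eps) / nb
    dW3 <- crossprod(f$h2$y, dpred); db3 <- colSums(dpred)
    dh2 <- voxgen:::act_bwd(f$h2$cache, dpred %*% t(params$W3))
    dW2 <- crossprod(f$h1$y, dh2); db2 <- colSums(dh2)
    dh1 <- voxgen:::act_bwd(f$h1$cache, dh2 %*% t(params$W2))
    dW1 <- crossprod(inp, dh1); db1 <- colSums(dh1)
    upd <- voxgen:::adam_step(params,
                              list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
                                   W3 = dW3, b3 = db3), opt, lr = 5e-3)
    params <- upd$params; opt <- upd$state
  }
  model <- function(xt, t) as.numeric(fwd(feats(xt, t), params)$out)
  samples <- vapply(1:200, function(i)
    as.numeric(sample_latent(model, 1L, sched, seed = 1000L + i)),
    numeric(1))
  near_mode <- abs(abs(samples) - 0.5) < 0.25
  expect_gte(mean(near_mode), 0.9)
})

test_that("latent normalization is the exact codebook min-max map", {
  cb <- codebook(4, 2, init = matrix(c(-2, 0, 1, 2, -1, 0.5, 1.5, -0.5),
                                     4, 2))
  nr <- latent_normalizer(cb)
  expect_equal(nr$cb_min, -2)
  expect_equal(nr$cb_max, 2)
  expect_equal(latent_normalize(0, nr), 0)
  expect_equal(latent_normalize(2, nr), 1)
  expect_equal(latent_normalize(-2, nr), -1)
  z <- array(rnorm(12, sd = 2), c(3, 4))
  expect_equal(latent_denormalize(latent_normalize(z, nr), nr), z,
               tolerance = 1e-12)
  bad <- codebook(2, 1, init = matrix(c(1, 1), 2, 1))
  expect_error(latent_normalizer(bad), "degenerate")
})

test_that("attention treats plane and depth axes as documented", {
  set.seed(71)
  x <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  p <- voxgen:::attn_params(2L)
  y <- spatial_attention(x, p)
  expect_equal(dim(y), dim(x))
  # spatial attention: a slice's output ignores other slices
  x2 <- x; x2[, , 3, ] <- rnorm(32)
  y2 <- spatial_attention(x2, p)
  expect_equal(y[, , 1, ], y2[, , 1, ])
  expect_equal(y[, , 2, ], y2[, , 2, ])
  # depth attention: permutation equivariance over slices
  perm <- c(2, 3, 1)
  yd <- depth_attention(x, p)
  ydp <- depth_attention(x[, , perm, , drop = FALSE], p)
  expect_equal(ydp, yd[, , perm, , drop = FALSE], tolerance = 1e-12)
})

test_that("the full generation path decodes shaped, bounded, seed-stable volumes", {
  dd <- toy_ddpm()
  vq <- toy_vqgan()
  v1 <- generate_volume(vq, dd, seed = 5L)
  expect_identical(dim(v1$voxels), c(16L, 16L, 8L))
  expect_true(all(v1$voxels >= -1 & v1$voxels <= 1))
  v1b <- generate_volume(vq, dd, seed = 5L)
  expect_identical(v1$voxels, v1b$voxels)
  v2 <- generate_volume(vq, dd, seed = 6L)
  expect_lt(ms_ssim(v1, v2), 0.999)
})
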