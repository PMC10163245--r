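test_that("patch masking hits the requested fraction and is seeded", {
  v <- generate_phantom(toy_spec(2L))$volume
  sp <- masking_spec(c(4L, 4L, 2L), mask_ratio = 0.3)
  set.seed(1); a <- mask_random_patches(v, sp)
  set.seed(1); b <- mask_random_patches(v, sp)
  expect_identical(a$masked$voxels, b$masked$voxels)
  expect_identical(a$mask$voxels, b$mask$voxels)
  frac <- mean(a$mask$voxels)
  patch_frac <- prod(c(4, 4, 2)) / prod(dim(v$voxels))
  expect_gte(frac, 0.3)
  expect_lt(frac, 0.3 + patch_frac)
  expect_true(all(a$masked$voxels[a$mask$voxels == 1] == 0))

  # ratio 0: no voxels masked, target equals the (flipped) input
  set.seed(2)
  z <- mask_random_patches(v, masking_spec(mask_ratio = 0), flip_p = 0)
  expect_identical(z$masked$voxels, v$voxels)
  expect_equal(sum(z$mask$voxels), 0)

  # a single patch masks exactly its voxel count
  set.seed(3)
  one <- mask_random_patches(v, masking_spec(c(4L, 4L, 2L), 1e-4),
                             flip_p = 0)
  expect_equal(sum(one$mask$voxels), 32)
  expect_equal(sum(one$masked$voxels == 0), 32)
  expect_error(mask_random_patches(v, masking_spec(c(32L, 4L, 2L), 0.1)),
               "larger")
})

test_that("inpainting loss is a calibrated distance", {
  v <- generate_phantom(toy_spec(4L))$volume
  expect_equal(inpaint_loss(v, v), 0, tolerance = 1e-12)
  set.seed(5)
  noise <- array(rnorm(length(v$voxels)), dim(v$voxels))
  ls <- vapply(c(0.05, 0.2, 0.6), function(a)
    inpaint_loss(volume3d(v$voxels + a * noise), v), numeric(1))
  expect_true(all(diff(ls) > 0))
  # pure-L1 mode with a constant residual
  pred <- volume3d(v$voxels * 0 + 0.5)
  targ <- volume3d(v$voxels * 0)
  expect_equal(inpaint_loss(pred, targ, w_l1 = 1, w_msssim = 0), 0.5)
  expect_error(inpaint_loss(v, volume3d(array(0, c(4, 4, 4)))), "shapes")
})

test_that("segmentation loss: closed forms and limits", {
  tr <- array(rep(c(0, 1), each = 16), c(4, 4, 2))
  sc0 <- array(0, c(4, 4, 2, 2))
  out <- voxgen:::seg_loss_grad(sc0, tr)
  expect_equal(out$ce, log(2), tolerance = 1e-6)
  expect_gte(seg_loss(sc0, tr), 0)
  # near-one-hot correct scores drive the loss toward zero
  conf <- array(0, c(4, 4, 2, 2))
  conf[, , , 1] <- 20 * (1 - tr)
  conf[, , , 2] <- 20 * tr
  expect_lt(seg_loss(conf, tr), 1e-4)
  soft <- array(0, c(4, 4, 2, 2))
  soft[, , , 1] <- 3 * (1 - tr); soft[, , , 2] <- 3 * tr
  expect_lt(seg_loss(conf, tr), seg_loss(soft, tr))
  expect_error(seg_loss(array(0, c(4, 4, 2, 2)), array(0, c(4, 4, 3))),
               "shape")
})

test_that("augmentations honour probabilities, seeds and identity cases", {
  pair <- generate_phantom(toy_spec(6L))
  off <- augment_config(flip_p = 0, affine_p = 0, ghost_p = 0, noise_p = 0,
                        blur_p = 0, bias_p = 0, gamma_p = 0)
  set.seed(1)
  a <- augment(pair$volume, pair$mask, off)
  expect_identical(a$volume$voxels, pair$volume$voxels)
  expect_identical(a$mask$voxels, pair$mask$voxels)
  # gamma with exponent 1 is the identity on [-1, 1]
  g1 <- augment_config(flip_p = 0, affine_p = 0, ghost_p = 0, noise_p = 0,
                       blur_p = 0, bias_p = 0, gamma_p = 1,
                       gamma_range = c(1, 1))
  set.seed(2)
  b <- augment(pair$volume, NULL, g1)
  expect_equal(b$volume$voxels, pair$volume$voxels, tolerance = 1e-12)
  # seeded reproducibility with everything on
  set.seed(3); c1 <- augment(pair$volume, pair$mask)
  set.seed(3); c2 <- augment(pair$volume, pair$mask)
  expect_identical(c1$volume$voxels, c2$volume$voxels)
  expect_identical(c1$mask$voxels, c2$mask$voxels)
  expect_true(all(c1$mask$voxels %in% c(0, 1)))
  expect_error(augment_config(flip_p = 2), "probabilities")
})

test_that("inpainting pretraining reduces the pretext loss and is seed-stable", {
  vols <- lapply(generate_cohort(8L, toy_spec(40L)), `[[`, "volume")
  fit <- pretrain_inpainter(vols, masking_spec(), steps = 40L,
                            batch_size = 2L, width = 8L, seed = 2L)
  h <- fit$history
  expect_lt(mean(tail(h, 5)), 0.7 * mean(head(h, 5)))
  fit2 <- pretrain_inpainter(vols, masking_spec(), steps = 40L,
                             batch_size = 2L, width = 8L, seed = 2L)
  expect_identical(tail(fit$history, 1), tail(fit2$history, 1))
  # zero learning rate leaves the initialization untouched
  fit0 <- pretrain_inpainter(vols, masking_spec(), steps = 3L, width = 8L,
                             lr = 0, seed = 4L)
  old <- voxgen:::get_rng_state(); set.seed(4L)
  init <- voxgen:::unet_init(8L, "recon")
  voxgen:::restore_rng_state(old)
  expect_equal(fit0$params$e1$W, init$e1$W, tolerance = 1e-12)
})

test_that("fraction subsets are nested, reproducible and fail cleanly when empty", {
  coh <- generate_cohort(12L, toy_spec(60L))
  ex <- finetune_fractions(coh, fractions = c(25, 50), seed = 5L,
                           steps = 6L, width = 6L, n_boot = 100L)
  expect_s3_class(ex, "fraction_experiment")
  r <- ex$results
  expect_equal(r$fraction, c(25, 50))
  expect_true(all(diff(r$n_train) > 0))
  expect_true(all(r$dice >= 0 & r$dice <= 1))
  expect_true(all(is.finite(r$dice_sd)))
  # reproducibility of the whole experiment
  ex2 <- finetune_fractions(coh, fractions = c(25, 50), seed = 5L,
                            steps = 6L, width = 6L, n_boot = 100L)
  expect_identical(ex$results$dice, ex2$results$dice)
  # nesting: the training pool order is a seeded permutation shared across
  # fractions, so the smaller subset is a prefix of the larger
  expect_error(finetune_fractions(coh, fractions = 101), "fractions")
})

test_that("fine-tuning beats a frozen random backbone", {
  coh <- generate_cohort(12L, toy_spec(80L))
  train <- coh[1:8]; test <- coh[9:12]
  model <- finetune_segmenter(train, steps = 40L, width = 8L, seed = 6L,
                              config = NULL)
  d_fit <- mean(vapply(test, function(p)
    dice(predict(model, p$volume), p$mask), numeric(1)))
  set.seed(7)
  frozen <- structure(list(params = voxgen:::unet_init(8L, "seg"),
                           width = 8L, history = numeric(),
                           pretrained = FALSE, seed = 7L),
                      class = "segmenter")
  d_frz <- mean(vapply(test, function(p)
    dice(predict(frozen, p$volume), p$mask), numeric(1)))
  expect_gt(d_fit, d_frz)
  expect_gt(d_fit, 0.6)
})
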