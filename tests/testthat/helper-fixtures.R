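# Shared fixtures, built once per test run and memoised. All data is
# generated in code; the toy models are small enough to train on one CPU in
# a couple of minutes and are reused across test files.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

toy_spec <- function(seed = 10L)
  phantom_spec(shape = c(16L, 16L, 8L), n_structures = 2L,
               radius_range = c(2, 4), noise_sd = 0.01,
               bias_amplitude = 0.1, seed = seed)

toy_cohort <- function() memo("toy_cohort", function()
  generate_cohort(8L, toy_spec(10L)))

heldout_cohort <- function() memo("heldout_cohort", function()
  generate_cohort(10L, toy_spec(500L)))

toy_vqgan <- function() memo("toy_vqgan", function()
  fit_vqgan(toy_cohort(), s = 2L, steps = 200L, batch_size = 4L, seed = 1L))

toy_ddpm <- function() memo("toy_ddpm", function()
  fit_latent_ddpm(toy_vqgan(), toy_cohort(), T_steps = 100L, steps = 250L,
                  batch_size = 4L, seed = 1L))

# central-difference gradient for spot checks
num_grad_at <- function(f, x, idx, eps = 1e-5) {
  vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}

ramp_volume <- function(shape = c(4L, 4L, 4L), spacing = c(1, 1, 1)) {
  n <- prod(shape)
  volume3d(array(seq(-1, 1, length.out = n), shape), spacing = spacing)
}
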