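#' Specification of a synthetic 3D phantom cohort
#'
#' Describes the procedural phantoms that stand in for medical cohorts
#' throughout voxgen: a large centered body ellipsoid containing a number of
#' smaller ellipsoidal structures of varying position, size and intensity,
#' modulated by a smooth multiplicative bias field (the MR inhomogeneity
#' analog) and additive Gaussian noise, then min-max normalized to \[-1, 1\].
#'
#' @param shape Integer length-3 grid extents (H, W, D).
#' @param n_structures Number of inner ellipsoids.
#' @param radius_range Min/max semi-axis of inner structures, in voxels.
#' @param intensity_range Min/max intensity of inner structures (pre
#'   normalization).
#' @param body_intensity Intensity of the body ellipsoid.
#' @param body_axes_frac Semi-axes of the body ellipsoid as a fraction of each
#'   half-extent.
#' @param jitter Structure-placement spread in \[0, 1\]: centers are drawn
#'   uniformly within `jitter` of the body center (0 places every structure at
#'   the grid center, useful for analytic checks).
#' @param noise_sd Standard deviation of additive Gaussian noise, >= 0.
#' @param bias_amplitude Maximum deviation of the multiplicative bias field
#'   from 1, in `[0, 1)`.
#' @param seed Base seed; cohort member `i` (1-based) uses `seed + i - 1`.
#' @return An object of class `phantom_spec`.
#' @examples
#' spec <- phantom_spec(shape = c(16, 16, 8), seed = 1)
#' pair <- generate_phantom(spec)
#' range(pair$volume$voxels)
#' @export
phantom_spec <- function(shape = c(32, 32, 16), n_structures = 3L,
                         radius_range = c(2, 5), intensity_range = c(0.5, 1),
                         body_intensity = 0.25, body_axes_frac = 0.8,
                         jitter = 0.7, noise_sd = 0.02, bias_amplitude = 0.2,
                         seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 4L))
    stop("phantom_spec: shape must be 3 extents >= 4", call. = FALSE)
  if (noise_sd < 0) stop("phantom_spec: noise_sd must be >= 0", call. = FALSE)
  if (bias_amplitude < 0 || bias_amplitude >= 1)
    stop("phantom_spec: bias_amplitude must be in [0, 1)", call. = FALSE)
  if (radius_range[2] > min(shape) / 2)
    stop("phantom_spec: radius_range exceeds the grid", call. = FALSE)
  if (body_axes_frac <= 0 || body_axes_frac > 1)
    stop("phantom_spec: body_axes_frac must be in (0, 1]", call. = FALSE)
  structure(list(shape = shape, n_structures = as.integer(n_structures),
                 radius_range = as.numeric(radius_range),
                 intensity_range = as.numeric(intensity_range),
                 body_intensity = body_intensity,
                 body_axes_frac = body_axes_frac, jitter = jitter,
                 noise_sd = noise_sd, bias_amplitude = bias_amplitude,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0("<phantom_spec> %s grid, %d structures ",
                     "(r %g-%g vox, intensity %g-%g), noise sd %g, ",
                     "bias %g, seed %d\n"),
              paste(x$shape, collapse = "x"), x$n_structures,
              x$radius_range[1], x$radius_range[2],
              x$intensity_range[1], x$intensity_range[2],
              x$noise_sd, x$bias_amplitude, x$seed))
  invisible(x)
}

## Indicator of an axis-aligned ellipsoid on the voxel grid (0-based centers).
ellipsoid_indicator <- function(shape, center, semi_axes) {
  ax <- lapply(1:3, function(a) ((0:(shape[a] - 1)) - center[a]) / semi_axes[a])
  q <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  array(q < 1, shape)
}

## Random degree-<=2 polynomial in coordinates normalized to [-1,1], rescaled
## so its maximum absolute value equals `amplitude`.
bias_field <- function(shape, amplitude) {
  if (amplitude == 0) return(array(0, shape))
  cs <- lapply(shape, function(n)
    if (n > 1) 2 * (0:(n - 1)) / (n - 1) - 1 else 0)
  terms <- list(
    function(x, y, z) x, function(x, y, z) y, function(x, y, z) z,
    function(x, y, z) x * y, function(x, y, z) x * z,
    function(x, y, z) y * z,
    function(x, y, z) x^2, function(x, y, z) y^2, function(x, y, z) z^2)
  co <- stats::rnorm(length(terms))
  g <- expand.grid(x = cs[[1]], y = cs[[2]], z = cs[[3]])
  f <- Reduce(`+`, lapply(seq_along(terms),
                          function(i) co[i] * terms[[i]](g$x, g$y, g$z)))
  m <- max(abs(f))
  if (m == 0) return(array(0, shape))
  array(f / m * amplitude, shape)
}

#' Generate one phantom volume with its paired mask
#'
#' Draws structure positions, sizes and intensities from the spec's seed,
#' composes body + structures, applies the bias field and noise, and min-max
#' normalizes to \[-1, 1\]. The mask marks the interior of the body ellipsoid.
#'
#' @param spec A [phantom_spec()].
#' @param seed Optional seed overriding `spec$seed`.
#' @return A list with elements `volume` ([volume3d()]) and `mask`
#'   ([label_mask()]).
#' @export
generate_phantom <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  sh <- spec$shape
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  center <- (sh - 1) / 2
  body_axes <- spec$body_axes_frac * sh / 2
  body <- ellipsoid_indicator(sh, center, body_axes)
  img <- array(0, sh)
  img[body] <- spec$body_intensity
  if (spec$n_structures > 0) {
    for (i in seq_len(spec$n_structures)) {
      r <- stats::runif(3, spec$radius_range[1], spec$radius_range[2])
      # center drawn inside the body so structures stay on anatomy
      ctr <- center + (body_axes - r) * stats::runif(3, -spec$jitter, spec$jitter)
      val <- stats::runif(1, spec$intensity_range[1], spec$intensity_range[2])
      ind <- ellipsoid_indicator(sh, ctr, r)
      img[ind & body] <- val
    }
  }
  img <- img * (1 + bias_field(sh, spec$bias_amplitude))
  if (spec$noise_sd > 0)
    img <- img + stats::rnorm(length(img), sd = spec$noise_sd)
  vol <- minmax_normalize(volume3d(array(img, sh), modality = "synthetic"))
  list(volume = vol,
       mask = label_mask(array(as.numeric(body), sh), spacing = vol$spacing))
}

#' Generate a reproducible cohort of phantoms
#'
#' Member `i` is drawn with seed `spec$seed + i - 1`, so cohorts are
#' reproducible and extendable.
#'
#' @param n Number of phantom pairs, >= 0.
#' @param spec A [phantom_spec()].
#' @return A list of `n` lists, each with `volume` and `mask`.
#' @export
generate_cohort <- function(n, spec) {
  stopifnot(n >= 0)
  lapply(seq_len(n), function(i) generate_phantom(spec, seed = spec$seed + i - 1L))
}

## Save/restore .Random.seed so seeded generators do not disturb the caller's
## RNG stream.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
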