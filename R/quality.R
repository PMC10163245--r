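## Structural-similarity metrics in 3D, a pairwise-diversity probe for mode
## collapse, the Dice coefficient, and bootstrap uncertainty.
##
## SSIM local statistics use a separable 3D Gaussian window with zero-padded
## "same" filtering; because the window is symmetric this filter is its own
## adjoint, which keeps the analytic MS-SSIM gradient (used as a training
## loss) exact. Gradients are verified against finite differences in the
## test suite.

gauss_kernel <- function(window, sigma) {
  r <- (window - 1) / 2
  g <- exp(-((seq_len(window) - 1 - r)^2) / (2 * sigma^2))
  g / sum(g)
}

## Separable Gaussian filtering of a 3D array (zero-padded, self-adjoint).
gauss_filter3 <- function(arr, g) {
  w <- length(g)
  a4 <- array(arr, c(dim(arr), 1L))
  k1 <- array(g, c(w, 1, 1, 1, 1))
  k2 <- array(g, c(1, w, 1, 1, 1))
  k3 <- array(g, c(1, 1, w, 1, 1))
  a4 <- conv3d_fwd(a4, k1, 0)$y
  a4 <- conv3d_fwd(a4, k2, 0)$y
  a4 <- conv3d_fwd(a4, k3, 0)$y
  array(a4, dim(arr))
}

as_vox <- function(x) if (inherits(x, c("volume3d", "label_mask"))) x$voxels else x

## Local SSIM statistics and the mean map value, optionally with the gradient
## of the mean wrt the second argument. `luminance` switches between the full
## SSIM term (l * cs) and the contrast/structure-only term used at the finer
## scales of MS-SSIM.
ssim_stat <- function(x, y, window, sigma, data_range, luminance = TRUE,
                      grad = FALSE) {
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  g <- gauss_kernel(window, sigma)
  mx <- gauss_filter3(x, g); my <- gauss_filter3(y, g)
  sxx <- gauss_filter3(x * x, g) - mx^2
  syy <- gauss_filter3(y * y, g) - my^2
  sxy <- gauss_filter3(x * y, g) - mx * my
  A <- 2 * sxy + C2
  B <- sxx + syy + C2
  cs_map <- A / B
  if (luminance) {
    Bl <- mx^2 + my^2 + C1
    l_map <- (2 * mx * my + C1) / Bl
    s_map <- l_map * cs_map
  } else {
    s_map <- cs_map
  }
  val <- mean(s_map)
  if (!grad) return(list(value = val))
  N <- length(s_map)
  if (luminance) {
    G2 <- l_map * (-A / B^2)      # d s / d syy
    G3 <- l_map * (2 / B)         # d s / d sxy
    dl_dmy <- (2 * mx * Bl - 2 * my * (2 * mx * my + C1)) / Bl^2
    Gm <- cs_map * dl_dmy         # d s / d my (explicit luminance part)
  } else {
    G2 <- -A / B^2
    G3 <- 2 / B
    Gm <- array(0, dim(x))
  }
  grad_y <- (gauss_filter3(Gm, g) +
               2 * y * gauss_filter3(G2, g) -
               2 * gauss_filter3(G2 * my, g) +
               x * gauss_filter3(G3, g) -
               gauss_filter3(G3 * mx, g)) / N
  list(value = val, grad_y = grad_y)
}

#' Structural similarity between two volumes
#'
#' Single-scale SSIM computed with 3D Gaussian windows (the volumes, not
#' their slices, are the objects of comparison). Constants follow the
#' standard choice C1 = (0.01 L)^2, C2 = (0.03 L)^2 for data range L.
#' Symmetric, and equal to 1 exactly when the inputs are identical.
#'
#' @param a,b [volume3d()] objects or 3D arrays of the same shape.
#' @param window Odd window size in voxels.
#' @param sigma Gaussian window standard deviation, in voxels.
#' @param data_range Value range L of the data (2 for \[-1, 1\] volumes).
#' @return Scalar SSIM in (-1, 1].
#' @export
ssim <- function(a, b, window = 7L, sigma = 1.5, data_range = 2) {
  a <- as_vox(a); b <- as_vox(b)
  if (!identical(dim(a), dim(b)))
    stop("ssim: shapes differ", call. = FALSE)
  if (data_range <= 0) stop("ssim: data_range must be > 0", call. = FALSE)
  if (any(dim(a) < window))
    stop("ssim: volume smaller than the window", call. = FALSE)
  ssim_stat(a, b, window, sigma, data_range)$value
}

## 2x2x2 average pooling with floor truncation, and its adjoint.
avg_pool2 <- function(x) {
  d <- dim(x)
  h <- pmax(d %/% 2L, 1L)
  keep <- pmin(2L * h, d)
  x <- x[seq_len(keep[1]), seq_len(keep[2]), seq_len(keep[3]), drop = FALSE]
  f <- ifelse(d >= 2L, 2L, 1L)
  i1 <- (seq_len(keep[1]) - 1L) %/% f[1]
  i2 <- (seq_len(keep[2]) - 1L) %/% f[2]
  i3 <- (seq_len(keep[3]) - 1L) %/% f[3]
  grp <- outer(outer(i1, h[1] * i2, `+`), h[1] * h[2] * i3, `+`)
  sums <- as.vector(rowsum(as.vector(x), as.vector(grp)))
  array(sums / prod(f), h)
}

avg_pool2_adjoint <- function(gc, dims_fine) {
  f <- ifelse(dims_fine >= 2L, 2L, 1L)
  h <- dim(gc)
  keep <- pmin(f * h, dims_fine)
  out <- array(0, dims_fine)
  i1 <- 1L + (seq_len(keep[1]) - 1L) %/% f[1]
  i2 <- 1L + (seq_len(keep[2]) - 1L) %/% f[2]
  i3 <- 1L + (seq_len(keep[3]) - 1L) %/% f[3]
  out[seq_len(keep[1]), seq_len(keep[2]), seq_len(keep[3])] <-
    gc[i1, i2, i3, drop = FALSE] / prod(f)
  out
}

#' Multiscale structural similarity between two volumes
#'
#' MS-SSIM with 3D windows: contrast/structure terms are computed at each
#' scale (obtained by 2x average pooling), the luminance term only at the
#' coarsest, and the result is the weighted product of the per-scale means.
#' The number of scales is automatically reduced so the smallest axis at the
#' coarsest scale still accommodates the window (shallow volumes such as
#' depth-8 grids support fewer scales), and the weights are renormalized.
#' This is the similarity score used both as reconstruction/inpainting loss
#' term and as the pairwise diversity probe.
#'
#' @inheritParams ssim
#' @param n_scales Maximum number of scales; the standard 5-scale weights are
#'   truncated and renormalized when fewer fit.
#' @param weights Per-scale weights (summing to 1 after truncation).
#' @return Scalar MS-SSIM in (-1, 1].
#' @export
ms_ssim <- function(a, b, n_scales = 5L, window = 7L, sigma = 1.5,
                    data_range = 2,
                    weights = c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)) {
  ms_ssim_engine(as_vox(a), as_vox(b), n_scales, window, sigma, data_range,
                 weights, grad = FALSE)$value
}

ms_ssim_engine <- function(x, y, n_scales, window, sigma, data_range,
                           weights, grad = FALSE) {
  if (!identical(dim(x), dim(y)))
    stop("ms_ssim: shapes differ", call. = FALSE)
  if (any(dim(x) < window))
    stop("ms_ssim: volume smaller than the window", call. = FALSE)
  # reduce scales until the coarsest grid still holds the window
  usable <- 1L
  d <- dim(x)
  while (usable < n_scales && all(d %/% 2L >= window)) {
    d <- d %/% 2L
    usable <- usable + 1L
  }
  w <- weights[seq_len(usable)]
  w <- w / sum(w)
  xs <- x; ys <- y
  terms <- numeric(usable)
  grads <- if (grad) vector("list", usable)
  dims_chain <- vector("list", usable)
  for (i in seq_len(usable)) {
    dims_chain[[i]] <- dim(ys)
    st <- ssim_stat(xs, ys, window, sigma, data_range,
                    luminance = (i == usable), grad = grad)
    terms[i] <- st$value
    if (grad) grads[[i]] <- st$grad_y
    if (i < usable) { xs <- avg_pool2(xs); ys <- avg_pool2(ys) }
  }
  tc <- pmax(terms, 1e-6)   # clamp so the weighted product stays defined
  val <- prod(tc^w)
  if (!grad) return(list(value = val, terms = terms, weights = w))
  gy <- array(0, dim(y))
  for (i in seq_len(usable)) {
    if (terms[i] <= 1e-6) next
    coef <- val * w[i] / tc[i]
    g <- grads[[i]] * coef
    # chain back through the pooling pyramid to full resolution
    for (j in rev(seq_len(i - 1L)))
      g <- avg_pool2_adjoint(g, dims_chain[[j]])
    gy <- gy + g
  }
  list(value = val, grad_y = gy, terms = terms, weights = w)
}

## Combined L1 + (1 - MS-SSIM) objective with gradient wrt `y` (the
## prediction). Shared by the VQ-GAN reconstruction loss and the
## self-supervised inpainting loss.
l1_msssim_grad <- function(x, y, w_l1 = 0.5, w_ms = 0.5, window = 7L,
                           sigma = 1.5, data_range = 2) {
  l1 <- mean(abs(y - x))
  gl1 <- sign(y - x) / length(y)
  if (w_ms == 0)
    return(list(value = w_l1 * l1, grad_y = w_l1 * gl1, l1 = l1, msssim = NA))
  ms <- ms_ssim_engine(x, y, 5L, window, sigma, data_range,
                       c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333), grad = TRUE)
  list(value = w_l1 * l1 + w_ms * (1 - ms$value),
       grad_y = w_l1 * gl1 - w_ms * ms$grad_y,
       l1 = l1, msssim = ms$value)
}

#' Pairwise diversity of a set of volumes
#'
#' The mode-collapse probe: draws unordered pairs of distinct items uniformly
#' (with replacement across pairs) and averages their MS-SSIM. A collapsed
#' generator that always emits the same volume scores exactly 1; a diverse
#' cohort scores lower.
#'
#' @param volumes A list of [volume3d()] (or 3D arrays), or a function
#'   `f(n)` returning such a list of `n` samples.
#' @param n_pairs Number of sampled pairs, >= 1.
#' @param seed Seed for pair sampling.
#' @param n_items When `volumes` is a sampler function, how many samples to
#'   draw.
#' @param ... Passed to [ms_ssim()].
#' @return An object of class `diversity_report` with fields `mean_msssim`,
#'   `n_pairs`, `seed`.
#' @export
pairwise_diversity <- function(volumes, n_pairs = 100L, seed = 1L,
                               n_items = 20L, ...) {
  if (is.function(volumes)) volumes <- volumes(n_items)
  if (length(volumes) < 2L)
    stop("pairwise_diversity: need at least 2 items", call. = FALSE)
  if (n_pairs < 1L) stop("pairwise_diversity: n_pairs must be >= 1",
                         call. = FALSE)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  n <- length(volumes)
  vals <- vapply(seq_len(n_pairs), function(p) {
    ij <- sample.int(n, 2L, replace = FALSE)
    ms_ssim(volumes[[ij[1]]], volumes[[ij[2]]], ...)
  }, numeric(1))
  structure(list(mean_msssim = mean(vals), n_pairs = as.integer(n_pairs),
                 seed = as.integer(seed)),
            class = "diversity_report")
}

#' @export
print.diversity_report <- function(x, ...) {
  cat(sprintf("<diversity_report> mean pairwise MS-SSIM %.4f over %d pairs (seed %d)\n",
              x$mean_msssim, x$n_pairs, x$seed))
  invisible(x)
}

#' Dice similarity coefficient of two binary masks
#'
#' `2 |A and B| / (|A| + |B|)`; two empty masks score 1 by convention.
#'
#' @param pred,truth [label_mask()] objects or binary arrays of equal shape.
#' @return Scalar in \[0, 1\].
#' @export
dice <- function(pred, truth) {
  p <- as_vox(pred); t <- as_vox(truth)
  if (!identical(dim(p), dim(t))) stop("dice: shapes differ", call. = FALSE)
  sp <- sum(p); st <- sum(t)
  if (sp + st == 0) return(1)
  2 * sum(p * t) / (sp + st)
}

#' Bootstrap standard deviation of a mean
#'
#' Resamples the values with replacement `n_boot` times and returns the
#' standard deviation of the resampled means — the uncertainty attached to
#' per-cohort Dice scores.
#'
#' @param values Numeric vector, length >= 1.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Seed for resampling.
#' @return Scalar standard deviation.
#' @export
bootstrap_sd <- function(values, n_boot = 1000L, seed = 1L) {
  if (length(values) < 1L) stop("bootstrap_sd: empty input", call. = FALSE)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  n <- length(values)
  means <- vapply(seq_len(n_boot),
                  function(i) mean(values[sample.int(n, n, replace = TRUE)]),
                  numeric(1))
  stats::sd(means)
}
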