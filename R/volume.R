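#' 3D image volume
#'
#' A `volume3d` is the universal image carrier in voxgen: a 3D array of finite
#' scalar voxel values indexed (row, column, slice) with extents (H, W, D),
#' together with the physical voxel spacing in millimetres along each axis and
#' a free-text modality tag.
#'
#' @param voxels 3D numeric array of finite values.
#' @param spacing Numeric length-3 vector of positive voxel sizes in mm.
#' @param modality Free-text tag, e.g. `"MR"`, `"CT"` or `"synthetic"`.
#' @return An object of class `volume3d` with fields `voxels`, `spacing`,
#'   `modality`.
#' @examples
#' v <- volume3d(array(0, c(4, 4, 2)), spacing = c(1, 1, 3))
#' dim(v$voxels)
#' @export
volume3d <- function(voxels, spacing = c(1, 1, 1), modality = "synthetic") {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L)
    stop("volume3d: voxels must be a 3D array, got ", length(dim(voxels)),
         " dimensions", call. = FALSE)
  if (!all(is.finite(voxels)))
    stop("volume3d: all voxel values must be finite", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("volume3d: spacing must be 3 positive finite values", call. = FALSE)
  structure(list(voxels = voxels, spacing = spacing,
                 modality = as.character(modality)[1]),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<volume3d> %d x %d x %d voxels, spacing %s mm, modality %s\n",
              d[1], d[2], d[3],
              paste(format(x$spacing, digits = 4), collapse = " x "),
              x$modality))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Binary segmentation mask
#'
#' A `label_mask` pairs with a [volume3d()]: a 3D array of 0/1 values on the
#' same grid with the same spacing.
#'
#' @param voxels 3D array with values in {0, 1}.
#' @param spacing Numeric length-3 vector of positive voxel sizes in mm.
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(voxels, spacing = c(1, 1, 1)) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L)
    stop("label_mask: voxels must be a 3D array", call. = FALSE)
  if (!all(voxels %in% c(0, 1)))
    stop("label_mask: values must be 0 or 1", call. = FALSE)
  storage.mode(voxels) <- "double"
  structure(list(voxels = voxels, spacing = as.numeric(spacing)),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<label_mask> %d x %d x %d voxels, foreground fraction %.3f\n",
              d[1], d[2], d[3], mean(x$voxels)))
  invisible(x)
}

vox_dim <- function(vol) dim(vol$voxels)

#' Read a 3D volume from a NIfTI file
#'
#' Reads a `.nii` / `.nii.gz` file into a [volume3d()]. Voxel spacing is taken
#' from the header pixdim fields; affine metadata beyond spacing is ignored
#' and the on-disk axis order is used as the canonical (row, column, slice)
#' order.
#'
#' @param path Path to a NIfTI file.
#' @param modality Modality tag to attach.
#' @return A [volume3d()].
#' @export
read_volume <- function(path, modality = "unknown") {
  if (!file.exists(path)) stop("read_volume: file not found: ", path,
                               call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("read_volume: unreadable file ",
                                           path, " (", conditionMessage(e),
                                           ")", call. = FALSE))
  arr <- as.array(img)
  arr <- array(as.vector(arr), dim(arr))   # strip NIfTI attributes
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- array(arr, dim(arr)[1:3])
  if (length(dim(arr)) != 3L)
    stop("read_volume: expected a 3D image, got ",
         length(dim(arr)), " dimensions", call. = FALSE)
  sp <- RNifti::pixdim(img)[1:3]
  volume3d(arr, spacing = sp, modality = modality)
}

#' Write a 3D volume to a NIfTI file
#'
#' @param vol A [volume3d()] or [label_mask()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$voxels)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI mask file as a label mask
#'
#' @inheritParams read_volume
#' @return A [label_mask()].
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  label_mask(round(v$voxels), spacing = v$spacing)
}

## Trilinear interpolation of a 3D array at fractional (0-based) coordinates.
## Coordinates are clamped to the valid range, so queries exactly on the
## boundary are well defined.
trilinear_at <- function(arr, gi, gj, gk) {
  d <- dim(arr)
  gi <- pmin(pmax(gi, 0), d[1] - 1L)
  gj <- pmin(pmax(gj, 0), d[2] - 1L)
  gk <- pmin(pmax(gk, 0), d[3] - 1L)
  i0 <- pmin(floor(gi), d[1] - 1L); i1 <- pmin(i0 + 1, d[1] - 1L)
  j0 <- pmin(floor(gj), d[2] - 1L); j1 <- pmin(j0 + 1, d[2] - 1L)
  k0 <- pmin(floor(gk), d[3] - 1L); k1 <- pmin(k0 + 1, d[3] - 1L)
  fi <- gi - i0; fj <- gj - j0; fk <- gk - k0
  at <- function(i, j, k) arr[1L + i + d[1] * (j + d[2] * k)]
  v000 <- at(i0, j0, k0); v100 <- at(i1, j0, k0)
  v010 <- at(i0, j1, k0); v110 <- at(i1, j1, k0)
  v001 <- at(i0, j0, k1); v101 <- at(i1, j0, k1)
  v011 <- at(i0, j1, k1); v111 <- at(i1, j1, k1)
  c00 <- v000 * (1 - fi) + v100 * fi
  c10 <- v010 * (1 - fi) + v110 * fi
  c01 <- v001 * (1 - fi) + v101 * fi
  c11 <- v011 * (1 - fi) + v111 * fi
  c0 <- c00 * (1 - fj) + c10 * fj
  c1 <- c01 * (1 - fj) + c11 * fj
  c0 * (1 - fk) + c1 * fk
}

## Trilinear scaling of an array to a target shape, endpoint-aligned: output
## corner voxels sample input corner voxels exactly, so linear ramps are
## preserved with their endpoints.
resize_array <- function(arr, target) {
  d <- dim(arr)
  if (identical(as.integer(d), as.integer(target))) return(arr)
  src <- lapply(1:3, function(a) {
    if (target[a] == 1L) (d[a] - 1) / 2
    else (seq_len(target[a]) - 1) * (d[a] - 1) / (target[a] - 1)
  })
  g <- expand.grid(i = src[[1]], j = src[[2]], k = src[[3]])
  array(trilinear_at(arr, g$i, g$j, g$k), dim = target)
}

#' Resample a volume to a target voxel spacing
#'
#' Trilinear resampling to a new physical voxel spacing, as in the standard
#' preprocessing of anisotropic MR (e.g. to 0.66 x 0.66 x 3 mm) and CT (1 mm
#' isotropic). The output extent along each axis is
#' `round(extent * spacing / target)`, with a minimum of 1.
#'
#' @param vol A [volume3d()].
#' @param target Numeric length-3 vector of positive target spacings in mm.
#' @return A [volume3d()] with spacing equal to `target`.
#' @export
resample_to_spacing <- function(vol, target) {
  target <- as.numeric(target)
  if (length(target) != 3L || any(!is.finite(target)) || any(target <= 0))
    stop("resample_to_spacing: target spacing must be 3 positive values",
         call. = FALSE)
  d <- vox_dim(vol)
  newd <- pmax(1L, as.integer(round(d * vol$spacing / target)))
  if (all(newd == d) && all(abs(target - vol$spacing) < 1e-12)) {
    out <- vol; out$spacing <- target; return(out)
  }
  volume3d(resize_array(vol$voxels, newd), spacing = target,
           modality = vol$modality)
}

#' Center-crop (or pad) a volume to a target shape
#'
#' Along each axis with input extent `n` and target `m <= n`, keeps indices
#' `floor((n - m)/2) .. floor((n - m)/2) + m - 1` (0-based). Where `m > n` the
#' volume is padded symmetrically with its minimum value (the air/background
#' analog), with the extra voxel on the high side when the padding is odd, so
#' cropping heterogeneous cohorts to a uniform shape always succeeds.
#'
#' @param vol A [volume3d()] or [label_mask()].
#' @param target_shape Integer length-3 target extents, each >= 1.
#' @param pad_value Fill value for padding; defaults to the volume minimum.
#' @return Object of the same class as `vol` with extents `target_shape`.
#' @export
center_crop <- function(vol, target_shape, pad_value = NULL) {
  target_shape <- as.integer(target_shape)
  if (length(target_shape) != 3L || any(target_shape < 1L))
    stop("center_crop: target_shape must be 3 extents >= 1", call. = FALSE)
  arr <- vol$voxels
  d <- dim(arr)
  if (is.null(pad_value)) pad_value <- min(arr)
  if (any(target_shape > d)) {
    padded_dim <- pmax(d, target_shape)
    out <- array(pad_value, padded_dim)
    lo <- ifelse(target_shape > d, floor((target_shape - d) / 2), 0L)
    out[lo[1] + seq_len(d[1]), lo[2] + seq_len(d[2]), lo[3] + seq_len(d[3])] <-
      arr
    arr <- out
    d <- padded_dim
  }
  off <- floor((d - target_shape) / 2)
  arr <- arr[off[1] + seq_len(target_shape[1]),
             off[2] + seq_len(target_shape[2]),
             off[3] + seq_len(target_shape[3]), drop = FALSE]
  out <- vol
  out$voxels <- array(arr, target_shape)
  out
}

#' Resize a volume to a target shape
#'
#' Trilinear scaling to the requested extents. Spacing is rescaled so the
#' physical extent of the volume is preserved.
#'
#' @param vol A [volume3d()].
#' @param target_shape Integer length-3 target extents, each >= 1.
#' @return A [volume3d()] with extents `target_shape`.
#' @export
resize_volume <- function(vol, target_shape) {
  target_shape <- as.integer(target_shape)
  if (length(target_shape) != 3L || any(target_shape < 1L))
    stop("resize_volume: target_shape must be 3 extents >= 1", call. = FALSE)
  d <- vox_dim(vol)
  volume3d(resize_array(vol$voxels, target_shape),
           spacing = vol$spacing * d / target_shape,
           modality = vol$modality)
}

#' Convert raw scanner values to Hounsfield units
#'
#' Elementwise linear rescale `slope * raw + intercept`, the standard CT
#' calibration (water = 0 HU, air about -1000 HU).
#'
#' @param raw A [volume3d()] of raw stored values.
#' @param slope,intercept Rescale parameters from the acquisition.
#' @return A [volume3d()] in Hounsfield units with modality `"CT"`.
#' @export
hu_convert <- function(raw, slope = 1, intercept = -1024) {
  volume3d(slope * raw$voxels + intercept, spacing = raw$spacing,
           modality = "CT")
}

#' Min-max normalize a volume to a target intensity range
#'
#' Affinely maps the volume's own min/max onto `[out_lo, out_hi]` (default
#' \[-1, 1\], the input range both generative stages assume). A constant
#' volume maps to the constant midpoint of the output range.
#'
#' @param vol A [volume3d()].
#' @param out_lo,out_hi Output range bounds, `out_lo < out_hi`.
#' @return A [volume3d()] with values in `[out_lo, out_hi]`.
#' @export
minmax_normalize <- function(vol, out_lo = -1, out_hi = 1) {
  if (!(out_lo < out_hi))
    stop("minmax_normalize: need out_lo < out_hi", call. = FALSE)
  v <- vol$voxels
  lo <- min(v); hi <- max(v)
  out <- vol
  if (hi == lo) {
    out$voxels <- array((out_lo + out_hi) / 2, dim(v))
  } else {
    out$voxels <- out_lo + (v - lo) * (out_hi - out_lo) / (hi - lo)
  }
  out
}

#' Randomly flip a volume along one axis
#'
#' The training-time flip augmentation: with probability `p` the voxel order
#' along `axis` is reversed. Axis 1 is the vertical (row) axis. Deterministic
#' given the R random-number state.
#'
#' @param vol A [volume3d()] or [label_mask()].
#' @param axis Axis to flip (1, 2 or 3).
#' @param p Flip probability in \[0, 1\].
#' @return Object of the same class as `vol`.
#' @export
random_flip <- function(vol, axis = 1L, p = 0.5) {
  axis <- as.integer(axis)
  if (is.na(axis) || axis < 1L || axis > 3L)
    stop("random_flip: axis must be 1, 2 or 3", call. = FALSE)
  if (p < 0 || p > 1) stop("random_flip: p must be in [0, 1]", call. = FALSE)
  if (stats::runif(1) < p) flip_axis(vol, axis) else vol
}

#' Deterministically flip a volume along one axis
#'
#' @inheritParams random_flip
#' @return Object of the same class as `vol` with reversed voxel order along
#'   `axis`.
#' @export
flip_axis <- function(vol, axis = 1L) {
  d <- dim(vol$voxels)
  idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  idx[[axis]] <- rev(idx[[axis]])
  out <- vol
  out$voxels <- vol$voxels[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  dim(out$voxels) <- d
  out
}

#' Split a volume into left and right halves
#'
#' Splits along the column axis so paired lateral anatomy (e.g. left/right
#' breast) lands on separate images: left keeps columns `[0, floor(W/2))`,
#' right keeps `[ceil(W/2), W)` (0-based). For odd widths the middle column is
#' dropped; for even widths concatenating the halves reproduces the input.
#'
#' @param vol A [volume3d()].
#' @return A list with elements `left` and `right`, both [volume3d()].
#' @export
split_bilateral <- function(vol) {
  w <- vox_dim(vol)[2]
  if (w < 2L) stop("split_bilateral: width must be >= 2", call. = FALSE)
  lw <- floor(w / 2)
  left <- vol;  left$voxels <- vol$voxels[, seq_len(lw), , drop = FALSE]
  right <- vol; right$voxels <- vol$voxels[, (w - lw + 1):w, , drop = FALSE]
  list(left = left, right = right)
}
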