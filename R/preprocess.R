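## Geometry and grayscale standardisation before any feature computation.

#' Load an image/mask pair from NIfTI files
#'
#' Reads a grayscale volume and its tumour mask, binarises the mask (any
#' single positive foreground value is accepted) and, if the grids differ,
#' resamples the mask to the image grid with nearest-neighbour interpolation.
#'
#' @param img_path path to the image NIfTI
#' @param mask_path path to the mask NIfTI
#' @return list with `volume` and `mask` (`hab_volume`s on a common grid)
#' @export
load_case <- function(img_path, mask_path) {
  for (p in c(img_path, mask_path))
    if (!file.exists(p)) stopf("file not found: '%s'", p)
  img <- RNifti::readNifti(img_path)
  msk <- RNifti::readNifti(mask_path)
  sp_img <- RNifti::pixdim(img)[1:3]
  sp_msk <- RNifti::pixdim(msk)[1:3]
  vol <- volume(array(as.numeric(img), dim(img)[1:3]), sp_img)
  mdat <- array(as.numeric(msk), dim(msk)[1:3])
  vals <- sort(unique(as.vector(mdat)))
  if (length(vals) > 2 || any(vals < 0))
    stopf("mask is not binary: values {%s}",
          paste(head(vals, 5), collapse = ", "))
  mdat <- (mdat > 0) * 1
  if (!identical(dim(mdat), dim(vol$data))) {
    mdat <- resample_array(mdat, sp_msk, sp_img,
                           method = "nearest", target_dim = dim(vol$data))
  }
  if (sum(mdat) == 0) stopf("empty VOI: mask contains no foreground voxels")
  list(volume = vol, mask = volume(mdat, sp_img))
}

## Resample a 3D array from `spacing` to `target_spacing` by separable
## interpolation: cubic convolution (Keys kernel, a smooth 3rd-order
## interpolator) for images, nearest neighbour for masks/labels.
resample_array <- function(arr, spacing, target_spacing,
                           method = c("cubic", "nearest"),
                           target_dim = NULL) {
  method <- match.arg(method)
  d <- dim(arr)
  for (axis in 1:3) {
    n_in <- dim(arr)[axis]
    n_out <- if (!is.null(target_dim)) target_dim[axis] else
      max(1L, floor((n_in - 1) * spacing[axis] / target_spacing[axis]) + 1L)
    if (n_out == n_in && abs(spacing[axis] - target_spacing[axis]) < 1e-9)
      next
    pos <- (seq_len(n_out) - 1) * target_spacing[axis] / spacing[axis] + 1
    arr <- resample_axis(arr, axis, pos, n_out, method)
  }
  arr
}

resample_axis <- function(arr, axis, pos, n_out, method) {
  d <- dim(arr)
  n_in <- d[axis]
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(arr, perm), nrow = n_in)
  if (method == "nearest") {
    idx <- pmin(pmax(round(pos), 1L), n_in)
    out <- m[idx, , drop = FALSE]
  } else {
    W <- matrix(0, n_out, n_in)
    base <- floor(pos)
    frac <- pos - base
    for (t in -1:2) {
      w <- keys_kernel(frac - t)
      src <- pmin(pmax(base + t, 1L), n_in)   # clamp at edges
      W[cbind(seq_len(n_out), src)] <- W[cbind(seq_len(n_out), src)] + w
    }
    out <- W %*% m
  }
  d_out <- d[perm]
  d_out[1] <- n_out
  aperm(array(out, d_out), order(perm))
}

## Keys cubic convolution kernel, a = -0.5.
keys_kernel <- function(x) {
  ax <- abs(x)
  a <- -0.5
  ifelse(ax <= 1, (a + 2) * ax^3 - (a + 3) * ax^2 + 1,
         ifelse(ax < 2, a * (ax^3 - 5 * ax^2 + 8 * ax - 4), 0))
}

#' Resample an image/mask pair to a target spacing
#'
#' Image values are interpolated with a smooth cubic (3rd-order convolution)
#' kernel, the mask with nearest neighbour so it stays binary. The default
#' target grid of 1 x 1 x 3 mm is the standard anisotropic radiomics grid
#' for thick-slice acquisitions.
#'
#' @param vol image `hab_volume`
#' @param mask mask `hab_volume` on the same grid
#' @param target_spacing mm per axis
#' @return list with resampled `volume` and `mask`
#' @export
resample_case <- function(vol, mask, target_spacing = c(1, 1, 3)) {
  if (!identical(dim(vol$data), dim(mask$data))) stopf("grid mismatch")
  if (all(abs(vol$spacing - target_spacing) < 1e-9))
    return(list(volume = vol, mask = mask))
  vdat <- resample_array(vol$data, vol$spacing, target_spacing, "cubic")
  mdat <- resample_array(mask$data, mask$spacing, target_spacing, "nearest")
  if (sum(mdat) == 0) stopf("resampling emptied the mask")
  list(volume = volume(vdat, target_spacing),
       mask = volume(mdat, target_spacing))
}

#' Min-max grayscale normalisation over the VOI
#'
#' Rescales the intensities of the mask voxels so that the VOI minimum maps
#' to `range[1]` and the maximum to `range[2]` (default 0-255). Voxels
#' outside the mask are left untouched; a constant VOI maps to `range[1]`.
#'
#' @param vol image `hab_volume`
#' @param mask mask `hab_volume` or logical array
#' @param range output grayscale range
#' @return normalised `hab_volume`
#' @export
normalize_grayscale <- function(vol, mask, range = c(0, 255)) {
  m <- if (inherits(mask, "hab_volume")) mask$data > 0 else mask > 0
  if (!identical(dim(m), dim(vol$data))) stopf("grid mismatch")
  if (!any(m)) stopf("empty VOI: mask contains no foreground voxels")
  v <- vol$data[m]
  lo <- min(v); hi <- max(v)
  out <- vol$data
  out[m] <- if (hi > lo)
    (v - lo) / (hi - lo) * (range[2] - range[1]) + range[1]
  else range[1]
  volume(out, vol$spacing, vol$origin)
}
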