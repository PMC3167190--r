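#' Build an a priori lesion probability map
#'
#' Voxelwise arithmetic mean of binary lesion masks (or of fractional
#' resampled segmentations) that already live on one common grid, e.g.
#' affine-registered into a standard space by an external tool. The result
#' is the a priori probability distribution of lesions across the cohort.
#'
#' @param masks List of [wmh_mask] (or [wmh_probmap] with fractional
#'   values) on identical grids.
#' @return A [wmh_probmap] with `n_subjects = length(masks)`.
#' @export
build_prior <- function(masks) {
  if (length(masks) == 0L) stop("need at least one mask", call. = FALSE)
  ref <- masks[[1]]
  g0 <- grid_of(ref)
  acc <- array(0, dim = dim(ref$data))
  for (i in seq_along(masks)) {
    m <- masks[[i]]
    gi <- grid_of(m)
    if (!same_grid(g0, gi))
      stop(sprintf("incompatible grids: mask %d has %s but mask 1 has %s",
                   i, format_grid(gi), format_grid(g0)), call. = FALSE)
    v <- if (is.logical(m$data)) m$data + 0 else as.numeric(m$data)
    acc <- acc + v
  }
  avg <- acc / length(masks)
  avg[avg < 0] <- 0
  avg[avg > 1] <- 1
  dim(avg) <- dim(ref$data)
  wmh_probmap(avg, spacing = ref$spacing, affine = ref$affine,
              n_subjects = length(masks))
}

#' Gaussian smoothing of a probability map
#'
#' Separable Gaussian smoothing with the kernel width given as full width
#' at half maximum in mm (the neuroimaging convention), applied per axis in
#' world units. `fwhm_mm = 0` is the identity. The kernel is normalised
#' (renormalised over its in-bounds support at the array boundary), so
#' values stay in \[0, 1\], a uniform map is a fixed point, and mass with
#' support away from the boundary is conserved exactly.
#'
#' @param prior A [wmh_probmap].
#' @param fwhm_mm Full width at half maximum in mm, >= 0.
#' @return A smoothed [wmh_probmap].
#' @export
smooth_prior <- function(prior, fwhm_mm) {
  stopifnot(inherits(prior, "wmh_probmap"))
  if (fwhm_mm < 0) stop("fwhm_mm must be >= 0", call. = FALSE)
  if (fwhm_mm == 0) return(prior)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  out <- prior$data
  for (axis in 1:3) {
    sigma_vox <- sigma_mm / prior$spacing[axis]
    out <- convolve_axis(out, gaussian_kernel(sigma_vox), axis)
  }
  out[out < 0] <- 0
  out[out > 1] <- 1
  wmh_probmap(out, spacing = prior$spacing, affine = prior$affine,
              n_subjects = prior$n_subjects)
}

gaussian_kernel <- function(sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# Convolution along one axis via a banded matrix product. At the array
# boundary the kernel is renormalised over its in-bounds support, so a
# uniform field is an exact fixed point; for a kernel supported entirely in
# the interior this reduces to plain convolution and conserves mass.
convolve_axis <- function(arr, kern, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  x <- aperm(arr, perm)
  n <- d[axis]
  m <- matrix(x, nrow = n)
  r <- (length(kern) - 1L) / 2L
  band <- matrix(0, n, n)
  for (off in -r:r) {
    idx <- which(seq_len(n) + off >= 1 & seq_len(n) + off <= n)
    band[cbind(idx, idx + off)] <- kern[off + r + 1L]
  }
  band <- band / rowSums(band)
  res <- band %*% m
  res <- array(res, dim = d[perm])
  aperm(res, order(perm))
}
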