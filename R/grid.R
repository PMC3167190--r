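#' @title Image containers and grid compatibility
#'
#' @description A `wmh_volume` is a 3D scalar image (the FLAIR or T1 carrier)
#' with per-axis voxel spacing in mm and a 4x4 voxel-index-to-world affine
#' (RAS+, 0-based indices). A `wmh_mask` is a 3D logical image living on the
#' same kind of grid; it caches its `TRUE`-voxel count. A `wmh_probmap` is a
#' 3D field in \[0, 1\] (tissue posterior or lesion frequency). Any two
#' images combined anywhere in the package must share shape and affine; there
#' is no silent resampling.
#'
#' @name wmhseg-containers
NULL

AFFINE_TOL <- 1e-4  # absolute tolerance on affine entries for grid equality

new_grid <- function(shape, spacing, affine) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive voxel sizes in mm", call. = FALSE)
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || any(!is.finite(affine)))
    stop("affine must be a finite 4x4 matrix", call. = FALSE)
  if (abs(det(affine)) < .Machine$double.eps)
    stop("affine must be invertible", call. = FALSE)
  list(shape = shape, spacing = spacing, affine = affine)
}

default_affine <- function(spacing) {
  diag(c(spacing, 1))
}

grid_of <- function(x) {
  new_grid(dim(x$data), x$spacing, x$affine)
}

format_grid <- function(g) {
  sprintf("shape %s, affine [%s]",
          paste(g$shape, collapse = "x"),
          paste(signif(as.vector(g$affine), 6), collapse = " "))
}

same_grid <- function(a, b, tol = AFFINE_TOL) {
  identical(a$shape, b$shape) && all(abs(a$affine - b$affine) <= tol)
}

stop_incompatible_grid <- function(a, b, what = "images") {
  stop(sprintf("incompatible grids: %s have %s vs %s",
               what, format_grid(a), format_grid(b)),
       call. = FALSE)
}

check_same_grid <- function(x, y, what = "images") {
  gx <- grid_of(x)
  gy <- grid_of(y)
  if (!same_grid(gx, gy)) stop_incompatible_grid(gx, gy, what)
  invisible(TRUE)
}

#' Construct a volume
#'
#' @param data 3D numeric array of voxel intensities.
#' @param spacing Per-axis voxel size in mm (length 3).
#' @param affine 4x4 voxel-index-to-world map; defaults to a diagonal
#'   scaling by `spacing`.
#' @param meta Named list of free-form provenance.
#' @return A `wmh_volume` object.
#' @export
wmh_volume <- function(data, spacing = c(1, 1, 1),
                       affine = default_affine(spacing), meta = list()) {
  if (length(dim(data)) != 3L)
    stop("volume data must be a 3D array", call. = FALSE)
  g <- new_grid(dim(data), spacing, affine)
  if (anyNA(data))
    stop(sprintf("volume contains %d NaN/NA voxels", sum(is.na(data))),
         call. = FALSE)
  structure(list(data = data, spacing = g$spacing, affine = g$affine,
                 meta = meta),
            class = "wmh_volume")
}

#' Construct a binary mask
#'
#' @param data 3D logical array (or coercible 0/1 numeric).
#' @inheritParams wmh_volume
#' @return A `wmh_mask` object; `n_voxels(m)` is its cached `TRUE` count.
#' @export
wmh_mask <- function(data, spacing = c(1, 1, 1),
                     affine = default_affine(spacing)) {
  if (length(dim(data)) != 3L)
    stop("mask data must be a 3D array", call. = FALSE)
  g <- new_grid(dim(data), spacing, affine)
  dims <- dim(data)
  data <- as.logical(data)
  if (anyNA(data)) stop("mask contains NA voxels", call. = FALSE)
  dim(data) <- dims
  structure(list(data = data, spacing = g$spacing, affine = g$affine,
                 n_true = sum(data)),
            class = "wmh_mask")
}

#' Construct a probability map
#'
#' @param data 3D numeric array with values in \[0, 1\].
#' @inheritParams wmh_volume
#' @param n_subjects Number of subjects contributing (for averaged lesion
#'   frequency maps); `NA` when not applicable.
#' @return A `wmh_probmap` object.
#' @export
wmh_probmap <- function(data, spacing = c(1, 1, 1),
                        affine = default_affine(spacing), n_subjects = NA_integer_) {
  if (length(dim(data)) != 3L)
    stop("probability map data must be a 3D array", call. = FALSE)
  g <- new_grid(dim(data), spacing, affine)
  if (anyNA(data) || any(data < -1e-9) || any(data > 1 + 1e-9))
    stop("probability map values must lie in [0, 1]", call. = FALSE)
  data[data < 0] <- 0
  data[data > 1] <- 1
  structure(list(data = data, spacing = g$spacing, affine = g$affine,
                 n_subjects = as.integer(n_subjects)),
            class = "wmh_probmap")
}

#' Number of TRUE voxels in a mask
#' @param mask A `wmh_mask`.
#' @return Integer count (cached at construction, O(1)).
#' @export
n_voxels <- function(mask) {
  stopifnot(inherits(mask, "wmh_mask"))
  mask$n_true
}

#' Make a mask on the same grid as a reference image
#' @param ref A `wmh_volume`, `wmh_mask` or `wmh_probmap` providing the grid.
#' @param data 3D logical array on that grid.
#' @return A `wmh_mask`.
#' @export
mask_like <- function(ref, data) {
  wmh_mask(data, spacing = ref$spacing, affine = ref$affine)
}

voxel_volume_mm3 <- function(x) prod(x$spacing)

#' @export
print.wmh_volume <- function(x, ...) {
  cat(sprintf("<wmh_volume> %s voxels, spacing %s mm, range [%g, %g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.wmh_mask <- function(x, ...) {
  cat(sprintf("<wmh_mask> %s voxels, %d TRUE (%.3g mL)\n",
              paste(dim(x$data), collapse = "x"), x$n_true,
              x$n_true * voxel_volume_mm3(x) / 1000))
  invisible(x)
}

#' @export
print.wmh_probmap <- function(x, ...) {
  cat(sprintf("<wmh_probmap> %s voxels, range [%g, %g], n_subjects %s\n",
              paste(dim(x$data), collapse = "x"),
              min(x$data), max(x$data),
              ifelse(is.na(x$n_subjects), "NA", x$n_subjects)))
  invisible(x)
}

#' @export
dim.wmh_volume <- function(x) dim(x$data)
#' @export
dim.wmh_mask <- function(x) dim(x$data)
#' @export
dim.wmh_probmap <- function(x) dim(x$data)
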