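#' Read a NIfTI-1 volume
#'
#' Reads a `.nii` or `.nii.gz` file into a [wmh_volume]. Spacing is taken
#' from the header `pixdim`, the affine from the sform/qform (RAS+). A 4D
#' file whose trailing dimensions are singletons is squeezed to 3D.
#'
#' @param path Path to a NIfTI-1 file.
#' @return A [wmh_volume].
#' @details NaN voxels are rejected with an error naming how many voxels are
#'   affected; magnitude MRI should contain none and downstream histogram
#'   statistics would silently mishandle them.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (is.null(d)) stop(sprintf("not a volume: %s", path), call. = FALSE)
  if (length(d) > 3L) {
    extra <- d[-(1:3)]
    if (any(extra != 1L))
      stop(sprintf("%s has %d non-singleton dimensions; only 3D volumes are supported",
                   path, sum(d != 1L)), call. = FALSE)
    img_arr <- array(as.numeric(img), dim = d[1:3])
  } else if (length(d) < 3L) {
    stop(sprintf("%s is %dD; only 3D volumes are supported", path, length(d)),
         call. = FALSE)
  } else {
    img_arr <- array(as.numeric(img), dim = d)
  }
  n_bad <- sum(is.na(img_arr))
  if (n_bad > 0)
    stop(sprintf("%s contains %d NaN voxels", path, n_bad), call. = FALSE)
  spacing <- abs(RNifti::pixdim(img)[1:3])
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = c(4L, 4L))
  wmh_volume(img_arr, spacing = spacing, affine = affine,
             meta = list(path = path))
}

#' Read a binary mask
#'
#' Reads a NIfTI-1 file that encodes a binary mask in any common dialect
#' ({0,1}, {0,255}, float 0/1): after rounding, at most two distinct values
#' may occur, and voxels with raw value > 0.5 become `TRUE`.
#'
#' @param path Path to a NIfTI-1 file.
#' @param grid Optional reference image (`wmh_volume`/`wmh_mask`/
#'   `wmh_probmap`) whose grid the mask must match; a mismatch in shape or
#'   affine (tolerance 1e-4 on entries) is an error. `NULL` skips the check.
#' @return A [wmh_mask].
#' @export
read_mask <- function(path, grid = NULL) {
  vol <- read_volume(path)
  vals <- unique(round(as.vector(vol$data)))
  if (length(vals) > 2L)
    stop(sprintf("%s is not a binary mask: %d distinct rounded values (e.g. %s)",
                 path, length(vals),
                 paste(utils::head(sort(vals), 5), collapse = ", ")),
         call. = FALSE)
  m <- wmh_mask(vol$data > 0.5, spacing = vol$spacing, affine = vol$affine)
  if (!is.null(grid)) check_same_grid(m, grid, what = c("mask and reference grid"))
  m
}

#' Write a binary mask as NIfTI-1
#'
#' `TRUE` is written as 1, `FALSE` as 0, 8-bit unsigned, carrying the mask's
#' affine and spacing. `read_mask(write_mask(m, p))` reproduces `m` exactly.
#'
#' @param mask A [wmh_mask].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return The output path, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "wmh_mask"))
  arr <- array(as.integer(mask$data), dim = dim(mask$data))
  write_nifti_array(arr, mask, path, datatype = "uint8")
}

#' Write a volume as NIfTI-1 (float64)
#'
#' @param vol A [wmh_volume] or [wmh_probmap].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return The output path, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "wmh_volume") || inherits(vol, "wmh_probmap"))
  write_nifti_array(vol$data, vol, path, datatype = "double")
}

write_nifti_array <- function(arr, grid_src, path, datatype) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- grid_src$spacing
  RNifti::sform(img) <- structure(grid_src$affine, code = 2L)
  RNifti::qform(img) <- structure(grid_src$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}
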