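#' Specify a synthetic FLAIR brain phantom
#'
#' The phantom emulates a skull-stripped FLAIR acquisition of an ageing
#' brain: concentric ellipsoidal tissue compartments (a CSF shell around a
#' GM shell around a WM core), hyperintense lesion spheres inside the white
#' matter, additive Gaussian noise within the brain, and optionally a number
#' of single bright "flow artifact" voxels in grey matter mimicking blood
#' flow, which appears brighter than the lesions themselves on real scans.
#'
#' Default intensities follow FLAIR contrast with suppressed CSF: background
#' 0, CSF 30, WM 100, GM 110 (slightly brighter than WM), lesions at
#' `intensity_factor` times the WM mean. The WM core is the largest
#' compartment, so with zero noise the modal in-brain intensity equals the
#' WM mean -- the anchor both segmenters rely on.
#'
#' @param shape Grid dimensions in voxels (length 3).
#' @param spacing Voxel size in mm (length 3).
#' @param intensities Named list with compartment means `background`, `csf`,
#'   `gm`, `wm` (intensity units) and `flow_factor`, the flow-artifact
#'   intensity as a multiple of the WM mean (must be at least the largest
#'   lesion factor).
#' @param lesions List of [lesion_spec()] entries; every sphere must lie
#'   entirely inside the WM core.
#' @param noise_sd SD of additive Gaussian noise (intensity units), applied
#'   inside the brain mask only.
#' @param n_flow_voxels Number of single-voxel bright artifacts placed
#'   uniformly at random in GM, never inside a lesion.
#' @param seed Integer seed fixing all randomness.
#' @return A `phantom_spec` list.
#' @seealso [generate_phantom()]
#' @export
phantom_spec <- function(shape = c(64, 64, 64), spacing = c(1, 1, 1),
                         intensities = list(background = 0, csf = 30,
                                            gm = 110, wm = 100,
                                            flow_factor = 2.0),
                         lesions = list(), noise_sd = 5,
                         n_flow_voxels = 0, seed = 42L) {
  need <- c("background", "csf", "gm", "wm", "flow_factor")
  missing_int <- setdiff(need, names(intensities))
  if (length(missing_int) > 0)
    stop(sprintf("intensities is missing: %s", paste(missing_int, collapse = ", ")),
         call. = FALSE)
  ii <- intensities
  if (!(ii$wm > ii$background) || ii$background < 0)
    stop("FLAIR-like ordering requires wm > background >= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (n_flow_voxels < 0) stop("n_flow_voxels must be >= 0", call. = FALSE)
  max_lf <- if (length(lesions) > 0)
    max(vapply(lesions, function(l) l$intensity_factor, numeric(1))) else 1
  if (ii$flow_factor < max_lf)
    stop("flow_factor must be >= every lesion intensity_factor (flow is brighter than WMHs)",
         call. = FALSE)
  spec <- list(shape = as.integer(shape), spacing = as.numeric(spacing),
               intensities = ii, lesions = lesions,
               noise_sd = noise_sd, n_flow_voxels = as.integer(n_flow_voxels),
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  spec
}

#' Specify a spherical lesion
#'
#' @param center Voxel coordinate (1-based, length 3) of the sphere centre.
#' @param radius_mm Sphere radius in mm.
#' @param intensity_factor Lesion intensity as a multiple of the WM mean;
#'   must exceed 1 (lesions are hyperintense).
#' @return A `lesion_spec` list.
#' @export
lesion_spec <- function(center, radius_mm, intensity_factor = 1.8) {
  if (intensity_factor <= 1)
    stop("intensity_factor must exceed 1", call. = FALSE)
  if (radius_mm <= 0) stop("radius_mm must be positive", call. = FALSE)
  structure(list(center = as.numeric(center), radius_mm = radius_mm,
                 intensity_factor = intensity_factor),
            class = "lesion_spec")
}

# Ellipsoid membership: voxel centres (1-based index grid) against semi-axes
# in mm around the grid centre.
ellipsoid_mask <- function(shape, spacing, semi_axes_mm) {
  ctr <- (shape + 1) / 2
  x <- (seq_len(shape[1]) - ctr[1]) * spacing[1]
  y <- (seq_len(shape[2]) - ctr[2]) * spacing[2]
  z <- (seq_len(shape[3]) - ctr[3]) * spacing[3]
  q <- outer(outer((x / semi_axes_mm[1])^2, (y / semi_axes_mm[2])^2, `+`),
             (z / semi_axes_mm[3])^2, `+`)
  q <= 1
}

sphere_mask <- function(shape, spacing, center, radius_mm) {
  x <- (seq_len(shape[1]) - center[1]) * spacing[1]
  y <- (seq_len(shape[2]) - center[2]) * spacing[2]
  z <- (seq_len(shape[3]) - center[3]) * spacing[3]
  q <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  q <= radius_mm^2
}

#' Tissue label codes used by the phantom
#'
#' 0 background, 1 CSF, 2 GM, 3 WM, 4 lesion. Flow-artifact voxels keep the
#' GM label (they are bright blood signal inside tissue, not a compartment).
#' @export
PHANTOM_LABELS <- c(background = 0L, csf = 1L, gm = 2L, wm = 3L, lesion = 4L)

#' Generate a synthetic FLAIR phantom
#'
#' Builds the label image (concentric ellipsoids; semi-axes fixed at 0.45,
#' 0.40 and 0.34 of the field of view for the CSF, GM and WM surfaces so the
#' WM core is the largest compartment), paints compartment mean intensities,
#' overrides lesion spheres at `intensity_factor * wm`, places flow-artifact
#' voxels, and adds Gaussian noise inside the brain. Deterministic given
#' `spec$seed`; the caller's RNG state is left untouched.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `flair` ([wmh_volume]), `brain_mask`
#'   ([wmh_mask], the union of CSF/GM/WM/lesion), `lesion_truth`
#'   ([wmh_mask]), and `tissue_labels` (integer 3D array, see
#'   [PHANTOM_LABELS]).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape
  spacing <- spec$spacing
  fov <- shape * spacing
  csf_ax <- 0.45 * fov
  gm_ax <- 0.40 * fov
  wm_ax <- 0.34 * fov

  in_csf <- ellipsoid_mask(shape, spacing, csf_ax)
  in_gm <- ellipsoid_mask(shape, spacing, gm_ax)
  in_wm <- ellipsoid_mask(shape, spacing, wm_ax)

  labels <- array(PHANTOM_LABELS[["background"]], dim = shape)
  labels[in_csf] <- PHANTOM_LABELS[["csf"]]
  labels[in_gm] <- PHANTOM_LABELS[["gm"]]
  labels[in_wm] <- PHANTOM_LABELS[["wm"]]

  lesion <- array(FALSE, dim = shape)
  for (i in seq_along(spec$lesions)) {
    les <- spec$lesions[[i]]
    sph <- sphere_mask(shape, spacing, les$center, les$radius_mm)
    if (any(labels[sph] != PHANTOM_LABELS[["wm"]]))
      stop(sprintf("lesion %d (centre %s, radius %g mm) is not entirely inside the WM core",
                   i, paste(les$center, collapse = ","), les$radius_mm),
           call. = FALSE)
    lesion <- lesion | sph
  }
  labels[lesion] <- PHANTOM_LABELS[["lesion"]]

  ii <- spec$intensities
  flair <- array(ii$background, dim = shape)
  flair[labels == PHANTOM_LABELS[["csf"]]] <- ii$csf
  flair[labels == PHANTOM_LABELS[["gm"]]] <- ii$gm
  flair[labels == PHANTOM_LABELS[["wm"]]] <- ii$wm
  for (les in spec$lesions) {
    sph <- sphere_mask(shape, spacing, les$center, les$radius_mm)
    flair[sph] <- les$intensity_factor * ii$wm
  }

  brain <- labels != PHANTOM_LABELS[["background"]]

  with_preserved_rng(spec$seed, {
    gm_idx <- which(labels == PHANTOM_LABELS[["gm"]])
    if (spec$n_flow_voxels > 0) {
      if (length(gm_idx) < spec$n_flow_voxels)
        stop("not enough GM voxels for the requested flow artifacts", call. = FALSE)
      flow_idx <- sample(gm_idx, spec$n_flow_voxels)
      flair[flow_idx] <- ii$flow_factor * ii$wm
    }
    if (spec$noise_sd > 0) {
      nb <- sum(brain)
      flair[brain] <- flair[brain] + rnorm(nb, 0, spec$noise_sd)
    }
  })

  affine <- default_affine(spacing)
  list(flair = wmh_volume(flair, spacing = spacing, affine = affine,
                          meta = list(phantom_seed = spec$seed)),
       brain_mask = wmh_mask(brain, spacing = spacing, affine = affine),
       lesion_truth = wmh_mask(lesion, spacing = spacing, affine = affine),
       tissue_labels = labels)
}

# Run expr under a fixed seed, restoring the caller's RNG state afterwards.
with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Lesion volume in millilitres
#'
#' @param mask A [wmh_mask].
#' @return `n_voxels(mask) * voxel volume in mm^3 / 1000`.
#' @examples
#' m <- wmh_mask(array(TRUE, c(10, 10, 10)), spacing = c(1.016, 1.016, 2.5))
#' lesion_volume_ml(m)  # 2.58064 mL
#' @export
lesion_volume_ml <- function(mask) {
  stopifnot(inherits(mask, "wmh_mask"))
  n_voxels(mask) * voxel_volume_mm3(mask) / 1000
}
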