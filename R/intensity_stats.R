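#' In-mask intensity statistics
#'
#' Computes the histogram mode, mean and SD of the intensities inside a
#' brain mask. The mode anchors the threshold segmenter (threshold =
#' factor x mode) and the mean/SD anchor the fuzzy segmenter's seed
#' threshold (mean + k SD). Statistics are computed over in-mask voxels
#' only: the zeroed background of a skull-stripped image would otherwise
#' dominate the histogram and drag the mode to zero.
#'
#' @param image A [wmh_volume].
#' @param mask A nonempty [wmh_mask] on the image's grid.
#' @param bin_width Histogram bin width in intensity units, or `"auto"`:
#'   1 for integer-valued intensities, otherwise the Freedman-Diaconis
#'   width clamped to at least (max - min)/512. The mode is the centre of
#'   the highest-count bin; on ties the lower-intensity bin wins
#'   (deterministic, and conservative for a threshold multiplied onto it).
#' @return A `wmh_stats` list with `mode`, `mean`, `sd`, `bin_width`,
#'   `n_voxels`.
#' @export
compute_stats <- function(image, mask, bin_width = "auto") {
  stopifnot(inherits(image, "wmh_volume"), inherits(mask, "wmh_mask"))
  check_same_grid(image, mask, "image and mask")
  if (n_voxels(mask) == 0L)
    stop("empty mask: no voxels to compute statistics over", call. = FALSE)
  vals <- image$data[mask$data]
  mn <- min(vals)
  mx <- max(vals)
  is_integerish <- all(abs(vals - round(vals)) < 1e-8)
  if (identical(bin_width, "auto")) {
    if (is_integerish) {
      bw <- 1
    } else {
      iqr <- diff(quantile(vals, c(0.25, 0.75), names = FALSE, type = 7))
      bw <- 2 * iqr / length(vals)^(1 / 3)           # Freedman-Diaconis
      bw <- max(bw, (mx - mn) / 512)
      if (bw <= 0) bw <- 1                            # constant image
    }
  } else {
    bw <- as.numeric(bin_width)
    if (!is.finite(bw) || bw <= 0) stop("bin_width must be > 0", call. = FALSE)
  }
  if (mx == mn) {
    mode_val <- mn
  } else {
    # bins centred so that `mn` sits at a bin centre
    b <- floor((vals - (mn - bw / 2)) / bw)
    counts <- tabulate(b + 1L)
    top <- which.max(counts)                          # ties: lowest bin
    mode_val <- mn + (top - 1L) * bw
    mode_val <- min(max(mode_val, mn), mx)
  }
  s <- if (length(vals) > 1L) stats::sd(vals) else 0
  structure(list(mode = mode_val, mean = mean(vals), sd = s,
                 bin_width = bw, n_voxels = length(vals)),
            class = "wmh_stats")
}

#' Seed threshold: mean + k SD
#'
#' The minimum-intensity threshold used to detect lesion seeds, `k = 3` by
#' default in the fuzzy segmenter with a 2.5 variant.
#'
#' @param stats A `wmh_stats` from [compute_stats()].
#' @param k SD multiplier, > 0.
#' @return `stats$mean + k * stats$sd` in intensity units.
#' @export
seed_threshold <- function(stats, k) {
  stopifnot(inherits(stats, "wmh_stats"))
  if (k <= 0) stop("k must be > 0", call. = FALSE)
  stats$mean + k * stats$sd
}

#' @export
print.wmh_stats <- function(x, ...) {
  cat(sprintf("<wmh_stats> mode %.6g, mean %.6g, sd %.6g (bin width %.4g, n = %d)\n",
              x$mode, x$mean, x$sd, x$bin_width, x$n_voxels))
  invisible(x)
}
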