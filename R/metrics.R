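#' Overlap ratio between two segmentations
#'
#' The validation statistic `Overlap = 100 * |ROI1 ∩ ROI2| / |ROI1 ∪ ROI2|`
#' — the Jaccard index expressed as a percentage. Symmetric in its
#' arguments; 100 for identical nonempty masks, 0 for disjoint ones.
#'
#' @param roi1,roi2 [wmh_mask]s on the same grid.
#' @return A `wmh_overlap` list: `n_intersection`, `n_union`,
#'   `overlap_pct`, `n_roi1`, `n_roi2`, `both_empty`.
#' @details When both masks are empty the ratio is 0/0; by convention the
#'   overlap is reported as 100 (two raters agreeing there are no lesions
#'   is perfect agreement), flagged via `both_empty = TRUE` and a warning.
#' @export
overlap <- function(roi1, roi2) {
  stopifnot(inherits(roi1, "wmh_mask"), inherits(roi2, "wmh_mask"))
  check_same_grid(roi1, roi2, "ROI masks")
  ni <- sum(roi1$data & roi2$data)
  nu <- sum(roi1$data | roi2$data)
  both_empty <- nu == 0L
  pct <- if (both_empty) {
    warning("both masks are empty; reporting overlap 100 by convention",
            call. = FALSE)
    100
  } else {
    100 * ni / nu
  }
  structure(list(n_intersection = ni, n_union = nu, overlap_pct = pct,
                 n_roi1 = n_voxels(roi1), n_roi2 = n_voxels(roi2),
                 both_empty = both_empty),
            class = "wmh_overlap")
}

#' @export
print.wmh_overlap <- function(x, ...) {
  cat(sprintf("<wmh_overlap> %.2f%% (|∩| = %d, |∪| = %d; |ROI1| = %d, |ROI2| = %d)\n",
              x$overlap_pct, x$n_intersection, x$n_union, x$n_roi1, x$n_roi2))
  invisible(x)
}

#' Summarise per-subject overlaps by method
#'
#' Collapses per-subject overlap percentages into the per-method mean,
#' sample SD, minimum and maximum used to compare segmentation methods.
#'
#' @param rows Data frame with at least columns `method` and `overlap_pct`
#'   (one row per subject and method); other columns (e.g. `subject`,
#'   volumes) are carried in the returned `rows`.
#' @return A `wmh_comparison` list: `rows` (the input) and `summary`, a
#'   data frame with `method`, `n`, `mean`, `sd`, `min`, `max`,
#'   `sd_defined` (FALSE where n = 1, in which case `sd` is reported as 0).
#' @export
summarize_overlaps <- function(rows) {
  rows <- as.data.frame(rows)
  if (nrow(rows) == 0L) stop("need at least one row", call. = FALSE)
  if (!all(c("method", "overlap_pct") %in% names(rows)))
    stop("rows must have columns 'method' and 'overlap_pct'", call. = FALSE)
  summ <- do.call(rbind, lapply(split(rows, rows$method), function(g) {
    n <- nrow(g)
    data.frame(method = g$method[1], n = n,
               mean = mean(g$overlap_pct),
               sd = if (n > 1) stats::sd(g$overlap_pct) else 0,
               min = min(g$overlap_pct), max = max(g$overlap_pct),
               sd_defined = n > 1)
  }))
  rownames(summ) <- NULL
  structure(list(rows = rows, summary = summ), class = "wmh_comparison")
}

#' @export
print.wmh_comparison <- function(x, ...) {
  cat("<wmh_comparison>\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %s: %.1f (%.1f) %.0f-%.0f, n = %d\n", s$method[i],
                s$mean[i], s$sd[i], s$min[i], s$max[i], s$n[i]))
  invisible(x)
}

#' Rater agreement between paired manual segmentations
#'
#' Computes the overlap for each pair of masks (e.g. a rater's repeat
#' segmentations, or two raters' segmentations of the same scans) and
#' summarises them — the within-/between-rater reliability check for a
#' manual reference standard.
#'
#' @param manual_a,manual_b Paired lists of [wmh_mask]s on matching grids.
#' @param label Method label for the summary (e.g. "within_rater").
#' @return A `wmh_comparison` (see [summarize_overlaps()]).
#' @export
rater_agreement <- function(manual_a, manual_b, label = "rater_agreement") {
  if (length(manual_a) == 0L) stop("empty mask lists", call. = FALSE)
  if (length(manual_a) != length(manual_b))
    stop(sprintf("paired lists differ in length: %d vs %d",
                 length(manual_a), length(manual_b)), call. = FALSE)
  rows <- do.call(rbind, lapply(seq_along(manual_a), function(i) {
    ov <- overlap(manual_a[[i]], manual_b[[i]])
    data.frame(subject = i, method = label, overlap_pct = ov$overlap_pct,
               volume_a_ml = lesion_volume_ml(manual_a[[i]]),
               volume_b_ml = lesion_volume_ml(manual_b[[i]]))
  }))
  summarize_overlaps(rows)
}
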