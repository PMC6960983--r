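#' Reconstruct edge heights for one grain pair
#'
#' Every matched edge-point pair is triangulated by
#' [space_intersection()]; the grain's edge height is the mean of the
#' reconstructed Z values. Optionally, pairs whose reprojection residual
#' exceeds `residual_cap` are dropped before averaging (off by default,
#' reproducing the plain mean). Negative heights are kept so the noise
#' distribution stays unbiased.
#'
#' @param pairs A list with `left_xy` and `right_xy` (Nx2 photo
#'   coordinates), as from [correspondence_to_image_points()].
#' @param left_cam,right_cam Oriented [camera_model()] objects.
#' @param residual_cap Optional residual threshold in pixels.
#' @return An object of class `grain_height_result`: `point_heights`
#'   (mm), `edge_height` (their mean, mm), `mean_residual` (pixels),
#'   `n_used` and `n_total`.
#' @export
reconstruct_edge_heights <- function(pairs, left_cam, right_cam,
                                     residual_cap = NULL) {
  n <- nrow(pairs$left_xy)
  if (is.null(n) || n < 1) stop("no edge-point pairs to intersect")
  sol <- space_intersection(pairs$left_xy, pairs$right_xy,
                            left_cam, right_cam)
  z <- sol$points[, 3]
  res <- sol$residual
  keep <- rep(TRUE, n)
  if (!is.null(residual_cap)) keep <- res <= residual_cap
  if (!any(keep)) stop("all edge-point pairs exceeded the residual cap")
  structure(list(point_heights = z[keep],
                 edge_height = mean(z[keep]),
                 mean_residual = mean(res[keep]),
                 n_used = sum(keep),
                 n_total = n),
            class = "grain_height_result")
}

#' Aggregate per-grain edge heights into a thickness estimate
#'
#' Thickness is twice the mean edge height over grains: each grain's rim
#' sits near half the thickness above the board, offset up or down by the
#' grain's front/back asymmetry, and fair random flips cancel the offset
#' in the population average. The per-grain mean is taken first so every
#' grain carries equal weight regardless of boundary length.
#'
#' @param results List of `grain_height_result` objects.
#' @param grain_pairs Optional data.frame from [match_grains()] carried
#'   into the report.
#' @return An object of class `thickness_report`: `n_grains`,
#'   `edge_heights` (mm), `thickness` (mm), `per_grain` (data.frame) and
#'   the mean reprojection residual.
#' @export
aggregate_thickness <- function(results, grain_pairs = NULL) {
  if (length(results) < 1) stop("no grains to aggregate")
  eh <- vapply(results, `[[`, numeric(1), "edge_height")
  per <- data.frame(
    grain = seq_along(results),
    n_points_used = vapply(results, `[[`, numeric(1), "n_used"),
    edge_height_mm = eh,
    residual_px = vapply(results, `[[`, numeric(1), "mean_residual")
  )
  if (!is.null(grain_pairs) && nrow(grain_pairs) == length(results)) {
    per$left_id <- grain_pairs$left_id
    per$right_id <- grain_pairs$right_id
  }
  structure(list(n_grains = length(results),
                 edge_heights = eh,
                 thickness = 2 * mean(eh),
                 mean_residual = mean(per$residual_px),
                 per_grain = per),
            class = "thickness_report")
}

#' @export
print.thickness_report <- function(x, ...) {
  cat("Grain thickness report\n")
  cat(sprintf("  grains measured : %d\n", x$n_grains))
  cat(sprintf("  mean edge height: %.4f mm\n", mean(x$edge_heights)))
  cat(sprintf("  thickness       : %.4f mm  (2 x mean edge height)\n",
              x$thickness))
  cat(sprintf("  mean reprojection residual: %.3f px\n", x$mean_residual))
  invisible(x)
}

#' @export
summary.thickness_report <- function(object, ...) {
  print(object)
  cat("\nPer-grain edge heights (mm):\n")
  print(object$per_grain, digits = 4)
  invisible(object)
}

#' Write a thickness report as CSV
#'
#' One row per grain plus a `summary` row holding the grain count and the
#' thickness estimate.
#'
#' @param report A `thickness_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_thickness_csv <- function(report, path) {
  per <- report$per_grain
  per$kind <- "grain"
  summary_row <- per[1, ]
  summary_row[] <- NA
  summary_row$kind <- "summary"
  summary_row$grain <- report$n_grains
  summary_row$edge_height_mm <- mean(report$edge_heights)
  summary_row$residual_px <- report$mean_residual
  out <- rbind(per, summary_row)
  out$thickness_mm <- c(rep(NA_real_, nrow(per)), report$thickness)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Measure grain thickness from an oriented stereo pair
#'
#' Runs the full measurement chain on two images whose cameras are
#' already oriented: segmentation (with the calibration circles masked
#' out), grain matching, edge-point matching by circular correlation of
#' the polar-distance profiles, space intersection of every matched edge
#' point, and aggregation into the thickness estimate.
#'
#' @param left_image,right_image Image matrices/arrays in `[0, 1]`, or
#'   file paths.
#' @param left_cam,right_cam Oriented [camera_model()] objects.
#' @param board Optional [board_layout()]; when given, the calibration
#'   circles are detected and excluded from the grain candidates.
#' @param median_kernel,min_area,max_area Segmentation controls, see
#'   [segment_grains()].
#' @param residual_cap Optional per-point reprojection residual cap in
#'   pixels (default `NULL`: plain mean over all points).
#' @param min_correlation Grain pairs whose best edge correlation falls
#'   below this value are discarded (default 0.5).
#' @param shift_tie_tol Correlation margin within which alternative
#'   circular shifts count as tied with the maximum; tied shifts are
#'   disambiguated by the reprojection residual of the triangulated edge
#'   points. Centrally symmetric silhouettes make the correlation nearly
#'   180-degree periodic, so this tie-break is what keeps such grains
#'   from matching diametrically opposite points.
#' @param exclude_masks Optional list with `left` and `right` 0/1
#'   matrices of pixels to exclude from grain candidates (e.g. the
#'   `circle_masks` returned by [orient_stereo()]); when `NULL` and a
#'   `board` is given the circles are detected here.
#' @return A `thickness_report` with attribute `matches` (the grain
#'   pairing table) and `correspondences` (per-pair matched edge points).
#' @export
measure_thickness <- function(left_image, right_image, left_cam, right_cam,
                              board = NULL, median_kernel = 3,
                              min_area = NULL, max_area = NULL,
                              residual_cap = NULL, min_correlation = 0.5,
                              shift_tie_tol = 0.01, exclude_masks = NULL) {
  if (is.character(left_image)) left_image <- read_raster(left_image)
  if (is.character(right_image)) right_image <- read_raster(right_image)
  seg <- function(img, cam, excl) {
    if (is.null(excl) && !is.null(board)) {
      det <- detect_circle_centers(img, board,
                                   px_per_mm = cam$io$f / cam$eo$Zs)
      excl <- attr(det, "mask")
    }
    segment_grains(img, median_kernel = median_kernel, min_area = min_area,
                   max_area = max_area, exclude = excl)
  }
  left_regions <- seg(left_image, left_cam, exclude_masks$left)
  right_regions <- seg(right_image, right_cam, exclude_masks$right)
  matches <- match_grains(left_regions, right_regions, left_cam, right_cam)
  if (nrow(matches) == 0) stop("no corresponding grains found")
  left_by_label <- stats::setNames(left_regions,
                                   vapply(left_regions, `[[`, 0, "label"))
  right_by_label <- stats::setNames(right_regions,
                                    vapply(right_regions, `[[`, 0, "label"))
  results <- list()
  correspondences <- list()
  kept <- logical(nrow(matches))
  for (m in seq_len(nrow(matches))) {
    pl <- region_profile(left_by_label[[as.character(matches$left_id[m])]],
                         left_cam)
    pr <- region_profile(right_by_label[[as.character(matches$right_id[m])]],
                         right_cam)
    corr <- match_edge_points(pl, pr)
    if (isTRUE(corr$degenerate) ||
        (!is.na(corr$correlation) && corr$correlation < min_correlation)) {
      next
    }
    ## a centrally symmetric silhouette makes the correlation nearly
    ## 180-degree periodic; resolve near-tied shifts by the reprojection
    ## residual of the triangulated edge points
    cand <- which(corr$correlations >= corr$correlation - shift_tie_tol) - 1L
    best <- NULL
    for (k in cand) {
      ck <- corr
      ck$shift <- k
      ck$correlation <- corr$correlations[k + 1]
      cpk <- correspondence_to_image_points(ck, pl, pr)
      hk <- reconstruct_edge_heights(cpk, left_cam, right_cam,
                                     residual_cap = residual_cap)
      if (is.null(best) || hk$mean_residual < best$h$mean_residual) {
        best <- list(h = hk, cp = cpk)
      }
    }
    results[[length(results) + 1]] <- best$h
    cp <- best$cp
    correspondences[[length(correspondences) + 1]] <- cp
    kept[m] <- TRUE
  }
  if (length(results) == 0) stop("no grain pair survived edge matching")
  report <- aggregate_thickness(results, matches[kept, , drop = FALSE])
  attr(report, "matches") <- matches[kept, , drop = FALSE]
  attr(report, "correspondences") <- correspondences
  report
}
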