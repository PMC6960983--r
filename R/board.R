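#' Calibration-board layout
#'
#' A regular grid of circles of known radius and spacing printed on the
#' background board; the detected circle centres supply the control
#' points for space resection.
#'
#' @param n_rows,n_cols Grid dimensions (each `>= 2`).
#' @param spacing_x,spacing_y Centre-to-centre distances (mm); must
#'   exceed the circle diameter.
#' @param radius Circle radius (mm).
#' @param polarity `"bright"` circles on a dark board (default) or
#'   `"dark"`.
#' @return An object of class `board_layout`.
#' @export
board_layout <- function(n_rows, n_cols, spacing_x, spacing_y = spacing_x,
                         radius, polarity = c("bright", "dark")) {
  polarity <- match.arg(polarity)
  stopifnot(n_rows >= 2, n_cols >= 2, radius > 0)
  if (spacing_x <= 2 * radius || spacing_y <= 2 * radius) {
    stop("circle spacing must exceed the circle diameter")
  }
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 spacing_x = spacing_x, spacing_y = spacing_y,
                 radius = radius, polarity = polarity),
            class = "board_layout")
}

#' Object-space coordinates of the board circles
#'
#' The circle at grid cell `(i, j)` (0-based) has coordinates
#' `(j * spacing_x, i * spacing_y, 0)`: the origin is the corner circle,
#' X runs along the long side and Y along the short side, and the board
#' plane is the datum `Z = 0`.
#'
#' @param layout A [board_layout()].
#' @return Nx3 matrix of object coordinates with attribute `grid_index`
#'   (Nx2 matrix of 0-based `(row, col)` cell indices).
#' @export
board_object_coordinates <- function(layout) {
  ij <- expand.grid(i = 0:(layout$n_rows - 1), j = 0:(layout$n_cols - 1))
  out <- cbind(X = ij$j * layout$spacing_x,
               Y = ij$i * layout$spacing_y,
               Z = 0)
  attr(out, "grid_index") <- cbind(row = ij$i, col = ij$j)
  out
}

#' Detect circle centres on the board
#'
#' Otsu thresholding, 8-connected components, an area gate of
#' `[0.5, 2] x` the expected projected circle area, and an
#' intensity-weighted (sub-pixel) centroid per surviving component.
#'
#' @param image Image matrix/array in `[0, 1]`.
#' @param layout A [board_layout()].
#' @param px_per_mm Approximate image scale at the board plane, used for
#'   the expected circle area. `NULL` estimates it from the median area
#'   of the largest `n_rows * n_cols` components.
#' @return Nx2 matrix of sub-pixel centres as `(row, col)`, with
#'   attributes `mask` (0/1 matrix of the accepted circle components,
#'   usable as a segmentation exclusion mask) and `areas`.
#' @export
detect_circle_centers <- function(image, layout, px_per_mm = NULL) {
  g <- to_gray(image)
  pol <- if (layout$polarity == "bright") "bright" else "dark"
  bin <- otsu_binarize(g, polarity = pol)
  lab <- label_components(bin$binary)
  nlab <- max(lab)
  if (nlab == 0) stop("insufficient control: no circles detected")
  areas <- tabulate(lab[lab > 0], nbins = nlab)
  if (is.null(px_per_mm)) {
    k <- min(layout$n_rows * layout$n_cols, length(areas))
    expected <- stats::median(sort(areas, decreasing = TRUE)[seq_len(k)])
  } else {
    expected <- pi * (layout$radius * px_per_mm)^2
  }
  keep <- which(areas >= 0.5 * expected & areas <= 2.0 * expected)
  if (length(keep) < 4) {
    stop("insufficient control: fewer than 4 circle candidates detected")
  }
  nr <- nrow(lab)
  bg <- stats::median(g[lab == 0])
  centers <- t(vapply(keep, function(k) {
    idx <- which(lab == k)
    rows <- ((idx - 1) %% nr) + 1
    cols <- ((idx - 1) %/% nr) + 1
    w <- pmax(g[idx] - bg, 0)
    if (sum(w) == 0) w <- rep(1, length(idx))
    c(sum(rows * w), sum(cols * w)) / sum(w)
  }, numeric(2)))
  colnames(centers) <- c("row", "col")
  mask <- matrix(0L, nr, ncol(lab))
  mask[lab %in% keep] <- 1L
  attr(centers, "mask") <- mask
  attr(centers, "areas") <- areas[keep]
  centers
}

#' Order detected circle centres into control points
#'
#' Assigns each detection a unique grid cell by one-dimensional
#' clustering: detections are grouped into rows on their raster row
#' coordinate and into columns on their raster column coordinate, then
#' paired with [board_object_coordinates()]. Grid rows are numbered in
#' the +Y object direction, which for a near-nadir camera with small
#' kappa runs from the bottom of the displayed image upward. Requires the
#' in-plane rotation of the board in the image to be below ~45 degrees.
#'
#' @param detected Nx2 matrix of `(row, col)` centres from
#'   [detect_circle_centers()] (any order).
#' @param layout A [board_layout()].
#' @param width,height Image size in pixels (for the photo-frame
#'   conversion done later by the caller; recorded for reference).
#' @return A list of class `control_points` with `object` (Nx3 mm),
#'   `image_rc` (Nx2 raster), `grid_index` (Nx2, 0-based) and
#'   `missing` (cells with no detection).
#' @export
order_control_points <- function(detected, layout, width = NA, height = NA) {
  det <- as_xy_matrix(detected)
  if (nrow(det) < 4) {
    stop("insufficient control: need at least 4 detected circle centres")
  }
  row_idx <- cluster_1d(det[, 1], layout$n_rows)
  col_idx <- cluster_1d(det[, 2], layout$n_cols)
  ## grid row 0 lies at Y = 0; +Y maps to photo +y = decreasing raster row
  row_idx <- (max(row_idx) - row_idx)
  cell <- paste(row_idx, col_idx)
  if (anyDuplicated(cell)) {
    stop("ambiguous ordering: two detections map to the same grid cell")
  }
  obj <- cbind(X = col_idx * layout$spacing_x,
               Y = row_idx * layout$spacing_y,
               Z = 0)
  all_cells <- expand.grid(row = 0:(layout$n_rows - 1),
                           col = 0:(layout$n_cols - 1))
  have <- paste(row_idx, col_idx)
  missing <- all_cells[!paste(all_cells$row, all_cells$col) %in% have, ,
                       drop = FALSE]
  structure(list(object = obj,
                 image_rc = det,
                 grid_index = cbind(row = row_idx, col = col_idx),
                 missing = missing,
                 width = width, height = height),
            class = "control_points")
}

## 1-D clustering of coordinates into at most k grid lines: sort, split at
## gaps larger than half the typical line pitch.
cluster_1d <- function(v, k) {
  ord <- order(v)
  s <- v[ord]
  if (length(s) == 1) return(0L)
  pitch <- (max(s) - min(s)) / max(k - 1, 1)
  gaps <- diff(s)
  breaks <- which(gaps > pitch / 2)
  grp <- integer(length(s))
  g <- 0L
  last_break <- 0L
  for (i in seq_along(s)) {
    if ((i - 1L) %in% breaks) g <- g + 1L
    grp[i] <- g
  }
  if (max(grp) + 1L > k) {
    stop("ordering failed: detections form more than ", k, " grid lines")
  }
  out <- integer(length(v))
  out[ord] <- grp
  out
}

#' Orient both cameras of a stereo rig from the board
#'
#' Detects and orders the circle-grid control points in each image,
#' removes lens distortion from the image observations and runs
#' [space_resection()] per camera.
#'
#' @param left_image,right_image Image matrices/arrays or file paths.
#' @param board A [board_layout()].
#' @param left_cam,right_cam [camera_model()] objects carrying interior
#'   orientation and distortion (exterior orientation is replaced).
#' @param px_per_mm Approximate board-plane scale for circle detection
#'   (`NULL` = estimate from component areas).
#' @return A list with the two oriented cameras (`left`, `right`), the
#'   per-camera resection RMS (`rms_left`, `rms_right`, pixels), and
#'   `circle_masks` (the detected circle components per image, reusable
#'   as segmentation exclusion masks).
#' @export
orient_stereo <- function(left_image, right_image, board,
                          left_cam, right_cam, px_per_mm = NULL) {
  one <- function(img, cam) {
    if (is.character(img)) img <- read_raster(img)
    det <- detect_circle_centers(img, board, px_per_mm = px_per_mm)
    ctrl <- order_control_points(det, board, cam$width, cam$height)
    xy <- raster_to_photo(ctrl$image_rc, cam$width, cam$height)
    xy <- undistort_points(xy, cam$io, cam$distortion)
    fit <- space_resection(list(object = ctrl$object, image = xy), cam$io)
    cam$eo <- fit$eo
    list(cam = cam, rms = fit$rms, mask = attr(det, "mask"))
  }
  l <- one(left_image, left_cam)
  r <- one(right_image, right_cam)
  list(left = l$cam, right = r$cam, rms_left = l$rms, rms_right = r$rms,
       circle_masks = list(left = l$mask, right = r$mask))
}

#' Read / write a board layout in YAML
#'
#' Keys: `n_rows, n_cols, spacing_x_mm, spacing_y_mm, radius_mm,
#' polarity`.
#'
#' @param path File path.
#' @return A [board_layout()].
#' @export
read_board_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  board_layout(n_rows = cfg$n_rows, n_cols = cfg$n_cols,
               spacing_x = cfg$spacing_x_mm,
               spacing_y = cfg$spacing_y_mm %||% cfg$spacing_x_mm,
               radius = cfg$radius_mm,
               polarity = cfg$polarity %||% "bright")
}

#' @rdname read_board_yaml
#' @param layout A [board_layout()].
#' @export
write_board_yaml <- function(layout, path) {
  yaml::write_yaml(list(n_rows = layout$n_rows, n_cols = layout$n_cols,
                        spacing_x_mm = layout$spacing_x,
                        spacing_y_mm = layout$spacing_y,
                        radius_mm = layout$radius,
                        polarity = layout$polarity),
                   path, precision = 15)
  invisible(path)
}
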