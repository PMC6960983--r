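#' Polar distances from the centroid to the boundary
#'
#' For every boundary point, the distance to the region centroid and its
#' polar angle. The polar axis points along +x (rightward in the photo
#' frame) and angles grow counter-clockwise. The sequence starts at the
#' boundary point nearest the polar-axis crossing and follows the
#' counter-clockwise boundary order.
#'
#' @param boundary Nx2 matrix of boundary points in photo coordinates
#'   (columns x, y), counter-clockwise.
#' @param centroid Length-2 vector `(x, y)`; must lie inside the boundary
#'   polygon.
#' @return A data.frame with columns `angle` (degrees, `[0, 360)`) and
#'   `d` (pixels), in boundary order starting near angle 0.
#' @export
polar_distances <- function(boundary, centroid) {
  b <- as_xy_matrix(boundary)
  dx <- b[, 1] - centroid[1]
  dy <- b[, 2] - centroid[2]
  if (!point_in_polygon(centroid[1], centroid[2], b)) {
    stop("centroid lies outside the boundary polygon")
  }
  ang <- (atan2(dy, dx) * 180 / pi) %% 360
  d <- sqrt(dx * dx + dy * dy)
  ## start at the crossing of the polar axis: angle closest to 0 (circular)
  start <- which.min(pmin(ang, 360 - ang))
  n <- length(ang)
  ord <- c(start:n, seq_len(start - 1))
  data.frame(angle = ang[ord], d = d[ord])
}

## even-odd ray-casting point-in-polygon test
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1))
  xi <- poly[, 1]; yi <- poly[, 2]
  xj <- poly[j, 1]; yj <- poly[j, 2]
  cross <- ((yi > py) != (yj > py)) &
    (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
  sum(cross) %% 2 == 1
}

#' Resample a polar profile to 1-degree steps
#'
#' Linear interpolation of the raw centroid-to-boundary distances at
#' integer degrees 0..359 with circular wrap-around, producing the
#' 360-element feature substrate used for edge-point matching. Where the
#' boundary crosses an angle more than once (slightly non-star-shaped
#' outlines from rasterisation), the outermost crossing is kept.
#'
#' @param raw Data.frame with columns `angle` (degrees) and `d` (pixels),
#'   as from [polar_distances()].
#' @param max_gap Largest tolerated angular gap between consecutive raw
#'   samples (degrees); a wider gap signals a pathological boundary.
#' @return An object of class `edge_profile`: list with `h` (numeric 360,
#'   `h[i+1]` = distance at angle `i` degrees) and the raw sample count
#'   `n_raw`.
#' @export
resample_profile <- function(raw, max_gap = 20) {
  stopifnot(all(c("angle", "d") %in% names(raw)))
  a <- raw$angle %% 360
  d <- raw$d
  ord <- order(a, -d)
  a <- a[ord]
  d <- d[ord]
  ## outermost crossing per (near-)duplicate angle
  keep <- !duplicated(round(a, 9))
  a <- a[keep]
  d <- d[keep]
  if (length(a) < 4) stop("too few distinct angles to resample")
  gaps <- diff(c(a, a[1] + 360))
  if (max(gaps) > max_gap) {
    stop("angular gap of ", round(max(gaps), 1),
         " degrees exceeds ", max_gap, " (pathological boundary)")
  }
  ## circular padding for interpolation at 0..359
  a_pad <- c(a[length(a)] - 360, a, a[1] + 360)
  d_pad <- c(d[length(d)], d, d[1])
  h <- stats::approx(a_pad, d_pad, xout = 0:359, method = "linear")$y
  structure(list(h = h, n_raw = length(a)), class = "edge_profile")
}

#' Build the edge profile of a segmented region
#'
#' Converts the region's traced boundary and centroid to photo
#' coordinates, removes lens distortion, and resamples the polar-distance
#' profile at 1-degree steps.
#'
#' @param region A `grain_region` from [segment_grains()].
#' @param cam The [camera_model()] the region was observed with.
#' @return An `edge_profile` with an added `centroid` element (photo
#'   coordinates, undistorted).
#' @export
region_profile <- function(region, cam) {
  bxy <- raster_to_photo(region$boundary, cam$width, cam$height)
  cxy <- raster_to_photo(rbind(region$centroid), cam$width, cam$height)
  bxy <- undistort_points(bxy, cam$io, cam$distortion)
  cxy <- undistort_points(cxy, cam$io, cam$distortion)
  prof <- resample_profile(polar_distances(bxy, cxy[1, ]))
  prof$centroid <- cxy[1, ]
  prof
}

#' Match corresponding grains across the stereo pair
#'
#' For each grain in the right image, its centroid ray is intersected with
#' the board plane `Z = 0` to approximate the grain position, which is
#' then projected into the left image; the grain is paired with the
#' nearest left centroid. Pairings are made one-to-one greedily in order
#' of increasing projected distance.
#'
#' @param left_regions,right_regions Region lists from [segment_grains()].
#' @param left_cam,right_cam Oriented [camera_model()] objects.
#' @param max_distance Pairing gate in pixels; defaults to half the
#'   smallest inter-centroid distance in the left image (infinite when
#'   fewer than two left grains).
#' @return A data.frame with columns `left_id`, `right_id` and
#'   `projected_distance` (pixels); unmatched region labels are attached
#'   as attributes `unmatched_left` and `unmatched_right`.
#' @export
match_grains <- function(left_regions, right_regions, left_cam, right_cam,
                         max_distance = NULL) {
  empty <- data.frame(left_id = integer(0), right_id = integer(0),
                      projected_distance = numeric(0))
  if (length(left_regions) == 0 || length(right_regions) == 0) {
    attr(empty, "unmatched_left") <- vapply(left_regions, `[[`, 0, "label")
    attr(empty, "unmatched_right") <- vapply(right_regions, `[[`, 0, "label")
    return(empty)
  }
  cent_photo <- function(regions, cam) {
    rc <- do.call(rbind, lapply(regions, `[[`, "centroid"))
    xy <- raster_to_photo(rc, cam$width, cam$height)
    undistort_points(xy, cam$io, cam$distortion)
  }
  lc <- cent_photo(left_regions, left_cam)
  rc <- cent_photo(right_regions, right_cam)
  ## approximate object position from the right image via the board plane
  pos <- backproject_to_plane(rc, right_cam$eo, right_cam$io, z = 0)
  proj <- project_points(pos, left_cam$eo, left_cam$io)
  if (is.null(max_distance)) {
    max_distance <- if (nrow(lc) >= 2) min(stats::dist(lc)) / 2 else Inf
  }
  dmat <- sqrt(outer(proj[, 1], lc[, 1], `-`)^2 +
                 outer(proj[, 2], lc[, 2], `-`)^2)  # right x left
  cand <- which(dmat <= max_distance, arr.ind = TRUE)
  matches <- empty
  if (nrow(cand) > 0) {
    cand <- cand[order(dmat[cand]), , drop = FALSE]
    used_r <- logical(nrow(rc))
    used_l <- logical(nrow(lc))
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (used_r[i] || used_l[j]) next
      used_r[i] <- TRUE
      used_l[j] <- TRUE
      matches <- rbind(matches, data.frame(
        left_id = left_regions[[j]]$label,
        right_id = right_regions[[i]]$label,
        projected_distance = dmat[i, j]))
    }
  } else {
    used_r <- logical(nrow(rc))
    used_l <- logical(nrow(lc))
  }
  attr(matches, "unmatched_left") <-
    vapply(left_regions[!used_l], `[[`, 0, "label")
  attr(matches, "unmatched_right") <-
    vapply(right_regions[!used_r], `[[`, 0, "label")
  matches
}

#' Match corresponding edge points by circular correlation
#'
#' The feature vector of edge point `i` is the profile rotated to start at
#' angle `i`; matching the two profiles therefore reduces to finding the
#' circular shift `k` maximising the correlation coefficient (Pearson)
#' between the left profile and the right profile rotated by `k`. Left
#' point at angle `i` then corresponds to the right point at angle
#' `(i + k) mod 360`.
#'
#' @param left,right `edge_profile` objects.
#' @return An object of class `edge_correspondence`: list with `shift`
#'   (integer degrees in 0..359), `correlation` (the maximum), and
#'   `correlations` (all 360). A zero-variance profile is flagged with
#'   `degenerate = TRUE` and `shift = 0`.
#' @export
match_edge_points <- function(left, right) {
  hl <- left$h
  hr <- right$h
  stopifnot(length(hl) == 360, length(hr) == 360)
  if (stats::sd(hl) == 0 || stats::sd(hr) == 0) {
    return(structure(list(shift = 0L, correlation = NA_real_,
                          correlations = rep(NA_real_, 360),
                          degenerate = TRUE),
                     class = "edge_correspondence"))
  }
  idx <- 0:359
  cors <- vapply(idx, function(k) {
    stats::cor(hl, hr[((idx + k) %% 360) + 1])
  }, numeric(1))
  k <- which.max(cors) - 1L
  structure(list(shift = k, correlation = cors[k + 1], correlations = cors,
                 degenerate = FALSE),
            class = "edge_correspondence")
}

#' Matched edge points in photo coordinates
#'
#' Converts the matched angle pairs back to sub-pixel photo coordinates:
#' point `i` on the left edge is `centroid + h[i] * (cos i, sin i)` and
#' corresponds to angle `(i + shift) mod 360` on the right edge.
#'
#' @param corr An `edge_correspondence` from [match_edge_points()].
#' @param left,right The matched `edge_profile` objects (must carry a
#'   `centroid`).
#' @return A list with `left_xy` and `right_xy`, each a 360x2 matrix of
#'   photo coordinates, plus `angle_left` and `angle_right` (degrees).
#' @export
correspondence_to_image_points <- function(corr, left, right) {
  i <- 0:359
  j <- (i + corr$shift) %% 360
  th_l <- i * pi / 180
  th_r <- j * pi / 180
  list(
    left_xy = cbind(x = left$centroid[1] + left$h[i + 1] * cos(th_l),
                    y = left$centroid[2] + left$h[i + 1] * sin(th_l)),
    right_xy = cbind(x = right$centroid[1] + right$h[j + 1] * cos(th_r),
                     y = right$centroid[2] + right$h[j + 1] * sin(th_r)),
    angle_left = i,
    angle_right = j
  )
}

#' Export edge correspondences as CSV
#'
#' One row per matched edge point:
#' `left_id, right_id, angle_left, angle_right, x_l, y_l, x_r, y_r`.
#'
#' @param matches Data.frame from [match_grains()].
#' @param correspondences List (per match) of outputs of
#'   [correspondence_to_image_points()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_correspondence_csv <- function(matches, correspondences, path) {
  rows <- lapply(seq_len(nrow(matches)), function(m) {
    cp <- correspondences[[m]]
    data.frame(left_id = matches$left_id[m], right_id = matches$right_id[m],
               angle_left = cp$angle_left, angle_right = cp$angle_right,
               x_l = cp$left_xy[, 1], y_l = cp$left_xy[, 2],
               x_r = cp$right_xy[, 1], y_r = cp$right_xy[, 2])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
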