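#' Default calibration board for synthetic scenes
#'
#' A 3x4 circle grid with 30 mm spacing and 4 mm circle radius —
#' comfortably resolvable at the default desk-scale imaging geometry.
#'
#' @return A [board_layout()].
#' @export
default_board <- function() {
  board_layout(n_rows = 3, n_cols = 4, spacing_x = 30, spacing_y = 30,
               radius = 4, polarity = "bright")
}

#' Default stereo rig for synthetic scenes
#'
#' Two cameras 350 mm above the board with an 80 mm baseline
#' (base-height ratio ~0.23) and a principal distance giving ~0.1 mm/px
#' on the board plane. By default both cameras point straight down
#' (parallel nadir axes): a nadir view maps the board plane to the image
#' by a pure similarity, so polar angles about a grain's centroid are
#' identical in the two views and the shape correspondence is exact. A
#' convergent rig (each axis through the board centre) is also supported;
#' its mild projective anisotropy perturbs the angle correspondence by a
#' fraction of a degree, which shows up as a small per-grain height
#' systematic.
#'
#' @param height Camera height above the board (mm).
#' @param baseline Distance between the two projection centres (mm).
#' @param pixel_scale Ground sample distance at the board plane (mm/px).
#' @param convergent Tilt each camera so its optical axis passes through
#'   the board centre (default `FALSE`: parallel nadir axes).
#' @return A list with fields `height`, `baseline`, `pixel_scale`,
#'   `convergent` and `f` (pixels).
#' @export
default_rig <- function(height = 350, baseline = 80, pixel_scale = 0.1,
                        convergent = FALSE) {
  stopifnot(height > 0, baseline >= 0, pixel_scale > 0)
  list(height = height, baseline = baseline, pixel_scale = pixel_scale,
       convergent = convergent, f = height / pixel_scale)
}

#' Sample a ground-truthed synthetic scene
#'
#' Places `n_grains` elliptical grains on the calibration board with
#' rejection sampling: silhouette bounding circles must keep
#' `min_spacing` clearance from each other and from the board circles.
#' Which side faces up is a fair Bernoulli draw per grain, so the rim
#' plane sits at `H/2 + delta` or `H/2 - delta` above the board. All
#' draws are reproducible from `seed`.
#'
#' @param n_grains Number of grains.
#' @param H Grain thickness (mm).
#' @param delta Rim-plane offset from mid-height (mm); `0 <= delta < H/2`.
#' @param a_range,b_range Ranges (mm) for the silhouette semi-major and
#'   semi-minor axes, drawn uniformly per grain.
#' @param board A [board_layout()].
#' @param rig A [default_rig()]-style list.
#' @param noise_sd Additive Gaussian image noise, in 0-255 gray levels.
#' @param blur_sigma Gaussian blur sigma applied to the rendered images
#'   (pixels).
#' @param min_spacing Minimum silhouette clearance (mm).
#' @param seed Integer RNG seed (`NULL` leaves the RNG state alone).
#' @param max_tries Rejection-sampling cap per grain.
#' @return An object of class `scene_truth` with `grains` (data.frame:
#'   `a, b, H, delta, X, Y, yaw, flip, rim_z`), `board`, `left_cam`,
#'   `right_cam`, `rig`, `noise_sd`, `blur_sigma` and `seed`.
#' @export
sample_scene <- function(n_grains = 20, H = 1.8, delta = 0.15,
                         a_range = c(3.2, 3.8), b_range = c(1.1, 1.4),
                         board = default_board(), rig = default_rig(),
                         noise_sd = 2, blur_sigma = 0.5,
                         min_spacing = 5, seed = NULL, max_tries = 2000) {
  stopifnot(delta >= 0, delta < H / 2, a_range[1] > 0,
            b_range[1] > 0, a_range[1] >= b_range[2])
  if (!is.null(seed)) set.seed(seed)
  bx <- (board$n_cols - 1) * board$spacing_x
  by <- (board$n_rows - 1) * board$spacing_y
  margin <- 5
  xlim <- c(-margin, bx + margin)
  ylim <- c(-margin, by + margin)
  circ <- board_object_coordinates(board)
  a <- stats::runif(n_grains, a_range[1], a_range[2])
  b <- stats::runif(n_grains, b_range[1], b_range[2])
  yaw <- stats::runif(n_grains, 0, pi)
  flip <- stats::runif(n_grains) < 0.5
  X <- numeric(n_grains)
  Y <- numeric(n_grains)
  for (i in seq_len(n_grains)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      x <- stats::runif(1, xlim[1], xlim[2])
      y <- stats::runif(1, ylim[1], ylim[2])
      dc <- sqrt((circ[, 1] - x)^2 + (circ[, 2] - y)^2)
      if (any(dc < a[i] + board$radius + 1)) next
      if (i > 1) {
        dg <- sqrt((X[seq_len(i - 1)] - x)^2 + (Y[seq_len(i - 1)] - y)^2)
        if (any(dg < a[i] + a[seq_len(i - 1)] + min_spacing)) next
      }
      X[i] <- x
      Y[i] <- y
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("packing failure: could not place grain ", i, " after ",
           max_tries, " tries")
    }
  }
  grains <- data.frame(a = a, b = b, H = rep(H, n_grains),
                       delta = rep(delta, n_grains), X = X, Y = Y,
                       yaw = yaw, flip = flip,
                       rim_z = H / 2 + ifelse(flip, delta, -delta))
  cams <- make_rig_cameras(rig, board)
  structure(list(grains = grains, board = board,
                 left_cam = cams$left, right_cam = cams$right, rig = rig,
                 noise_sd = noise_sd, blur_sigma = blur_sigma, seed = seed),
            class = "scene_truth")
}

## Build the two oriented cameras and a raster size that covers the board
## plus grain margin from both viewpoints.
make_rig_cameras <- function(rig, board) {
  bx <- (board$n_cols - 1) * board$spacing_x
  by <- (board$n_rows - 1) * board$spacing_y
  cx <- bx / 2
  cy <- by / 2
  f <- rig$f
  io <- interior_orientation(0, 0, f)
  phi_l <- if (rig$convergent) -atan(rig$baseline / 2 / rig$height) else 0
  phi_r <- -phi_l
  eo_l <- exterior_orientation(cx - rig$baseline / 2, cy, rig$height,
                               phi = phi_l)
  eo_r <- exterior_orientation(cx + rig$baseline / 2, cy, rig$height,
                               phi = phi_r)
  ## frame: project the padded board corners through both cameras
  pad <- 12
  corners <- as.matrix(expand.grid(X = c(-pad, bx + pad),
                                   Y = c(-pad, by + pad), Z = c(0, 2)))
  pr <- rbind(project_points(corners, eo_l, io),
              project_points(corners, eo_r, io))
  width <- 2 * ceiling(max(abs(pr[, 1]))) + 9
  height <- 2 * ceiling(max(abs(pr[, 2]))) + 9
  list(left = camera_model(io, eo_l, width = width, height = height),
       right = camera_model(io, eo_r, width = width, height = height))
}

#' Separable Gaussian blur
#'
#' Convolution with a truncated (4 sigma) Gaussian kernel applied along
#' rows then columns, with edge-replicated borders.
#'
#' @param img Numeric matrix.
#' @param sigma Kernel standard deviation (pixels).
#' @return Blurred matrix of the same size.
#' @export
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  conv_rows <- function(m) {
    nr <- nrow(m)
    out <- matrix(0, nr, ncol(m))
    for (i in seq_along(k)) {
      rows <- pmin(pmax(seq_len(nr) + (i - r - 1L), 1L), nr)
      out <- out + k[i] * m[rows, , drop = FALSE]
    }
    out
  }
  t(conv_rows(t(conv_rows(img))))
}

## Paint one planar ellipse (at height z) into a gray image by
## back-projecting sub-pixel samples; returns the image with the ellipse
## composited at intensity `value` via coverage alpha.
paint_ellipse <- function(img, cam, cx, cy, a, b, yaw, z, value,
                          subsamples = 2) {
  th <- seq(0, 2 * pi, length.out = 73)[-73]
  rim <- cbind(cx + a * cos(th) * cos(yaw) - b * sin(th) * sin(yaw),
               cy + a * cos(th) * sin(yaw) + b * sin(th) * cos(yaw),
               z)
  pr <- project_points(rim, cam$eo, cam$io)
  rc <- photo_to_raster(pr, cam$width, cam$height)
  r0 <- max(1L, floor(min(rc[, 1])) - 2L)
  r1 <- min(nrow(img), ceiling(max(rc[, 1])) + 2L)
  c0 <- max(1L, floor(min(rc[, 2])) - 2L)
  c1 <- min(ncol(img), ceiling(max(rc[, 2])) + 2L)
  if (r1 < r0 || c1 < c0) return(img)
  rows <- r0:r1
  cols <- c0:c1
  off <- (seq_len(subsamples) - (subsamples + 1) / 2) / subsamples
  cov <- matrix(0, length(rows), length(cols))
  for (orow in off) {
    for (ocol in off) {
      g <- expand.grid(row = rows + orow, col = cols + ocol)
      xy <- raster_to_photo(as.matrix(g), cam$width, cam$height)
      P <- backproject_to_plane(xy, cam$eo, cam$io, z = z)
      u <- P[, 1] - cx
      v <- P[, 2] - cy
      uu <- u * cos(-yaw) - v * sin(-yaw)
      vv <- u * sin(-yaw) + v * cos(-yaw)
      inside <- (uu / a)^2 + (vv / b)^2 <= 1
      cov <- cov + matrix(inside, length(rows), length(cols))
    }
  }
  cov <- cov / subsamples^2
  img[rows, cols] <- img[rows, cols] + cov * (value - img[rows, cols])
  img
}

#' Render the stereo pair of a synthetic scene
#'
#' Each grain's silhouette is its rim ellipse (the planar ellipse at the
#' grain's rim height) projected through each camera; board circles are
#' rendered at the datum plane. Edges are anti-aliased by sub-pixel
#' sampling, then the configured Gaussian blur and gray noise are
#' applied. Grains and circles are bright on a dark board.
#'
#' @param scene A `scene_truth` from [sample_scene()].
#' @param seed Optional seed for the noise draw (defaults to the scene
#'   seed offset by 1 so that scene sampling and rendering noise are
#'   independent streams).
#' @return A list with `left` and `right` gray image matrices in `[0, 1]`.
#' @export
render_stereo <- function(scene, seed = NULL) {
  if (is.null(seed) && !is.null(scene$seed)) seed <- scene$seed + 1L
  if (!is.null(seed)) set.seed(seed)
  bg <- 0.15
  circle_val <- 0.9
  grain_val <- 0.85
  render_one <- function(cam) {
    img <- matrix(bg, cam$height, cam$width)
    circ <- board_object_coordinates(scene$board)
    for (k in seq_len(nrow(circ))) {
      img <- paint_ellipse(img, cam, circ[k, 1], circ[k, 2],
                           scene$board$radius, scene$board$radius, 0, 0,
                           circle_val)
    }
    g <- scene$grains
    for (k in seq_len(nrow(g))) {
      img <- paint_ellipse(img, cam, g$X[k], g$Y[k], g$a[k], g$b[k],
                           g$yaw[k], g$rim_z[k], grain_val)
    }
    if (scene$blur_sigma > 0) {
      img <- gaussian_blur(img, sigma = scene$blur_sigma)
    }
    if (scene$noise_sd > 0) {
      img <- img + matrix(stats::rnorm(length(img), 0,
                                       scene$noise_sd / 255),
                          nrow(img), ncol(img))
    }
    img[img < 0] <- 0
    img[img > 1] <- 1
    img
  }
  list(left = render_one(scene$left_cam), right = render_one(scene$right_cam))
}

#' Simulate rim heights under the half-thickness hypothesis
#'
#' Draws `n` grains of thickness `H` with rim asymmetry `delta` and fair
#' random flips and returns the rim heights `H/2 +- delta` — the
#' population whose mean the thickness estimator doubles. This isolates
#' the statistical content of the hypothesis from the imaging chain.
#'
#' @param n Number of grains.
#' @param H Thickness (mm).
#' @param delta Rim offset (mm).
#' @param seed Optional RNG seed.
#' @return Numeric vector of `n` rim heights (mm).
#' @export
simulate_rim_heights <- function(n, H = 1.8, delta = 0.2, seed = NULL) {
  stopifnot(n >= 1, delta >= 0, delta < H / 2)
  if (!is.null(seed)) set.seed(seed)
  flip <- stats::runif(n) < 0.5
  H / 2 + ifelse(flip, delta, -delta)
}

#' Write / read a self-contained synthetic fixture bundle
#'
#' Writes the rendered stereo pair (PNG), the full ground truth (JSON),
#' the board layout (YAML) and both camera models (YAML) into `dir`.
#'
#' @param scene A `scene_truth`.
#' @param dir Output directory (created if needed).
#' @param images Optional pre-rendered list from [render_stereo()].
#' @return `dir`, invisibly.
#' @export
write_scene_bundle <- function(scene, dir, images = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(images)) images <- render_stereo(scene)
  write_raster(images$left, file.path(dir, "left.png"))
  write_raster(images$right, file.path(dir, "right.png"))
  write_board_yaml(scene$board, file.path(dir, "board.yaml"))
  write_camera_yaml(scene$left_cam, file.path(dir, "camera_left.yaml"))
  write_camera_yaml(scene$right_cam, file.path(dir, "camera_right.yaml"))
  truth <- list(grains = scene$grains,
                rig = scene$rig,
                noise_sd = scene$noise_sd,
                blur_sigma = scene$blur_sigma,
                seed = scene$seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_scene_bundle
#' @export
read_scene_bundle <- function(dir) {
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  board <- read_board_yaml(file.path(dir, "board.yaml"))
  structure(list(grains = truth$grains, board = board,
                 left_cam = read_camera_yaml(file.path(dir, "camera_left.yaml")),
                 right_cam = read_camera_yaml(file.path(dir, "camera_right.yaml")),
                 rig = truth$rig, noise_sd = truth$noise_sd,
                 blur_sigma = truth$blur_sigma, seed = truth$seed),
            class = "scene_truth")
}

#' Run the full pipeline on a synthetic scene and score it
#'
#' Renders the stereo pair, re-orients both cameras from the board
#' circles (the ground-truth exterior orientation is *not* used), runs
#' [measure_thickness()] and compares against the known thickness.
#'
#' @param scene A `scene_truth`.
#' @param render_seed Optional seed for the rendering noise.
#' @param ... Passed on to [measure_thickness()].
#' @return A list with `thickness`, `true_H`, `error` (mm), the
#'   `report`, and the two resection RMS values (pixels).
#' @export
evaluate_pipeline <- function(scene, render_seed = NULL, ...) {
  imgs <- render_stereo(scene, seed = render_seed)
  cams0 <- list(
    camera_model(scene$left_cam$io, NULL, scene$left_cam$distortion,
                 scene$left_cam$width, scene$left_cam$height),
    camera_model(scene$right_cam$io, NULL, scene$right_cam$distortion,
                 scene$right_cam$width, scene$right_cam$height))
  ppm <- scene$rig$f / scene$rig$height
  ori <- orient_stereo(imgs$left, imgs$right, scene$board,
                       cams0[[1]], cams0[[2]], px_per_mm = ppm)
  report <- measure_thickness(imgs$left, imgs$right, ori$left, ori$right,
                              board = scene$board,
                              exclude_masks = ori$circle_masks, ...)
  true_H <- scene$grains$H[1]
  list(thickness = report$thickness, true_H = true_H,
       error = report$thickness - true_H, report = report,
       rms_left = ori$rms_left, rms_right = ori$rms_right)
}

#' Sweep the number of grains per scene
#'
#' Runs the end-to-end pipeline over `n_seeds` scenes for each sample
#' size and reports the per-size error spread — the empirical analogue of
#' asking how many grains are needed before the flip average settles.
#'
#' @param n_grains Vector of sample sizes.
#' @param n_seeds Scenes per sample size.
#' @param seed Base seed; scene `s` at size `n` uses a seed derived from
#'   it deterministically.
#' @param ... Passed to [sample_scene()].
#' @return A data.frame with one row per (n, seed): `n_grains`, `seed`,
#'   `thickness`, `error`.
#' @export
sweep_sample_size <- function(n_grains = c(2, 5, 10, 20), n_seeds = 20,
                              seed = 1, ...) {
  rows <- list()
  for (n in n_grains) {
    for (s in seq_len(n_seeds)) {
      sc_seed <- (seed * 1000L + n * 37L + s) %% .Machine$integer.max
      scene <- sample_scene(n_grains = n, seed = sc_seed, ...)
      ev <- evaluate_pipeline(scene)
      rows[[length(rows) + 1]] <- data.frame(
        n_grains = n, seed = sc_seed,
        thickness = ev$thickness, error = ev$error)
    }
  }
  do.call(rbind, rows)
}

#' Sweep the stereo baseline
#'
#' Re-renders the same grain arrangement under different baselines and
#' reports the thickness error per baseline, probing the intersection
#' conditioning as the base-height ratio shrinks or grows.
#'
#' @param baselines Baselines to test (mm).
#' @param n_grains Grains per scene.
#' @param seed Scene seed (same arrangement for every baseline).
#' @param ... Passed to [sample_scene()].
#' @return A data.frame with `baseline`, `base_height_ratio`, `thickness`,
#'   `error`.
#' @export
sweep_baseline <- function(baselines = seq(30, 160, by = 10), n_grains = 20,
                           seed = 1, ...) {
  rows <- list()
  for (b in baselines) {
    rig <- default_rig(baseline = b)
    scene <- sample_scene(n_grains = n_grains, rig = rig, seed = seed, ...)
    ev <- evaluate_pipeline(scene)
    rows[[length(rows) + 1]] <- data.frame(
      baseline = b, base_height_ratio = b / rig$height,
      thickness = ev$thickness, error = ev$error)
  }
  do.call(rbind, rows)
}
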