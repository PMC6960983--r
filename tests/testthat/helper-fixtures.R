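# Shared fixtures: a compact board/rig for fast unit tests (the full-scale
# defaults are exercised by the acceptance tests), plus simple rasterised
# shapes used as segmentation oracles.

small_board <- function() {
  board_layout(n_rows = 3, n_cols = 4, spacing_x = 24, spacing_y = 24,
               radius = 4, polarity = "bright")
}

small_rig <- function(baseline = 60, convergent = FALSE) {
  default_rig(height = 300, baseline = baseline, pixel_scale = 0.18,
              convergent = convergent)
}

ppm <- function(scene) scene$rig$f / scene$rig$height

small_scene <- function(n_grains = 5, seed = 1, ...) {
  sample_scene(n_grains = n_grains, board = small_board(),
               rig = small_rig(), seed = seed, ...)
}

fresh_cam <- function(cam) {
  camera_model(cam$io, NULL, cam$distortion, cam$width, cam$height)
}

orient_scene <- function(scene, imgs) {
  orient_stereo(imgs$left, imgs$right, scene$board,
                fresh_cam(scene$left_cam), fresh_cam(scene$right_cam),
                px_per_mm = scene$rig$f / scene$rig$height)
}

# binary disk of radius r centred in a (2r+pad) square matrix
make_disk <- function(r, pad = 4) {
  n <- 2 * r + 2 * pad + 1
  cen <- pad + r + 1
  idx <- expand.grid(row = 1:n, col = 1:n)
  m <- matrix(as.integer((idx$row - cen)^2 + (idx$col - cen)^2 <= r^2), n, n)
  m
}

# binary axis-aligned ellipse with semi-axes (a, b) in (col, row)
make_ellipse <- function(a, b, pad = 4) {
  nr <- 2 * b + 2 * pad + 1
  nc <- 2 * a + 2 * pad + 1
  cr <- pad + b + 1
  cc <- pad + a + 1
  idx <- expand.grid(row = 1:nr, col = 1:nc)
  matrix(as.integer(((idx$col - cc) / a)^2 + ((idx$row - cr) / b)^2 <= 1),
         nr, nc)
}

# brute-force median filter with edge replication (oracle)
median_oracle <- function(m, k = 3) {
  r <- (k - 1) / 2
  out <- m
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      rr <- pmin(pmax((i - r):(i + r), 1), nrow(m))
      cc <- pmin(pmax((j - r):(j + r), 1), ncol(m))
      out[i, j] <- stats::median(m[rr, cc])
    }
  }
  out
}

# exhaustive Otsu scan (oracle): maximise between-class variance over all
# 256 candidate thresholds on the [0, 1] scale
otsu_oracle <- function(v) {
  cand <- (0:255) / 255
  best <- -Inf
  best_t <- NA
  for (t in cand) {
    lo <- v[v <= t]
    hi <- v[v > t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(v)
    s <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (s > best) {
      best <- s
      best_t <- t
    }
  }
  best_t
}

# analytic boundary of an ellipse in photo coordinates (dense, CCW)
ellipse_boundary_xy <- function(cx, cy, a, b, yaw = 0, n = 720) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(x = cx + a * cos(th) * cos(yaw) - b * sin(th) * sin(yaw),
        y = cy + a * cos(th) * sin(yaw) + b * sin(th) * cos(yaw))
}
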