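test_that("polar distances of a rasterised disk are near-constant", {
  r <- 20
  disk <- make_disk(r)
  b <- trace_boundary(disk)
  cen <- region_centroid(disk)
  # photo frame: x = col, y = -row (any consistent similarity works here)
  bxy <- cbind(b[, 2], -b[, 1])
  raw <- polar_distances(bxy, c(cen["col"], -cen["row"]))
  # boundary pixel centres of a digital disk lie within one pixel of the
  # ideal circle (the inner corners of the staircase are the worst case)
  expect_true(all(abs(raw$d - r) < 1.0))
  expect_equal(nrow(raw), nrow(b))
  # angles increase monotonically after unwrapping (CCW order)
  un <- raw$angle + 360 * cumsum(c(0, diff(raw$angle) < -180))
  expect_true(all(diff(un) > -1e-9))
  expect_lt(raw$angle[1], 2.5)   # starts at the polar-axis crossing
})

test_that("polar distances of an ellipse hit the semi-axes", {
  ell <- make_ellipse(50, 10)
  b <- trace_boundary(ell)
  cen <- region_centroid(ell)
  raw <- polar_distances(cbind(b[, 2], -b[, 1]),
                         c(cen["col"], -cen["row"]))
  prof <- resample_profile(raw)
  expect_equal(prof$h[1], 50, tolerance = 0.05)        # 0 degrees
  expect_equal(prof$h[91], 10, tolerance = 0.1)        # 90 degrees
  expect_equal(prof$h[181], 50, tolerance = 0.05)      # 180 degrees
})

test_that("a centroid outside the boundary is rejected", {
  sq <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  expect_error(polar_distances(sq, c(50, 50)), "outside")
})

test_that("resampling interpolates linearly on the circle", {
  # samples already at integer degrees pass through unchanged
  raw <- data.frame(angle = 0:359, d = 10 + sin((0:359) * pi / 180))
  prof <- resample_profile(raw)
  expect_equal(prof$h, raw$d)

  # midpoint of a linear segment
  raw2 <- data.frame(angle = c(seq(0, 358, by = 2)),
                     d = rep(10, 180))
  raw2$d[1:2] <- c(10, 14)
  h <- resample_profile(raw2)$h
  expect_equal(h[2], 12)   # angle 1 between (0, 10) and (2, 14)

  # gap guard
  bad <- data.frame(angle = c(0, 10, 40, 300), d = c(5, 5, 5, 5))
  expect_error(resample_profile(bad), "gap")
})

test_that("resampled values are bounded by the raw extremes", {
  set.seed(14)
  for (rep in 1:25) {
    n <- sample(40:200, 1)
    ang <- sort(stats::runif(n, 0, 360))
    d <- stats::runif(n, 5, 30)
    prof <- resample_profile(data.frame(angle = ang, d = d),
                             max_gap = 360)
    expect_gte(min(prof$h), min(d) - 1e-12)
    expect_lte(max(prof$h), max(d) + 1e-12)
  }
})

test_that("circular-shift recovery is exact for noiseless rotated profiles", {
  set.seed(6)
  base <- 20 + 8 * cos(2 * (0:359) * pi / 180) +
    3 * sin(3 * (0:359) * pi / 180) + stats::rnorm(360, 0, 0.3)
  left <- structure(list(h = base), class = "edge_profile")
  for (k in c(0, 1, 37, 90, 179, 180, 255, 359)) {
    # left angle i corresponds to right angle i + k: right[j] = left[j - k]
    right <- structure(list(h = base[((0:359 - k) %% 360) + 1]),
                       class = "edge_profile")
    m <- match_edge_points(left, right)
    expect_equal(m$shift, k)
    expect_equal(m$correlation, 1.0, tolerance = 1e-12)
  }
})

test_that("matching is symmetric between the two profiles", {
  set.seed(61)
  base <- 20 + 8 * cos(2 * (0:359) * pi / 180) + stats::rnorm(360, 0, 0.5)
  other <- base[((0:359 - 123) %% 360) + 1] + stats::rnorm(360, 0, 0.2)
  l <- structure(list(h = base), class = "edge_profile")
  r <- structure(list(h = other), class = "edge_profile")
  m1 <- match_edge_points(l, r)
  m2 <- match_edge_points(r, l)
  expect_equal(m1$correlation, m2$correlation, tolerance = 1e-12)
  expect_equal((m1$shift + m2$shift) %% 360, 0)
})

test_that("shift recovery tolerates sub-pixel boundary noise", {
  # elongated grain profile (a/b = 2.8), 0.2 px noise, 100 repetitions
  a <- 35
  b <- 12.5
  th <- (0:359) * pi / 180
  clean <- a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
  set.seed(70)
  hits <- 0
  cors <- numeric(100)
  for (rep in 1:100) {
    k <- sample(0:359, 1)
    l <- structure(list(h = clean + stats::rnorm(360, 0, 0.2)),
                   class = "edge_profile")
    r <- structure(list(h = clean[((0:359 - k) %% 360) + 1] +
                          stats::rnorm(360, 0, 0.2)),
                   class = "edge_profile")
    m <- match_edge_points(l, r)
    # the ellipse is 180-periodic, so k and k+180 are equivalent here
    if ((m$shift - k) %% 180 == 0) hits <- hits + 1
    cors[rep] <- m$correlation
  }
  expect_gte(hits, 99)
  expect_gt(mean(cors), 0.99)
})

test_that("a zero-variance profile is flagged as degenerate", {
  flat <- structure(list(h = rep(10, 360)), class = "edge_profile")
  bumpy <- structure(list(h = 10 + sin((0:359) / 20)),
                     class = "edge_profile")
  m <- match_edge_points(flat, bumpy)
  expect_true(m$degenerate)
  expect_equal(m$shift, 0L)
  expect_true(is.na(m$correlation))
})

test_that("matched angles convert back to boundary-accurate photo points", {
  cen <- c(100, 100)
  prof <- structure(list(h = rep(20, 360), centroid = cen),
                    class = "edge_profile")
  corr <- structure(list(shift = 0L, correlation = 1,
                         correlations = rep(1, 360)),
                    class = "edge_correspondence")
  cp <- correspondence_to_image_points(corr, prof, prof)
  expect_equal(nrow(cp$left_xy), 360)
  expect_equal(unname(cp$left_xy[1, ]), c(120, 100))

  # reconstructed points stay within a pixel of the traced boundary
  ell <- make_ellipse(30, 12)
  b <- trace_boundary(ell)
  cenp <- region_centroid(ell)
  bxy <- cbind(b[, 2], -b[, 1])
  raw <- polar_distances(bxy, c(cenp["col"], -cenp["row"]))
  pr <- resample_profile(raw)
  pr$centroid <- c(cenp["col"], -cenp["row"])
  cp2 <- correspondence_to_image_points(corr, pr, pr)
  dmin <- apply(cp2$left_xy, 1, function(p) {
    min(sqrt((bxy[, 1] - p[1])^2 + (bxy[, 2] - p[2])^2))
  })
  expect_lt(max(dmin), 1)
})

test_that("grain matching pairs every rendered grain correctly", {
  set.seed(500)
  n_correct <- 0
  n_total <- 0
  for (rep in 1:20) {
    scene <- small_scene(n_grains = 6, seed = 500 + rep)
    imgs <- render_stereo(scene)
    ori <- orient_scene(scene, imgs)
    seg <- function(img, cam) {
      det <- detect_circle_centers(img, scene$board, px_per_mm = ppm(scene))
      segment_grains(img, exclude = attr(det, "mask"))
    }
    lr <- seg(imgs$left, ori$left)
    rr <- seg(imgs$right, ori$right)
    m <- match_grains(lr, rr, ori$left, ori$right)
    # ground truth by nearest true grain to each region's board position
    truth_of <- function(regions, cam) {
      rc <- do.call(rbind, lapply(regions, `[[`, "centroid"))
      xy <- raster_to_photo(rc, cam$width, cam$height)
      pos <- backproject_to_plane(xy, cam$eo, cam$io, z = 0.9)
      apply(pos, 1, function(p) {
        which.min((scene$grains$X - p[1])^2 + (scene$grains$Y - p[2])^2)
      })
    }
    tl <- truth_of(lr, ori$left)
    tr <- truth_of(rr, ori$right)
    n_total <- n_total + nrow(m)
    n_correct <- n_correct + sum(tl[m$left_id] == tr[m$right_id])
    expect_equal(nrow(m), 6)
  }
  expect_equal(n_correct, n_total)
})

test_that("grain matching handles empty and one-sided inputs", {
  scene <- small_scene(n_grains = 3, seed = 77)
  imgs <- render_stereo(scene)
  ori <- orient_scene(scene, imgs)
  det <- detect_circle_centers(imgs$left, scene$board, px_per_mm = ppm(scene))
  lr <- segment_grains(imgs$left, exclude = attr(det, "mask"))

  m0 <- match_grains(lr, list(), ori$left, ori$right)
  expect_equal(nrow(m0), 0)
  expect_length(attr(m0, "unmatched_left"), length(lr))

  # drop one right-image grain: its left partner must stay unmatched
  detr <- detect_circle_centers(imgs$right, scene$board, px_per_mm = ppm(scene))
  rr <- segment_grains(imgs$right, exclude = attr(detr, "mask"))
  m_full <- match_grains(lr, rr, ori$left, ori$right)
  gone <- m_full$right_id[1]
  partner <- m_full$left_id[1]
  rr2 <- rr[vapply(rr, `[[`, 0, "label") != gone]
  m <- match_grains(lr, rr2, ori$left, ori$right)
  expect_equal(nrow(m), 2)
  expect_false(partner %in% m$left_id)
  expect_true(partner %in% attr(m, "unmatched_left"))
})
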