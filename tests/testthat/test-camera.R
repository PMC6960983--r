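test_that("rotation matrix reproduces the elementary factor product", {
  expect_equal(rotation_matrix(0, 0, 0), diag(3))

  # phi = pi/2 about the Y axis
  expect_equal(rotation_matrix(pi / 2, 0, 0),
               matrix(c(0, 0, -1, 0, 1, 0, 1, 0, 0), 3, 3, byrow = TRUE),
               tolerance = 1e-12)

  # independent oracle: multiply the three factor matrices built here
  set.seed(11)
  for (i in 1:20) {
    ang <- stats::runif(3, -pi, pi)
    Rp <- rbind(c(cos(ang[1]), 0, -sin(ang[1])), c(0, 1, 0),
                c(sin(ang[1]), 0, cos(ang[1])))
    Ro <- rbind(c(1, 0, 0), c(0, cos(ang[2]), -sin(ang[2])),
                c(0, sin(ang[2]), cos(ang[2])))
    Rk <- rbind(c(cos(ang[3]), -sin(ang[3]), 0),
                c(sin(ang[3]), cos(ang[3]), 0), c(0, 0, 1))
    expect_equal(rotation_matrix(ang[1], ang[2], ang[3]), Rp %*% Ro %*% Rk,
                 tolerance = 1e-14)
  }
})

test_that("rotation matrices are orthonormal with determinant +1", {
  set.seed(42)
  worst_orth <- 0
  worst_det <- 0
  for (i in 1:1000) {
    ang <- stats::runif(3, -pi, pi)
    R <- rotation_matrix(ang[1], ang[2], ang[3])
    worst_orth <- max(worst_orth, max(abs(t(R) %*% R - diag(3))))
    worst_det <- max(worst_det, abs(det(R) - 1))
  }
  expect_lt(worst_orth, 1e-10)
  expect_lt(worst_det, 1e-10)
})

test_that("collinearity projection matches hand-evaluated cases", {
  io <- interior_orientation(0, 0, 5000)
  eo <- exterior_orientation(0, 0, 350)
  expect_equal(project_points(c(0, 0, 0), eo, io),
               cbind(x = 0, y = 0))
  # x = -f (X - Xs) / (Z - Zs) = -5000 * 7 / (-350) = 100
  expect_equal(project_points(c(7, 0, 0), eo, io),
               cbind(x = 100, y = 0))
  # principal point offset shifts the image point rigidly
  io2 <- interior_orientation(3, -2, 5000)
  expect_equal(project_points(c(7, 0, 0), eo, io2),
               cbind(x = 103, y = -2))
  # point in the focal plane is degenerate
  expect_error(project_points(c(0, 0, 350), eo, io), "degenerate")
})

test_that("back-projection inverts projection on a known plane", {
  io <- interior_orientation(1.5, -0.5, 3500)
  eo <- exterior_orientation(40, 25, 350, 0.05, -0.03, 0.4)
  P <- cbind(c(10, 55, 80), c(5, 30, 58), c(0.9, 0.9, 0.9))
  xy <- project_points(P, eo, io)
  back <- backproject_to_plane(xy, eo, io, z = 0.9)
  expect_equal(unname(back), unname(P), tolerance = 1e-10)
})

test_that("undistortion inverts the forward Brown-Conrady model", {
  io <- interior_orientation(0, 0, 3500)
  dist0 <- distortion_coefficients()
  pts <- cbind(x = c(0, 150, -800, 430), y = c(0, -90, 600, 911))
  expect_equal(undistort_points(pts, io, dist0), pts)

  # consumer-lens magnitudes
  dist <- distortion_coefficients(k1 = -0.12, k2 = 0.05, k3 = -0.01,
                                  p1 = 4e-4, p2 = -2e-4)
  set.seed(3)
  ideal <- cbind(x = stats::runif(50, -900, 900),
                 y = stats::runif(50, -600, 600))
  distorted <- distort_points(ideal, io, dist)
  recovered <- undistort_points(distorted, io, dist)
  expect_lt(max(abs(recovered - ideal)), 1e-6)

  # the principal point has zero radius and is a fixed point
  pp <- cbind(x = 0, y = 0)
  expect_equal(distort_points(pp, io, dist), pp)
  expect_equal(undistort_points(pp, io, dist), pp, tolerance = 1e-9)
})

test_that("space resection recovers a known exterior orientation exactly", {
  io <- interior_orientation(2, -1, 3500)
  eo_true <- exterior_orientation(45, 30, 352, 0.02, -0.015, 0.08)
  board <- board_object_coordinates(default_board())
  image <- project_points(board, eo_true, io)
  fit <- space_resection(list(object = board, image = image), io)
  expect_lt(abs(fit$eo$Xs - eo_true$Xs), 1e-6)
  expect_lt(abs(fit$eo$Ys - eo_true$Ys), 1e-6)
  expect_lt(abs(fit$eo$Zs - eo_true$Zs), 1e-6)
  expect_lt(abs(fit$eo$phi - eo_true$phi), 1e-8)
  expect_lt(abs(fit$eo$omega - eo_true$omega), 1e-8)
  expect_lt(abs(fit$eo$kappa - eo_true$kappa), 1e-8)
  expect_lt(fit$rms, 1e-8)
})

test_that("resection residual under image noise matches least-squares theory", {
  io <- interior_orientation(0, 0, 3500)
  eo_true <- exterior_orientation(45, 30, 350, 0, 0, 0)
  board <- board_object_coordinates(default_board())
  image <- project_points(board, eo_true, io)
  sigma <- 0.2
  n_obs <- 2 * nrow(board)
  set.seed(7)
  rms <- replicate(40, {
    noisy <- image + matrix(stats::rnorm(length(image), 0, sigma),
                            nrow(image), 2)
    space_resection(list(object = board, image = noisy), io)$rms
  })
  # E[rms] ~ sigma * sqrt(1 - 6/n_obs) for 6 estimated parameters
  expect_equal(mean(rms), sigma * sqrt(1 - 6 / n_obs), tolerance = 0.15)
})

test_that("resection rejects under-determined or degenerate control", {
  io <- interior_orientation(0, 0, 3500)
  eo <- exterior_orientation(0, 0, 350)
  obj3 <- cbind(c(0, 30, 0), c(0, 0, 30), 0)
  img3 <- project_points(obj3, eo, io)
  expect_error(space_resection(list(object = obj3, image = img3), io),
               "at least 4")
  # collinear control
  objc <- cbind(seq(0, 90, by = 10), 0, 0)
  imgc <- project_points(objc, eo, io)
  expect_error(space_resection(list(object = objc, image = imgc), io),
               "collinear")
})

test_that("space intersection recovers a known point from its projections", {
  io <- interior_orientation(0, 0, 3500)
  left <- camera_model(io, exterior_orientation(5, 30, 350),
                       width = 1000, height = 800)
  right <- camera_model(io, exterior_orientation(85, 30, 350),
                        width = 1000, height = 800)
  P <- c(12.0, 30.0, 0.85)
  xl <- project_points(P, left$eo, left$io)
  xr <- project_points(P, right$eo, right$io)
  sol <- space_intersection(xl, xr, left, right)
  expect_lt(max(abs(sol$points - rbind(P))), 1e-8)
  expect_lt(sol$rms, 1e-10)

  # board circle centres sit on the datum plane
  B <- cbind(c(0, 30, 60), c(0, 30, 0), 0)
  sol0 <- space_intersection(project_points(B, left$eo, left$io),
                             project_points(B, right$eo, right$io),
                             left, right)
  expect_lt(max(abs(sol0$points[, 3])), 1e-8)

  # zero baseline: coincident rays are degenerate
  expect_error(space_intersection(xl, xl, left, left), "degenerate")
})

test_that("project/intersect closure holds over random well-conditioned rigs", {
  set.seed(99)
  worst <- 0
  for (rep in 1:100) {
    f <- stats::runif(1, 2000, 6000)
    io <- interior_orientation(stats::runif(1, -5, 5),
                               stats::runif(1, -5, 5), f)
    h <- stats::runif(1, 250, 450)
    b <- stats::runif(1, 0.15, 0.3) * h
    tilt <- stats::runif(6, -0.08, 0.08)
    left <- camera_model(io, exterior_orientation(-b / 2, 0, h, tilt[1],
                                                  tilt[2], tilt[3]),
                         width = 2000, height = 1500)
    right <- camera_model(io, exterior_orientation(b / 2, 0, h, tilt[4],
                                                   tilt[5], tilt[6]),
                          width = 2000, height = 1500)
    P <- cbind(stats::runif(10, -40, 40), stats::runif(10, -30, 30),
               stats::runif(10, 0, 3))
    sol <- space_intersection(project_points(P, left$eo, left$io),
                              project_points(P, right$eo, right$io),
                              left, right)
    worst <- max(worst, max(abs(sol$points - P)))
  }
  expect_lt(worst, 1e-6)
})

test_that("raster/photo conversion is a bijection with the stated convention", {
  w <- 101
  h <- 81
  # centre pixel maps to the photo origin
  expect_equal(raster_to_photo(cbind(41, 51), w, h), cbind(x = 0, y = 0))
  # y axis points up: smaller row = larger y
  expect_equal(raster_to_photo(cbind(1, 51), w, h)[, "y"], c(y = 40))
  set.seed(5)
  rc <- cbind(stats::runif(30, 1, h), stats::runif(30, 1, w))
  expect_equal(unname(photo_to_raster(raster_to_photo(rc, w, h), w, h)),
               unname(rc), tolerance = 1e-12)
})

test_that("camera YAML round-trips including degree-unit angles", {
  dir <- withr::local_tempdir()
  cam <- camera_model(interior_orientation(1.25, -0.5, 3500),
                      exterior_orientation(45, 30, 352, 0.02, -0.015, 0.08),
                      distortion_coefficients(k1 = -0.1, p1 = 2e-4),
                      width = 1200, height = 900)
  p <- file.path(dir, "cam.yaml")
  write_camera_yaml(cam, p)
  back <- read_camera_yaml(p)
  expect_equal(back$io, cam$io, tolerance = 1e-12)
  expect_equal(back$eo, cam$eo, tolerance = 1e-12)
  expect_equal(back$distortion, cam$distortion, tolerance = 1e-12)

  # degrees are converted on read
  cfg <- yaml::read_yaml(p)
  cfg$eo$phi <- cam$eo$phi * 180 / pi
  cfg$eo$omega <- cam$eo$omega * 180 / pi
  cfg$eo$kappa <- cam$eo$kappa * 180 / pi
  cfg$eo$angle_unit <- "degrees"
  yaml::write_yaml(cfg, p, precision = 15)
  expect_equal(read_camera_yaml(p)$eo, cam$eo, tolerance = 1e-9)
})
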