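#' Interior orientation
#'
#' Camera-internal parameters relating the lens centre to the image plane:
#' the principal-point offset `(x0, y0)` and the principal distance `f`,
#' all in pixels.
#'
#' @param x0,y0 Principal-point offset in photo coordinates (pixels).
#' @param f Principal distance (pixels); must be positive.
#' @return An object of class `interior_orientation`.
#' @export
interior_orientation <- function(x0 = 0, y0 = 0, f) {
  stopifnot(is.finite(x0), is.finite(y0), is.finite(f))
  if (f <= 0) stop("principal distance f must be > 0")
  structure(list(x0 = x0, y0 = y0, f = f), class = "interior_orientation")
}

#' Brown-Conrady lens distortion coefficients
#'
#' Radial terms `k1, k2, k3` and tangential terms `p1, p2`, applied to
#' coordinates normalised by the principal distance. All zero means
#' distortion-free.
#'
#' @param k1,k2,k3 Radial distortion coefficients.
#' @param p1,p2 Tangential distortion coefficients.
#' @return An object of class `distortion_coefficients`.
#' @export
distortion_coefficients <- function(k1 = 0, k2 = 0, k3 = 0, p1 = 0, p2 = 0) {
  v <- c(k1 = k1, k2 = k2, k3 = k3, p1 = p1, p2 = p2)
  if (!all(is.finite(v))) stop("distortion coefficients must be finite")
  structure(as.list(v), class = "distortion_coefficients")
}

#' Exterior orientation
#'
#' Position `(Xs, Ys, Zs)` of the projection centre in object space (mm)
#' and the attitude angles `phi, omega, kappa` (radians) of the camera at
#' exposure time.
#'
#' @param Xs,Ys,Zs Projection-centre coordinates (mm). `Zs > 0` for a
#'   camera above the board plane.
#' @param phi,omega,kappa Rotation angles (radians) about the Y, X and Z
#'   axes, applied in that order.
#' @return An object of class `exterior_orientation`.
#' @export
exterior_orientation <- function(Xs, Ys, Zs, phi = 0, omega = 0, kappa = 0) {
  v <- c(Xs, Ys, Zs, phi, omega, kappa)
  if (!all(is.finite(v))) stop("exterior orientation parameters must be finite")
  structure(list(Xs = Xs, Ys = Ys, Zs = Zs,
                 phi = phi, omega = omega, kappa = kappa),
            class = "exterior_orientation")
}

#' Full camera model
#'
#' Bundles interior orientation, lens distortion, exterior orientation and
#' the sensor raster size. The raster size fixes the bijection between
#' raster indices and photo coordinates (see [raster_to_photo()]).
#'
#' @param io An [interior_orientation()].
#' @param eo An [exterior_orientation()], or `NULL` for a not-yet-oriented
#'   camera.
#' @param distortion A [distortion_coefficients()]; defaults to
#'   distortion-free.
#' @param width,height Raster size in pixels.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(io, eo = NULL, distortion = distortion_coefficients(),
                         width, height) {
  stopifnot(inherits(io, "interior_orientation"))
  if (!is.null(eo)) stopifnot(inherits(eo, "exterior_orientation"))
  stopifnot(inherits(distortion, "distortion_coefficients"))
  stopifnot(width >= 1, height >= 1)
  structure(list(io = io, eo = eo, distortion = distortion,
                 width = as.integer(width), height = as.integer(height)),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat("Camera model (", x$width, "x", x$height, " px)\n", sep = "")
  cat(sprintf("  interior:  x0=%.3f y0=%.3f f=%.2f px\n",
              x$io$x0, x$io$y0, x$io$f))
  d <- unlist(x$distortion)
  if (any(d != 0)) {
    cat("  distortion:", paste(names(d), signif(d, 4), sep = "=",
                               collapse = " "), "\n")
  } else cat("  distortion: none\n")
  if (is.null(x$eo)) {
    cat("  exterior:  not oriented\n")
  } else {
    cat(sprintf("  exterior:  S=(%.3f, %.3f, %.3f) mm  phi=%.6f omega=%.6f kappa=%.6f rad\n",
                x$eo$Xs, x$eo$Ys, x$eo$Zs, x$eo$phi, x$eo$omega, x$eo$kappa))
  }
  invisible(x)
}

#' Rotation matrix from the attitude angles
#'
#' Builds the direction-cosine matrix as the product of the three
#' elementary factors: a rotation about the Y axis by `phi`, about the X
#' axis by `omega`, then about the Z axis by `kappa`. Rows are the
#' direction cosines `(alpha_i, beta_i, gamma_i)` used by the collinearity
#' equations.
#'
#' @param phi,omega,kappa Angles in radians.
#' @return A 3x3 orthonormal matrix with determinant +1.
#' @export
rotation_matrix <- function(phi, omega, kappa) {
  stopifnot(is.finite(phi), is.finite(omega), is.finite(kappa))
  Rphi <- matrix(c(cos(phi), 0, -sin(phi),
                   0, 1, 0,
                   sin(phi), 0, cos(phi)), 3, 3, byrow = TRUE)
  Romega <- matrix(c(1, 0, 0,
                     0, cos(omega), -sin(omega),
                     0, sin(omega), cos(omega)), 3, 3, byrow = TRUE)
  Rkappa <- matrix(c(cos(kappa), -sin(kappa), 0,
                     sin(kappa), cos(kappa), 0,
                     0, 0, 1), 3, 3, byrow = TRUE)
  Rphi %*% Romega %*% Rkappa
}

as_xyz_matrix <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  p <- as.matrix(p)
  stopifnot(ncol(p) == 3)
  dimnames(p) <- NULL
  p
}

as_xy_matrix <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  p <- as.matrix(p)
  stopifnot(ncol(p) == 2)
  dimnames(p) <- NULL
  p
}

#' Project object points into the image (collinearity equations)
#'
#' Applies the collinearity equations: with `(U,V,W) = R (P - S)`,
#' `x = x0 - f U / W` and `y = y0 - f V / W`. Photo coordinates are
#' centre-referenced, x right, y up (see [raster_to_photo()]).
#'
#' @param points Nx3 matrix of object coordinates (mm), or a length-3
#'   vector.
#' @param eo An [exterior_orientation()].
#' @param io An [interior_orientation()].
#' @return Nx2 matrix of photo coordinates (pixels), columns `x`, `y`.
#' @export
project_points <- function(points, eo, io) {
  P <- as_xyz_matrix(points)
  R <- rotation_matrix(eo$phi, eo$omega, eo$kappa)
  d <- cbind(P[, 1] - eo$Xs, P[, 2] - eo$Ys, P[, 3] - eo$Zs)
  UVW <- d %*% t(R)   # row i = R %*% d[i, ]
  W <- UVW[, 3]
  if (any(abs(W) < 1e-12)) {
    stop("degenerate geometry: object point in the camera focal plane ",
         "(collinearity denominator ~ 0)")
  }
  cbind(x = io$x0 - io$f * UVW[, 1] / W,
        y = io$y0 - io$f * UVW[, 2] / W)
}

#' Back-project photo coordinates onto a horizontal plane
#'
#' Inverts the collinearity equations for points known to lie on the plane
#' `Z = z`: the ray through the projection centre with direction
#' `t(R) %*% c(x - x0, y - y0, -f)` is intersected with the plane.
#'
#' @param xy Nx2 matrix of photo coordinates (pixels).
#' @param eo An [exterior_orientation()].
#' @param io An [interior_orientation()].
#' @param z Plane height (mm); default the board datum `0`.
#' @return Nx3 matrix of object coordinates (mm).
#' @export
backproject_to_plane <- function(xy, eo, io, z = 0) {
  xy <- as_xy_matrix(xy)
  R <- rotation_matrix(eo$phi, eo$omega, eo$kappa)
  v <- cbind(xy[, 1] - io$x0, xy[, 2] - io$y0, -io$f)
  d <- v %*% R        # row i = t(R) %*% v[i, ]
  if (any(abs(d[, 3]) < 1e-15)) {
    stop("degenerate geometry: ray parallel to the plane")
  }
  tt <- (z - eo$Zs) / d[, 3]
  cbind(X = eo$Xs + tt * d[, 1], Y = eo$Ys + tt * d[, 2], Z = z)
}

## Forward Brown-Conrady distortion on coordinates normalised by f,
## measured from the principal point.
brown_conrady_forward <- function(xn, yn, dist) {
  r2 <- xn * xn + yn * yn
  radial <- 1 + dist$k1 * r2 + dist$k2 * r2^2 + dist$k3 * r2^3
  xd <- xn * radial + 2 * dist$p1 * xn * yn + dist$p2 * (r2 + 2 * xn * xn)
  yd <- yn * radial + dist$p1 * (r2 + 2 * yn * yn) + 2 * dist$p2 * xn * yn
  list(x = xd, y = yd)
}

#' Apply lens distortion to ideal photo coordinates
#'
#' Forward Brown-Conrady model: radial `(k1,k2,k3)` and tangential
#' `(p1,p2)` terms applied to coordinates normalised by the principal
#' distance, measured from the principal point.
#'
#' @param xy Nx2 matrix of ideal (distortion-free) photo coordinates
#'   (pixels).
#' @param io An [interior_orientation()].
#' @param dist A [distortion_coefficients()].
#' @return Nx2 matrix of distorted photo coordinates (pixels).
#' @export
distort_points <- function(xy, io, dist) {
  xy <- as_xy_matrix(xy)
  xn <- (xy[, 1] - io$x0) / io$f
  yn <- (xy[, 2] - io$y0) / io$f
  d <- brown_conrady_forward(xn, yn, dist)
  cbind(x = io$x0 + io$f * d$x, y = io$y0 + io$f * d$y)
}

#' Remove lens distortion from observed photo coordinates
#'
#' Iteratively inverts the forward Brown-Conrady model by fixed-point
#' iteration until the forward-projected residual falls below `tol`
#' pixels. With all-zero coefficients the input is returned unchanged.
#'
#' @param xy Nx2 matrix of observed (distorted) photo coordinates (pixels).
#' @param io An [interior_orientation()].
#' @param dist A [distortion_coefficients()].
#' @param tol Convergence tolerance in pixels (default `1e-6`).
#' @param max_iter Iteration cap; exceeding it signals bad coefficients.
#' @return Nx2 matrix of ideal photo coordinates (pixels).
#' @export
undistort_points <- function(xy, io, dist, tol = 1e-6, max_iter = 50) {
  xy <- as_xy_matrix(xy)
  if (all(unlist(dist) == 0)) {
    return(cbind(x = xy[, 1], y = xy[, 2]))
  }
  xd <- (xy[, 1] - io$x0) / io$f
  yd <- (xy[, 2] - io$y0) / io$f
  xn <- xd
  yn <- yd
  tol_n <- tol / io$f
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    r2 <- xn * xn + yn * yn
    radial <- 1 + dist$k1 * r2 + dist$k2 * r2^2 + dist$k3 * r2^3
    tx <- 2 * dist$p1 * xn * yn + dist$p2 * (r2 + 2 * xn * xn)
    ty <- dist$p1 * (r2 + 2 * yn * yn) + 2 * dist$p2 * xn * yn
    xn_new <- (xd - tx) / radial
    yn_new <- (yd - ty) / radial
    f <- brown_conrady_forward(xn_new, yn_new, dist)
    err <- sqrt((f$x - xd)^2 + (f$y - yd)^2)
    xn <- xn_new
    yn <- yn_new
    if (all(err < tol_n)) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop("undistortion did not converge within ", max_iter,
         " iterations; distortion coefficients are implausible")
  }
  cbind(x = io$x0 + io$f * xn, y = io$y0 + io$f * yn)
}

## Residuals of the collinearity equations for one camera:
## observed - projected, stacked (x1, y1, x2, y2, ...).
resection_residuals <- function(par, object, image, io) {
  eo <- exterior_orientation(par[1], par[2], par[3], par[4], par[5], par[6])
  pr <- project_points(object, eo, io)
  as.numeric(t(image - pr))
}

#' Single-image space resection
#'
#' Recovers a camera's exterior orientation from control points with known
#' object and image coordinates, by Gauss-Newton least squares on the
#' linearised collinearity equations (numerical Jacobian, step halving on
#' divergent steps).
#'
#' If no initial value is supplied, a near-nadir initialisation is used:
#' attitude `(0, 0, 0)`, `(Xs, Ys)` at the centroid of the control object
#' points and `Zs` from the board-extent / image-extent scale ratio.
#'
#' @param control A list with elements `object` (Nx3 matrix, mm) and
#'   `image` (Nx2 matrix of photo coordinates, pixels), as produced by
#'   [order_control_points()].
#' @param io An [interior_orientation()].
#' @param initial Optional [exterior_orientation()] starting value.
#' @param tol Convergence: stop when the largest parameter update is below
#'   `tol` (default `1e-8`).
#' @param max_iter Iteration cap (default 100).
#' @return A list with elements `eo` (the recovered
#'   [exterior_orientation()]), `rms` (RMS image residual, pixels),
#'   `iterations`, and `residuals` (Nx2 matrix).
#' @export
space_resection <- function(control, io, initial = NULL,
                            tol = 1e-8, max_iter = 100) {
  object <- as_xyz_matrix(control$object)
  image <- as_xy_matrix(control$image)
  n <- nrow(object)
  if (n < 4) {
    stop("insufficient control: space resection needs at least 4 control points")
  }
  ## collinearity check (object points must span a 2-D set)
  sv <- svd(scale(object[, 1:2], scale = FALSE))$d
  if (sv[2] < 1e-9 * max(sv[1], 1)) {
    stop("degenerate control: object points are collinear")
  }
  if (is.null(initial)) {
    obj_extent <- max(dist(object[, 1:2]))
    img_extent <- max(dist(image))
    zs0 <- io$f * obj_extent / img_extent
    initial <- exterior_orientation(mean(object[, 1]), mean(object[, 2]),
                                    zs0, 0, 0, 0)
  }
  par <- c(initial$Xs, initial$Ys, initial$Zs,
           initial$phi, initial$omega, initial$kappa)
  res <- resection_residuals(par, object, image, io)
  sse <- sum(res^2)
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    ## numerical Jacobian, central differences
    J <- matrix(0, length(res), 6)
    h <- pmax(1e-6, 1e-8 * abs(par))
    for (j in 1:6) {
      pp <- par; pp[j] <- pp[j] + h[j]
      pm <- par; pm[j] <- pm[j] - h[j]
      J[, j] <- (resection_residuals(pp, object, image, io) -
                   resection_residuals(pm, object, image, io)) / (2 * h[j])
    }
    JtJ <- crossprod(J)
    if (rcond(JtJ) < 1e-14) {
      stop("singular normal equations in space resection ",
           "(collinear or coincident control points)")
    }
    delta <- solve(JtJ, crossprod(J, res))
    ## residuals are observed - projected, so the GN update is -delta of
    ## d(residual)/d(par); J above is d(residual)/d(par) already
    step <- -as.numeric(delta)
    lambda <- 1
    repeat {
      par_new <- par + lambda * step
      res_new <- resection_residuals(par_new, object, image, io)
      sse_new <- sum(res_new^2)
      if (sse_new <= sse || lambda < 1 / 1024) break
      lambda <- lambda / 2
    }
    moved <- max(abs(lambda * step))
    par <- par_new
    res <- res_new
    sse <- sse_new
    if (moved < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop("space resection did not converge within ", max_iter, " iterations")
  }
  eo <- exterior_orientation(par[1], par[2], par[3], par[4], par[5], par[6])
  list(eo = eo,
       rms = sqrt(mean(res^2)),
       iterations = it,
       residuals = matrix(res, ncol = 2, byrow = TRUE,
                          dimnames = list(NULL, c("x", "y"))))
}

## Coefficient rows of the rearranged collinearity equations for one
## camera and many image points: a %*% (P - S) = 0, two rows per point.
intersection_rows <- function(xy, cam) {
  io <- cam$io
  eo <- cam$eo
  R <- rotation_matrix(eo$phi, eo$omega, eo$kappa)
  u <- xy[, 1] - io$x0
  v <- xy[, 2] - io$y0
  ## (x - x0) * row3 + f * row1, and same for y with row2
  a1 <- cbind(u * R[3, 1] + io$f * R[1, 1],
              u * R[3, 2] + io$f * R[1, 2],
              u * R[3, 3] + io$f * R[1, 3])
  a2 <- cbind(v * R[3, 1] + io$f * R[2, 1],
              v * R[3, 2] + io$f * R[2, 2],
              v * R[3, 3] + io$f * R[2, 3])
  s <- c(eo$Xs, eo$Ys, eo$Zs)
  list(a1 = a1, b1 = as.numeric(a1 %*% s),
       a2 = a2, b2 = as.numeric(a2 %*% s))
}

## Batched solve of 3x3 normal equations given lists of row blocks.
solve3_batch <- function(M, rhs) {
  a <- M[[1]][[1]]; b <- M[[1]][[2]]; c <- M[[1]][[3]]
  d <- M[[2]][[2]]; e <- M[[2]][[3]]; f <- M[[3]][[3]]
  det <- a * (d * f - e * e) - b * (b * f - e * c) + c * (b * e - d * c)
  i11 <- (d * f - e * e) / det
  i12 <- (c * e - b * f) / det
  i13 <- (b * e - c * d) / det
  i22 <- (a * f - c * c) / det
  i23 <- (b * c - a * e) / det
  i33 <- (a * d - b * b) / det
  X <- i11 * rhs[[1]] + i12 * rhs[[2]] + i13 * rhs[[3]]
  Y <- i12 * rhs[[1]] + i22 * rhs[[2]] + i23 * rhs[[3]]
  Z <- i13 * rhs[[1]] + i23 * rhs[[2]] + i33 * rhs[[3]]
  list(X = X, Y = Y, Z = Z, det = det)
}

## Normal-equation accumulation for a set of 2-row blocks.
accumulate_normals <- function(blocks) {
  n <- nrow(blocks[[1]]$a1)
  N <- list(list(numeric(n), numeric(n), numeric(n)),
            list(NULL, numeric(n), numeric(n)),
            list(NULL, NULL, numeric(n)))
  rhs <- list(numeric(n), numeric(n), numeric(n))
  for (blk in blocks) {
    for (rowset in list(list(a = blk$a1, b = blk$b1),
                        list(a = blk$a2, b = blk$b2))) {
      a <- rowset$a
      for (i in 1:3) {
        for (j in i:3) {
          N[[i]][[j]] <- N[[i]][[j]] + a[, i] * a[, j]
        }
        rhs[[i]] <- rhs[[i]] + a[, i] * rowset$b
      }
    }
  }
  list(N = N, rhs = rhs)
}

#' Stereopair space intersection
#'
#' Solves object coordinates from a pair of corresponding image
#' observations in an oriented stereopair: the four collinearity equations
#' (two per image) are rearranged into a linear system in `(X, Y, Z)`,
#' solved by least squares, then refined by one Gauss-Newton step on the
#' reprojection residuals. Vectorised over points.
#'
#' @param left_xy,right_xy Nx2 matrices of corresponding photo coordinates
#'   (pixels), already undistorted.
#' @param left_cam,right_cam Oriented [camera_model()] objects.
#' @return A list with `points` (Nx3 matrix, mm), `residual` (per-point
#'   RMS reprojection error over the four equations, pixels) and `rms`
#'   (overall RMS, pixels).
#' @export
space_intersection <- function(left_xy, right_xy, left_cam, right_cam) {
  left_xy <- as_xy_matrix(left_xy)
  right_xy <- as_xy_matrix(right_xy)
  stopifnot(nrow(left_xy) == nrow(right_xy))
  if (is.null(left_cam$eo) || is.null(right_cam$eo)) {
    stop("both cameras must be oriented before space intersection")
  }
  bl <- intersection_rows(left_xy, left_cam)
  br <- intersection_rows(right_xy, right_cam)
  acc <- accumulate_normals(list(bl, br))
  sol <- solve3_batch(acc$N, acc$rhs)
  ## scale-aware degeneracy check: det(N) of near-parallel rays collapses
  scale <- (rowSums(bl$a1^2) + rowSums(bl$a2^2) +
              rowSums(br$a1^2) + rowSums(br$a2^2)) / 4
  if (any(!is.finite(sol$det)) || any(abs(sol$det) < 1e-12 * scale^3)) {
    stop("degenerate geometry: rays are (near-)parallel, baseline ~ 0")
  }
  P <- cbind(X = sol$X, Y = sol$Y, Z = sol$Z)
  P <- gauss_newton_refine(P, left_xy, right_xy, left_cam, right_cam)
  prl <- project_points(P, left_cam$eo, left_cam$io)
  prr <- project_points(P, right_cam$eo, right_cam$io)
  res2 <- (prl[, 1] - left_xy[, 1])^2 + (prl[, 2] - left_xy[, 2])^2 +
    (prr[, 1] - right_xy[, 1])^2 + (prr[, 2] - right_xy[, 2])^2
  residual <- sqrt(res2 / 4)
  list(points = P, residual = residual, rms = sqrt(mean(res2 / 4)))
}

## One vectorised Gauss-Newton step on the reprojection residuals.
gauss_newton_refine <- function(P, left_xy, right_xy, left_cam, right_cam) {
  jac_blocks <- function(xy, cam) {
    io <- cam$io
    eo <- cam$eo
    R <- rotation_matrix(eo$phi, eo$omega, eo$kappa)
    d <- cbind(P[, 1] - eo$Xs, P[, 2] - eo$Ys, P[, 3] - eo$Zs)
    UVW <- d %*% t(R)
    U <- UVW[, 1]; V <- UVW[, 2]; W <- UVW[, 3]
    ## x = x0 - f U/W  =>  dx/dP = -f (W r1 - U r3) / W^2
    Jx <- -io$f * (outer(W, R[1, ]) - outer(U, R[3, ])) / W^2
    Jy <- -io$f * (outer(W, R[2, ]) - outer(V, R[3, ])) / W^2
    ex <- (io$x0 - io$f * U / W) - xy[, 1]
    ey <- (io$y0 - io$f * V / W) - xy[, 2]
    list(Jx = Jx, Jy = Jy, ex = ex, ey = ey)
  }
  L <- jac_blocks(left_xy, left_cam)
  Rr <- jac_blocks(right_xy, right_cam)
  n <- nrow(P)
  N <- list(list(numeric(n), numeric(n), numeric(n)),
            list(NULL, numeric(n), numeric(n)),
            list(NULL, NULL, numeric(n)))
  rhs <- list(numeric(n), numeric(n), numeric(n))
  for (blk in list(L, Rr)) {
    for (rowset in list(list(J = blk$Jx, e = blk$ex),
                        list(J = blk$Jy, e = blk$ey))) {
      J <- rowset$J
      for (i in 1:3) {
        for (j in i:3) N[[i]][[j]] <- N[[i]][[j]] + J[, i] * J[, j]
        rhs[[i]] <- rhs[[i]] + J[, i] * rowset$e
      }
    }
  }
  sol <- solve3_batch(N, rhs)
  ok <- is.finite(sol$det) & abs(sol$det) > 0
  step <- cbind(sol$X, sol$Y, sol$Z)
  step[!ok, ] <- 0
  P - step
}

#' Convert raster indices to photo coordinates
#'
#' The raster uses R's native 1-based `(row, col)` indices with the origin
#' at the top-left pixel centre. Photo coordinates are centre-referenced,
#' x right and y up: `x = col - (width + 1)/2`, `y = (height + 1)/2 - row`.
#' The principal-point offset is *not* applied here; it enters through the
#' collinearity equations.
#'
#' @param rc Nx2 matrix of `(row, col)` indices (may be fractional).
#' @param width,height Raster size in pixels.
#' @return Nx2 matrix of photo coordinates, columns `x`, `y`.
#' @export
raster_to_photo <- function(rc, width, height) {
  rc <- as_xy_matrix(rc)
  cbind(x = rc[, 2] - (width + 1) / 2,
        y = (height + 1) / 2 - rc[, 1])
}

#' @rdname raster_to_photo
#' @param xy Nx2 matrix of photo coordinates.
#' @export
photo_to_raster <- function(xy, width, height) {
  xy <- as_xy_matrix(xy)
  cbind(row = (height + 1) / 2 - xy[, 2],
        col = xy[, 1] + (width + 1) / 2)
}

#' Read / write a camera configuration in YAML
#'
#' The file holds keys `io: {x0, y0, f}`, `distortion: {k1, k2, k3, p1,
#' p2}`, optionally `eo: {Xs, Ys, Zs, phi, omega, kappa, angle_unit}` and
#' `image: {width, height}`. `angle_unit` may be `"radians"` (default) or
#' `"degrees"`.
#'
#' @param path File path.
#' @return A [camera_model()].
#' @export
read_camera_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  io <- interior_orientation(x0 = cfg$io$x0 %||% 0, y0 = cfg$io$y0 %||% 0,
                             f = cfg$io$f)
  d <- cfg$distortion %||% list()
  dist <- distortion_coefficients(k1 = d$k1 %||% 0, k2 = d$k2 %||% 0,
                                  k3 = d$k3 %||% 0, p1 = d$p1 %||% 0,
                                  p2 = d$p2 %||% 0)
  eo <- NULL
  if (!is.null(cfg$eo)) {
    unit <- cfg$eo$angle_unit %||% "radians"
    k <- if (identical(unit, "degrees")) pi / 180 else 1
    eo <- exterior_orientation(cfg$eo$Xs, cfg$eo$Ys, cfg$eo$Zs,
                               (cfg$eo$phi %||% 0) * k,
                               (cfg$eo$omega %||% 0) * k,
                               (cfg$eo$kappa %||% 0) * k)
  }
  camera_model(io, eo, dist,
               width = cfg$image$width, height = cfg$image$height)
}

#' @rdname read_camera_yaml
#' @param cam A [camera_model()].
#' @export
write_camera_yaml <- function(cam, path) {
  cfg <- list(io = cam$io[c("x0", "y0", "f")],
              distortion = cam$distortion[c("k1", "k2", "k3", "p1", "p2")],
              image = list(width = cam$width, height = cam$height))
  if (!is.null(cam$eo)) {
    cfg$eo <- c(cam$eo[c("Xs", "Ys", "Zs", "phi", "omega", "kappa")],
                list(angle_unit = "radians"))
  }
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
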