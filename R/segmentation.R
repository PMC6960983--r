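#' Convert an RGB raster to grayscale
#'
#' Weighted channel sum `0.2989 R + 0.5870 G + 0.1140 B` (the standard
#' luma weights). Single-channel input is passed through unchanged.
#'
#' @param image Numeric matrix (grayscale) or `h x w x 3` array.
#' @return Numeric matrix.
#' @export
to_gray <- function(image) {
  if (is.matrix(image)) return(image)
  d <- dim(image)
  if (length(d) == 3 && d[3] == 3) {
    return(0.2989 * image[, , 1] + 0.5870 * image[, , 2] +
             0.1140 * image[, , 3])
  }
  stop("to_gray expects a matrix or a 3-channel array, got ",
       paste(d, collapse = "x"))
}

#' Median filter with edge-replicated padding
#'
#' Each output pixel is the median of its `kernel x kernel` neighbourhood;
#' pixels beyond the border are replicated from the nearest edge pixel.
#' Implemented as a vectorised insertion-sort network over the shifted
#' image planes, so cost grows with `kernel^4` but is independent of
#' content; the default 3x3 kernel is the practical choice for speckle
#' noise on a plain background.
#'
#' @param image Numeric matrix.
#' @param kernel Odd window size `>= 3`.
#' @return Filtered matrix of the same size.
#' @export
median_denoise <- function(image, kernel = 3) {
  stopifnot(is.matrix(image))
  if (kernel %% 2 != 1 || kernel < 3) {
    stop("median kernel must be an odd integer >= 3")
  }
  nr <- nrow(image)
  nc <- ncol(image)
  if (kernel == 3) {
    ## exact 3x3 median by the column min/median/max decomposition:
    ## med9 = med3(max3(col mins), med3(col medians), min3(col maxs))
    N <- nr * nc
    m0 <- as.numeric(image)
    up <- as.numeric(image[c(1L, seq_len(nr - 1L)), , drop = FALSE])
    dn <- as.numeric(image[c(2:nr, nr), , drop = FALSE])
    vmin <- pmin.int(pmin.int(up, m0), dn)
    vmax <- pmax.int(pmax.int(up, m0), dn)
    vmed <- up + m0 + dn - vmin - vmax
    lf_idx <- c(seq_len(nr), seq_len(N - nr))          # replicate first col
    rt_idx <- c((nr + 1L):N, (N - nr + 1L):N)          # replicate last col
    a <- pmax.int(pmax.int(vmin[lf_idx], vmin), vmin[rt_idx])
    lfm <- vmed[lf_idx]; rtm <- vmed[rt_idx]
    bmn <- pmin.int(pmin.int(lfm, vmed), rtm)
    bmx <- pmax.int(pmax.int(lfm, vmed), rtm)
    b <- lfm + vmed + rtm - bmn - bmx
    c3 <- pmin.int(pmin.int(vmax[lf_idx], vmax), vmax[rt_idx])
    mn <- pmin.int(pmin.int(a, b), c3)
    mx <- pmax.int(pmax.int(a, b), c3)
    return(matrix(a + b + c3 - mn - mx, nr, nc))
  }
  r <- (kernel - 1) / 2
  n <- kernel * kernel
  planes <- vector("list", n)
  idx <- 1
  for (dr in -r:r) {
    rows <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
    for (dc in -r:r) {
      cols <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
      planes[[idx]] <- image[rows, cols, drop = FALSE]
      idx <- idx + 1
    }
  }
  sort2 <- function(i, j) {
    lo <- pmin(planes[[i]], planes[[j]])
    planes[[j]] <<- pmax(planes[[i]], planes[[j]])
    planes[[i]] <<- lo
  }
  if (n == 9) {
    ## 19-exchange median-of-9 selection network
    net <- list(c(2,3), c(5,6), c(8,9), c(1,2), c(4,5), c(7,8), c(2,3),
                c(5,6), c(8,9), c(1,4), c(6,9), c(5,8), c(4,7), c(2,5),
                c(3,6), c(5,8), c(5,3), c(7,5), c(5,3))
    for (p in net) sort2(p[1], p[2])
    planes[[5]]
  } else {
    ## vectorised insertion-sort network for larger windows
    for (i in 2:n) {
      for (j in i:2) sort2(j - 1, j)
    }
    planes[[(n + 1) / 2]]
  }
}

#' Otsu threshold
#'
#' Exhaustive scan over a 256-bin histogram for the threshold maximising
#' the between-class variance. Values are expected in `[0, 1]`; inputs on
#' a 0-255 integer scale are normalised automatically.
#'
#' @param image Numeric matrix with at least two distinct values.
#' @param levels Number of histogram bins (default 256).
#' @return The threshold, on the same scale as the input.
#' @export
otsu_threshold <- function(image, levels = 256) {
  v <- as.numeric(image)
  scale <- if (max(v) > 1) 255 else 1
  v <- v / scale
  if (max(v) - min(v) < .Machine$double.eps) {
    stop("cannot threshold a constant image")
  }
  breaks <- seq(0, 1, length.out = levels + 1)
  v[v < 0] <- 0
  v[v > 1] <- 1
  h <- tabulate(pmin(floor(v * levels) + 1, levels), nbins = levels)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(levels + 1)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[levels]
  ## between-class variance for threshold after bin k
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b)
  breaks[k + 1] * scale
}

#' Otsu binarisation
#'
#' Thresholds the image with [otsu_threshold()]. With `polarity =
#' "bright"` (default) pixels above the threshold become foreground 1
#' (the grains) and the rest background 0; `"dark"` inverts this.
#'
#' @inheritParams otsu_threshold
#' @param polarity `"bright"` or `"dark"` foreground.
#' @return A list with `binary` (0/1 integer matrix) and `threshold`.
#' @export
otsu_binarize <- function(image, polarity = c("bright", "dark")) {
  polarity <- match.arg(polarity)
  thr <- otsu_threshold(image)
  b <- if (polarity == "bright") image > thr else image < thr
  list(binary = matrix(as.integer(b), nrow(image), ncol(image)),
       threshold = thr)
}

#' 8-connected component labelling
#'
#' Labels foreground components using 8-connectivity (diagonal neighbours
#' belong to the same component). Built on 4-connected flood labelling
#' with a union-find pass merging diagonally touching labels.
#'
#' @param binary 0/1 matrix.
#' @return Integer matrix of labels (0 = background).
#' @export
label_components <- function(binary) {
  stopifnot(is.matrix(binary))
  lab <- EBImage::bwlabel(binary)
  lab <- matrix(as.integer(lab), nrow(binary), ncol(binary))
  nlab <- max(lab)
  if (nlab <= 1) return(lab)
  nr <- nrow(lab)
  nc <- ncol(lab)
  ## diagonal neighbour label pairs (only differing positive labels kept)
  diag_pairs <- function(a, b) {
    sel <- a > 0L & b > 0L & a != b
    cbind(a[sel], b[sel])
  }
  pairs <- rbind(diag_pairs(lab[-nr, -nc], lab[-1, -1]),
                 diag_pairs(lab[-nr, -1], lab[-1, -nc]))
  parent <- seq_len(nlab)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(pairs) > 0) {
    pairs <- unique(pairs)
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1])
      b <- find(pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- dense[lab[lab > 0]]
  out
}

#' Filter connected components by area
#'
#' Labels the binary image with 8-connectivity and removes components
#' whose area falls outside `[min_area, max_area]` — broken fragments
#' below, clumps of touching grains above. When limits are not given they
#' default to `[0.2, 3] x` the median component area, a self-scaling rule
#' for images whose absolute scale is unknown.
#'
#' @param binary 0/1 matrix.
#' @param min_area,max_area Area limits in pixels, or `NULL` for the
#'   self-scaling defaults.
#' @param exclude Optional 0/1 matrix: components overlapping it are
#'   dropped before the area statistics are computed.
#' @return A list of regions, each with `label`, `area` and `centroid`
#'   (`(row, col)`, sub-pixel); the relabelled matrix is attached as
#'   attribute `labels`.
#' @export
filter_by_area <- function(binary, min_area = NULL, max_area = NULL,
                           exclude = NULL) {
  lab <- label_components(binary)
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  excluded <- integer(0)
  if (!is.null(exclude) && length(areas) > 0) {
    excluded <- unique(lab[exclude > 0 & lab > 0])
  }
  alive <- setdiff(seq_along(areas), excluded)
  if (length(alive) == 0) {
    out <- list()
    attr(out, "labels") <- matrix(0L, nrow(lab), ncol(lab))
    return(out)
  }
  med <- stats::median(areas[alive])
  if (is.null(min_area)) min_area <- 0.2 * med
  if (is.null(max_area)) max_area <- 3.0 * med
  keep <- alive[areas[alive] >= min_area & areas[alive] <= max_area]
  regions <- vector("list", length(keep))
  nr <- nrow(lab)
  idx <- which(lab > 0)
  l <- lab[idx]
  rows <- ((idx - 1) %% nr) + 1
  cols <- ((idx - 1) %/% nr) + 1
  out_lab <- matrix(0L, nr, ncol(lab))
  for (i in seq_along(keep)) {
    k <- keep[i]
    sel <- l == k
    regions[[i]] <- list(
      label = i,
      area = areas[k],
      centroid = c(row = mean(rows[sel]), col = mean(cols[sel]))
    )
    out_lab[idx[sel]] <- i
  }
  attr(regions, "labels") <- out_lab
  regions
}

## Moore neighbourhood in clockwise raster order starting east.
moore_dr <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
moore_dc <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)

#' Trace the ordered closed boundary of a region
#'
#' Moore-neighbour tracing with Jacob's stopping criterion on a single
#' filled component. The returned boundary is ordered counter-clockwise in
#' the photo frame (x right, y up), i.e. its signed area in photo
#' coordinates is positive; no point repeats except implicit closure
#' (first follows last).
#'
#' @param mask 0/1 matrix containing one 8-connected component (holes are
#'   filled internally).
#' @return Nx2 integer matrix of `(row, col)` boundary pixel positions.
#' @export
trace_boundary <- function(mask) {
  stopifnot(is.matrix(mask))
  if (sum(mask > 0) < 5) {
    stop("component too small to trace (area < 5 px)")
  }
  m <- EBImage::fillHull(matrix(as.integer(mask > 0), nrow(mask), ncol(mask)))
  m <- matrix(as.integer(m), nrow(mask), ncol(mask))
  nr <- nrow(m)
  nc <- ncol(m)
  inside <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc && m[r, c] > 0
  ## start: first foreground pixel in column-major order = leftmost column,
  ## topmost row within it; its west neighbour is guaranteed background
  start_idx <- which(m > 0)[1]
  sr <- ((start_idx - 1) %% nr) + 1
  sc <- ((start_idx - 1) %/% nr) + 1
  boundary_r <- integer(0)
  boundary_c <- integer(0)
  r <- sr; c <- sc
  ## backtrack direction: we entered from the west (index 5 in moore order)
  dir_from <- 5L   # neighbour index of the backtrack pixel
  first_dir <- NA_integer_
  repeat {
    boundary_r <- c(boundary_r, r)
    boundary_c <- c(boundary_c, c)
    found <- FALSE
    ## scan clockwise starting just after the backtrack direction
    for (s in 1:8) {
      d <- ((dir_from + s - 1L) %% 8L) + 1L
      rr <- r + moore_dr[d]
      cc <- c + moore_dc[d]
      if (inside(rr, cc)) {
        ## new backtrack = the previously checked (background) neighbour,
        ## expressed as a direction from the new pixel
        prev <- ((dir_from + s - 2L) %% 8L) + 1L
        pr <- r + moore_dr[prev]
        pc <- c + moore_dc[prev]
        dr_new <- pr - rr
        dc_new <- pc - cc
        dir_from <- which(moore_dr == dr_new & moore_dc == dc_new)
        if (length(boundary_r) == 1) first_dir <- d
        r <- rr; c <- cc
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated blob (cannot happen for area >= 5 unless 1 px wide)
    ## Jacob's criterion: stop when re-entering the start pixel the same way
    if (r == sr && c == sc) {
      ## check next move repeats the first move
      for (s in 1:8) {
        d <- ((dir_from + s - 1L) %% 8L) + 1L
        rr <- r + moore_dr[d]
        cc <- c + moore_dc[d]
        if (inside(rr, cc)) break
      }
      if (d == first_dir) break
    }
    if (length(boundary_r) > 8 * (nr + nc)) {
      stop("boundary tracing failed to terminate")  # defensive; should not occur
    }
  }
  b <- cbind(row = boundary_r, col = boundary_c)
  ## drop consecutive duplicates of the closure point
  if (nrow(b) > 1 && all(b[nrow(b), ] == b[1, ])) b <- b[-nrow(b), , drop = FALSE]
  ## Moore tracing with clockwise scan runs counter-clockwise in raster
  ## terms; enforce CCW in the *photo* frame (y up): signed area > 0
  xy <- cbind(b[, 2], -b[, 1])
  n <- nrow(b)
  if (n >= 3) {
    nxt <- c(2:n, 1)
    area2 <- sum(xy[, 1] * xy[nxt, 2] - xy[nxt, 1] * xy[, 2])
    if (area2 < 0) b <- b[n:1, , drop = FALSE]
  }
  b
}

#' Binary centroid of a region
#'
#' Unweighted mean of the member pixel coordinates.
#'
#' @param mask 0/1 matrix, or an Nx2 matrix of `(row, col)` pixel
#'   positions.
#' @return Length-2 vector `(row, col)`.
#' @export
region_centroid <- function(mask) {
  if (is.matrix(mask) && ncol(mask) == 2 && !all(mask %in% c(0, 1))) {
    px <- mask
  } else {
    idx <- which(mask > 0)
    if (length(idx) == 0) stop("empty region")
    nr <- nrow(mask)
    px <- cbind(((idx - 1) %% nr) + 1, ((idx - 1) %/% nr) + 1)
  }
  c(row = mean(px[, 1]), col = mean(px[, 2]))
}

#' Segment grain regions from one image
#'
#' The extraction chain: grayscale conversion, median denoising, Otsu
#' binarisation, optional exclusion mask (e.g. the calibration circles),
#' 8-connected labelling with area filtering, hole filling and ordered
#' boundary tracing.
#'
#' @param image Matrix or RGB array, values in `[0, 1]`.
#' @param median_kernel Odd median window (default 3); `0` skips
#'   denoising.
#' @param min_area,max_area Component area limits in pixels (`NULL` for
#'   the self-scaling `[0.2, 3] x` median-area rule).
#' @param exclude Optional 0/1 matrix; any component overlapping it is
#'   dropped (used to remove the board's calibration circles, which are
#'   bright like the grains).
#' @param polarity Foreground polarity for the binarisation.
#' @return A list of `grain_region` objects (`label`, `area`, `centroid`
#'   `(row, col)`, `boundary` Nx2 raster matrix), with attributes
#'   `image_dim` (image size) and `threshold`.
#' @export
segment_grains <- function(image, median_kernel = 3, min_area = NULL,
                           max_area = NULL, exclude = NULL,
                           polarity = "bright") {
  g <- to_gray(image)
  if (median_kernel >= 3) g <- median_denoise(g, median_kernel)
  bin <- otsu_binarize(g, polarity = polarity)
  regions <- filter_by_area(bin$binary, min_area = min_area,
                            max_area = max_area, exclude = exclude)
  lab <- attr(regions, "labels")
  nr <- nrow(lab)
  out <- lapply(regions, function(rg) {
    idx <- which(lab == rg$label)
    rows <- ((idx - 1) %% nr) + 1
    cols <- ((idx - 1) %/% nr) + 1
    r0 <- min(rows) - 1L
    c0 <- min(cols) - 1L
    sub <- matrix(0L, max(rows) - r0 + 1L, max(cols) - c0 + 1L)
    sub[cbind(rows - r0, cols - c0)] <- 1L
    b <- trace_boundary(sub)
    rg$boundary <- cbind(row = b[, 1] + r0, col = b[, 2] + c0)
    class(rg) <- "grain_region"
    rg
  })
  attr(out, "image_dim") <- dim(g)
  attr(out, "threshold") <- bin$threshold
  out
}
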