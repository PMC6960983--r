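config_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("grainstereo_config_error",
                                             "error", "condition")))
}

require_files <- function(...) {
  paths <- c(...)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    config_error("missing input file(s): ", paste(missing, collapse = ", "))
  }
  invisible(paths)
}

#' Orient command: resect both cameras from the board
#'
#' Reads the stereo pair, the board layout and the shared interior
#' orientation, runs circle detection, ordering and space resection per
#' image, and writes one oriented camera YAML per image into `out_dir`.
#'
#' @param left,right Image paths.
#' @param board_yaml Board layout YAML path.
#' @param camera_yaml Camera YAML path holding `io`, `distortion` and
#'   `image` size (any `eo` present is ignored).
#' @param out_dir Output directory.
#' @param px_per_mm Optional approximate board-plane scale (px/mm).
#' @return Invisibly, a list with the two written paths and the two
#'   resection RMS values (pixels).
#' @export
cmd_orient <- function(left, right, board_yaml, camera_yaml, out_dir = ".",
                       px_per_mm = NULL) {
  require_files(left, right, board_yaml, camera_yaml)
  board <- read_board_yaml(board_yaml)
  cam <- read_camera_yaml(camera_yaml)
  cam$eo <- NULL
  ori <- orient_stereo(left, right, board, cam, cam, px_per_mm = px_per_mm)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pl <- file.path(out_dir, "camera_left.yaml")
  pr <- file.path(out_dir, "camera_right.yaml")
  write_camera_yaml(ori$left, pl)
  write_camera_yaml(ori$right, pr)
  message(sprintf("resection RMS: left %.4f px, right %.4f px",
                  ori$rms_left, ori$rms_right))
  invisible(list(camera_left = pl, camera_right = pr,
                 rms_left = ori$rms_left, rms_right = ori$rms_right))
}

#' Measure command: full thickness pipeline on an oriented pair
#'
#' @param left,right Image paths.
#' @param camera_left,camera_right Oriented camera YAML paths.
#' @param board_yaml Optional board layout YAML (circles are then masked
#'   out of the grain candidates).
#' @param out Output CSV path for the thickness report.
#' @param overlay Optional path prefix; when given, a matched-points
#'   overlay PNG is written per grain pair composite.
#' @param ... Passed to [measure_thickness()].
#' @return The `thickness_report`, invisibly.
#' @export
cmd_measure <- function(left, right, camera_left, camera_right,
                        board_yaml = NULL, out = "thickness.csv",
                        overlay = NULL, ...) {
  require_files(left, right, camera_left, camera_right)
  if (!is.null(board_yaml)) require_files(board_yaml)
  lcam <- read_camera_yaml(camera_left)
  rcam <- read_camera_yaml(camera_right)
  if (is.null(lcam$eo) || is.null(rcam$eo)) {
    config_error("camera files must contain exterior orientation; ",
                 "run the orient step first")
  }
  board <- if (!is.null(board_yaml)) read_board_yaml(board_yaml) else NULL
  limg <- read_raster(left)
  rimg <- read_raster(right)
  report <- measure_thickness(limg, rimg, lcam, rcam, board = board, ...)
  write_thickness_csv(report, out)
  if (!is.null(overlay)) {
    write_match_overlay(limg, rimg, lcam, rcam, report,
                        paste0(overlay, "_matches.png"))
  }
  print(report)
  invisible(report)
}

#' Simulate command: write a synthetic fixture bundle
#'
#' @param out_dir Output directory for the bundle.
#' @param n_grains,H,delta,seed Scene parameters, see [sample_scene()].
#' @param baseline Stereo baseline (mm), used when no `rig` is given.
#' @param rig Optional rig (see [default_rig()]).
#' @param ... Passed to [sample_scene()].
#' @return The `scene_truth`, invisibly.
#' @export
cmd_simulate <- function(out_dir, n_grains = 20, H = 1.8, delta = 0.15,
                         baseline = 80, seed = 1, rig = NULL, ...) {
  if (is.null(rig)) rig <- default_rig(baseline = baseline)
  scene <- sample_scene(n_grains = n_grains, H = H, delta = delta,
                        rig = rig, seed = seed, ...)
  write_scene_bundle(scene, out_dir)
  invisible(scene)
}

#' Evaluate command: synthetic sweeps with error curves
#'
#' Runs the full pipeline over synthetic scenes: a single scored scene,
#' a sweep over the number of grains, or a sweep over the stereo
#' baseline, and writes the error table as CSV.
#'
#' @param mode `"single"`, `"samples"` or `"baseline"`.
#' @param out Output CSV path.
#' @param seed Base seed.
#' @param ... Passed to the underlying sweep / scene functions.
#' @return The result data.frame, invisibly.
#' @export
cmd_evaluate <- function(mode = c("single", "samples", "baseline"),
                         out = "evaluate.csv", seed = 1, ...) {
  mode <- match.arg(mode)
  res <- switch(mode,
    single = {
      ev <- evaluate_pipeline(sample_scene(seed = seed, ...))
      data.frame(thickness = ev$thickness, true_H = ev$true_H,
                 error = ev$error, rms_left = ev$rms_left,
                 rms_right = ev$rms_right)
    },
    samples = sweep_sample_size(seed = seed, ...),
    baseline = sweep_baseline(seed = seed, ...)
  )
  utils::write.csv(res, out, row.names = FALSE)
  invisible(res)
}

## Draw a line segment into an RGB array by dense interpolation.
draw_segment <- function(img, r0, c0, r1, c1, color) {
  n <- max(2, ceiling(max(abs(r1 - r0), abs(c1 - c0))) * 2)
  rr <- round(seq(r0, r1, length.out = n))
  cc <- round(seq(c0, c1, length.out = n))
  ok <- rr >= 1 & rr <= dim(img)[1] & cc >= 1 & cc <= dim(img)[2]
  for (ch in 1:3) {
    img[cbind(rr[ok], cc[ok], ch)] <- color[ch]
  }
  img
}

#' Write a matched-edge-points overlay image
#'
#' Places the two images side by side and joins every 15th matched edge
#' point pair with a line, for visual inspection of the correspondence.
#'
#' @param left_img,right_img Gray image matrices.
#' @param left_cam,right_cam The camera models (for the photo-to-raster
#'   conversion).
#' @param report A `thickness_report` carrying `correspondences`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_match_overlay <- function(left_img, right_img, left_cam, right_cam,
                                report, path) {
  lg <- to_gray(left_img)
  rg <- to_gray(right_img)
  h <- max(nrow(lg), nrow(rg))
  canvas <- matrix(0, h, ncol(lg) + ncol(rg))
  canvas[seq_len(nrow(lg)), seq_len(ncol(lg))] <- lg
  canvas[seq_len(nrow(rg)), ncol(lg) + seq_len(ncol(rg))] <- rg
  rgb <- array(rep(canvas, 3), c(dim(canvas), 3))
  yellow <- c(1, 0.9, 0)
  for (cp in attr(report, "correspondences")) {
    lrc <- photo_to_raster(cp$left_xy, left_cam$width, left_cam$height)
    rrc <- photo_to_raster(cp$right_xy, right_cam$width, right_cam$height)
    for (i in seq(1, 360, by = 15)) {
      rgb <- draw_segment(rgb, lrc[i, 1], lrc[i, 2],
                          rrc[i, 1], rrc[i, 2] + ncol(lg), yellow)
    }
  }
  write_raster(rgb, path)
  invisible(path)
}
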