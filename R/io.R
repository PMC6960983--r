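#' Read a raster image
#'
#' Reads PNG or TIFF (8- or 16-bit, grayscale or RGB) into a numeric
#' matrix (grayscale) or `height x width x channels` array with values in
#' `[0, 1]`. An alpha channel, if present, is dropped.
#'
#' @param path File path; format chosen by extension.
#' @return A numeric matrix or 3-d array.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported raster format: .", ext, " (use PNG or TIFF)")
  )
  if (length(dim(img)) == 3 && dim(img)[3] == 4) img <- img[, , 1:3]
  if (length(dim(img)) == 3 && dim(img)[3] == 2) img <- img[, , 1]
  if (length(dim(img)) == 3 && dim(img)[3] == 1) img <- img[, , 1]
  img
}

#' Write a raster image
#'
#' @param img Matrix or array with values in `[0, 1]`.
#' @param path Output path (`.png`, `.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @export
write_raster <- function(img, path) {
  img[img < 0] <- 0
  img[img > 1] <- 1
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 16L),
    stop("unsupported raster format: .", ext, " (use PNG or TIFF)")
  )
  invisible(path)
}
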