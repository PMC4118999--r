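#' Grayscale 2DE gel image
#'
#' Container for a single two-dimensional electrophoresis (2DE) gel scan.
#' Pixels are stored as a numeric matrix on the native digitisation scale,
#' i.e. `0 .. 2^bit_depth - 1`. Silver-stained gels scanned on a densitometer
#' show dark spots on a light background, which is the default polarity;
#' all intensity measurements first polarity-correct the image so that spots
#' carry *high* corrected values (see [corrected_pixels()]).
#'
#' @param pixels numeric matrix of nonnegative intensities, at least 32 x 32.
#' @param bit_depth integer, 8 or 16.
#' @param sample_id,replicate_id character identifiers for the biological
#'   sample and the technical run.
#' @param polarity `"dark-on-light"` (silver stain scans, default) or
#'   `"light-on-dark"` (e.g. fluorescence or synthetic renders).
#'
#' @return An object of class `gel_image`: a list with elements `pixels`,
#'   `bit_depth`, `sample_id`, `replicate_id`, `polarity`.
#' @export
#' @examples
#' img <- gel_image(matrix(100, 40, 40), bit_depth = 8)
#' dim(img$pixels)
gel_image <- function(pixels, bit_depth = 16, sample_id = "", replicate_id = "",
                      polarity = c("dark-on-light", "light-on-dark")) {
  polarity <- match.arg(polarity)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (any(dim(pixels) < 32L))
    stop("gel image must be at least 32 x 32 pixels")
  if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16")
  maxval <- 2^bit_depth - 1
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > maxval)
    stop("pixel intensities must lie in [0, 2^bit_depth - 1]")
  structure(
    list(pixels = pixels, bit_depth = as.integer(bit_depth),
         sample_id = sample_id, replicate_id = replicate_id,
         polarity = polarity),
    class = "gel_image"
  )
}

#' @export
print.gel_image <- function(x, ...) {
  cat(sprintf("gel_image: %d x %d px, %d-bit, %s, sample='%s' replicate='%s'\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth, x$polarity,
              x$sample_id, x$replicate_id))
  invisible(x)
}

#' Polarity-corrected pixel matrix
#'
#' Returns pixels transformed so that protein spots have high values:
#' dark-on-light images are inverted as `max(pixels) - pixels` (using the
#' observed image maximum so that rescaling the image rescales corrected
#' values proportionally); light-on-dark images are returned as is.
#'
#' @param image a [gel_image()].
#' @return numeric matrix, same dimensions as `image$pixels`.
#' @export
corrected_pixels <- function(image) {
  stopifnot(inherits(image, "gel_image"))
  if (image$polarity == "dark-on-light") max(image$pixels) - image$pixels
  else image$pixels
}

#' Read / write gel images
#'
#' Thin wrappers around the **png** and **tiff** packages. Images are read
#' as grayscale; RGB input with identical channels is collapsed, anything
#' else is rejected. On disk intensities live in `[0, 1]`; they are scaled
#' to the native `0 .. 2^bit_depth - 1` range in memory.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @param bit_depth bit depth to assume for the in-memory scale.
#' @param ... passed to [gel_image()] (ids, polarity).
#' @return `read_gel_image()` returns a [gel_image()]; `write_gel_image()`
#'   returns `path` invisibly.
#' @export
read_gel_image <- function(path, bit_depth = 16, ...) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext)
  )
  if (length(dim(arr)) == 3L) {
    ch <- dim(arr)[3L]
    flat <- matrix(arr, ncol = ch)
    if (!all(abs(flat - flat[, 1L]) < 1e-9))
      stop("non-grayscale image: channels differ")
    arr <- arr[, , 1L]
  }
  gel_image(arr * (2^bit_depth - 1), bit_depth = bit_depth, ...)
}

#' @rdname read_gel_image
#' @param image a [gel_image()] to write.
#' @export
write_gel_image <- function(image, path) {
  stopifnot(inherits(image, "gel_image"))
  ext <- tolower(tools::file_ext(path))
  norm <- image$pixels / (2^image$bit_depth - 1)
  switch(ext,
    png = png::writePNG(norm, path),
    tif = ,
    tiff = tiff::writeTIFF(norm, path, bits.per.sample = image$bit_depth),
    stop("unsupported image format: .", ext)
  )
  invisible(path)
}
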