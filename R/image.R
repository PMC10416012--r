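# RGB image container and Beer-Lambert optical-density transforms.
#
# Images live in memory as real-valued H x W x 3 arrays on the 0..i0 intensity
# scale (i0 = white point, 255 by default). On disk they are 8-bit PNG.

#' Construct an RGB image
#'
#' @param pixels numeric H x W x 3 array with finite values in \[0, i0\]
#' @param i0 white-point intensity (default 255)
#' @return an `rgb_image` object (the array, with an `i0` attribute)
#' @export
rgb_image <- function(pixels, i0 = 255) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop_stainpipe("invalid_input", "pixels must be an H x W x 3 array")
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop_stainpipe("invalid_input", "image must have H >= 1, W >= 1")
  if (!all(is.finite(pixels)))
    stop_stainpipe("invalid_input", "non-finite pixel values")
  if (min(pixels) < 0 || max(pixels) > i0)
    stop_stainpipe("invalid_input", sprintf(
      "pixel intensities must lie in [0, %g]", i0))
  structure(pixels, i0 = i0, class = "rgb_image")
}

is_rgb_image <- function(x) inherits(x, "rgb_image")

img_i0 <- function(img) {
  i0 <- attr(img, "i0")
  if (is.null(i0)) 255 else i0
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image %d x %d, i0 = %g, range [%.1f, %.1f]>\n",
              d[1], d[2], img_i0(x), min(x), max(x)))
  invisible(x)
}

#' Convert RGB intensities to optical density (base-10 Beer-Lambert)
#'
#' OD = -log10(I / i0). Intensities are floored at `min_intensity` before the
#' log so that fully dark pixels map to a finite maximum density rather than
#' infinity; the white point maps exactly to OD 0.
#'
#' @param img an [rgb_image()]
#' @param min_intensity positive intensity floor (default 1 on the 0-255 scale)
#' @return an `od_image`: H x W x 3 array of non-negative densities
#' @export
rgb_to_od <- function(img, min_intensity = 1) {
  if (!all(is.finite(img)))
    stop_stainpipe("invalid_input", "non-finite pixel values")
  i0 <- img_i0(img)
  p <- pmin(pmax(unclass(img), min_intensity), i0)
  od <- -log10(p / i0)
  structure(od, i0 = i0, class = "od_image")
}

#' Convert an optical-density image back to RGB
#'
#' I = i0 * 10^(-OD), clipped to \[0, i0\].
#'
#' @param od an `od_image` (or bare non-negative H x W x 3 array)
#' @param i0 white point; defaults to the array's `i0` attribute or 255
#' @return an [rgb_image()]
#' @export
od_to_rgb <- function(od, i0 = NULL) {
  if (is.null(i0)) i0 <- if (!is.null(attr(od, "i0"))) attr(od, "i0") else 255
  if (!all(is.finite(od)) || min(od) < 0)
    stop_stainpipe("invalid_input", "OD values must be finite and >= 0")
  rgb_image(pmin(pmax(i0 * 10^(-unclass(od)), 0), i0), i0 = i0)
}

#' Rec. 601 luminance of an RGB image
#' @param img an [rgb_image()]
#' @return H x W numeric matrix on the image's intensity scale
#' @export
luminance <- function(img) {
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# PNG I/O ---------------------------------------------------------------------

#' Read an 8-bit RGB PNG as an [rgb_image()]
#' @param path file path
#' @export
read_image <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  rgb_image(a * 255, i0 = 255)
}

#' Write an [rgb_image()] as an 8-bit PNG
#' @param img image; quantized by rounding to 0..255
#' @param path file path
#' @export
write_image <- function(img, path) {
  i0 <- img_i0(img)
  png::writePNG(round(unclass(img) / i0 * 255) / 255, path)
  invisible(path)
}
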