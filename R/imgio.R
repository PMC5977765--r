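# Image container, I/O, histograms and contrast enhancement.

#' Grayscale image with physical scale metadata
#'
#' Construct the basic image container used throughout the package: an integer
#' brightness matrix (rows = image rows, columns = image columns, values in
#' 0--255) together with the metric scale of a pixel and a free-text
#' magnification tag.
#'
#' @param pixels numeric matrix of brightness values in `[0, 255]`; fractional
#'   values are rounded.
#' @param scale physical size of one pixel, in micrometres per pixel; must be
#'   positive.
#' @param magnification free-text magnification tag, e.g. `"300x"`.
#' @return An object of class `gray_image`: a list with elements `pixels`
#'   (integer matrix), `scale`, `magnification`. The total pixel count is
#'   `length(img$pixels)`.
#' @examples
#' img <- gray_image(matrix(c(0, 255, 10, 250), 2, 2), scale = 0.1)
#' range(img$pixels)
#' @export
gray_image <- function(pixels, scale = 1, magnification = NA_character_) {
  if (!is.matrix(pixels) || length(pixels) == 0L)
    stop("'pixels' must be a non-empty matrix")
  px <- round(pixels)
  if (anyNA(px) || any(px < 0) || any(px > 255))
    stop("brightness values must lie in [0, 255]")
  if (!is.numeric(scale) || length(scale) != 1L || is.na(scale) || scale <= 0)
    stop("'scale' (μm per pixel) must be a single positive number")
  storage.mode(px) <- "integer"
  structure(
    list(pixels = px, scale = scale,
         magnification = as.character(magnification)),
    class = "gray_image"
  )
}

#' @export
print.gray_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("gray_image: %d x %d px, scale %g um/px, magnification %s\n",
              d[2], d[1], x$scale, x$magnification))
  cat(sprintf("  brightness range [%d, %d]\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

#' Read a grayscale SEM image from PNG or TIFF
#'
#' RGB inputs are converted to luminance with the standard Rec. 601 weights
#' (0.299, 0.587, 0.114); SEM micrographs are effectively monochrome so the
#' exact weights are immaterial, but the conversion is deterministic.
#'
#' @param path path to a PNG or TIFF file (single-channel or RGB, 8-bit).
#' @param scale micrometres per pixel.
#' @param magnification free-text tag attached as metadata.
#' @return A [gray_image()].
#' @seealso [write_image()]
#' @export
read_image <- function(path, scale = 1, magnification = NA_character_) {
  if (!file.exists(path)) stop("cannot read image: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '", ext, "' (PNG or TIFF expected)")
  )
  if (length(arr) == 0L) stop("zero-sized image: ", path)
  if (length(dim(arr)) == 3L) {
    ch <- dim(arr)[3]
    if (ch >= 3L) {
      arr <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      arr <- arr[, , 1]
    }
  }
  gray_image(round(arr * 255), scale = scale, magnification = magnification)
}

#' Write a grayscale image to PNG or TIFF
#'
#' @param img a [gray_image()].
#' @param path destination path; format chosen from the extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "gray_image"))
  ext <- tolower(tools::file_ext(path))
  norm <- img$pixels / 255
  switch(ext,
    png = png::writePNG(norm, target = path),
    tif = ,
    tiff = tiff::writeTIFF(norm, where = path, bits.per.sample = 8L),
    stop("unsupported image format '", ext, "'")
  )
  invisible(path)
}

#' Brightness histogram of an image
#'
#' With `bin_width = 1` there is one bin per gray level (0--255). With
#' `bin_width = 10` the scale is divided into coarse sub-intervals of 10 units
#' (0--9, 10--19, ..., with the last bin truncated at 255), the form used to
#' inspect whether the brightest bin dominates the histogram when choosing the
#' brightness margin epsilon.
#'
#' @param img a [gray_image()], or a plain numeric vector of brightness values
#'   (e.g. a profile) in `[0, 255]`.
#' @param bin_width 1 or 10.
#' @return An object of class `brightness_histogram`: a list with `bin_lo`,
#'   `bin_hi` (inclusive bounds), `counts`, and `bin_width`. Counts always sum
#'   to the number of samples histogrammed.
#' @export
brightness_histogram <- function(img, bin_width = 1) {
  beta <- if (inherits(img, "gray_image")) as.vector(img$pixels)
          else as.vector(img)
  if (length(beta) == 0L) stop("nothing to histogram")
  if (any(beta < 0 | beta > 255)) stop("brightness values outside [0, 255]")
  if (!bin_width %in% c(1, 10)) stop("'bin_width' must be 1 or 10")
  if (bin_width == 1) {
    lo <- 0:255
    hi <- 0:255
  } else {
    lo <- seq(0L, 250L, by = 10L)
    hi <- pmin(lo + 9L, 255L)
  }
  idx <- pmin(floor(beta / bin_width), length(lo) - 1L)
  counts <- tabulate(idx + 1L, nbins = length(lo))
  structure(list(bin_lo = lo, bin_hi = hi, counts = counts,
                 bin_width = bin_width),
            class = "brightness_histogram")
}

#' @export
print.brightness_histogram <- function(x, ...) {
  cat(sprintf("brightness_histogram: %d bins of width %d, %d samples\n",
              length(x$counts), x$bin_width, sum(x$counts)))
  invisible(x)
}

#' Convert a histogram to a data frame
#'
#' @param x a `brightness_histogram`.
#' @param ... unused.
#' @return data frame with columns `bin_lo`, `bin_hi`, `count`.
#' @export
as.data.frame.brightness_histogram <- function(x, ...) {
  data.frame(bin_lo = x$bin_lo, bin_hi = x$bin_hi, count = x$counts)
}

#' Contrast enhancement by stretching the histogram to the left
#'
#' Linearly remaps brightness so that the darkest observed level goes to 0
#' while the brightest observed level is preserved:
#' `beta' = round((beta - beta_min) * beta_max / (beta_max - beta_min))`.
#' This makes pore borders and inner details more visible while keeping the
#' bright background saturated. Note that the remap destroys the linear
#' brightness-depth relationship, so depth estimation ([depth_map()]) must
#' always run on the *unenhanced* image; the enhanced image is for display and
#' segmentation only.
#'
#' @param img a [gray_image()].
#' @return The enhanced [gray_image()] (same scale/metadata). A constant image
#'   is returned unchanged with a warning.
#' @export
enhance_left_stretch <- function(img) {
  stopifnot(inherits(img, "gray_image"))
  b <- img$pixels
  bmin <- min(b); bmax <- max(b)
  if (bmax == bmin) {
    warning("constant image: histogram stretch is undefined, returning input")
    return(img)
  }
  out <- round((b - bmin) * (bmax / (bmax - bmin)))
  gray_image(out, scale = img$scale, magnification = img$magnification)
}
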