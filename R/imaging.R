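#' Construct an 8-bit RGB image object
#'
#' Wraps an integer array of per-pixel RGB values into the container used by
#' the cuticle-scoring functions. Channel values are 8-bit integers in
#' \[0, 255\], as delivered by consumer digital cameras.
#'
#' @param pixels numeric array of dimension `height x width x 3`, all values
#'   integers in \[0, 255\].
#' @return An object of class `rgb_image` (the array, with class attribute).
#' @export
rgb_image <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be a height x width x 3 array", call. = FALSE)
  if (anyNA(pixels) || any(pixels < 0) || any(pixels > 255))
    stop("RGB channel values must lie in [0, 255]", call. = FALSE)
  if (any(pixels != round(pixels)))
    stop("RGB channel values must be 8-bit integers", call. = FALSE)
  storage.mode(pixels) <- "integer"
  structure(pixels, class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image> %d x %d pixels (8-bit RGB)\n", d[2], d[1]))
  invisible(x)
}

image_width <- function(img) dim(img)[2]
image_height <- function(img) dim(img)[1]

#' Read an 8-bit RGB image from PNG or TIFF
#'
#' Alpha channels and grayscale images are rejected: the redness index is
#' defined on plain 3-channel RGB data.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @return An [rgb_image].
#' @export
read_rgb_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '", ext, "' (expected png/tif/tiff)", call. = FALSE)
  )
  if (length(dim(raw)) != 3L)
    stop("grayscale image: 3-channel RGB required (", path, ")", call. = FALSE)
  if (dim(raw)[3] == 4L)
    stop("image has an alpha channel; flatten to plain RGB first (", path, ")",
         call. = FALSE)
  if (dim(raw)[3] != 3L)
    stop("expected 3 channels, found ", dim(raw)[3], " (", path, ")", call. = FALSE)
  rgb_image(round(raw * 255))
}

#' Write an 8-bit RGB image as PNG
#'
#' @param img an [rgb_image].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rgb_png <- function(img, path) {
  stopifnot(inherits(img, "rgb_image"))
  arr <- unclass(img) / 255
  png::writePNG(arr, target = path)
  invisible(path)
}

#' Maximal square region inside a rectangle
#'
#' Given a user-supplied rectangle bounding the metasternum, returns the
#' largest square inscribed in it, centred along the rectangle's longer axis
#' (ties broken toward the top-left: the centring offset is floored).
#' Coordinates are 0-based and half-open.
#'
#' @param image an [rgb_image].
#' @param rect integer vector `c(x0, y0, width, height)`, 0-based pixel
#'   coordinates of the rectangle's top-left corner plus its size.
#' @return A list of class `square_roi` with fields `x0`, `y0`, `side`.
#' @export
extract_square <- function(image, rect) {
  stopifnot(inherits(image, "rgb_image"))
  if (length(rect) != 4L || anyNA(rect) || any(rect != round(rect)))
    stop("`rect` must be integer c(x0, y0, width, height)", call. = FALSE)
  x0 <- rect[1]; y0 <- rect[2]; w <- rect[3]; h <- rect[4]
  if (w < 1 || h < 1) stop("degenerate rectangle: width and height must be >= 1",
                           call. = FALSE)
  if (x0 < 0 || y0 < 0 || x0 + w > image_width(image) || y0 + h > image_height(image))
    stop("rectangle extends outside the image bounds", call. = FALSE)
  side <- min(w, h)
  if (w >= h) {
    sq <- list(x0 = x0 + (w - side) %/% 2, y0 = y0, side = side)
  } else {
    sq <- list(x0 = x0, y0 = y0 + (h - side) %/% 2, side = side)
  }
  structure(sq, class = "square_roi")
}

#' Extract the pixel matrix of a square region
#'
#' @param image an [rgb_image].
#' @param roi a `square_roi` from [extract_square()].
#' @return Integer matrix with `side^2` rows and columns R, G, B; rows are in
#'   column-major order within the square. The index and mask are invariant to
#'   pixel order, so the ordering is only a bookkeeping convention.
#' @export
roi_pixels <- function(image, roi) {
  stopifnot(inherits(image, "rgb_image"), inherits(roi, "square_roi"))
  rows <- (roi$y0 + 1):(roi$y0 + roi$side)
  cols <- (roi$x0 + 1):(roi$x0 + roi$side)
  sub <- unclass(image)[rows, cols, , drop = FALSE]
  m <- cbind(as.vector(sub[, , 1]), as.vector(sub[, , 2]), as.vector(sub[, , 3]))
  colnames(m) <- c("R", "G", "B")
  m
}

#' Per-pixel brightness
#'
#' Brightness of an RGB pixel. The default, the arithmetic mean of the three
#' channels, matches the reference scale of the redness index itself (which is
#' expressed relative to mean(R,G,B)); max-channel and Rec.601 luma are
#' available as alternatives.
#'
#' @param pixels integer matrix with columns R, G, B (or a length-3 vector).
#' @param method one of `"mean"`, `"max"`, `"luma"`.
#' @return Numeric vector of brightness values (exact floating point).
#' @export
pixel_brightness <- function(pixels, method = c("mean", "max", "luma")) {
  method <- match.arg(method)
  if (is.null(dim(pixels))) pixels <- matrix(pixels, ncol = 3)
  if (anyNA(pixels) || any(pixels < 0) || any(pixels > 255))
    stop("RGB channel values must lie in [0, 255]", call. = FALSE)
  switch(method,
    mean = rowMeans(pixels),
    max  = pmax(pixels[, 1], pixels[, 2], pixels[, 3]),
    luma = 0.299 * pixels[, 1] + 0.587 * pixels[, 2] + 0.114 * pixels[, 3]
  )
}

#' Mask brightness extremes of a pixel set
#'
#' Flags pixels whose brightness falls in the darkest `low_frac` or brightest
#' `high_frac` tails, to exclude specular highlights and shadows before the
#' redness index is averaged. Quantiles are nearest-rank over all pixels:
#' the low cut is the value at rank `ceiling(low_frac * N)` and the high cut
#' the value at rank `ceiling((1 - high_frac) * N)` of the sorted brightness;
#' a pixel is masked iff its brightness is strictly below the low cut or
#' strictly above the high cut. Strict inequalities guarantee that a uniform
#' region masks nothing and that at least `(1 - low_frac - high_frac) * N`
#' pixels are always retained.
#'
#' @param pixels integer matrix with columns R, G, B.
#' @param low_frac,high_frac tail fractions in \[0, 1) with
#'   `low_frac + high_frac < 1`; defaults 0.10 and 0.10.
#' @param brightness brightness definition passed to [pixel_brightness()].
#' @return Logical vector of class `brightness_mask` (`TRUE` = excluded), with
#'   attributes `low_cut` and `high_cut`.
#' @export
mask_extremes <- function(pixels, low_frac = 0.10, high_frac = 0.10,
                          brightness = "mean") {
  if (is.null(dim(pixels))) pixels <- matrix(pixels, ncol = 3)
  n <- nrow(pixels)
  if (n < 1L) stop("empty pixel set", call. = FALSE)
  if (low_frac < 0 || high_frac < 0 || low_frac + high_frac >= 1)
    stop("need 0 <= low_frac, high_frac and low_frac + high_frac < 1",
         call. = FALSE)
  b <- pixel_brightness(pixels, method = brightness)
  sorted <- sort(b)
  low_cut <- if (low_frac > 0) sorted[max(1L, ceiling(low_frac * n))] else -Inf
  high_cut <- if (high_frac > 0) sorted[ceiling((1 - high_frac) * n)] else Inf
  mask <- b < low_cut | b > high_cut
  structure(mask, low_cut = low_cut, high_cut = high_cut,
            class = "brightness_mask")
}

#' Redness index over unmasked pixels
#'
#' The per-specimen cuticle colour score: the average over retained pixels of
#' `R - mean(R, G, B)`, in 8-bit intensity units. Zero for any grayscale
#' region; +170 for pure red; -170 for pure cyan.
#'
#' @param pixels integer matrix with columns R, G, B.
#' @param mask logical vector (`TRUE` = excluded), e.g. from
#'   [mask_extremes()]; `NULL` uses every pixel.
#' @return A list of class `redness_result`: `n_pixels_total`,
#'   `n_pixels_used`, `index`.
#' @export
redness_index <- function(pixels, mask = NULL) {
  if (is.null(dim(pixels))) pixels <- matrix(pixels, ncol = 3)
  n <- nrow(pixels)
  if (is.null(mask)) mask <- rep(FALSE, n)
  if (length(mask) != n)
    stop("mask length (", length(mask), ") != pixel count (", n, ")",
         call. = FALSE)
  used <- !mask
  if (!any(used))
    stop("all pixels masked: redness index undefined", call. = FALSE)
  dev <- pixels[used, 1] - rowMeans(pixels[used, , drop = FALSE])
  structure(
    list(n_pixels_total = n, n_pixels_used = sum(used), index = mean(dev)),
    class = "redness_result"
  )
}

#' @export
print.redness_result <- function(x, ...) {
  cat(sprintf("redness index: %.3f  (n = %d of %d pixels retained)\n",
              x$index, x$n_pixels_used, x$n_pixels_total))
  invisible(x)
}

#' Score one cuticle image
#'
#' Full scoring pipeline for a single specimen photograph: extract the maximal
#' square inside the metasternum rectangle, mask brightness extremes, and
#' average the redness index over retained pixels.
#'
#' @inheritParams extract_square
#' @inheritParams mask_extremes
#' @param mask_out optional path; if given, a PNG is written in which masked
#'   pixels of the square region are painted blue.
#' @return A `redness_result` (see [redness_index()]), with the `square_roi`
#'   attached as attribute `roi`.
#' @export
score_image <- function(image, rect, low_frac = 0.10, high_frac = 0.10,
                        brightness = "mean", mask_out = NULL) {
  roi <- extract_square(image, rect)
  pix <- roi_pixels(image, roi)
  mask <- mask_extremes(pix, low_frac, high_frac, brightness = brightness)
  res <- redness_index(pix, mask)
  attr(res, "roi") <- roi
  if (!is.null(mask_out)) {
    arr <- unclass(image)
    rows <- (roi$y0 + 1):(roi$y0 + roi$side)
    cols <- (roi$x0 + 1):(roi$x0 + roi$side)
    sub <- arr[rows, cols, , drop = FALSE]
    mk <- matrix(mask, nrow = roi$side)  # column-major, matches roi_pixels()
    sub[, , 1][mk] <- 0L
    sub[, , 2][mk] <- 0L
    sub[, , 3][mk] <- 255L
    arr[rows, cols, ] <- sub
    write_rgb_png(rgb_image(arr), mask_out)
  }
  res
}
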