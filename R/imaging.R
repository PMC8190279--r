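#' Construct a masked fluorescence image
#'
#' @param pixels numeric matrix of nonnegative pixel intensities
#'   (row-major, 0-based pixel coordinates with centers at +0.5).
#' @param mask logical matrix of the same shape delimiting the body region.
#' @param exposure_ms camera exposure time, ms.
#' @param channel filter-set identifier.
#' @return An object of class `masked_image`.
#' @export
masked_image <- function(pixels, mask = NULL, exposure_ms = NA_real_,
                         channel = NA_character_) {
  stopifnot(is.matrix(pixels))
  if (any(pixels < 0)) {
    abort_zfpk("pixel intensities must be nonnegative", "zfpk_invalid_input")
  }
  if (is.null(mask)) mask <- matrix(TRUE, nrow(pixels), ncol(pixels))
  stopifnot(is.logical(mask))
  if (!identical(dim(pixels), dim(mask))) {
    abort_zfpk("mask and pixel shapes differ", "zfpk_invalid_input")
  }
  structure(list(pixels = pixels, mask = mask, exposure_ms = exposure_ms,
                 channel = channel), class = "masked_image")
}

#' Rasterize a body contour into a pixel mask
#'
#' Converts a manually delineated whole-body contour (closed polygon in
#' pixel coordinates) into a boolean mask by an even-odd point-in-polygon
#' test at pixel centers. Convention: 0-based, row-major pixel grid; the
#' center of pixel (row, col) is at (x, y) = (col + 0.5, row + 0.5).
#'
#' @param contour two-column matrix or data.frame of (x, y) polygon
#'   vertices, at least 3, implicitly closed.
#' @param shape integer vector `c(rows, cols)` of the target image.
#' @return Logical matrix of dimension `shape`.
#' @export
#' @examples
#' # a 4x6 pixel rectangle
#' rect <- cbind(c(2, 8, 8, 2), c(1, 1, 5, 5))
#' sum(rasterize_body_contour(rect, c(8, 10)))  # 24
rasterize_body_contour <- function(contour, shape) {
  contour <- as.matrix(contour)
  if (nrow(contour) < 3) {
    abort_zfpk("a polygon needs at least 3 vertices", "zfpk_invalid_polygon")
  }
  rows <- shape[1]; cols <- shape[2]
  px <- rep(seq_len(cols) - 0.5, each = rows)   # x of pixel centers
  py <- rep(seq_len(rows) - 0.5, times = cols)  # y of pixel centers
  inside <- rep(FALSE, rows * cols)
  vx <- contour[, 1]; vy <- contour[, 2]
  nv <- length(vx)
  j <- nv
  for (i in seq_len(nv)) {
    # even-odd rule: toggle when the ray to x = -Inf crosses edge (j, i)
    crosses <- ((vy[i] > py) != (vy[j] > py))
    if (any(crosses)) {
      xint <- vx[i] + (py - vy[i]) * (vx[j] - vx[i]) / (vy[j] - vy[i])
      hit <- crosses & (px < xint)
      inside[hit] <- !inside[hit]
    }
    j <- i
  }
  matrix(inside, nrow = rows, ncol = cols)
}

#' Whole-body integrated fluorescence intensity
#'
#' The sum of all pixel intensity values inside the body mask, the RFU
#' readout quantified from each fluorescence micrograph.
#'
#' @param image a [masked_image()].
#' @return Integrated intensity, RFU. An empty mask returns 0 with a
#'   warning.
#' @export
integrated_intensity <- function(image) {
  stopifnot(inherits(image, "masked_image"))
  if (!any(image$mask)) {
    warn_zfpk("empty mask: integrated intensity is 0", "zfpk_empty_mask")
    return(0)
  }
  sum(image$pixels[image$mask])
}

#' Exposure-time correction of an integrated intensity
#'
#' Camera response is assumed linear in exposure time, so intensities
#' acquired at different exposures are made comparable by rescaling to a
#' reference exposure (used e.g. to avoid saturation for bright compounds
#' in combination treatments).
#'
#' @param rfu integrated intensity, RFU.
#' @param exposure_ms exposure the image was acquired at, ms (> 0).
#' @param reference_exposure_ms exposure to normalise to, ms (> 0).
#' @return Corrected RFU.
#' @export
exposure_correction <- function(rfu, exposure_ms, reference_exposure_ms) {
  check_number(rfu, "rfu", lower = 0)
  check_number(exposure_ms, "exposure_ms", lower = 0, strict = TRUE)
  check_number(reference_exposure_ms, "reference_exposure_ms", lower = 0,
               strict = TRUE)
  rfu * reference_exposure_ms / exposure_ms
}

#' Render a synthetic embryo image with known ground truth
#'
#' Draws a teardrop-shaped "embryo" (elliptical trunk tapering into a tail)
#' whose within-contour intensity sum equals `fluor * amount` exactly before
#' noise, then adds Poisson background counts over the whole frame. Returns
#' both the image and the ground-truth contour so that rasterization,
#' integration and the amount-fluorescence mapping can be tested from pixels
#' upward.
#'
#' @param amount intrabody amount, ng.
#' @param fluor fluorescence constant, RFU/ng.
#' @param shape image dimensions `c(rows, cols)`, each >= 64.
#' @param background mean Poisson background per pixel (0 for noiseless).
#' @param seed integer seed.
#' @return A list with `image` ([masked_image()] whose mask is the
#'   rasterized truth contour) and `contour` (vertex matrix).
#' @export
render_synthetic_embryo <- function(amount, fluor, shape = c(96, 128),
                                    background = 0, seed = 1) {
  check_number(amount, "amount", lower = 0)
  check_number(fluor, "fluor", lower = 0, strict = TRUE)
  if (any(shape < 64)) {
    abort_zfpk("image shape must be at least 64 x 64", "zfpk_invalid_input")
  }
  set.seed(seed)
  rows <- shape[1]; cols <- shape[2]
  cx <- cols * 0.35; cy <- rows * 0.5
  a <- cols * 0.18; b <- rows * 0.22
  theta <- seq(0, 2 * pi, length.out = 64)[-64]
  # teardrop: radius stretched toward the tail (theta = 0 direction)
  stretch <- 1 + 1.6 * pmax(cos(theta), 0)^3
  contour <- cbind(x = cx + a * stretch * cos(theta),
                   y = cy + b * sin(theta) / (1 + 0.8 * pmax(cos(theta), 0)))
  mask <- rasterize_body_contour(contour, shape)
  pixels <- matrix(0, rows, cols)
  k <- sum(mask)
  pixels[mask] <- fluor * amount / k  # uniform: mask sum is exactly fluor*amount
  if (background > 0) {
    pixels <- pixels + matrix(rpois(rows * cols, background), rows, cols)
  }
  list(image = masked_image(pixels, mask), contour = contour)
}

#' Read a grayscale image as a pixel matrix
#'
#' Reads a grayscale PNG or TIFF into a matrix of intensities on a 16-bit
#' scale (values 0..65535). TIFF files are stored at full 16-bit depth; PNG
#' files are stored at 8-bit depth, so PNG intensities are quantised to 256
#' levels (spread over the same 0..65535 scale). Saturated
#' pixels (at the dtype maximum) are counted in the `"saturated"`
#' attribute, flagging frames that need the exposure-correction path.
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @return Numeric matrix with attribute `saturated`.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                abort_zfpk("unsupported image format (use png/tif/tiff)",
                           "zfpk_invalid_input"))
  if (length(dim(img)) == 3) img <- img[, , 1]
  out <- round(img * 65535)
  attr(out, "saturated") <- sum(out >= 65535)
  out
}

#' Write a pixel matrix as a grayscale image
#'
#' TIFF output is lossless 16-bit; PNG output is quantised to 8-bit depth.
#'
#' @param pixels numeric matrix, values 0..65535.
#' @param path output path ending in .png, .tif or .tiff.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(pixels, path) {
  stopifnot(is.matrix(pixels))
  scaled <- pmin(pmax(pixels, 0), 65535) / 65535
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(scaled, path),
         tif = ,
         tiff = tiff::writeTIFF(scaled, path, bits.per.sample = 16),
         abort_zfpk("unsupported image format (use png/tif/tiff)",
                    "zfpk_invalid_input"))
  invisible(path)
}
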