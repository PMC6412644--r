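#' Deposition-carrier image
#'
#' Wraps a raster of the deposition carrier together with the spatial scale
#' and acquisition metadata the pipeline needs. Pixel values live in
#' `[0, 1]`; RGB rasters are numeric arrays with a third dimension of 3,
#' grayscale rasters are plain matrices.
#'
#' @param pixels Numeric matrix (grayscale) or 3-channel array (RGB) with
#'   values in `[0, 1]`.
#' @param scale Spatial scale in cm per pixel (> 0).
#' @param illumination Ambient illumination in lux at acquisition time, or
#'   `NULL` when unknown.
#' @param polarity Either `"dark"` (droplet spots darker than the carrier)
#'   or `"bright"` (spots brighter, as on a back-lit achromatic carrier).
#' @return An object of class `carrier_image`.
#' @export
carrier_image <- function(pixels, scale, illumination = NULL,
                          polarity = c("dark", "bright")) {
  polarity <- match.arg(polarity)
  if (!is.numeric(pixels)) stop("pixels must be numeric")
  nd <- length(dim(pixels))
  if (!(nd == 2L || (nd == 3L && dim(pixels)[3] == 3L)))
    stop("pixels must be a matrix or an RGB array with 3 channels")
  rng <- range(pixels)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 1)
    stop("pixel values must be finite and within [0, 1]")
  stopifnot(is.numeric(scale), length(scale) == 1L, is.finite(scale))
  if (scale <= 0) stop("scale (cm per pixel) must be positive")
  if (!is.null(illumination)) {
    stopifnot(is.numeric(illumination), length(illumination) == 1L)
    if (!is.finite(illumination) || illumination < 0)
      stop("illumination must be a non-negative number of lux")
  }
  structure(list(pixels = pixels, scale = scale,
                 illumination = illumination, polarity = polarity),
            class = "carrier_image")
}

#' @export
print.carrier_image <- function(x, ...) {
  d <- dim(x$pixels)
  kind <- if (length(d) == 2L) "grayscale" else "RGB"
  cat(sprintf("carrier_image: %d x %d %s, %.4g cm/px (%s spots)\n",
              d[1], d[2], kind, x$scale, x$polarity))
  if (!is.null(x$illumination))
    cat(sprintf("  illumination: %.4g Lx\n", x$illumination))
  invisible(x)
}

#' @export
dim.carrier_image <- function(x) dim(x$pixels)

# image area in cm^2 from pixel count and scale
carrier_area_cm2 <- function(x) {
  d <- dim(x$pixels)
  d[1] * d[2] * x$scale^2
}

as_gray_matrix <- function(x) {
  if (inherits(x, "carrier_image")) x <- x$pixels
  if (length(dim(x)) == 3L) stop("expected a grayscale raster")
  if (inherits(x, "Image")) x <- EBImage::imageData(x)
  as.matrix(x)
}
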