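#' Preprocess a carrier image for segmentation
#'
#' Converts RGB input to luma (BT.601 weights 0.299, 0.587, 0.114 — the Y
#' channel of YCbCr), applies a 3x3 median smoother to suppress pixel
#' noise, and normalizes polarity so that droplet spots are *dark*: images
#' whose spots are bright (back-lit achromatic carrier) are inverted.
#'
#' @param image A [carrier_image()] (or a bare grayscale matrix, treated as
#'   dark-spot polarity).
#' @param median_radius Radius of the median filter window (default 1,
#'   i.e. 3x3); 0 disables smoothing.
#' @return Grayscale matrix in `[0, 1]` with droplets dark.
#' @export
preprocess <- function(image, median_radius = 1) {
  if (!inherits(image, "carrier_image"))
    image <- carrier_image(as_gray_matrix(image), scale = 1)
  px <- image$pixels
  if (length(dim(px)) == 3L) {
    gray <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  } else {
    gray <- px
  }
  if (median_radius >= 1) {
    gray <- EBImage::imageData(
      EBImage::medianFilter(EBImage::Image(gray), as.integer(median_radius)))
  }
  if (image$polarity == "bright") gray <- 1 - gray
  gray
}

#' Otsu binarization
#'
#' Global threshold maximizing the between-class variance of a 256-bin
#' histogram. After [preprocess()] droplets are dark, so the foreground is
#' the at-or-below-threshold side.
#'
#' @param gray Grayscale matrix in `[0, 1]` with droplets dark.
#' @param levels Number of histogram bins (default 256).
#' @return Logical matrix, `TRUE` on droplet (foreground) pixels. A
#'   constant image yields an empty foreground with a warning.
#' @export
otsu_binarize <- function(gray, levels = 256) {
  gray <- as_gray_matrix(gray)
  if (diff(range(gray)) == 0) {
    warning("constant image: empty foreground")
    return(matrix(FALSE, nrow(gray), ncol(gray)))
  }
  thr <- EBImage::otsu(EBImage::Image(gray), range = c(0, 1),
                       levels = as.integer(levels))
  gray <= thr
}

#' Gradient magnitude segmentation function
#'
#' Sobel gradient magnitude `sqrt(Ix^2 + Iy^2)` (default), or the
#' morphological gradient `dilate(g) - erode(g)` by a disk.
#'
#' @param gray Grayscale matrix.
#' @param method `"sobel"` or `"morphological"`.
#' @param b Structuring element for the morphological gradient.
#' @return Non-negative matrix; 0 on constant regions.
#' @export
gradient_magnitude <- function(gray, method = c("sobel", "morphological"),
                               b = se_disk(3)) {
  method <- match.arg(method)
  gray <- as_gray_matrix(gray)
  if (method == "sobel") {
    kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
    ky <- t(kx)
    img <- EBImage::Image(gray)
    ix <- EBImage::imageData(EBImage::filter2(img, kx, boundary = "replicate"))
    iy <- EBImage::imageData(EBImage::filter2(img, ky, boundary = "replicate"))
    sqrt(ix^2 + iy^2)
  } else {
    ebi_op(gray, EBImage::dilate, b) - ebi_op(gray, EBImage::erode, b)
  }
}

#' Foreground (droplet) markers
#'
#' Smooths the intensity relief with an opening-by-reconstruction followed
#' by a closing-by-reconstruction (both by the disk `b`), then takes the
#' regional intensity extrema on the droplet side and keeps those inside
#' the Otsu foreground. Each sufficiently large droplet contributes at
#' least one marker component; flat fused stains may share one (see
#' [mmcws()] for the splitting marker strategy).
#'
#' @param gray Grayscale matrix with droplets dark (from [preprocess()]).
#' @param b Structuring element (default disk of radius 3).
#' @param foreground Optional logical foreground mask; computed by
#'   [otsu_binarize()] when `NULL`.
#' @param conn Connectivity (default 8).
#' @return Logical marker mask (possibly empty).
#' @export
foreground_markers <- function(gray, b = se_disk(3), foreground = NULL,
                               conn = 8) {
  gray <- as_gray_matrix(gray)
  if (is.null(foreground)) {
    foreground <- suppressWarnings(otsu_binarize(gray))
  } else {
    foreground <- as_gray_matrix(foreground) != 0
  }
  v <- 1 - gray # droplets bright on v
  iobr <- reconstruct_dilate(ebi_op(v, EBImage::erode, b), v, conn)
  dil <- ebi_op(iobr, EBImage::dilate, b)
  iobrcbr <- 1 - reconstruct_dilate(1 - dil, 1 - iobr, conn)
  regional_maxima(iobrcbr, conn) & foreground
}

#' Background markers
#'
#' Classical marker-controlled recipe: the background distance transform
#' (distance of each background pixel to the nearest droplet) is flooded
#' from the droplet components; the resulting watershed ridge lines are
#' thin curves running midway between droplets and never touching them.
#' The image border frame (where it is background) is always included so a
#' background marker exists even for a single-droplet image.
#'
#' @param binary Logical foreground mask.
#' @param conn Connectivity (default 8).
#' @return Logical mask of background marker pixels. All-foreground input
#'   yields an empty mask with a warning.
#' @export
background_markers <- function(binary, conn = 8) {
  bw <- as_gray_matrix(binary) != 0
  nr <- nrow(bw); nc <- ncol(bw)
  if (all(bw)) {
    warning("all-foreground mask: no background markers")
    return(matrix(FALSE, nr, nc))
  }
  border <- matrix(FALSE, nr, nc)
  border[c(1, nr), ] <- TRUE
  border[, c(1, nc)] <- TRUE
  if (!any(bw)) {
    warning("empty foreground: background markers reduced to the image border")
    return(border)
  }
  d <- EBImage::imageData(EBImage::distmap(EBImage::Image(1 - bw)))
  ws <- cpp_watershed(d, cpp_label(bw, as.integer(conn)), as.integer(conn),
                      FALSE)
  ridge <- ws == 0 & !bw
  ridge | (border & !bw)
}
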