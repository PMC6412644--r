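#' Disk structuring element
#'
#' Flat disk-shaped structuring element used by all morphological
#' operations in the pipeline.
#'
#' @param radius Radius in pixels (>= 1). Default 3.
#' @return A 0/1 matrix of odd side `2 * radius + 1` (class
#'   `structuring_element`).
#' @export
se_disk <- function(radius = 3) {
  stopifnot(is.numeric(radius), length(radius) == 1L, is.finite(radius))
  radius <- as.integer(radius)
  if (radius < 1L) stop("radius must be >= 1 pixel")
  b <- EBImage::makeBrush(2L * radius + 1L, shape = "disc")
  structure(b, class = c("structuring_element", class(b)), radius = radius)
}

check_same_shape <- function(a, b, what = c("g", "r")) {
  if (!identical(dim(a)[1:2], dim(b)[1:2]))
    stop(sprintf("%s and %s must have the same dimensions", what[1], what[2]))
}

#' Morphological reconstruction by dilation
#'
#' Iterated geodesic dilation of `marker` under `mask` to convergence
#' (the marker is clipped to the mask first). This is the primitive behind
#' the opening/closing-by-reconstruction operators and minima imposition.
#'
#' @param marker,mask Numeric matrices of identical shape.
#' @param conn Pixel connectivity, 4 or 8 (default 8).
#' @return The reconstructed raster.
#' @export
reconstruct_dilate <- function(marker, mask, conn = 8) {
  marker <- as_gray_matrix(marker)
  mask <- as_gray_matrix(mask)
  check_same_shape(marker, mask, c("marker", "mask"))
  cpp_reconstruct_dilate(marker, mask, as.integer(conn))
}

#' Morphological reconstruction by erosion (dual of [reconstruct_dilate()])
#'
#' @inheritParams reconstruct_dilate
#' @return The reconstructed raster.
#' @export
reconstruct_erode <- function(marker, mask, conn = 8) {
  marker <- as_gray_matrix(marker)
  mask <- as_gray_matrix(mask)
  check_same_shape(marker, mask, c("marker", "mask"))
  -cpp_reconstruct_dilate(-marker, -mask, as.integer(conn))
}

ebi_op <- function(x, fun, b) {
  EBImage::imageData(fun(EBImage::Image(x), unclass(b)))
}

#' Opening by reconstruction
#'
#' Morphological opening of `g` by the structuring element, used as the
#' marker of a reconstruction by dilation under the reference `r`. Bright
#' structures smaller than the element are removed; surviving structures
#' regain their exact shape.
#'
#' @param g Grayscale raster.
#' @param r Reference raster (defaults to `g`).
#' @param b A [se_disk()] structuring element.
#' @param conn Connectivity for the geodesic propagation (default 8).
#' @return The reconstructed raster.
#' @export
open_reconstruction <- function(g, r = g, b = se_disk(3), conn = 8) {
  g <- as_gray_matrix(g); r <- as_gray_matrix(r)
  check_same_shape(g, r)
  reconstruct_dilate(ebi_op(g, EBImage::opening, b), r, conn)
}

#' Closing by reconstruction (dual of [open_reconstruction()])
#'
#' Morphological closing of `g` followed by reconstruction by erosion under
#' `r`; dark structures smaller than the element are filled.
#'
#' @inheritParams open_reconstruction
#' @return The reconstructed raster.
#' @export
close_reconstruction <- function(g, r = g, b = se_disk(3), conn = 8) {
  g <- as_gray_matrix(g); r <- as_gray_matrix(r)
  check_same_shape(g, r)
  # dual through complementation within the pixel range
  hi <- max(g, r, 1)
  hi - open_reconstruction(hi - g, hi - r, b, conn)
}

#' Hybrid open-close reconstruction
#'
#' Opening by reconstruction followed by closing by reconstruction:
#' removes bright, then dark, irregularities smaller than the structuring
#' element while preserving remaining contours. The second stage is
#' referenced on the opened result (a reconstruction by erosion is bounded
#' below by its reference, so re-using the original reference would
#' re-inject the bright structures the first stage removed).
#'
#' @inheritParams open_reconstruction
#' @return The reconstructed raster.
#' @export
hybrid_reconstruction <- function(g, r = g, b = se_disk(3), conn = 8) {
  o <- open_reconstruction(g, r, b, conn)
  close_reconstruction(o, o, b, conn)
}

#' Regional minima / maxima of a raster
#'
#' A regional minimum is a connected plateau of constant value with no
#' lower neighbour.
#'
#' @param x Numeric matrix.
#' @param conn Connectivity, 4 or 8.
#' @return Logical matrix marking the extremal plateaus.
#' @export
regional_minima <- function(x, conn = 8) {
  cpp_regional_minima(as_gray_matrix(x), as.integer(conn))
}

#' @rdname regional_minima
#' @export
regional_maxima <- function(x, conn = 8) {
  cpp_regional_minima(-as_gray_matrix(x), as.integer(conn))
}

#' Label connected components
#'
#' @param mask Logical matrix (or 0/1 numeric).
#' @param conn Connectivity, 4 or 8 (default 8: foreground objects are
#'   8-connected throughout the pipeline).
#' @return Integer matrix of labels, 0 = background; labels are assigned in
#'   raster order of first encounter, hence contiguous and deterministic.
#' @export
label_components <- function(mask, conn = 8) {
  m <- as_gray_matrix(mask)
  cpp_label(matrix(as.logical(m != 0), nrow(m), ncol(m)), as.integer(conn))
}

#' Impose regional minima at marker locations
#'
#' Modifies a raster so that its regional minima are exactly the connected
#' components of `markers`: the marker pixels are forced to the global
#' minimum and every other minimum is flooded away by a reconstruction by
#' erosion.
#'
#' @param gradient Numeric matrix (typically a gradient magnitude).
#' @param markers Logical matrix of marker pixels; must be non-empty.
#' @param delta Positive contrast step separating marker minima from the
#'   rest of the relief (default 1e-3; any positive value preserves the
#'   exact-minima property).
#' @param conn Connectivity (default 8).
#' @return Raster whose regional minima equal the marker components.
#' @export
impose_minima <- function(gradient, markers, delta = 1e-3, conn = 8) {
  g <- as_gray_matrix(gradient)
  m <- as_gray_matrix(markers) != 0
  check_same_shape(g, m, c("gradient", "markers"))
  if (!any(m)) stop("markers must contain at least one pixel")
  if (delta <= 0) stop("delta must be positive")
  lo <- min(g)
  g <- g - lo # work on a non-negative relief; minima are shift-invariant
  hi <- max(g) + delta
  fm <- matrix(hi, nrow(g), ncol(g))
  fm[m] <- 0
  out <- reconstruct_erode(fm, pmin(g + delta, fm), conn)
  out + lo
}

#' Marker-driven watershed transform
#'
#' Priority-flood (Meyer) watershed of a surface starting from labeled
#' markers. Flooding is deterministic: pixels enter the queue keyed by
#' surface value with first-in-first-out tie-breaking, and ridge pixels
#' (touching two basins) are assigned to the lowest adjacent label when
#' `assign_ridge` is `TRUE`, or left 0 otherwise.
#'
#' @param surface Numeric matrix to flood.
#' @param markers Either a logical marker mask (components are labeled in
#'   raster order) or an integer matrix of non-negative labels.
#' @param conn Connectivity (default 8).
#' @param assign_ridge Assign ridge pixels to the lowest adjacent basin
#'   (default `TRUE`), making the labels a partition of the flooded area.
#' @return Integer label matrix; 0 marks unflooded or ridge pixels.
#' @export
watershed_transform <- function(surface, markers, conn = 8,
                                assign_ridge = TRUE) {
  s <- as_gray_matrix(surface)
  if (is.logical(markers)) {
    markers <- label_components(markers, conn)
  } else {
    markers <- as_gray_matrix(markers)
    storage.mode(markers) <- "integer"
  }
  check_same_shape(s, markers, c("surface", "markers"))
  if (!any(markers > 0)) stop("markers must contain at least one labeled pixel")
  cpp_watershed(s, markers, as.integer(conn), isTRUE(assign_ridge))
}
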