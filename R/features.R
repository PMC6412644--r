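#' Shape degree (circularity) of a region
#'
#' `E = 4 * pi * A / L^2`, equal to 1 for a perfect disk and decreasing for
#' elongated or fused shapes. Values are capped at 1 so that the estimator
#' respects the analytic range `0 < E <= 1` (digital perimeter estimates
#' fluctuate slightly around the true contour length).
#'
#' @param area_px Region area in pixels (> 0).
#' @param perimeter_px Region boundary length in pixels (> 0).
#' @return Shape degree in `(0, 1]`.
#' @examples
#' shape_degree(pi * 10^2, 2 * pi * 10) # disk -> 1
#' shape_degree(4^2, 4 * 4)             # square -> pi / 4
#' @export
shape_degree <- function(area_px, perimeter_px) {
  stopifnot(is.numeric(area_px), is.numeric(perimeter_px))
  if (any(area_px <= 0)) stop("area must be positive")
  if (any(perimeter_px <= 0)) stop("perimeter must be positive")
  pmin(4 * pi * area_px / perimeter_px^2, 1)
}

#' Adhesion-test area threshold
#'
#' Mean area of the connected regions of the binarized image; regions at or
#' above this size are routed to the splitting stage.
#'
#' @param areas_px Vector of region areas in pixels (one per region).
#' @return Arithmetic mean area `d`.
#' @export
area_threshold <- function(areas_px) {
  if (length(areas_px) < 1L) stop("at least one region is required")
  stopifnot(is.numeric(areas_px))
  mean(areas_px)
}

#' Shape-degree threshold from group means
#'
#' The decision threshold between single and adhesive stains is placed at
#' the midpoint of the mean shape degree of the two groups. With the
#' calibrated group means 0.86 (single) and 0.48 (adhesive) this yields
#' the default threshold 0.67; the generic textbook value is 0.5.
#'
#' @param single_mean Mean shape degree of single droplets (default 0.86).
#' @param adhesive_mean Mean shape degree of adhesive stains (default 0.48).
#' @return The midpoint threshold `e`.
#' @export
shape_degree_threshold <- function(single_mean = 0.86, adhesive_mean = 0.48) {
  stopifnot(is.numeric(single_mean), is.numeric(adhesive_mean))
  (single_mean + adhesive_mean) / 2
}

#' Single-versus-adhesive decision
#'
#' A region is a single droplet only when its shape degree exceeds `e`
#' *and* its area is below the area threshold `d`; otherwise it is treated
#' as adhesive and sent to the watershed splitter. Large near-circular
#' blobs (good circularity but area at/above `d`) are deliberately routed
#' to splitting because fully engulfed overlaps keep high circularity.
#'
#' @param shape_deg Shape degree(s) `E` of the region(s).
#' @param area_px Area(s) in pixels.
#' @param e Shape-degree threshold in `(0, 1]` (default
#'   [shape_degree_threshold()], i.e. 0.67).
#' @param d Area threshold in pixels (from [area_threshold()]).
#' @return Logical vector: `TRUE` when the region is a single droplet.
#' @export
classify_adhesion <- function(shape_deg, area_px, e = shape_degree_threshold(),
                              d) {
  stopifnot(is.numeric(e), length(e) == 1L, e > 0, e <= 1)
  stopifnot(is.numeric(d), length(d) == 1L, d > 0)
  shape_deg > e & area_px < d
}

# Chain-code perimeter with the Vossepoel-Smeulders correction:
#   P = 0.980 * N_even + 1.406 * N_odd - 0.091 * N_corner
# where N_even counts axial steps, N_odd diagonal steps and N_corner the
# direction changes along the closed 8-connected boundary chain.
chain_perimeter <- function(contour) {
  n <- nrow(contour)
  if (n < 2L) return(0)
  d <- rbind(diff(contour), contour[1L, ] - contour[n, ])
  keep <- !(d[, 1] == 0 & d[, 2] == 0)
  d <- d[keep, , drop = FALSE]
  if (nrow(d) < 2L) return(0)
  odd <- d[, 1] != 0 & d[, 2] != 0
  code <- atan2(d[, 2], d[, 1])
  ncorner <- sum(code != c(code[-1L], code[1L]))
  0.980 * sum(!odd) + 1.406 * sum(odd) - 0.091 * ncorner
}

#' Per-region features of a label image
#'
#' Computes, for every labeled region, the pixel area, the chain-code
#' perimeter (Vossepoel-Smeulders weighted, so digital disks approach
#' shape degree 1), the shape degree and the centroid. Degenerate regions
#' whose boundary chain is too short for the estimator (a few pixels) fall
#' back to the perimeter of the equivalent disk.
#'
#' @param labels Integer label matrix (0 = background) with contiguous
#'   labels `1..n`.
#' @return A data frame with columns `label`, `area_px`, `perimeter_px`,
#'   `shape_degree`, `centroid_r`, `centroid_c`.
#' @export
region_features <- function(labels) {
  labels <- as_gray_matrix(labels)
  storage.mode(labels) <- "integer"
  n <- max(labels)
  if (n == 0L)
    return(data.frame(label = integer(), area_px = numeric(),
                      perimeter_px = numeric(), shape_degree = numeric(),
                      centroid_r = numeric(), centroid_c = numeric()))
  areas <- tabulate(labels[labels > 0L], nbins = n)
  idx <- which(labels > 0L)
  rr <- (idx - 1L) %% nrow(labels) + 1L
  cc <- (idx - 1L) %/% nrow(labels) + 1L
  lab <- labels[idx]
  cr <- tapply(rr, lab, mean)
  ccn <- tapply(cc, lab, mean)
  contours <- EBImage::ocontour(EBImage::Image(labels))
  per <- vapply(seq_len(n), function(i) {
    ct <- if (i <= length(contours)) contours[[i]] else NULL
    p <- if (is.null(ct)) 0 else chain_perimeter(ct)
    if (p <= 0) 2 * sqrt(pi * areas[i]) else p
  }, numeric(1))
  data.frame(label = seq_len(n), area_px = as.numeric(areas),
             perimeter_px = per,
             shape_degree = shape_degree(areas, per),
             centroid_r = as.numeric(cr[as.character(seq_len(n))]),
             centroid_c = as.numeric(ccn[as.character(seq_len(n))]))
}
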