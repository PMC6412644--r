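#' Droplet coverage
#'
#' Percentage of the image area occupied by droplet stains:
#' `C = 100 * S(PIX = 1) / S(PIX = 0 or 1)`.
#'
#' @param binary Logical (or 0/1) foreground mask.
#' @return Coverage in percent, in `[0, 100]`.
#' @export
coverage <- function(binary) {
  bw <- as_gray_matrix(binary)
  if (length(bw) == 0) stop("mask must be non-empty")
  100 * mean(bw != 0)
}

#' Droplet coverage density
#'
#' Droplet count per unit carrier area, `K = N / S` in droplets per cm^2.
#'
#' @param n Droplet count `N`.
#' @param image_area_cm2 Imaged carrier area `S` in cm^2 (> 0).
#' @return Coverage density in n per cm^2.
#' @export
coverage_density <- function(n, image_area_cm2) {
  stopifnot(is.numeric(n), is.numeric(image_area_cm2))
  if (any(image_area_cm2 <= 0)) stop("image area must be positive")
  n / image_area_cm2
}

#' Deposition report from a segmentation
#'
#' Collects the deposition parameters of a segmented carrier image: the
#' droplet count `N` (post-split, post-minimum-area regions), coverage `C`
#' (percent of carrier area stained) and coverage density `K = N / S` in
#' droplets per cm^2, along with the per-region feature table.
#'
#' @param seg A `segmentation_result` from [mmcws()].
#' @param scale Optional cm-per-pixel override; defaults to the scale
#'   recorded in the segmentation.
#' @return An object of class `deposition_report`.
#' @export
deposition_report <- function(seg, scale = NULL) {
  stopifnot(inherits(seg, "segmentation_result"))
  scale <- if (is.null(scale)) seg$scale else scale
  stopifnot(is.numeric(scale), scale > 0)
  area_cm2 <- nrow(seg$labels) * ncol(seg$labels) * scale^2
  n <- nrow(seg$regions)
  structure(list(n_droplets = n,
                 coverage_pct = coverage(seg$binary),
                 coverage_density = coverage_density(n, area_cm2),
                 image_area_cm2 = area_cm2,
                 per_region = seg$regions,
                 scale = scale,
                 schema_version = "1.0"),
            class = "deposition_report")
}

#' @export
print.deposition_report <- function(x, ...) {
  cat("Droplet deposition report\n")
  cat(sprintf("  droplets N:          %d\n", x$n_droplets))
  cat(sprintf("  coverage C:          %.2f %%\n", x$coverage_pct))
  cat(sprintf("  coverage density K:  %.1f n/cm^2\n", x$coverage_density))
  cat(sprintf("  carrier area S:      %.3f cm^2\n", x$image_area_cm2))
  invisible(x)
}

#' Compare a segmentation against synthetic ground truth
#'
#' Matches detected regions to ground-truth droplets by a greedy one-to-one
#' assignment: a detected region may claim the nearest unclaimed truth
#' droplet whose disk contains the region centroid. Reported rates:
#' \describe{
#'   \item{count_error_pct}{`100 * |N_detected - N_true| / N_true`}
#'   \item{false_positive_pct}{unmatched detected regions / detected}
#'   \item{false_negative_pct}{unclaimed truth droplets / truth count}
#'   \item{coverage_error_pct}{absolute difference between measured and
#'     analytic coverage, in percentage points}
#' }
#'
#' @param result A `segmentation_result` from [mmcws()].
#' @param truth A `synthetic_scene` from [generate_scene()].
#' @return A one-row data frame with the error rates and the raw counts.
#' @export
evaluate_against_truth <- function(result, truth) {
  stopifnot(inherits(result, "segmentation_result"),
            inherits(truth, "synthetic_scene"))
  if (!identical(dim(result$labels), dim(truth$image$pixels)[1:2]))
    stop("segmentation and scene geometry differ")
  regs <- result$regions
  nd <- nrow(regs)
  nt <- truth$truth_n
  claimed <- logical(nt)
  matched <- logical(nd)
  if (nd > 0 && nt > 0) {
    for (i in seq_len(nd)) {
      dr <- truth$truth_centers[, 1] - regs$centroid_r[i]
      dc <- truth$truth_centers[, 2] - regs$centroid_c[i]
      dist <- sqrt(dr^2 + dc^2)
      inside <- which(dist <= truth$truth_radii & !claimed)
      if (length(inside)) {
        j <- inside[which.min(dist[inside])]
        claimed[j] <- TRUE
        matched[i] <- TRUE
      }
    }
  }
  cov_meas <- coverage(result$binary)
  data.frame(
    n_detected = nd,
    n_true = nt,
    count_error_pct = if (nt > 0) 100 * abs(nd - nt) / nt else NA_real_,
    false_positive_pct = if (nd > 0) 100 * mean(!matched) else 0,
    false_negative_pct = if (nt > 0) 100 * mean(!claimed) else 0,
    coverage_measured_pct = cov_meas,
    coverage_truth_pct = truth$truth_coverage_pct,
    coverage_error_pct = abs(cov_meas - truth$truth_coverage_pct)
  )
}
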