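#' Parameters of the marker-controlled watershed pipeline
#'
#' @param e_threshold Shape-degree threshold separating single from
#'   adhesive stains (default [shape_degree_threshold()] = 0.67; the
#'   generic alternative is 0.5).
#' @param se_radius Disk structuring-element radius in pixels (default 3).
#'   When the spatial scale implies droplets narrower than 6 px the radius
#'   is scaled down automatically inside [mmcws()].
#' @param min_area Minimum region area in pixels kept in the final
#'   labeling (default 4); smaller protrusions and specks are removed.
#' @param min_droplet_px Assumed smallest droplet diameter in pixels used
#'   for the automatic structuring-element scaling (default 6).
#' @param gradient `"sobel"` (default) or `"morphological"` segmentation
#'   function.
#' @param median_radius Median prefilter radius (default 1; 0 disables).
#' @param split_markers Marker source for splitting adhesive regions:
#'   `"distance"` (default; h-maxima of the in-region distance transform,
#'   robust for uniformly cleared stains) or `"intensity"` (regional
#'   extrema of the reconstructed intensity relief, the [foreground_markers()]
#'   construction).
#' @param h_maxima Depth in pixels of an optional h-maxima suppression of
#'   the distance transform before marker extraction (default 0: raw
#'   regional maxima; the Euclidean distance transform of a connected
#'   stain has one maximal plateau per circular lobe, and any positive
#'   depth also swallows the shallow saddles of strongly overlapping
#'   pairs).
#' @param assign_ridge Assign watershed ridge pixels to the lowest adjacent
#'   label so region areas partition the foreground (default `TRUE`).
#' @param keep_background_markers Also compute the global background marker
#'   ridge map for provenance/plots (default `TRUE`).
#' @return A list of class `mmcws_params`.
#' @export
mmcws_params <- function(e_threshold = shape_degree_threshold(),
                         se_radius = 3,
                         min_area = 4,
                         min_droplet_px = 6,
                         gradient = c("sobel", "morphological"),
                         median_radius = 1,
                         split_markers = c("distance", "intensity"),
                         h_maxima = 0,
                         assign_ridge = TRUE,
                         keep_background_markers = TRUE) {
  gradient <- match.arg(gradient)
  split_markers <- match.arg(split_markers)
  stopifnot(e_threshold > 0, e_threshold <= 1, se_radius >= 1, min_area >= 0,
            h_maxima >= 0)
  structure(list(e_threshold = e_threshold, se_radius = as.integer(se_radius),
                 min_area = min_area, min_droplet_px = min_droplet_px,
                 gradient = gradient, median_radius = median_radius,
                 split_markers = split_markers, h_maxima = h_maxima,
                 assign_ridge = isTRUE(assign_ridge),
                 keep_background_markers = isTRUE(keep_background_markers)),
            class = "mmcws_params")
}

empty_segmentation <- function(dims, binary, params, scale) {
  structure(list(labels = matrix(0L, dims[1], dims[2]), binary = binary,
                 foreground_markers = matrix(FALSE, dims[1], dims[2]),
                 background_markers = matrix(FALSE, dims[1], dims[2]),
                 regions = cbind(region_features(matrix(0L, 1, 1))[0, ],
                                 is_adhesive = logical(0)),
                 area_threshold_px = NA_real_, params = params,
                 scale = scale),
            class = "segmentation_result")
}

# markers used to split one adhesive region (logical submask)
split_markers_for_region <- function(submask, subgray, b, params, conn = 8) {
  if (params$split_markers == "distance") {
    d <- EBImage::imageData(EBImage::distmap(EBImage::Image(submask * 1)))
    if (params$h_maxima > 0) d <- reconstruct_dilate(d - params$h_maxima, d, conn)
    regional_maxima(d, conn) & submask
  } else {
    foreground_markers(subgray, b, foreground = submask, conn = conn)
  }
}

#' Modified marker-controlled watershed segmentation
#'
#' Full droplet segmentation of a carrier image:
#' \enumerate{
#'   \item preprocess (luma, median smoothing, polarity normalization);
#'   \item Otsu binarization and 8-connected component labeling;
#'   \item per-region shape degree `E = 4 pi A / L^2` and area threshold
#'     `d = mean(A)`; a region is a single droplet only if `E > e` and
#'     `A < d`, otherwise it is adhesive;
#'   \item adhesive regions are split by a marker-controlled watershed:
#'     markers are imposed as the only regional minima of the gradient
#'     magnitude and the relief is flooded inside the region;
#'   \item regions smaller than `min_area` pixels are removed and labels
#'     are renumbered contiguously.
#' }
#'
#' @param image A [carrier_image()].
#' @param params A [mmcws_params()] configuration.
#' @return A `segmentation_result`: `labels` (integer matrix), `binary`
#'   (Otsu foreground), marker provenance masks, and a `regions` data
#'   frame (area, perimeter, shape degree, adhesion flag, centroid).
#' @examples
#' sc <- generate_scene(scene_spec(n_droplets = 12, width_px = 128,
#'                                 height_px = 128, seed = 1))
#' seg <- mmcws(sc$image)
#' seg
#' @export
mmcws <- function(image, params = mmcws_params()) {
  stopifnot(inherits(image, "carrier_image"), inherits(params, "mmcws_params"))
  conn <- 8

  # scale the structuring element down for very fine-grained imagery
  se_radius <- params$se_radius
  droplet_px <- params$min_droplet_px
  est_min_px <- 0.015 / image$scale # smallest stain ~150 um across
  if (est_min_px < droplet_px)
    se_radius <- max(1L, as.integer(floor(se_radius * est_min_px / droplet_px)))
  b <- se_disk(se_radius)

  gray <- preprocess(image, median_radius = params$median_radius)
  binary <- otsu_binarize(gray)
  dims <- dim(gray)
  if (!any(binary)) {
    warning("empty foreground: no droplets detected")
    return(empty_segmentation(dims, binary, params, image$scale))
  }

  labels0 <- cpp_label(binary, conn)
  feats0 <- region_features(labels0)
  d_thr <- area_threshold(feats0$area_px)
  single <- classify_adhesion(feats0$shape_degree, feats0$area_px,
                              e = params$e_threshold, d = d_thr)

  grad <- gradient_magnitude(gray, method = params$gradient, b = b)

  labels <- matrix(0L, dims[1], dims[2])
  fg_markers <- matrix(FALSE, dims[1], dims[2])
  adhesive_parent <- logical(0)
  next_label <- 0L

  for (i in feats0$label) {
    in_region <- labels0 == i
    if (single[i]) {
      next_label <- next_label + 1L
      labels[in_region] <- next_label
      adhesive_parent[next_label] <- FALSE
      next
    }
    # bounding box with a 1-px pad
    rows <- range(which(rowSums(in_region) > 0))
    cols <- range(which(colSums(in_region) > 0))
    r0 <- max(1L, rows[1] - 1L); r1 <- min(dims[1], rows[2] + 1L)
    c0 <- max(1L, cols[1] - 1L); c1 <- min(dims[2], cols[2] + 1L)
    submask <- in_region[r0:r1, c0:c1, drop = FALSE]
    subgray <- gray[r0:r1, c0:c1, drop = FALSE]
    mk <- split_markers_for_region(submask, subgray, b, params, conn)
    mk_lab <- cpp_label(mk, conn)
    k <- max(mk_lab)
    if (k < 2L) { # nothing to split against
      next_label <- next_label + 1L
      labels[in_region] <- next_label
      adhesive_parent[next_label] <- TRUE
      next
    }
    surf <- impose_minima(grad[r0:r1, c0:c1, drop = FALSE], mk, conn = conn)
    ws <- cpp_watershed(surf, mk_lab, conn, TRUE)
    ws[!submask] <- 0L
    for (piece in seq_len(k)) {
      sel <- ws == piece
      if (!any(sel)) next
      next_label <- next_label + 1L
      labels[r0:r1, c0:c1][sel] <- next_label
      adhesive_parent[next_label] <- TRUE
    }
    fg_markers[r0:r1, c0:c1] <- fg_markers[r0:r1, c0:c1] | mk
  }

  # drop regions below the minimum area, renumber in raster order
  pos <- which(labels > 0L)
  lab <- labels[pos]
  areas <- tabulate(lab, nbins = next_label)
  keep <- areas >= params$min_area
  first <- match(seq_len(next_label), lab)
  ord <- order(first)
  ord <- ord[keep[ord]]
  remap <- integer(next_label)
  remap[ord] <- seq_along(ord)
  labels[pos] <- remap[lab]
  adhesive_flag <- adhesive_parent[ord]

  feats <- region_features(labels)
  feats$is_adhesive <- adhesive_flag[feats$label]

  bg_markers <- if (params$keep_background_markers)
    suppressWarnings(background_markers(binary, conn))
  else matrix(FALSE, dims[1], dims[2])

  structure(list(labels = labels, binary = binary,
                 foreground_markers = fg_markers,
                 background_markers = bg_markers,
                 regions = feats, area_threshold_px = d_thr,
                 params = params, scale = image$scale),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat("MMCWS segmentation\n")
  cat(sprintf("  image:   %d x %d px (%.4g cm/px)\n",
              nrow(x$labels), ncol(x$labels), x$scale))
  cat(sprintf("  regions: %d (%d from adhesive stains)\n",
              nrow(x$regions), sum(x$regions$is_adhesive)))
  cat(sprintf("  coverage: %.2f %%\n", coverage(x$binary)))
  invisible(x)
}

#' Map region labels to display colors
#'
#' @param labels Integer label matrix.
#' @param seed Seed for the color shuffle (default 1; colors are assigned
#'   from a shuffled hue wheel so neighbouring labels contrast).
#' @return An RGB array (rows x cols x 3) with background black.
#' @export
label2rgb <- function(labels, seed = 1) {
  labels <- as_gray_matrix(labels)
  storage.mode(labels) <- "integer"
  n <- max(labels)
  out <- array(0, dim = c(nrow(labels), ncol(labels), 3))
  if (n == 0L) return(out)
  hues <- (seq_len(n) - 1) / n
  hues <- with_seed(seed, sample(hues))
  cols <- grDevices::hsv(hues, s = 0.85, v = 1)
  rgb <- grDevices::col2rgb(cols) / 255
  pos <- labels > 0L
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[pos] <- rgb[ch, labels[pos]]
    out[, , ch] <- plane
  }
  out
}

#' @export
plot.segmentation_result <- function(x, ...) {
  rgb <- label2rgb(x$labels)
  op <- graphics::par(mar = c(0, 0, 2, 0))
  on.exit(graphics::par(op))
  graphics::plot(c(0, ncol(x$labels)), c(0, nrow(x$labels)), type = "n",
                 asp = 1, axes = FALSE, xlab = "", ylab = "",
                 main = sprintf("%d droplet regions", nrow(x$regions)))
  graphics::rasterImage(rgb, 0, 0, ncol(x$labels), nrow(x$labels))
  invisible(x)
}
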