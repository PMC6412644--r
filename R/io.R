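#' Read a carrier image from disk
#'
#' Reads PNG, TIFF or JPEG rasters, normalizes them to `[0, 1]` floats and
#' attaches acquisition metadata. Metadata can come from the arguments or
#' from a sidecar JSON file (`<path>.json` with any of the keys
#' `scale_cm_per_px`, `illumination_lx`, `polarity`); explicit arguments
#' win over the sidecar.
#'
#' @param path Image file path.
#' @param scale Spatial scale in cm per pixel (required here or in the
#'   sidecar).
#' @param illumination Ambient illumination in lux, or `NULL`.
#' @param polarity `"dark"` or `"bright"`, or `NULL` to take the sidecar
#'   value (default `"dark"` when absent).
#' @return A [carrier_image()].
#' @export
read_carrier_image <- function(path, scale = NULL, illumination = NULL,
                               polarity = NULL) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  img <- try(EBImage::readImage(path), silent = TRUE)
  if (inherits(img, "try-error"))
    stop("unreadable or unsupported image file: ", path)
  px <- EBImage::imageData(img)
  if (length(dim(px)) == 3L && dim(px)[3] > 3L)
    px <- px[, , 1:3] # drop alpha
  px <- pmin(pmax(px, 0), 1)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  if (is.null(scale)) scale <- meta$scale_cm_per_px
  if (is.null(scale))
    stop("no spatial scale given (argument or sidecar ", sidecar, ")")
  if (is.null(illumination) && !is.null(meta$illumination_lx))
    illumination <- as.numeric(meta$illumination_lx)
  if (is.null(polarity))
    polarity <- if (!is.null(meta$polarity)) meta$polarity else "dark"
  carrier_image(px, scale = as.numeric(scale), illumination = illumination,
                polarity = polarity)
}

#' Write a carrier image (or plain raster) to disk
#'
#' @param image A [carrier_image()] or numeric raster in `[0, 1]`.
#' @param path Output path; format follows the extension (png/tiff/jpeg).
#' @return The path, invisibly.
#' @export
write_carrier_image <- function(image, path) {
  px <- if (inherits(image, "carrier_image")) image$pixels else image
  EBImage::writeImage(EBImage::Image(px,
    colormode = if (length(dim(px)) == 3L) "Color" else "Grayscale"), path)
  invisible(path)
}

#' Write a label image
#'
#' Region labels are stored losslessly as a 16-bit grayscale TIFF
#' (value = label index).
#'
#' @param labels Integer label matrix (values 0..65535).
#' @param path Output path (`.tif`/`.tiff`).
#' @return The path, invisibly.
#' @export
write_label_image <- function(labels, path) {
  labels <- as_gray_matrix(labels)
  if (max(labels) > 65535) stop("more than 65535 labels")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a label image written by [write_label_image()]
#'
#' @param path Path to the 16-bit label TIFF.
#' @return Integer label matrix.
#' @export
read_label_image <- function(path) {
  m <- tiff::readTIFF(path)
  storage.mode(m) <- "double"
  lab <- round(m * 65535)
  storage.mode(lab) <- "integer"
  lab
}

#' Serialize a deposition report
#'
#' Writes the machine-readable JSON summary and, optionally, the
#' per-region CSV table.
#'
#' @param report A [deposition_report()].
#' @param json_path Output JSON path.
#' @param csv_path Optional per-region CSV path.
#' @return `json_path`, invisibly.
#' @export
write_report <- function(report, json_path, csv_path = NULL) {
  stopifnot(inherits(report, "deposition_report"))
  payload <- list(
    schema_version = report$schema_version,
    n_droplets = report$n_droplets,
    coverage_pct = report$coverage_pct,
    coverage_density_n_cm2 = report$coverage_density,
    image_area_cm2 = report$image_area_cm2,
    scale_cm_per_px = report$scale,
    per_region = report$per_region)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  if (!is.null(csv_path))
    utils::write.csv(report$per_region, csv_path, row.names = FALSE)
  invisible(json_path)
}

#' Read back a serialized deposition report
#'
#' @param json_path Path written by [write_report()].
#' @return A `deposition_report`.
#' @export
read_report <- function(json_path) {
  x <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  per_region <- if (length(x$per_region)) as.data.frame(x$per_region)
                else data.frame()
  structure(list(n_droplets = x$n_droplets,
                 coverage_pct = x$coverage_pct,
                 coverage_density = x$coverage_density_n_cm2,
                 image_area_cm2 = x$image_area_cm2,
                 per_region = per_region,
                 scale = x$scale_cm_per_px,
                 schema_version = x$schema_version),
            class = "deposition_report")
}
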