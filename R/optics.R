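#' Beer-Lambert ink model for the deposition carrier
#'
#' The achromatic-ink carrier sits between the ambient light and the camera
#' inside the detection box. Dry ink is opaque; a droplet clears it locally.
#' Light transmitted through an ink layer of thickness `L` cm follows the
#' Beer-Lambert law `It = Io * 10^(-tau * L)`, where `tau` collects the
#' absorption coefficient and (constant) pigment concentration of the dry
#' ink. An `ink_model` bundles the fitted mean absorbance coefficient with
#' the transmitted-light target below which droplet/background separation is
#' stable.
#'
#' @param tau_mean Absorbance coefficient per cm of ink (dimensionless per
#'   cm). The default 257.11 is the calibrated constant for T-310
#'   achromatic ink on silicone oil paper.
#' @param it_threshold Transmitted-light target in lux. Below this in-box
#'   intensity the segmentation contrast no longer depends on ambient
#'   illumination; default 50 Lx.
#' @return An object of class `ink_model`.
#' @examples
#' m <- ink_model()
#' required_thickness(3540, m) # ~0.0072 cm
#' @export
ink_model <- function(tau_mean = 257.11, it_threshold = 50) {
  stopifnot(is.numeric(tau_mean), length(tau_mean) == 1L, is.finite(tau_mean),
            is.numeric(it_threshold), length(it_threshold) == 1L,
            is.finite(it_threshold))
  if (tau_mean <= 0) stop("tau_mean must be positive")
  if (it_threshold <= 0) stop("it_threshold must be positive")
  structure(list(tau_mean = tau_mean, it_threshold = it_threshold),
            class = "ink_model")
}

#' @export
print.ink_model <- function(x, ...) {
  cat("Beer-Lambert ink model\n")
  cat(sprintf("  tau_mean:     %.4g per cm\n", x$tau_mean))
  cat(sprintf("  it_threshold: %.4g Lx\n", x$it_threshold))
  invisible(x)
}

#' Absorbance of the ink layer
#'
#' Decadic absorbance `A = log10(Io / It)` of a medium given incident and
#' transmitted intensities.
#'
#' @param io Incident (ambient) intensity in lux; must be positive.
#' @param it Transmitted intensity in lux; must be positive.
#' @return Dimensionless absorbance; 0 when `io == it`.
#' @export
absorbance <- function(io, it) {
  stopifnot(is.numeric(io), is.numeric(it))
  if (any(!is.finite(io)) || any(!is.finite(it)))
    stop("intensities must be finite")
  if (any(io <= 0) || any(it <= 0))
    stop("intensities must be positive")
  log10(io / it)
}

#' Transmitted intensity through an ink layer
#'
#' Inverts the absorbance relation: `It = Io * 10^(-tau * L)`.
#'
#' @param io Incident intensity in lux (>= 0).
#' @param thickness Ink thickness in cm (>= 0).
#' @param tau Absorbance coefficient per cm (> 0).
#' @return Transmitted intensity in lux.
#' @export
transmitted_intensity <- function(io, thickness, tau) {
  stopifnot(is.numeric(io), is.numeric(thickness), is.numeric(tau))
  if (any(io < 0)) stop("io must be non-negative")
  if (any(thickness < 0)) stop("thickness must be non-negative")
  if (any(tau <= 0)) stop("tau must be positive")
  io * 10^(-tau * thickness)
}

#' Minimum ink thickness for a given ambient illumination
#'
#' The ink layer must be thick enough that the light transmitted into the
#' detection box falls to the model's transmitted-light target:
#' `L = (1 / tau_mean) * log10(io / it_threshold)`. With the default
#' calibration this is `L = log10(Io / 50) / 257.11`.
#'
#' @param io Ambient illumination in lux; must exceed the model's
#'   transmitted-light target (otherwise no ink is needed and the relation
#'   is undefined).
#' @param model An [ink_model()].
#' @return Required ink thickness in cm; strictly increasing in `io`.
#' @examples
#' required_thickness(3540, ink_model()) # 0.0072 cm at 4 decimal places
#' @export
required_thickness <- function(io, model = ink_model()) {
  stopifnot(inherits(model, "ink_model"), is.numeric(io))
  if (any(!is.finite(io))) stop("io must be finite")
  if (any(io <= model$it_threshold))
    stop("io must exceed the transmitted-light threshold (",
         model$it_threshold, " Lx)")
  absorbance(io, model$it_threshold) / model$tau_mean
}

#' Fit the mean absorbance coefficient from calibration readings
#'
#' Each calibration reading pairs an ambient intensity `io` with the ink
#' thickness `li` at which the transmitted light equals `it_threshold`.
#' The per-reading coefficient is `log10(io / it_threshold) / li`; the
#' fitted value is their arithmetic mean.
#'
#' @param readings A data frame with numeric columns `io` (lux) and `li`
#'   (cm), one row per calibration test.
#' @param it_threshold Transmitted-light target in lux (default 50).
#' @return The mean absorbance coefficient per cm.
#' @export
fit_tau_mean <- function(readings, it_threshold = 50) {
  if (!is.data.frame(readings) || !all(c("io", "li") %in% names(readings)))
    stop("readings must be a data frame with columns 'io' and 'li'")
  if (nrow(readings) < 1L) stop("at least one reading is required")
  io <- readings$io
  li <- readings$li
  if (any(!is.finite(io)) || any(!is.finite(li)))
    stop("readings must be finite")
  if (any(li <= 0)) stop("all ink thicknesses li must be positive")
  if (any(io <= it_threshold))
    stop("all intensities io must exceed it_threshold")
  mean(log10(io / it_threshold) / li)
}
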