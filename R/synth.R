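#' Specification of a synthetic droplet scene
#'
#' Describes a ground-truthed synthetic carrier image. Droplet stains are
#' rendered as anti-aliased disks whose brightness against the dark ink
#' background follows the Beer-Lambert carrier optics: the background is
#' the light transmitted through the full ink layer at the given ambient
#' illumination, the spots transmit almost all of it. A configurable
#' fraction of droplets is placed to overlap a neighbour (adhesive pairs).
#'
#' Defaults emulate the deposition conditions the detector targets: a
#' 576 x 576 px window at 0.002 cm/px (a 1.33 cm^2 test window), 200
#' droplets (about 150 n/cm^2), 15% of droplets in adhesive pairs,
#' ambient illumination 3550 Lx over 0.01 cm of ink, and mild sensor
#' noise (sd 0.02).
#'
#' @param width_px,height_px Image size in pixels.
#' @param scale Spatial scale in cm per pixel.
#' @param n_droplets Number of droplets (ground-truth count).
#' @param radius_meanlog,radius_sdlog Log-normal radius law in pixels;
#'   radii are clamped to >= 2 px.
#' @param adhesion_fraction Fraction of droplets that belong to an
#'   adhesive pair (each pair consumes two droplets).
#' @param illumination Ambient illumination in lux.
#' @param ink_thickness Ink layer thickness in cm.
#' @param tau_mean Absorbance coefficient per cm (default 257.11).
#' @param spot_transmission Fraction of ambient light transmitted through a
#'   cleared (wet) spot (default 0.85).
#' @param camera_full_scale_lx Illuminance mapped to pixel value 1.0
#'   (default 4000 Lx).
#' @param edge_darkening Radial attenuation of a spot at its rim: the spot
#'   profile is `1 - edge_darkening * rho^2` with `rho` the normalized
#'   center distance (default 0.35). Stains clear less at their rim, which
#'   also gives each droplet an intensity peak.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise.
#' @param supersample Anti-aliasing supersampling factor (default 4).
#' @param seed RNG seed; scenes are bit-reproducible given a seed.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(width_px = 576, height_px = 576, scale = 0.002,
                       n_droplets = 200,
                       radius_meanlog = log(4.5), radius_sdlog = 0.22,
                       adhesion_fraction = 0.15,
                       illumination = 3550, ink_thickness = 0.01,
                       tau_mean = 257.11,
                       spot_transmission = 0.85,
                       camera_full_scale_lx = 4000,
                       edge_darkening = 0.35,
                       noise_sd = 0.02, supersample = 4, seed = NULL) {
  stopifnot(width_px >= 8, height_px >= 8, scale > 0, n_droplets >= 0,
            adhesion_fraction >= 0, adhesion_fraction <= 1,
            illumination > 0, ink_thickness >= 0, tau_mean > 0,
            spot_transmission > 0, spot_transmission <= 1,
            camera_full_scale_lx > 0,
            edge_darkening >= 0, edge_darkening < 1,
            noise_sd >= 0, supersample >= 1)
  structure(as.list(environment()), class = "scene_spec")
}

# circle-circle intersection (lens) area
lens_area <- function(d, r1, r2) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(pi * min(r1, r2)^2)
  r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1)) +
    r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2)) -
    0.5 * sqrt((-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) * (d + r1 + r2))
}

# rejection-sampled droplet layout honouring the adhesion plan
place_droplets <- function(spec) {
  n <- spec$n_droplets
  radii <- pmax(2, rlnorm(n, spec$radius_meanlog, spec$radius_sdlog))
  n_pairs <- round(n * spec$adhesion_fraction / 2)
  n_primary <- n - n_pairs
  centers <- matrix(NA_real_, n, 2)
  gap <- 3
  max_tries <- 500L
  ok_pos <- function(i, cr, cc) {
    m <- radii[i] + 2
    if (cr < m || cc < m || cr > spec$height_px - m || cc > spec$width_px - m)
      return(FALSE)
    placed <- which(!is.na(centers[, 1]))
    placed <- setdiff(placed, i)
    if (!length(placed)) return(TRUE)
    dd <- sqrt((centers[placed, 1] - cr)^2 + (centers[placed, 2] - cc)^2)
    all(dd >= radii[placed] + radii[i] + gap)
  }
  for (i in seq_len(n_primary)) {
    tries <- 0L
    repeat {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("infeasible packing: too many droplets for the image area")
      cr <- runif(1, 1, spec$height_px)
      cc <- runif(1, 1, spec$width_px)
      if (ok_pos(i, cr, cc)) break
    }
    centers[i, ] <- c(cr, cc)
  }
  pairs <- if (n_pairs > 0) cbind(seq_len(n_pairs), n_primary + seq_len(n_pairs))
           else matrix(integer(), 0, 2)
  for (k in seq_len(n_pairs)) {
    i <- n_primary + k
    host <- k
    tries <- 0L
    repeat {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("infeasible packing: could not attach an adhesive partner")
      dist <- (radii[host] + radii[i]) * runif(1, 0.6, 0.95)
      ang <- runif(1, 0, 2 * pi)
      cr <- centers[host, 1] + dist * sin(ang)
      cc <- centers[host, 2] + dist * cos(ang)
      m <- radii[i] + 2
      if (cr < m || cc < m || cr > spec$height_px - m ||
          cc > spec$width_px - m) next
      placed <- which(!is.na(centers[, 1]))
      placed <- setdiff(placed, c(i, host))
      dd <- if (length(placed))
        sqrt((centers[placed, 1] - cr)^2 + (centers[placed, 2] - cc)^2)
      else numeric(0)
      if (all(dd >= radii[placed] + radii[i] + gap)) break
    }
    centers[i, ] <- c(cr, cc)
  }
  union_px <- sum(pi * radii^2)
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      a <- pairs[k, 1]; b <- pairs[k, 2]
      d <- sqrt(sum((centers[a, ] - centers[b, ])^2))
      union_px <- union_px - lens_area(d, radii[a], radii[b])
    }
  }
  list(centers = centers, radii = radii, pairs = pairs, union_px = union_px)
}

render_layout <- function(layout, spec, illumination) {
  s <- as.integer(spec$supersample)
  nr <- spec$height_px; nc <- spec$width_px
  v_bg <- min(transmitted_intensity(illumination, spec$ink_thickness,
                                    spec$tau_mean) /
                spec$camera_full_scale_lx, 1)
  v_spot <- min(illumination * spec$spot_transmission /
                  spec$camera_full_scale_lx, 1)
  fld <- matrix(v_bg, nr * s, nc * s)
  n <- nrow(layout$centers)
  for (i in seq_len(n)) {
    cr <- layout$centers[i, 1]; cc <- layout$centers[i, 2]
    r <- layout$radii[i]
    ri <- max(1L, floor((cr - r - 1) * s)):min(nr * s, ceiling((cr + r + 1) * s))
    ci <- max(1L, floor((cc - r - 1) * s)):min(nc * s, ceiling((cc + r + 1) * s))
    yr <- (ri - 0.5) / s - cr
    yc <- (ci - 0.5) / s - cc
    rho2 <- outer(yr^2, yc^2, "+") / r^2
    val <- v_spot * (1 - spec$edge_darkening * rho2)
    val[rho2 > 1] <- -Inf
    fld[ri, ci] <- pmax(fld[ri, ci], val)
  }
  img <- colMeans(aperm(array(fld, c(s, nr, s, nc)), c(1, 3, 2, 4)), dims = 2)
  if (spec$noise_sd > 0)
    img <- img + matrix(rnorm(nr * nc, sd = spec$noise_sd), nr, nc)
  pmin(pmax(img, 0), 1)
}

#' Generate a ground-truthed synthetic droplet scene
#'
#' Renders the scene described by a [scene_spec()] and returns it together
#' with its ground truth: droplet centers and radii (in pixel coordinates),
#' the adhesive pair index list, the true count and the analytic union
#' coverage (inclusion-exclusion over the adhesive lenses).
#'
#' @param spec A [scene_spec()].
#' @param illumination Optional illumination override in lux.
#' @return An object of class `synthetic_scene` with fields `image`
#'   (a [carrier_image()] with bright spots), `truth_centers`,
#'   `truth_radii`, `truth_adhesion_pairs`, `truth_n`,
#'   `truth_coverage_pct` and `spec`.
#' @examples
#' sc <- generate_scene(scene_spec(n_droplets = 10, width_px = 128,
#'                                 height_px = 128, seed = 7))
#' sc
#' @export
generate_scene <- function(spec, illumination = spec$illumination) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    layout <- place_droplets(spec)
    img <- render_layout(layout, spec, illumination)
    structure(list(
      image = carrier_image(img, scale = spec$scale,
                            illumination = illumination,
                            polarity = "bright"),
      truth_centers = layout$centers,
      truth_radii = layout$radii,
      truth_adhesion_pairs = layout$pairs,
      truth_n = spec$n_droplets,
      truth_coverage_pct = 100 * layout$union_px /
        (spec$width_px * spec$height_px),
      spec = spec), class = "synthetic_scene")
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("synthetic_scene: %d droplets (%d adhesive pairs), %.2f %% coverage\n",
              x$truth_n, nrow(x$truth_adhesion_pairs), x$truth_coverage_pct))
  print(x$image)
  invisible(x)
}

#' Ground-truth foreground mask of a synthetic scene
#'
#' Rasterizes the truth disks (pixel-center-in-disk test).
#'
#' @param scene A `synthetic_scene`.
#' @return Logical matrix of the true droplet pixels.
#' @export
truth_mask <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  d <- dim(scene$image$pixels)[1:2]
  out <- matrix(FALSE, d[1], d[2])
  for (i in seq_len(scene$truth_n)) {
    cr <- scene$truth_centers[i, 1]; cc <- scene$truth_centers[i, 2]
    r <- scene$truth_radii[i]
    ri <- max(1L, floor(cr - r)):min(d[1], ceiling(cr + r))
    ci <- max(1L, floor(cc - r)):min(d[2], ceiling(cc + r))
    hit <- outer((ri - 0.5 - cr)^2, (ci - 0.5 - cc)^2, "+") <= r^2
    out[ri, ci] <- out[ri, ci] | hit
  }
  out
}

#' Render the same droplet layout under a series of illuminations
#'
#' Reuses one seeded droplet layout (and noise realization) across a list
#' of ambient illuminations so that only the optical contrast changes —
#' the training corpus for the contrast-adaptation agent.
#'
#' @param spec A [scene_spec()]; must carry a seed for the layouts to be
#'   identical across the series.
#' @param illum_values Numeric vector of illuminations in lux.
#' @return A list of `synthetic_scene` objects sharing geometry and truth.
#' @export
generate_illumination_series <- function(spec, illum_values) {
  stopifnot(inherits(spec, "scene_spec"), is.numeric(illum_values),
            length(illum_values) >= 1)
  lapply(illum_values, function(il) generate_scene(spec, illumination = il))
}
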