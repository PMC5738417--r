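#' Specify a synthetic nucleus class
#'
#' A class specification parameterises the generator of DAPI-like nuclei:
#' size and shape of the nuclear ellipse, baseline chromatin intensity, and
#' the heterochromatin focus model (number, size, and brightness gain of
#' punctate foci). All intensities are 12-bit counts (0--4095); lengths are
#' pixels at the package-wide pixel size of 0.2150 um.
#'
#' @param name Label for the class (e.g. a cell-line name).
#' @param nucleus_radius_px Mean equivalent radius of the nucleus, px.
#' @param nucleus_radius_sd Standard deviation of the radius across nuclei, px.
#' @param eccentricity_range Length-2 interval in `[0, 1)` from which each
#'   nucleus' eccentricity is drawn uniformly.
#' @param base_intensity Baseline (euchromatin) intensity, counts.
#' @param intensity_noise_sd Per-pixel Gaussian intensity noise, counts.
#' @param foci_mean Mean number of heterochromatin foci (Poisson).
#' @param foci_radius_px Focus radius, px; foci are rendered as Gaussian
#'   bumps with `sigma = foci_radius_px / 2`, truncated at 3 sigma.
#' @param foci_gain Peak multiplicative intensity of a focus relative to the
#'   baseline (>= 1); a focus peaks at `base_intensity * foci_gain`.
#'
#' @return An object of class `nm_class_spec`.
#' @seealso [synth_nucleus()], [synth_field()], [preset_classes()]
#' @export
class_spec <- function(name,
                       nucleus_radius_px = 24,
                       nucleus_radius_sd = 2.5,
                       eccentricity_range = c(0.1, 0.6),
                       base_intensity = 1500,
                       intensity_noise_sd = 40,
                       foci_mean = 5,
                       foci_radius_px = 2.5,
                       foci_gain = 1.3) {
  stopifnot(is.character(name), length(name) == 1)
  if (nucleus_radius_px <= 0 || nucleus_radius_sd < 0) {
    abort("nucleus radius parameters must be positive")
  }
  if (length(eccentricity_range) != 2 ||
      any(eccentricity_range < 0) || any(eccentricity_range >= 1) ||
      diff(eccentricity_range) < 0) {
    abort("`eccentricity_range` must be an ordered interval within [0, 1)")
  }
  if (base_intensity < 0 || base_intensity > MAX_COUNT) {
    abort("`base_intensity` must be a 12-bit count")
  }
  if (intensity_noise_sd < 0) abort("`intensity_noise_sd` must be >= 0")
  if (foci_mean < 0) abort("`foci_mean` must be >= 0")
  if (foci_radius_px <= 0) abort("`foci_radius_px` must be > 0")
  if (foci_gain < 1) abort("`foci_gain` must be >= 1")
  structure(
    list(name = name,
         nucleus_radius_px = nucleus_radius_px,
         nucleus_radius_sd = nucleus_radius_sd,
         eccentricity_range = eccentricity_range,
         base_intensity = base_intensity,
         intensity_noise_sd = intensity_noise_sd,
         foci_mean = foci_mean,
         foci_radius_px = foci_radius_px,
         foci_gain = foci_gain),
    class = "nm_class_spec")
}

#' @export
print.nm_class_spec <- function(x, ...) {
  cat("<nm_class_spec>", x$name, "\n")
  cat(sprintf("  radius %.1f +/- %.1f px, eccentricity [%.2f, %.2f]\n",
              x$nucleus_radius_px, x$nucleus_radius_sd,
              x$eccentricity_range[1], x$eccentricity_range[2]))
  cat(sprintf("  base %d counts (noise sd %.0f); foci: mean %.1f, r %.1f px, gain %.2f\n",
              round(x$base_intensity), x$intensity_noise_sd,
              x$foci_mean, x$foci_radius_px, x$foci_gain))
  invisible(x)
}

#' Built-in synthetic class presets
#'
#' Two classes bracketing the chromatin-condensation axis the pipeline is
#' designed to measure: `"open"` emulates a normal-like nucleus with few
#' heterochromatin foci, and `"condensed"` a transformed-like nucleus with
#' many (higher HC/EC ratio). Individual foci are identical objects in both
#' classes (same radius and peak gain, as for real heterochromatin puncta);
#' the classes differ in focus density, so texture -- not the brightness of
#' any single structure -- carries the class signal. Geometry and baseline
#' intensity are shared.
#'
#' @return Named list of two [class_spec()] objects.
#' @export
preset_classes <- function() {
  list(
    open = class_spec("open",
                      nucleus_radius_px = 24, nucleus_radius_sd = 2.5,
                      eccentricity_range = c(0.1, 0.6),
                      base_intensity = 1500, intensity_noise_sd = 40,
                      foci_mean = 5, foci_radius_px = 2.5, foci_gain = 2.0),
    condensed = class_spec("condensed",
                           nucleus_radius_px = 24, nucleus_radius_sd = 2.5,
                           eccentricity_range = c(0.1, 0.6),
                           base_intensity = 1500, intensity_noise_sd = 40,
                           foci_mean = 30, foci_radius_px = 2.5, foci_gain = 2.0)
  )
}

#' Specify an acquisition-noise corruption
#'
#' Describes the three microscope noise modes the quality-control stages are
#' built to catch: overexposure (a fraction of nucleus pixels saturating
#' above 3700 counts), drift blur (linear motion blur from specimen drift,
#' which destroys texture while approximately preserving the intensity
#' histogram), and edge placement (a nucleus overlapping the frame border,
#' whose rim is corrupted by deconvolution edge blur).
#'
#' @param overexposure_fraction Fraction of targeted-nucleus pixels forced
#'   above 3700 counts (0 disables).
#' @param drift_vector Integer `(dx, dy)` extent of the motion-blur kernel
#'   in pixels; `c(0, 0)` disables.
#' @param place_on_edge If `TRUE`, the targeted nucleus is translated so its
#'   mask intersects the frame border.
#' @return An object of class `nm_noise_spec`.
#' @export
noise_spec <- function(overexposure_fraction = 0,
                       drift_vector = c(0L, 0L),
                       place_on_edge = FALSE) {
  if (overexposure_fraction < 0 || overexposure_fraction > 1) {
    abort("`overexposure_fraction` must be in [0, 1]")
  }
  if (length(drift_vector) != 2 || any(drift_vector != round(drift_vector))) {
    abort("`drift_vector` must be two integers")
  }
  structure(list(overexposure_fraction = overexposure_fraction,
                 drift_vector = as.integer(drift_vector),
                 place_on_edge = isTRUE(place_on_edge)),
            class = "nm_noise_spec")
}

#' @export
print.nm_noise_spec <- function(x, ...) {
  modes <- c(
    if (x$overexposure_fraction > 0)
      sprintf("overexposure %.0f%%", 100 * x$overexposure_fraction),
    if (any(x$drift_vector != 0))
      sprintf("drift (%d, %d) px", x$drift_vector[1], x$drift_vector[2]),
    if (x$place_on_edge) "edge placement")
  cat("<nm_noise_spec>",
      if (length(modes)) paste(modes, collapse = " + ") else "no-op", "\n")
  invisible(x)
}
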