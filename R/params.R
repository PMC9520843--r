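#' Simulation parameters for synthetic fields of view
#'
#' Bundles everything the synthetic-micrograph generator needs: field
#' geometry, vesicle density and size, photometry of the detection and
#' secondary channels, background texture, and the camera noise model.
#' Identical parameter sets (including `seed`) reproduce bit-identical
#' fields.
#'
#' Vesicles are rendered as isotropic 2D Gaussian blobs (SD = radius / 2),
#' the standard approximation of diffraction-blurred confocal puncta, on a
#' smooth random background. Secondary channels (e.g. Endoglin, SMAD1) carry
#' an enriched copy of each truly positive vesicle and only a small bleed
#' for negative vesicles, so the enrichment classifier has real work to do.
#'
#' @param field_shape integer (rows, cols) in pixels.
#' @param vesicle_density expected vesicles per 1000 px^2; the realized
#'   count is Poisson with mean `density * rows * cols / 1000`.
#' @param radius_range (min, max) vesicle radius in px; radii are uniform.
#' @param primary_amplitude mean peak intensity of a vesicle above
#'   background in the detection channel (arbitrary units).
#' @param secondary_enrichment_factor multiplicative boost applied to a
#'   vesicle's amplitude in a secondary channel when it is truly positive
#'   for that marker (> 1).
#' @param true_positive_fraction probability in `[0, 1]` that a vesicle is
#'   positive for the default secondary marker.
#' @param background_level mean background intensity.
#' @param background_sd SD of the smooth background variation (0 gives a
#'   perfectly flat background).
#' @param background_smoothness correlation length (Gaussian blur sigma, px)
#'   of the background random field.
#' @param gaussian_noise_sd additive read-noise SD.
#' @param poisson_noise logical; apply shot noise to the expected signal
#'   before read noise.
#' @param bleed_fraction fraction of a vesicle's primary amplitude that
#'   leaks into a secondary channel when the vesicle is negative for that
#'   marker, so negatives are dim but not blank.
#' @param amplitude_jitter per-vesicle amplitudes are drawn uniformly in
#'   `primary_amplitude * (1 +/- amplitude_jitter)`.
#' @param min_separation minimum center-to-center distance in px enforced by
#'   rejection sampling (0 disables; use ~2x max radius for guaranteed
#'   non-overlapping vesicles).
#' @param detection_channel name of the channel vesicles are detected in.
#' @param secondary_channels named list describing the secondary markers;
#'   each element is a list with `enrichment_factor`, `positive_fraction`,
#'   optional `conditional_on` (name of another secondary channel:
#'   positivity is then drawn only among vesicles positive for that
#'   channel, giving nested co-positivity) and optional `bleed_fraction`.
#'   Default: a single channel `"endoglin"` built from the scalar
#'   arguments.
#' @param condition_label free-text condition tag (e.g. "LSS", "HSS").
#' @param seed integer RNG seed.
#' @return an object of class `SimulationParams`.
#' @seealso [simulate_field()], [shear_presets()]
#' @export
simulation_params <- function(field_shape = c(512L, 512L),
                              vesicle_density = 0.8,
                              radius_range = c(2, 5),
                              primary_amplitude = 60,
                              secondary_enrichment_factor = 3,
                              true_positive_fraction = 0.5,
                              background_level = 100,
                              background_sd = 6,
                              background_smoothness = 20,
                              gaussian_noise_sd = 4,
                              poisson_noise = TRUE,
                              bleed_fraction = 0.1,
                              amplitude_jitter = 0.2,
                              min_separation = 0,
                              detection_channel = "cav1",
                              secondary_channels = NULL,
                              condition_label = "field",
                              seed = 1L) {
  p <- list(
    field_shape = as.integer(field_shape),
    vesicle_density = vesicle_density,
    radius_range = as.numeric(radius_range),
    primary_amplitude = primary_amplitude,
    secondary_enrichment_factor = secondary_enrichment_factor,
    true_positive_fraction = true_positive_fraction,
    background_level = background_level,
    background_sd = background_sd,
    background_smoothness = background_smoothness,
    gaussian_noise_sd = gaussian_noise_sd,
    poisson_noise = isTRUE(poisson_noise),
    bleed_fraction = bleed_fraction,
    amplitude_jitter = amplitude_jitter,
    min_separation = min_separation,
    detection_channel = detection_channel,
    secondary_channels = secondary_channels,
    condition_label = condition_label,
    seed = as.integer(seed)
  )
  if (is.null(p$secondary_channels)) {
    p$secondary_channels <- list(endoglin = list(
      enrichment_factor = secondary_enrichment_factor,
      positive_fraction = true_positive_fraction
    ))
  }
  validate_simulation_params(p)
  structure(p, class = "SimulationParams")
}

validate_simulation_params <- function(p) {
  .assert(length(p$field_shape) == 2L && all(p$field_shape >= 8L),
          "field_shape must be two integers >= 8")
  num <- c(p$vesicle_density, p$radius_range, p$primary_amplitude,
           p$secondary_enrichment_factor, p$true_positive_fraction,
           p$background_level, p$background_sd, p$background_smoothness,
           p$gaussian_noise_sd, p$bleed_fraction, p$amplitude_jitter,
           p$min_separation)
  .assert(all(is.finite(num)) && all(num >= 0),
          "simulation parameters must be finite and non-negative")
  .assert(p$true_positive_fraction <= 1, "true_positive_fraction must be in [0, 1]")
  .assert(p$radius_range[1] <= p$radius_range[2],
          "radius_range must satisfy min <= max")
  .assert(p$amplitude_jitter < 1, "amplitude_jitter must be < 1")
  .assert(is.character(p$detection_channel) && nzchar(p$detection_channel),
          "detection_channel must be a non-empty name")
  .assert(length(p$secondary_channels) >= 1 &&
            !is.null(names(p$secondary_channels)) &&
            all(nzchar(names(p$secondary_channels))),
          "secondary_channels must be a named list")
  for (nm in names(p$secondary_channels)) {
    s <- p$secondary_channels[[nm]]
    pf <- s$positive_fraction %||% p$true_positive_fraction
    .assert(.is_number(pf) && pf >= 0 && pf <= 1,
            "positive_fraction of channel '%s' must be in [0, 1]", nm)
    cond <- s$conditional_on
    .assert(is.null(cond) || cond %in% names(p$secondary_channels),
            "conditional_on of channel '%s' names an unknown channel", nm)
  }
  invisible(p)
}

#' Default simulation presets for the two shear-stress conditions
#'
#' Encodes the qualitative biology the pipeline is built to quantify: under
#' low laminar shear stress (LSS, atheroprone) endothelial cells form more
#' Caveolin-1 vesicles, more of them are Endoglin-positive, and more of the
#' Endoglin-positive ones carry SMAD1, than under high laminar shear stress
#' (HSS, atheroprotective). Magnitudes are order-of-magnitude choices (no
#' public per-field counts exist), not measured values.
#'
#' @param field_shape (rows, cols) of each simulated field.
#' @param seed base seed stored in each preset (usually overridden by
#'   [simulate_experiment()]).
#' @return named list with `SimulationParams` elements `LSS` and `HSS`.
#' @export
shear_presets <- function(field_shape = c(512L, 512L), seed = 1L) {
  chans <- function(tpf_eng, frac_eea1, frac_smad1) list(
    endoglin = list(enrichment_factor = 3, positive_fraction = tpf_eng),
    eea1     = list(enrichment_factor = 3, positive_fraction = frac_eea1),
    smad1    = list(enrichment_factor = 3, positive_fraction = frac_smad1,
                    conditional_on = "endoglin")
  )
  list(
    LSS = simulation_params(
      field_shape = field_shape, vesicle_density = 0.8,
      true_positive_fraction = 0.6,
      secondary_channels = chans(0.6, 0.7, 0.45),
      condition_label = "LSS", seed = seed
    ),
    HSS = simulation_params(
      field_shape = field_shape, vesicle_density = 0.4,
      true_positive_fraction = 0.35,
      secondary_channels = chans(0.35, 0.5, 0.3),
      condition_label = "HSS", seed = seed
    )
  )
}

#' Vesicle detection parameters
#'
#' Controls the detect stage: pre-smoothing, top-hat background subtraction,
#' automatic thresholding, hole filling, connected-component labeling and
#' the particle filters (area and circularity). The defaults suit endosome-
#' scale puncta at typical confocal sampling and are deliberate choices, all
#' overridable.
#'
#' @param background_radius radius (px) of the disc structuring element used
#'   for the white top-hat background subtraction; should exceed the largest
#'   vesicle radius by severalfold.
#' @param threshold_method `"otsu"` (default), `"triangle"`, or a fixed
#'   numeric threshold applied to the background-subtracted raster.
#' @param smoothing_sigma Gaussian pre-smoothing sigma in px applied before
#'   background subtraction (0 disables); suppresses single-pixel shot
#'   noise that would otherwise survive the top-hat.
#' @param min_area,max_area inclusive component area bounds in px^2.
#' @param min_circularity minimum circularity, `4 * pi * area / perimeter^2`
#'   (1 for a perfect disc), inclusive.
#' @param fill_holes logical; fill holes in the thresholded mask before
#'   labeling.
#' @param connectivity 4 or 8 (pixel neighborhood for labeling).
#' @param noise_floor_k automatic thresholds are clamped from below at
#'   `median + k * MAD` of the background-subtracted raster, so a field
#'   containing no real puncta yields no detections (histogram-splitting
#'   methods otherwise bisect pure noise). 0 disables; ignored for fixed
#'   numeric thresholds.
#' @return an object of class `DetectionParams`.
#' @export
detection_params <- function(background_radius = 15,
                             threshold_method = "otsu",
                             smoothing_sigma = 1,
                             min_area = 4,
                             max_area = 400,
                             min_circularity = 0.3,
                             fill_holes = TRUE,
                             connectivity = 8L,
                             noise_floor_k = 4) {
  .assert(.is_number(background_radius) && background_radius > 0,
          "background_radius must be > 0")
  .assert(is.numeric(threshold_method) ||
            threshold_method %in% c("otsu", "triangle"),
          "threshold_method must be 'otsu', 'triangle' or a number")
  .assert(.is_number(min_area) && .is_number(max_area) && min_area <= max_area,
          "min_area must be <= max_area")
  .assert(.is_number(min_circularity) &&
            min_circularity >= 0 && min_circularity <= 1,
          "min_circularity must be in [0, 1]")
  .assert(connectivity %in% c(4L, 8L), "connectivity must be 4 or 8")
  .assert(.is_number(noise_floor_k) && noise_floor_k >= 0,
          "noise_floor_k must be >= 0")
  structure(list(
    background_radius = background_radius,
    threshold_method = threshold_method,
    smoothing_sigma = smoothing_sigma,
    min_area = min_area, max_area = max_area,
    min_circularity = min_circularity,
    fill_holes = isTRUE(fill_holes),
    connectivity = as.integer(connectivity),
    noise_floor_k = noise_floor_k
  ), class = "DetectionParams")
}

#' Enrichment-classification parameters
#'
#' Parameters of the object-based positivity rule: a vesicle is positive for
#' a marker when its mean intensity in that marker's channel is at least
#' `(1 + f)` times the reference intensity of the same image (default
#' reference: the mean over all pixels of the channel). The default
#' `f = 0.15` is the "at least 15% higher than the image mean" rule.
#'
#' @param f relative enrichment margin (>= 0); default 0.15.
#' @param reference_scope which pixels define the image reference mean:
#'   `"image"` (all pixels, default), `"outside"` (pixels outside every
#'   vesicle), or `"vesicles"` (pixels inside vesicles).
#' @param measure_on `"raw"` (default) measures marker intensities on the
#'   raw raster; `"subtracted"` measures on the background-subtracted
#'   raster (same top-hat radius as detection).
#' @param strict logical; if TRUE the rule uses a strict `>` instead of the
#'   default inclusive `>=` ("at least").
#' @param overrides optional named list of per-marker parameter overrides,
#'   e.g. `list(smad1 = list(f = 0.25))`.
#' @return an object of class `ClassificationParams`.
#' @export
classification_params <- function(f = 0.15,
                                  reference_scope = c("image", "outside", "vesicles"),
                                  measure_on = c("raw", "subtracted"),
                                  strict = FALSE,
                                  overrides = list()) {
  .assert(.is_number(f) && f >= 0, "f must be a finite number >= 0")
  reference_scope <- match.arg(reference_scope)
  measure_on <- match.arg(measure_on)
  structure(list(
    f = f, reference_scope = reference_scope, measure_on = measure_on,
    strict = isTRUE(strict), overrides = overrides
  ), class = "ClassificationParams")
}

# Per-marker view of ClassificationParams with overrides applied.
.marker_params <- function(params, marker) {
  ov <- params$overrides[[marker]]
  if (is.null(ov)) return(params)
  out <- modifyList(unclass(params), ov)
  structure(out, class = "ClassificationParams")
}
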