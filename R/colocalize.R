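#' Measure per-vesicle mean intensity of a channel
#'
#' For each labeled vesicle, the arithmetic mean of the raster over that
#' vesicle's mask pixels, plus the image reference statistic the enrichment
#' rule compares against.
#'
#' @param mask a `LabeledMask` from [detect_vesicles()] (or an integer
#'   label matrix).
#' @param raster the channel to measure, same shape as the mask.
#' @param scope reference statistic scope: `"image"` (mean over all
#'   pixels, default), `"outside"` (pixels with label 0), `"vesicles"`
#'   (pixels with label > 0).
#' @return list with `means` (named numeric vector, one per label) and
#'   `reference` (the image reference mean).
#' @export
measure_channel <- function(mask, raster, scope = "image") {
  lab <- if (inherits(mask, "LabeledMask")) mask$labels else mask
  .assert(identical(dim(lab), dim(raster)),
          "mask (%d x %d) and raster (%d x %d) shapes differ",
          nrow(lab), ncol(lab), nrow(raster), ncol(raster))
  reference <- switch(scope,
    image = mean(raster),
    outside = mean(raster[lab == 0]),
    vesicles = mean(raster[lab > 0]),
    stop(sprintf("unknown reference scope '%s'", scope), call. = FALSE))
  nlab <- max(lab)
  if (nlab == 0L)
    return(list(means = setNames(numeric(0), character(0)), reference = reference))
  idx <- which(lab > 0)
  labs <- lab[idx]
  means <- as.numeric(rowsum(raster[idx], labs) / tabulate(labs, nlab))
  list(means = setNames(means, seq_len(nlab)), reference = reference)
}

#' Classify vesicles as marker-positive by relative enrichment
#'
#' The object-based positivity rule: a vesicle is positive when its mean
#' intensity is at least `(1 + f)` times the image reference mean of the
#' same channel ("at least f higher than the image mean"; inclusive
#' boundary by default).
#'
#' @param vesicle_means numeric vector of per-vesicle mean intensities.
#' @param image_mean the image reference mean (> 0).
#' @param params a [classification_params()] object (uses `f`, `strict`).
#' @return data.frame with `ratio` (enrichment ratio, vesicle mean / image
#'   mean) and `positive` (logical flag).
#' @examples
#' classify_positive(c(114.9, 115, 130), 100, classification_params(f = 0.15))
#' @export
classify_positive <- function(vesicle_means, image_mean,
                              params = classification_params()) {
  .assert(.is_number(image_mean) && image_mean > 0,
          "degenerate reference: image mean must be > 0 (got %g)", image_mean)
  ratio <- as.numeric(vesicle_means) / image_mean
  positive <- if (params$strict) ratio > 1 + params$f else ratio >= 1 + params$f
  data.frame(ratio = ratio, positive = positive)
}

# Raster a marker's intensities are measured on, honoring measure_on.
.measurement_raster <- function(field, mask, marker, params) {
  raster <- field$channels[[marker]]
  if (params$measure_on == "subtracted")
    raster <- subtract_background(raster,
                                  mask$params$background_radius %||% 15)
  raster
}

#' Measure and classify one marker for every vesicle
#'
#' Convenience wrapper: measures the marker channel inside the vesicle
#' mask, applies the enrichment rule, and appends `mean_<marker>`,
#' `ratio_<marker>` and `pos_<marker>` columns to the vesicle table.
#'
#' @param table a `VesicleTable` from [detect_vesicles()].
#' @param mask the matching `LabeledMask`.
#' @param field the `FieldOfView`.
#' @param marker channel role to classify (e.g. `"endoglin"`).
#' @param params [classification_params()]; per-marker overrides apply.
#' @return the augmented `VesicleTable`.
#' @export
classify_vesicles <- function(table, mask, field, marker,
                              params = classification_params()) {
  .assert(marker %in% names(field$channels),
          "channel '%s' not present in field", marker)
  mp <- .marker_params(params, marker)
  raster <- .measurement_raster(field, mask, marker, mp)
  meas <- measure_channel(mask, raster, scope = mp$reference_scope)
  table[[paste0("mean_", marker)]] <- as.numeric(meas$means[as.character(table$label)])
  if (nrow(table) > 0) {
    cls <- classify_positive(table[[paste0("mean_", marker)]],
                             meas$reference, mp)
    table[[paste0("ratio_", marker)]] <- cls$ratio
    table[[paste0("pos_", marker)]] <- cls$positive
  } else {
    table[[paste0("ratio_", marker)]] <- numeric(0)
    table[[paste0("pos_", marker)]] <- logical(0)
  }
  attr(table, paste0("reference_", marker)) <- meas$reference
  table
}

#' Screen marker-positive vesicles for an additional marker
#'
#' Nested co-positivity: only vesicles positive for every base marker are
#' evaluated against the screen channel, with the same enrichment rule
#' (per-marker `f` override permitted). Vesicles failing the base set get
#' a `FALSE` co-positivity flag, never a missing value.
#'
#' @param table a classified `VesicleTable` carrying `pos_<m>` columns for
#'   all `base_markers`.
#' @param base_markers character vector of marker names whose positivity
#'   gates the screen (e.g. `"endoglin"`; the detection channel itself is
#'   implicitly positive for all detected vesicles).
#' @param screen_channel channel role to screen for (e.g. `"smad1"`).
#' @param mask,field as in [classify_vesicles()].
#' @param params [classification_params()].
#' @return the table with `mean_`/`ratio_` columns for the screen channel
#'   and a `copos_<screen>` logical column.
#' @export
screen_copositive <- function(table, base_markers, screen_channel,
                              mask, field, params = classification_params()) {
  .assert(screen_channel %in% names(field$channels),
          "channel '%s' not present in field", screen_channel)
  base_cols <- paste0("pos_", base_markers)
  .assert(all(base_cols %in% names(table)),
          "base marker flags missing from table: %s",
          paste(setdiff(base_cols, names(table)), collapse = ", "))
  table <- classify_vesicles(table, mask, field, screen_channel, params)
  base_ok <- if (nrow(table) == 0) logical(0)
             else Reduce(`&`, lapply(base_cols, function(cc) table[[cc]]))
  table[[paste0("copos_", screen_channel)]] <-
    base_ok & table[[paste0("pos_", screen_channel)]]
  # the marginal screen flag is kept for inspection but co-positivity is
  # the gated conjunction above
  table
}

#' Multi-channel intensity profile along a line segment
#'
#' Bilinear interpolation of each requested channel at `n_samples`
#' equispaced points from `p0` to `p1`, averaged over `width` parallel
#' lines offset perpendicular to the segment (1 px apart, centered).
#'
#' @param field a `FieldOfView`.
#' @param channels channel roles to profile (default: all).
#' @param p0,p1 segment endpoints as 0-based `(row, col)`; must lie inside
#'   the image.
#' @param width averaging width in px (>= 1).
#' @param n_samples number of sample positions (>= 2).
#' @return a `ProfileResult` data.frame: `position_px` (0 to segment
#'   length), `position_um` when pixel size is set, one intensity column
#'   per channel.
#' @export
line_profile <- function(field, channels = names(field$channels),
                         p0, p1, width = 1L, n_samples = 100L) {
  .assert(inherits(field, "FieldOfView"), "field must be a FieldOfView")
  .assert(all(channels %in% names(field$channels)), "unknown channel in 'channels'")
  .assert(n_samples >= 2, "n_samples must be >= 2")
  .assert(width >= 1, "width must be >= 1")
  shp <- dim(field$channels[[1]])
  for (p in list(p0, p1))
    .assert(length(p) == 2 && p[1] >= 0 && p[1] <= shp[1] - 1 &&
              p[2] >= 0 && p[2] <= shp[2] - 1,
            "segment endpoint (%g, %g) outside image", p[1], p[2])
  len <- sqrt(sum((p1 - p0)^2))
  .assert(len > 0, "segment endpoints coincide")
  u <- (p1 - p0) / len                  # unit direction
  v <- c(-u[2], u[1])                   # unit normal
  pos <- seq(0, len, length.out = n_samples)
  offs <- seq_len(width) - (width + 1) / 2
  out <- data.frame(position_px = pos)
  if (!is.null(field$pixel_size) && field$pixel_size > 0)
    out$position_um <- pos * field$pixel_size
  for (ch in channels) {
    acc <- 0
    for (o in offs) {
      r <- p0[1] + pos * u[1] + o * v[1]
      c <- p0[2] + pos * u[2] + o * v[2]
      acc <- acc + .bilinear(field$channels[[ch]], r, c)
    }
    out[[ch]] <- acc / width
  }
  class(out) <- c("ProfileResult", "data.frame")
  attr(out, "p0") <- p0; attr(out, "p1") <- p1; attr(out, "width") <- width
  out
}
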