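#' Simulate one multi-channel field of view with ground truth
#'
#' Generates a synthetic confocal-like micrograph: a Poisson number of
#' vesicles (mean `vesicle_density * rows * cols / 1000`) is placed
#' uniformly in the field, each rendered as an isotropic Gaussian blob of
#' SD `radius / 2` on a smooth random background; secondary channels carry
#' an enriched copy of truly positive vesicles and a small bleed for
#' negatives; shot (Poisson) and read (Gaussian) noise are applied last.
#' The returned ground truth records centers, radii, per-channel peak
#' amplitudes and true positivity labels before any noise.
#'
#' @param params a [simulation_params()] object.
#' @param render logical; if FALSE, skip raster rendering and return only
#'   the ground truth (fast path for count-level studies).
#' @return a list with elements `field` (a [field_of_view()]; NULL when
#'   `render = FALSE`) and `truth` (a `GroundTruth` data.frame with columns
#'   `id`, `row`, `col`, `radius`, one `amp_<channel>` column per channel
#'   and one `pos_<channel>` logical column per secondary channel).
#' @examples
#' sim <- simulate_field(simulation_params(field_shape = c(128, 128), seed = 7))
#' nrow(sim$truth)
#' @export
simulate_field <- function(params, render = TRUE) {
  validate_simulation_params(params)
  withr::with_seed(params$seed, .simulate_field_impl(params, render))
}

.simulate_field_impl <- function(p, render) {
  nr <- p$field_shape[1]; nc <- p$field_shape[2]
  npix <- as.numeric(nr) * nc

  n <- rpois(1L, p$vesicle_density * npix / 1000)
  centers <- .draw_centers(n, nr, nc, p$min_separation)
  n <- nrow(centers)

  radius <- runif(n, p$radius_range[1], p$radius_range[2])
  amp <- p$primary_amplitude *
    runif(n, 1 - p$amplitude_jitter, 1 + p$amplitude_jitter)

  truth <- data.frame(id = seq_len(n),
                      row = centers[, 1], col = centers[, 2],
                      radius = radius)
  truth[[paste0("amp_", p$detection_channel)]] <- amp

  # positivity labels; conditional channels are drawn among the positives
  # of their parent channel (nested co-positivity)
  sec <- names(p$secondary_channels)
  pos <- list()
  for (nm in sec) {
    s <- p$secondary_channels[[nm]]
    pf <- s$positive_fraction %||% p$true_positive_fraction
    flag <- runif(n) < pf
    if (!is.null(s$conditional_on)) flag <- flag & pos[[s$conditional_on]]
    pos[[nm]] <- flag
  }
  for (nm in sec) {
    s <- p$secondary_channels[[nm]]
    ef <- s$enrichment_factor %||% p$secondary_enrichment_factor
    bf <- s$bleed_fraction %||% p$bleed_fraction
    truth[[paste0("amp_", nm)]] <- ifelse(pos[[nm]], amp * ef, amp * bf)
    truth[[paste0("pos_", nm)]] <- pos[[nm]]
  }
  class(truth) <- c("GroundTruth", "data.frame")
  attr(truth, "condition_label") <- p$condition_label
  attr(truth, "params") <- p

  if (!render) return(list(field = NULL, truth = truth))

  channels <- list()
  for (ch in c(p$detection_channel, sec)) {
    img <- .render_background(nr, nc, p)
    img <- .render_blobs(img, truth$row, truth$col, radius,
                         truth[[paste0("amp_", ch)]])
    if (p$poisson_noise)
      img <- matrix(rpois(npix, pmax(img, 0)), nr, nc)
    if (p$gaussian_noise_sd > 0)
      img <- img + matrix(rnorm(npix, 0, p$gaussian_noise_sd), nr, nc)
    channels[[ch]] <- pmax(img, 0)
  }

  field <- field_of_view(channels, condition_label = p$condition_label,
                         source_path = sprintf("simulated(seed=%d)", p$seed))
  list(field = field, truth = truth)
}

# Smooth random background: white noise blurred at the stated correlation
# length, then standardized so the rendered field has mean exactly
# background_level and SD background_sd.
.render_background <- function(nr, nc, p) {
  if (p$background_sd == 0) return(matrix(p$background_level, nr, nc))
  z <- matrix(rnorm(nr * nc), nr, nc)
  # cap the blur kernel so small fields still work
  rad <- min(2L * ceiling(3 * p$background_smoothness) + 1L,
             min(nr, nc) - (min(nr, nc) + 1L) %% 2L)
  z <- as.matrix(EBImage::gblur(z, sigma = p$background_smoothness, radius = rad))
  p$background_level + p$background_sd * (z - mean(z)) / sd(z)
}

# Add Gaussian blobs; each blob is rendered on a +/- 6 SD patch, which
# retains all but ~1.5e-8 of its mass.
.render_blobs <- function(img, row, col, radius, amp) {
  nr <- nrow(img); nc <- ncol(img)
  for (i in seq_along(row)) {
    if (amp[i] <= 0) next
    s <- radius[i] / 2
    R <- ceiling(6 * s)
    rr <- max(1, floor(row[i]) + 1 - R):min(nr, ceiling(row[i]) + 1 + R)
    cc <- max(1, floor(col[i]) + 1 - R):min(nc, ceiling(col[i]) + 1 + R)
    g <- amp[i] * exp(-outer((rr - 1 - row[i])^2, (cc - 1 - col[i])^2, "+") /
                        (2 * s^2))
    img[rr, cc] <- img[rr, cc] + g
  }
  img
}

# Uniform centers in [0, nr) x [0, nc) (0-based, continuous); when
# min_separation > 0, rejection sampling enforces the pairwise distance.
.draw_centers <- function(n, nr, nc, min_sep) {
  if (n == 0L) return(matrix(numeric(0), 0, 2))
  if (min_sep <= 0) {
    return(cbind(runif(n, 0, nr), runif(n, 0, nc)))
  }
  out <- matrix(NA_real_, n, 2)
  k <- 0L; tries <- 0L; max_tries <- 400L * n
  while (k < n && tries < max_tries) {
    tries <- tries + 1L
    cand <- c(runif(1, 0, nr), runif(1, 0, nc))
    if (k == 0L ||
        min((out[seq_len(k), 1] - cand[1])^2 +
              (out[seq_len(k), 2] - cand[2])^2) >= min_sep^2) {
      k <- k + 1L
      out[k, ] <- cand
    }
  }
  if (k < n)
    warning(sprintf(
      "placed %d of %d vesicles before exhausting rejection sampling", k, n))
  out[seq_len(k), , drop = FALSE]
}

#' Simulate a two-condition experiment
#'
#' Generates `n_fields_per_condition` fields for each of two conditions
#' (e.g. low vs high shear stress). Each field gets an independent sub-seed
#' derived deterministically from the master seed, the condition label and
#' the field index, so experiments are reproducible and fields independent.
#'
#' @param lss_params,hss_params [simulation_params()] for the two
#'   conditions; their `condition_label`s name the groups. Defaults:
#'   [shear_presets()].
#' @param n_fields_per_condition number of fields per condition (>= 1).
#' @param seed master seed.
#' @param render passed to [simulate_field()].
#' @return list of `list(field, truth)` elements, conditions interleaved in
#'   order (all LSS fields, then all HSS fields).
#' @export
simulate_experiment <- function(lss_params = shear_presets()$LSS,
                                hss_params = shear_presets()$HSS,
                                n_fields_per_condition = 10L,
                                seed = 1L,
                                render = TRUE) {
  .assert(.is_number(n_fields_per_condition) && n_fields_per_condition >= 1,
          "n_fields_per_condition must be >= 1")
  out <- list()
  for (params in list(lss_params, hss_params)) {
    for (i in seq_len(n_fields_per_condition)) {
      p <- params
      p$seed <- subseed(seed, paste0(params$condition_label, "/", i))
      out[[length(out) + 1L]] <- simulate_field(p, render = render)
    }
  }
  out
}
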