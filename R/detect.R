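#' Top-hat background subtraction
#'
#' Removes smooth background by a morphological white top-hat: the raster
#' minus its grayscale opening with a disc structuring element of the given
#' radius. Features smaller than the disc are preserved; the result is
#' non-negative everywhere. The raster is normalized to `[0, 1]` for the
#' morphology and rescaled afterwards, so inputs of any bit depth behave
#' identically.
#'
#' @param raster numeric matrix.
#' @param background_radius disc radius in px; must be positive and smaller
#'   than half the smallest image dimension.
#' @return background-subtracted matrix, same shape as `raster`.
#' @export
subtract_background <- function(raster, background_radius) {
  .assert(is.matrix(raster) && is.numeric(raster), "raster must be a numeric matrix")
  .assert(.is_number(background_radius) && background_radius > 0,
          "background_radius must be > 0")
  size <- 2L * ceiling(background_radius) + 1L
  .assert(size <= min(dim(raster)),
          "background_radius %g too large for a %d x %d image",
          background_radius, nrow(raster), ncol(raster))
  mx <- max(raster)
  if (mx <= 0) return(raster * 0)
  kern <- EBImage::makeBrush(size, shape = "disc")
  out <- as.matrix(EBImage::whiteTopHat(raster / mx, kern)) * mx
  pmax(out, 0)
}

#' Automatic threshold of a raster
#'
#' @param raster numeric matrix (typically background-subtracted).
#' @param method `"otsu"`, `"triangle"`, or a fixed numeric value.
#' @return threshold on the raster's intensity scale; pixels strictly above
#'   it are foreground.
#' @export
threshold_value <- function(raster, method = "otsu") {
  if (is.numeric(method)) return(method)
  rng <- range(raster)
  if (diff(rng) == 0) return(rng[1])  # flat image: nothing above threshold
  xn <- (raster - rng[1]) / diff(rng)
  t01 <- switch(method,
    otsu = EBImage::otsu(EBImage::Image(xn), range = c(0, 1), levels = 256L),
    triangle = .triangle_threshold(xn, levels = 256L),
    stop(sprintf("unknown threshold method '%s'", method), call. = FALSE)
  )
  t01 * diff(rng) + rng[1]
}

# Triangle method (Zack): maximize the distance between the histogram and
# the chord joining its peak to the far empty end.
.triangle_threshold <- function(xn, levels = 256L) {
  h <- tabulate(pmin(floor(xn * levels), levels - 1L) + 1L, nbins = levels)
  peak <- which.max(h)
  nz <- which(h > 0)
  tail_end <- if ((max(nz) - peak) >= (peak - min(nz))) max(nz) else min(nz)
  if (tail_end == peak) return((peak - 0.5) / levels)
  ks <- seq(peak, tail_end)
  # distance from (k, h[k]) to the line through (peak, h[peak]) and (tail_end, 0)
  d <- abs((0 - h[peak]) * ks - (tail_end - peak) * h[ks] +
             tail_end * h[peak] - 0 * peak) /
    sqrt((0 - h[peak])^2 + (tail_end - peak)^2)
  ((ks[which.max(d)]) - 0.5) / levels
}

#' Label connected components of a binary mask
#'
#' 4- or 8-connected component labeling; labels are consecutive positive
#' integers, 0 is background.
#'
#' @param bw logical (or 0/1) matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of labels.
#' @export
label_components <- function(bw, connectivity = 8L) {
  .assert(connectivity %in% c(4L, 8L), "connectivity must be 4 or 8")
  lab <- as.matrix(EBImage::bwlabel(bw * 1))  # 4-connected
  storage.mode(lab) <- "integer"
  nlab <- max(lab)
  if (connectivity == 4L || nlab < 2L) return(lab)
  # merge labels that touch diagonally (union-find over label ids)
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]    # down-right diagonal
  c1 <- lab[-nr, -1]; d <- lab[-1, -nc]   # down-left diagonal
  pairs <- rbind(cbind(as.vector(a), as.vector(b)),
                 cbind(as.vector(c1), as.vector(d)))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  remap <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- remap[lab[lab > 0]]
  out
}

#' Detect vesicles in one channel of a field of view
#'
#' The particle-analysis stage: Gaussian pre-smoothing, top-hat background
#' subtraction, automatic thresholding, optional hole filling, connected-
#' component labeling, then filtering by area and circularity
#' (`4 * pi * area / perimeter^2`, inclusive bounds). Surviving components
#' are relabeled consecutively.
#'
#' @param field a [field_of_view()].
#' @param detection_channel channel role to detect in (e.g. `"cav1"`).
#' @param params a [detection_params()] object.
#' @return a list with `mask` (class `LabeledMask`: integer `labels`
#'   raster, `channel`, `params`, plus the background-subtracted raster
#'   `subtracted`) and `table` (class `VesicleTable` data.frame: `label`,
#'   intensity-weighted 0-based centroid `row`/`col`, `area` in px^2,
#'   `circularity`).
#' @export
detect_vesicles <- function(field, detection_channel,
                            params = detection_params()) {
  .assert(inherits(field, "FieldOfView"), "field must be a FieldOfView")
  .assert(detection_channel %in% names(field$channels),
          "channel '%s' not present in field [%s]", detection_channel,
          paste(names(field$channels), collapse = ", "))
  raster <- field$channels[[detection_channel]]

  x <- raster
  if (params$smoothing_sigma > 0)
    x <- as.matrix(EBImage::gblur(x, sigma = params$smoothing_sigma))
  sub <- subtract_background(x, params$background_radius)
  thr <- threshold_value(sub, params$threshold_method)
  if (!is.numeric(params$threshold_method) &&
      (params$noise_floor_k %||% 0) > 0) {
    # histogram-splitting methods bisect pure noise; clamp at a robust
    # noise floor so empty fields yield no detections
    thr <- max(thr, stats::median(sub) + params$noise_floor_k * stats::mad(sub))
  }
  bw <- sub > thr
  if (all(bw)) warning("all pixels above threshold (saturated image?)")
  if (params$fill_holes)
    bw <- as.matrix(EBImage::fillHull(EBImage::Image(bw * 1))) > 0
  lab <- label_components(bw, params$connectivity)

  empty_table <- function() {
    t0 <- data.frame(label = integer(0), row = numeric(0), col = numeric(0),
                     area = numeric(0), circularity = numeric(0))
    class(t0) <- c("VesicleTable", "data.frame")
    t0
  }
  mask <- structure(list(labels = lab, channel = detection_channel,
                         params = params, subtracted = sub),
                    class = "LabeledMask")
  if (max(lab) == 0L) {
    mask$labels[] <- 0L
    return(list(mask = mask, table = empty_table()))
  }

  shp <- EBImage::computeFeatures.shape(lab)
  area <- shp[, "s.area"]
  perim <- pmax(shp[, "s.perimeter"], 1)
  circ <- pmin(4 * pi * area / perim^2, 1)
  keep <- which(area >= params$min_area & area <= params$max_area &
                  circ >= params$min_circularity)

  relab <- integer(max(lab))
  relab[keep] <- seq_along(keep)
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  mask$labels <- out
  if (length(keep) == 0L) return(list(mask = mask, table = empty_table()))

  # intensity-weighted centroids on the subtracted raster, 0-based
  nr <- nrow(out)
  idx <- which(out > 0)
  labs <- out[idx]
  w <- pmax(sub[idx], .Machine$double.eps)
  ri <- (idx - 1) %% nr
  ci <- (idx - 1) %/% nr
  wsum <- rowsum(w, labs)
  cen_r <- rowsum(w * ri, labs) / wsum
  cen_c <- rowsum(w * ci, labs) / wsum

  table <- data.frame(label = seq_along(keep),
                      row = as.numeric(cen_r), col = as.numeric(cen_c),
                      area = as.numeric(area[keep]),
                      circularity = as.numeric(circ[keep]))
  class(table) <- c("VesicleTable", "data.frame")
  list(mask = mask, table = table)
}
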