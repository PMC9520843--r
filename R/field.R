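#' Construct a field of view
#'
#' A field of view is one acquired (or simulated) multi-channel image: a
#' named list of equally shaped, non-negative intensity rasters plus the
#' acquisition metadata the pipeline needs (pixel size, condition label).
#'
#' @param channels named list of numeric matrices, one per channel role
#'   (e.g. `cav1`, `endoglin`, `eea1`, `smad1`, `dapi`).
#' @param pixel_size physical pixel size in micrometers per pixel.
#' @param condition_label free-text experimental condition (e.g. "LSS").
#' @param source_path provenance string (file path or simulation tag).
#' @return an object of class `FieldOfView`.
#' @export
field_of_view <- function(channels, pixel_size = 1.0,
                          condition_label = "", source_path = "") {
  .assert(is.list(channels) && length(channels) >= 1 &&
            !is.null(names(channels)) && all(nzchar(names(channels))),
          "channels must be a non-empty named list of matrices")
  shp <- dim(channels[[1]])
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    .assert(is.matrix(ch) && is.numeric(ch), "channel '%s' must be a numeric matrix", nm)
    .assert(identical(dim(ch), shp), "channel '%s' shape differs from the first channel", nm)
    .assert(all(ch >= 0), "channel '%s' has negative intensities", nm)
  }
  structure(list(channels = channels, pixel_size = pixel_size,
                 condition_label = condition_label,
                 source_path = source_path),
            class = "FieldOfView")
}

#' @export
print.FieldOfView <- function(x, ...) {
  shp <- dim(x$channels[[1]])
  cat(sprintf("FieldOfView: %d x %d px, %d channel(s) [%s], condition '%s'\n",
              shp[1], shp[2], length(x$channels),
              paste(names(x$channels), collapse = ", "),
              x$condition_label))
  invisible(x)
}

#' Read a multi-channel TIFF as a field of view
#'
#' Reads a single- or multi-page TIFF (one page per channel) and assigns
#' channel roles by page index. Integer pixel values are kept on their
#' native scale.
#'
#' @param path TIFF file path.
#' @param channels named integer vector mapping channel role to page index,
#'   e.g. `c(cav1 = 1, endoglin = 2)`. Default: pages named `ch1`, `ch2`...
#' @param pixel_size,condition_label metadata, see [field_of_view()].
#' @return a `FieldOfView`.
#' @export
read_field <- function(path, channels = NULL, pixel_size = 1.0,
                       condition_label = "") {
  .assert(file.exists(path), "image not found: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # first plane of RGB pages
    matrix(as.numeric(p), nrow(p), ncol(p))
  })
  if (is.null(channels)) {
    channels <- seq_along(pages)
    names(channels) <- paste0("ch", channels)
  }
  .assert(all(channels >= 1 & channels <= length(pages)),
          "channel map indexes a page outside 1..%d", length(pages))
  chans <- lapply(channels, function(i) pages[[i]])
  names(chans) <- names(channels)
  field_of_view(chans, pixel_size = pixel_size,
                condition_label = condition_label, source_path = path)
}

#' Write a field of view as a multi-page 16-bit TIFF
#'
#' One page per channel, in the order of `field$channels`; intensities are
#' clipped to `[0, 65535]`. A JSON sidecar (`<path>.json`) records channel
#' names, pixel size and condition label.
#'
#' @param field a `FieldOfView`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  pages <- lapply(field$channels, function(ch)
    pmin(pmax(round(ch), 0), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(channels = names(field$channels), pixel_size = field$pixel_size,
         condition_label = field$condition_label),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Write / read vesicle ground truth as CSV
#'
#' One row per vesicle; the condition label travels as a column.
#'
#' @param truth a `GroundTruth` data.frame from [simulate_field()].
#' @param path CSV path.
#' @return `path` invisibly; `read_ground_truth()` returns the data.frame.
#' @export
write_ground_truth <- function(truth, path) {
  df <- as.data.frame(truth)
  df$condition_label <- attr(truth, "condition_label") %||% ""
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  df <- read.csv(path)
  cond <- if ("condition_label" %in% names(df)) df$condition_label[1] else ""
  df$condition_label <- NULL
  class(df) <- c("GroundTruth", "data.frame")
  attr(df, "condition_label") <- cond
  df
}
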