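#' @importFrom stats rnorm rpois runif sd quantile pnorm t.test setNames
#' @importFrom utils read.csv write.csv modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}

.is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Deterministic sub-seed from a master seed and a string tag
#'
#' Streams the tag bytes through a multiplicative hash modulo 2^31 - 1 so
#' that each (seed, condition, field index) combination yields an
#' independent, reproducible RNG seed.
#'
#' @param seed master integer seed.
#' @param tag character tag (e.g. "LSS/3").
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
subseed <- function(seed, tag) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (b in utf8ToInt(paste0(tag, "#"))) h <- (h * 31 + b) %% m
  as.integer(h %% (m - 2L) + 1L)
}

# Bilinear interpolation of a matrix at fractional 0-based (row, col)
# coordinates; coordinates are clamped to the image rectangle.
.bilinear <- function(raster, r, c) {
  nr <- nrow(raster); nc <- ncol(raster)
  r <- pmin(pmax(r, 0), nr - 1)
  c <- pmin(pmax(c, 0), nc - 1)
  r0 <- pmin(floor(r), nr - 2); r0 <- pmax(r0, 0)
  c0 <- pmin(floor(c), nc - 2); c0 <- pmax(c0, 0)
  fr <- r - r0; fc <- c - c0
  i00 <- cbind(r0 + 1, c0 + 1); i10 <- cbind(r0 + 2, c0 + 1)
  i01 <- cbind(r0 + 1, c0 + 2); i11 <- cbind(r0 + 2, c0 + 2)
  raster[i00] * (1 - fr) * (1 - fc) + raster[i10] * fr * (1 - fc) +
    raster[i01] * (1 - fr) * fc + raster[i11] * fr * fc
}
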