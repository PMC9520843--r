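# Independent brute-force oracles the suite checks the implementation
# against. These deliberately share no code with the package internals.

# Flood-fill connected-component labeling with an explicit stack.
oracle_label <- function(bw, connectivity = 8L) {
  nr <- nrow(bw); nc <- ncol(bw)
  nbr <- if (connectivity == 8L)
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
          c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  else rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!bw[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    stack <- list(c(i, j)); lab[i, j] <- cur
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(nbr))) {
        q <- p + nbr[k, ]
        if (q[1] >= 1 && q[1] <= nr && q[2] >= 1 && q[2] <= nc &&
            bw[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
          lab[q[1], q[2]] <- cur
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
  }
  lab
}

# Per-label mean intensity by an explicit per-pixel accumulation loop.
oracle_label_means <- function(lab, raster) {
  sums <- list(); counts <- list()
  for (j in seq_len(ncol(lab))) for (i in seq_len(nrow(lab))) {
    k <- lab[i, j]
    if (k == 0L) next
    key <- as.character(k)
    sums[[key]] <- (sums[[key]] %||% 0) + raster[i, j]
    counts[[key]] <- (counts[[key]] %||% 0) + 1
  }
  ks <- sort(as.integer(names(sums)))
  vapply(as.character(ks), function(key) sums[[key]] / counts[[key]],
         numeric(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One Gaussian blob on a constant background, for detection unit tests.
blob_image <- function(nr, nc, centers, amp = 50, sd_px = 2, bg = 10) {
  img <- matrix(bg, nr, nc)
  for (k in seq_len(nrow(centers))) {
    r0 <- centers[k, 1]; c0 <- centers[k, 2]
    img <- img + amp * exp(-outer((seq_len(nr) - 1 - r0)^2,
                                  (seq_len(nc) - 1 - c0)^2, "+") /
                             (2 * sd_px^2))
  }
  img
}
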