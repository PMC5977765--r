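# Independent oracles used across the suite. These deliberately avoid the
# package's code paths: brute-force enumeration, direct formula transcription.

# brute-force digitized disk: all grid points with x^2 + y^2 <= thr
brute_disk <- function(thr, extent = ceiling(sqrt(thr)) + 1) {
  g <- expand.grid(x = -extent:extent, y = -extent:extent)
  as.matrix(g[g$x^2 + g$y^2 <= thr, c("x", "y")])
}

# brute-force modal estimator: literal transcription of the binning rule with
# a scan over sub-intervals and recursive tie reduction
oracle_g_mode <- function(phi, K) {
  J <- length(phi)
  if (J < 10) return(mean(phi))
  h_min <- min(phi); h_max <- max(phi)
  if (h_max == h_min) return(h_min)
  while (TRUE) {
    if (K == 1) return(mean(phi))
    cc <- (h_max - h_min) / K
    n <- integer(K)
    for (kap in 1:K) {
      for (h in phi) {
        x <- h - h_min
        lo <- (kap - 1) * cc
        if ((x > lo && x <= kap * cc) || (kap == 1 && x <= 0)) {
          n[kap] <- n[kap] + 1L
        }
      }
    }
    best <- which(n == max(n))
    if (length(best) == 1) return(h_min + (best - 0.5) * cc)
    K <- K - 1
  }
}

# square pore region builder: a filled w x h rectangle placed inside a larger
# frame, labeled through the package's segmentation machinery
make_rect_region <- function(w = 10, h = w, frame = w + 10) {
  mask <- matrix(FALSE, frame, frame)
  y0 <- (frame - h) %/% 2
  x0 <- (frame - w) %/% 2
  mask[(y0 + 1):(y0 + h), (x0 + 1):(x0 + w)] <- TRUE
  label_regions(mask)
}

# disk-shaped region (plain digitization x^2 + y^2 <= r^2) inside a frame
make_disk_region <- function(r, margin = 5) {
  ext <- r + margin
  n <- 2 * ext + 1
  g <- expand.grid(x = -ext:ext, y = -ext:ext)
  mask <- matrix(FALSE, n, n)
  mask[cbind(g$y + ext + 1, g$x + ext + 1)] <- g$x^2 + g$y^2 <= r^2
  label_regions(mask)
}
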