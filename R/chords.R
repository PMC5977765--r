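# Statistical chord-extension volume estimator: horizontal strip chords,
# vertical chord samples, mean/mode estimation of the invisible third axis,
# and elliptic-cylinder volume accumulation.

# internal: local bounding-box mask of a pore region, with offsets
region_local_mask <- function(region) {
  bb <- region$bbox
  h <- bb["ymax"] - bb["ymin"] + 1L
  w <- bb["xmax"] - bb["xmin"] + 1L
  m <- matrix(FALSE, h, w)
  m[cbind(region$pixels[, "y"] - bb["ymin"] + 1L,
          region$pixels[, "x"] - bb["xmin"] + 1L)] <- TRUE
  list(mask = m, x0 = unname(bb["xmin"]), y0 = unname(bb["ymin"]))
}

#' Horizontal chords of a pore section
#'
#' Divides the pore's section into horizontal strips of equal breadth `delta`
#' pixels, anchored at the region's top row, and measures on each strip's
#' center row the maximal horizontal runs of region pixels. Each run is one
#' chord; non-convex sections therefore yield several chords per strip. Under
#' the elliptic-section assumption each strip corresponds to cutting the 3D
#' pore into a flat disk of thickness `delta` whose in-plane axis is the chord
#' length `l_i`.
#'
#' @param region a `pore_region` from [label_regions()].
#' @param delta strip breadth in pixels (also the disk thickness), at least 1.
#' @return A list of class `strip_chord_set`: `region_label`, `delta`, and
#'   `chords`, a data frame with columns `chord` (id), `strip`, `row`
#'   (absolute image row of the strip center), `x_start`, `x_end`, `length`.
#' @export
horizontal_chords <- function(region, delta = 1) {
  stopifnot(inherits(region, "pore_region"))
  if (delta < 1) stop("'delta' must be at least 1")
  delta <- as.integer(delta)
  lm <- region_local_mask(region)
  h <- nrow(lm$mask)
  if (delta > h) {
    warning("strip breadth exceeds region height; using a single strip")
  }
  starts <- seq(1L, h, by = delta)
  out <- list()
  chord_id <- 0L
  strip_id <- 0L
  for (s in starts) {
    strip_id <- strip_id + 1L
    n_rows <- min(delta, h - s + 1L)
    center <- s + (n_rows - 1L) %/% 2L
    v <- lm$mask[center, ]
    if (!any(v)) next
    rl <- rle(v)
    ends <- cumsum(rl$lengths)
    begs <- ends - rl$lengths + 1L
    for (k in which(rl$values)) {
      chord_id <- chord_id + 1L
      out[[chord_id]] <- data.frame(
        chord = chord_id, strip = strip_id,
        row = center + lm$y0 - 1L,
        x_start = begs[k] + lm$x0 - 1L,
        x_end = ends[k] + lm$x0 - 1L,
        length = ends[k] - begs[k] + 1L
      )
    }
  }
  chords <- if (length(out)) do.call(rbind, out) else
    data.frame(chord = integer(0), strip = integer(0), row = integer(0),
               x_start = integer(0), x_end = integer(0), length = integer(0))
  structure(list(region_label = region$label, delta = delta, chords = chords),
            class = "strip_chord_set")
}

#' @export
print.strip_chord_set <- function(x, ...) {
  cat(sprintf("strip_chord_set: region %d, delta = %d, %d chord(s)\n",
              x$region_label, x$delta, nrow(x$chords)))
  invisible(x)
}

#' Vertical chords crossing a horizontal chord
#'
#' Samples, at equally spaced columns along a horizontal chord, the lengths of
#' the maximal vertical runs of region pixels through the chord's row. The
#' resulting set Phi = {h_1, ..., h_J} is the empirical material for
#' estimating the pore's out-of-plane axis: under 3D isotropy the distribution
#' of vertical chord lengths matches the distribution of chords along the
#' invisible depth direction.
#'
#' @param region a `pore_region`.
#' @param row absolute image row of the horizontal chord.
#' @param x_start,x_end absolute column span of the chord.
#' @param spacing column spacing in pixels (default 1); a chord shorter than
#'   `spacing` is sampled once at its midpoint.
#' @return Integer vector of vertical chord lengths (pixels), one per sampled
#'   column.
#' @export
vertical_chords <- function(region, row, x_start, x_end, spacing = 1) {
  stopifnot(inherits(region, "pore_region"))
  if (spacing < 1) stop("'spacing' must be at least 1")
  lm <- region_local_mask(region)
  r <- row - lm$y0 + 1L
  span <- x_end - x_start + 1L
  cols <- if (span < spacing) (x_start + x_end) %/% 2L
          else seq(x_start, x_end, by = spacing)
  vapply(cols, function(x) {
    cc <- x - lm$x0 + 1L
    v <- lm$mask[, cc]
    if (!v[r]) return(0L)  # defensive; chord pixels are region pixels
    up <- r
    while (up > 1L && v[up - 1L]) up <- up - 1L
    dn <- r
    while (dn < length(v) && v[dn + 1L]) dn <- dn + 1L
    dn - up + 1L
  }, integer(1))
}

#' Estimate the out-of-plane axis by the mean vertical chord
#'
#' `g = M = mean(Phi)`, the arithmetic mean of the sampled vertical chord
#' lengths. For elliptic sections this estimator has the remarkable property
#' that strip-wise accumulation recovers the volume of a sphere exactly in the
#' continuum limit.
#'
#' @param phi numeric vector of vertical chord lengths; nonempty.
#' @return A list of class `modal_fit` with `g`, `method = "mean"`, `M` (the
#'   mean), and `J` (the sample count).
#' @export
estimate_g_mean <- function(phi) {
  if (length(phi) == 0L) stop("empty chord-length set")
  m <- mean(phi)
  structure(list(g = m, method = "mean", M = m, J = length(phi)),
            class = "modal_fit")
}

#' Estimate the out-of-plane axis by the modal vertical chord
#'
#' Bins the chord lengths into `K` equal sub-intervals of length
#' `c = (h_max - h_min) / K` spanning `[h_min, h_max]` (right-closed, with the
#' left edge included in the first sub-interval) and takes the center of the
#' uniquely most populated sub-interval:
#' `g = h_min + (kappa* - 1/2) * c`. When the maximal count is tied, `K` is
#' decremented by 1 and the binning repeated; at `K = 1` all lengths are
#' treated as approximately equal and the mean is returned. The procedure is
#' reasonable only for large samples, so for `J < 10` it falls back to
#' [estimate_g_mean()].
#'
#' The published binning enumerates sub-intervals from 0 although the
#' sub-interval length spans `[h_min, h_max]`; with `offset_by_hmin = FALSE`
#' that literal variant (bins `((kappa-1) c, kappa c]` anchored at 0 and
#' `g = (kappa* - 1/2) c`) is used instead of the default anchoring at
#' `h_min`.
#'
#' @param phi numeric vector of vertical chord lengths.
#' @param K initial sub-interval count, `0 < K < J`; default `min(10, J - 1)`.
#' @param offset_by_hmin anchor the sub-intervals at `h_min` (default) rather
#'   than at 0.
#' @return A list of class `modal_fit` with `g`, `method` (`"mode"`, or
#'   `"mean"` after fallback), `K` (final sub-interval count), `c`
#'   (sub-interval length), `counts`, `kappa_star`, `h_min`, `h_max`, `J`.
#' @examples
#' estimate_g_mode(c(rep(10, 8), 20, 30), K = 4)$g  # 12.5
#' @export
estimate_g_mode <- function(phi, K = NULL, offset_by_hmin = TRUE) {
  J <- length(phi)
  if (J == 0L) stop("empty chord-length set")
  if (J < 10L) {
    fit <- estimate_g_mean(phi)
    fit$note <- "J < 10: fell back to the mean estimator"
    return(fit)
  }
  if (is.null(K)) K <- min(10L, J - 1L)
  if (K <= 0 || K >= J) stop("'K' must satisfy 0 < K < J")
  h_min <- min(phi); h_max <- max(phi)
  if (h_max == h_min) {
    return(structure(list(g = h_min, method = "mode", K = 1L, c = 0,
                          counts = J, kappa_star = 1L,
                          h_min = h_min, h_max = h_max, J = J),
                     class = "modal_fit"))
  }
  base <- if (offset_by_hmin) h_min else 0
  x <- phi - base
  while (K >= 1L) {
    if (K == 1L) {
      # marginal case: all lengths approximately equal; accept the mean
      return(structure(list(g = mean(phi), method = "mode", K = 1L,
                            c = h_max - h_min, counts = J, kappa_star = 1L,
                            h_min = h_min, h_max = h_max, J = J),
                       class = "modal_fit"))
    }
    cc <- (h_max - h_min) / K
    counts <- integer(K)
    for (kap in seq_len(K)) {
      in_bin <- x > (kap - 1L) * cc & x <= kap * cc
      if (kap == 1L) in_bin <- in_bin | x <= 0  # left edge joins first bin
      counts[kap] <- sum(in_bin)
    }
    top <- which(counts == max(counts))
    if (length(top) == 1L) {
      return(structure(list(g = base + (top - 0.5) * cc, method = "mode",
                            K = K, c = cc, counts = counts, kappa_star = top,
                            h_min = h_min, h_max = h_max, J = J),
                       class = "modal_fit"))
    }
    K <- K - 1L
  }
}

#' @export
print.modal_fit <- function(x, ...) {
  cat(sprintf("modal_fit (%s): g = %.4g from J = %d chord(s)\n",
              x$method, x$g, x$J))
  invisible(x)
}

#' Volume of one elliptic-cylinder strip disk
#'
#' Each horizontal strip of a pore section is modeled as a flat cylinder of
#' elliptic base (axes `l` in-plane and `g` out-of-plane) and height `delta`:
#' `v = (pi / 4) * delta * l * g`.
#'
#' @param l horizontal chord length (pix); positive.
#' @param g estimated out-of-plane axis (pix); positive.
#' @param delta strip breadth / disk thickness (pix); positive.
#' @return Disk volume in pix^3.
#' @examples
#' disk_volume(2, 2, 1)  # pi
#' @export
disk_volume <- function(l, g, delta) {
  if (any(l <= 0) || any(g <= 0) || any(delta <= 0))
    stop("'l', 'g' and 'delta' must be positive")
  (pi / 4) * delta * l * g
}

#' Chord-extension estimate of pore volumes and specimen porosity
#'
#' For every eligible pore region: divide it into horizontal strips of breadth
#' `delta`, measure the strip chords `l_i`, sample the crossing vertical
#' chords, estimate the out-of-plane axis `g_i` by the mean or modal method,
#' and accumulate the elliptic-disk volumes `v_i = (pi/4) delta l_i g_i`. The
#' specimen totals are `V_sigma = sum(v_i)`, the density
#' `rho = V_sigma / V` with reference volume `V = frame area x
#' reference_depth`, and the per-pore volume mean `m_V` and population
#' standard deviation `Delta_V`.
#'
#' Border-touching regions are excluded by default because their lateral
#' extent is censored, which would bias the chord statistics.
#'
#' @param seg a `segmentation` from [segment_pores()], or a `pore_regions`
#'   object (then `frame_area` and `scale` must be given).
#' @param delta strip breadth in pixels.
#' @param spacing vertical-chord column spacing; defaults to `delta`.
#' @param method `"mean"` or `"mode"` (the modal method falls back to the
#'   mean for samples smaller than 10).
#' @param reference_depth depth of the reference volume in pixels, or
#'   `"auto"` = the maximum estimated `g` over all strips. Reported with the
#'   result; densities are comparable only at equal settings.
#' @param K initial sub-interval count for the modal method (`NULL` = its
#'   default).
#' @param include_border include border-touching regions.
#' @param frame_area,scale overrides when `seg` is a bare `pore_regions`.
#' @return A list of class `volume_estimate`: `per_pore` (data frame `label`,
#'   `n_chords`, `volume_pix3`, `volume_um3`), `V_sigma`, `V_ref`, `rho`,
#'   `m_V`, `Delta_V` (pix^3), `m_V_um3`, `Delta_V_um3`, and `settings`.
#' @export
estimate_volumes <- function(seg, delta = 1, spacing = delta,
                             method = c("mean", "mode"),
                             reference_depth = "auto", K = NULL,
                             include_border = FALSE,
                             frame_area = NULL, scale = NULL) {
  method <- match.arg(method)
  if (inherits(seg, "segmentation")) {
    regions <- seg$regions$regions
    frame_area <- seg$S_frame
    scale <- seg$scale
    epsilon <- seg$epsilon
    conn <- seg$regions$connectivity
  } else if (inherits(seg, "pore_regions")) {
    regions <- seg$regions
    if (is.null(frame_area) || is.null(scale))
      stop("'frame_area' and 'scale' are required with bare pore_regions")
    epsilon <- NA_real_
    conn <- seg$connectivity
  } else stop("'seg' must be a segmentation or pore_regions object")
  eligible <- Filter(function(r) include_border || !r$touches_border, regions)
  settings <- list(method = method, delta = delta, spacing = spacing,
                   K = K, reference_depth = reference_depth,
                   epsilon = epsilon, connectivity = conn,
                   include_border = include_border)
  if (length(eligible) == 0L) {
    warning("no eligible pore regions: empty volume estimate")
    return(structure(list(
      per_pore = data.frame(label = integer(0), n_chords = integer(0),
                            volume_pix3 = numeric(0), volume_um3 = numeric(0)),
      V_sigma = 0, V_ref = NA_real_, rho = NA_real_,
      m_V = NA_real_, Delta_V = NA_real_,
      m_V_um3 = NA_real_, Delta_V_um3 = NA_real_,
      settings = settings), class = "volume_estimate"))
  }
  per <- vector("list", length(eligible))
  all_g <- numeric(0)
  for (i in seq_along(eligible)) {
    reg <- eligible[[i]]
    cs <- horizontal_chords(reg, delta = delta)
    vol <- 0
    nch <- nrow(cs$chords)
    if (nch > 0L) {
      for (k in seq_len(nch)) {
        ch <- cs$chords[k, ]
        phi <- vertical_chords(reg, ch$row, ch$x_start, ch$x_end,
                               spacing = spacing)
        phi <- phi[phi > 0]
        if (!length(phi)) next
        fit <- if (method == "mean") estimate_g_mean(phi)
               else estimate_g_mode(phi, K = K)
        all_g <- c(all_g, fit$g)
        vol <- vol + disk_volume(ch$length, fit$g, delta)
      }
    }
    per[[i]] <- data.frame(label = reg$label, n_chords = nch,
                           volume_pix3 = vol,
                           volume_um3 = vol * scale^3)
  }
  per <- do.call(rbind, per)
  V_sigma <- sum(per$volume_pix3)
  depth <- if (identical(reference_depth, "auto")) {
    if (length(all_g)) max(all_g) else 0
  } else reference_depth
  V_ref <- frame_area * depth
  vols <- per$volume_pix3
  m_V <- mean(vols)
  Delta_V <- sqrt(mean((vols - m_V)^2))  # population sd: describes the set
  structure(list(
    per_pore = per,
    V_sigma = V_sigma,
    V_ref = V_ref,
    rho = if (V_ref > 0) V_sigma / V_ref else NA_real_,
    m_V = m_V, Delta_V = Delta_V,
    m_V_um3 = m_V * scale^3, Delta_V_um3 = Delta_V * scale^3,
    settings = c(settings, list(reference_depth_used = depth, scale = scale))
  ), class = "volume_estimate")
}

#' @export
print.volume_estimate <- function(x, ...) {
  cat(sprintf("volume_estimate (%s method): %d pore(s)\n",
              x$settings$method, nrow(x$per_pore)))
  cat(sprintf("  V_sigma = %.4g pix^3, V_ref = %.4g pix^3, rho = %.4g\n",
              x$V_sigma, x$V_ref, x$rho))
  cat(sprintf("  m_V = %.4g pix^3, Delta_V = %.4g pix^3\n", x$m_V, x$Delta_V))
  invisible(x)
}
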