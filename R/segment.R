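# Pore segmentation: brightness thresholding, connected-component labeling,
# per-pore 2D morphometry, and the anisotropic bright-spot density shortcut.

#' Threshold pore pixels by a brightness margin
#'
#' Pixels darker than `255 - epsilon` are qualified as belonging to pores;
#' pixels at or above that level are background material. The margin epsilon
#' is the same quantity used by the depth estimator (see [depth_model()]) and
#' is typically 10 for SEM micrographs whose background saturates near 255.
#'
#' @param img a [gray_image()].
#' @param epsilon brightness margin, strictly between 0 and 255.
#' @return Logical matrix of the image size, `TRUE` on pore pixels.
#' @export
threshold_pores <- function(img, epsilon = 10) {
  stopifnot(inherits(img, "gray_image"))
  if (!is.numeric(epsilon) || length(epsilon) != 1L ||
      epsilon <= 0 || epsilon >= 255)
    stop("'epsilon' must lie strictly between 0 and 255")
  img$pixels < 255 - epsilon
}

#' Estimate the brightness margin epsilon from a coarse histogram
#'
#' Inspects the coarse (bin width 10) brightness histogram for domination of
#' the brightest bin over the preceding bins: when the last bin's count
#' exceeds each of the preceding `n_preceding` bins by at least
#' `dominance` times, the bright background is well separated and the margin
#' is taken as one coarse bin, `epsilon = 10`. Otherwise the same default is
#' returned flagged as low-confidence.
#'
#' @param h a [brightness_histogram()] with `bin_width = 10`.
#' @param dominance required ratio of the last bin over each preceding bin
#'   (default 2).
#' @param n_preceding number of preceding bins inspected (default 5).
#' @return A list with `epsilon` (always 10), `confident` (logical), and the
#'   inspected counts.
#' @export
estimate_epsilon <- function(h, dominance = 2, n_preceding = 5) {
  if (!inherits(h, "brightness_histogram"))
    stop("'h' must be a brightness_histogram")
  if (h$bin_width != 10)
    stop("'h' must use the coarse bin width 10")
  if (sum(h$counts) == 0L) stop("empty histogram")
  nb <- length(h$counts)
  last <- h$counts[nb]
  prev <- h$counts[seq(max(1L, nb - n_preceding), nb - 1L)]
  confident <- all(last > dominance * prev)
  list(epsilon = 10, confident = confident,
       last_count = last, preceding_counts = prev)
}

# internal: connected-component labeling of a logical mask by run-based
# union-find; connectivity 4 joins vertically overlapping runs, 8 also joins
# runs touching diagonally
label_components <- function(mask, kind = 8L) {
  stopifnot(is.logical(mask), is.matrix(mask), kind %in% c(4L, 8L))
  nr <- nrow(mask); nc <- ncol(mask)
  runs_row <- integer(0); runs_xs <- integer(0); runs_xe <- integer(0)
  row_first <- integer(nr + 1L)  # index of first run of each row (stack style)
  # collect maximal horizontal runs per row
  run_of_row <- vector("list", nr)
  for (r in seq_len(nr)) {
    v <- mask[r, ]
    if (!any(v)) { run_of_row[[r]] <- integer(0); next }
    rl <- rle(v)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    sel <- rl$values
    ids <- seq_along(runs_row)  # placeholder
    n0 <- length(runs_row)
    runs_row <- c(runs_row, rep.int(r, sum(sel)))
    runs_xs <- c(runs_xs, starts[sel])
    runs_xe <- c(runs_xe, ends[sel])
    run_of_row[[r]] <- n0 + seq_len(sum(sel))
  }
  n_runs <- length(runs_row)
  parent <- seq_len(n_runs)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  slack <- if (kind == 8L) 1L else 0L
  for (r in 2:max(2L, nr)) {
    if (r > nr) break
    above <- run_of_row[[r - 1L]]
    here <- run_of_row[[r]]
    if (!length(above) || !length(here)) next
    for (i in here) {
      for (j in above) {
        if (runs_xs[j] <= runs_xe[i] + slack &&
            runs_xe[j] >= runs_xs[i] - slack) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  labels <- matrix(0L, nr, nc)
  if (n_runs) {
    roots <- vapply(seq_len(n_runs), find, integer(1))
    relab <- match(roots, sort(unique(roots)))  # deterministic 1..K
    for (i in seq_len(n_runs)) {
      labels[runs_row[i], runs_xs[i]:runs_xe[i]] <- relab[i]
    }
  }
  labels
}

# internal: pixels of a mask with at least one neighbor (under `kind`
# connectivity) outside the mask; image border counts as outside
mask_boundary <- function(mask, kind = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  off <- neighbor_offsets(connectivity(kind))
  all_in <- mask
  for (k in seq_len(nrow(off))) {
    dy <- off[k, 2]; dx <- off[k, 1]
    shifted <- pad[(2:(nr + 1L)) + dy, (2:(nc + 1L)) + dx]
    all_in <- all_in & shifted
  }
  mask & !all_in
}

#' Label pore regions in a binary mask
#'
#' Finds maximal connected components of the mask under the chosen 2D
#' connectivity, computes each region's contour (member pixels with at least
#' one neighbor outside the region, the image border counting as outside),
#' and the per-pore morphometry: area `S_i` (pixel count), contour length
#' `L_i` (contour pixel count, the discrete counting measure, not a polygonal
#' perimeter), and regularity `eta_i = 4 pi S_i / L_i^2`. Components smaller
#' than `min_area` pixels are dropped and counted, not measured. Regions
#' touching the image border are measured but flagged, since their lateral
#' extent is censored; the volume estimators exclude them by default.
#'
#' @param mask logical matrix, `TRUE` on pore pixels.
#' @param c a 2D [connectivity()]; 8-connectivity (the default) describes
#'   irregular contours better and is the convention used throughout.
#' @param min_area minimum region area in pixels (default 5); smaller
#'   components are suppressed as noise specks.
#' @return A list of class `pore_regions` with elements `regions` (list of
#'   `pore_region` objects: `label`, `pixels` (x,y matrix), `contour`, `S`,
#'   `L`, `eta`, `touches_border`, `bbox`), `labels` (integer label matrix),
#'   `n_dropped`, `connectivity`, `min_area`.
#' @export
label_regions <- function(mask, c = connectivity(8), min_area = 5) {
  stopifnot(is.logical(mask), is.matrix(mask), inherits(c, "connectivity"))
  if (c$dimension != 2L) stop("label_regions needs a 2D connectivity")
  labels <- label_components(mask, kind = c$kind)
  boundary <- mask_boundary(mask, kind = c$kind)
  nlab <- max(labels)
  nr <- nrow(mask); nc <- ncol(mask)
  regions <- list()
  n_dropped <- 0L
  keep_id <- 0L
  relabeled <- matrix(0L, nr, nc)
  for (l in seq_len(nlab)) {
    idx <- which(labels == l)
    if (length(idx) < min_area) {
      n_dropped <- n_dropped + 1L
      next
    }
    keep_id <- keep_id + 1L
    rows <- ((idx - 1L) %% nr) + 1L   # y
    cols <- ((idx - 1L) %/% nr) + 1L  # x
    relabeled[idx] <- keep_id
    on_contour <- boundary[idx]
    px <- cbind(x = cols, y = rows)
    S <- length(idx)
    L <- sum(on_contour)
    regions[[keep_id]] <- structure(list(
      label = keep_id,
      pixels = px,
      contour = px[on_contour, , drop = FALSE],
      S = S,
      L = L,
      eta = regularity_2d(L, S),
      touches_border = any(rows == 1L | rows == nr | cols == 1L | cols == nc),
      bbox = c(xmin = min(cols), xmax = max(cols),
               ymin = min(rows), ymax = max(rows))
    ), class = "pore_region")
  }
  structure(list(regions = regions, labels = relabeled,
                 n_dropped = n_dropped, connectivity = c$kind,
                 min_area = min_area),
            class = "pore_regions")
}

#' @export
print.pore_regions <- function(x, ...) {
  cat(sprintf("pore_regions: %d region(s) (%d-connectivity, min area %d px, %d dropped)\n",
              length(x$regions), x$connectivity, x$min_area, x$n_dropped))
  invisible(x)
}

#' Per-region morphometry table
#'
#' @param regions a `pore_regions` object from [label_regions()].
#' @param scale micrometres per pixel, used for the metric area column.
#' @return Data frame with columns `label`, `S_pix2`, `L_pix`, `eta`,
#'   `S_um2`, `touches_border`.
#' @export
region_table <- function(regions, scale = 1) {
  stopifnot(inherits(regions, "pore_regions"))
  rs <- regions$regions
  data.frame(
    label = vapply(rs, `[[`, integer(1), "label"),
    S_pix2 = vapply(rs, `[[`, numeric(1), "S"),
    L_pix = vapply(rs, `[[`, numeric(1), "L"),
    eta = vapply(rs, `[[`, numeric(1), "eta"),
    S_um2 = vapply(rs, `[[`, numeric(1), "S") * scale^2,
    touches_border = vapply(rs, `[[`, logical(1), "touches_border")
  )
}

#' Segment pores in a grayscale image
#'
#' Convenience pipeline: threshold at the brightness margin (estimated from
#' the coarse histogram when `epsilon = "auto"`), label connected components,
#' and record frame and bright-spot areas.
#'
#' @param img a [gray_image()].
#' @param epsilon brightness margin, or `"auto"` to derive it with
#'   [estimate_epsilon()].
#' @param c a 2D [connectivity()].
#' @param min_area minimum region area in pixels.
#' @return A list of class `segmentation` with `mask`, `regions` (a
#'   `pore_regions`), `epsilon`, `epsilon_confident`, `S_frame` (frame area,
#'   pix^2), `S_white` (bright-spot area, pix^2), `scale`.
#' @export
segment_pores <- function(img, epsilon = "auto", c = connectivity(8),
                          min_area = 5) {
  stopifnot(inherits(img, "gray_image"))
  confident <- TRUE
  if (identical(epsilon, "auto")) {
    est <- estimate_epsilon(brightness_histogram(img, bin_width = 10))
    epsilon <- est$epsilon
    confident <- est$confident
    if (!confident)
      warning("no dominant bright bin in the coarse histogram; ",
              "using default epsilon = 10 with low confidence")
  }
  mask <- threshold_pores(img, epsilon)
  regions <- label_regions(mask, c = c, min_area = min_area)
  structure(list(
    mask = mask,
    regions = regions,
    epsilon = epsilon,
    epsilon_confident = confident,
    S_frame = length(img$pixels),
    S_white = sum(img$pixels >= 255 - epsilon),
    scale = img$scale
  ), class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("segmentation: epsilon = %g, %d region(s), frame %d px, bright %d px\n",
              x$epsilon, length(x$regions$regions), x$S_frame, x$S_white))
  invisible(x)
}

#' Areal porosity of an anisotropic (fiber-perpendicular) cross-section
#'
#' For porous structures formed by bundles of parallel fibers, a cross-section
#' perpendicular to the fiber axis shows bright fiber cross-sections over dark
#' pore space, and the pore density reduces to an area fraction:
#' `rho ~= (S - S_sigma) / S`, where `S` is the image frame area and `S_sigma`
#' the total area of bright spots (pixels with brightness at or above
#' `255 - epsilon`). The caller is responsible for supplying an image whose
#' section plane is perpendicular to the dominant fiber direction.
#'
#' @param img a [gray_image()].
#' @param epsilon brightness margin separating bright fiber material.
#' @return The areal density estimate in `[0, 1]`.
#' @examples
#' dark <- gray_image(matrix(0L, 4, 4))
#' anisotropic_density(dark)  # 1: all pore
#' @export
anisotropic_density <- function(img, epsilon = 10) {
  stopifnot(inherits(img, "gray_image"))
  if (epsilon <= 0 || epsilon >= 255)
    stop("'epsilon' must lie strictly between 0 and 255")
  S <- length(img$pixels)
  S_white <- sum(img$pixels >= 255 - epsilon)
  (S - S_white) / S
}
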