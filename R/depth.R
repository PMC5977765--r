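# Brightness-profile depth estimator: line profiles, dark-run lengths, the
# maximal expected depth, and the linear brightness-to-depth map.

#' Extract a horizontal brightness profile
#'
#' @param img a [gray_image()].
#' @param row image row index (1-based).
#' @return A list of class `brightness_profile` with `row` and `samples` (the
#'   row's brightness values, left to right).
#' @export
extract_profile <- function(img, row) {
  stopifnot(inherits(img, "gray_image"))
  nr <- nrow(img$pixels)
  if (row < 1 || row > nr)
    stop("'row' out of range (image has ", nr, " rows)")
  structure(list(row = as.integer(row), samples = img$pixels[row, ]),
            class = "brightness_profile")
}

#' @export
print.brightness_profile <- function(x, ...) {
  cat(sprintf("brightness_profile: row %d, %d samples in [%d, %d]\n",
              x$row, length(x$samples), min(x$samples), max(x$samples)))
  invisible(x)
}

#' Lengths of dark runs along a profile
#'
#' Measures the lengths `D_a` of the maximal consecutive sub-intervals of the
#' profile whose brightness satisfies `beta < 255 - epsilon`, i.e. the pore
#' crossings of the line.
#'
#' @param p a `brightness_profile` from [extract_profile()], or a bare
#'   numeric vector of brightness values.
#' @param epsilon brightness margin, strictly between 0 and 255.
#' @return Integer vector of run lengths (possibly empty).
#' @examples
#' dark_run_lengths(c(250, 100, 100, 250), 10)  # 2
#' @export
dark_run_lengths <- function(p, epsilon = 10) {
  if (epsilon <= 0 || epsilon >= 255)
    stop("'epsilon' must lie strictly between 0 and 255")
  beta <- if (inherits(p, "brightness_profile")) p$samples else as.vector(p)
  rl <- rle(beta < 255 - epsilon)
  as.integer(rl$lengths[rl$values])
}

#' Maximal expected pore depth from profiles
#'
#' `D_max = max{D_a}` over the dark-run lengths of all supplied profiles.
#' Under isotropy the longest in-plane pore crossing is representative of the
#' largest pore extent in the invisible depth direction, so it serves as the
#' maximal expected depth in the brightness-depth map.
#'
#' @param profiles a list of `brightness_profile` objects (or numeric
#'   vectors), or a single profile.
#' @param epsilon brightness margin.
#' @return The maximal dark-run length in pixels; 0 (with a warning) when no
#'   profile contains any dark pixel.
#' @export
estimate_dmax <- function(profiles, epsilon = 10) {
  if (inherits(profiles, "brightness_profile") || is.numeric(profiles))
    profiles <- list(profiles)
  if (length(profiles) == 0L) stop("no profiles supplied")
  runs <- unlist(lapply(profiles, dark_run_lengths, epsilon = epsilon))
  if (length(runs) == 0L) {
    warning("no dark runs found in any profile: D_max = 0")
    return(0L)
  }
  max(runs)
}

#' Linear brightness-to-depth model
#'
#' Parameterizes the assumed linear relation between recorded brightness and
#' pore depth: brightness 0 (black) corresponds to the maximal expected depth
#' `D_max`, brightness `255 - epsilon` (the pore/background threshold) and
#' anything brighter corresponds to depth 0. The scaling coefficient is
#' `q = D_max / (255 - epsilon)`, so the depth function is
#' `zeta(beta) = D_max - q * beta = D_max * (1 - beta / (255 - epsilon))` for
#' `beta < 255 - epsilon`, and 0 otherwise.
#'
#' Two reference-volume conventions for the density are carried by the model:
#' `"consistent"` uses `V = N * D_max` (each of the N pixel columns can be at
#' most `D_max` deep, so `rho` is in `[0, 1]`), while `"as-printed"` uses
#' `V = N * 255`, the literal published reference that mixes brightness and
#' depth units; the two densities differ exactly by the factor `D_max / 255`.
#'
#' @param epsilon brightness margin, strictly between 0 and 255.
#' @param d_max maximal expected pore depth in pixels (non-negative), e.g.
#'   from [estimate_dmax()].
#' @param mode `"consistent"` (default) or `"as-printed"`.
#' @return A list of class `depth_model` with `epsilon`, `d_max`, `q`, `mode`.
#' @export
depth_model <- function(epsilon = 10, d_max, mode = c("consistent", "as-printed")) {
  mode <- match.arg(mode)
  if (epsilon <= 0 || epsilon >= 255)
    stop("'epsilon' must lie strictly between 0 and 255")
  if (d_max < 0) stop("'d_max' must be non-negative")
  structure(list(epsilon = epsilon, d_max = d_max,
                 q = d_max / (255 - epsilon), mode = mode),
            class = "depth_model")
}

#' @export
print.depth_model <- function(x, ...) {
  cat(sprintf("depth_model: epsilon = %g, D_max = %g pix, q = %.4g, mode = %s\n",
              x$epsilon, x$d_max, x$q, x$mode))
  invisible(x)
}

#' Depth assigned to a brightness level
#'
#' The piecewise-linear, non-increasing depth function of the model:
#' `zeta(0) = D_max`, `zeta(beta >= 255 - epsilon) = 0`, linear in between.
#'
#' @param beta brightness value(s) in `[0, 255]`.
#' @param model a [depth_model()].
#' @return Depth(s) in pixels.
#' @examples
#' m <- depth_model(10, d_max = 40)
#' pore_depth(0, m)    # 40
#' pore_depth(245, m)  # 0
#' @export
pore_depth <- function(beta, model) {
  stopifnot(inherits(model, "depth_model"))
  if (any(beta < 0 | beta > 255)) stop("brightness outside [0, 255]")
  thr <- 255 - model$epsilon
  ifelse(beta < thr, model$d_max * (1 - beta / thr), 0)
}

#' Per-pixel depth map and brightness-based porosity
#'
#' Applies the depth function to every pixel of the (unenhanced) image: each
#' pixel represents a cuboid of size 1 x 1 x zeta, so the total pore volume is
#' `V_sigma = sum(zeta)` and the density `rho = V_sigma / V` with the model's
#' reference volume (`N * D_max` in `"consistent"` mode, `N * 255` in
#' `"as-printed"` mode).
#'
#' The image must be the raw SEM image: contrast enhancement (e.g.
#' [enhance_left_stretch()]) destroys the linear brightness-depth relation.
#'
#' @param img a [gray_image()].
#' @param model a [depth_model()].
#' @return A list of class `depth_map` with `zeta` (depth matrix, pixels),
#'   `V_sigma` (pix^3), `V_ref`, `rho`, and `model`.
#' @export
depth_map <- function(img, model) {
  stopifnot(inherits(img, "gray_image"), inherits(model, "depth_model"))
  zeta <- matrix(pore_depth(as.vector(img$pixels), model),
                 nrow(img$pixels), ncol(img$pixels))
  N <- length(zeta)
  V_sigma <- sum(zeta)
  V_ref <- if (model$mode == "consistent") N * model$d_max else N * 255
  rho <- if (V_ref > 0) V_sigma / V_ref else 0
  structure(list(zeta = zeta, V_sigma = V_sigma, V_ref = V_ref, rho = rho,
                 model = model),
            class = "depth_map")
}

#' @export
print.depth_map <- function(x, ...) {
  cat(sprintf("depth_map: V_sigma = %.4g pix^3, V_ref = %.4g, rho = %.4g (%s mode)\n",
              x$V_sigma, x$V_ref, x$rho, x$model$mode))
  invisible(x)
}

#' Depth-based porosity of an image
#'
#' Convenience wrapper: extracts every `stride`-th row as a profile, estimates
#' `D_max` (unless supplied), builds the depth model and returns the depth
#' map.
#'
#' @param img a [gray_image()] (unenhanced).
#' @param epsilon brightness margin.
#' @param d_max maximal depth in pixels, or `"auto"` to estimate from the
#'   profiles.
#' @param stride row stride for the profile set (default 64); ignored when
#'   `rows` is given.
#' @param rows explicit profile rows (overrides `stride`).
#' @param mode reference-volume convention, see [depth_model()].
#' @return A `depth_map` (see [depth_map()]).
#' @export
depth_porosity <- function(img, epsilon = 10, d_max = "auto", stride = 64,
                           rows = NULL, mode = c("consistent", "as-printed")) {
  mode <- match.arg(mode)
  stopifnot(inherits(img, "gray_image"))
  if (identical(d_max, "auto")) {
    if (is.null(rows)) rows <- seq(1L, nrow(img$pixels), by = stride)
    profiles <- lapply(rows, extract_profile, img = img)
    d_max <- estimate_dmax(profiles, epsilon = epsilon)
  }
  depth_map(img, depth_model(epsilon, d_max, mode = mode))
}
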