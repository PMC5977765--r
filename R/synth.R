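# Synthetic porous scenes: seeded ellipsoid packings in a slab, rendered as
# SEM-like cross-section or depth-shaded images with exact ground truth.

# internal: uniform random 3D rotation matrix (QR of a Gaussian matrix with
# sign correction; Haar-distributed)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  Q <- Q %*% diag(d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# internal: quadric matrix of an ellipsoid with semi-axes abc and rotation R:
# points u with t(u) %*% A %*% u <= 1 are inside
ellipsoid_quadric <- function(axes, R) {
  R %*% diag(1 / axes^2) %*% t(R)
}

#' Generate a synthetic 3D porous scene
#'
#' Places `n_pores` quasi-ellipsoidal pores inside a `W x H x Z` slab. Pore
#' semi-axes are drawn from a log-normal distribution; with
#' `isotropic_shape = TRUE` each pore is a sphere (one radius draw), otherwise
#' the three semi-axes are drawn independently and the pore receives a uniform
#' random 3D orientation, so that the scene statistics remain isotropic.
#' Pores are placed wholly inside the slab (margin = bounding radius), so
#' every pore's ground-truth volume is the analytic `(4/3) pi a b c`.
#' Non-overlapping placement (the default) is attempted by rejection sampling
#' with `max_retries` draws per pore.
#'
#' All randomness is scoped to the supplied seed; the global RNG state is left
#' untouched, and identical seed and parameters reproduce the identical scene.
#'
#' @param n_pores number of pores (may be 0).
#' @param dims integer vector `c(W, H, Z)`: slab width, height and depth, pix.
#' @param axis_meanlog,axis_sdlog parameters of the log-normal semi-axis
#'   distribution, pix (defaults log(10) and 0.25).
#' @param isotropic_shape spheres (`TRUE`, default) or oriented triaxial
#'   ellipsoids.
#' @param allow_overlap permit overlapping pores (default `FALSE`).
#' @param max_retries rejection-sampling budget per pore.
#' @param seed integer RNG seed.
#' @return A list of class `pore_scene`: `dims`, `pores` (list of
#'   `center`/`axes`/`rotation`/`quadric`), `true_volumes` (analytic, pix^3),
#'   `true_density` (total pore volume over slab volume), `seed`, `params`.
#' @examples
#' sc <- generate_scene(1, dims = c(100, 100, 100),
#'                      axis_meanlog = log(10), axis_sdlog = 0, seed = 1)
#' sc$true_volumes          # 4/3 * pi * 10^3 = 4188.79
#' @export
generate_scene <- function(n_pores, dims = c(128L, 128L, 64L),
                           axis_meanlog = log(10), axis_sdlog = 0.25,
                           isotropic_shape = TRUE, allow_overlap = FALSE,
                           max_retries = 500L, seed = 1L) {
  stopifnot(length(dims) == 3L, all(dims >= 1))
  if (n_pores < 0) stop("'n_pores' must be non-negative")
  pores <- withr::with_seed(seed, {
    out <- vector("list", n_pores)
    i <- 0L
    while (i < n_pores) {
      placed <- FALSE
      for (try in seq_len(max_retries)) {
        axes <- if (isotropic_shape) rep(stats::rlnorm(1, axis_meanlog, axis_sdlog), 3)
                else stats::rlnorm(3, axis_meanlog, axis_sdlog)
        rmax <- max(axes)
        if (any(dims <= 2 * rmax + 2))
          stop("pore with bounding radius ", round(rmax, 1),
               " cannot fit inside slab of dims ",
               paste(dims, collapse = "x"))
        center <- stats::runif(3, min = rmax + 1, max = dims - rmax - 1)
        R <- if (isotropic_shape) diag(3) else random_rotation()
        ok <- TRUE
        if (!allow_overlap && i > 0L) {
          for (p in out[seq_len(i)]) {
            # conservative bounding-sphere test
            if (sqrt(sum((center - p$center)^2)) < rmax + max(p$axes)) {
              ok <- FALSE
              break
            }
          }
        }
        if (ok) {
          out[[i + 1L]] <- list(center = center, axes = axes, rotation = R,
                                quadric = ellipsoid_quadric(axes, R))
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place pore ", i + 1L, " without overlap after ",
             max_retries, " retries; reduce n_pores or pore size")
      i <- i + 1L
    }
    out
  })
  true_volumes <- vapply(pores, function(p) 4 / 3 * pi * prod(p$axes),
                         numeric(1))
  structure(list(
    dims = as.numeric(dims),
    pores = pores,
    true_volumes = true_volumes,
    true_density = sum(true_volumes) / prod(dims),
    seed = seed,
    params = list(n_pores = n_pores, axis_meanlog = axis_meanlog,
                  axis_sdlog = axis_sdlog, isotropic_shape = isotropic_shape,
                  allow_overlap = allow_overlap)
  ), class = "pore_scene")
}

#' @export
print.pore_scene <- function(x, ...) {
  cat(sprintf("pore_scene: %d pore(s) in %s slab, true density %.4g (seed %d)\n",
              length(x$pores), paste(x$dims, collapse = "x"),
              x$true_density, x$seed))
  invisible(x)
}

#' Voxel-counted total pore volume of a scene
#'
#' Counts grid points inside any pore at the requested resolution; converges
#' to the analytic total volume as `step` decreases. Assumes non-overlapping
#' pores (the generator default).
#'
#' @param scene a `pore_scene`.
#' @param step voxel spacing in pixels (default 1).
#' @return Total voxelized pore volume in pix^3.
#' @export
voxelized_volume <- function(scene, step = 1) {
  stopifnot(inherits(scene, "pore_scene"))
  total <- 0
  for (p in scene$pores) {
    rmax <- max(p$axes)
    gx <- seq(p$center[1] - rmax - step, p$center[1] + rmax + step, by = step)
    gy <- seq(p$center[2] - rmax - step, p$center[2] + rmax + step, by = step)
    gz <- seq(p$center[3] - rmax - step, p$center[3] + rmax + step, by = step)
    A <- p$quadric
    # evaluate the quadric over the separable grid
    n_in <- 0
    for (z in gz) {
      dx <- rep(gx - p$center[1], times = length(gy))
      dy <- rep(gy - p$center[2], each = length(gx))
      dz <- z - p$center[3]
      q <- A[1, 1] * dx^2 + A[2, 2] * dy^2 + A[3, 3] * dz^2 +
        2 * A[1, 2] * dx * dy + 2 * A[1, 3] * dx * dz + 2 * A[2, 3] * dy * dz
      n_in <- n_in + sum(q <= 1)
    }
    total <- total + n_in * step^3
  }
  total
}

#' Render a synthetic scene as an SEM-like grayscale image
#'
#' Two rendering modes:
#'
#' * `"cross-section"`: the plane `z = z0` cuts the slab; pixels whose center
#'   lies inside any pore's elliptic section are drawn dark (`beta_pore`,
#'   guaranteed below `255 - epsilon_render`), all others at the background
#'   level. The exact section mask is returned.
#' * `"depth-render"`: per pixel, the true depth is the total vertical (z)
#'   extent of pore material in that pixel's column, clipped to the slab; the
#'   brightness encodes it linearly,
#'   `beta = (255 - epsilon_render) * (1 - depth / d_true)` clipped at 0,
#'   with depth-0 pixels at the background level. The exact depth field is
#'   returned, enabling round-trip validation of the depth estimator.
#'
#' Gaussian brightness noise (`noise_sd`) is added last, seeded; the rendered
#' image is rounded and clipped to `[0, 255]`.
#'
#' @param scene a `pore_scene` from [generate_scene()].
#' @param mode `"cross-section"` or `"depth-render"`.
#' @param z0 section plane for cross-section mode (default mid-slab); must
#'   lie inside the slab.
#' @param bg background brightness (default 255).
#' @param epsilon_render brightness margin used by the renderer.
#' @param beta_pore interior brightness of sections in cross-section mode.
#' @param noise_sd standard deviation of additive Gaussian brightness noise.
#' @param d_true depth normalization of the brightness code (default: slab
#'   depth `Z`).
#' @param scale micrometres per pixel attached to the rendered image.
#' @param seed seed for the noise (default derived from the scene seed).
#' @return A list of class `rendered_scene` with `image` (a [gray_image()]),
#'   `mask` (cross-section mode) or `depth` (depth-render mode: the exact
#'   depth field matrix, pixels), and `spec` (the render settings).
#' @export
render_scene <- function(scene, mode = c("cross-section", "depth-render"),
                         z0 = NULL, bg = 255, epsilon_render = 10,
                         beta_pore = 100, noise_sd = 0, d_true = NULL,
                         scale = 1, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(scene, "pore_scene"))
  W <- scene$dims[1]; H <- scene$dims[2]; Z <- scene$dims[3]
  if (is.null(z0)) z0 <- Z / 2
  if (mode == "cross-section" && (z0 < 0 || z0 > Z))
    stop("section plane z0 = ", z0, " lies outside the slab [0, ", Z, "]")
  if (is.null(d_true)) d_true <- Z
  if (is.null(seed)) seed <- scene$seed + 1000L
  if (beta_pore >= 255 - epsilon_render)
    stop("'beta_pore' must lie below 255 - epsilon_render")
  # pixel-center coordinate grids (x across columns, y down rows)
  dx_g <- matrix(rep(seq_len(W), each = H), H, W)
  dy_g <- matrix(rep(seq_len(H), times = W), H, W)
  if (mode == "cross-section") {
    mask <- matrix(FALSE, H, W)
    for (p in scene$pores) {
      A <- p$quadric
      ddx <- dx_g - p$center[1]
      ddy <- dy_g - p$center[2]
      ddz <- z0 - p$center[3]
      q <- A[1, 1] * ddx^2 + A[2, 2] * ddy^2 + A[3, 3] * ddz^2 +
        2 * A[1, 2] * ddx * ddy + 2 * A[1, 3] * ddx * ddz +
        2 * A[2, 3] * ddy * ddz
      mask <- mask | (q <= 1)
    }
    beta <- matrix(bg, H, W)
    beta[mask] <- beta_pore
    beta <- add_render_noise(beta, noise_sd, seed)
    return(structure(list(
      image = gray_image(beta, scale = scale, magnification = "synthetic"),
      mask = mask,
      spec = list(mode = mode, z0 = z0, bg = bg,
                  epsilon_render = epsilon_render, beta_pore = beta_pore,
                  noise_sd = noise_sd, seed = seed)
    ), class = "rendered_scene"))
  }
  # depth-render: per-pixel z-extent of pore material, clipped to the slab
  depth <- matrix(0, H, W)
  for (p in scene$pores) {
    A <- p$quadric
    ddx <- dx_g - p$center[1]
    ddy <- dy_g - p$center[2]
    # quadric restricted to the vertical line through (x, y):
    # A33 t^2 + 2(A13 dx + A23 dy) t + (quadratic in dx,dy) <= 1, t = z - cz
    a <- A[3, 3]
    b <- 2 * (A[1, 3] * ddx + A[2, 3] * ddy)
    cc <- A[1, 1] * ddx^2 + 2 * A[1, 2] * ddx * ddy + A[2, 2] * ddy^2 - 1
    disc <- b^2 - 4 * a * cc
    hit <- disc > 0
    if (!any(hit)) next
    sq <- sqrt(pmax(disc, 0))
    z_lo <- p$center[3] + (-b - sq) / (2 * a)
    z_hi <- p$center[3] + (-b + sq) / (2 * a)
    ext <- pmax(0, pmin(z_hi, Z) - pmax(z_lo, 0))
    depth <- depth + ifelse(hit, ext, 0)
  }
  beta <- (255 - epsilon_render) * (1 - depth / d_true)
  beta <- pmax(beta, 0)
  beta[depth == 0] <- bg
  beta <- add_render_noise(beta, noise_sd, seed)
  structure(list(
    image = gray_image(beta, scale = scale, magnification = "synthetic"),
    depth = depth,
    spec = list(mode = mode, bg = bg, epsilon_render = epsilon_render,
                d_true = d_true, noise_sd = noise_sd, seed = seed)
  ), class = "rendered_scene")
}

# internal: seeded additive Gaussian noise, then round and clip to [0, 255]
add_render_noise <- function(beta, noise_sd, seed) {
  if (noise_sd > 0) {
    noise <- withr::with_seed(seed,
      matrix(stats::rnorm(length(beta), 0, noise_sd),
             nrow(beta), ncol(beta)))
    beta <- beta + noise
  }
  pmin(pmax(round(beta), 0), 255)
}

#' @export
print.rendered_scene <- function(x, ...) {
  cat(sprintf("rendered_scene (%s): %d x %d px\n",
              x$spec$mode, ncol(x$image$pixels), nrow(x$image$pixels)))
  invisible(x)
}

#' Ground-truth table of a scene
#'
#' @param scene a `pore_scene`.
#' @return Data frame with one row per pore: center coordinates, semi-axes,
#'   analytic volume.
#' @export
scene_truth <- function(scene) {
  stopifnot(inherits(scene, "pore_scene"))
  n <- length(scene$pores)
  data.frame(
    pore = seq_len(n),
    cx = vapply(scene$pores, function(p) p$center[1], numeric(1)),
    cy = vapply(scene$pores, function(p) p$center[2], numeric(1)),
    cz = vapply(scene$pores, function(p) p$center[3], numeric(1)),
    a = vapply(scene$pores, function(p) p$axes[1], numeric(1)),
    b = vapply(scene$pores, function(p) p$axes[2], numeric(1)),
    c = vapply(scene$pores, function(p) p$axes[3], numeric(1)),
    volume_pix3 = scene$true_volumes
  )
}
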