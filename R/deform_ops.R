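# Diffeomorphic deformation machinery: stationary-velocity-field integration
# by scaling and squaring, spatial-transformer warping, field composition and
# Jacobian diagnostics.  Displacements are in voxel units throughout; they
# are converted to mm only inside the evaluation metrics.

.check_field <- function(phi, name = "field") {
  if (!is.array(phi) || length(dim(phi)) != 4L || dim(phi)[1L] != 3L)
    stop(name, " must be a (3, D, H, W) array")
  if (!all(is.finite(phi))) stop(name, " contains non-finite values")
  invisible(phi)
}

#' Integrate a stationary velocity field (scaling and squaring)
#'
#' Computes the flow of the velocity field `v` at pseudo-time 1 by halving the
#' field `2^steps` times and self-composing the resulting small deformation
#' `steps` times.  With 7 steps (the default) the result is diffeomorphic for
#' any smooth, moderately sized velocity field.
#'
#' @param v velocity field, array of dim (3, D, H, W), voxel units, component
#'   order (depth, height, width).
#' @param steps number of squaring steps (non-negative integer; default 7).
#' @return deformation field of the same shape: warped(p) samples p + phi(p).
#' @export
vecint <- function(v, steps = 7L) {
  .check_field(v, "velocity")
  if (length(steps) != 1L || is.na(steps) || steps < 0)
    stop("steps must be a non-negative integer")
  steps <- as.integer(steps)
  phi <- v / 2^steps
  for (i in seq_len(steps)) phi <- compose(phi, phi)
  phi
}

#' Autodiff version of [vecint()] operating on `ad_node`s.
#' @keywords internal
vecint_ad <- function(v, steps = 7L) {
  phi <- ad_scale(as_ad(v), 1 / 2^steps)
  for (i in seq_len(steps)) phi <- ad_add(phi, ad_warp(phi, phi))
  phi
}

#' Warp an image or label by a deformation field
#'
#' `out(p) = img(p + phi(p))` with trilinear (images) or nearest-neighbor
#' (labels) interpolation; out-of-bounds sample positions clamp to the border.
#'
#' @param img array of dim (D, H, W) or (C, D, H, W).
#' @param phi deformation field (3, D, H, W) in voxel units.
#' @param mode "trilinear" or "nearest".
#' @return warped array with the shape of `img`.
#' @export
warp <- function(img, phi, mode = c("trilinear", "nearest")) {
  mode <- match.arg(mode)
  .check_field(phi)
  dm <- dim(img)
  squeeze <- FALSE
  if (length(dm) == 3L) {
    dim(img) <- c(1L, dm)
    squeeze <- TRUE
  } else if (length(dm) != 4L) {
    stop("img must have 3 or 4 dimensions")
  }
  if (!all(dim(img)[2:4] == dim(phi)[2:4]))
    stop("img and phi spatial shapes differ")
  out <- cpp_grid_sample_fw(img, dim(img), phi,
                            mode == "nearest")
  dim(out) <- if (squeeze) dm else dim(img)
  out
}

#' Compose two deformation fields
#'
#' Returns the field of "apply `phi_inner` first, then `phi_outer`":
#' `(phi_outer o phi_inner)(p) = phi_inner(p) + phi_outer(p + phi_inner(p))`,
#' sampling `phi_outer` trilinearly.
#'
#' @param phi_outer,phi_inner deformation fields (3, D, H, W).
#' @return composed deformation field.
#' @export
compose <- function(phi_outer, phi_inner) {
  .check_field(phi_outer, "phi_outer"); .check_field(phi_inner, "phi_inner")
  if (!all(dim(phi_outer) == dim(phi_inner)))
    stop("field shapes differ")
  s <- cpp_grid_sample_fw(phi_outer, dim(phi_outer),
                          phi_inner, FALSE)
  dim(s) <- dim(phi_inner)
  phi_inner + s
}

#' Jacobian determinant diagnostics of a deformation
#'
#' Central-difference Jacobian of the map p -> p + phi(p) over the interior
#' (one-voxel margin excluded to avoid boundary artifacts).
#'
#' @param phi deformation field (3, D, H, W).
#' @return list with `det_field` (array over the (D-2, H-2, W-2) interior) and
#'   `folding_fraction` (share of interior voxels with non-positive
#'   determinant).
#' @export
jacobian_stats <- function(phi) {
  .check_field(phi)
  d <- dim(phi)[2:4]
  if (any(d < 3L)) stop("spatial dims must be >= 3 for an interior Jacobian")
  di <- 2:(d[1] - 1); hi <- 2:(d[2] - 1); wi <- 2:(d[3] - 1)
  # J[i, j] = d(p_i + phi_i)/d p_j, central differences (spacing 1 voxel)
  J <- array(0, c(3, 3, length(di), length(hi), length(wi)))
  for (i in 1:3) {
    J[i, 1, , , ] <- (phi[i, di + 1, hi, wi] - phi[i, di - 1, hi, wi]) / 2
    J[i, 2, , , ] <- (phi[i, di, hi + 1, wi] - phi[i, di, hi - 1, wi]) / 2
    J[i, 3, , , ] <- (phi[i, di, hi, wi + 1] - phi[i, di, hi, wi - 1]) / 2
    J[i, i, , , ] <- J[i, i, , , ] + 1
  }
  det <- J[1, 1, , , ] * (J[2, 2, , , ] * J[3, 3, , , ] - J[2, 3, , , ] * J[3, 2, , , ]) -
         J[1, 2, , , ] * (J[2, 1, , , ] * J[3, 3, , , ] - J[2, 3, , , ] * J[3, 1, , , ]) +
         J[1, 3, , , ] * (J[2, 1, , , ] * J[3, 2, , , ] - J[2, 2, , , ] * J[3, 1, , , ])
  dim(det) <- c(length(di), length(hi), length(wi))
  list(det_field = det, folding_fraction = mean(det <= 0))
}

#' Sample a deformation field at arbitrary (possibly fractional) points
#'
#' Trilinear interpolation of each displacement component at 0-based voxel
#' coordinates; used to map landmarks through a field.
#'
#' @param phi deformation field (3, D, H, W).
#' @param pts n x 3 matrix of 0-based voxel coordinates (axis order d, h, w).
#' @return n x 3 matrix of displacements.
#' @export
sample_field <- function(phi, pts) {
  .check_field(phi)
  pts <- matrix(pts, ncol = 3L)
  d <- dim(phi)[2:4]
  out <- matrix(0, nrow(pts), 3L)
  for (n in seq_len(nrow(pts))) {
    p <- pmin(pmax(pts[n, ], 0), d - 1)
    i0 <- pmin(floor(p), d - 2); f <- p - i0
    i0 <- pmax(i0, 0)
    for (comp in 1:3) {
      acc <- 0
      for (od in 0:1) for (oh in 0:1) for (ow in 0:1) {
        wgt <- (if (od) f[1] else 1 - f[1]) * (if (oh) f[2] else 1 - f[2]) *
               (if (ow) f[3] else 1 - f[3])
        acc <- acc + wgt * phi[comp, min(i0[1] + od + 1, d[1]),
                               min(i0[2] + oh + 1, d[2]),
                               min(i0[3] + ow + 1, d[3])]
      }
      out[n, comp] <- acc
    }
  }
  out
}

#' Map landmark coordinates through a deformation field
#'
#' A fixed-grid point p corresponds to the moving-image location p + phi(p).
#'
#' @param pts n x 3 matrix of 0-based voxel coordinates.
#' @param phi deformation field (3, D, H, W).
#' @return n x 3 matrix of warped coordinates.
#' @export
warp_landmarks <- function(pts, phi) {
  pts <- matrix(pts, ncol = 3L)
  pts + sample_field(phi, pts)
}
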