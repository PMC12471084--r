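# Synthetic prostate phantom generator.
#
# Produces pre-aligned cross-modal volume pairs with a known, guaranteed
# diffeomorphic ground-truth deformation: the base anatomy (an ellipsoidal
# organ with smooth internal structure) is rendered once with an MRI-like
# intensity model (piecewise-smooth, high contrast, additive Gaussian noise)
# and once with a TRUS-like model (remapped contrast, multiplicative
# log-normal speckle, radial intensity falloff).  Ground truth is a stationary
# velocity field integrated by the same scaling-and-squaring integrator used
# everywhere else, so recovery experiments compare like with like.

.local_seed <- function(seed, code) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", globalenv())
  set.seed(seed)
  on.exit(if (has) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  force(code)
}

#' Phantom generation parameters
#'
#' Defaults describe a desk-scale case: a 32^3 isotropic grid holding an
#' ellipsoidal organ of semiaxes (8, 10, 9) voxels, deformed by a smooth
#' random field of about 3 voxels maximum displacement.
#'
#' @param grid_shape 3 positive integers (voxels).
#' @param spacing_mm 3 positive reals.
#' @param organ_semiaxes_vox ellipsoid semiaxes in voxels.
#' @param deform_amplitude_vox target maximum displacement of the integrated
#'   ground-truth field (>= 0).
#' @param deform_smoothness_vox Gaussian scale of the random velocity field.
#' @param speckle_sigma log-normal speckle sigma of the TRUS-like rendering.
#' @param noise_sigma additive Gaussian noise sigma of the MRI-like rendering.
#' @param n_landmarks landmarks sampled inside the organ.
#' @param seed integer seed; identical seeds give bit-identical phantoms.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(32, 32, 32), spacing_mm = c(1, 1, 1),
                         organ_semiaxes_vox = c(8, 10, 9),
                         deform_amplitude_vox = 3, deform_smoothness_vox = 8,
                         speckle_sigma = 0.3, noise_sigma = 0.02,
                         n_landmarks = 10, seed = 0L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape > 0),
            length(spacing_mm) == 3L, all(spacing_mm > 0),
            length(organ_semiaxes_vox) == 3L, all(organ_semiaxes_vox > 0),
            deform_amplitude_vox >= 0, deform_smoothness_vox > 0,
            speckle_sigma >= 0, noise_sigma >= 0, n_landmarks >= 1)
  if (any(organ_semiaxes_vox + 2 > (grid_shape - 1) / 2))
    stop("organ does not fit inside the grid with a 2-voxel margin")
  structure(list(grid_shape = grid_shape, spacing_mm = as.numeric(spacing_mm),
                 organ_semiaxes_vox = as.numeric(organ_semiaxes_vox),
                 deform_amplitude_vox = deform_amplitude_vox,
                 deform_smoothness_vox = deform_smoothness_vox,
                 speckle_sigma = speckle_sigma, noise_sigma = noise_sigma,
                 n_landmarks = as.integer(n_landmarks), seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Random smooth stationary velocity field
#'
#' Three channels of Gaussian-smoothed white noise, rescaled so the maximum
#' displacement magnitude of the *integrated* field is approximately
#' `amplitude` voxels (two rescaling passes; integration is nearly linear at
#' these amplitudes).
#'
#' @param shape 3 integers (>= 8 per axis).
#' @param amplitude target maximum displacement after integration (voxels).
#' @param smoothness Gaussian scale in voxels (> 0).
#' @param seed integer seed.
#' @return velocity field (3, D, H, W), deterministic in `seed`.
#' @export
make_velocity_field <- function(shape, amplitude, smoothness, seed) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 8L))
  if (smoothness <= 0) stop("smoothness must be positive")
  if (amplitude < 0) stop("amplitude must be non-negative")
  v <- array(0, c(3L, shape))
  if (amplitude == 0) return(v)
  # smooth white noise on an extended grid and crop, so the field statistics
  # are stationary (replicate-padded smoothing would inflate border variance)
  pad <- as.integer(ceiling(3 * smoothness))
  ext <- shape + 2L * pad
  noise <- .local_seed(seed, array(stats::rnorm(3 * prod(ext)), c(ext, 3L)))
  # smoothstep taper to zero over a 4-voxel margin keeps the flow interior
  edge <- function(n, m) {
    i <- seq_len(n) - 1
    t <- pmin(i / m, (n - 1 - i) / m, 1)
    t^2 * (3 - 2 * t)
  }
  win <- outer(outer(edge(shape[1], 4), edge(shape[2], 4)), edge(shape[3], 4))
  core <- lapply(shape, function(n) pad + seq_len(n))
  for (comp in 1:3) {
    sm <- cpp_smooth_gauss3(as.vector(noise[, , , comp]), ext, smoothness)
    dim(sm) <- ext
    v[comp, , , ] <- sm[core[[1]], core[[2]], core[[3]]] * win
  }
  for (pass in 1:2) {
    phi <- vecint(v)
    m <- max(sqrt(colSums(matrix(phi, nrow = 3)^2)))
    if (m == 0) return(array(0, c(3L, shape)))
    v <- v * (amplitude / m)
  }
  v
}

# base anatomy: list(structure = smooth scalar field in [0,1], organ = soft
# indicator, r = normalized ellipsoid radius)
.phantom_anatomy <- function(spec) {
  d <- spec$grid_shape
  ctr <- (d - 1) / 2
  ax <- spec$organ_semiaxes_vox
  gd <- (seq_len(d[1]) - 1 - ctr[1]) / ax[1]
  gh <- (seq_len(d[2]) - 1 - ctr[2]) / ax[2]
  gw <- (seq_len(d[3]) - 1 - ctr[3]) / ax[3]
  r2 <- outer(outer(gd^2, gh^2, `+`), gw^2, `+`)
  r <- sqrt(r2)
  organ <- 1 / (1 + exp((r - 1) / 0.06))          # soft ellipsoid boundary
  # internal texture: deterministic smooth bumps inside the organ
  bl <- .local_seed(spec$seed + 7L, {
    nb <- 3L
    pos <- matrix(stats::runif(3 * nb, -0.45, 0.45), nb, 3)
    amp <- stats::runif(nb, -0.35, 0.35)
    wid <- stats::runif(nb, 0.18, 0.3)
    list(pos = pos, amp = amp, wid = wid)
  })
  tex <- array(0, d)
  for (b in seq_along(bl$amp)) {
    q2 <- outer(outer((gd - bl$pos[b, 1])^2, (gh - bl$pos[b, 2])^2, `+`),
                (gw - bl$pos[b, 3])^2, `+`)
    tex <- tex + bl$amp[b] * exp(-q2 / (2 * bl$wid[b]^2))
  }
  structure_field <- organ * (0.6 + tex)
  list(structure = structure_field, organ = organ, mask = (r <= 1) + 0)
}

.render_mri <- function(s, noise_sigma, seed) {
  img <- 0.15 + 0.8 * s
  if (noise_sigma > 0)
    img <- img + .local_seed(seed, array(stats::rnorm(length(s), 0, noise_sigma), dim(s)))
  img
}

.render_trus <- function(s, speckle_sigma, seed, shape) {
  # inverted, compressed contrast; probe-like radial falloff from the center
  # of the last face; multiplicative log-normal speckle
  base <- 0.9 - 0.65 * s + 0.1 * s^2
  ctr <- (shape - 1) / 2
  gd <- seq_len(shape[1]) - 1 - ctr[1]
  gh <- seq_len(shape[2]) - 1 - ctr[2]
  gw <- seq_len(shape[3]) - 1 - (shape[3] - 1)
  dist <- sqrt(outer(outer(gd^2, gh^2, `+`), gw^2, `+`))
  falloff <- 1 - 0.35 * dist / max(dist)
  img <- base * falloff
  if (speckle_sigma > 0) {
    sp <- .local_seed(seed, array(stats::rnorm(length(s), 0, speckle_sigma), dim(s)))
    img <- img * exp(sp - speckle_sigma^2 / 2)
  }
  img
}

#' Generate a cross-modal phantom pair with known ground truth
#'
#' The fixed image is a TRUS-like rendering of the base anatomy; the moving
#' image is an MRI-like rendering of the anatomy warped by the *inverse* of
#' the ground-truth field, so that warping the moving image by `gt_field`
#' aligns it with the fixed image.  Landmarks are organ-interior voxel centers
#' mapped exactly through the field.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `phantom_case`: fields `moving`, `fixed`
#'   ([volume()]), `moving_mask`, `fixed_mask` ([label_mask()]),
#'   `landmarks_moving`, `landmarks_fixed` ([landmark_set()]), `gt_field`
#'   (3, D, H, W array) and `gt_velocity`.
#' @export
make_phantom_pair <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  v <- make_velocity_field(d, spec$deform_amplitude_vox,
                           spec$deform_smoothness_vox, spec$seed)
  .phantom_from_velocity(spec, v, frame_seed = spec$seed)
}

.phantom_from_velocity <- function(spec, v, frame_seed) {
  d <- spec$grid_shape
  anat <- .phantom_anatomy(spec)
  if (all(v == 0)) {
    phi <- phi_inv <- array(0, c(3L, d))
  } else {
    phi <- vecint(v)
    phi_inv <- vecint(-v)
  }
  s_moving <- warp(anat$structure, phi_inv)
  mask_moving <- warp(anat$mask, phi_inv, mode = "nearest")
  moving <- volume(.render_mri(s_moving, spec$noise_sigma, frame_seed + 101L),
                   spec$spacing_mm, "MRI_like")
  fixed <- volume(.render_trus(anat$structure, spec$speckle_sigma,
                               frame_seed + 202L, d),
                  spec$spacing_mm, "TRUS_like")
  # landmarks: voxel centers well inside the organ on the fixed grid
  idx <- which(anat$organ > 0.95, arr.ind = TRUE) - 1L
  sel <- .local_seed(spec$seed + 11L,
                     sample.int(nrow(idx), min(spec$n_landmarks, nrow(idx))))
  lf <- idx[sel, , drop = FALSE]
  lm <- warp_landmarks(lf, phi)
  structure(list(
    moving = moving, fixed = fixed,
    moving_mask = label_mask(mask_moving, spec$spacing_mm),
    fixed_mask = label_mask(anat$mask, spec$spacing_mm),
    landmarks_moving = landmark_set(lm),
    landmarks_fixed = landmark_set(lf),
    gt_field = phi, gt_velocity = v, spec = spec
  ), class = "phantom_case")
}

#' Generate a pseudo-respiratory 4D phantom sequence
#'
#' Frames share the anatomy; frame `t` (0-based) uses the base velocity field
#' scaled by `sin(2*pi*t/period)`, integrated to its ground-truth deformation,
#' emulating a breathing cycle.
#'
#' @param spec a [phantom_spec()].
#' @param n_frames number of frames (>= 2).
#' @param period cycle length in frames (> 0).
#' @return list of `phantom_case`, deterministic in `spec$seed`.
#' @export
make_4d_sequence <- function(spec, n_frames, period) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (period <= 0) stop("period must be positive")
  if (n_frames < 2) stop("n_frames must be >= 2")
  v <- make_velocity_field(spec$grid_shape, spec$deform_amplitude_vox,
                           spec$deform_smoothness_vox, spec$seed)
  lapply(seq_len(n_frames) - 1L, function(t) {
    .phantom_from_velocity(spec, v * sin(2 * pi * t / period),
                           frame_seed = spec$seed + 1000L * t)
  })
}
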