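# Shared fixtures, built once per test run.

.fx <- new.env(parent = emptyenv())

# default 32^3 phantom case (deterministic)
fx_case <- function(seed = 3) {
  key <- paste0("case", seed)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- make_phantom_pair(phantom_spec(seed = seed))
  .fx[[key]]
}

# small 16^3 case for cheap training smokes
fx_case16 <- function(seed = 1, amplitude = 2) {
  key <- paste0("c16_", seed, "_", amplitude)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- make_phantom_pair(phantom_spec(
      grid_shape = c(16, 16, 16), organ_semiaxes_vox = c(4, 5, 4.5),
      deform_amplitude_vox = amplitude, n_landmarks = 5, seed = seed))
  .fx[[key]]
}

# forward-Euler integration of a stationary velocity field (oracle for the
# scaling-and-squaring integrator; a different algorithm over the same
# trilinear sampling primitive)
euler_integrate <- function(v, n_steps = 1024L) {
  phi <- v * 0
  for (i in seq_len(n_steps)) phi <- phi + warp(v, phi) / n_steps
  phi
}

interior16 <- function(x) x[, 3:14, 3:14, 3:14, drop = FALSE]

# central-difference gradient check helper
fd_grad <- function(f, x, idxs, eps = 1e-4) {
  vapply(idxs, function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, 0)
}
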