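# velocity integration, warping, composition, Jacobian diagnostics

test_that("vecint handles trivial and constant fields", {
  z <- array(0, c(3, 8, 8, 8))
  expect_identical(vecint(z), z)
  expect_error(vecint(z, -1), "non-negative")
  # constant velocity integrates to the same translation in the interior
  v <- array(0, c(3, 24, 24, 24)); v[1, , , ] <- 2
  phi <- vecint(v)
  inn <- phi[, 5:18, 5:18, 5:18]
  expect_lt(max(abs(inn[1, , , ] - 2)), 1e-3)
  expect_lt(max(abs(inn[2:3, , , ])), 1e-3)
})

test_that("scaling-and-squaring agrees with the Euler oracle on smooth fields", {
  for (s in 1:3) {
    v <- make_velocity_field(c(16, 16, 16), 1, 4, s)
    err <- max(abs(interior16(vecint(v, 7)) - interior16(euler_integrate(v))))
    expect_lt(err, 0.05)
  }
})

test_that("the squaring recursion doubles velocity exactly", {
  v <- make_velocity_field(c(16, 16, 16), 2, 4, 4)
  lhs <- vecint(2 * v, 8)
  p <- vecint(v, 7)
  expect_identical(lhs, compose(p, p))
})

test_that("warp identities hold", {
  case <- fx_case16(2)
  img <- case$moving$data
  z <- array(0, c(3, dim(img)))
  expect_identical(warp(img, z), img)                    # bit-exact identity
  expect_error(warp(img, z, mode = "bilinear"))          # unknown mode
  # integer shift moves an impulse exactly (nearest)
  imp <- array(0, c(8, 8, 8)); imp[5, 5, 5] <- 1
  sh <- array(0, c(3, 8, 8, 8)); sh[1, , , ] <- 2; sh[3, , , ] <- -1
  out <- warp(imp, sh, mode = "nearest")
  expect_equal(out[3, 5, 6], 1)                          # p + phi(p) = source
  expect_equal(sum(out), 1)
  # trilinear warp is exact on affine images in the interior
  dm <- c(12, 12, 12)
  co <- expand.grid(d = 0:11, h = 0:11, w = 0:11)
  aff <- array(1.5 + 0.2 * co$d - 0.3 * co$h + 0.05 * co$w, dm)
  set.seed(9)
  phi <- array(stats::runif(3 * prod(dm), -1.5, 1.5), c(3, dm))
  out <- warp(aff, phi)
  pos_d <- array(co$d, dm) + phi[1, , , ]
  pos_h <- array(co$h, dm) + phi[2, , , ]
  pos_w <- array(co$w, dm) + phi[3, , , ]
  expected <- 1.5 + 0.2 * pos_d - 0.3 * pos_h + 0.05 * pos_w
  inn <- function(x) x[3:10, 3:10, 3:10]
  expect_lt(max(abs(inn(out) - inn(expected))), 1e-10)
  # warp is linear in the image argument
  a <- array(stats::rnorm(prod(dm)), dm); b <- array(stats::rnorm(prod(dm)), dm)
  expect_equal(warp(a, phi) + 2 * warp(b, phi), warp(a + 2 * b, phi),
               tolerance = 1e-12)
})

test_that("the compiled sampler matches the R-level field sampler", {
  v <- make_velocity_field(c(12, 12, 12), 2, 4, 3)
  set.seed(4)
  pts <- matrix(stats::runif(30, 1, 10), 10, 3)
  byr <- sample_field(v, pts)
  # express point sampling as a warp of each component at integer voxels
  for (i in seq_len(nrow(pts))) {
    shift <- array(0, c(3, 12, 12, 12))
    shift[1, 1, 1, 1] <- pts[i, 1]; shift[2, 1, 1, 1] <- pts[i, 2]
    shift[3, 1, 1, 1] <- pts[i, 3]
    out <- warp(v, shift)
    expect_equal(out[, 1, 1, 1], byr[i, ], tolerance = 1e-10)
  }
})

test_that("compose has identity element and adds translations", {
  v <- make_velocity_field(c(16, 16, 16), 2, 4, 5)
  phi <- vecint(v)
  z <- phi * 0
  expect_equal(compose(z, phi), phi, tolerance = 1e-12)
  expect_equal(compose(phi, z), phi, tolerance = 1e-12)
  a <- z; a[1, , , ] <- 0.5
  b <- z; b[2, , , ] <- -0.75
  ab <- compose(a, b)
  expect_equal(ab[1, 5:12, 5:12, 5:12], array(0.5, c(8, 8, 8)), tolerance = 1e-12)
  expect_equal(ab[2, 5:12, 5:12, 5:12], array(-0.75, c(8, 8, 8)), tolerance = 1e-12)
  # associativity within interpolation tolerance on small smooth fields
  f1 <- vecint(make_velocity_field(c(16, 16, 16), 0.5, 6, 6))
  f2 <- vecint(make_velocity_field(c(16, 16, 16), 0.5, 6, 7))
  f3 <- vecint(make_velocity_field(c(16, 16, 16), 0.5, 6, 8))
  lhs <- compose(compose(f3, f2), f1)
  rhs <- compose(f3, compose(f2, f1))
  expect_lt(max(abs(interior16(lhs) - interior16(rhs))), 1e-2)
  expect_error(compose(f1, array(0, c(3, 8, 8, 8))), "shapes")
})

test_that("jacobian_stats matches analytic determinants", {
  z <- array(0, c(3, 10, 10, 10))
  js <- jacobian_stats(z)
  expect_true(all(js$det_field == 1))
  expect_equal(js$folding_fraction, 0)
  # uniform scaling phi(p) = 0.1 (p - center) -> det = 1.1^3
  co <- expand.grid(d = 0:9, h = 0:9, w = 0:9)
  phi <- array(0, c(3, 10, 10, 10))
  phi[1, , , ] <- 0.1 * (co$d - 4.5)
  phi[2, , , ] <- 0.1 * (co$h - 4.5)
  phi[3, , , ] <- 0.1 * (co$w - 4.5)
  js <- jacobian_stats(phi)
  expect_lt(max(abs(js$det_field - 1.1^3)), 1e-10)
})

test_that("integrated smooth bounded velocities never fold", {
  for (s in 1:20) {
    v <- make_velocity_field(c(16, 16, 16), 3, 4, 100 + s)
    expect_equal(jacobian_stats(vecint(v))$folding_fraction, 0)
  }
})

test_that("vecint(v) and vecint(-v) invert each other on smooth fields", {
  for (s in 1:3) {
    v <- make_velocity_field(c(16, 16, 16), 1, 4, 10 + s)
    res <- compose(vecint(v), vecint(-v))
    expect_lt(max(sqrt(colSums(matrix(interior16(res), nrow = 3)^2))), 0.1)
  }
})
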