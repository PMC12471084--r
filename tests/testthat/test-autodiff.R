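# reverse-mode autodiff engine: gradient checks against central differences

ad <- function(x) prostreg:::ad_param(x)
bk <- prostreg:::ad_backward
val <- prostreg:::ad_val

test_that("conv3d gradients match finite differences", {
  set.seed(1)
  x <- array(stats::rnorm(2 * 5 * 4 * 6), c(2, 5, 4, 6))
  w <- array(stats::rnorm(3 * 2 * 27) * 0.3, c(3, 2, 3, 3, 3))
  b <- stats::rnorm(3) * 0.1
  f_of <- function(xx, ww, bb) {
    out <- prostreg:::ad_conv3d(prostreg:::ad_node(xx), prostreg:::ad_node(ww),
                                prostreg:::ad_node(bb))
    sum(sin(val(out)))
  }
  xn <- ad(x); wn <- ad(w); bn <- ad(b)
  out <- prostreg:::ad_conv3d(xn, wn, bn)
  loss <- prostreg:::ad_sum(prostreg:::ad_node(sin(val(out)), list(out),
                                               function(g) list(g * cos(val(out)))))
  bk(loss)
  idx <- c(1, 17, 100)
  expect_equal(xn$grad[idx], fd_grad(function(z) f_of(z, w, b), x, idx, 1e-3),
               tolerance = 5e-2)
  expect_equal(wn$grad[idx], fd_grad(function(z) f_of(x, z, b), w, idx, 1e-3),
               tolerance = 5e-2)
  expect_equal(bn$grad, fd_grad(function(z) f_of(x, w, z), b, 1:3, 1e-3),
               tolerance = 5e-2)
})

test_that("warp gradients (image and field) match finite differences", {
  set.seed(2)
  img <- array(stats::rnorm(2 * 6 * 6 * 6), c(2, 6, 6, 6))
  phi <- array(stats::rnorm(3 * 6 * 6 * 6) * 0.4, c(3, 6, 6, 6))
  f_of <- function(ii, pp) sum(warp(ii, pp)^2)
  iin <- ad(img); pn <- ad(phi)
  out <- prostreg:::ad_warp(iin, pn)
  loss <- prostreg:::ad_sum(prostreg:::ad_mul(out, out))
  bk(loss)
  idx <- c(3, 50, 200)
  expect_equal(iin$grad[idx], fd_grad(function(z) f_of(z, phi), img, idx),
               tolerance = 1e-4)
  # avoid field entries whose sample position sits near a voxel boundary
  idxp <- c(10, 100, 400)
  expect_equal(pn$grad[idxp], fd_grad(function(z) f_of(img, z), phi, idxp),
               tolerance = 1e-3)
})

test_that("pooling, upsampling and pointwise op gradients are exact", {
  set.seed(3)
  x <- array(stats::rnorm(2 * 4 * 4 * 4), c(2, 4, 4, 4))
  xn <- ad(x)
  net <- prostreg:::ad_upsample2(prostreg:::ad_maxpool(prostreg:::ad_leaky_relu(xn)))
  loss <- prostreg:::ad_mean(prostreg:::ad_mul(net, net))
  bk(loss)
  f_of <- function(z) {
    zz <- prostreg:::ad_upsample2(prostreg:::ad_maxpool(
      prostreg:::ad_leaky_relu(prostreg:::ad_node(z))))
    mean(val(zz)^2)
  }
  idx <- c(1, 40, 99)
  expect_equal(xn$grad[idx], fd_grad(f_of, x, idx), tolerance = 1e-5)
})

test_that("mutual-information gradient matches finite differences", {
  set.seed(4)
  dm <- c(6, 6, 6)
  a <- array(stats::runif(prod(dm)), dm)
  b <- array(stats::runif(prod(dm)), dm)
  roi <- array(1, dm)
  an <- ad(a)
  loss <- mi_loss(an, b, roi, bins = 8)
  bk(loss)
  f_of <- function(z) mi_loss(z, b, roi, bins = 8)
  idx <- c(5, 60, 150)
  expect_equal(an$grad[idx], fd_grad(f_of, a, idx), tolerance = 2e-3)
})

test_that("dice and gradient-penalty gradients match finite differences", {
  set.seed(5)
  p <- array(stats::runif(4^3), c(1, 4, 4, 4))
  q <- (array(stats::runif(4^3), c(1, 4, 4, 4)) > 0.5) + 0
  pn <- ad(p)
  bk(dice_loss(pn, q))
  idx <- c(2, 30)
  expect_equal(pn$grad[idx], fd_grad(function(z) dice_loss(z, q), p, idx),
               tolerance = 1e-6)
  phi <- array(stats::rnorm(3 * 4 * 4 * 4), c(3, 4, 4, 4))
  fn <- ad(phi)
  bk(grad_loss(fn))
  expect_equal(fn$grad[idx], fd_grad(grad_loss, phi, idx), tolerance = 1e-6)
})

test_that("vecint_ad gradient agrees with finite differences", {
  set.seed(6)
  v <- make_velocity_field(c(8, 8, 8), 1, 3, 2)
  vn <- ad(v)
  phi <- prostreg:::vecint_ad(vn, 4)
  bk(prostreg:::ad_sum(prostreg:::ad_mul(phi, phi)))
  f_of <- function(z) sum(vecint(z, 4)^2)
  idx <- c(8, 300, 900)
  expect_equal(vn$grad[idx], fd_grad(f_of, v, idx), tolerance = 1e-3)
})

test_that("gradients accumulate over shared subexpressions", {
  x <- ad(c(1.5, -2))
  y <- prostreg:::ad_add(prostreg:::ad_mul(x, x), prostreg:::ad_scale(x, 3))
  bk(prostreg:::ad_sum(y))
  expect_equal(x$grad, 2 * c(1.5, -2) + 3)
})

test_that("softmax, lincomb and matmul gradients are correct", {
  set.seed(7)
  s <- stats::rnorm(4)
  sn <- ad(s)
  xs <- lapply(1:4, function(i) array(stats::rnorm(8), c(2, 2, 2)))
  out <- prostreg:::ad_lincomb(xs, prostreg:::ad_softmax(sn))
  bk(prostreg:::ad_sum(prostreg:::ad_mul(out, out)))
  f_of <- function(z) {
    w <- exp(z - max(z)); w <- w / sum(w)
    sum(Reduce(`+`, Map(function(x, wi) x * wi, xs, w))^2)
  }
  expect_equal(sn$grad, fd_grad(f_of, s, 1:4), tolerance = 1e-6)
  A <- matrix(stats::rnorm(6), 2, 3); B <- matrix(stats::rnorm(12), 3, 4)
  An <- ad(A); Bn <- ad(B)
  bk(prostreg:::ad_sum(prostreg:::ad_mul(prostreg:::ad_matmul(An, Bn),
                                         prostreg:::ad_matmul(An, Bn))))
  f_of <- function(z) sum((z %*% B)^2)
  expect_equal(An$grad[1:3], fd_grad(f_of, A, 1:3), tolerance = 1e-6)
})
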