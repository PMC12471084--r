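# attention modules: MSFA, DCA, cross-modal gate, FuseConv

# identity convolution: center tap 1 on the matching channel
.id_conv <- function(C, k) {
  w <- array(0, c(C, C, k, k, k))
  c0 <- (k + 1) / 2
  for (ch in seq_len(C)) w[ch, ch, c0, c0, c0] <- 1
  w
}

test_that("MSFA softmax weights form a probability vector", {
  set.seed(1)
  p <- ecmca_params(4)
  F <- array(stats::rnorm(4 * 6 * 6 * 6), c(4, 6, 6, 6))
  out <- msfa(F, p, 1)
  w <- attr(out, "scale_weights")
  expect_length(w, 3)
  expect_true(all(w > 0))
  expect_equal(sum(w), 1, tolerance = 1e-6)
  expect_equal(dim(out), dim(F))
  expect_error(msfa(array(NaN, c(4, 2, 2, 2)), p, 1), "finite")
})

test_that("MSFA with identity convolutions reduces to the input", {
  set.seed(2)
  p <- ecmca_params(2)
  for (j in 1:3) {
    p$msfa[[1]][[j]]$w <- .id_conv(2, c(3, 5, 7)[j])
    p$msfa[[1]][[j]]$b <- numeric(2)
  }
  F <- array(stats::rnorm(2 * 4 * 4 * 4), c(2, 4, 4, 4))
  out <- msfa(F, p, 1)
  # conv kernels run in float32, so identity holds to single precision
  expect_equal(attr(out, "scale_weights"), rep(1 / 3, 3), tolerance = 1e-6)
  expect_equal(as.vector(out), as.vector(F), tolerance = 1e-6)
})

test_that("MSFA matches a hand computation on a tiny instance", {
  set.seed(11)
  p <- ecmca_params(2)
  F <- array(c(0.3, -0.2, 0.5, 0.1, -0.4, 0.2, 0.6, -0.1,
               0.2, 0.4, -0.3, 0.25, 0.15, -0.5, 0.35, 0.05), c(2, 2, 2, 2))
  Fk <- lapply(1:3, function(j) {
    k <- c(3, 5, 7)[j]
    w <- p$msfa[[1]][[j]]$w; b <- p$msfa[[1]][[j]]$b
    # direct dense convolution, same padding, computed independently
    out <- array(0, dim(F)); pd <- (k - 1) / 2
    for (d in 1:2) for (h in 1:2) for (wd in 1:2) for (o in 1:2) {
      acc <- b[o]
      for (kd in 1:k) for (kh in 1:k) for (kw in 1:k) {
        sd <- d + kd - 1 - pd; sh <- h + kh - 1 - pd; sw <- wd + kw - 1 - pd
        if (sd >= 1 && sd <= 2 && sh >= 1 && sh <= 2 && sw >= 1 && sw <= 2)
          acc <- acc + sum(w[o, , kd, kh, kw] * F[, sd, sh, sw])
      }
      out[o, d, h, wd] <- acc
    }
    out
  })
  sc <- vapply(Fk, function(x) mean(x) + max(x), 0)
  wts <- exp(sc - max(sc)); wts <- wts / sum(wts)
  expected <- wts[1] * Fk[[1]] + wts[2] * Fk[[2]] + wts[3] * Fk[[3]]
  out <- msfa(F, p, 1)
  expect_equal(as.vector(out), as.vector(expected), tolerance = 1e-5)
  expect_equal(attr(out, "scale_weights"), wts, tolerance = 1e-5)
})

test_that("DCA produces sigmoid channel weights and bounded output", {
  set.seed(3)
  p <- ecmca_params(2)
  F <- array(stats::rnorm(2 * 4 * 4 * 4), c(2, 4, 4, 4))
  out <- dca(F, p, 1)
  w <- attr(out, "channel_weights")
  expect_true(all(w > 0 & w < 1))
  expect_true(all(abs(out) <= abs(F) + 1e-12))
  # zero input with zero-bias conv -> weights exactly 0.5, output 0
  p$dca[[1]]$b <- 0
  z <- array(0, c(2, 4, 4, 4))
  outz <- dca(z, p, 1)
  expect_equal(attr(outz, "channel_weights"), c(0.5, 0.5))
  expect_true(all(outz == 0))
  # identity 1D conv (kernel 0,1,0): out_c = F_c * sigmoid(mean(F_c))
  p$dca[[1]]$w <- c(0, 1, 0); p$dca[[1]]$b <- 0
  outi <- dca(F, p, 1)
  for (ch in 1:2) {
    s <- 1 / (1 + exp(-mean(F[ch, , , ])))
    expect_equal(as.vector(outi[ch, , , ]), as.vector(F[ch, , , ] * s),
                 tolerance = 1e-12)
  }
})

test_that("cross-modal gate is a sigmoid spatial map", {
  set.seed(4)
  p <- ecmca_params(4)
  F1 <- array(stats::rnorm(4 * 3 * 3 * 3), c(4, 3, 3, 3))
  F2 <- array(stats::rnorm(4 * 3 * 3 * 3), c(4, 3, 3, 3))
  g <- cross_modal_gate(F1, F2, p)
  expect_true(all(g$att > 0 & g$att < 1))
  expect_equal(dim(g$att), c(1, 3, 3, 3))
  expect_true(all(abs(g$gated) <= abs(F2) + 1e-12))
  # all-zero weights -> att = 0.5 everywhere, gated = F2 / 2
  pz <- p
  pz$gate_a <- lapply(p$gate_a, function(x) x * 0)
  gz <- cross_modal_gate(F1, F2, pz)
  expect_true(all(gz$att == 0.5))
  expect_equal(gz$gated, F2 * 0.5, tolerance = 1e-12)
  expect_error(cross_modal_gate(F1[1:3, , , , drop = FALSE],
                                F2[1:3, , , , drop = FALSE], p), "even")
})

test_that("gate matches a hand-computed scalar case", {
  set.seed(12)
  p <- ecmca_params(2)
  p$gate_a$W1 <- matrix(c(0.5, -0.25), 2, 1)
  p$gate_a$W2 <- matrix(c(0.75, 0.1), 2, 1)
  p$gate_a$b12 <- 0.05
  p$gate_a$W3 <- matrix(2, 1, 1)
  p$gate_a$b3 <- -0.1
  F1 <- array(c(0.4, -0.6), c(2, 1, 1, 1))
  F2 <- array(c(0.2, 0.8), c(2, 1, 1, 1))
  h <- max(0, 0.5 * 0.4 - 0.25 * (-0.6) + 0.75 * 0.2 + 0.1 * 0.8 + 0.05)
  att <- 1 / (1 + exp(-(2 * h - 0.1)))
  g <- cross_modal_gate(F1, F2, p)
  expect_equal(as.numeric(g$att), att, tolerance = 1e-12)
  expect_equal(as.vector(g$gated), as.vector(F2) * att, tolerance = 1e-12)
})

test_that("ecmca_forward preserves shapes and trivial cases", {
  set.seed(5)
  p <- ecmca_params(4)
  F1 <- array(stats::rnorm(4 * 4 * 4 * 4), c(4, 4, 4, 4))
  F2 <- array(stats::rnorm(4 * 4 * 4 * 4), c(4, 4, 4, 4))
  out <- ecmca_forward(F1, F2, p)
  expect_equal(dim(out$f_mri), dim(F1))
  expect_equal(dim(out$f_trus), dim(F2))
  z <- array(0, dim(F1))
  outz <- ecmca_forward(z, z, p)
  expect_true(all(outz$f_mri == 0) && all(outz$f_trus == 0))
  # with MSFA and DCA disabled the TRUS stream equals the original gate
  pg <- ecmca_params(4, use_msfa = FALSE, use_dca = FALSE)
  pg$gate_a <- p$gate_a
  outg <- ecmca_forward(F1, F2, pg)
  ref <- cross_modal_gate(F1, F2, p$gate_a)
  expect_equal(outg$f_trus, ref$gated, tolerance = 1e-12)
  # f2_only mode passes the MRI stream through
  pf <- ecmca_params(4, gate_mode = "f2_only", use_msfa = FALSE, use_dca = FALSE)
  outf <- ecmca_forward(F1, F2, pf)
  expect_equal(outf$f_mri, F1, tolerance = 1e-12)
})

test_that("fuse_conv concatenates, projects and rectifies", {
  set.seed(6)
  C <- 2
  a <- abs(array(stats::rnorm(C * 8), c(C, 2, 2, 2)))
  b <- array(stats::rnorm(C * 8), c(C, 2, 2, 2))
  # identity projection selecting the first C channels of positive input
  p <- list(w = rbind(diag(C), matrix(0, C, C)), b = numeric(C))
  expect_equal(fuse_conv(a, b, p), a, tolerance = 1e-12)
  # negative pre-activation is scaled by 0.2
  pn <- list(w = rbind(-diag(C), matrix(0, C, C)), b = numeric(C))
  expect_equal(fuse_conv(a, b, pn), -0.2 * a, tolerance = 1e-12)
  # scalar toy: out = LeakyReLU(wa * a + wb * b + bias)
  ps <- list(w = matrix(c(0.3, -0.7), 2, 1), b = 0.1)
  a1 <- array(0.5, c(1, 1, 1, 1)); b1 <- array(0.9, c(1, 1, 1, 1))
  pre <- 0.3 * 0.5 - 0.7 * 0.9 + 0.1
  expect_equal(as.numeric(fuse_conv(a1, b1, ps)),
               ifelse(pre >= 0, pre, 0.2 * pre), tolerance = 1e-12)
})

test_that("ecmca_forward maps batches case-wise (permutation equivariance)", {
  set.seed(7)
  p <- ecmca_params(2)
  batch <- lapply(1:3, function(i)
    list(m = array(stats::rnorm(16), c(2, 2, 2, 2)),
         f = array(stats::rnorm(16), c(2, 2, 2, 2))))
  outs <- lapply(batch, function(x) ecmca_forward(x$m, x$f, p))
  perm <- c(2, 3, 1)
  outs_p <- lapply(batch[perm], function(x) ecmca_forward(x$m, x$f, p))
  expect_equal(outs[perm], outs_p)
})
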