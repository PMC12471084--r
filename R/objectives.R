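# Composite training objective: soft Dice on warped masks, Parzen-window
# mutual information inside the prostate ROI, and a gradient (smoothness)
# penalty on the deformation field.  Every loss has a plain-array form and an
# autodiff form; the public functions accept either and dispatch on class.

#' Loss weights of the composite objective
#'
#' @param alpha gradient-smoothness weight (default 0.4).
#' @param beta Dice weight (default 1.0).
#' @param gamma mutual-information weight (default 1.0).
#' @return object of class `loss_weights`.
#' @export
loss_weights <- function(alpha = 0.4, beta = 1.0, gamma = 1.0) {
  stopifnot(alpha >= 0, beta >= 0, gamma >= 0)
  structure(list(alpha = alpha, beta = beta, gamma = gamma),
            class = "loss_weights")
}

#' Soft Dice loss
#'
#' `1 - 2 * sum(pred * true) / (sum(pred) + sum(true) + eps)`.  Masks may be
#' real-valued in [0, 1] so that warped labels stay differentiable.
#'
#' @param pred,true arrays (or `ad_node`s) of equal shape with values in [0,1].
#' @param eps stabilizer (default 1e-6).
#' @return scalar loss in [0, 1] (an `ad_node` if an input is one).
#' @export
dice_loss <- function(pred, true, eps = 1e-6) {
  if (!is_ad(pred) && !is_ad(true)) {
    if (!all(dim(pred) == dim(true))) stop("mask shapes differ")
    return(1 - 2 * sum(pred * true) / (sum(pred) + sum(true) + eps))
  }
  pred <- as_ad(pred); true <- as_ad(true)
  pv <- pred$val; tv <- true$val
  if (!all(dim(pv) == dim(tv))) stop("mask shapes differ")
  s <- sum(pv * tv); den <- sum(pv) + sum(tv) + eps
  ad_node(1 - 2 * s / den, list(pred, true), function(g) {
    list(g * (-2 * tv * den + 2 * s) / den^2,
         g * (-2 * pv * den + 2 * s) / den^2)
  })
}

# Parzen joint-histogram machinery shared by value and gradient paths.
# Returns NULL for degenerate (constant) inputs.
.mi_core <- function(av, bv, bins) {
  n <- length(av)
  ra <- range(av); rb <- range(bv)
  if (diff(ra) < 1e-12 || diff(rb) < 1e-12) return(NULL)
  ca <- seq(ra[1], ra[2], length.out = bins); sa <- (ra[2] - ra[1]) / (bins - 1)
  cb <- seq(rb[1], rb[2], length.out = bins); sb <- (rb[2] - rb[1]) / (bins - 1)
  Wa <- exp(-0.5 * (outer(av, ca, `-`) / sa)^2); Wa <- Wa / rowSums(Wa)
  Wb <- exp(-0.5 * (outer(bv, cb, `-`) / sb)^2); Wb <- Wb / rowSums(Wb)
  pab <- crossprod(Wa, Wb) / n
  pa <- colSums(Wa) / n; pb <- colSums(Wb) / n
  lpab <- log(pmax(pab, 1e-12))
  mi_nats <- sum(pab * (lpab - log(pmax(outer(pa, pb), 1e-12))))
  list(Wa = Wa, Wb = Wb, pab = pab, pa = pa, pb = pb, ca = ca, cb = cb,
       sa = sa, sb = sb, lpab = lpab, n = n, mi_bits = mi_nats / log(2))
}

#' Mutual-information loss inside a region of interest
#'
#' Negative mutual information (in bits) of the intensities of `a` and `b`
#' inside `roi`, estimated with a differentiable Parzen-window joint histogram
#' (Gaussian kernels, `bins` bins spanning each image's observed range).
#' Lower loss means higher statistical dependency.
#'
#' @param a,b arrays (or `ad_node`s) of equal shape.
#' @param roi a [label_mask()] or logical/0-1 array; must be non-empty.
#' @param bins histogram bins (default 32).
#' @return scalar loss (an `ad_node` if an input is one).
#' @export
mi_loss <- function(a, b, roi, bins = 32L) {
  rv <- if (inherits(roi, "prostreg_mask")) roi$data else roi
  ridx <- which(as.logical(rv))
  if (length(ridx) == 0L) stop("empty ROI")
  plain <- !is_ad(a) && !is_ad(b)
  a <- as_ad(a); b <- as_ad(b)
  if (!all(dim(a$val) == dim(b$val))) stop("image shapes differ")
  av <- as.vector(a$val)[ridx]; bv <- as.vector(b$val)[ridx]
  mc <- .mi_core(av, bv, bins)
  if (is.null(mc)) {
    out <- ad_node(0, list(a, b), function(g) list(NULL, NULL))
    return(if (plain) 0 else out)
  }
  if (plain) return(-mc$mi_bits)
  ad_node(-mc$mi_bits, list(a, b), function(g) {
    mk <- function(dv, node) {
      gr <- array(0, dim(node$val) %||% length(node$val))
      gr[ridx] <- -g * dv
      gr
    }
    ga <- if (a$requires) mk(.mi_grad_vec(mc$Wa, mc$Wb, mc$lpab, mc$pa,
                                          av, mc$ca, mc$sa, mc$n), a)
    gb <- if (b$requires) mk(.mi_grad_vec(mc$Wb, mc$Wa, t(mc$lpab), mc$pb,
                                          bv, mc$cb, mc$sb, mc$n), b)
    list(ga, gb)
  })
}

# dMI_bits/dv where Wv are the Parzen weights of intensity vector v;
# Wo the other image's weights; lp = log joint (v-bins on rows)
.mi_grad_vec <- function(Wv, Wo, lp, pv, v, cv, sv, n) {
  dWv <- (Wo %*% t(lp) - matrix(log(pmax(pv, 1e-12)), n, length(pv),
                                byrow = TRUE)) / n
  z <- outer(-v, cv, `+`) / sv^2
  corr <- rowSums(Wv * z)
  rowSums(dWv * Wv * (z - corr)) / log(2)
}

#' Gradient-smoothness loss of a deformation field
#'
#' Mean squared forward-difference gradient,
#' `(1/|Omega|) * sum_p ||grad phi(p)||^2`, summed over the 3 components and
#' 3 directions; |Omega| is the number of voxels.
#'
#' @param phi deformation field (3, D, H, W), array or `ad_node`.
#' @return scalar loss (an `ad_node` if the input is one).
#' @export
grad_loss <- function(phi) {
  plain <- !is_ad(phi)
  phi <- as_ad(phi)
  pv <- phi$val
  dm <- dim(pv)
  if (length(dm) != 4L || dm[1] != 3L) stop("phi must be (3, D, H, W)")
  V <- prod(dm[2:4])
  diffs <- list()
  if (dm[2] > 1) diffs$d <- pv[, -1, , , drop = FALSE] - pv[, -dm[2], , , drop = FALSE]
  if (dm[3] > 1) diffs$h <- pv[, , -1, , drop = FALSE] - pv[, , -dm[3], , drop = FALSE]
  if (dm[4] > 1) diffs$w <- pv[, , , -1, drop = FALSE] - pv[, , , -dm[4], drop = FALSE]
  val <- sum(vapply(diffs, function(x) sum(x^2), 0)) / V
  if (plain) return(val)
  ad_node(val, list(phi), function(g) {
    gr <- array(0, dm)
    if (!is.null(diffs$d)) {
      gr[, -1, , ] <- gr[, -1, , ] + 2 * diffs$d / V
      gr[, -dm[2], , ] <- gr[, -dm[2], , ] - 2 * diffs$d / V
    }
    if (!is.null(diffs$h)) {
      gr[, , -1, ] <- gr[, , -1, ] + 2 * diffs$h / V
      gr[, , -dm[3], ] <- gr[, , -dm[3], ] - 2 * diffs$h / V
    }
    if (!is.null(diffs$w)) {
      gr[, , , -1] <- gr[, , , -1] + 2 * diffs$w / V
      gr[, , , -dm[4]] <- gr[, , , -dm[4]] - 2 * diffs$w / V
    }
    list(g * gr)
  })
}

#' Weighted total loss
#'
#' `alpha * grad + beta * dice + gamma * mi`.
#'
#' @param terms list with elements `grad`, `dice`, `mi` (scalars or nodes).
#' @param weights a [loss_weights()].
#' @return scalar (an `ad_node` if any term is one).
#' @export
total_loss <- function(terms, weights = loss_weights()) {
  stopifnot(inherits(weights, "loss_weights"))
  if (!any(vapply(terms, is_ad, FALSE))) {
    stopifnot(all(vapply(terms, is.finite, FALSE)))
    return(weights$alpha * terms$grad + weights$beta * terms$dice +
           weights$gamma * terms$mi)
  }
  ad_add(ad_add(ad_scale(as_ad(terms$grad), weights$alpha),
                ad_scale(as_ad(terms$dice), weights$beta)),
         ad_scale(as_ad(terms$mi), weights$gamma))
}
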