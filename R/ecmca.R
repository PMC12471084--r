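# Enhanced Cross-Modal Channel Attention (E-CMCA) and the FuseConv fusion
# layer.
#
# Per modality: Multi-Scale Feature Aggregation (parallel 3/5/7 convolutions
# blended by softmax-normalized global scores), then Dynamic Channel
# Attention (a squeeze-and-excitation-style gate driven by a small 1D
# convolution over the channel-pooled vector).  The two streams are then
# coupled by a cross-modal sigmoid gate built from voxel-wise channel
# projections.  All pieces work on plain arrays or autodiff nodes.

# per-channel spatial mean -> length-C vector (autodiff)
ad_gap_c <- function(x) {
  x <- as_ad(x)
  xv <- x$val; C <- dim(xv)[1L]; V <- prod(dim(xv)[-1L])
  ad_node(rowMeans(matrix(xv, nrow = C)), list(x), function(g) {
    gr <- array(rep(g / V, V), dim(xv))
    list(gr)
  })
}

# concatenate scalar nodes into one vector node
ad_cat_scalars <- function(xs) {
  xs <- lapply(xs, as_ad)
  ad_node(vapply(xs, function(x) as.numeric(x$val), 0), xs,
          function(g) as.list(g))
}

# voxel-wise channel projection: out = t(W) %*% F + b (a 1x1x1 convolution)
ad_projc <- function(x, w, b) {
  x <- as_ad(x); w <- as_ad(w); b <- as_ad(b)
  xv <- x$val; wv <- w$val; dm <- dim(xv)
  cin <- dm[1L]; cout <- ncol(wv)
  Xm <- matrix(xv, nrow = cin)
  v <- crossprod(wv, Xm) + as.vector(b$val)
  dim(v) <- c(cout, dm[2:4])
  ad_node(v, list(x, w, b), function(g) {
    Gm <- matrix(g, nrow = cout)
    gx <- wv %*% Gm; dim(gx) <- dm
    gw <- Xm %*% t(Gm)
    list(gx, gw, rowSums(Gm))
  })
}

.he_init <- function(dims, fan_in) array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)

#' Initialize E-CMCA parameters for channel width C
#'
#' @param C channel count (must be even).
#' @param gate_mode "symmetric" (each modality gates the other; two weight
#'   sets) or "f2_only" (only the second/TRUS stream is gated).
#' @param dca_kernel odd kernel size of the DCA 1D convolution (default 3).
#' @param use_msfa,use_dca include the multi-scale and channel-attention
#'   sub-modules (disabling both reduces E-CMCA to the original cross-modal
#'   gate).
#' @return parameter list of class `ecmca_params`.
#' @export
ecmca_params <- function(C, gate_mode = c("symmetric", "f2_only"),
                         dca_kernel = 3L, use_msfa = TRUE, use_dca = TRUE) {
  gate_mode <- match.arg(gate_mode)
  if (C %% 2L != 0L) stop("channel count C must be even")
  if (dca_kernel %% 2L != 1L) stop("dca_kernel must be odd")
  ks <- c(3L, 5L, 7L)
  msfa <- lapply(1:2, function(i) lapply(ks, function(k)
    list(w = .he_init(c(C, C, k, k, k), C * k^3), b = numeric(C))))
  dca <- lapply(1:2, function(i)
    list(w = stats::rnorm(dca_kernel, 0, 0.5), b = 0))
  gate_set <- function() list(
    W1 = .he_init(c(C, C / 2), C), W2 = .he_init(c(C, C / 2), C),
    b12 = numeric(C / 2), W3 = .he_init(c(C / 2, 1), C / 2), b3 = 0)
  structure(list(C = as.integer(C), gate_mode = gate_mode, kernels = ks,
                 use_msfa = use_msfa, use_dca = use_dca,
                 msfa = msfa, dca = dca,
                 gate_a = gate_set(),
                 gate_b = if (gate_mode == "symmetric") gate_set()),
            class = "ecmca_params")
}

.maybe_val <- function(node, plain) if (plain) node$val else node

#' Multi-Scale Feature Aggregation
#'
#' Parallel same-padding convolutions with kernels 3, 5, 7; each scale gets a
#' global scalar score GAP + GMP (pooled over all channels and voxels), the
#' scores are softmax-normalized across scales, and the output is the
#' weighted sum of the scale features.
#'
#' @param F feature array (C, D, H, W) or `ad_node`.
#' @param params an [ecmca_params()].
#' @param modality 1 (MRI stream) or 2 (TRUS stream).
#' @return array/node of the input shape.  Plain-array results carry the
#'   scale weights in `attr(, "scale_weights")`.
#' @export
msfa <- function(F, params, modality = 1L) {
  plain <- !is_ad(F)
  F <- as_ad(F)
  if (!all(is.finite(F$val))) stop("non-finite input")
  ws <- params$msfa[[modality]]
  Fk <- lapply(seq_along(params$kernels), function(j)
    ad_conv3d(F, ws[[j]]$w, ws[[j]]$b))
  scores <- ad_cat_scalars(lapply(Fk, function(x) ad_add(ad_mean(x), ad_max(x))))
  wts <- ad_softmax(scores)
  out <- ad_lincomb(Fk, wts)
  if (plain) return(structure(out$val, scale_weights = wts$val))
  out
}

#' Dynamic Channel Attention
#'
#' `w = sigmoid(Conv1D(GAP_spatial(F)))`; the feature map is rescaled
#' channel-wise by `w` (values in (0, 1)).
#'
#' @inheritParams msfa
#' @return array/node of the input shape; plain results carry
#'   `attr(, "channel_weights")`.
#' @export
dca <- function(F, params, modality = 1L) {
  plain <- !is_ad(F)
  F <- as_ad(F)
  p <- params$dca[[modality]]
  wvec <- ad_sigmoid(ad_conv1d(ad_gap_c(F), p$w, p$b))
  out <- ad_chan_scale(F, wvec)
  if (plain) return(structure(out$val, channel_weights = wvec$val))
  out
}

#' Cross-modal sigmoid gate
#'
#' `att = sigmoid(W3' relu(W1' F1 + W2' F2 + b12) + b3)`, a single-channel
#' spatial map in (0, 1) from voxel-wise channel projections; `gated` is
#' `att * F2` broadcast over channels.
#'
#' @param F1d,F2d feature arrays (C, D, H, W) or nodes (channel-enhanced
#'   modality-1 and modality-2 features).
#' @param params an [ecmca_params()] (uses its `gate_a` weight set) or a
#'   single gate weight-set list.
#' @return list with `att` (1, D, H, W) and `gated` (C, D, H, W).
#' @export
cross_modal_gate <- function(F1d, F2d, params) {
  plain <- !is_ad(F1d) && !is_ad(F2d)
  F1d <- as_ad(F1d); F2d <- as_ad(F2d)
  if (!all(dim(F1d$val) == dim(F2d$val))) stop("feature shapes differ")
  if (dim(F1d$val)[1L] %% 2L != 0L) stop("channel count must be even")
  gs <- if (inherits(params, "ecmca_params")) params$gate_a else params
  h <- ad_relu(ad_add(ad_projc(F1d, gs$W1, numeric(ncol(ad_val(gs$W1)))),
                      ad_projc(F2d, gs$W2, gs$b12)))
  att <- ad_sigmoid(ad_projc(h, gs$W3, gs$b3))
  gated <- ad_spatial_gate(F2d, att)
  if (plain) list(att = att$val, gated = gated$val)
  else list(att = att, gated = gated)
}

#' E-CMCA forward pass for a cross-modal feature pair
#'
#' Each modality runs through MSFA then DCA; the cross-modal gate is then
#' applied symmetrically (MRI-enhanced features gate TRUS and vice versa,
#' with independent weight sets) or, with `gate_mode = "f2_only"`, only to
#' the second stream as in the original formulation.
#'
#' @param f_mri,f_trus feature arrays (C, D, H, W) or nodes.
#' @param params an [ecmca_params()].
#' @return list with enhanced `f_mri` and `f_trus` of the input shapes.
#' @export
ecmca_forward <- function(f_mri, f_trus, params) {
  plain <- !is_ad(f_mri) && !is_ad(f_trus)
  f_mri <- as_ad(f_mri); f_trus <- as_ad(f_trus)
  if (!all(dim(f_mri$val) == dim(f_trus$val))) stop("feature shapes differ")
  e1 <- f_mri; e2 <- f_trus
  if (params$use_msfa) { e1 <- msfa(e1, params, 1L); e2 <- msfa(e2, params, 2L) }
  if (params$use_dca)  { e1 <- dca(e1, params, 1L);  e2 <- dca(e2, params, 2L) }
  out2 <- cross_modal_gate(e1, e2, params$gate_a)$gated
  out1 <- if (params$gate_mode == "symmetric")
    cross_modal_gate(e2, e1, params$gate_b)$gated else e1
  list(f_mri = .maybe_val(out1, plain), f_trus = .maybe_val(out2, plain))
}

#' Initialize FuseConv parameters
#'
#' @param c_in total input channels after concatenation (2C).
#' @param c_out output channels.
#' @return parameter list.
#' @export
fuse_params <- function(c_in, c_out) {
  list(w = .he_init(c(c_in, c_out), c_in), b = numeric(c_out))
}

#' FuseConv: concatenate two feature maps, 1x1x1 convolution, LeakyReLU(0.2)
#'
#' @param a,b feature arrays (C, D, H, W) or nodes.
#' @param params a [fuse_params()] with `w` of shape (2C, C_out).
#' @return fused array/node with `C_out` channels.
#' @export
fuse_conv <- function(a, b, params) {
  plain <- !is_ad(a) && !is_ad(b)
  a <- as_ad(a); b <- as_ad(b)
  if (!all(dim(a$val) == dim(b$val))) stop("feature shapes differ")
  out <- ad_leaky_relu(ad_projc(ad_concat_c(a, b), params$w, params$b), 0.2)
  .maybe_val(out, plain)
}
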