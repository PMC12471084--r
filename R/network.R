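# Dual-encoder registration U-Net.
#
# Two weight-independent encoders (four ConvBlocks, 2x pooling between
# levels) process the moving (MRI-like) and fixed (TRUS-like) volumes.
# E-CMCA couples the streams at each post-pooling level (the first attention
# level therefore sees C = enc_channels[2] features at half resolution, the
# deepest the bottleneck resolution); FuseConv merges the two streams into
# skip connections and the bottleneck.  The decoder upsamples trilinearly,
# concatenates skips, refines at full resolution and emits a 3-channel
# stationary velocity field from a near-zero-initialized flow head, which is
# integrated to a diffeomorphism by scaling and squaring.

#' Network configuration
#'
#' @param grid_side cubic working grid side; 32 for desk-scale testing, 128
#'   to match full-resolution clinical volumes.  Must be divisible by 8
#'   (three poolings).
#' @param enc_channels encoder ConvBlock channels (length 4).
#' @param dec_channels decoder channels (length 4; the last level refines at
#'   full resolution without upsampling).
#' @param remaining_channels full-resolution refinement ConvBlock channels.
#' @param vecint_steps scaling-and-squaring steps (default 7).
#' @param lstm_hidden,lstm_layers LSTM size for the pseudo-temporal
#'   refinement (defaults 128 and 2).
#' @param n_slices pseudo-temporal slices T (default 10).
#' @param gate_mode cross-modal gate mode, see [ecmca_params()].
#' @param use_ecmca disable to obtain the plain dual-encoder U-Net ablation.
#' @param use_msfa,use_dca sub-module switches (both off reduces E-CMCA to
#'   the original cross-modal gate).
#' @param lstm_residual additive residual connection around the LSTM
#'   (default TRUE); FALSE gives the literal replacement formulation.
#' @param lstm_proj_dim optional learned down-projection of flattened slices
#'   before the LSTM (NULL = off, the faithful full-size graph).
#' @param seed initialization seed.
#' @return object of class `net_config`.
#' @export
net_config <- function(grid_side = 32L, enc_channels = c(16L, 32L, 32L, 32L),
                       dec_channels = c(32L, 32L, 32L, 16L),
                       remaining_channels = c(32L, 16L, 16L),
                       vecint_steps = 7L, lstm_hidden = 128L, lstm_layers = 2L,
                       n_slices = 10L, gate_mode = "symmetric",
                       use_ecmca = TRUE, use_msfa = TRUE, use_dca = TRUE,
                       lstm_residual = TRUE, lstm_proj_dim = NULL, seed = 0L) {
  grid_side <- as.integer(grid_side)
  if (length(enc_channels) != 4L) stop("enc_channels must have length 4")
  if (grid_side %% 8L != 0L || grid_side < 16L)
    stop("grid_side must be a multiple of 8 and >= 16")
  if (n_slices > grid_side) stop("n_slices exceeds grid depth")
  structure(list(grid_side = grid_side,
                 enc_channels = as.integer(enc_channels),
                 dec_channels = as.integer(dec_channels),
                 remaining_channels = as.integer(remaining_channels),
                 vecint_steps = as.integer(vecint_steps),
                 lstm_hidden = as.integer(lstm_hidden),
                 lstm_layers = as.integer(lstm_layers),
                 n_slices = as.integer(n_slices),
                 gate_mode = gate_mode, use_ecmca = isTRUE(use_ecmca),
                 use_msfa = isTRUE(use_msfa), use_dca = isTRUE(use_dca),
                 lstm_residual = isTRUE(lstm_residual),
                 lstm_proj_dim = if (!is.null(lstm_proj_dim)) as.integer(lstm_proj_dim),
                 seed = as.integer(seed)),
            class = "net_config")
}

.conv_init <- function(cin, cout, k = 3L, sd = NULL) {
  if (is.null(sd)) sd <- sqrt(2 / (cin * k^3))
  list(w = array(stats::rnorm(cout * cin * k^3, 0, sd), c(cout, cin, k, k, k)),
       b = numeric(cout))
}

#' Initialize all model parameters
#'
#' @param cfg a [net_config()].
#' @return model list with `cfg` and structured `params` (all double-typed
#'   leaves are learnable).
#' @export
init_model <- function(cfg) {
  stopifnot(inherits(cfg, "net_config"))
  ec <- cfg$enc_channels; dc <- cfg$dec_channels; rc <- cfg$remaining_channels
  S <- cfg$grid_side; TT <- cfg$n_slices; hh <- cfg$lstm_hidden
  d_slice <- (S %/% TT)
  slice_len <- 3L * d_slice * S * S
  lstm_in <- if (is.null(cfg$lstm_proj_dim)) slice_len else cfg$lstm_proj_dim
  u <- 1 / sqrt(hh)
  lstm_layer <- function(insz) list(
    Wih = matrix(stats::runif(4 * hh * insz, -u, u), 4 * hh, insz),
    Whh = matrix(stats::runif(4 * hh * hh, -u, u), 4 * hh, hh),
    bih = numeric(4 * hh), bhh = numeric(4 * hh))
  params <- .local_seed(cfg$seed, {
    p <- list(
      enc = list(
        m = list(.conv_init(1L, ec[1]), .conv_init(ec[1], ec[2]),
                 .conv_init(ec[2], ec[3]), .conv_init(ec[3], ec[4])),
        f = list(.conv_init(1L, ec[1]), .conv_init(ec[1], ec[2]),
                 .conv_init(ec[2], ec[3]), .conv_init(ec[3], ec[4]))),
      fuse = list(l1 = fuse_params(2L * ec[1], ec[1]),
                  l2 = fuse_params(2L * ec[2], ec[2]),
                  l3 = fuse_params(2L * ec[3], ec[3]),
                  bn = fuse_params(2L * ec[4], dc[1])),
      dec = list(d1 = .conv_init(dc[1] + ec[3], dc[1]),
                 d2 = .conv_init(dc[2] + ec[2], dc[2]),
                 d3 = .conv_init(dc[3] + ec[1], dc[3]),
                 d4 = .conv_init(dc[3], dc[4])),
      rem = list(.conv_init(dc[4], rc[1]), .conv_init(rc[1], rc[2]),
                 .conv_init(rc[2], rc[3])),
      flow = .conv_init(rc[3], 3L, sd = 1e-5),
      lstm = c(
        if (!is.null(cfg$lstm_proj_dim))
          list(proj = list(w = matrix(stats::rnorm(cfg$lstm_proj_dim * slice_len,
                                                   0, 1 / sqrt(slice_len)),
                                      cfg$lstm_proj_dim, slice_len))),
        list(layers = c(list(lstm_layer(lstm_in)),
                        lapply(seq_len(cfg$lstm_layers - 1L),
                               function(i) lstm_layer(hh))),
             fc = list(w = matrix(stats::rnorm(slice_len * hh, 0, 1e-4),
                                  slice_len, hh),
                       b = numeric(slice_len)))),
      task = list(
        br1 = list(W1 = matrix(stats::rnorm(rc[3] * 256, 0, sqrt(2 / rc[3])), rc[3], 256),
                   b1 = numeric(256),
                   W2 = matrix(stats::rnorm(256 * TT, 0, sqrt(2 / 256)), 256, TT),
                   b2 = numeric(TT)),
        br2 = list(W1 = matrix(stats::rnorm(rc[3] * 256, 0, sqrt(2 / rc[3])), rc[3], 256),
                   b1 = numeric(256),
                   W2 = matrix(stats::rnorm(256 * TT, 0, sqrt(2 / 256)), 256, TT),
                   b2 = numeric(TT))))
    if (cfg$use_ecmca) {
      p$ecmca <- lapply(ec[2:4], function(C)
        ecmca_params(C, cfg$gate_mode, use_msfa = cfg$use_msfa,
                     use_dca = cfg$use_dca))
    }
    p
  })
  structure(list(cfg = cfg, params = params), class = "prostreg_model")
}

# ------------------------------------------------- parameter flattening ---

#' Flatten the double-typed leaves of a structured parameter list
#' @param x nested parameter list.
#' @param path name prefix.
#' @return named flat list of numeric arrays.
#' @export
param_flatten <- function(x, path = "") {
  if (is.double(x)) return(stats::setNames(list(x), path))
  if (is.list(x)) {
    nms <- names(x) %||% as.character(seq_along(x))
    out <- list()
    for (i in seq_along(x))
      out <- c(out, param_flatten(x[[i]], paste0(path, "/", nms[i])))
    return(out)
  }
  list()
}

#' Replace double leaves by `ad_param` nodes, registering them by path
#' @keywords internal
param_wrap <- function(x, registry, path = "") {
  if (is.double(x)) {
    nd <- ad_param(x)
    assign(path, nd, envir = registry)
    return(nd)
  }
  if (is.list(x)) {
    nms <- names(x) %||% as.character(seq_along(x))
    for (i in seq_along(x))
      x[[i]] <- param_wrap(x[[i]], registry, paste0(path, "/", nms[i]))
    return(x)
  }
  x
}

#' Write updated flat values back into the structured parameter list
#' @keywords internal
param_assign <- function(x, flat, path = "") {
  if (is.double(x)) return(flat[[path]])
  if (is.list(x)) {
    nms <- names(x) %||% as.character(seq_along(x))
    for (i in seq_along(x))
      x[[i]] <- param_assign(x[[i]], flat, paste0(path, "/", nms[i]))
    return(x)
  }
  x
}

# ----------------------------------------------------------- forward ---

.conv_block <- function(x, p) ad_leaky_relu(ad_conv3d(x, p$w, p$b), 0.2)

# encoder levels for one stream; returns list of 4 nodes (post-ConvBlock)
.enc_forward <- function(x, enc) {
  l1 <- .conv_block(x, enc[[1]])
  l2 <- .conv_block(ad_maxpool(l1), enc[[2]])
  l3 <- .conv_block(ad_maxpool(l2), enc[[3]])
  l4 <- .conv_block(ad_maxpool(l3), enc[[4]])
  list(l1, l2, l3, l4)
}

#' Run one encoder over a single-channel volume
#'
#' @param vol array (D, H, W) or (1, D, H, W) at the configured grid.
#' @param model a model from [init_model()].
#' @param stream "m" (moving/MRI) or "f" (fixed/TRUS).
#' @return list of 4 feature arrays, spatial side halving between levels.
#' @export
encoder_forward <- function(vol, model, stream = c("m", "f")) {
  stream <- match.arg(stream)
  if (length(dim(vol)) == 3L) dim(vol) <- c(1L, dim(vol))
  if (dim(vol)[2] %% 8L != 0L) stop("grid side must be divisible by 8")
  feats <- .enc_forward(ad_node(vol), model$params$enc[[stream]])
  lapply(feats, ad_val)
}

# full forward graph; wp = (possibly node-wrapped) params, cfg = net_config
.net_forward <- function(xm, xf, wp, cfg) {
  m1 <- .conv_block(xm, wp$enc$m[[1]])
  f1 <- .conv_block(xf, wp$enc$f[[1]])
  m2 <- .conv_block(ad_maxpool(m1), wp$enc$m[[2]])
  f2 <- .conv_block(ad_maxpool(f1), wp$enc$f[[2]])
  # cross-modal enhancement at each post-pooling level; enhanced features
  # feed both the fused skip connections and the next pooling stage
  enh <- function(a, b, lvl) {
    if (cfg$use_ecmca) ecmca_forward(a, b, wp$ecmca[[lvl]])
    else list(f_mri = a, f_trus = b)
  }
  lv2 <- enh(m2, f2, 1L)
  m3 <- .conv_block(ad_maxpool(lv2$f_mri), wp$enc$m[[3]])
  f3 <- .conv_block(ad_maxpool(lv2$f_trus), wp$enc$f[[3]])
  lv3 <- enh(m3, f3, 2L)
  m4 <- .conv_block(ad_maxpool(lv3$f_mri), wp$enc$m[[4]])
  f4 <- .conv_block(ad_maxpool(lv3$f_trus), wp$enc$f[[4]])
  lv4 <- enh(m4, f4, 3L)
  skip1 <- fuse_conv(m1, f1, wp$fuse$l1)
  skip2 <- fuse_conv(lv2$f_mri, lv2$f_trus, wp$fuse$l2)
  skip3 <- fuse_conv(lv3$f_mri, lv3$f_trus, wp$fuse$l3)
  bott <- fuse_conv(lv4$f_mri, lv4$f_trus, wp$fuse$bn)
  d <- .conv_block(ad_concat_c(ad_upsample2(bott), skip3), wp$dec$d1)
  d <- .conv_block(ad_concat_c(ad_upsample2(d), skip2), wp$dec$d2)
  d <- .conv_block(ad_concat_c(ad_upsample2(d), skip1), wp$dec$d3)
  d <- .conv_block(d, wp$dec$d4)
  r <- d
  for (p in wp$rem) r <- .conv_block(r, p)
  v <- ad_conv3d(r, wp$flow$w, wp$flow$b)
  list(velocity = v, feat = r)
}

#' Predict a stationary velocity field for a volume pair
#'
#' @param moving,fixed single-channel arrays (D, H, W) on the same grid.
#' @param model a model from [init_model()].
#' @return velocity field array (3, D, H, W).
#' @export
forward_flow <- function(moving, fixed, model) {
  if (!all(dim(moving) == dim(fixed))) stop("moving and fixed grids differ")
  dm <- dim(moving)
  dim(moving) <- c(1L, dm); dim(fixed) <- c(1L, dm)
  out <- .net_forward(ad_node(moving), ad_node(fixed), model$params, model$cfg)
  ad_val(out$velocity)
}

#' Register a moving volume onto a fixed volume
#'
#' Runs the network, integrates the velocity field (7 scaling-and-squaring
#' steps by default), optionally refines the field with the pseudo-temporal
#' LSTM, and warps the moving image (trilinear) and its mask (nearest).
#'
#' @param moving,fixed [volume()]s on the same grid.
#' @param moving_mask optional [label_mask()]; absence only disables label
#'   warping.
#' @param model a model from [init_model()].
#' @param use_lstm apply the LSTM refinement stage (default TRUE).
#' @param fixed_mask optional [label_mask()] used for diagnostic loss terms.
#' @return object of class `registration_result` with fields `warped_image`,
#'   `warped_label`, `field`, `velocity`, `diagnostics`.
#' @export
register <- function(moving, fixed, moving_mask = NULL, model,
                     use_lstm = TRUE, fixed_mask = NULL) {
  stopifnot(inherits(moving, "prostreg_volume"), inherits(fixed, "prostreg_volume"))
  if (!all(dim(moving$data) == dim(fixed$data)))
    stop("moving and fixed grids differ")
  mv <- moving$data; fx <- fixed$data
  mroi <- if (!is.null(moving_mask)) mv * moving_mask$data else mv
  froi <- if (!is.null(fixed_mask)) fx * fixed_mask$data else fx
  vel <- forward_flow(mroi, froi, model)
  phi <- vecint(vel, model$cfg$vecint_steps)
  if (use_lstm)
    phi <- lstm_refine(slice_flow(phi, model$cfg$n_slices), model$params$lstm,
                       residual = model$cfg$lstm_residual,
                       proj = !is.null(model$cfg$lstm_proj_dim))
  warped <- warp(mv, phi)
  wlab <- NULL
  if (!is.null(moving_mask))
    wlab <- label_mask(warp(moving_mask$data, phi, mode = "nearest"),
                       moving$spacing_mm)
  js <- jacobian_stats(phi)
  diag <- list(folding_fraction = js$folding_fraction)
  if (!is.null(moving_mask) && !is.null(fixed_mask)) {
    roi <- (fixed_mask$data + wlab$data) > 0
    diag$loss_terms <- list(
      dice = dice_loss(wlab$data, fixed_mask$data),
      mi = if (any(roi)) mi_loss(warped, fx, roi) else NA_real_,
      grad = grad_loss(phi))
  }
  structure(list(warped_image = volume(warped, moving$spacing_mm, moving$modality),
                 warped_label = wlab, field = phi, velocity = vel,
                 diagnostics = diag),
            class = "registration_result")
}
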