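# End-to-end training: dataset splitting, the Adam loop over the composite
# (optionally task-mask-weighted, per-slice) objective, history logging and
# checkpointing.  Batch size defaults to 1 (3D volumes are large); all
# randomness flows from the configured seeds.

#' Training configuration
#'
#' @param lr Adam learning rate (default 0.001).
#' @param epochs training epochs (default 10 at desk scale; the clinical
#'   protocol uses 100).
#' @param batch_size gradient-accumulation batch (default 1).
#' @param split train/validation/test fractions (must sum to 1).
#' @param weights a [loss_weights()].
#' @param use_lstm include the pseudo-temporal LSTM refinement stage.
#' @param use_task_mask weight the per-slice registration and smoothness
#'   losses with the task-mask subnet.
#' @param seed root seed for shuffling.
#' @param device label only; computation is CPU.
#' @return object of class `train_config`.
#' @export
train_config <- function(lr = 0.001, epochs = 10L, batch_size = 1L,
                         split = c(0.70, 0.15, 0.15), weights = loss_weights(),
                         use_lstm = TRUE, use_task_mask = TRUE, seed = 0L,
                         device = "cpu") {
  stopifnot(lr > 0, epochs >= 1, batch_size >= 1,
            abs(sum(split) - 1) < 1e-8, inherits(weights, "loss_weights"))
  structure(list(lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), split = split,
                 weights = weights, use_lstm = isTRUE(use_lstm),
                 use_task_mask = isTRUE(use_task_mask),
                 seed = as.integer(seed), device = device),
            class = "train_config")
}

#' Deterministic shuffled train/validation/test partition
#'
#' Validation and test sizes are floors of their fractions; the remainder
#' goes to training.  The three lists are pairwise disjoint and cover the
#' input.
#'
#' @param case_ids vector of identifiers (>= 3).
#' @param split fractions summing to 1.
#' @param seed shuffle seed.
#' @return list with `train`, `val`, `test`.
#' @export
split_cases <- function(case_ids, split = c(0.70, 0.15, 0.15), seed = 0L) {
  n <- length(case_ids)
  if (n < 3L) stop("need at least 3 cases to partition")
  stopifnot(abs(sum(split) - 1) < 1e-8)
  perm <- .local_seed(seed, sample.int(n))
  n_val <- floor(split[2] * n); n_test <- floor(split[3] * n)
  n_train <- n - n_val - n_test
  ids <- case_ids[perm]
  list(train = ids[seq_len(n_train)],
       val = ids[n_train + seq_len(n_val)],
       test = ids[n_train + n_val + seq_len(n_test)])
}

# plain-value view of a (possibly node-wrapped) parameter subtree
wp_plain_task <- function(wp) {
  unwrap <- function(x) {
    if (is_ad(x)) return(x$val)
    if (is.list(x)) return(lapply(x, unwrap))
    x
  }
  unwrap(wp$task)
}

# ad-native version of slice_flow for graph building
.slice_flow_ad <- function(phi, T) {
  dm <- dim(phi$val)
  D <- dm[2L]; d <- D %/% T
  slices <- lapply(seq_len(T), function(t)
    ad_slice_depth(phi, (t - 1L) * d + 1L, t * d))
  residual <- if (D > T * d) ad_slice_depth(phi, T * d + 1L, D)
              else ad_node(array(0, c(dm[1], 0, dm[3], dm[4])))
  structure(list(slices = slices, residual = residual, T = T, d = d, dim = dm),
            class = "slice_sequence")
}

# Build the full loss graph for one case.  Returns list(loss = node,
# log = plain loss terms for the history).
.case_loss <- function(case, wp, mcfg, tcfg) {
  dmv <- dim(case$moving$data)
  as4 <- function(x) { dim(x) <- c(1L, dmv); x }
  mmask <- as4(case$moving_mask$data)
  fmask <- as4(case$fixed_mask$data)
  xm <- ad_node(as4(case$moving$data * case$moving_mask$data))
  xf <- ad_node(as4(case$fixed$data * case$fixed_mask$data))
  img_m <- ad_node(as4(case$moving$data))
  img_f <- as4(case$fixed$data)
  net <- .net_forward(xm, xf, wp, mcfg)
  phi <- vecint_ad(net$velocity, mcfg$vecint_steps)
  if (tcfg$use_lstm)
    phi <- lstm_refine(.slice_flow_ad(phi, mcfg$n_slices), wp$lstm,
                       residual = mcfg$lstm_residual,
                       proj = !is.null(mcfg$lstm_proj_dim))
  wmask <- ad_warp(ad_node(mmask), phi)
  wimg <- ad_warp(img_m, phi)
  roi <- (fmask + (wmask$val > 0.5)) > 0
  w <- tcfg$weights
  dice_full <- dice_loss(wmask, fmask)
  mi_full <- mi_loss(wimg, ad_node(img_f), roi)
  grad_full <- grad_loss(phi)
  log <- list(dice = ad_val(dice_full), mi = ad_val(mi_full),
              grad = ad_val(grad_full))
  log$total <- w$alpha * log$grad + w$beta * log$dice + w$gamma * log$mi
  if (!tcfg$use_task_mask) {
    loss <- total_loss(list(grad = grad_full, dice = dice_full, mi = mi_full), w)
    return(list(loss = loss, log = log))
  }
  # Per-slice two-task losses weighted by the task mask.  The mask is
  # detached (stop-gradient): letting the loss gradient flow into the subnet
  # lets it trivially collapse all weight onto the near-zero smoothness task
  # at the identity initialization, silencing the registration signal.
  M <- task_mask(ad_val(net$feat), wp_plain_task(wp))
  TT <- mcfg$n_slices
  d <- dim(phi$val)[2L] %/% TT
  l_reg <- vector("list", TT); l_smooth <- vector("list", TT)
  D <- dim(phi$val)[2L]
  for (t in seq_len(TT)) {
    d0 <- (t - 1L) * d + 1L; d1 <- t * d
    wm_t <- ad_slice_depth(wmask, d0, d1)
    fm_t <- fmask[, d0:d1, , , drop = FALSE]
    dice_t <- if (sum(fm_t) + sum(ad_val(wm_t)) > 1e-6)
      dice_loss(wm_t, ad_node(fm_t)) else ad_node(0)
    roi_t <- roi[, d0:d1, , , drop = FALSE]
    mi_t <- if (sum(roi_t) >= 8)
      mi_loss(ad_slice_depth(wimg, d0, d1),
              ad_node(img_f[, d0:d1, , , drop = FALSE]), roi_t)
    else ad_node(0)
    l_reg[[t]] <- ad_add(ad_scale(dice_t, w$beta), ad_scale(mi_t, w$gamma))
    # slab extended one plane so the penalty also covers inter-slab jumps
    l_smooth[[t]] <- ad_scale(grad_loss(ad_slice_depth(phi, d0, min(d1 + 1L, D))),
                              w$alpha)
  }
  loss <- masked_loss(M, l_reg, l_smooth)
  list(loss = loss, log = log)
}

#' Train the registration network
#'
#' Runs Adam over the composite objective (per-slice task-mask-weighted when
#' `cfg$use_task_mask`); logs per-epoch training and validation losses and
#' keeps the parameters of the best validation epoch (training loss when no
#' validation cases are given).
#'
#' @param dataset list of `phantom_case`-like objects (fields `moving`,
#'   `fixed`, `moving_mask`, `fixed_mask`).
#' @param model a model from [init_model()]; its `net_config` decides grid
#'   size and ablation switches.
#' @param cfg a [train_config()].
#' @param val_dataset optional validation cases.
#' @param verbose print per-epoch losses.
#' @return list with `model` (best parameters), `history` (data.frame with
#'   one row per epoch), `final_model` (last-epoch parameters).
#' @export
train_model <- function(dataset, model, cfg = train_config(),
                        val_dataset = list(), verbose = FALSE) {
  stopifnot(length(dataset) >= 1L, inherits(model, "prostreg_model"),
            inherits(cfg, "train_config"))
  mcfg <- model$cfg
  # private copy first: updates below are in place and must not leak into
  # the caller's model object
  model$params <- param_assign(model$params,
                               lapply(param_flatten(model$params),
                                      function(x) x + 0))
  # flat *views* of the structured parameters (same arrays, not copies);
  # Adam updates them in place through C++, so no flatten/relist roundtrip
  flat <- param_flatten(model$params)
  nms <- names(flat)
  adam_m <- lapply(flat, function(x) x * 0)
  adam_v <- lapply(flat, function(x) x * 0)
  adam_t <- 0L
  hist <- data.frame()
  best <- list(loss = Inf, params = model$params)
  deep_copy <- function() param_assign(model$params,
                                       lapply(flat, function(x) x + 0))
  nb <- cfg$batch_size
  for (ep in seq_len(cfg$epochs)) {
    ord <- .local_seed(cfg$seed + 7919L * ep, sample.int(length(dataset)))
    ep_losses <- c(); ep_terms <- c()
    i <- 1L
    while (i <= length(ord)) {
      batch <- ord[i:min(i + nb - 1L, length(ord))]
      i <- i + nb
      grads <- list()
      for (ci in batch) {
        registry <- new.env(parent = emptyenv())
        wp <- param_wrap(model$params, registry)
        cl <- .case_loss(dataset[[ci]], wp, mcfg, cfg)
        lv <- as.numeric(ad_val(cl$loss))
        if (!is.finite(lv))
          stop("training diverged: non-finite loss at epoch ", ep,
               " (case ", ci, ")")
        ad_backward(cl$loss)
        for (nm in nms) {
          nd <- get0(nm, envir = registry)
          if (!is.null(nd) && !is.null(nd$grad))
            grads[[nm]] <- if (is.null(grads[[nm]])) nd$grad / length(batch)
                           else grads[[nm]] + nd$grad / length(batch)
        }
        ep_losses <- c(ep_losses, lv)
        ep_terms <- c(ep_terms, cl$log$total)
      }
      adam_t <- adam_t + 1L
      for (nm in names(grads))
        cpp_adam_step(flat[[nm]], grads[[nm]], adam_m[[nm]], adam_v[[nm]],
                      adam_t, cfg$lr, 0.9, 0.999, 1e-8)
    }
    gc(FALSE)  # compact between epochs; per-iteration graphs churn ~0.5 GB
    val_loss <- NA_real_
    if (length(val_dataset)) {
      vl <- vapply(val_dataset, function(cs)
        as.numeric(ad_val(.case_loss(cs, model$params, mcfg, cfg)$loss)), 0)
      val_loss <- mean(vl)
    }
    sel_loss <- if (is.na(val_loss)) mean(ep_losses) else val_loss
    if (sel_loss < best$loss) best <- list(loss = sel_loss, params = deep_copy())
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = mean(ep_losses),
                                   train_total = mean(ep_terms),
                                   val_loss = val_loss))
    if (verbose)
      message(sprintf("epoch %d  train %.4f  val %s", ep, mean(ep_losses),
                      ifelse(is.na(val_loss), "-", sprintf("%.4f", val_loss))))
  }
  final <- model
  final$params <- deep_copy()
  model$params <- best$params
  list(model = model, history = hist, final_model = final)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is an opaque, versioned serialized list holding the
#' network configuration and all parameters.
#'
#' @param model a `prostreg_model`.
#' @param path file path.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "prostreg_model"))
  saveRDS(list(format = "prostreg-ckpt-1", cfg = model$cfg,
               params = model$params), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "prostreg-ckpt-1")) stop("unrecognized checkpoint: ", path)
  structure(list(cfg = x$cfg, params = x$params), class = "prostreg_model")
}
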