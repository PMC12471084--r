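# Pseudo-temporal deformation refinement.
#
# The static 3D deformation field is sliced along depth into T slabs, each
# flattened and fed as one time step to a 2-layer LSTM; hidden states are
# mapped back to slab shape by a fully connected layer and the slabs are
# reassembled, with leftover depth planes passed through from the static
# field.  A residual connection (default on) makes an untrained LSTM an
# identity refinement.  The task-mask subnet emits per-slice softmax weights
# that trade off the registration loss against the smoothness loss during
# dynamic training.

#' Slice a deformation field along depth into pseudo-temporal steps
#'
#' The first `T * floor(D/T)` depth planes split evenly into T slabs; any
#' leftover planes are kept in `residual`.  Concatenating slabs and residual
#' restores the field bit-exactly.
#'
#' @param phi deformation field (3, D, H, W).
#' @param T number of pseudo-temporal slices (default 10; requires D >= T).
#' @return object of class `slice_sequence`: `slices` (list of (3, d, H, W)
#'   arrays with d = floor(D/T)), `residual` ((3, r, H, W), r possibly 0),
#'   and bookkeeping fields.
#' @export
slice_flow <- function(phi, T = 10L) {
  .check_field(phi)
  T <- as.integer(T)
  D <- dim(phi)[2L]
  if (D < T) stop("depth ", D, " smaller than T = ", T)
  d <- D %/% T
  slices <- lapply(seq_len(T), function(t)
    phi[, ((t - 1L) * d + 1L):(t * d), , , drop = FALSE])
  residual <- phi[, seq_len(D - T * d) + T * d, , , drop = FALSE]
  structure(list(slices = slices, residual = residual, T = T, d = d,
                 dim = dim(phi)),
            class = "slice_sequence")
}

#' Reassemble a slice sequence into a field (inverse of [slice_flow()])
#' @param seq a `slice_sequence`.
#' @return deformation field (3, D, H, W).
#' @export
concat_slices <- function(seq) {
  stopifnot(inherits(seq, "slice_sequence"))
  out <- array(0, seq$dim)
  d <- seq$d
  for (t in seq_len(seq$T))
    out[, ((t - 1L) * d + 1L):(t * d), , ] <- seq$slices[[t]]
  if (dim(seq$residual)[2L] > 0L)
    out[, seq$T * d + seq_len(dim(seq$residual)[2L]), , ] <- seq$residual
  out
}

# slice rows of a column-vector/matrix node
ad_rows <- function(x, r0, r1) {
  x <- as_ad(x)
  nr <- nrow(x$val)
  ad_node(x$val[r0:r1, , drop = FALSE], list(x), function(g) {
    gr <- matrix(0, nr, ncol(x$val))
    gr[r0:r1, ] <- g
    list(gr)
  })
}

# one LSTM step; zin is the precomputed input contribution (Wih x + biases),
# h and c the previous states as column vectors
.lstm_cell <- function(zin, h, c, p, hh) {
  z <- ad_add(zin, ad_matmul(p$Whh, h))
  i <- ad_sigmoid(ad_rows(z, 1L, hh))
  f <- ad_sigmoid(ad_rows(z, hh + 1L, 2L * hh))
  g <- ad_tanh(ad_rows(z, 2L * hh + 1L, 3L * hh))
  o <- ad_sigmoid(ad_rows(z, 3L * hh + 1L, 4L * hh))
  cn <- ad_add(ad_mul(f, c), ad_mul(i, g))
  hn <- ad_mul(o, ad_tanh(cn))
  list(h = hn, c = cn)
}

#' LSTM refinement of a sliced deformation field
#'
#' Each slab is flattened, processed as one time step by a unidirectional
#' 2-layer LSTM, mapped back to slab shape by a fully connected layer and
#' reassembled; residual depth planes pass through from the static field.
#' With `residual = TRUE` (default) the LSTM output is added to the static
#' slabs, so zero LSTM output reproduces the input field exactly; with
#' `residual = FALSE` the output replaces them.
#'
#' @param seq a `slice_sequence` from [slice_flow()] (slices may be arrays
#'   or `ad_node`s).
#' @param params LSTM parameter list (`model$params$lstm`).
#' @param residual additive residual connection (default TRUE).
#' @param proj use the optional learned down-projection (requires `proj` in
#'   `params`).
#' @return refined deformation field (3, D, H, W) array, or an `ad_node` if
#'   the input slices are nodes.
#' @export
lstm_refine <- function(seq, params, residual = TRUE, proj = FALSE) {
  stopifnot(inherits(seq, "slice_sequence"))
  plain <- !any(vapply(seq$slices, is_ad, FALSE))
  hh <- ncol(ad_val(params$layers[[1]]$Whh))
  nlayers <- length(params$layers)
  slice_len <- prod(seq$dim[c(1, 3, 4)]) * seq$d
  # the large input and output projections run once over all T steps; only
  # the small recurrent matmuls stay sequential
  X <- ad_cbind(lapply(seq$slices, function(s)
    ad_reshape(as_ad(s), c(slice_len, 1L))))
  if (proj) X <- ad_matmul(params$proj$w, X)
  zin_base <- vector("list", nlayers)
  p1 <- params$layers[[1]]
  zin_base[[1]] <- ad_add_colvec(ad_matmul(p1$Wih, X),
                                 ad_add(as_ad(p1$bih), as_ad(p1$bhh)))
  h <- rep(list(ad_node(matrix(0, hh, 1))), nlayers)
  cc <- rep(list(ad_node(matrix(0, hh, 1))), nlayers)
  hs_top <- vector("list", seq$T)
  for (t in seq_len(seq$T)) {
    for (l in seq_len(nlayers)) {
      pl <- params$layers[[l]]
      zin <- if (l == 1L) ad_col(zin_base[[1]], t)
             else ad_add(ad_matmul(pl$Wih, h[[l - 1L]]),
                         ad_reshape(ad_add(as_ad(pl$bih), as_ad(pl$bhh)),
                                    c(4L * hh, 1L)))
      st <- .lstm_cell(zin, h[[l]], cc[[l]], pl, hh)
      h[[l]] <- st$h; cc[[l]] <- st$c
    }
    hs_top[[t]] <- h[[nlayers]]
  }
  Y <- ad_add_colvec(ad_matmul(params$fc$w, ad_cbind(hs_top)), params$fc$b)
  refined <- vector("list", seq$T)
  for (t in seq_len(seq$T)) {
    y <- ad_reshape(ad_col(Y, t), c(seq$dim[1], seq$d, seq$dim[3], seq$dim[4]))
    refined[[t]] <- if (residual) ad_add(as_ad(seq$slices[[t]]), y) else y
  }
  parts <- refined
  if (dim(ad_val(seq$residual))[2L] > 0L)
    parts <- c(parts, list(as_ad(seq$residual)))
  out <- ad_concat_depth(parts)
  if (plain) ad_val(out) else out
}

#' Task-mask subnet: per-slice two-task softmax weights
#'
#' Global average pooling of the decoder features feeds two parallel
#' branches of two fully connected layers (hidden width 256) producing
#' per-slice scores for the registration and smoothing tasks; the mask is
#' their per-slice softmax, so every row sums to 1.
#'
#' @param features decoder feature array (C, D, H, W), an `ad_node`, or a
#'   list of such (batch).
#' @param params task-subnet parameters (`model$params$task`).
#' @return array (N, T, 2) for plain input; for node input a list with
#'   vector nodes `m1`, `m2` (the two columns).
#' @export
task_mask <- function(features, params) {
  if (is.list(features) && !is_ad(features)) {
    ms <- lapply(features, task_mask, params = params)
    return(array(unlist(lapply(ms, as.vector)),
                 c(dim(ms[[1]])[2], 2, length(ms))) |> aperm(c(3, 1, 2)))
  }
  plain <- !is_ad(features)
  x <- ad_gap_c(as_ad(features))
  xcol <- ad_reshape(x, c(length(ad_val(x)), 1L))
  score <- function(p) {
    hdn <- ad_relu(ad_add(ad_matmul(ad_t(p$W1), xcol),
                          ad_reshape(as_ad(p$b1), c(length(ad_val(p$b1)), 1L))))
    ad_add(ad_matmul(ad_t(p$W2), hdn),
           ad_reshape(as_ad(p$b2), c(length(ad_val(p$b2)), 1L)))
  }
  w1 <- score(params$br1)
  w2 <- score(params$br2)
  m1 <- ad_sigmoid(ad_sub(w1, w2))     # softmax over two entries
  m2 <- ad_sub(ad_node(1), m1)
  if (plain) {
    TT <- length(ad_val(m1))
    m <- array(0, c(1L, TT, 2L))
    m[1, , 1] <- ad_val(m1); m[1, , 2] <- ad_val(m2)
    return(m)
  }
  list(m1 = m1, m2 = m2)
}

# matrix transpose node
ad_t <- function(x) {
  x <- as_ad(x)
  ad_node(t(x$val), list(x), function(g) list(t(g)))
}

#' Task-mask-weighted two-task loss
#'
#' Mean over cases and slices of
#' `M[n,t,1] * L_reg[t] + M[n,t,2] * L_smooth[t]`.
#'
#' @param M task mask: array (N, T, 2) or the node list from [task_mask()].
#' @param l_reg,l_smooth per-slice losses, length-T vectors (or lists of
#'   scalar nodes).
#' @return scalar loss (node if inputs are nodes).
#' @export
masked_loss <- function(M, l_reg, l_smooth) {
  node_mode <- is.list(M) && !is.null(M$m1)
  if (!node_mode) {
    if (dim(M)[2] != length(l_reg) || length(l_reg) != length(l_smooth))
      stop("per-slice loss lengths do not match the mask")
    if (is.list(l_reg)) {
      # constant (detached) mask weighting scalar-node losses
      TT <- dim(M)[2]
      acc <- ad_node(0)
      for (t in seq_len(TT))
        acc <- ad_add(acc, ad_add(ad_scale(as_ad(l_reg[[t]]), mean(M[, t, 1])),
                                  ad_scale(as_ad(l_smooth[[t]]), mean(M[, t, 2]))))
      return(ad_scale(acc, 1 / TT))
    }
    acc <- 0
    for (n in seq_len(dim(M)[1]))
      acc <- acc + sum(M[n, , 1] * l_reg + M[n, , 2] * l_smooth)
    return(acc / (dim(M)[1] * dim(M)[2]))
  }
  TT <- length(ad_val(M$m1))
  if (length(l_reg) != TT || length(l_smooth) != TT)
    stop("per-slice loss lengths do not match the mask")
  lr <- if (is.list(l_reg)) ad_cat_scalars(l_reg) else as_ad(as.numeric(l_reg))
  ls <- if (is.list(l_smooth)) ad_cat_scalars(l_smooth) else as_ad(as.numeric(l_smooth))
  tot <- ad_add(ad_sum(ad_mul(ad_reshape(M$m1, TT), lr)),
                ad_sum(ad_mul(ad_reshape(M$m2, TT), ls)))
  ad_scale(tot, 1 / TT)
}
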