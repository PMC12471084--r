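# Minimal reverse-mode automatic differentiation on dense arrays.
#
# Every differentiable quantity is an `ad_node`: an environment holding the
# value, its parents, and a backward closure that maps the incoming gradient
# to one gradient per parent.  Graphs are rebuilt per training iteration;
# `ad_backward()` topologically sorts the graph and accumulates gradients.
# Heavy ops (3D convolution, pooling, resampling, warping) delegate to the
# compiled kernels in src/.

.ad_env <- new.env(parent = emptyenv())
.ad_env$counter <- 0L

#' Create an autodiff node
#'
#' @param val numeric array or scalar value of the node.
#' @param parents list of parent `ad_node`s this node depends on.
#' @param backfn function taking the incoming gradient and returning a list
#'   of gradients, one per parent (NULL entries allowed).
#' @param requires force gradient tracking (used for leaf parameters).
#' @return an object of class `ad_node`.
#' @keywords internal
ad_node <- function(val, parents = list(), backfn = NULL, requires = FALSE) {
  e <- new.env(parent = emptyenv())
  e$val <- val
  e$parents <- parents
  e$backfn <- backfn
  e$requires <- requires ||
    (length(parents) > 0L && any(vapply(parents, function(p) p$requires, FALSE)))
  e$grad <- NULL
  .ad_env$counter <- .ad_env$counter + 1L
  e$id <- .ad_env$counter
  class(e) <- "ad_node"
  e
}

is_ad <- function(x) inherits(x, "ad_node")

as_ad <- function(x) if (is_ad(x)) x else ad_node(x)

#' Leaf parameter node (tracked for gradients)
#' @param val numeric array.
#' @keywords internal
ad_param <- function(val) ad_node(val, requires = TRUE)

ad_val <- function(x) if (is_ad(x)) x$val else x

#' Run backpropagation from a scalar root node
#'
#' Accumulates gradients into `$grad` of every node with `requires = TRUE`.
#' @param root scalar `ad_node`.
#' @keywords internal
ad_backward <- function(root) {
  stopifnot(is_ad(root), length(root$val) == 1L)
  # iterative DFS topological sort over gradient-requiring nodes
  topo <- vector("list", 256L)
  nt <- 0L
  state <- new.env(parent = emptyenv())
  stack <- list(root)
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    key <- as.character(nd$id)
    st <- state[[key]]
    if (is.null(st)) {
      state[[key]] <- 1L
      for (p in nd$parents) {
        if (p$requires && is.null(state[[as.character(p$id)]])) {
          stack[[length(stack) + 1L]] <- p
        }
      }
      if (identical(stack[[length(stack)]], nd) && length(nd$parents) == 0L) {
        # leaf: fall through to emit below
      }
      if (!identical(stack[[length(stack)]], nd)) next
    }
    # all children processed: emit
    stack[[length(stack)]] <- NULL
    if (identical(state[[key]], 1L)) {
      nt <- nt + 1L
      if (nt > length(topo)) topo <- c(topo, vector("list", length(topo)))
      topo[[nt]] <- nd
      state[[key]] <- 2L
    }
  }
  root$grad <- 1
  for (i in seq(nt, 1L)) {
    nd <- topo[[i]]
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    gs <- nd$backfn(nd$grad)
    for (j in seq_along(nd$parents)) {
      p <- nd$parents[[j]]
      if (!p$requires || is.null(gs[[j]])) next
      p$grad <- if (is.null(p$grad)) gs[[j]] else p$grad + gs[[j]]
    }
    if (!identical(nd, root)) nd$grad <- NULL  # only leaves keep grads
  }
  invisible(root)
}

# ---------------------------------------------------------------- basics ---

ad_add <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ad_node(a$val + b$val, list(a, b), function(g) {
    gb <- if (length(b$val) == 1L && length(a$val) > 1L) sum(g) else g
    ga <- if (length(a$val) == 1L && length(b$val) > 1L) sum(g) else g
    list(ga, gb)
  })
}

ad_sub <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ad_node(a$val - b$val, list(a, b), function(g) {
    gb <- if (length(b$val) == 1L && length(a$val) > 1L) -sum(g) else -g
    ga <- if (length(a$val) == 1L && length(b$val) > 1L) sum(g) else g
    list(ga, gb)
  })
}

ad_mul <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  av <- a$val; bv <- b$val
  ad_node(av * bv, list(a, b), function(g) {
    ga <- g * bv; gb <- g * av
    if (length(bv) == 1L && length(av) > 1L) gb <- sum(gb)
    if (length(av) == 1L && length(bv) > 1L) ga <- sum(ga)
    list(ga, gb)
  })
}

ad_scale <- function(a, s) {
  # multiply by a fixed (non-tracked) scalar
  a <- as_ad(a)
  ad_node(a$val * s, list(a), function(g) list(g * s))
}

ad_leaky_relu <- function(x, slope = 0.2) {
  x <- as_ad(x)
  xv <- x$val
  ad_node(pmax(xv, 0) + slope * pmin(xv, 0), list(x),
          function(g) list(g * (1 + (slope - 1) * (xv < 0))))
}

ad_relu <- function(x) {
  x <- as_ad(x)
  xv <- x$val
  ad_node(pmax(xv, 0), list(x), function(g) list(g * (xv > 0)))
}

ad_sigmoid <- function(x) {
  x <- as_ad(x)
  s <- 1 / (1 + exp(-x$val))
  ad_node(s, list(x), function(g) list(g * s * (1 - s)))
}

ad_tanh <- function(x) {
  x <- as_ad(x)
  t <- tanh(x$val)
  ad_node(t, list(x), function(g) list(g * (1 - t * t)))
}

ad_sum <- function(x) {
  x <- as_ad(x)
  n <- length(x$val); dm <- dim(x$val)
  ad_node(sum(x$val), list(x), function(g) {
    gr <- rep(g, n); if (!is.null(dm)) dim(gr) <- dm
    list(gr)
  })
}

ad_mean <- function(x) {
  x <- as_ad(x)
  n <- length(x$val); dm <- dim(x$val)
  ad_node(mean(x$val), list(x), function(g) {
    gr <- rep(g / n, n); if (!is.null(dm)) dim(gr) <- dm
    list(gr)
  })
}

ad_max <- function(x) {
  x <- as_ad(x)
  i <- which.max(x$val); n <- length(x$val); dm <- dim(x$val)
  ad_node(x$val[i], list(x), function(g) {
    gr <- numeric(n); gr[i] <- g; if (!is.null(dm)) dim(gr) <- dm
    list(gr)
  })
}

ad_softmax <- function(x) {
  # numerically stable softmax of a vector
  x <- as_ad(x)
  z <- exp(x$val - max(x$val))
  s <- z / sum(z)
  ad_node(s, list(x), function(g) list(s * (g - sum(g * s))))
}

ad_reshape <- function(x, dm) {
  x <- as_ad(x)
  old <- dim(x$val)
  v <- x$val; dim(v) <- dm
  ad_node(v, list(x), function(g) { dim(g) <- old %||% length(x$val); list(g) })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ------------------------------------------------------- linear algebra ---

# bind column-vector nodes into a matrix node
ad_cbind <- function(xs) {
  xs <- lapply(xs, as_ad)
  v <- do.call(cbind, lapply(xs, function(x) x$val))
  ad_node(v, xs, function(g)
    lapply(seq_along(xs), function(j) g[, j, drop = FALSE]))
}

# extract one column as an (n x 1) matrix node
ad_col <- function(x, j) {
  x <- as_ad(x)
  nc <- ncol(x$val)
  ad_node(x$val[, j, drop = FALSE], list(x), function(g) {
    gr <- matrix(0, nrow(x$val), nc)
    gr[, j] <- g
    list(gr)
  })
}

# add a length-n vector to every column of an (n x m) matrix node
ad_add_colvec <- function(x, b) {
  x <- as_ad(x); b <- as_ad(b)
  ad_node(x$val + as.vector(b$val), list(x, b),
          function(g) list(g, rowSums(g)))
}

ad_matmul <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  av <- a$val; bv <- b$val
  ad_node(av %*% bv, list(a, b),
          function(g) list(g %*% t(bv), crossprod(av, g)))
}

#' Linear combination of same-shape arrays with a weight vector
#' @keywords internal
ad_lincomb <- function(xs, w) {
  # xs: list of nodes/arrays of equal shape; w: node/vector of length(xs)
  xs <- lapply(xs, as_ad); w <- as_ad(w)
  wv <- w$val
  v <- xs[[1L]]$val * wv[1L]
  for (k in seq_along(xs)[-1L]) v <- v + xs[[k]]$val * wv[k]
  ad_node(v, c(xs, list(w)), function(g) {
    gs <- lapply(seq_along(xs), function(k) g * wv[k])
    gw <- vapply(xs, function(x) sum(g * x$val), 0)
    c(gs, list(gw))
  })
}

#' Per-channel scaling of a (C,D,H,W) array by a length-C vector
#' @keywords internal
ad_chan_scale <- function(x, w) {
  x <- as_ad(x); w <- as_ad(w)
  xv <- x$val; wv <- as.vector(w$val)
  C <- dim(xv)[1L]
  ad_node(xv * wv, list(x, w), function(g) {
    gw <- rowSums(matrix(g * xv, nrow = C))
    list(g * wv, gw)
  })
}

#' Voxel-wise gating of a (C,D,H,W) array by a (1,D,H,W) map
#' @keywords internal
ad_spatial_gate <- function(x, att) {
  x <- as_ad(x); att <- as_ad(att)
  xv <- x$val; am <- att$val
  C <- dim(xv)[1L]
  arep <- array(rep(as.vector(am), each = C), dim(xv))
  ad_node(xv * arep, list(x, att), function(g) {
    ga <- colSums(matrix(g * xv, nrow = C))
    dim(ga) <- dim(am)
    list(g * arep, ga)
  })
}

#' 1D convolution over a length-C vector (single channel, zero padding)
#' @keywords internal
ad_conv1d <- function(x, w, b) {
  x <- as_ad(x); w <- as_ad(w); b <- as_ad(b)
  xv <- as.vector(x$val); wv <- as.vector(w$val); C <- length(xv)
  kk <- length(wv); p <- (kk - 1L) %/% 2L
  xp <- c(numeric(p), xv, numeric(p))
  v <- vapply(seq_len(C), function(i) sum(wv * xp[i:(i + kk - 1L)]), 0) + ad_val(b)
  ad_node(v, list(x, w, b), function(g) {
    gx <- numeric(C)
    gw <- numeric(kk)
    for (j in seq_len(kk)) {
      idx <- seq_len(C) + j - 1L - p
      ok <- idx >= 1L & idx <= C
      gx[idx[ok]] <- gx[idx[ok]] + g[ok] * wv[j]
      gw[j] <- sum(g[ok] * xv[idx[ok]])
    }
    list(gx, gw, sum(g))
  })
}

# --------------------------------------------------------- spatial ops ---

#' 3D same-padding convolution (autodiff)
#' @param x node/array (C,D,H,W); w array (Cout,Cin,k,k,k); b length Cout.
#' @keywords internal
ad_conv3d <- function(x, w, b) {
  x <- as_ad(x); w <- as_ad(w); b <- as_ad(b)
  xv <- x$val; wd <- dim(w$val)
  cout <- wd[1L]; k <- wd[3L]
  xd <- dim(xv)
  v <- cpp_conv3d_fw(xv, xd, w$val, cout, k, b$val)
  dim(v) <- c(cout, xd[2:4])
  ad_node(v, list(x, w, b), function(g) {
    bw <- cpp_conv3d_bw(g, xv, xd, w$val,
                        cout, k, x$requires)
    gx <- NULL
    if (x$requires) { gx <- bw$gx; dim(gx) <- xd }
    gw <- bw$gw; dim(gw) <- wd
    list(gx, gw, bw$gb)
  })
}

#' 2x2x2 max pooling (autodiff)
#' @keywords internal
ad_maxpool <- function(x) {
  x <- as_ad(x)
  xd <- dim(x$val)
  r <- cpp_maxpool3d_fw(x$val, xd)
  v <- r$out; dim(v) <- c(xd[1L], xd[2:4] %/% 2L)
  am <- r$argmax
  ad_node(v, list(x), function(g) {
    gx <- cpp_maxpool3d_bw(g, am, prod(xd))
    dim(gx) <- xd
    list(gx)
  })
}

#' Trilinear x2 upsampling (autodiff)
#' @keywords internal
ad_upsample2 <- function(x) {
  x <- as_ad(x)
  xd <- dim(x$val)
  od <- xd[2:4] * 2L
  v <- cpp_resample3d(x$val, xd, od, FALSE)
  dim(v) <- c(xd[1L], od)
  ad_node(v, list(x), function(g) {
    gx <- cpp_resample3d_bw(g, xd, od)
    dim(gx) <- xd
    list(gx)
  })
}

#' Channel concatenation (autodiff)
#' @keywords internal
ad_concat_c <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  da <- dim(a$val); db <- dim(b$val)
  v <- array(0, c(da[1L] + db[1L], da[2:4]))
  v[seq_len(da[1L]), , , ] <- a$val
  v[da[1L] + seq_len(db[1L]), , , ] <- b$val
  ad_node(v, list(a, b), function(g) {
    list(array(g[seq_len(da[1L]), , , ], da),
         array(g[da[1L] + seq_len(db[1L]), , , ], db))
  })
}

#' Depth-slab extraction x[, d0:d1, , ] (autodiff)
#' @keywords internal
ad_slice_depth <- function(x, d0, d1) {
  x <- as_ad(x)
  xd <- dim(x$val)
  v <- x$val[, d0:d1, , , drop = FALSE]
  ad_node(v, list(x), function(g) {
    gx <- array(0, xd)
    gx[, d0:d1, , ] <- g
    list(gx)
  })
}

#' Concatenate arrays along the depth axis (autodiff)
#' @keywords internal
ad_concat_depth <- function(xs) {
  xs <- lapply(xs, as_ad)
  dms <- lapply(xs, function(x) dim(x$val))
  Dtot <- sum(vapply(dms, `[`, 0, 2L))
  d1 <- dms[[1L]]
  v <- array(0, c(d1[1L], Dtot, d1[3L], d1[4L]))
  at <- 0L
  for (x in xs) {
    dd <- dim(x$val)[2L]
    v[, at + seq_len(dd), , ] <- x$val
    at <- at + dd
  }
  ad_node(v, xs, function(g) {
    out <- vector("list", length(xs))
    at <- 0L
    for (i in seq_along(xs)) {
      dd <- dms[[i]][2L]
      out[[i]] <- array(g[, at + seq_len(dd), , ], dms[[i]])
      at <- at + dd
    }
    out
  })
}

#' Differentiable spatial-transformer warp (trilinear, border clamp)
#'
#' `out(p) = img(p + phi(p))`; gradients flow to both the image and field.
#' @param img node/array (C,D,H,W); phi node/array (3,D,H,W).
#' @keywords internal
ad_warp <- function(img, phi) {
  img <- as_ad(img); phi <- as_ad(phi)
  idim <- dim(img$val)
  v <- cpp_grid_sample_fw(img$val, idim, phi$val, FALSE)
  dim(v) <- idim
  ad_node(v, list(img, phi), function(g) {
    bw <- cpp_grid_sample_bw(g, img$val, idim,
                             phi$val)
    gi <- bw$gimg; dim(gi) <- idim
    gp <- bw$gphi; dim(gp) <- dim(phi$val)
    list(gi, gp)
  })
}
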