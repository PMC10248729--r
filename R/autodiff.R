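# Minimal reverse-mode tape for the segmentation network.
#
# A tape is an environment holding an append-only list of nodes. Each node
# carries its value (an array, dim = c(H, W, C, N), or a C x N matrix for
# pooled channel vectors), the ids of its parents and a backward closure
# mapping the gradient at the node to gradients at the parents. Parameter
# gradients are accumulated directly into the owning layer environment, so
# a backward sweep leaves every layer ready for an optimizer step.

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- list()
  tp$n <- 0L
  tp
}

tp_add <- function(tp, value, parents = integer(), backward = NULL) {
  tp$n <- tp$n + 1L
  tp$nodes[[tp$n]] <- list(value = value, parents = parents, backward = backward)
  tp$n
}

tp_value <- function(tp, id) {
  force(id)  # id may be a call that appends to the tape; force it first
  tp$nodes[[id]]$value
}

#' @keywords internal
tape_backward <- function(tp, seed_id, seed_grad) {
  grads <- vector("list", tp$n)
  grads[[seed_id]] <- seed_grad
  for (id in seq(tp$n, 1L)) {
    node <- tp$nodes[[id]]
    g <- grads[[id]]
    if (is.null(g) || is.null(node$backward)) next
    pg <- node$backward(g)
    for (k in seq_along(node$parents)) {
      p <- node$parents[[k]]
      if (is.null(pg[[k]])) next
      grads[[p]] <- if (is.null(grads[[p]])) pg[[k]] else grads[[p]] + pg[[k]]
    }
    grads[[id]] <- NULL  # free memory as we sweep
  }
  invisible(NULL)
}

# ---- parameter containers ---------------------------------------------------

new_param <- function(value) {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- NULL
  p$m <- NULL   # Adam first moment
  p$v <- NULL   # Adam second moment
  p
}

acc_grad <- function(param, g) {
  param$grad <- if (is.null(param$grad)) g else param$grad + g
}

he_uniform <- function(dims, fan_in) {
  lim <- sqrt(6 / fan_in)
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

# A convolution layer: weights (kh, kw, Cin, Cout) + bias, He-uniform init.
layer_conv <- function(kh, kw, cin, cout) {
  l <- new.env(parent = emptyenv())
  l$type <- "conv"
  l$W <- new_param(he_uniform(c(kh, kw, cin, cout), kh * kw * cin))
  l$b <- new_param(numeric(cout))
  l$params <- list(l$W, l$b)
  l
}

# Batch normalization layer (per-channel; TensorFlow-style defaults).
layer_bn <- function(channels, momentum = 0.99, eps = 1e-3) {
  l <- new.env(parent = emptyenv())
  l$type <- "bn"
  l$gamma <- new_param(rep(1, channels))
  l$beta <- new_param(numeric(channels))
  l$rmean <- numeric(channels)
  l$rvar <- rep(1, channels)
  l$momentum <- momentum
  l$eps <- eps
  l$params <- list(l$gamma, l$beta)
  l
}

# Dense layer acting on pooled channel vectors (C x N matrices).
layer_dense <- function(cin, cout) {
  l <- new.env(parent = emptyenv())
  l$type <- "dense"
  l$W <- new_param(he_uniform(c(cout, cin), cin))
  l$b <- new_param(numeric(cout))
  l$params <- list(l$W, l$b)
  l
}

# ---- tape operations --------------------------------------------------------

tp_input <- function(tp, x) tp_add(tp, x)

tp_conv <- function(tp, xid, layer, dilation = 1L) {
  x <- tp_value(tp, xid)
  out <- cpp_conv2d_forward(x, layer$W$value, layer$b$value, as.integer(dilation))
  tp_add(tp, out, xid, function(g) {
    bw <- cpp_conv2d_backward(x, layer$W$value, g, as.integer(dilation))
    acc_grad(layer$W, bw$gw)
    acc_grad(layer$b, bw$gb)
    list(bw$gx)
  })
}

tp_bn <- function(tp, xid, layer, training) {
  x <- tp_value(tp, xid)
  fw <- cpp_bn_forward(x, layer$gamma$value, layer$beta$value,
                       layer$rmean, layer$rvar,
                       layer$momentum, layer$eps, training)
  if (training) {
    layer$rmean <- fw$rmean
    layer$rvar <- fw$rvar
  }
  tp_add(tp, fw$out, xid, function(g) {
    bw <- cpp_bn_backward(x, g, layer$gamma$value, fw$mean, fw$invstd)
    acc_grad(layer$gamma, bw$ggamma)
    acc_grad(layer$beta, bw$gbeta)
    list(bw$gx)
  })
}

# Fused batch norm + ReLU node.
tp_bn_relu <- function(tp, xid, layer, training) {
  x <- tp_value(tp, xid)
  fw <- cpp_bn_relu_forward(x, layer$gamma$value, layer$beta$value,
                            layer$rmean, layer$rvar,
                            layer$momentum, layer$eps, training)
  if (training) {
    layer$rmean <- fw$rmean
    layer$rvar <- fw$rvar
  }
  tp_add(tp, fw$out, xid, function(g) {
    bw <- cpp_bn_relu_backward(x, fw$out, g, layer$gamma$value, fw$mean, fw$invstd)
    acc_grad(layer$gamma, bw$ggamma)
    acc_grad(layer$beta, bw$gbeta)
    list(bw$gx)
  })
}

tp_relu <- function(tp, xid) {
  out <- cpp_relu_forward(tp_value(tp, xid))
  tp_add(tp, out, xid, function(g) list(cpp_relu_backward(out, g)))
}

tp_sigmoid <- function(tp, xid) {
  s <- 1 / (1 + exp(-tp_value(tp, xid)))
  tp_add(tp, s, xid, function(g) list(cpp_sigmoid_backward(s, g)))
}

tp_maxpool <- function(tp, xid) {
  x <- tp_value(tp, xid)
  fw <- cpp_maxpool2_forward(x)
  tp_add(tp, fw$out, xid, function(g)
    list(cpp_maxpool2_backward(g, fw$argmax, dim(x))))
}

# Nearest-neighbour 2x upsampling.
tp_upsample2 <- function(tp, xid) {
  x <- tp_value(tp, xid)
  d <- dim(x)
  out <- x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , , drop = FALSE]
  tp_add(tp, out, xid, function(g) {
    oh <- seq(1L, 2L * d[1], by = 2L)
    ow <- seq(1L, 2L * d[2], by = 2L)
    gx <- g[oh, ow, , , drop = FALSE] + g[oh + 1L, ow, , , drop = FALSE] +
      g[oh, ow + 1L, , , drop = FALSE] + g[oh + 1L, ow + 1L, , , drop = FALSE]
    list(gx)
  })
}

# Channel concatenation of feature maps sharing H, W, N.
tp_concat <- function(tp, ids) {
  vals <- lapply(ids, tp_value, tp = tp)
  chans <- vapply(vals, function(v) dim(v)[3], integer(1))
  out <- cpp_concat_channels(vals)
  tp_add(tp, out, ids, function(g) {
    res <- vector("list", length(ids))
    at <- 0L
    for (k in seq_along(ids)) {
      res[[k]] <- cpp_slice_channels(g, at, chans[k])
      at <- at + chans[k]
    }
    res
  })
}

tp_mul <- function(tp, aid, bid) {
  a <- tp_value(tp, aid)
  b <- tp_value(tp, bid)
  tp_add(tp, a * b, c(aid, bid), function(g) list(g * b, g * a))
}

# Global max pooling over H, W: (H, W, C, N) -> C x N matrix.
tp_gmaxpool <- function(tp, xid) {
  x <- tp_value(tp, xid)
  d <- dim(x)
  hw <- d[1] * d[2]
  m <- matrix(x, nrow = hw)                     # HW x (C*N)
  arg <- max.col(t(m), ties.method = "first")   # row index of max per column
  out <- matrix(m[cbind(arg, seq_len(ncol(m)))], nrow = d[3])
  tp_add(tp, out, xid, function(g) {
    gx <- matrix(0, nrow = hw, ncol = ncol(m))
    gx[cbind(arg, seq_len(ncol(m)))] <- as.numeric(g)
    list(array(gx, dim = d))
  })
}

# Dense layer on a C x N channel-vector matrix.
tp_dense <- function(tp, xid, layer) {
  x <- tp_value(tp, xid)
  out <- layer$W$value %*% x + layer$b$value
  tp_add(tp, out, xid, function(g) {
    acc_grad(layer$W, g %*% t(x))
    acc_grad(layer$b, rowSums(g))
    list(crossprod(layer$W$value, g))
  })
}

tp_sigmoid_mat <- function(tp, xid) {
  s <- 1 / (1 + exp(-tp_value(tp, xid)))
  tp_add(tp, s, xid, function(g) list(g * s * (1 - s)))
}

# Scale feature map channels by per-(channel, sample) weights (C x N),
# broadcasting over H and W.
tp_scale_channels <- function(tp, xid, wid) {
  x <- tp_value(tp, xid)
  w <- tp_value(tp, wid)
  d <- dim(x)
  wfull <- array(rep(as.numeric(w), each = d[1] * d[2]), dim = d)
  tp_add(tp, x * wfull, c(xid, wid), function(g) {
    gw <- colSums(matrix(g * x, nrow = d[1] * d[2]))
    list(g * wfull, matrix(gw, nrow = d[3]))
  })
}
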