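# Independent oracles used across the suite. These deliberately avoid the
# package's own kernels: plain R loops, brute-force enumeration.

# Naive same-padding stride-1 convolution with dilation (quadruple loop).
naive_conv <- function(x, w, b, dil = 1L) {
  d <- dim(x); wd <- dim(w)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  kh <- wd[1]; kw <- wd[2]; Cout <- wd[4]
  ph <- dil * (kh - 1) %/% 2; pw <- dil * (kw - 1) %/% 2
  out <- array(0, c(H, W, Cout, N))
  for (n in 1:N) for (co in 1:Cout) for (h in 1:H) for (wc in 1:W) {
    s <- b[co]
    for (ci in 1:C) for (ki in 1:kh) for (kj in 1:kw) {
      hh <- h + (ki - 1) * dil - ph; ww <- wc + (kj - 1) * dil - pw
      if (hh >= 1 && hh <= H && ww >= 1 && ww <= W)
        s <- s + x[hh, ww, ci, n] * w[ki, kj, ci, co]
    }
    out[h, wc, co, n] <- s
  }
  out
}

# Count 8-connected components of a binary matrix with a BFS flood fill.
flood_fill_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  count <- 0L
  sizes <- integer()
  for (w0 in seq_len(W)) for (h0 in seq_len(H)) {
    if (mask[h0, w0] == 0 || seen[h0, w0]) next
    count <- count + 1L
    queue <- list(c(h0, w0))
    seen[h0, w0] <- TRUE
    size <- 0L
    while (length(queue) > 0) {
      p <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      size <- size + 1L
      for (dh in -1:1) for (dw in -1:1) {
        h <- p[1] + dh; w <- p[2] + dw
        if (h >= 1 && h <= H && w >= 1 && w <= W &&
            mask[h, w] == 1 && !seen[h, w]) {
          seen[h, w] <- TRUE
          queue[[length(queue) + 1L]] <- c(h, w)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  list(count = count, sizes = sizes)
}

# Pixel-counting metric oracles (explicit confusion-table loops).
oracle_metrics <- function(pred, truth, threshold = 0.5) {
  tp <- tn <- fp <- fn <- 0L
  p <- as.numeric(pred); y <- as.numeric(truth)
  for (i in seq_along(p)) {
    ph <- as.integer(p[i] >= threshold)
    if (ph == 1 && y[i] == 1) tp <- tp + 1L
    if (ph == 0 && y[i] == 0) tn <- tn + 1L
    if (ph == 1 && y[i] == 0) fp <- fp + 1L
    if (ph == 0 && y[i] == 1) fn <- fn + 1L
  }
  list(accuracy = (tp + tn) / (tp + tn + fp + fn),
       dice = if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn),
       jaccard = if (tp + fp + fn == 0) 1 else tp / (tp + fp + fn))
}

oracle_bce <- function(pred, truth, clip = 1e-7) {
  p <- pmin(pmax(as.numeric(pred), clip), 1 - clip)
  y <- as.numeric(truth)
  s <- 0
  for (i in seq_along(p)) s <- s + y[i] * log(p[i]) + (1 - y[i]) * log(1 - p[i])
  -s / length(p)
}

# Straight-line transcription of the spatial attention equation chain
# using the naive convolution and explicit normalization arithmetic,
# reading weights out of a built module (inference-mode statistics).
oracle_dcsam <- function(mod, x4) {
  bn_inf <- function(z, bn) {
    d <- dim(z)
    for (c in seq_len(d[3])) {
      g <- bn$gamma$value[c]; b <- bn$beta$value[c]
      mu <- bn$rmean[c]; v <- bn$rvar[c]
      z[, , c, ] <- g * (z[, , c, ] - mu) / sqrt(v + bn$eps) + b
    }
    z
  }
  relu <- function(z) pmax(z, 0)
  sigm <- function(z) 1 / (1 + exp(-z))
  D <- mod$dilation
  conv1 <- relu(bn_inf(naive_conv(x4, mod$conv1$W$value, mod$conv1$b$value, D), mod$bn1))
  conv2 <- relu(bn_inf(naive_conv(conv1, mod$conv2$W$value, mod$conv2$b$value, D), mod$bn2))
  squeeze <- relu(bn_inf(naive_conv(x4, mod$squeeze$W$value, mod$squeeze$b$value, 1L), mod$bn_sq))
  d <- dim(x4)
  concat <- array(0, c(d[1], d[2], 4 * d[3], d[4]))
  concat[, , seq_len(d[3]), ] <- x4
  concat[, , d[3] + seq_len(d[3]), ] <- conv1
  concat[, , 2 * d[3] + seq_len(d[3]), ] <- conv2
  concat[, , 3 * d[3] + seq_len(d[3]), ] <- squeeze
  fc1 <- relu(naive_conv(x4, mod$fc1$W$value, mod$fc1$b$value, 1L))
  hid <- relu(naive_conv(concat, mod$fc2_reduce$W$value, mod$fc2_reduce$b$value, 1L))
  fc2 <- sigm(naive_conv(hid, mod$fc2_expand$W$value, mod$fc2_expand$b$value, 1L))
  fc1 * fc2
}

# Compact tile spec for fast tests.
tiny_tile_spec <- function(size = 64L, n = c(2L, 6L)) {
  synthetic_tile_spec(height = size, width = size, n_nuclei_range = n,
                      radius_range = c(4, 10))
}

# A stub segmentation model with a fixed per-patch output; exercises the
# evaluation pipeline without network cost.
stub_model <- function(fn) structure(list(fn = fn), class = "stub_model")
predict_probs.stub_model <- function(model, images, ...) {
  d <- dim(images)
  if (length(d) == 3L) d <- c(d, 1L)
  out <- array(0, dim = c(d[1], d[2], d[4]))
  for (k in seq_len(d[4])) out[, , k] <- model$fn(images[, , , k], k)
  out
}
registerS3method("predict_probs", "stub_model", predict_probs.stub_model,
                 envir = asNamespace("dcsanet"))
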