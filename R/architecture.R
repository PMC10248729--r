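#' Network configuration for the DCSA segmentation model
#'
#' Fully determines the built model: an encoder-decoder with `depth` 2x2
#' max-pooling levels, whose block filter counts start at `base_channels`
#' and double at each level. Three ablation switches recover a plain U-Net:
#' `use_parallel_block` replaces the two stacked 3x3 convolutions of each
#' block with parallel 5x5 and 3x3 branches (concatenated, so the block
#' output is twice its filter count); `use_dcsam` inserts the densely
#' convolutional spatial attention module after every encoder and decoder
#' block; `use_channel_attention` gates each decoder feature map with a
#' sigmoid channel weight (from a dense layer on its global-max-pooled
#' channel vector) before the skip concatenation.
#'
#' @param depth Number of pooling levels.
#' @param base_channels Filter count of the first block; doubled per level.
#' @param parallel_kernels Kernel sizes of the two parallel branches.
#' @param dilation_rate Dilation of the DCSAM 3x3 convolutions on the
#'   encoder side (the decoder side uses `dilation_decoder`).
#' @param dilation_decoder Decoder-side DCSAM dilation.
#' @param reduction_ratio Channel reduction `r` of the DCSAM attention
#'   bottleneck (`C -> C/r -> C`); must divide every channel width at which
#'   the module is instantiated.
#' @param use_parallel_block,use_dcsam,use_channel_attention Ablation flags.
#' @param input_channels,output_channels Image and prediction channels.
#' @return An object of class `dcsa_config`.
#' @export
network_config <- function(depth = 4L, base_channels = 16L,
                           parallel_kernels = c(5L, 3L),
                           dilation_rate = 2L, dilation_decoder = 1L,
                           reduction_ratio = 8L,
                           use_parallel_block = TRUE, use_dcsam = TRUE,
                           use_channel_attention = TRUE,
                           input_channels = 3L, output_channels = 1L) {
  if (depth < 1L || base_channels < 1L)
    stop("network_config: depth and base_channels must be positive")
  if (length(parallel_kernels) != 2L || any(parallel_kernels < 1L))
    stop("network_config: parallel_kernels must be two positive kernel sizes")
  if (reduction_ratio < 1L)
    stop("network_config: reduction_ratio must be >= 1")
  structure(list(
    depth = as.integer(depth), base_channels = as.integer(base_channels),
    parallel_kernels = as.integer(parallel_kernels),
    dilation_rate = as.integer(dilation_rate),
    dilation_decoder = as.integer(dilation_decoder),
    reduction_ratio = as.integer(reduction_ratio),
    use_parallel_block = isTRUE(use_parallel_block),
    use_dcsam = isTRUE(use_dcsam),
    use_channel_attention = isTRUE(use_channel_attention),
    input_channels = as.integer(input_channels),
    output_channels = as.integer(output_channels)
  ), class = "dcsa_config")
}

as_batch4 <- function(x) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L, 1L)
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  x
}

# ---- building blocks --------------------------------------------------------

# Parallel block: 5x5 and 3x3 convolutions side by side, each followed by
# batch normalization and ReLU, concatenated -> 2k output channels.
parallel_block_module <- function(in_channels, filters, kernels = c(5L, 3L)) {
  if (filters < 1L) stop("parallel_block: filters must be >= 1")
  m <- list(
    conv_a = layer_conv(kernels[1], kernels[1], in_channels, filters),
    bn_a = layer_bn(filters),
    conv_b = layer_conv(kernels[2], kernels[2], in_channels, filters),
    bn_b = layer_bn(filters)
  )
  m$out_channels <- 2L * as.integer(filters)
  m$kind <- "parallel"
  m
}

# Plain block: two stacked 3x3 conv + BN + ReLU -> k output channels.
plain_block_module <- function(in_channels, filters) {
  m <- list(
    conv_a = layer_conv(3L, 3L, in_channels, filters),
    bn_a = layer_bn(filters),
    conv_b = layer_conv(3L, 3L, filters, filters),
    bn_b = layer_bn(filters)
  )
  m$out_channels <- as.integer(filters)
  m$kind <- "plain"
  m
}

block_forward <- function(tp, xid, m, training) {
  if (m$kind == "parallel") {
    a <- tp_bn_relu(tp, tp_conv(tp, xid, m$conv_a), m$bn_a, training)
    b <- tp_bn_relu(tp, tp_conv(tp, xid, m$conv_b), m$bn_b, training)
    tp_concat(tp, c(a, b))
  } else {
    h <- tp_bn_relu(tp, tp_conv(tp, xid, m$conv_a), m$bn_a, training)
    tp_bn_relu(tp, tp_conv(tp, h, m$conv_b), m$bn_b, training)
  }
}

#' Densely convolutional spatial attention module
#'
#' Builds the attention block applied after encoder and decoder blocks.
#' The input map `F` (H x W x C) passes through a chain of two dilated 3x3
#' convolutions and a 1x1 squeeze, each with batch normalization and ReLU:
#' \deqn{conv1 = R[BN(f_{3x3}(F, D))],\quad conv2 = R[BN(f_{3x3}(conv1, D))],}
#' \deqn{squeeze = R[BN(f_{1x1}(F))].}
#' The dense concatenation `F (+) conv1 (+) conv2 (+) squeeze` (4C channels)
#' feeds a sigmoid-activated channel-mixing branch routed through a `C/r`
#' bottleneck, while `F` itself feeds a ReLU channel-mixing branch of width
#' C; the module output is their elementwise product. With C = 256 and
#' r = 8 the bottleneck is 32 units wide. Channel mixing is implemented as
#' 1x1 convolution so both branches keep the H x W extent that the final
#' elementwise product requires.
#'
#' @param channels Input channel count C.
#' @param reduction Reduction ratio r; must divide `channels`.
#' @param dilation Dilation rate D of the two 3x3 convolutions.
#' @return A module whose `hidden_width` field is the bottleneck width.
#' @export
dcsam_module <- function(channels, reduction = 8L, dilation = 1L) {
  channels <- as.integer(channels)
  if (channels %% reduction != 0L)
    stop(sprintf("dcsam: channels (%d) not divisible by reduction ratio (%d)",
                 channels, as.integer(reduction)))
  hidden <- channels %/% as.integer(reduction)
  m <- list(
    conv1 = layer_conv(3L, 3L, channels, channels),
    bn1 = layer_bn(channels),
    conv2 = layer_conv(3L, 3L, channels, channels),
    bn2 = layer_bn(channels),
    squeeze = layer_conv(1L, 1L, channels, channels),
    bn_sq = layer_bn(channels),
    fc1 = layer_conv(1L, 1L, channels, channels),
    fc2_reduce = layer_conv(1L, 1L, 4L * channels, hidden),
    fc2_expand = layer_conv(1L, 1L, hidden, channels)
  )
  m$channels <- channels
  m$hidden_width <- hidden
  m$dilation <- as.integer(dilation)
  m
}

dcsam_forward <- function(tp, xid, m, training) {
  c1 <- tp_bn_relu(tp, tp_conv(tp, xid, m$conv1, m$dilation), m$bn1, training)
  c2 <- tp_bn_relu(tp, tp_conv(tp, c1, m$conv2, m$dilation), m$bn2, training)
  sq <- tp_bn_relu(tp, tp_conv(tp, xid, m$squeeze), m$bn_sq, training)
  cat4 <- tp_concat(tp, c(xid, c1, c2, sq))
  fc1 <- tp_relu(tp, tp_conv(tp, xid, m$fc1))
  fc2 <- tp_sigmoid(tp, tp_conv(tp, tp_relu(tp, tp_conv(tp, cat4, m$fc2_reduce)),
                                m$fc2_expand))
  tp_mul(tp, fc1, fc2)
}

# Channel attention on a decoder feature map: sigmoid(dense(global max
# pool)) gates the channels, then the gated map is concatenated with the
# skip-connection input.
channel_attention_module <- function(channels) {
  list(dense = layer_dense(channels, channels), channels = as.integer(channels))
}

channel_attention_forward <- function(tp, block_id, skip_id, m) {
  pooled <- tp_gmaxpool(tp, block_id)
  w <- tp_sigmoid_mat(tp, tp_dense(tp, pooled, m$dense))
  scaled <- tp_scale_channels(tp, block_id, w)
  tp_concat(tp, c(scaled, skip_id))
}

# ---- functional single-map wrappers (inference mode) ------------------------

#' Apply a parallel convolution block to a feature map
#'
#' Convenience wrapper that builds a freshly initialized block (batch
#' normalization in inference mode with identity statistics) and runs one
#' H x W x C map through it. Mainly useful for inspecting shapes; training
#' always goes through [build_network()].
#'
#' @param input H x W x C array.
#' @param filters Filters per branch; the output has `2 * filters` channels.
#' @param kernels Kernel sizes of the two branches.
#' @param module Optionally a prebuilt module (from an internal constructor)
#'   so repeated calls share weights.
#' @return H x W x 2k array.
#' @export
parallel_block <- function(input, filters, kernels = c(5L, 3L), module = NULL) {
  x <- as_batch4(input)
  if (is.null(module))
    module <- parallel_block_module(dim(x)[3], as.integer(filters), as.integer(kernels))
  tp <- tape_new()
  out <- tp_value(tp, block_forward(tp, tp_input(tp, x), module, training = FALSE))
  array(out, dim = dim(out)[1:3])
}

#' Apply the spatial attention module to a feature map
#'
#' @param input H x W x C array.
#' @param dilation Dilation rate of the 3x3 convolutions.
#' @param reduction Reduction ratio r (must divide C).
#' @param module Optionally a prebuilt [dcsam_module()] for weight sharing.
#' @return H x W x C array.
#' @export
dcsam <- function(input, dilation = 1L, reduction = 8L, module = NULL) {
  x <- as_batch4(input)
  if (is.null(module))
    module <- dcsam_module(dim(x)[3], reduction, dilation)
  tp <- tape_new()
  out <- tp_value(tp, dcsam_forward(tp, tp_input(tp, x), module, training = FALSE))
  array(out, dim = dim(out)[1:3])
}

#' Apply channel attention and skip concatenation
#'
#' @param block_output H x W x C decoder feature map.
#' @param skip_input H x W x Cs skip feature map (same H, W).
#' @param module Optionally a prebuilt module for weight sharing.
#' @return H x W x (C + Cs) array.
#' @export
channel_attention <- function(block_output, skip_input, module = NULL) {
  x <- as_batch4(block_output)
  s <- as_batch4(skip_input)
  if (!all(dim(x)[1:2] == dim(s)[1:2]))
    stop("channel_attention: spatial sizes of block output and skip input differ")
  if (is.null(module)) module <- channel_attention_module(dim(x)[3])
  tp <- tape_new()
  out <- tp_value(tp, channel_attention_forward(tp, tp_input(tp, x),
                                                tp_input(tp, s), module))
  array(out, dim = dim(out)[1:3])
}

# ---- full network -----------------------------------------------------------

make_block <- function(cfg, in_channels, filters) {
  if (cfg$use_parallel_block)
    parallel_block_module(in_channels, filters, cfg$parallel_kernels)
  else
    plain_block_module(in_channels, filters)
}

check_reduction <- function(cfg, channels) {
  if (channels %% cfg$reduction_ratio != 0L)
    stop(sprintf(
      "network_config: reduction_ratio %d does not divide channel width %d",
      cfg$reduction_ratio, channels))
}

#' Build the segmentation network
#'
#' Assembles the encoder-decoder from a [network_config()]: each encoder
#' level applies its block (parallel or plain), optionally the spatial
#' attention module, then 2x2 max pooling; a bottleneck block sits below;
#' each decoder level applies 2x nearest-neighbour upsampling, its block,
#' optionally the attention module, then fuses the matching encoder skip
#' (gated by channel attention when enabled, plain concatenation
#' otherwise). A 1x1 convolution to one channel plus sigmoid produces the
#' per-pixel nucleus probability. Input height and width must be divisible
#' by `2^depth`.
#'
#' @param config A [network_config()].
#' @param seed Optional integer seed for the He-uniform weight draw.
#' @return An object of class `dcsa_net`.
#' @export
build_network <- function(config = network_config(), seed = NULL) {
  stopifnot(inherits(config, "dcsa_config"))
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  enc <- vector("list", cfg$depth)
  ch <- cfg$input_channels
  skip_ch <- integer(cfg$depth)
  for (l in seq_len(cfg$depth)) {
    filters <- cfg$base_channels * 2L^(l - 1L)
    blk <- make_block(cfg, ch, filters)
    ch <- blk$out_channels
    att <- NULL
    if (cfg$use_dcsam) {
      check_reduction(cfg, ch)
      att <- dcsam_module(ch, cfg$reduction_ratio, cfg$dilation_rate)
    }
    enc[[l]] <- list(block = blk, dcsam = att, out_channels = ch)
    skip_ch[l] <- ch
  }
  bottleneck <- make_block(cfg, ch, cfg$base_channels * 2L^cfg$depth)
  ch <- bottleneck$out_channels
  dec <- vector("list", cfg$depth)
  for (l in seq(cfg$depth, 1L)) {
    filters <- cfg$base_channels * 2L^(l - 1L)
    blk <- make_block(cfg, ch, filters)
    bch <- blk$out_channels
    att <- NULL
    if (cfg$use_dcsam) {
      check_reduction(cfg, bch)
      att <- dcsam_module(bch, cfg$reduction_ratio, cfg$dilation_decoder)
    }
    catt <- if (cfg$use_channel_attention) channel_attention_module(bch) else NULL
    dec[[l]] <- list(block = blk, dcsam = att, channel_attention = catt,
                     out_channels = bch + skip_ch[l])
    ch <- bch + skip_ch[l]
  }
  head <- layer_conv(1L, 1L, ch, cfg$output_channels)
  model <- structure(list(config = cfg, encoder = enc, bottleneck = bottleneck,
                          decoder = dec, head = head),
                     class = "dcsa_net")
  model
}

collect_layers <- function(model) {
  layers <- list()
  grab <- function(m) {
    for (el in m)
      if (is.environment(el)) layers[[length(layers) + 1L]] <<- el
  }
  for (st in model$encoder) {
    grab(st$block)
    if (!is.null(st$dcsam)) grab(st$dcsam)
  }
  grab(model$bottleneck)
  for (st in model$decoder) {
    grab(st$block)
    if (!is.null(st$dcsam)) grab(st$dcsam)
    if (!is.null(st$channel_attention)) grab(st$channel_attention)
  }
  layers[[length(layers) + 1L]] <- model$head
  layers
}

collect_params <- function(model) {
  unlist(lapply(collect_layers(model), function(l) l$params), recursive = FALSE)
}

#' Forward pass of the network
#'
#' @param model A [build_network()] model.
#' @param x Input array: H x W x C or H x W x C x N batch, values in [0, 1].
#' @param training Use batch statistics (and update running averages) in
#'   batch normalization when `TRUE`; running averages when `FALSE`.
#' @return List with the tape and node ids of logits and probabilities;
#'   `value` holds the H x W x 1 x N probability array.
#' @keywords internal
network_forward <- function(model, x, training = FALSE) {
  x <- as_batch4(x)
  cfg <- model$config
  d <- dim(x)
  if (d[1] %% 2L^cfg$depth != 0L || d[2] %% 2L^cfg$depth != 0L)
    stop(sprintf("input %d x %d not divisible by 2^depth = %d",
                 d[1], d[2], 2L^cfg$depth))
  tp <- tape_new()
  cur <- tp_input(tp, x)
  skips <- integer(cfg$depth)
  for (l in seq_len(cfg$depth)) {
    st <- model$encoder[[l]]
    cur <- block_forward(tp, cur, st$block, training)
    if (!is.null(st$dcsam)) cur <- dcsam_forward(tp, cur, st$dcsam, training)
    skips[l] <- cur
    cur <- tp_maxpool(tp, cur)
  }
  cur <- block_forward(tp, cur, model$bottleneck, training)
  for (l in seq(cfg$depth, 1L)) {
    st <- model$decoder[[l]]
    cur <- tp_upsample2(tp, cur)
    cur <- block_forward(tp, cur, st$block, training)
    if (!is.null(st$dcsam)) cur <- dcsam_forward(tp, cur, st$dcsam, training)
    cur <- if (!is.null(st$channel_attention))
      channel_attention_forward(tp, cur, skips[l], st$channel_attention)
    else
      tp_concat(tp, c(cur, skips[l]))
  }
  logits <- tp_conv(tp, cur, model$head)
  prob <- tp_sigmoid(tp, logits)
  list(tape = tp, logits = logits, prob = prob, value = tp_value(tp, prob))
}

#' Predict nucleus probabilities for image patches
#'
#' @param model Trained or freshly built model.
#' @param images H x W x 3 array, H x W x 3 x N batch, or list of arrays.
#' @param batch_size Samples per forward pass.
#' @param ... Unused.
#' @return H x W x N array of probabilities in (0, 1).
#' @export
predict_probs <- function(model, images, ...) UseMethod("predict_probs")

#' @rdname predict_probs
#' @export
predict_probs.dcsa_net <- function(model, images, batch_size = 8L, ...) {
  if (is.list(images))
    images <- array(unlist(images, use.names = FALSE),
                    dim = c(dim(images[[1]]), length(images)))
  images <- as_batch4(images)
  d <- dim(images)
  out <- array(0, dim = c(d[1], d[2], d[4]))
  for (at in seq(1L, d[4], by = batch_size)) {
    idx <- at:min(at + batch_size - 1L, d[4])
    fw <- network_forward(model, images[, , , idx, drop = FALSE], training = FALSE)
    out[, , idx] <- fw$value[, , 1L, ]
  }
  out
}

#' Count trainable parameters
#'
#' Sums the lengths of all trainable weights (convolution kernels and
#' biases, batch-norm scales and shifts, dense layers). Parameters of
#' frozen layers (see [freeze_layer()]) are excluded; batch-norm running
#' statistics are never counted.
#'
#' @param model A `dcsa_net` model (or any module list of layers).
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  params <- if (inherits(model, "dcsa_net")) collect_params(model)
  else unlist(lapply(model, function(l) if (is.environment(l)) l$params),
              recursive = FALSE)
  total <- 0
  for (p in params)
    if (is.null(p$trainable) || isTRUE(p$trainable))
      total <- total + length(p$value)
  as.integer(total)
}

#' Freeze a layer's parameters
#'
#' Frozen parameters are skipped by the optimizer and excluded from
#' [count_parameters()].
#' @param layer A layer environment (e.g. `model$head`).
#' @export
freeze_layer <- function(layer) {
  for (p in layer$params) p$trainable <- FALSE
  invisible(layer)
}

#' @export
print.dcsa_net <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("DCSA segmentation network (depth %d, base %d)\n",
              cfg$depth, cfg$base_channels))
  cat(sprintf("  parallel block: %s | spatial attention: %s | channel attention: %s\n",
              cfg$use_parallel_block, cfg$use_dcsam, cfg$use_channel_attention))
  enc_ch <- vapply(x$encoder, function(s) s$out_channels, integer(1))
  cat("  encoder block channels:", paste(enc_ch, collapse = ", "), "\n")
  cat("  bottleneck channels:", x$bottleneck$out_channels, "\n")
  dec_ch <- vapply(x$decoder, function(s) s$out_channels, integer(1))
  cat("  decoder output channels:", paste(rev(dec_ch), collapse = ", "), "\n")
  cat("  trainable parameters:", count_parameters(x), "\n")
  invisible(x)
}

#' Save / load a model
#'
#' Serializes the configuration, all parameter values and the batch-norm
#' running statistics; loading rebuilds the network and restores them.
#'
#' @param model A `dcsa_net` model.
#' @param path Checkpoint file path (RDS).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "dcsa_net"))
  layers <- collect_layers(model)
  state <- lapply(layers, function(l) {
    s <- list(params = lapply(l$params, function(p) p$value))
    if (identical(l$type, "bn")) {
      s$rmean <- l$rmean
      s$rvar <- l$rvar
    }
    s
  })
  saveRDS(list(config = model$config, state = state), path)
  invisible(path)
}

#' @rdname save_model
#' @return `load_model` returns the rebuilt `dcsa_net`.
#' @export
load_model <- function(path) {
  ck <- readRDS(path)
  model <- build_network(ck$config)
  layers <- collect_layers(model)
  stopifnot(length(layers) == length(ck$state))
  for (k in seq_along(layers)) {
    l <- layers[[k]]
    for (j in seq_along(l$params)) l$params[[j]]$value <- ck$state[[k]]$params[[j]]
    if (identical(l$type, "bn")) {
      l$rmean <- ck$state[[k]]$rmean
      l$rvar <- ck$state[[k]]$rvar
    }
  }
  model
}
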