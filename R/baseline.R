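# Classical pixel-classification baseline: a bank of texture and edge
# filters on the grayscale image feeds a per-pixel random forest.

FILTER_NAMES <- c("gabor", "canny", "sobel", "scharr", "roberts", "prewitt",
                  "gaussian", "median")

#' Filter-bank configuration
#'
#' @param gabor_frequencies Spatial frequencies (cycles/pixel) of the Gabor
#'   grid.
#' @param gabor_orientations Orientations in degrees.
#' @param gaussian_sigmas Gaussian blur scales (pixels).
#' @param median_window Median filter window side (odd).
#' @param include Subset of
#'   `c("gabor", "canny", "sobel", "scharr", "roberts", "prewitt",
#'   "gaussian", "median")`.
#' @return An object of class `filter_bank_config`.
#' @export
filter_bank_config <- function(gabor_frequencies = c(0.1, 0.2, 0.4),
                               gabor_orientations = c(0, 45, 90, 135),
                               gaussian_sigmas = c(1, 2, 4),
                               median_window = 3L,
                               include = FILTER_NAMES) {
  unknown <- setdiff(include, FILTER_NAMES)
  if (length(unknown) > 0)
    stop("filter_bank_config: unknown filter name(s): ",
         paste(unknown, collapse = ", "))
  if (length(include) == 0) stop("filter_bank_config: include must be non-empty")
  if (any(gaussian_sigmas < 0) || median_window < 1)
    stop("filter_bank_config: windows and sigmas must be positive")
  structure(list(gabor_frequencies = gabor_frequencies,
                 gabor_orientations = gabor_orientations,
                 gaussian_sigmas = gaussian_sigmas,
                 median_window = as.integer(median_window),
                 include = include),
            class = "filter_bank_config")
}

to_gray <- function(image) {
  if (length(dim(image)) == 2L) return(image)
  0.2989 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

pad_replicate <- function(x, pr, pc) {
  ri <- c(rep(1L, pr), seq_len(nrow(x)), rep(nrow(x), pr))
  ci <- c(rep(1L, pc), seq_len(ncol(x)), rep(ncol(x), pc))
  x[ri, ci]
}

# Convolve a single-channel image with one kernel (same size output,
# edge-replicate padding so uniform regions stay uniform at the borders).
convolve_plane <- function(x, kernel) {
  pr <- nrow(kernel) - 1L
  pc <- ncol(kernel) - 1L
  xp <- pad_replicate(x, pr, pc)
  xa <- array(xp, dim = c(dim(xp), 1L, 1L))
  ka <- array(kernel, dim = c(dim(kernel), 1L, 1L))
  out <- matrix(cpp_conv2d_forward(xa, ka, 0, 1L), nrow(xp), ncol(xp))
  out[pr + seq_len(nrow(x)), pc + seq_len(ncol(x)), drop = FALSE]
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  g <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

gabor_kernel <- function(frequency, theta_deg, sigma = 0.56 / frequency) {
  r <- max(2L, ceiling(3 * sigma))
  th <- theta_deg * pi / 180
  xy <- expand.grid(y = -r:r, x = -r:r)
  xr <- xy$x * cos(th) + xy$y * sin(th)
  yr <- -xy$x * sin(th) + xy$y * cos(th)
  env <- exp(-(xr^2 + yr^2) / (2 * sigma^2))
  matrix(env * cos(2 * pi * frequency * xr), nrow = 2 * r + 1)
}

grad_magnitude <- function(x, kx) {
  gx <- convolve_plane(x, kx)
  gy <- convolve_plane(x, t(kx))
  sqrt(gx^2 + gy^2)
}

sobel_k <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, byrow = TRUE)
scharr_k <- matrix(c(-3, -10, -3, 0, 0, 0, 3, 10, 3), 3, byrow = TRUE)
prewitt_k <- matrix(c(-1, -1, -1, 0, 0, 0, 1, 1, 1), 3, byrow = TRUE)

roberts_magnitude <- function(x) {
  k1 <- matrix(c(1, 0, 0, -1), 2)
  k2 <- matrix(c(0, 1, -1, 0), 2)
  sqrt(convolve_plane(x, k1)^2 + convolve_plane(x, k2)^2)
}

# Basic Canny edge detector: Gaussian smoothing, Sobel gradients,
# non-maximum suppression along the quantized gradient direction, double
# threshold with hysteresis (weak edges kept only in components that touch
# a strong edge).
canny_edges <- function(x, sigma = 1.4, low_q = 0.8, high_q = 0.93) {
  s <- convolve_plane(x, gaussian_kernel(sigma))
  gx <- convolve_plane(s, sobel_k)
  gy <- convolve_plane(s, t(sobel_k))
  mag <- sqrt(gx^2 + gy^2)
  H <- nrow(x); W <- ncol(x)
  if (max(mag) < 1e-8 * max(1, max(abs(s))))  # flat image: no edges
    return(matrix(0, H, W))
  ang <- atan2(gy, gx)
  sector <- (round(ang / (pi / 4)) %% 4)  # 0:E-W 1:NE-SW 2:N-S 3:NW-SE
  pad <- matrix(0, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- mag
  off <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  keep <- matrix(TRUE, H, W)
  for (sct in 0:3) {
    d <- off[[sct + 1]]
    n1 <- pad[2:(H + 1) + d[1], 2:(W + 1) + d[2]]
    n2 <- pad[2:(H + 1) - d[1], 2:(W + 1) - d[2]]
    sel <- sector == sct
    keep[sel] <- mag[sel] >= n1[sel] & mag[sel] >= n2[sel]
  }
  nms <- mag * keep
  pos <- nms[nms > 0]
  if (length(pos) == 0) return(matrix(0, H, W))
  lo <- stats::quantile(pos, low_q, names = FALSE)
  hi <- stats::quantile(pos, high_q, names = FALSE)
  weak <- matrix(as.integer(nms >= lo), H, W)
  strong <- nms >= hi
  lab <- cpp_label_components(weak)
  good <- unique(lab[strong & lab > 0])
  matrix(as.numeric(lab %in% good & weak > 0), H, W)
}

#' Extract per-pixel filter-bank features
#'
#' Converts the image to grayscale and stacks one response plane per
#' enabled filter: raw intensity, Gabor responses over the frequency by
#' orientation grid, a Canny edge map, Sobel/Scharr/Roberts/Prewitt
#' gradient magnitudes, Gaussian blurs per sigma, and a median filter.
#' Planes are flattened to a pixel-by-feature table (column-major pixel
#' order).
#'
#' @param image H x W x 3 image (0-255) or H x W grayscale.
#' @param config A [filter_bank_config()].
#' @return An object of class `pixel_feature_table`: list with `features`
#'   (matrix, H*W rows) and `shape`.
#' @export
extract_features <- function(image, config = filter_bank_config()) {
  g <- to_gray(image)
  planes <- list(gray = g)
  inc <- config$include
  if ("gabor" %in% inc)
    for (f in config$gabor_frequencies)
      for (o in config$gabor_orientations)
        planes[[sprintf("gabor_f%g_o%g", f, o)]] <-
          convolve_plane(g, gabor_kernel(f, o))
  if ("canny" %in% inc) planes$canny <- canny_edges(g)
  if ("sobel" %in% inc) planes$sobel <- grad_magnitude(g, sobel_k)
  if ("scharr" %in% inc) planes$scharr <- grad_magnitude(g, scharr_k)
  if ("roberts" %in% inc) planes$roberts <- roberts_magnitude(g)
  if ("prewitt" %in% inc) planes$prewitt <- grad_magnitude(g, prewitt_k)
  if ("gaussian" %in% inc)
    for (s in config$gaussian_sigmas)
      planes[[sprintf("gaussian_s%g", s)]] <-
        if (s < 0.15) g else convolve_plane(g, gaussian_kernel(s))
  if ("median" %in% inc)
    planes$median <- cpp_median_filter(g, config$median_window)
  feat <- do.call(cbind, lapply(planes, as.numeric))
  structure(list(features = feat, shape = dim(g)), class = "pixel_feature_table")
}

#' Train the random-forest pixel classifier
#'
#' @param features A [extract_features()] table, or a plain matrix with one
#'   row per pixel.
#' @param labels Per-pixel labels in \{0, 1\}, aligned with the rows.
#' @param n_trees Number of trees.
#' @param seed Integer seed (the forest is fully reproducible given the
#'   data and seed).
#' @param sample_cap Per-class cap on training pixels (balanced
#'   subsampling keeps memory at desk scale); `Inf` disables it.
#' @return An object of class `pixel_rf`.
#' @export
train_pixel_classifier <- function(features, labels, n_trees = 100L, seed = 42L,
                                   sample_cap = 20000L) {
  feat <- if (inherits(features, "pixel_feature_table")) features$features
  else features
  labels <- as.integer(labels)
  if (nrow(feat) != length(labels))
    stop("train_pixel_classifier: features and labels are not aligned")
  if (length(unique(labels)) < 2L)
    stop("train_pixel_classifier: labels contain a single class")
  keep <- with_seed(seed, {
    unlist(lapply(c(0L, 1L), function(cl) {
      idx <- which(labels == cl)
      if (length(idx) > sample_cap) sample(idx, sample_cap) else idx
    }))
  })
  df <- as.data.frame(feat[keep, , drop = FALSE])
  df$.label <- factor(labels[keep], levels = c(0L, 1L))
  fit <- ranger::ranger(.label ~ ., data = df, num.trees = n_trees,
                        probability = TRUE, seed = seed,
                        num.threads = 1L)
  structure(list(forest = fit, feature_names = colnames(feat),
                 n_trees = as.integer(n_trees), seed = as.integer(seed)),
            class = "pixel_rf")
}

#' Convenience trainer over labeled tiles
#'
#' Extracts features from every tile, pools pixels (balanced per class via
#' `sample_cap`), and fits the forest.
#'
#' @param tiles List of `labeled_tile` records.
#' @param config A [filter_bank_config()]; stored in the model so that
#'   prediction uses identical features.
#' @inheritParams train_pixel_classifier
#' @return A `pixel_rf` model carrying its `config`.
#' @export
fit_pixel_rf <- function(tiles, config = filter_bank_config(), n_trees = 100L,
                         seed = 42L, sample_cap = 20000L) {
  feats <- do.call(rbind, lapply(tiles, function(t)
    extract_features(t$image, config)$features))
  labels <- unlist(lapply(tiles, function(t) as.integer(t$mask)))
  model <- train_pixel_classifier(feats, labels, n_trees, seed, sample_cap)
  model$config <- config
  model
}

rf_prob_plane <- function(model, image, config) {
  ft <- extract_features(image, config)
  if (!is.null(model$feature_names) &&
      ncol(ft$features) != length(model$feature_names))
    stop(sprintf(
      "pixel_rf: feature dimension mismatch (%d planes here, %d at training)",
      ncol(ft$features), length(model$feature_names)))
  pr <- stats::predict(model$forest, data = as.data.frame(ft$features),
                       num.threads = 1L)$predictions
  matrix(pr[, "1"], nrow = ft$shape[1])
}

#' Predict a binary nuclei mask with the random-forest baseline
#'
#' @param model A [train_pixel_classifier()] / [fit_pixel_rf()] model.
#' @param image H x W x 3 image (0-255).
#' @param config Filter configuration; must match training (defaults to
#'   the one stored in the model).
#' @param threshold Vote threshold.
#' @return H x W integer mask in \{0, 1\}.
#' @export
predict_mask_rf <- function(model, image, config = model$config,
                            threshold = 0.5) {
  stopifnot(inherits(model, "pixel_rf"))
  if (is.null(config)) config <- filter_bank_config()
  pr <- rf_prob_plane(model, image, config)
  matrix(as.integer(pr >= threshold), nrow = nrow(pr))
}

#' @rdname predict_probs
#' @export
predict_probs.pixel_rf <- function(model, images, ...) {
  config <- if (is.null(model$config)) filter_bank_config() else model$config
  images <- as_batch4(images)
  d <- dim(images)
  out <- array(0, dim = c(d[1], d[2], d[4]))
  for (k in seq_len(d[4]))
    out[, , k] <- rf_prob_plane(model, images[, , , k] * 255, config)
  out
}
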