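#' Stain-normalization parameters
#'
#' Parameters of the optical-density (OD) stain normalization used before
#' patching. Pixels are mapped to OD via Beer-Lambert, tissue pixels are
#' projected onto the plane of their top-2 principal OD directions, and
#' the hematoxylin/eosin stain vectors are taken at extreme percentile
#' angles within that plane; concentrations are then rescaled to a target
#' appearance.
#'
#' @param od_threshold Transparency cutoff beta: pixels with OD magnitude
#'   below it count as background, not tissue.
#' @param angular_percentile alpha: the stain vectors are the alpha-th and
#'   (100 - alpha)-th percentile angles of the projected tissue pixels.
#' @param target_stain_matrix 2 x 3 matrix of unit-norm OD vectors
#'   (hematoxylin row first). Default: the widely used H&E reference,
#'   H = (0.65, 0.70, 0.29), E = (0.07, 0.99, 0.11), unit-normalized.
#' @param target_max_concentrations Robust (99th percentile) concentration
#'   maxima the two stains are scaled to.
#' @param white_level Intensity of unstained background (I0).
#' @return An object of class `stain_params`.
#' @export
stain_params <- function(od_threshold = 0.15, angular_percentile = 1,
                         target_stain_matrix = NULL,
                         target_max_concentrations = c(1.9705, 1.0308),
                         white_level = 255) {
  if (od_threshold <= 0) stop("stain_params: od_threshold must be positive")
  if (angular_percentile <= 0 || angular_percentile >= 50)
    stop("stain_params: angular_percentile must be in (0, 50)")
  if (is.null(target_stain_matrix))
    target_stain_matrix <- rbind(c(0.65, 0.70, 0.29), c(0.07, 0.99, 0.11))
  target_stain_matrix <- target_stain_matrix /
    sqrt(rowSums(target_stain_matrix^2))
  structure(list(od_threshold = od_threshold,
                 angular_percentile = angular_percentile,
                 target_stain_matrix = target_stain_matrix,
                 target_max_concentrations = as.numeric(target_max_concentrations),
                 white_level = white_level),
            class = "stain_params")
}

#' Convert between RGB intensity and optical density
#'
#' `OD = -log10((I + eps) / white_level)` with a small epsilon guarding
#' zero intensities; the inverse clips to [0, white_level].
#'
#' @param image Array of intensities in [0, white_level].
#' @param white_level Unstained intensity I0.
#' @return Array of the same shape.
#' @export
rgb_to_od <- function(image, white_level = 255) {
  eps <- 1e-6 * white_level
  -log10((image + eps) / white_level)
}

#' @rdname rgb_to_od
#' @param od Optical-density array.
#' @export
od_to_rgb <- function(od, white_level = 255) {
  pmin(pmax(white_level * 10^(-od), 0), white_level)
}

cond_no_tissue <- function(msg) {
  structure(class = c("dcsanet_no_tissue", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

#' Estimate the stain matrix of an H&E image
#'
#' Tissue pixels (OD magnitude above the threshold) are projected onto the
#' plane spanned by the top-2 principal directions of their OD covariance;
#' the two stain directions are the `alpha`-th and `(100 - alpha)`-th
#' percentile angles within that plane, mapped back to unit-norm 3-vectors.
#' The hematoxylin row is the direction with the larger blue-channel OD
#' component.
#'
#' @param image H x W x 3 array in [0, white_level].
#' @param params A [stain_params()].
#' @return 2 x 3 matrix with unit-norm rows (hematoxylin first).
#' @export
estimate_stain_matrix <- function(image, params = stain_params()) {
  od <- matrix(rgb_to_od(image, params$white_level), ncol = 3)
  tissue <- od[sqrt(rowSums(od^2)) > params$od_threshold, , drop = FALSE]
  if (nrow(tissue) < 100)
    stop(cond_no_tissue(sprintf(
      "estimate_stain_matrix: only %d tissue pixels above OD threshold %.3g",
      nrow(tissue), params$od_threshold)))
  ev <- eigen(stats::cov(tissue), symmetric = TRUE)
  basis <- ev$vectors[, 1:2]  # 3 x 2 plane of top-2 principal directions
  proj <- tissue %*% basis
  # orient the basis so projections lie in a consistent half-plane
  if (sum(proj[, 1]) < 0) { basis[, 1] <- -basis[, 1]; proj[, 1] <- -proj[, 1] }
  if (sum(proj[, 2]) < 0) { basis[, 2] <- -basis[, 2]; proj[, 2] <- -proj[, 2] }
  phi <- atan2(proj[, 2], proj[, 1])
  a <- params$angular_percentile / 100
  q <- stats::quantile(phi, c(a, 1 - a), names = FALSE)
  v <- rbind(as.numeric(basis %*% c(cos(q[1]), sin(q[1]))),
             as.numeric(basis %*% c(cos(q[2]), sin(q[2]))))
  v <- v * ifelse(rowSums(v) < 0, -1, 1)   # stain vectors have nonnegative OD
  v <- v / sqrt(rowSums(v^2))
  if (v[1, 3] >= v[2, 3]) v else v[2:1, , drop = FALSE]  # hematoxylin first
}

#' Normalize an H&E tile to the target stain appearance
#'
#' Solves per-pixel stain concentrations against the estimated source
#' matrix by least squares (clipped at zero), rescales each stain so its
#' 99th-percentile concentration matches the target maximum, and
#' recomposes the image with the target stain matrix.
#'
#' @param image H x W x 3 array in [0, white_level].
#' @param params A [stain_params()].
#' @return Normalized H x W x 3 array (rounded, 0-255 scale).
#' @export
stain_normalize <- function(image, params = stain_params()) {
  src <- estimate_stain_matrix(image, params)
  od <- matrix(rgb_to_od(image, params$white_level), ncol = 3)
  conc <- od %*% t(src) %*% solve(src %*% t(src))  # least squares, n x 2
  conc[conc < 0] <- 0
  src_max <- apply(conc, 2, stats::quantile, probs = 0.99)
  src_max[src_max < 1e-8] <- 1e-8
  conc <- sweep(conc, 2, params$target_max_concentrations / src_max, `*`)
  od_new <- conc %*% params$target_stain_matrix
  out <- round(od_to_rgb(od_new, params$white_level))
  array(out, dim = dim(image))
}

#' Normalize a batch of tiles, passing blank tiles through
#'
#' Tiles without enough tissue pixels (e.g. all-white) are returned
#' unchanged with a warning instead of aborting the pipeline.
#'
#' @param images List of H x W x 3 arrays.
#' @param params A [stain_params()].
#' @return List of normalized arrays.
#' @export
stain_normalize_batch <- function(images, params = stain_params()) {
  lapply(seq_along(images), function(i)
    tryCatch(stain_normalize(images[[i]], params),
             dcsanet_no_tissue = function(e) {
               warning(sprintf("tile %d passed through unnormalized: %s",
                               i, conditionMessage(e)))
               images[[i]]
             }))
}

#' Derive normalization targets from a reference tile
#'
#' Estimates the stain matrix and robust maximum concentrations of a
#' reference image and returns a [stain_params()] whose targets reproduce
#' that appearance.
#'
#' @param image H x W x 3 reference tile in [0, white_level].
#' @param params Base parameters (thresholds, percentiles, white level).
#' @return A [stain_params()] with targets taken from the reference.
#' @export
stain_params_from_reference <- function(image, params = stain_params()) {
  S <- estimate_stain_matrix(image, params)
  od <- matrix(rgb_to_od(image, params$white_level), ncol = 3)
  conc <- od %*% t(S) %*% solve(S %*% t(S))
  conc[conc < 0] <- 0
  params$target_stain_matrix <- S
  params$target_max_concentrations <- apply(conc, 2, stats::quantile, probs = 0.99)
  params
}
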