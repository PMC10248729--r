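#' Specification for synthetic H&E-like tiles
#'
#' Describes a generator of toy histology tiles: filled ellipses with a
#' hematoxylin-like dark blue-violet mean color on an eosin-like pink
#' background, per-object color jitter, additive Gaussian pixel noise, and
#' a paired binary ground-truth mask (union of the ellipse interiors).
#' Defaults mimic a 512 x 512 prostate-tissue crop carrying on the order
#' of two hundred round-to-oval nuclei.
#'
#' @param height,width Tile size in pixels (> 0).
#' @param n_nuclei_range Integer interval for the nucleus count (lower
#'   bound >= 0).
#' @param radius_range Interval for the ellipse semi-axes in pixels (lower
#'   bound >= 2).
#' @param nucleus_color_mean,background_color_mean RGB triples (0-255).
#' @param color_jitter_sd Per-channel SD of the per-object color draw.
#' @param noise_sd SD of the additive per-pixel noise.
#' @param allow_overlap If `FALSE`, nuclei are rejection-sampled so that no
#'   two masks touch (even diagonally); if `TRUE`, overlapping nuclei merge
#'   into one mask region.
#' @param seed Optional default seed used when [generate_tile()] is called
#'   without one.
#' @return An object of class `synthetic_tile_spec`.
#' @export
synthetic_tile_spec <- function(height = 512L, width = 512L,
                                n_nuclei_range = c(150L, 250L),
                                radius_range = c(4, 12),
                                nucleus_color_mean = c(90, 60, 150),
                                background_color_mean = c(230, 180, 200),
                                color_jitter_sd = 12, noise_sd = 8,
                                allow_overlap = TRUE, seed = NULL) {
  if (height <= 0L || width <= 0L)
    stop("synthetic_tile_spec: height and width must be positive")
  if (radius_range[1] < 2)
    stop("synthetic_tile_spec: radius_range lower bound must be >= 2 px")
  if (n_nuclei_range[1] < 0L)
    stop("synthetic_tile_spec: n_nuclei_range lower bound must be >= 0")
  structure(list(
    height = as.integer(height), width = as.integer(width),
    n_nuclei_range = as.integer(n_nuclei_range),
    radius_range = as.numeric(radius_range),
    nucleus_color_mean = as.numeric(nucleus_color_mean),
    background_color_mean = as.numeric(background_color_mean),
    color_jitter_sd = as.numeric(color_jitter_sd),
    noise_sd = as.numeric(noise_sd),
    allow_overlap = isTRUE(allow_overlap),
    seed = seed
  ), class = "synthetic_tile_spec")
}

# Rasterize one rotated ellipse; returns row/col indices of interior pixels.
rasterize_ellipse <- function(cy, cx, a, b, theta, height, width) {
  r <- max(a, b)
  rows <- max(1L, floor(cy - r)):min(height, ceiling(cy + r))
  cols <- max(1L, floor(cx - r)):min(width, ceiling(cx + r))
  dy <- rows - cy
  dx <- cols - cx
  ct <- cos(theta); st <- sin(theta)
  u <- outer(dy, dx, function(y, x) (x * ct + y * st) / a)
  v <- outer(dy, dx, function(y, x) (-x * st + y * ct) / b)
  inside <- which(u * u + v * v <= 1, arr.ind = TRUE)
  cbind(rows[inside[, 1]], cols[inside[, 2]])
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Generate one synthetic labeled tile
#'
#' Draws the nucleus count, then for each nucleus a center, semi-axes and
#' rotation; rasterizes the ellipses into the mask; paints the image around
#' the two color means with per-object jitter; adds Gaussian pixel noise
#' and clips to [0, 255]. Identical `(spec, seed)` pairs give bit-identical
#' output.
#'
#' @param spec A [synthetic_tile_spec()].
#' @param seed Integer seed (falls back to `spec$seed`).
#' @return An object of class `labeled_tile`: list with `image`
#'   (H x W x 3, 0-255) and `mask` (H x W in \{0, 1\}); the sampled ellipse
#'   parameters are attached as attribute `"nuclei"`.
#' @export
generate_tile <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_tile_spec"))
  with_seed(seed, {
    H <- spec$height; W <- spec$width
    n <- if (spec$n_nuclei_range[1] == spec$n_nuclei_range[2])
      spec$n_nuclei_range[1]
    else sample(spec$n_nuclei_range[1]:spec$n_nuclei_range[2], 1L)
    mask <- matrix(0L, H, W)
    image <- array(rep(spec$background_color_mean, each = H * W), dim = c(H, W, 3))
    nuclei <- list()
    placed <- 0L
    attempts <- 0L
    max_attempts <- max(200L, 60L * n)
    while (placed < n && attempts < max_attempts) {
      attempts <- attempts + 1L
      cy <- stats::runif(1, 1, H)
      cx <- stats::runif(1, 1, W)
      ab <- stats::runif(2, spec$radius_range[1], spec$radius_range[2])
      theta <- stats::runif(1, 0, pi)
      px <- rasterize_ellipse(cy, cx, ab[1], ab[2], theta, H, W)
      if (nrow(px) == 0L) next
      if (!spec$allow_overlap) {
        # forbid 8-adjacency with existing nuclei so components stay distinct
        halo <- rasterize_ellipse(cy, cx, ab[1] + 1.6, ab[2] + 1.6, theta, H, W)
        if (any(mask[halo] == 1L)) next
      }
      mask[px] <- 1L
      col <- spec$nucleus_color_mean + stats::rnorm(3, 0, spec$color_jitter_sd)
      for (ch in 1:3) {
        plane <- image[, , ch]
        plane[px] <- col[ch]
        image[, , ch] <- plane
      }
      nuclei[[length(nuclei) + 1L]] <-
        c(cy = cy, cx = cx, a = ab[1], b = ab[2], theta = theta)
      placed <- placed + 1L
    }
    if (placed < n)
      warning(sprintf("generate_tile: placed %d of %d nuclei (tile too crowded)",
                      placed, n))
    image <- image + array(stats::rnorm(H * W * 3, 0, spec$noise_sd), dim = dim(image))
    image <- round(pmin(pmax(image, 0), 255))
    tile <- structure(list(image = image, mask = mask), class = "labeled_tile")
    attr(tile, "nuclei") <- do.call(rbind, nuclei)
    tile
  })
}

#' Generate a dataset of synthetic labeled tiles
#'
#' Tile `i` uses the deterministic per-tile seed `seed + i - 1`, so any
#' subset of the dataset is reproducible independently.
#'
#' @param n_tiles Number of tiles (>= 0).
#' @param spec A [synthetic_tile_spec()].
#' @param seed Master seed.
#' @return List of [generate_tile()] results.
#' @export
generate_dataset <- function(n_tiles, spec, seed = 42L) {
  stopifnot(n_tiles >= 0L)
  lapply(seq_len(n_tiles), function(i) generate_tile(spec, seed = seed + i - 1L))
}
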