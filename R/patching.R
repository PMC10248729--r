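#' Sliding-window patch grid
#'
#' Computes the deterministic set of top-left window origins for a tile:
#' all `(i*stride, j*stride)` with the `patch_size` window fully inside the
#' image, ordered row-major (left to right, top to bottom). Coordinates are
#' 0-based and windows are half-open. For the standard geometry — 512 x 512
#' tiles, 128-pixel patches, stride 64 — this gives 7 x 7 = 49 windows per
#' tile. Trailing pixels beyond the last full window are dropped.
#'
#' @param height,width Image size in pixels.
#' @param patch_size Window side p (<= min(height, width)).
#' @param stride Grid spacing s (>= 1).
#' @return An object of class `patch_grid` with fields `patch_size`,
#'   `stride`, `height`, `width`, and `coords` (n x 2 matrix of 0-based
#'   (row, col) origins).
#' @export
compute_grid <- function(height, width, patch_size = 128L, stride = 64L) {
  if (patch_size > min(height, width))
    stop(sprintf("compute_grid: patch size %d exceeds image size %d x %d",
                 patch_size, height, width))
  if (stride < 1L) stop("compute_grid: stride must be >= 1")
  ri <- seq(0L, height - patch_size, by = stride)
  ci <- seq(0L, width - patch_size, by = stride)
  coords <- cbind(row = rep(ri, each = length(ci)),
                  col = rep(ci, times = length(ri)))
  structure(list(patch_size = as.integer(patch_size), stride = as.integer(stride),
                 height = as.integer(height), width = as.integer(width),
                 coords = coords),
            class = "patch_grid")
}

#' Extract patches from a tile
#'
#' @param tile H x W matrix (mask) or H x W x C array (image).
#' @param grid A [compute_grid()] for the tile's size.
#' @return An object of class `patch_set`: list with `patches` (list of
#'   p x p (x C) arrays), `grid`, and `source_shape`.
#' @export
extract_patches <- function(tile, grid) {
  stopifnot(inherits(grid, "patch_grid"))
  d <- dim(tile)
  if (d[1] != grid$height || d[2] != grid$width)
    stop(sprintf("extract_patches: tile is %d x %d but grid was computed for %d x %d",
                 d[1], d[2], grid$height, grid$width))
  p <- grid$patch_size
  patches <- lapply(seq_len(nrow(grid$coords)), function(k) {
    r <- grid$coords[k, 1]; c <- grid$coords[k, 2]
    if (length(d) == 2L) tile[(r + 1):(r + p), (c + 1):(c + p)]
    else tile[(r + 1):(r + p), (c + 1):(c + p), , drop = FALSE]
  })
  structure(list(patches = patches, grid = grid, source_shape = d[1:2]),
            class = "patch_set")
}

#' Merge predicted patches into a full-tile map
#'
#' Reassembles per-patch predictions to the source shape. Where windows
#' overlap, predictions are fused per pixel by the arithmetic mean (the
#' default) or the maximum. Every pixel of the source must be covered by at
#' least one window.
#'
#' @param patchset A `patch_set` whose patches are p x p (probability) maps.
#' @param reduce `"mean"` or `"max"`.
#' @return H x W matrix.
#' @export
merge_patches <- function(patchset, reduce = c("mean", "max")) {
  stopifnot(inherits(patchset, "patch_set"))
  reduce <- match.arg(reduce)
  grid <- patchset$grid
  p <- grid$patch_size
  H <- patchset$source_shape[1]; W <- patchset$source_shape[2]
  acc <- matrix(if (reduce == "mean") 0 else -Inf, H, W)
  cover <- matrix(0L, H, W)
  for (k in seq_len(nrow(grid$coords))) {
    r <- grid$coords[k, 1]; c <- grid$coords[k, 2]
    ri <- (r + 1):(r + p); ci <- (c + 1):(c + p)
    pk <- patchset$patches[[k]]
    if (length(dim(pk)) > 2L) pk <- array(pk, dim = dim(pk)[1:2])
    if (reduce == "mean") acc[ri, ci] <- acc[ri, ci] + pk
    else acc[ri, ci] <- pmax(acc[ri, ci], pk)
    cover[ri, ci] <- cover[ri, ci] + 1L
  }
  if (any(cover == 0L)) {
    miss <- which(cover == 0L, arr.ind = TRUE)[1, ]
    stop(sprintf("merge_patches: pixel (%d, %d) not covered by any window (0-based)",
                 miss[1] - 1L, miss[2] - 1L))
  }
  if (reduce == "mean") acc / cover else acc
}

# ---- image and mask I/O -----------------------------------------------------

read_image_raw <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image format: .", ext))
  img
}

#' Read / write an RGB tile
#'
#' PNG or TIFF by extension; pixels are returned on the 0-255 scale.
#' @param path File path.
#' @return H x W x 3 array in 0-255.
#' @export
read_tile <- function(path) {
  img <- read_image_raw(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3L))
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  round(img * 255)
}

#' @rdname read_tile
#' @param image H x W x 3 array in 0-255.
#' @export
write_tile <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  img <- pmin(pmax(image / 255, 0), 1)
  switch(ext,
         png = png::writePNG(img, path),
         tif = ,
         tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
         stop("unsupported image format: .", ext))
  invisible(path)
}

#' Read / write a binary nuclei mask
#'
#' Masks are stored on disk with intensities 0 and 255 (the annotation file
#' convention) and handled in memory as \{0, 1\}. Any other intensity in the
#' file is a corrupt mask and raises an error.
#'
#' @param path File path (PNG or TIFF).
#' @return H x W integer matrix in \{0, 1\}.
#' @export
read_mask <- function(path) {
  img <- read_image_raw(path)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
    spread <- 0
    for (ch in seq_len(dim(img)[3]))
      spread <- max(spread, max(abs(img[, , ch] - img[, , 1])))
    if (spread > 1e-9)
      stop("read_mask: multi-channel mask with unequal channels is not collapsible")
    img <- img[, , 1]
  }
  vals <- round(img * 255)
  bad <- setdiff(unique(as.vector(vals)), c(0, 255))
  if (length(bad) > 0)
    stop(sprintf("read_mask: corrupt mask, non-binary intensity %s in %s",
                 paste(bad[seq_len(min(3, length(bad)))], collapse = ", "), path))
  matrix(as.integer(vals == 255), nrow = nrow(vals))
}

#' @rdname read_mask
#' @param mask H x W matrix in \{0, 1\}.
#' @export
write_mask <- function(mask, path) {
  if (!all(mask %in% c(0L, 1L)))
    stop("write_mask: mask must contain only 0 and 1")
  ext <- tolower(tools::file_ext(path))
  img <- matrix(as.numeric(mask), nrow = nrow(mask))
  switch(ext,
         png = png::writePNG(img, path),
         tif = ,
         tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
         stop("unsupported image format: .", ext))
  invisible(path)
}
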