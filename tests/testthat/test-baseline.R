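test_that("edge filters vanish on a constant image", {
  img <- array(128, c(32, 32, 3))
  ft <- extract_features(img)
  f <- ft$features
  for (nm in c("canny", "sobel", "scharr", "roberts", "prewitt"))
    expect_true(all(abs(f[, nm]) < 1e-9), info = nm)
  # smoothing filters reproduce the constant
  g0 <- f[1, "gray"]
  expect_true(all(abs(f[, "median"] - g0) < 1e-9))
})

test_that("the feature table has one column per enabled response plane", {
  img <- generate_tile(tiny_tile_spec(size = 32L), seed = 1L)$image
  cfg <- filter_bank_config()
  ft <- extract_features(img, cfg)
  want <- 1 +                                    # gray
    length(cfg$gabor_frequencies) * length(cfg$gabor_orientations) +
    1 +                                          # canny
    4 +                                          # sobel/scharr/roberts/prewitt
    length(cfg$gaussian_sigmas) +
    1                                            # median
  expect_equal(ncol(ft$features), want)
  expect_equal(nrow(ft$features), 32 * 32)
  # subsets shrink the table
  small <- extract_features(img, filter_bank_config(include = c("sobel", "median")))
  expect_equal(ncol(small$features), 3L)
})

test_that("a vanishing Gaussian scale returns the input", {
  img <- generate_tile(tiny_tile_spec(size = 32L), seed = 2L)$image
  cfg <- filter_bank_config(gaussian_sigmas = 0.01, include = "gaussian")
  ft <- extract_features(img, cfg)
  expect_equal(ft$features[, 2], ft$features[, 1])
})

test_that("configuration errors are caught early", {
  expect_error(filter_bank_config(include = "laplacian"), "unknown filter")
  expect_error(filter_bank_config(include = character(0)), "non-empty")
  expect_error(filter_bank_config(median_window = 0), "positive")
})

test_that("the forest separates trivially separable pixels and is seeded", {
  set.seed(6)
  labels <- rbinom(800, 1, 0.5)
  feats <- cbind(signal = labels + rnorm(800, 0, 0.01),
                 noise = rnorm(800))
  model <- train_pixel_classifier(feats, labels, n_trees = 50L, seed = 1L)
  pred <- stats::predict(model$forest, data = as.data.frame(feats),
                         num.threads = 1L)$predictions[, "1"]
  expect_equal(mean((pred >= 0.5) == (labels == 1)), 1.0)

  m2 <- train_pixel_classifier(feats, labels, n_trees = 50L, seed = 1L)
  p2 <- stats::predict(m2$forest, data = as.data.frame(feats),
                       num.threads = 1L)$predictions[, "1"]
  expect_identical(pred, p2)

  expect_error(train_pixel_classifier(feats, rep(1L, 800)), "single class")
  expect_error(train_pixel_classifier(feats, labels[1:10]), "not aligned")
})

test_that("the pixel forest learns the toy segmentation task", {
  spec <- tiny_tile_spec(size = 128L, n = c(8L, 14L))
  train_tiles <- generate_dataset(2L, spec, seed = 90L)
  test_tile <- generate_tile(spec, seed = 99L)
  model <- fit_pixel_rf(train_tiles, n_trees = 50L, seed = 4L,
                        sample_cap = 4000L)
  # memorization sanity: training tile dice near 1
  d_train <- dice_score(predict_mask_rf(model, train_tiles[[1]]$image),
                        train_tiles[[1]]$mask)
  expect_gt(d_train, 0.9)
  pred <- predict_mask_rf(model, test_tile$image)
  expect_equal(dim(pred), dim(test_tile$mask))
  expect_gt(dice_score(pred, test_tile$mask), 0.5)
  # feature-dimension mismatch against the training configuration
  expect_error(predict_mask_rf(model, test_tile$image,
                               config = filter_bank_config(include = "sobel")),
               "mismatch")
})

test_that("interior feature planes are translation-consistent", {
  tile <- generate_tile(tiny_tile_spec(size = 64L, n = c(6L, 10L)), seed = 8L)
  img <- tile$image
  dy <- 5L
  shifted <- img[c((dy + 1):64, 1:dy), , , drop = FALSE]  # cyclic row shift
  cfg <- filter_bank_config(include = c("sobel", "gaussian", "median"),
                            gaussian_sigmas = 1)
  a <- extract_features(img, cfg)
  b <- extract_features(shifted, cfg)
  fold <- function(ft, j) matrix(ft$features[, j], 64, 64)
  interior <- 16:48
  for (j in seq_len(ncol(a$features))) {
    pa <- fold(a, j)[interior + dy, interior]
    pb <- fold(b, j)[interior, interior]
    expect_equal(pb, pa, tolerance = 1e-9)
  }
})

test_that("the baseline plugs into the shared evaluation pipeline", {
  spec <- tiny_tile_spec(size = 128L, n = c(8L, 14L))
  model <- fit_pixel_rf(generate_dataset(1L, spec, seed = 91L),
                        n_trees = 30L, seed = 4L, sample_cap = 3000L)
  tiles <- list(generate_tile(spec, seed = 95L))
  rep_rf <- evaluate_model(model, tiles, patch_size = 64L, stride = 64L,
                           n_boot = 100L, seed = 1L)
  stub <- stub_model(function(img, k) matrix(0.4, nrow(img), ncol(img)))
  rep_stub <- evaluate_model(stub, tiles, patch_size = 64L, stride = 64L,
                             n_boot = 100L, seed = 1L)
  expect_identical(class(rep_rf), class(rep_stub))
  expect_identical(names(rep_rf$per_patch), names(rep_stub$per_patch))
  expect_identical(names(rep_rf$ci95), names(rep_stub$ci95))
  expect_equal(nrow(rep_rf$per_patch), 4L)
})
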