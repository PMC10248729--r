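test_that("accuracy follows the confusion-table definition", {
  y <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(seg_accuracy(y, y), 1.0)
  expect_equal(seg_accuracy(1 - y, y), 0.0)
  # 4x4: truth has 4 positives; prediction hits 3 of them plus 1 false positive
  truth <- matrix(0, 4, 4); truth[1, 1:4] <- 1
  pred <- matrix(0, 4, 4); pred[1, 1:3] <- 1; pred[2, 1] <- 1
  expect_equal(seg_accuracy(pred, truth), (3 + 11) / 16)
  expect_error(seg_accuracy(numeric(0), numeric(0)), "empty")
})

test_that("overlap scores follow their closed forms", {
  y <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(dice_score(y, y), 1.0, tolerance = 1e-6)
  expect_equal(jaccard_score(y, y), 1.0, tolerance = 1e-6)
  disjoint <- matrix(c(0, 0, 1, 1), 2, 2)
  expect_lt(dice_score(disjoint, y), 1e-6)
  # |truth| = |pred| = n with overlap n/2 -> dice 1/2, jaccard 1/3
  truth <- matrix(0, 4, 4); truth[1:2, 1] <- 1
  pred <- matrix(0, 4, 4); pred[2:3, 1] <- 1
  expect_equal(dice_score(pred, truth), 0.5, tolerance = 1e-6)
  expect_equal(jaccard_score(pred, truth), 1 / 3, tolerance = 1e-6)
  # both empty -> defined as 1 by the smoothing convention
  z <- matrix(0, 3, 3)
  expect_equal(dice_score(z, z), 1.0)
  expect_equal(jaccard_score(z, z), 1.0)
})

test_that("binary cross-entropy matches its closed form and oracle", {
  y <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_lt(bce_loss(y, y), 1e-5)
  expect_equal(bce_loss(matrix(0.5, 2, 2), y), log(2), tolerance = 1e-12)
  set.seed(10)
  for (rep in 1:5) {
    p <- matrix(runif(64), 8, 8)
    yy <- matrix(rbinom(64, 1, 0.5), 8, 8)
    expect_equal(bce_loss(p, yy), oracle_bce(p, yy), tolerance = 1e-12)
  }
})

test_that("all metrics match pixel-counting oracles on random pairs", {
  set.seed(11)
  for (rep in 1:25) {
    p <- matrix(runif(256), 16, 16)
    y <- matrix(rbinom(256, 1, runif(1, 0.1, 0.9)), 16, 16)
    o <- oracle_metrics(p, y)
    expect_equal(seg_accuracy(p, y), o$accuracy, tolerance = 1e-9)
    expect_equal(dice_score(p, y), o$dice, tolerance = 1e-6)
    expect_equal(jaccard_score(p, y), o$jaccard, tolerance = 1e-6)
  }
})

test_that("jaccard and dice obey J = D / (2 - D) and J <= D", {
  set.seed(12)
  for (rep in 1:25) {
    p <- matrix(rbinom(256, 1, 0.4), 16, 16)
    y <- matrix(rbinom(256, 1, 0.4), 16, 16)
    D <- dice_score(p, y)
    J <- jaccard_score(p, y)
    expect_equal(J, D / (2 - D), tolerance = 1e-5)
    expect_lte(J, D + 1e-12)
  }
})

test_that("accuracy is FP/FN symmetric but the overlap scores are not", {
  truth <- matrix(0, 4, 4); truth[1:2, 1:2] <- 1
  fp <- truth; fp[3, 3] <- 1          # one extra false positive
  fn <- truth; fn[1, 1] <- 0          # one false negative instead
  expect_equal(seg_accuracy(fp, truth), seg_accuracy(fn, truth))
  expect_false(isTRUE(all.equal(dice_score(fp, truth), dice_score(fn, truth))))
})

test_that("losses are complements and decrease toward the truth", {
  set.seed(13)
  p <- matrix(runif(64), 8, 8)
  y <- matrix(rbinom(64, 1, 0.5), 8, 8)
  expect_equal(dice_loss(p, y) + dice_score(p, y, soft = TRUE), 1)
  expect_equal(jaccard_loss(p, y) + jaccard_score(p, y, soft = TRUE), 1)
  expect_lt(dice_loss(y, y), 1e-6)
  # moving the prediction toward the truth lowers every loss
  y1 <- matrix(1, 1, 1)
  for (fn in list(dice_loss, jaccard_loss, bce_loss)) {
    expect_lt(fn(matrix(0.6, 1, 1), y1), fn(matrix(0.4, 1, 1), y1))
  }
})

test_that("the bootstrap interval is seeded, ordered, and centered", {
  expect_error(bootstrap_ci(1), "at least 2")
  same <- bootstrap_ci(rep(0.7, 10), seed = 1L)
  expect_equal(unname(same), c(0.7, 0.7))
  set.seed(14)
  for (rep in 1:20) {
    v <- runif(30)
    ci <- bootstrap_ci(v, n_boot = 200L, seed = rep)
    expect_lte(ci["low"], mean(v))
    expect_gte(ci["high"], mean(v))
  }
  v <- runif(10)
  expect_identical(bootstrap_ci(v, seed = 3L), bootstrap_ci(v, seed = 3L))
})

test_that("metric reports aggregate per-patch scores with ordered intervals", {
  set.seed(15)
  per <- data.frame(accuracy = runif(40, 0.9, 1), dice = runif(40, 0.6, 0.9),
                    jaccard = runif(40, 0.4, 0.8))
  rep <- metric_report(per, n_boot = 200L, seed = 2L)
  for (m in c("accuracy", "dice", "jaccard")) {
    expect_lte(rep$ci95[[m]]["low"], rep$mean[[m]])
    expect_gte(rep$ci95[[m]]["high"], rep$mean[[m]])
    expect_equal(rep$mean[[m]], 100 * mean(per[[m]]))
  }
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_report(rep, csv, js)
  back <- utils::read.csv(csv)
  expect_equal(back$dice, per$dice)
  summ <- jsonlite::read_json(js)
  expect_named(summ, c("accuracy", "dice", "jaccard"))
  expect_equal(summ$dice$mean, round(rep$mean[["dice"]], 1))
})
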