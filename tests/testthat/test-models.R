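# models: RF / k-NN / SVM learners, OOB, rebalancing, CV, C tuning.

test_that("rebalance_weights inverts class counts with equal class mass", {
  w <- rebalance_weights(c(active = 25, inactive = 49))
  expect_equal(unname(w["active"] / w["inactive"]), 49 / 25)
  expect_equal(unname(w["active"] * 25), unname(w["inactive"] * 49))
  expect_equal(unname(rebalance_weights(c(a = 10, b = 10))), c(1, 1))
  expect_error(rebalance_weights(c(a = 0, b = 5)), "empty class")
})

test_that("rf separates clean two-class blobs with high OOB accuracy", {
  blobs <- make_blobs(n_per = 50, p = 5, seed = 1)
  spec <- model_spec("rf", "classification", seed = 1, n_trees = 100)
  m <- fit_model(spec, blobs$X, blobs$labels)
  rep <- oob_report(m, blobs$labels)
  expect_gt(rep$raw["q"], 0.95)
  # determinism under the seed
  m2 <- fit_model(spec, blobs$X, blobs$labels)
  expect_identical(m$oob$votes, m2$oob$votes)
  # default mtry = floor(sqrt(p))
  expect_identical(m$fitted$mtry, 2L)
})

test_that("rf predictions expose vote-fraction probabilities", {
  blobs <- make_blobs(n_per = 30, p = 4, seed = 2)
  spec <- model_spec("rf", "classification", seed = 2, n_trees = 50)
  m <- fit_model(spec, blobs$X, blobs$labels)
  pr <- predict(m, blobs$X)
  expect_true(all(pr$probability >= 0 & pr$probability <= 1))
  expect_equal(unname(rowSums(pr$probability)), rep(1, 60))
  # far inside blob 1 every tree votes blob1 -> probability 1
  far <- matrix(0, 1, 4)
  expect_equal(unname(predict(m, far)$probability[1, "blob1"]), 1)
  expect_error(predict(m, matrix(0, 1, 3)), "dimension mismatch")
})

test_that("rf regression tracks a linear signal and OOB agrees with CV", {
  d <- gen_regression(regression_sim_config(n = 150, p = 12,
                                            k_informative = 4,
                                            binary_features = FALSE,
                                            noise_sd = 0.4, seed = 3))
  spec <- model_spec("rf", "regression", seed = 3, n_trees = 150)
  m <- fit_model(spec, d$X, d$y)
  oob <- oob_report(m, d$y)
  expect_gt(oob$r2, 0.5)
  cv <- cross_validate(spec, d$X, d$y, folds = 5, seed = 3)
  expect_lt(abs(cv$metrics$rmse - oob$rmse) / oob$rmse, 0.25)
  # default regression mtry = floor(p/3)
  expect_identical(m$fitted$mtry, 4L)
})

test_that("rf permutation importance singles out planted descriptors", {
  d <- gen_regression(regression_sim_config(n = 120, p = 30,
                                            k_informative = 3,
                                            beta = 1.5, seed = 4))
  spec <- model_spec("rf", "regression", seed = 4, n_trees = 200)
  m <- fit_model(spec, d$X, d$y)
  imp <- m$importance$permutation
  noise_q95 <- quantile(imp[-(1:3)], 0.95)
  expect_true(all(imp[1:3] > noise_q95))
})

test_that("knn obeys the zero-distance rule and equidistant averaging", {
  X <- matrix(c(0, 0, 1, 0, 0, 1, -1, 0, 0, -1), ncol = 2, byrow = TRUE)
  y <- c(10, 2, 4, 6, 8)
  spec <- model_spec("knn", "regression", k = 4)
  m <- fit_model(spec, X, y)
  # duplicate of a training point -> that point's y
  expect_equal(predict(m, X[1, , drop = FALSE])$prediction, 10)
  # k equidistant neighbours -> unweighted mean (weights equal)
  q <- matrix(c(10, 10), 1, 2)
  spec2 <- model_spec("knn", "regression", k = 5)
  m2 <- fit_model(spec2, X, y)
  d <- sqrt(rowSums(sweep(X, 2, c(10, 10))^2))
  w <- (1 / d) / sum(1 / d)
  expect_equal(predict(m2, q)$prediction, sum(w * y))
})

test_that("knn classification votes by inverse distance with probabilities", {
  blobs <- make_blobs(n_per = 25, p = 3, seed = 5)
  spec <- model_spec("knn", "classification", k = 10)
  m <- fit_model(spec, blobs$X, blobs$labels)
  pr <- predict(m, blobs$X)
  expect_equal(mean(pr$prediction == blobs$labels), 1)
  expect_equal(unname(rowSums(pr$probability)), rep(1, 50))
})

test_that("knn prediction at doubled k matches on a duplicated training set", {
  # duplicating the training set doubles each neighbour, so the neighbour
  # multiset (and prediction) is preserved when k doubles with it
  set.seed(6)
  X <- matrix(rnorm(40), 20, 2)
  y <- rnorm(20)
  q <- matrix(rnorm(10), 5, 2)
  m1 <- fit_model(model_spec("knn", "regression", k = 5), X, y)
  m2 <- fit_model(model_spec("knn", "regression", k = 10),
                  rbind(X, X), c(y, y))
  expect_equal(predict(m1, q)$prediction, predict(m2, q)$prediction)
  # k = 1 is invariant under duplication as-is
  m3 <- fit_model(model_spec("knn", "regression", k = 1), X, y)
  m4 <- fit_model(model_spec("knn", "regression", k = 1), rbind(X, X),
                  c(y, y))
  expect_equal(predict(m3, q)$prediction, predict(m4, q)$prediction)
})

test_that("svm classifies blobs and respects the probability contract", {
  blobs <- make_blobs(n_per = 50, p = 5, seed = 7)
  spec <- model_spec("svm", "classification", C = 10)
  m <- fit_model(spec, blobs$X, blobs$labels)
  pr <- predict(m, blobs$X)
  expect_gt(mean(pr$prediction == blobs$labels), 0.95)
  expect_true(all(pr$probability >= 0 & pr$probability <= 1))
  expect_equal(unname(rowSums(pr$probability)), rep(1, 100))
})

test_that("svm regression fits a smooth 1-d signal", {
  set.seed(8)
  x <- matrix(seq(-3, 3, length.out = 120))
  y <- sin(x[, 1]) + rnorm(120, sd = 0.05)
  spec <- model_spec("svm", "regression", C = 100, gamma = 1, epsilon = 0.05)
  m <- fit_model(spec, x, y)
  pr <- predict(m, x)$prediction
  expect_lt(sqrt(mean((pr - sin(x[, 1]))^2)), 0.15)
})

test_that("cross_validate stratifies folds and nails a perfect signal", {
  blobs <- make_blobs(n_per = 40, p = 4, seed = 9)
  spec <- model_spec("knn", "classification", k = 5)
  cv <- cross_validate(spec, blobs$X, blobs$labels, folds = 10, seed = 9)
  expect_equal(unname(cv$metrics$raw["q"]), 1)
  sizes <- table(cv$fold)
  expect_lte(max(sizes) - min(sizes), 1)
  # per-class stratification
  for (lv in levels(blobs$labels)) {
    per <- table(cv$fold[blobs$labels == lv])
    expect_lte(max(per) - min(per), 1)
  }
  cv2 <- cross_validate(spec, blobs$X, blobs$labels, folds = 10, seed = 9)
  expect_identical(cv$predictions, cv2$predictions)
  expect_error(cross_validate(spec, blobs$X, blobs$labels, folds = 1), "two folds")
})

test_that("50:50 rebalancing raises sensitivity on imbalanced data", {
  # 2:1 imbalance with a weak minority (positive) class signal
  sim <- gen_spectra(spectra_sim_config(
    n_active = 30, n_inactive = 60,
    p_informative_active = 0.7, p_informative_inactive = 0.3,
    p_background = 0.1, seed = 11))
  sch <- default_schemes()
  X <- build_matrix(sim$peaklists, sch$h, sch$c)$values
  y <- sim$labels
  spec_plain <- model_spec("rf", "classification", seed = 11, n_trees = 200)
  spec_w <- model_spec("rf", "classification", seed = 11, n_trees = 200,
                       class_weights = rebalance_weights(table(y)))
  se_plain <- oob_report(fit_model(spec_plain, X, y), y)$raw["se"]
  se_w <- oob_report(fit_model(spec_w, X, y), y)$raw["se"]
  expect_gt(se_w, se_plain)
})

test_that("tune_c picks the grid argmax with smallest-C tie-break", {
  blobs <- make_blobs(n_per = 20, p = 3, seed = 12)
  spec <- model_spec("svm", "classification")
  # single-point grid returns that C
  t1 <- tune_c(spec, blobs$X, blobs$labels, grid = 250, folds = 4, seed = 1)
  expect_equal(t1$best_C, 250)
  # perfectly separable: all C score 1 -> tie goes to the smallest C
  t2 <- tune_c(spec, blobs$X, blobs$labels, grid = c(10, 100, 1000),
               folds = 4, seed = 1)
  expect_equal(max(t2$results$score), 1)
  expect_equal(t2$best_C, 10)
  t3 <- tune_c(spec, blobs$X, blobs$labels, grid = c(10, 100, 1000),
               folds = 4, seed = 1)
  expect_identical(t2$results, t3$results)
  expect_error(tune_c(spec, blobs$X, blobs$labels, grid = numeric()), "empty")
})

test_that("model bundles persist and predictions export to CSV", {
  blobs <- make_blobs(n_per = 15, p = 3, seed = 13)
  m <- fit_model(model_spec("rf", "classification", seed = 13, n_trees = 30),
                 blobs$X, blobs$labels)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(predict(m2, blobs$X)$prediction,
                   predict(m, blobs$X)$prediction)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_predictions_csv(predict(m, blobs$X), rownames(blobs$X), csv)
  df <- read.csv(csv)
  expect_identical(nrow(df), 30L)
  expect_true(all(df$probability >= 0 & df$probability <= 1))
})

test_that("fit_model validates inputs", {
  blobs <- make_blobs(n_per = 10, p = 2, seed = 14)
  spec <- model_spec("rf", "classification", seed = 1, n_trees = 10)
  expect_error(fit_model(spec, blobs$X, rep("one", 20)), "two classes")
  X_bad <- blobs$X; X_bad[1, 1] <- NA
  expect_error(fit_model(spec, X_bad, blobs$labels), "finite")
  expect_error(fit_model(spec, blobs$X[1, , drop = FALSE],
                         blobs$labels[1]), "two samples")
})
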