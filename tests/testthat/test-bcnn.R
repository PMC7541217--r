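test_that("model building validates shape arithmetic", {
  full <- cnn_architecture()           # 4 clusters
  m <- build_model(full, 91, seed = 1)
  expect_s3_class(m, "bcnn_model")
  # side 8 collapses below 1x1 at the fourth pooling stage
  expect_error(build_model(full, 8), "cluster 4")
  expect_error(cnn_architecture(dropout_rate = 0), "dropout_rate")
  expect_error(cnn_architecture(kernel_sides = c(3, 3),
                                channel_depths = c(4, 8, 16)), "equal length")
})

test_that("softmax outputs are normalized and builds are seed-deterministic", {
  tp <- toy_patches(n = 6, side = 15, seed = 2)
  m1 <- build_model(desk_architecture(), 15, seed = 9)
  m2 <- build_model(desk_architecture(), 15, seed = 9)
  p1 <- predict_deterministic(m1, tp$X)
  p2 <- predict_deterministic(m2, tp$X)
  expect_identical(p1$prob_true, p2$prob_true)
  expect_true(all(p1$prob_true >= 0 & p1$prob_true <= 1))
  # full softmax rows sum to 1
  probs <- cephmark:::cpp_cnn_predict_probs(m1$params, unclass(m1$arch),
                                            tp$X / 255)
  expect_close(rowSums(probs), rep(1, nrow(probs)), 1e-6)
})

test_that("training separates a bright/dark toy problem", {
  fx <- toy_model()
  det <- predict_deterministic(fx$model, fx$data$X)
  expect_gte(mean(det$label == (fx$data$y == 1)), 0.95)
  expect_true(length(fx$model$loss_trace) == 250)
  expect_true(all(is.finite(fx$model$loss_trace)))
})

test_that("zero training steps leave the model at initialization", {
  tp <- toy_patches(n = 10, side = 15, seed = 3)
  m0 <- build_model(desk_architecture(), 15, seed = 4)
  before <- predict_deterministic(m0, tp$X)$prob_true
  m0t <- train_model(m0, tp$X, desk_training_config(max_steps = 0),
                     labels = tp$y)
  expect_identical(predict_deterministic(m0t, tp$X)$prob_true, before)
})

test_that("single-class training sets are refused", {
  tp <- toy_patches(n = 10, side = 15, seed = 3)
  m <- build_model(desk_architecture(), 15, seed = 4)
  expect_error(train_model(m, tp$X, desk_training_config(max_steps = 5),
                           labels = rep(1L, 10)), "single class")
})

test_that("training is reproducible under a fixed seed", {
  tp <- toy_patches(n = 60, side = 15, seed = 5)
  cfg <- desk_training_config(max_steps = 40, rng_seed = 11)
  m1 <- train_model(build_model(desk_architecture(), 15, seed = 2), tp$X,
                    cfg, labels = tp$y)
  m2 <- train_model(build_model(desk_architecture(), 15, seed = 2), tp$X,
                    cfg, labels = tp$y)
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_identical(predict_deterministic(m1, tp$X)$prob_true,
                   predict_deterministic(m2, tp$X)$prob_true)
})

test_that("Bayesian prediction summarises dropout passes correctly", {
  fx <- toy_model()
  X <- fx$data$X[, , 1:30]
  bp <- predict_bayesian(fx$model, X, T = 9, seed = 21, keep_passes = TRUE)
  passes <- attr(bp, "passes")
  expect_equal(dim(passes), c(30, 9))
  # mu/sigma recomputable from the retained passes
  expect_close(bp$mu, rowMeans(passes), 1e-12)
  expect_close(bp$sigma, apply(passes, 1, sd), 1e-12)
  expect_true(all(bp$mu >= apply(passes, 1, min) - 1e-12 &
                    bp$mu <= apply(passes, 1, max) + 1e-12))
  # seed-reproducible
  bp2 <- predict_bayesian(fx$model, X, T = 9, seed = 21)
  expect_identical(bp$mu, bp2$mu)
  # T = 1 has zero uncertainty by definition
  expect_true(all(predict_bayesian(fx$model, X, T = 1)$sigma == 0))
  expect_error(predict_bayesian(fx$model, X, T = 0), "T must be")
})

test_that("the Monte-Carlo mean stabilises as passes accumulate", {
  fx <- toy_model()
  X <- fx$data$X[, , 1:5]
  mu_small <- predict_bayesian(fx$model, X, T = 8, seed = 1)$mu
  mu_big <- predict_bayesian(fx$model, X, T = 64, seed = 2)$mu
  sig <- predict_bayesian(fx$model, X, T = 64, seed = 2)$sigma
  # difference of means within a few Monte-Carlo standard errors
  tol <- 6 * sig / sqrt(8) + 1e-6
  expect_true(all(abs(mu_small - mu_big) <= tol))
})

test_that("deterministic prediction is dropout-free and repeatable", {
  fx <- toy_model()
  X <- fx$data$X[, , 1:10]
  d1 <- predict_deterministic(fx$model, X)
  d2 <- predict_deterministic(fx$model, X)
  expect_identical(d1$prob_true, d2$prob_true)
  # the label rule is strict, so an exact 0.5 tie falls to the false class
  expect_identical(d1$label, d1$prob_true > 0.5)
  # disabling dropout in the Bayesian path collapses to the deterministic one
  bp <- predict_bayesian(fx$model, X, T = 1, seed = 99)
  det_from_bayes <- cephmark:::cpp_cnn_predict(
    fx$model$params, unclass(fx$model$arch), X / 255, FALSE, 3L, 1L)
  expect_close(det_from_bayes[, 1], d1$prob_true, 1e-12)
  expect_identical(det_from_bayes[, 1], det_from_bayes[, 3])
})
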