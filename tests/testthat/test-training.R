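test_that("mse_loss is the mean of squared differences", {
  expect_equal(mse_loss(c(2, 2), c(2, 2)), 0)
  expect_equal(mse_loss(3, 1), 4)
  expect_equal(mse_loss(c(1, 2, 3), c(0, 0, 0)), 14 / 3)
  expect_error(mse_loss(1:3, 1:2), "equal length")
})

test_that("regression metrics agree with an independent brute-force oracle", {
  set.seed(99)
  for (rep in 1:4) {
    n <- 100L
    pred <- rnorm(n, 26, 4)
    truth <- pred + rnorm(n, 0, 2)
    m <- regression_metrics(pred, truth)
    o <- brute_metrics(pred, truth)
    for (f in names(o)) expect_lt(abs(m[[f]] - o[[f]]), 1e-10)
    expect_gte(m$rmse, m$mae)
  }
})

test_that("metric edge cases: perfect prediction and constant vectors", {
  p <- c(1, 2, 3)
  m <- suppressWarnings(regression_metrics(p, p))
  expect_equal(m$mae, 0)
  expect_equal(m$stdae, 0)
  expect_equal(m$rmse, 0)
  expect_equal(m$r_squared, 1)
  expect_warning(mc <- regression_metrics(c(2, 2, 2), c(1, 2, 3)),
                 "constant")
  expect_equal(mc$pearson_r, 0)
  m2 <- regression_metrics(c(1, 2, 3), c(1, 2, 4))
  expect_equal(m2$mae, 1 / 3)
  expect_equal(m2$rmse, sqrt(1 / 3))
  expect_error(regression_metrics(1, 1), "at least 2")
})

test_that("R^2 equals squared Pearson r for affine predictions", {
  set.seed(31)
  truth <- rnorm(50, 25, 4)
  # predictions that are an exact affine function of a noisy covariate,
  # fitted by least squares on the targets
  xcov <- truth + rnorm(50, 0, 2)
  fit <- lm(truth ~ xcov)
  pred <- fitted(fit)
  m <- regression_metrics(as.numeric(pred), truth)
  expect_equal(m$r_squared, m$pearson_r^2, tolerance = 1e-10)
})

test_that("training follows the snapshot-restore protocol deterministically", {
  sp <- small_phantom_splits(n = 32L, seed = 5)
  net <- initialize_net(build_model(reference_config(
    c(16L, 20L, 16L), TRUE)), 17)
  cfg <- train_config(epochs = 3L, seed = 23L)
  res <- train(net, sp$train, sp$validation, cfg)
  expect_equal(nrow(res$history), 3L)
  expect_true(res$best_epoch %in% 1:3)
  expect_equal(res$best_epoch, which.min(res$history$val_mae))
  # snapshot-restore: evaluating best_net on the validation set gives the
  # recorded minimum validation MAE (same engine precision as training)
  preds <- predict_cohort(res$best_net, sp$validation,
                          precision = cfg$precision)
  expect_equal(mean(abs(preds - sp$validation$bmi)),
               min(res$history$val_mae), tolerance = 1e-6)
  # determinism: identical data + config + seed reproduce the history
  res2 <- train(net, sp$train, sp$validation, cfg)
  expect_identical(res$history, res2$history)
  expect_identical(res$best_net$params, res2$best_net$params)
})

test_that("training reduces the loss on a clean, strongly coupled phantom", {
  sp <- small_phantom_splits(n = 28L, seed = 8, noise_sd = 0)
  net <- initialize_net(build_model(reference_config(
    c(16L, 20L, 16L), TRUE)), 2)
  res <- train(net, sp$train, sp$validation,
               train_config(epochs = 3L, seed = 3L))
  expect_lt(res$history$train_loss[3], res$history$train_loss[1])
})

test_that("training rejects records without targets and empty sets", {
  sp <- small_phantom_splits(n = 32L, seed = 6)
  broken <- sp$train
  broken$bmi[2] <- NA
  net <- initialize_net(build_model(reference_config(
    c(16L, 20L, 16L), TRUE)), 1)
  expect_error(train(net, broken, sp$validation, train_config(epochs = 1L)),
               "bmi")
  empty <- sp$train[0, ]
  expect_error(train(net, empty, sp$validation, train_config(epochs = 1L)),
               "non-empty")
})

test_that("augmentation bounds are honoured and zero bounds are identity", {
  arr <- array(rnorm(16 * 20 * 16), c(16, 20, 16))
  expect_identical(augment(arr, augment_spec(0, 0), seed = 11), arr)
  # pure translation: shifted-back output equals input on the overlap
  sp <- augment_spec(0, 4)
  p <- bminet:::with_seed(3, bminet:::draw_augment_params(sp))
  out <- augment(arr, sp, seed = 3)
  expect_identical(dim(out), dim(arr))
  s <- p$shifts
  src <- lapply(1:3, function(a)
    max(1, 1 - s[a]):min(dim(arr)[a], dim(arr)[a] - s[a]))
  dst <- lapply(1:3, function(a) src[[a]] + s[a])
  expect_equal(out[dst[[1]], dst[[2]], dst[[3]]],
               arr[src[[1]], src[[2]], src[[3]]])
  expect_true(abs(p$angle) <= sp$max_rotation_deg)
  expect_true(all(abs(p$shifts) <= 4))
  # rotation keeps shape and is deterministic given the seed
  sp2 <- augment_spec(5, 10)
  a1 <- augment(arr, sp2, seed = 9)
  a2 <- augment(arr, sp2, seed = 9)
  expect_identical(a1, a2)
  expect_identical(dim(a1), dim(arr))
})

test_that("fine-tuning with zero augmentation equals plain training", {
  sp <- small_phantom_splits(n = 28L, seed = 12)
  net <- initialize_net(build_model(reference_config(
    c(16L, 20L, 16L), TRUE)), 5)
  pre <- train(net, sp$train, sp$validation,
               train_config(epochs = 2L, seed = 31L))
  cfg0 <- train_config(epochs = 2L, seed = 77L,
                       augmentation = augment_spec(0, 0))
  ft <- fine_tune(pre$best_net, sp$train, sp$validation, cfg0)
  plain <- train(pre$best_net, sp$train, sp$validation,
                 train_config(epochs = 2L, seed = 77L))
  expect_identical(ft$history, plain$history)
  expect_identical(ft$best_net$params, plain$best_net$params)
})
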