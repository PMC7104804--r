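#' Training configuration
#'
#' Defaults follow the published protocol: mean-squared-error loss,
#' Adam with learning rate 5e-4 (beta1 0.9, beta2 0.999), batch size 8,
#' 50 epochs, dropout 0.4 on the hidden stage, validation evaluated
#' after every epoch and the best-validation-MAE snapshot restored.
#'
#' @param learning_rate,beta1,beta2 Adam hyperparameters.
#' @param batch_size minibatch size.
#' @param epochs number of epochs.
#' @param seed integer seed controlling shuffling, dropout and
#'   augmentation draws (each from an independent derived stream, so
#'   data order and weight initialization can be varied independently).
#' @param augmentation an [augment_spec()] or `NULL`; when present every
#'   training volume is augmented each time it is drawn (validation
#'   volumes never are).
#' @param adam_eps Adam stabilizer (framework-default 1e-8 convention).
#' @param precision `"single"` (default; memory-bandwidth-bound training
#'   runs about twice as fast) or `"double"`.
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 5e-4, beta1 = 0.9, beta2 = 0.999,
                         batch_size = 8L, epochs = 50L, seed = 1L,
                         augmentation = NULL, adam_eps = 1e-8,
                         precision = c("single", "double")) {
  stopifnot(learning_rate > 0, beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1,
            batch_size >= 1, epochs >= 1)
  if (!is.null(augmentation) && !inherits(augmentation, "augment_spec"))
    stop("`augmentation` must be an augment_spec or NULL")
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 augmentation = augmentation, adam_eps = adam_eps,
                 precision = match.arg(precision)),
            class = "train_config")
}

#' Rigid-body augmentation bounds
#'
#' One random rotation (uniform angle within the bound, about a
#' uniformly chosen grid axis) followed by an integer translation
#' (each axis uniform within the bound), with zero fill outside the
#' grid.  The published fine-tuning protocol uses 5 degrees and 10
#' voxels.
#'
#' @param max_rotation_deg non-negative rotation bound in degrees.
#' @param max_translation_voxels non-negative integer translation bound.
#' @export
augment_spec <- function(max_rotation_deg = 5, max_translation_voxels = 10L) {
  stopifnot(max_rotation_deg >= 0, max_translation_voxels >= 0)
  structure(list(max_rotation_deg = max_rotation_deg,
                 max_translation_voxels = as.integer(max_translation_voxels)),
            class = "augment_spec")
}

#' Mean squared error loss
#'
#' @param predicted,target numeric vectors of equal length (>= 1).
#' @return mean of squared differences.
#' @export
mse_loss <- function(predicted, target) {
  if (length(predicted) != length(target))
    stop("`predicted` and `target` must have equal length")
  if (length(predicted) < 1L) stop("empty input")
  mean((predicted - target)^2)
}

# Draw augmentation parameters from the current RNG.
draw_augment_params <- function(spec) {
  list(axis = sample.int(3L, 1L),
       angle = if (spec$max_rotation_deg > 0)
         runif(1, -spec$max_rotation_deg, spec$max_rotation_deg) else 0,
       shifts = if (spec$max_translation_voxels > 0)
         sample(seq(-spec$max_translation_voxels,
                    spec$max_translation_voxels), 3L, replace = TRUE)
       else c(0L, 0L, 0L))
}

# Apply a rotation + integer translation to a 3D array (zero fill).
apply_rigid <- function(arr, axis, angle, shifts, spline_order = 3L) {
  d <- dim(arr)
  if (angle != 0)
    arr <- array(.rotate3d(as.numeric(arr), as.integer(d),
                           as.integer(axis - 1L), angle,
                           as.integer(spline_order)), dim = d)
  if (any(shifts != 0)) {
    out <- array(0, d)
    src <- dst <- vector("list", 3L)
    for (a in 1:3) {
      s <- shifts[a]
      src[[a]] <- max(1L, 1L - s):min(d[a], d[a] - s)
      dst[[a]] <- src[[a]] + s
    }
    if (all(lengths(src) > 0))
      out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
    arr <- out
  }
  arr
}

#' Randomly augment a volume
#'
#' Applies one random rigid rotation (uniform in `[-max, +max]` degrees
#' about a uniformly chosen grid axis, cubic-spline resampled) followed
#' by one integer translation (each axis uniform within the bound),
#' zero-filled outside the grid.  With both bounds zero the input is
#' returned unchanged.
#'
#' @param volume a `volume3d` or 3D array.
#' @param spec an [augment_spec()].
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return augmented volume of the same type and shape.
#' @export
augment <- function(volume, spec, seed = 1L) {
  stopifnot(inherits(spec, "augment_spec"))
  arr <- as_volume_array(volume)
  p <- with_seed(seed, draw_augment_params(spec))
  out <- apply_rigid(arr, p$axis, p$angle, p$shifts)
  if (inherits(volume, "volume3d")) {
    volume$data <- out
    volume
  } else out
}

#' Train the regression network
#'
#' Runs Adam on mean-squared-error loss with per-epoch reshuffling,
#' evaluates validation MAE after every epoch, and restores the
#' parameter snapshot from the best (minimum-MAE; earliest on ties)
#' validation epoch.  The run is fully reproducible given the seeds and
#' platform.  When `config$augmentation` is set, every training volume
#' is augmented each time it is drawn; validation volumes never are.
#'
#' @param net an initialized `regression_net` (for fine-tuning, pass a
#'   pretrained network; see [fine_tune()]).
#' @param train_set,val_set [cohort_table()]s whose records all carry
#'   `bmi` targets and whose volumes match the configured input shape.
#' @param config a [train_config()].
#' @return an object of class `train_result`: `best_net`, `history`
#'   (one row per epoch: `epoch`, `train_loss`, `val_mae`, `val_stdae`),
#'   `best_epoch`.
#' @export
train <- function(net, train_set, val_set, config = train_config()) {
  stopifnot(inherits(net, "regression_net"), inherits(config, "train_config"))
  if (nrow(train_set) == 0L || nrow(val_set) == 0L)
    stop("training and validation sets must be non-empty")
  require_targets(train_set, "training")
  require_targets(val_set, "validation")
  cfg <- net$config
  arrays <- cohort_arrays(train_set)
  lapply(arrays, function(a) check_input_shape(cfg, dim(a)))
  val_arrays <- cohort_arrays(val_set)
  lapply(val_arrays, function(a) check_input_shape(cfg, dim(a)))
  cov <- cohort_covariates(train_set)
  val_cov <- cohort_covariates(val_set)
  targets <- train_set$bmi
  val_targets <- val_set$bmi
  n <- length(arrays)

  ctx <- net_context(net, config$precision)
  on.exit(.net_free(ctx))
  params <- net$params
  m <- v <- numeric(length(params))
  step <- 0L
  shuffle_stream <- new_rng_stream(derive_seed(config$seed, 1L))
  dropout_stream <- new_rng_stream(derive_seed(config$seed, 2L))
  augment_stream <- new_rng_stream(derive_seed(config$seed, 3L))

  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_mae = numeric(), val_stdae = numeric())
  best <- list(mae = Inf, params = NULL, running = NULL, epoch = NA_integer_)

  for (epoch in seq_len(config$epochs)) {
    ord <- stream_eval(shuffle_stream, function() sample.int(n))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    sq_err_sum <- 0
    for (batch in batches) {
      B <- length(batch)
      batch_arrays <- arrays[batch]
      if (!is.null(config$augmentation)) {
        draws <- stream_eval(augment_stream, function()
          lapply(seq_len(B), function(i)
            draw_augment_params(config$augmentation)))
        batch_arrays <- lapply(seq_len(B), function(i) {
          p <- draws[[i]]
          apply_rigid(batch_arrays[[i]], p$axis, p$angle, p$shifts)
        })
      }
      mask <- stream_eval(dropout_stream, function()
        dropout_mask(B, cfg, TRUE))
      X <- unlist(batch_arrays, use.names = FALSE)
      y <- .net_forward(ctx, X, B, cov[batch, , drop = FALSE], TRUE, mask)
      err <- y - targets[batch]
      sq_err_sum <- sq_err_sum + sum(err^2)
      grad <- .net_backward(ctx, 2 * err / B)
      # Adam with bias correction
      step <- step + 1L
      m <- config$beta1 * m + (1 - config$beta1) * grad
      v <- config$beta2 * v + (1 - config$beta2) * grad^2
      mhat <- m / (1 - config$beta1^step)
      vhat <- v / (1 - config$beta2^step)
      params <- params - config$learning_rate * mhat /
        (sqrt(vhat) + config$adam_eps)
      .net_set_params(ctx, params)
    }
    running <- .net_get_running(ctx)
    val_pred <- predict_with_ctx(ctx, cfg, val_arrays, val_cov,
                                 config$batch_size)
    abs_err <- abs(val_pred - val_targets)
    val_mae <- mean(abs_err)
    val_stdae <- if (length(abs_err) > 1L) sd(abs_err) else 0
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = sq_err_sum / n,
      val_mae = val_mae, val_stdae = val_stdae))
    if (val_mae < best$mae) {          # strict: earliest epoch wins ties
      best$mae <- val_mae
      best$params <- params
      best$running <- running
      best$epoch <- epoch
    }
  }
  best_net <- net
  best_net$params <- best$params
  best_net$running <- best$running
  structure(list(best_net = best_net, history = history,
                 best_epoch = best$epoch, config = config),
            class = "train_result")
}

#' Fine-tune a pretrained network
#'
#' Identical protocol to [train()] except that the starting weights are
#' those of the pretrained network and training volumes are augmented
#' per the configuration's [augment_spec()] each time they are drawn
#' (defaulting to the published 5-degree / 10-voxel bounds when the
#' configuration has none).  Validation volumes are never augmented.
#'
#' @param pretrained a trained `regression_net`.
#' @inheritParams train
#' @return a `train_result`.
#' @export
fine_tune <- function(pretrained, train_set, val_set,
                      config = train_config()) {
  if (is.null(config$augmentation)) config$augmentation <- augment_spec()
  train(pretrained, train_set, val_set, config)
}

# Evaluation-mode predictions through an existing context.
predict_with_ctx <- function(ctx, cfg, arrays, cov, batch_size) {
  n <- length(arrays)
  preds <- numeric(n)
  mask1 <- matrix(1, 1L, cfg$hidden_units)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    B <- j - i + 1L
    X <- unlist(arrays[i:j], use.names = FALSE)
    mask <- matrix(1, B, cfg$hidden_units)
    preds[i:j] <- .net_forward(ctx, X, B, cov[i:j, , drop = FALSE],
                               FALSE, mask)
    i <- j + 1L
  }
  preds
}

#' Predict for every record of a cohort
#'
#' Evaluation-mode forward passes; `bmi` targets are not needed.
#'
#' @param net a trained `regression_net`.
#' @param cohort a [cohort_table()].
#' @param precision engine precision, `"double"` (default) or `"single"`.
#' @return numeric vector of predictions named by subject id.
#' @export
predict_cohort <- function(net, cohort, precision = "double") {
  arrays <- cohort_arrays(cohort)
  lapply(arrays, function(a) check_input_shape(net$config, dim(a)))
  ctx <- net_context(net, precision)
  on.exit(.net_free(ctx))
  preds <- predict_with_ctx(ctx, net$config, arrays,
                            cohort_covariates(cohort), 8L)
  setNames(preds, cohort$subject_id)
}

#' Regression metrics
#'
#' MAE (mean absolute error), STDAE (standard deviation of the absolute
#' error), RMSE, R-squared (`1 - SS_res / SS_tot`) and Pearson r of
#' predicted versus true values.  A constant prediction (or target)
#' vector has no defined correlation; it is reported as 0 with a
#' warning.
#'
#' @param predicted,target numeric vectors of equal length >= 2.
#' @return object of class `regression_metrics`: `mae`, `stdae`, `rmse`,
#'   `r_squared`, `pearson_r`, `n`.
#' @export
regression_metrics <- function(predicted, target) {
  if (length(predicted) != length(target))
    stop("`predicted` and `target` must have equal length")
  if (length(predicted) < 2L)
    stop("need at least 2 pairs (correlation undefined otherwise)")
  err <- predicted - target
  abs_err <- abs(err)
  r <- if (sd(predicted) == 0 || sd(target) == 0) {
    warning("constant predictions or targets; reporting pearson_r = 0")
    0
  } else cor(predicted, target)
  structure(list(
    mae = mean(abs_err),
    stdae = sd(abs_err),
    rmse = sqrt(mean(err^2)),
    r_squared = 1 - sum(err^2) / sum((target - mean(target))^2),
    pearson_r = r,
    n = length(predicted)
  ), class = "regression_metrics")
}

#' Evaluate a trained network on a test cohort
#'
#' @param net a trained `regression_net`.
#' @param test_set a [cohort_table()] whose records all carry `bmi`.
#' @param precision engine precision for the forward passes.
#' @return a [regression_metrics()] object.
#' @export
evaluate <- function(net, test_set, precision = "double") {
  require_targets(test_set, "evaluation")
  if (nrow(test_set) < 2L) stop("need at least 2 test records")
  preds <- predict_cohort(net, test_set, precision = precision)
  regression_metrics(as.numeric(preds), test_set$bmi)
}

#' @export
print.regression_metrics <- function(x, ...) {
  cat(sprintf(
    "MAE = %.3f  STDAE = %.3f  RMSE = %.3f  R^2 = %.3f  Pearson r = %.3f  (n = %d)\n",
    x$mae, x$stdae, x$rmse, x$r_squared, x$pearson_r, x$n))
  invisible(x)
}

#' @export
print.train_result <- function(x, ...) {
  cat("<train_result> ", nrow(x$history), " epochs; best epoch ",
      x$best_epoch, " (validation MAE ",
      signif(min(x$history$val_mae), 4), ")\n", sep = "")
  invisible(x)
}
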