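#' Run the network on one volume
#'
#' In evaluation mode (`training_mode = FALSE`, the default) batch
#' normalization uses the stored running statistics and dropout is
#' inactive, so the output is a pure, batch-independent function of the
#' parameters and the input.  In training mode batch statistics are used
#' and a dropout mask is drawn from the current RNG.
#'
#' @param net an initialized `regression_net`.
#' @param volume a `volume3d` or a 3D numeric array matching the
#'   configured input shape.
#' @param covariates numeric vector of length `n_covariates` (ignored
#'   when the configuration has no covariate fusion).
#' @param training_mode logical.
#' @return a single finite numeric prediction.
#' @export
forward <- function(net, volume, covariates = numeric(), training_mode = FALSE) {
  arr <- as_volume_array(volume)
  check_input_shape(net$config, dim(arr))
  if (!all(is.finite(arr))) stop("input volume contains non-finite values")
  cov <- check_covariates(net$config, covariates)
  ctx <- net_context(net)
  on.exit(.net_free(ctx))
  mask <- dropout_mask(1L, net$config, training_mode)
  y <- .net_forward(ctx, as.numeric(arr), 1L, cov, training_mode, mask)
  as.numeric(y)
}

check_input_shape <- function(config, shape) {
  if (length(shape) != 3L || any(shape != config$input_shape))
    stop(sprintf("volume shape (%s) does not match configured input shape (%s)",
                 paste(shape, collapse = "x"),
                 paste(config$input_shape, collapse = "x")))
  invisible(TRUE)
}

check_covariates <- function(config, covariates) {
  if (!config$use_covariates)
    return(matrix(numeric(0), nrow = max(1L, NROW(covariates)), ncol = 0L))
  cov <- if (is.matrix(covariates)) covariates else
    matrix(as.numeric(covariates), nrow = 1L)
  if (ncol(cov) != config$n_covariates)
    stop(sprintf("expected %d covariates, got %d", config$n_covariates,
                 ncol(cov)))
  if (!all(is.finite(cov))) stop("covariates contain non-finite values")
  cov
}

# Inverted dropout mask (already scaled by 1/keep); all ones when inactive.
dropout_mask <- function(B, config, training_mode) {
  h <- config$hidden_units
  if (!training_mode || config$dropout_rate <= 0)
    return(matrix(1, B, h))
  keep <- 1 - config$dropout_rate
  matrix((runif(B * h) < keep) / keep, B, h)
}

# Batched forward pass over a list of 3D arrays sharing one shape.
# Returns predictions; the context is reused across calls by the caller.
forward_batch_ctx <- function(ctx, config, arrays, cov, training_mode, mask) {
  B <- length(arrays)
  X <- unlist(arrays, use.names = FALSE)
  .net_forward(ctx, X, B, cov, training_mode, mask)
}
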