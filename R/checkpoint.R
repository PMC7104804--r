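#' Save a network checkpoint
#'
#' One archive holding the full parameter state (trainable parameters
#' and batch-normalization running statistics) plus the configuration
#' serialized as YAML.  Loading a checkpoint reproduces evaluation-mode
#' outputs bitwise on identical input.
#'
#' @param net a `regression_net`.
#' @param path output path (conventionally `.rds`).
#' @export
save_checkpoint <- function(net, path) {
  stopifnot(inherits(net, "regression_net"))
  saveRDS(list(format = "bminet-checkpoint-1",
               config_yaml = yaml::as.yaml(unclass(net$config)),
               params = net$params,
               running = net$running), path)
  invisible(path)
}

#' Load a network checkpoint
#'
#' @param path a checkpoint written by [save_checkpoint()].
#' @return a `regression_net`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  obj <- readRDS(path)
  if (!identical(obj$format, "bminet-checkpoint-1"))
    stop("not a bminet checkpoint: ", path)
  raw <- yaml::yaml.load(obj$config_yaml)
  cfg <- structure(list(
    input_shape = as.integer(raw$input_shape),
    kernel = as.integer(raw$kernel),
    cin = as.integer(raw$cin),
    cout = as.integer(raw$cout),
    pool = as.logical(raw$pool),
    hidden_units = as.integer(raw$hidden_units),
    dropout_rate = raw$dropout_rate,
    use_covariates = isTRUE(raw$use_covariates),
    n_covariates = as.integer(raw$n_covariates),
    bn_eps = raw$bn_eps,
    bn_momentum = raw$bn_momentum
  ), class = "net_config")
  net <- build_model(cfg)
  if (length(obj$params) != length(net$params))
    stop("checkpoint parameter vector does not match its configuration")
  net$params <- obj$params
  net$running <- obj$running
  net
}
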