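#' Network configuration for the separable-convolution regression network
#'
#' A configuration describes an ordered sequence of convolution blocks.
#' Each block applies three chained asymmetric convolutions with kernel
#' extents `N x 1 x 1`, `1 x N x 1` and `1 x 1 x N` (each with a bias
#' term, stride 1, SAME zero padding), one batch-normalization stage over
#' the block's output channels, and a rectified-linear activation.
#' Blocks flagged in `pool_after` are followed by SAME max pooling
#' (window 3, stride 2).  After the last block, global average pooling
#' reduces each feature map to a scalar; the optional covariates are
#' appended to this vector before a fully connected hidden stage with
#' dropout and a single linear output unit.
#'
#' @param input_shape integer triple, spatial shape of the input volume.
#' @param kernel integer vector of odd kernel extents, one per block.
#' @param channels integer vector of output channel counts, one per block.
#' @param pool_after integer vector of block indices followed by max pooling.
#' @param hidden_units size of the fully connected hidden stage.
#' @param dropout_rate dropout rate applied to the hidden stage during
#'   training, in `[0, 1)`.
#' @param use_covariates logical; fuse scalar covariates after pooling?
#' @param n_covariates number of covariates (ignored when
#'   `use_covariates` is `FALSE`).
#' @param bn_eps,bn_momentum batch-normalization variance floor and
#'   running-statistic momentum.
#' @return an object of class `net_config`.
#' @seealso [reference_config()] for the published 8-block configuration.
#' @export
net_config <- function(input_shape, kernel, channels, pool_after = integer(),
                       hidden_units = 128L, dropout_rate = 0.4,
                       use_covariates = TRUE, n_covariates = 2L,
                       bn_eps = 1e-3, bn_momentum = 0.6) {
  input_shape <- as.integer(input_shape)
  stopifnot(length(input_shape) == 3, all(input_shape > 0))
  kernel <- as.integer(kernel)
  channels <- as.integer(channels)
  if (length(kernel) != length(channels))
    stop("`kernel` and `channels` must have one entry per block")
  if (any(kernel %% 2L == 0L)) stop("kernel extents must be odd")
  if (any(channels <= 0L)) stop("channel counts must be positive")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("`dropout_rate` must be in [0, 1)")
  nb <- length(kernel)
  pool_after <- as.integer(pool_after)
  if (any(pool_after < 1L | pool_after > nb))
    stop("`pool_after` indices out of range")
  cfg <- list(
    input_shape = input_shape,
    kernel = kernel,
    cin = c(1L, channels[-nb]),
    cout = channels,
    pool = seq_len(nb) %in% pool_after,
    hidden_units = as.integer(hidden_units),
    dropout_rate = dropout_rate,
    use_covariates = isTRUE(use_covariates),
    n_covariates = if (isTRUE(use_covariates)) as.integer(n_covariates) else 0L,
    bn_eps = bn_eps,
    bn_momentum = bn_momentum
  )
  structure(cfg, class = "net_config")
}

#' Reference 8-block network configuration
#'
#' The published configuration: kernel extents 5,3,3,3,3,3,3,3; channel
#' schedule 1 -> 8 -> 16 -> 16 -> 32 -> 32 -> 64 -> 64 -> 128 (the filter
#' count starts at eight and doubles entering blocks 2, 4, 6 and 8); max
#' pooling after blocks 2, 4 and 6; a 128-unit hidden stage with dropout
#' rate 0.4; and two covariates (age, sex).  With covariates the built
#' network has 231,681 parameters of which 230,961 are trainable (see
#' [count_parameters()] for the arithmetic).
#'
#' @param input_shape integer triple; the architecture is shape-agnostic
#'   because global average pooling absorbs the spatial size.
#' @param use_covariates fuse age and sex after global average pooling?
#' @return a `net_config`.
#' @export
reference_config <- function(input_shape = c(91L, 109L, 91L),
                             use_covariates = TRUE) {
  net_config(
    input_shape = input_shape,
    kernel = c(5L, rep(3L, 7L)),
    channels = c(8L, 16L, 16L, 32L, 32L, 64L, 64L, 128L),
    pool_after = c(2L, 4L, 6L),
    hidden_units = 128L,
    dropout_rate = 0.4,
    use_covariates = use_covariates,
    n_covariates = 2L
  )
}

# Parameter registry: ordered tensor descriptions matching the flat
# parameter vector layout shared with the C++ engine.
param_registry <- function(config) {
  nb <- length(config$kernel)
  entries <- list()
  add <- function(name, dims) {
    entries[[length(entries) + 1L]] <<- list(name = name, dims = dims,
                                             length = prod(dims))
  }
  for (b in seq_len(nb)) {
    N <- config$kernel[b]; cin <- config$cin[b]; cout <- config$cout[b]
    add(sprintf("block%d.conv1.W", b), c(N * cin, cout))
    add(sprintf("block%d.conv1.b", b), cout)
    add(sprintf("block%d.conv2.W", b), c(N * cout, cout))
    add(sprintf("block%d.conv2.b", b), cout)
    add(sprintf("block%d.conv3.W", b), c(N * cout, cout))
    add(sprintf("block%d.conv3.b", b), cout)
    add(sprintf("block%d.bn.gamma", b), cout)
    add(sprintf("block%d.bn.beta", b), cout)
  }
  zin <- config$cout[nb] + config$n_covariates
  add("head.hidden.W", c(zin, config$hidden_units))
  add("head.hidden.b", config$hidden_units)
  add("head.out.W", config$hidden_units)
  add("head.out.b", 1L)
  offsets <- cumsum(c(0L, vapply(entries, `[[`, numeric(1), "length")))
  for (i in seq_along(entries)) entries[[i]]$offset <- offsets[i]
  attr(entries, "total") <- offsets[length(offsets)]
  entries
}

#' Build the regression network
#'
#' Constructs the network state for a configuration: an unfilled
#' parameter vector (use [initialize_net()] to draw weights) plus the
#' non-trainable batch-normalization running statistics (running means 0,
#' running variances 1).
#'
#' @param config a [net_config()].
#' @return an object of class `regression_net` with elements `config`,
#'   `params` (flat trainable parameter vector) and `running` (flat
#'   running-statistic vector).
#' @export
build_model <- function(config) {
  if (!inherits(config, "net_config")) stop("`config` must be a net_config")
  nb <- length(config$kernel)
  if (nb < 1L) stop("configuration has no blocks")
  if (config$cin[1] != 1L)
    stop("first block must take a single-channel input")
  if (nb > 1L && any(config$cin[-1] != config$cout[-nb]))
    stop("channel mismatch between consecutive blocks")
  reg <- param_registry(config)
  net <- list(
    config = config,
    registry = reg,
    params = numeric(attr(reg, "total")),
    running = rep(c(0, 1), times = 0L) # filled below
  )
  running <- numeric(0)
  for (b in seq_len(nb))
    running <- c(running, rep(0, config$cout[b]), rep(1, config$cout[b]))
  net$running <- running
  class(net) <- "regression_net"
  net
}

#' Initialize network weights
#'
#' Convolution and fully connected weights are drawn with Xavier/Glorot
#' uniform initialization (limit `sqrt(6 / (fan_in + fan_out))`; for an
#' asymmetric convolution of extent N the fans are `N * c_in` and
#' `N * c_out`).  Batch-normalization scales start at one and shifts at
#' zero; fully connected biases start at 0.01; convolution biases at
#' zero; running means at zero and running variances at one.
#'
#' @param net a `regression_net` from [build_model()].
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return the network with initialized parameters.
#' @export
initialize_net <- function(net, seed = 1L) {
  stopifnot(inherits(net, "regression_net"))
  cfg <- net$config
  with_seed(seed, {
    for (e in net$registry) {
      vals <- if (grepl("\\.W$", e$name)) {
        if (grepl("^block", e$name)) {
          b <- as.integer(sub("^block(\\d+)\\..*$", "\\1", e$name))
          stage <- sub("^block\\d+\\.(conv\\d)\\.W$", "\\1", e$name)
          N <- cfg$kernel[b]
          cin <- if (stage == "conv1") cfg$cin[b] else cfg$cout[b]
          glorot_uniform(e$length, N * cin, N * cfg$cout[b])
        } else if (e$name == "head.hidden.W") {
          glorot_uniform(e$length, e$dims[1], e$dims[2])
        } else { # head.out.W
          glorot_uniform(e$length, cfg$hidden_units, 1L)
        }
      } else if (grepl("bn\\.gamma$", e$name)) {
        rep(1, e$length)
      } else if (grepl("bn\\.beta$", e$name)) {
        rep(0, e$length)
      } else if (e$name %in% c("head.hidden.b", "head.out.b")) {
        rep(0.01, e$length)
      } else { # convolution biases
        rep(0, e$length)
      }
      net$params[e$offset + seq_len(e$length)] <- vals
    }
  })
  net
}

glorot_uniform <- function(n, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  runif(n, -lim, lim)
}

#' Count network parameters
#'
#' Per block with kernel extent N and channels `c_in -> c_out` the
#' trainable count is `N*c_in*c_out + 2*N*c_out^2` convolution weights,
#' `3*c_out` convolution biases and `2*c_out` batch-normalization
#' scale/shift terms; each block additionally carries `2*c_out`
#' non-trainable running statistics.  For the reference configuration
#' this sums to 214,064 convolutional-block parameters, 16,768 hidden-
#' stage parameters (130 x 128 weights + 128 biases), 129 output-stage
#' parameters and 720 running statistics: 231,681 in total, 230,961
#' trainable.
#'
#' @param net a `regression_net`.
#' @return named integer vector with elements `total` and `trainable`.
#' @export
count_parameters <- function(net) {
  stopifnot(inherits(net, "regression_net"))
  trainable <- length(net$params)
  c(total = trainable + length(net$running), trainable = trainable)
}

# Extract one named tensor from the flat parameter vector.
net_param <- function(net, name) {
  for (e in net$registry) {
    if (e$name == name) {
      v <- net$params[e$offset + seq_len(e$length)]
      if (length(e$dims) > 1L) dim(v) <- e$dims
      return(v)
    }
  }
  stop("unknown parameter: ", name)
}

net_set_param <- function(net, name, value) {
  for (e in net$registry) {
    if (e$name == name) {
      if (length(value) != e$length) stop("length mismatch for ", name)
      net$params[e$offset + seq_len(e$length)] <- as.numeric(value)
      return(net)
    }
  }
  stop("unknown parameter: ", name)
}

#' @export
print.regression_net <- function(x, ...) {
  cnt <- count_parameters(x)
  cat("<regression_net> ", length(x$config$kernel), " blocks, input ",
      paste(x$config$input_shape, collapse = "x"),
      if (x$config$use_covariates) ", covariate fusion" else "",
      "\n  parameters: total=", cnt["total"],
      " trainable=", cnt["trainable"], "\n", sep = "")
  invisible(x)
}

# Config list handed to the C++ engine.
config_for_cpp <- function(config) {
  list(input_shape = config$input_shape, kernel = config$kernel,
       cin = config$cin, cout = config$cout, pool = config$pool,
       hidden_units = config$hidden_units,
       use_covariates = config$use_covariates,
       n_covariates = config$n_covariates,
       bn_eps = config$bn_eps, bn_momentum = config$bn_momentum)
}

# precision: "double" for exact/oracle work, "single" for large seeded
# training runs where memory bandwidth dominates.
net_context <- function(net, precision = "double") {
  .net_create(config_for_cpp(net$config), net$params, net$running, precision)
}
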