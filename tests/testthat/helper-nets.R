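# Shared fixtures: tiny configurations and phantom cohorts built in code.

toy_config <- function(input_shape = c(8L, 9L, 8L), kernel = c(3L, 3L),
                       channels = c(2L, 3L), pool_after = 2L,
                       hidden_units = 4L, dropout_rate = 0,
                       use_covariates = TRUE, n_covariates = 2L) {
  net_config(input_shape, kernel, channels, pool_after = pool_after,
             hidden_units = hidden_units, dropout_rate = dropout_rate,
             use_covariates = use_covariates, n_covariates = n_covariates)
}

toy_net <- function(seed = 7L, ...) {
  initialize_net(build_model(toy_config(...)), seed)
}

# A small, fast phantom spec (16 x 20 x 16) for protocol-level tests.
small_phantom_spec <- function(seed = 1L, noise_sd = 1, ...) {
  phantom_spec(
    volume_shape = c(16L, 20L, 16L),
    background = list(semi_axes = c(7, 9, 7), intensity = 100),
    signal_regions = list(
      list(center = c(8, 10, 8), radius = 2.5, beta = 1.0),
      list(center = c(6, 13, 9), radius = 2, beta = 0.8)),
    sex_region = list(center = c(11, 7, 6), radius = 1.5),
    noise_sd = noise_sd, seed = seed, ...)
}

small_phantom_splits <- function(n = 32L, seed = 1L, noise_sd = 1, ...) {
  gen <- generate_cohort(small_phantom_spec(seed = seed,
                                            noise_sd = noise_sd, ...), n)
  splits <- split_cohort(gen$cohort, c(0.75, 0.125, 0.125),
                         seed = seed + 1L)
  c(splits, list(truth = gen$truth))
}

# Independent brute-force regression metrics (oracle for evaluate()).
brute_metrics <- function(pred, truth) {
  n <- length(pred)
  e <- numeric(n)
  for (i in seq_len(n)) e[i] <- pred[i] - truth[i]
  ae <- abs(e)
  mae <- sum(ae) / n
  stdae <- sqrt(sum((ae - mae)^2) / (n - 1))
  rmse <- sqrt(sum(e^2) / n)
  mt <- sum(truth) / n
  ss_res <- sum(e^2)
  ss_tot <- sum((truth - mt)^2)
  r2 <- 1 - ss_res / ss_tot
  mp <- sum(pred) / n
  r <- sum((pred - mp) * (truth - mt)) /
    sqrt(sum((pred - mp)^2) * sum((truth - mt)^2))
  list(mae = mae, stdae = stdae, rmse = rmse, r_squared = r2, pearson_r = r)
}

# Brute-force separable-axis convolution (oracle for the C++ kernel):
# x is (V*B) x cin voxel-major, W ((N*cin) x cout) tap-major rows.
brute_conv_axis <- function(x, dims, B, axis, W, b, N) {
  V <- prod(dims)
  cin <- ncol(x)
  cout <- ncol(W)
  out <- matrix(0, nrow(x), cout)
  h <- N %/% 2
  coords <- arrayInd(seq_len(V), dims)
  for (bb in seq_len(B)) {
    for (v in seq_len(V)) {
      row <- (bb - 1L) * V + v
      for (co in seq_len(cout)) {
        acc <- b[co]
        for (t in seq_len(N)) {
          src <- coords[v, ]
          src[axis] <- src[axis] + (t - 1L - h)
          if (src[axis] < 1L || src[axis] > dims[axis]) next
          sv <- (bb - 1L) * V + src[1] +
            dims[1] * (src[2] - 1L + dims[2] * (src[3] - 1L))
          for (ci in seq_len(cin))
            acc <- acc + x[sv, ci] * W[(t - 1L) * cin + ci, co]
        }
        out[row, co] <- acc
      }
    }
  }
  out
}
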