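test_that("separable-axis convolution matches a brute-force oracle", {
  set.seed(5)
  dims <- c(5L, 4L, 3L)
  V <- prod(dims)
  B <- 2L
  for (axis in 1:3) {
    for (spec in list(c(N = 3L, cin = 2L, cout = 3L),
                      c(N = 5L, cin = 1L, cout = 2L))) {
      x <- matrix(rnorm(V * B * spec["cin"]), V * B, spec["cin"])
      W <- matrix(rnorm(spec["N"] * spec["cin"] * spec["cout"]),
                  spec["N"] * spec["cin"], spec["cout"])
      b <- rnorm(spec["cout"])
      got <- bminet:::.conv_axis(x, dims, B, axis - 1L, W, b, spec[["N"]])
      want <- brute_conv_axis(x, dims, B, axis, W, b, spec[["N"]])
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("SAME max pooling halves dims (ceil) and matches brute force", {
  set.seed(6)
  for (dims in list(c(6L, 6L, 6L), c(5L, 7L, 4L))) {
    V <- prod(dims)
    x <- matrix(rnorm(V * 2), V, 2)      # one subject, two channels
    got <- bminet:::.maxpool3(x, dims, 1L)
    expect_identical(got$dims, as.integer(ceiling(dims / 2)))
    # brute force with SAME padding (pad 0 before even dims, 1 before odd)
    odims <- ceiling(dims / 2)
    pad <- ifelse(dims %% 2 == 0, 0L, 1L)
    for (ch in 1:2) {
      a <- array(x[, ch], dims)
      want <- array(0, odims)
      for (ok in seq_len(odims[3])) for (oj in seq_len(odims[2]))
        for (oi in seq_len(odims[1])) {
          ir <- max(1, 2 * oi - 1 - pad[1]):min(dims[1], 2 * oi + 1 - pad[1])
          jr <- max(1, 2 * oj - 1 - pad[2]):min(dims[2], 2 * oj + 1 - pad[2])
          kr <- max(1, 2 * ok - 1 - pad[3]):min(dims[3], 2 * ok + 1 - pad[3])
          want[oi, oj, ok] <- max(a[ir, jr, kr])
        }
      expect_equal(array(got$values[, ch], odims), want)
    }
  }
})

test_that("evaluation-mode forward is deterministic and batch-invariant", {
  net <- toy_net(seed = 2)
  arrs <- lapply(1:3, function(i)
    array(rnorm(prod(net$config$input_shape)), net$config$input_shape))
  covs <- matrix(rnorm(6), 3, 2)
  y1 <- forward(net, arrs[[1]], covs[1, ])
  y2 <- forward(net, arrs[[1]], covs[1, ])
  expect_identical(y1, y2)
  # in-batch prediction equals single-subject prediction (running stats)
  ctx <- bminet:::net_context(net, "double")
  yb <- bminet:::.net_forward(ctx, unlist(arrs), 3L, covs, FALSE,
                              matrix(1, 3, net$config$hidden_units))
  singles <- vapply(1:3, function(i) forward(net, arrs[[i]], covs[i, ]),
                    numeric(1))
  expect_equal(as.numeric(yb), singles, tolerance = 1e-12)
})

test_that("all-zero input with a fresh net yields a finite scalar", {
  net <- toy_net(seed = 9)
  y <- forward(net, array(0, net$config$input_shape), c(0, 0))
  expect_length(y, 1L)
  expect_true(is.finite(y))
})

test_that("forward validates shapes and finiteness", {
  net <- toy_net()
  expect_error(forward(net, array(0, c(4, 4, 4)), c(0, 0)), "shape")
  bad <- array(0, net$config$input_shape)
  bad[1] <- NA
  expect_error(forward(net, bad, c(0, 0)), "finite")
  expect_error(forward(net, array(0, net$config$input_shape), c(0, 0, 0)),
               "covariates")
})

test_that("a constant-weight toy net reproduces a hand computation", {
  # One block: N=3, 1 -> 1 channel, all conv weights w, biases 0; input
  # constant c over a large interior.  Interior pre-BN value is
  # c * (3w)^3.  With gamma=1, beta=0 and running stats (mean mu, var s2)
  # the evaluation-mode output of BN is (x - mu)/sqrt(s2 + eps);
  # hidden stage: 1 unit, weight wh, bias bh; output weight wo, bias bo.
  cfg <- net_config(c(7L, 7L, 7L), kernel = 3L, channels = 1L,
                    hidden_units = 1L, use_covariates = FALSE,
                    bn_eps = 1e-3)
  net <- build_model(cfg)
  w <- 0.5
  net <- bminet:::net_set_param(net, "block1.conv1.W", rep(w, 3))
  net <- bminet:::net_set_param(net, "block1.conv2.W", rep(w, 3))
  net <- bminet:::net_set_param(net, "block1.conv3.W", rep(w, 3))
  net <- bminet:::net_set_param(net, "block1.bn.gamma", 1)
  net <- bminet:::net_set_param(net, "block1.bn.beta", 0)
  net <- bminet:::net_set_param(net, "head.hidden.W", 2)
  net <- bminet:::net_set_param(net, "head.hidden.b", 0.1)
  net <- bminet:::net_set_param(net, "head.out.W", 3)
  net <- bminet:::net_set_param(net, "head.out.b", -1)
  net$running <- c(0, 1)       # BN is x / sqrt(1 + eps) in eval mode
  cvol <- array(2, c(7, 7, 7))
  y <- forward(net, cvol)
  # conv cascade on a constant volume: voxel value factorizes over axes as
  # 2 * f_i * f_j * f_k where the 1D factor is 3w = 1.5 in the interior
  # and 2w = 1.0 at the two border voxels (SAME zero padding).
  axis_sum <- c(2 * w, rep(3 * w, 5), 2 * w)
  gap <- 2 * mean(as.numeric(outer(outer(axis_sum, axis_sum, `*`),
                                   axis_sum, `*`)))
  xhat <- gap / sqrt(1 + 1e-3)
  h <- max(0, 2 * xhat + 0.1)
  expect_equal(y, 3 * h - 1, tolerance = 1e-10)
})
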