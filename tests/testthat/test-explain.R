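# A net whose head is an exact pass-through: hidden_units = C feature
# maps, identity hidden weights with a large positive bias (so every
# hidden unit stays in the linear regime), output weights w.  Then
# y = sum_n w_n (g_n + M) + bo, so dy/dA^n_ijk = w_n / Z exactly and the
# localization map has the closed form L = (1/Z) sum_n w_n A^n.
identity_head_net <- function(seed = 21L, w = NULL) {
  C <- 3L
  cfg <- net_config(c(6L, 6L, 6L), kernel = c(3L, 3L), channels = c(2L, C),
                    pool_after = 1L, hidden_units = C,
                    use_covariates = FALSE)
  net <- initialize_net(build_model(cfg), seed)
  if (is.null(w)) w <- c(0.7, -1.3, 0.4)
  M <- 1e3
  net <- bminet:::net_set_param(net, "head.hidden.W", diag(C))
  net <- bminet:::net_set_param(net, "head.hidden.b", rep(M, C))
  net <- bminet:::net_set_param(net, "head.out.W", w)
  net <- bminet:::net_set_param(net, "head.out.b", 0)
  list(net = net, w = w)
}

test_that("captured gradients match the identity-head closed form", {
  ih <- identity_head_net()
  arr <- array(rnorm(6^3), c(6, 6, 6))
  cap <- capture_features_and_gradients(ih$net, arr)
  Z <- cap$features$Z
  expect_equal(dim(cap$features$maps), dim(cap$gradients$maps))
  alpha <- importance_weights(cap$gradients)
  expect_equal(alpha, ih$w / Z, tolerance = 1e-10)
  L <- localization_map(cap$features, alpha)
  closed <- Reduce(`+`, lapply(1:3, function(n)
    ih$w[n] * cap$features$maps[, , , n])) / Z
  expect_equal(L$values, closed, tolerance = 1e-6)
})

test_that("captured gradients match central finite differences on the head", {
  net <- toy_net(seed = 13)
  arr <- array(rnorm(prod(net$config$input_shape)), net$config$input_shape)
  cov <- c(61.5, 1)
  cap <- capture_features_and_gradients(net, arr, cov)
  alpha <- importance_weights(cap$gradients)
  dims4 <- dim(cap$features$maps)
  eps <- 1e-4
  for (n in seq_len(dims4[4])) {
    # gradient maps are spatially constant (GAP follows the last block),
    # so one unit per map determines alpha_n; probe an arbitrary unit
    up <- cap$features$maps
    dn <- cap$features$maps
    up[2, 2, 1, n] <- up[2, 2, 1, n] + eps
    dn[2, 2, 1, n] <- dn[2, 2, 1, n] - eps
    fd <- (head_forward(net, up, cov) - head_forward(net, dn, cov)) /
      (2 * eps)
    expect_equal(cap$gradients$maps[2, 2, 1, n], fd, tolerance = 1e-6)
    expect_equal(alpha[n], fd, tolerance = 1e-6)
  }
  expect_true(all(is.finite(cap$gradients$maps)))
  # prediction reported by capture equals the head on its own features
  expect_equal(cap$prediction, head_forward(net, cap$features, cov),
               tolerance = 1e-8)
})

test_that("importance weights are the spatial means of the gradients", {
  g <- array(2.5, c(2, 2, 2, 1))
  expect_equal(importance_weights(g), 2.5)
  g2 <- array(c(rep(1, 4), rep(-1, 4)), c(2, 2, 2, 1))
  expect_equal(importance_weights(g2), 0)
  set.seed(1)
  g3 <- array(rnorm(8), c(2, 2, 2, 1))
  expect_equal(importance_weights(g3), mean(g3))
})

test_that("localization map is the weighted sum, linear, unrectified", {
  set.seed(2)
  A <- array(rnorm(2 * 2 * 2 * 2), c(2, 2, 2, 2))
  expect_equal(localization_map(A[, , , 1, drop = FALSE], 1)$values,
               A[, , , 1])
  expect_true(all(localization_map(A, c(0, 0))$values == 0))
  w <- c(0.5, -2)
  L <- localization_map(A, w)
  expect_equal(L$values, 0.5 * A[, , , 1] - 2 * A[, , , 2])
  expect_identical(L$stage, "raw")
  # negative values are retained (no rectification)
  expect_lt(min(L$values), 0)
  # linearity in weights and features
  L2 <- localization_map(A, 2 * w)
  expect_equal(L2$values, 2 * L$values)
  expect_error(localization_map(A, c(1, 2, 3)), "weights")
})

test_that("upsampling enforces stages, shapes and constancy", {
  raw <- bminet:::new_localization_map(array(rnorm(6 * 7 * 6), c(6, 7, 6)),
                                       "raw")
  up <- upsample_map(raw, c(91, 109, 91))
  expect_identical(dim(up$values), c(91L, 109L, 91L))
  expect_identical(up$stage, "upsampled")
  expect_error(upsample_map(up, c(8, 8, 8)), "raw")
  cst <- bminet:::new_localization_map(array(2, c(4, 4, 4)), "raw")
  upc <- upsample_map(cst, c(12, 12, 12))
  expect_lt(max(abs(upc$values - 2)), 1e-6)
})

test_that("upsample/downsample round trip preserves smooth structure", {
  set.seed(7)
  coarse <- array(rnorm(5 * 6 * 5), c(5, 6, 5))
  # smooth it to emulate realistic maps
  sm <- bminet:::new_localization_map(
    array(.5 * coarse + .5 * mean(coarse), dim(coarse)), "raw")
  up <- upsample_map(sm, c(20, 24, 20))
  back <- array(bminet:::.resample3d(as.numeric(up$values),
                                     c(20L, 24L, 20L), c(5L, 6L, 5L), 3L),
                c(5, 6, 5))
  expect_gt(cor(as.numeric(back), as.numeric(sm$values)), 0.95)
})

test_that("standardization gives zero mean, unit variance and invariances", {
  set.seed(3)
  up <- bminet:::new_localization_map(array(rnorm(10^3, 5, 3),
                                            c(10, 10, 10)), "upsampled")
  st <- standardize_map(up)
  expect_lt(abs(mean(st$values)), 1e-10)
  expect_lt(abs(sqrt(mean(st$values^2)) - 1), 1e-10)
  expect_identical(st$stage, "standardized")
  # affine invariance (a > 0) and sign flip
  up2 <- up; up2$values <- 3.7 * up$values + 11
  expect_equal(standardize_map(up2)$values, st$values, tolerance = 1e-10)
  up3 <- up; up3$values <- -up$values
  expect_equal(standardize_map(up3)$values, -st$values, tolerance = 1e-10)
  flat <- up; flat$values <- array(4, dim(up$values))
  expect_error(standardize_map(flat), "degenerate")
  expect_error(standardize_map(st), "upsampled")
})

test_that("localization is spatially faithful through a pool-free net", {
  # with no pooling the last block keeps the input grid, so a localized
  # intensity bump must move the map peak with it (voxel-for-voxel up
  # to the convolution receptive field)
  cfg <- net_config(c(20L, 24L, 20L), kernel = 3L, channels = 4L,
                    hidden_units = 8L, use_covariates = FALSE)
  net <- initialize_net(build_model(cfg), 5)
  for (pos in list(c(5L, 6L, 15L), c(15L, 18L, 5L), c(10L, 12L, 10L))) {
    a <- array(0, c(20, 24, 20))
    a[pos[1] + (-1:1), pos[2] + (-1:1), pos[3] + (-1:1)] <- 50
    cap <- capture_features_and_gradients(net, a)
    L <- localization_map(cap$features, importance_weights(cap$gradients))
    peak <- which(abs(L$values) == max(abs(L$values)), arr.ind = TRUE)[1, ]
    expect_true(all(abs(peak - pos) <= 2),
                info = paste("bump at", paste(pos, collapse = ","),
                             "peak at", paste(peak, collapse = ",")))
  }
})

test_that("grand averaging re-standardizes, thresholds and is order-invariant", {
  set.seed(4)
  mk <- function() {
    m <- bminet:::new_localization_map(array(rnorm(8^3), c(8, 8, 8)),
                                       "upsampled")
    standardize_map(m)
  }
  maps <- replicate(10, mk(), simplify = FALSE)
  ga <- grand_average(maps, threshold_sd = 2)
  expect_equal(ga$n_subjects, 10L)
  expect_lt(abs(mean(ga$values)), 1e-10)
  # mask is exactly the brute-force |Z| > 2 count
  expect_identical(sum(ga$thresholded_mask), sum(abs(ga$values) > 2))
  # single subject: grand average equals that subject's map re-standardized
  ga1 <- grand_average(maps[1])
  expect_equal(ga1$values, maps[[1]]$values, tolerance = 1e-10)
  # subject order invariance
  ga_rev <- grand_average(rev(maps), threshold_sd = 2)
  expect_equal(ga_rev$values, ga$values, tolerance = 1e-12)
  # exact cancellation is a degenerate-map error
  neg <- maps[[1]]; neg$values <- -maps[[1]]$values
  expect_error(grand_average(list(maps[[1]], neg)), "degenerate")
  # stage and shape validation
  expect_error(grand_average(list(bminet:::new_localization_map(
    array(0, c(2, 2, 2)), "raw"))), "standardized")
})
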