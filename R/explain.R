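#' Capture last-block feature maps and their output gradients
#'
#' Runs an evaluation-mode forward pass and returns the last
#' convolutional block's post-activation feature maps A^n together with
#' the gradients dy/dA^n of the predicted value with respect to each
#' feature-map unit.  Because global average pooling immediately follows
#' the last block, each gradient map is spatially constant with value
#' `(dy/dg_n) / Z`, where g is the pooled feature vector and Z the
#' number of units per map; the head gradient is obtained by exact
#' backpropagation through the dense stages.
#'
#' @param net a trained `regression_net`.
#' @param volume a `volume3d` or 3D array matching the input shape.
#' @param covariates numeric vector of length `n_covariates`.
#' @return list with elements `features` and `gradients` (each a
#'   `feature_stack`: 4D array `u' x v' x w' x C` plus unit count `Z`)
#'   and `prediction` (the scalar network output).
#' @export
capture_features_and_gradients <- function(net, volume,
                                           covariates = numeric()) {
  arr <- as_volume_array(volume)
  check_input_shape(net$config, dim(arr))
  cov <- check_covariates(net$config, covariates)
  ctx <- net_context(net, "double")
  on.exit(.net_free(ctx))
  mask <- dropout_mask(1L, net$config, FALSE)
  y <- .net_forward(ctx, as.numeric(arr), 1L, cov, FALSE, mask)
  lf <- .net_last_features(ctx)
  dims <- lf$dims
  C <- ncol(lf$features)
  Z <- prod(dims)
  A <- array(lf$features, dim = c(dims, C))
  g <- colMeans(lf$features)
  dydg <- head_gradient(net, g, as.numeric(cov))
  G <- array(rep(dydg / Z, each = Z), dim = c(dims, C))
  list(features = feature_stack(A),
       gradients = feature_stack(G),
       prediction = as.numeric(y))
}

feature_stack <- function(maps) {
  stopifnot(is.array(maps), length(dim(maps)) == 4L)
  structure(list(maps = maps, Z = prod(dim(maps)[1:3])),
            class = "feature_stack")
}

# dy/dg for the dense head (ReLU hidden stage, linear output), plus the
# forward value; dropout is inactive (evaluation mode).
head_gradient <- function(net, g, cov) {
  Wh <- net_param(net, "head.hidden.W")
  bh <- net_param(net, "head.hidden.b")
  Wo <- net_param(net, "head.out.W")
  z <- c(g, cov)
  preh <- drop(z %*% Wh) + bh
  active <- preh > 0
  drop(Wh[seq_along(g), , drop = FALSE] %*% (Wo * active))
}

#' Recompute the prediction from a given feature stack
#'
#' Applies only the network head (global average pooling, covariate
#' fusion, hidden stage, output unit) to an explicitly supplied feature
#' stack.  Used to probe the head, e.g. for finite-difference checks of
#' the captured gradients.
#'
#' @param net a `regression_net`.
#' @param features a `feature_stack` (or 4D array) of last-block maps.
#' @param covariates numeric vector of length `n_covariates`.
#' @return the scalar prediction.
#' @export
head_forward <- function(net, features, covariates = numeric()) {
  maps <- if (inherits(features, "feature_stack")) features$maps else features
  stopifnot(length(dim(maps)) == 4L)
  C <- dim(maps)[4]
  g <- apply(maps, 4, mean)
  Wh <- net_param(net, "head.hidden.W")
  bh <- net_param(net, "head.hidden.b")
  Wo <- net_param(net, "head.out.W")
  bo <- net_param(net, "head.out.b")
  cov <- if (net$config$use_covariates) as.numeric(covariates) else numeric()
  z <- c(g, cov)
  h <- pmax(drop(z %*% Wh) + bh, 0)
  sum(h * Wo) + bo
}

#' Importance weight per feature map
#'
#' Global average pooling of the gradient maps: alpha_n is the mean of
#' dy/dA^n over all spatial units.
#'
#' @param gradients a `feature_stack` of gradient maps.
#' @return numeric vector alpha, one weight per feature map.
#' @export
importance_weights <- function(gradients) {
  maps <- if (inherits(gradients, "feature_stack")) gradients$maps
          else gradients
  stopifnot(length(dim(maps)) == 4L)
  apply(maps, 4, mean)
}

#' Localization map from features and importance weights
#'
#' The voxelwise weighted combination `L = sum_n alpha_n A^n`.  No
#' rectification is applied: for a regression output both positive and
#' negative contributions are of interest, so negative values are
#' retained.
#'
#' @param features a `feature_stack`.
#' @param weights numeric vector of importance weights, one per map.
#' @return a `localization_map` at stage `"raw"`.
#' @export
localization_map <- function(features, weights) {
  maps <- if (inherits(features, "feature_stack")) features$maps else features
  stopifnot(length(dim(maps)) == 4L)
  C <- dim(maps)[4]
  if (length(weights) != C)
    stop(sprintf("expected %d weights, got %d", C, length(weights)))
  d <- dim(maps)[1:3]
  flat <- matrix(maps, nrow = prod(d), ncol = C)
  L <- array(flat %*% as.numeric(weights), dim = d)
  new_localization_map(L, stage = "raw")
}

new_localization_map <- function(values, stage, affine = NULL) {
  structure(list(values = values, stage = stage, affine = affine),
            class = "localization_map")
}

#' @export
print.localization_map <- function(x, ...) {
  cat("<localization_map> ", paste(dim(x$values), collapse = " x "),
      ", stage ", x$stage, "\n", sep = "")
  invisible(x)
}

#' Upsample a raw localization map to the input-volume grid
#'
#' Separable B-spline interpolation (order 3 by default, matching the
#' volume resampler); the map inherits the subject volume's affine so
#' overlays align.
#'
#' @param map a `localization_map` at stage `"raw"`.
#' @param target_shape integer triple (the input volume shape).
#' @param spline_order integer in 0..5.
#' @param affine optional 4x4 affine to attach (e.g. the subject
#'   volume's).
#' @return a `localization_map` at stage `"upsampled"`.
#' @export
upsample_map <- function(map, target_shape, spline_order = 3L,
                         affine = NULL) {
  stopifnot(inherits(map, "localization_map"))
  if (map$stage != "raw")
    stop("upsample_map expects a raw map; got stage ", map$stage)
  target_shape <- as.integer(target_shape)
  stopifnot(length(target_shape) == 3L, all(target_shape > 0))
  vals <- .resample3d(as.numeric(map$values), as.integer(dim(map$values)),
                      target_shape, as.integer(spline_order))
  new_localization_map(array(vals, dim = target_shape),
                       stage = "upsampled", affine = affine)
}

#' Standardize a localization map to zero mean, unit variance
#'
#' Statistics are computed over the whole grid (population variance).
#'
#' @param map a `localization_map` at stage `"upsampled"`.
#' @return a `localization_map` at stage `"standardized"`.
#' @export
standardize_map <- function(map) {
  stopifnot(inherits(map, "localization_map"))
  if (map$stage != "upsampled")
    stop("standardize_map expects an upsampled map; got stage ", map$stage)
  x <- map$values
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  if (sigma < 1e-12 * max(1, abs(mu)))
    stop("degenerate localization map: zero variance")
  new_localization_map((x - mu) / sigma, stage = "standardized",
                       affine = map$affine)
}

#' Cohort grand-average localization map
#'
#' Voxelwise mean of the standardized per-subject maps, re-standardized
#' over voxels, then thresholded: the mask marks voxels with |Z| above
#' `threshold_sd` (default two standard deviations from the mean).
#'
#' @param maps list of `localization_map`s at stage `"standardized"`,
#'   sharing one shape.
#' @param threshold_sd positive threshold in standard-deviation units.
#' @return object of class `grand_average_map`: `values` (re-
#'   standardized mean map), `n_subjects`, `threshold_sd`,
#'   `thresholded_mask` (logical array), `affine`.
#' @export
grand_average <- function(maps, threshold_sd = 2) {
  stopifnot(length(maps) >= 1L, threshold_sd > 0)
  for (m in maps) {
    if (!inherits(m, "localization_map"))
      stop("`maps` must be localization_map objects")
    if (m$stage != "standardized")
      stop("grand_average expects standardized maps; got stage ", m$stage)
    if (!identical(dim(m$values), dim(maps[[1]]$values)))
      stop("maps differ in shape")
  }
  acc <- Reduce(`+`, lapply(maps, `[[`, "values")) / length(maps)
  mu <- mean(acc)
  sigma <- sqrt(mean((acc - mu)^2))
  if (sigma < 1e-12)
    stop("degenerate grand average: zero variance (subject maps cancel)")
  zmap <- (acc - mu) / sigma
  structure(list(values = zmap, n_subjects = length(maps),
                 threshold_sd = threshold_sd,
                 thresholded_mask = abs(zmap) > threshold_sd,
                 affine = maps[[1]]$affine),
            class = "grand_average_map")
}

#' Per-subject standardized localization map
#'
#' Convenience pipeline: capture features and gradients, pool the
#' gradients into importance weights, form the weighted combination,
#' upsample to the input grid, standardize.
#'
#' @param net a trained `regression_net`.
#' @param volume subject volume (`volume3d` or array).
#' @param covariates numeric vector of covariates.
#' @param spline_order upsampling spline order.
#' @return a standardized `localization_map` on the input grid.
#' @export
subject_localization_map <- function(net, volume, covariates = numeric(),
                                     spline_order = 3L) {
  cap <- capture_features_and_gradients(net, volume, covariates)
  alpha <- importance_weights(cap$gradients)
  L <- localization_map(cap$features, alpha)
  affine <- if (inherits(volume, "volume3d")) volume$affine else NULL
  arr <- as_volume_array(volume)
  standardize_map(upsample_map(L, dim(arr), spline_order, affine = affine))
}

#' Localization maps for a whole cohort
#'
#' @param net a trained `regression_net`.
#' @param cohort a [cohort_table()].
#' @param threshold_sd threshold for the grand-average mask.
#' @return list with `subject_maps` (named list of standardized maps)
#'   and `grand_average` (a `grand_average_map`).
#' @export
cohort_localization <- function(net, cohort, threshold_sd = 2) {
  maps <- lapply(seq_len(nrow(cohort)), function(i) {
    vol <- get_volume(cohort, i)
    subject_localization_map(net, vol,
                             as.numeric(cohort_covariates(cohort)[i, ]))
  })
  names(maps) <- cohort$subject_id
  list(subject_maps = maps,
       grand_average = grand_average(maps, threshold_sd))
}
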