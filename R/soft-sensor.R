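# The soft sensor identifies the inverse extended model of the
# fermentation process: three feed-forward networks, one per unmeasured
# state, mapping the 13-dimensional feature vector
#   (x4, x5, x6, x4', x4'', x5', u1..u4, Tw, Sa, Fa)
# built from the measurable signals to (x1, x2, x3) = (X, S, E).

.FEATURE_NAMES <- c("x4", "x5", "x6", "x4_dot", "x4_ddot", "x5_dot",
                    "u1", "u2", "u3", "u4", "Tw", "Sa", "Fa")
.TARGET_NAMES <- c("x1", "x2", "x3")

#' Build the inverse-extended-model feature table
#'
#' From a dense, uniformly sampled trajectory of measured channels the
#' measurable states (x4 = dissolved oxygen, x5 = hydrogen-ion
#' concentration, x6 = volume) are digitally filtered, then differentiated
#' with the five-point scheme (first and second derivative of x4, first
#' derivative of x5), and assembled with the feed rates and environment
#' into feature rows. Offline targets are attached at their own
#' timestamps when they lie on the dense grid, otherwise by local
#' least-squares alignment. Features are kept in physical units;
#' normalisation happens at fitting time, on training rows only.
#'
#' @param traj a `ferm_trajectory` (simulated or logged), uniform time
#'   grid.
#' @param offline optional data frame `t_h`, `x1`, `x2`, `x3` of offline
#'   assays; feature rows are then restricted to the assay span.
#' @param filter_cfg list with `D` (named per-channel outlier thresholds,
#'   or `NULL` for a robust data-driven default of 6 MAD of the
#'   increments) and `m` (window length, default 5); applied to the
#'   measured channels only.
#' @param add_x6_dot also include the volume derivative as a 14th feature.
#' @return A `soft_sensor_dataset` data frame: `t_h`, the 13 features,
#'   and targets `x1`, `x2`, `x3` (NA when no offline table is given).
#' @export
build_features <- function(traj, offline = NULL,
                           filter_cfg = list(D = NULL, m = 5L),
                           add_x6_dot = FALSE) {
  need <- c("t_h", "CL", "H_molL", "V_L", "fC_Lh", "fN_Lh", "fM_Lh",
            "fA_Lh", "Tw_C", "Sa_rpm", "Fa_Lmin")
  miss <- setdiff(need, names(traj))
  if (length(miss))
    stop("trajectory is missing column(s): ", paste(miss, collapse = ", "))
  t <- traj$t_h
  if (length(t) < 5L) stop("need at least 5 time points")
  hs <- diff(t)
  if (max(abs(hs - hs[1])) > 1e-9 * max(abs(hs)))
    stop("trajectory must be uniformly sampled for differentiation")
  hs <- hs[1]

  filt <- function(x) {
    D <- filter_cfg$D
    if (is.null(D)) {
      D <- 6 * stats::mad(diff(x))
      if (D <= 0) D <- Inf
    }
    if (!is.finite(D)) return(x)
    moving_average_filter(x, D = D, m = filter_cfg$m %||% 5L)
  }
  x4 <- filt(traj$CL)
  x5 <- filt(traj$H_molL)
  x6 <- filt(traj$V_L)

  feats <- data.frame(
    t_h = t, x4 = x4, x5 = x5, x6 = x6,
    x4_dot = five_point_derivative(x4, hs, 1L),
    x4_ddot = five_point_derivative(x4, hs, 2L),
    x5_dot = five_point_derivative(x5, hs, 1L),
    u1 = traj$fC_Lh, u2 = traj$fN_Lh, u3 = traj$fM_Lh, u4 = traj$fA_Lh,
    Tw = traj$Tw_C, Sa = traj$Sa_rpm, Fa = traj$Fa_Lmin)
  if (add_x6_dot) feats$x6_dot <- five_point_derivative(x6, hs, 1L)

  if (!is.null(offline)) {
    if (!all(c("t_h", .TARGET_NAMES) %in% names(offline)))
      stop("offline table must have columns t_h, x1, x2, x3")
    idx <- match(round(offline$t_h, 9), round(t, 9))
    if (!anyNA(idx)) {            # nested grids: attach directly
      feats <- feats[idx, , drop = FALSE]
      feats[.TARGET_NAMES] <- offline[.TARGET_NAMES]
    } else {                      # align targets onto the feature grid
      keep <- t >= min(offline$t_h) & t <= max(offline$t_h)
      feats <- feats[keep, , drop = FALSE]
      for (v in .TARGET_NAMES)
        feats[[v]] <- align_offline_samples(offline$t_h, offline[[v]],
                                            feats$t_h)
    }
  } else {
    feats[.TARGET_NAMES] <- NA_real_
  }
  rownames(feats) <- NULL
  class(feats) <- c("soft_sensor_dataset", "data.frame")
  feats
}

`%||%` <- function(a, b) if (is.null(a)) b else a

dataset_features <- function(data, feature_names) {
  miss <- setdiff(feature_names, names(data))
  if (length(miss))
    stop("dataset is missing feature column(s): ",
         paste(miss, collapse = ", "))
  extra <- setdiff(intersect(names(data), c(.FEATURE_NAMES, "x6_dot")),
                   feature_names)
  if (length(extra))
    stop("feature set mismatch: model was fitted without ",
         paste(extra, collapse = ", "))
  as.matrix(data[, feature_names, drop = FALSE])
}

#' Fit the inverse-system soft sensor
#'
#' Trains one fully connected network per unmeasured state on the feature
#' table, full batch, with the Adam optimizer (or plain gradient descent
#' for comparison). Features and targets are min-max normalised with
#' statistics frozen on the training rows only. Without an explicit
#' `split` column, rows are split chronologically within each batch
#' (earliest `train_frac` for training), which avoids look-ahead leakage
#' in time-series data.
#'
#' @param data a `soft_sensor_dataset` with targets.
#' @param hidden hidden layer sizes of each network.
#' @param epochs training epochs (full-batch iterations).
#' @param optimizer `"adam"` or `"sgd"`.
#' @param lam learning rate; `beta1`, `beta2`, `eps` are the Adam moment
#'   decays and stabiliser.
#' @param seed seed controlling weight initialisation (per-target offsets
#'   keep the three networks independent).
#' @param train_frac chronological training fraction when no `split`
#'   column is present.
#' @param normalization `"minmax"` or `"zscore"`.
#' @param patience early-stopping patience on the held-out split (`Inf`
#'   disables; the final parameters are then the last-epoch ones).
#' @param beta1,beta2,eps Adam hyperparameters.
#' @return Object of class `soft_sensor`.
#' @export
soft_sensor <- function(data, hidden = c(32L, 16L), epochs = 3000L,
                        optimizer = c("adam", "sgd"), lam = 1e-3,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                        seed = 1L, train_frac = 0.7,
                        normalization = c("minmax", "zscore"),
                        patience = Inf) {
  optimizer <- match.arg(optimizer)
  normalization <- match.arg(normalization)
  if (!all(.TARGET_NAMES %in% names(data)) ||
      anyNA(data[, .TARGET_NAMES]))
    stop("dataset must contain complete targets x1, x2, x3")
  feature_names <- intersect(c(.FEATURE_NAMES, "x6_dot"), names(data))
  if (!"split" %in% names(data)) {
    data$split <- "train"
    bs <- if ("batch" %in% names(data)) data$batch else 1L
    for (b in unique(bs)) {
      i <- which(bs == b)
      ntr <- floor(train_frac * length(i))
      data$split[i[order(data$t_h[i])][-seq_len(max(1L, ntr))]] <- "test"
    }
  }
  tr <- data$split == "train"
  if (!any(tr)) stop("training split is empty")

  Xall <- dataset_features(data, feature_names)
  Yall <- as.matrix(data[, .TARGET_NAMES])
  fs <- normalize_channels(Xall[tr, , drop = FALSE], normalization)
  ts_ <- withCallingHandlers(
    normalize_channels(Yall[tr, , drop = FALSE], normalization),
    warning = function(w) {
      warning("degenerate target(s); fitting anyway", call. = FALSE)
      invokeRestart("muffleWarning")
    })
  Xn <- normalize_channels(Xall, stats = fs$stats)$data
  Yn <- normalize_channels(Yall, stats = ts_$stats)$data

  use_val <- is.finite(patience) && any(!tr)
  networks <- list(); histories <- list()
  dims <- c(length(feature_names), hidden, 1L)
  for (k in seq_along(.TARGET_NAMES)) {
    fit <- train_fcnn(t(Xn[tr, , drop = FALSE]),
                      t(Yn[tr, k, drop = FALSE]),
                      layer_dims = dims, epochs = epochs,
                      optimizer = optimizer, lam = lam, beta1 = beta1,
                      beta2 = beta2, eps = eps, seed = seed + 101L * k,
                      X_val = if (use_val) t(Xn[!tr, , drop = FALSE]),
                      Y_val = if (use_val) t(Yn[!tr, k, drop = FALSE]),
                      patience = patience)
    networks[[.TARGET_NAMES[k]]] <- fit$params
    histories[[.TARGET_NAMES[k]]] <- fit$loss
  }
  structure(list(networks = networks, feature_stats = fs$stats,
                 target_stats = ts_$stats, feature_names = feature_names,
                 data = data, loss = histories,
                 config = list(hidden = hidden, epochs = epochs,
                               optimizer = optimizer, lam = lam,
                               beta1 = beta1, beta2 = beta2, eps = eps,
                               seed = seed, train_frac = train_frac,
                               normalization = normalization,
                               patience = patience)),
            class = "soft_sensor")
}

predict_normalized <- function(object, Xn) {
  sapply(.TARGET_NAMES, function(k)
    drop(fcnn_forward(object$networks[[k]], t(Xn))$Yhat))
}

#' Predict the unmeasured states
#'
#' Applies the three networks to new feature rows (physical units; the
#' model's frozen normalisation statistics are applied internally) and
#' returns denormalised point predictions of cell, substrate and enzyme
#' concentration.
#'
#' @param object a fitted [soft_sensor()].
#' @param newdata a `soft_sensor_dataset` or feature data frame; defaults
#'   to the training data.
#' @param ... unused.
#' @return Matrix with columns `x1`, `x2`, `x3` (g/L, g/L, U/mL).
#' @export
predict.soft_sensor <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  X <- dataset_features(newdata, object$feature_names)
  Xn <- normalize_channels(X, stats = object$feature_stats)$data
  Yn <- predict_normalized(object, Xn)
  if (is.null(dim(Yn))) Yn <- matrix(Yn, nrow = 1)
  out <- denormalize_channels(Yn, object$target_stats)
  colnames(out) <- .TARGET_NAMES
  out
}

#' @export
residuals.soft_sensor <- function(object, ...) {
  pred <- predict(object)
  as.matrix(object$data[, .TARGET_NAMES]) - pred
}

#' @export
coef.soft_sensor <- function(object, ...) object$networks

#' @export
print.soft_sensor <- function(x, ...) {
  cat(sprintf(
    "Inverse-system soft sensor: 3 x FCNN (%s), %s, %d epochs, seed %d\n",
    paste(c(length(x$feature_names), x$config$hidden, 1), collapse = "-"),
    x$config$optimizer, x$config$epochs, x$config$seed))
  cat(sprintf("  trained on %d rows (%d train / %d test)\n",
              nrow(x$data), sum(x$data$split == "train"),
              sum(x$data$split == "test")))
  invisible(x)
}

#' @export
summary.soft_sensor <- function(object, ...) {
  ev <- evaluate_soft_sensor(object, object$data)
  cat("Inverse-system soft sensor\n")
  print(object)
  cat("Per-target MSE (normalised units):\n")
  print(ev$mse)
  cat("Median relative error (test rows):\n")
  print(ev$median_rel_err)
  invisible(ev)
}

#' @export
plot.soft_sensor <- function(x, target = "x1", ...) {
  pred <- predict(x)
  d <- x$data
  ylab <- c(x1 = "cell concentration (g/L)",
            x2 = "substrate concentration (g/L)",
            x3 = "enzyme concentration (U/mL)")[target]
  graphics::plot(d$t_h, d[[target]], pch = 1, xlab = "time (h)",
                 ylab = ylab, ...)
  graphics::lines(d$t_h, pred[, target], col = 2, lwd = 2)
  graphics::legend("topleft", c("offline assay", "soft sensor"),
                   pch = c(1, NA), lty = c(NA, 1), col = c(1, 2), bty = "n")
  invisible(x)
}

#' Online correction with newly labelled samples
#'
#' Plant drift is absorbed by continuing the training of all three
#' networks for a few Adam epochs on a sliding window of the most recent
#' labelled samples whenever a new offline assay arrives. The
#' normalisation statistics stay frozen so the networks keep operating on
#' the scale they were identified on.
#'
#' @param object a fitted [soft_sensor()].
#' @param new_data newly labelled `soft_sensor_dataset` rows (features +
#'   targets).
#' @param epochs correction epochs (default 50; 0 returns the model
#'   unchanged).
#' @param window number of most recent labelled samples to train on
#'   (default 20).
#' @param ... unused.
#' @return The updated `soft_sensor`.
#' @export
online_correct <- function(object, new_data, epochs = 50L, window = 20L,
                           ...) {
  if (is.null(new_data) || nrow(new_data) == 0L) {
    warning("no new labelled samples; model unchanged")
    return(object)
  }
  if (anyNA(new_data[, .TARGET_NAMES]))
    stop("online correction needs labelled samples (x1, x2, x3)")
  new_data$split <- "train"
  add <- object$data[0, , drop = FALSE]
  add[seq_len(nrow(new_data)), ] <- NA
  for (cn in intersect(names(object$data), names(new_data)))
    add[[cn]] <- new_data[[cn]]
  pool <- rbind(object$data[object$data$split == "train", , drop = FALSE],
                add)
  pool <- pool[order(pool$t_h), , drop = FALSE]
  object$data <- rbind(object$data, add)
  if (epochs <= 0L) return(object)
  win <- utils::tail(pool, window)
  X <- dataset_features(win, object$feature_names)
  Xn <- normalize_channels(X, stats = object$feature_stats)$data
  Yn <- normalize_channels(as.matrix(win[, .TARGET_NAMES]),
                           stats = object$target_stats)$data
  for (k in seq_along(.TARGET_NAMES)) {
    fit <- train_fcnn(t(Xn), t(Yn[, k, drop = FALSE]),
                      layer_dims = NULL, epochs = epochs,
                      optimizer = "adam", lam = object$config$lam,
                      beta1 = object$config$beta1,
                      beta2 = object$config$beta2, eps = object$config$eps,
                      params = object$networks[[.TARGET_NAMES[k]]])
    object$networks[[.TARGET_NAMES[k]]] <- fit$params
  }
  object
}

#' @export
update.soft_sensor <- function(object, new_data, ...) {
  online_correct(object, new_data, ...)
}

#' Evaluate predictions against a labelled dataset
#'
#' Computes per-target mean squared error on the train and test splits in
#' normalised units (so the three targets are comparable) and the
#' per-timepoint relative error `|yhat - y| / |y|` at the assay
#' timestamps, with points where `|y|` falls below `rel_floor` flagged
#' and excluded from the medians. Prediction curves are also interpolated
#' onto a fine display grid (default 30 min) with the same local
#' least-squares scheme used for assay alignment.
#'
#' @param pred prediction matrix with columns `x1`, `x2`, `x3`.
#' @param data labelled `soft_sensor_dataset` the predictions refer to.
#' @param target_stats `norm_stats` used to express MSE in normalised
#'   units.
#' @param interp_min display-grid spacing in minutes (`NA` disables).
#' @param rel_floor guard on `|y|` (physical units) for relative errors.
#' @return Object of class `sensor_evaluation`.
#' @export
evaluate_predictions <- function(pred, data, target_stats,
                                 interp_min = 30, rel_floor = 1e-6) {
  if (anyNA(data[, .TARGET_NAMES])) stop("dataset has no targets")
  obs <- as.matrix(data[, .TARGET_NAMES])
  split <- data$split %||% rep("train", nrow(data))
  pn <- normalize_channels(pred, stats = target_stats)$data
  on_ <- normalize_channels(obs, stats = target_stats)$data
  mse_row <- function(idx) {
    if (!any(idx)) return(rep(NA_real_, 3))
    colMeans((pn[idx, , drop = FALSE] - on_[idx, , drop = FALSE])^2)
  }
  mse <- rbind(train = mse_row(split == "train"),
               test = mse_row(split == "test"))
  colnames(mse) <- .TARGET_NAMES
  if (!any(split == "test"))
    warning("no test rows; reporting training error only")

  guarded <- abs(obs) < rel_floor
  rel <- abs(pred - obs) / pmax(abs(obs), rel_floor)
  rel[guarded] <- NA_real_
  med <- apply(rel, 2, stats::median, na.rm = TRUE)

  curves <- NULL
  if (is.finite(interp_min) && nrow(data) >= 3L) {
    tg <- seq(min(data$t_h), max(data$t_h), by = interp_min / 60)
    curves <- data.frame(t_h = tg)
    for (k in .TARGET_NAMES)
      curves[[k]] <- align_offline_samples(data$t_h, pred[, k], tg)
  }
  structure(list(mse = mse, rel_err = rel, median_rel_err = med,
                 guarded = guarded, curves = curves, t_h = data$t_h,
                 split = split),
            class = "sensor_evaluation")
}

#' Evaluate a fitted soft sensor on a labelled dataset
#'
#' @param object a fitted [soft_sensor()].
#' @param data labelled dataset (defaults to the data the model stores).
#' @param ... passed to [evaluate_predictions()].
#' @return A `sensor_evaluation`.
#' @export
evaluate_soft_sensor <- function(object, data = NULL, ...) {
  if (is.null(data)) data <- object$data
  evaluate_predictions(predict(object, data), data, object$target_stats, ...)
}

#' @export
print.sensor_evaluation <- function(x, ...) {
  cat("Soft-sensor evaluation\nMSE (normalised units):\n")
  print(signif(x$mse, 4))
  cat("Median relative error:\n")
  print(signif(x$median_rel_err, 4))
  invisible(x)
}

#' Composite pseudo-linear cascade identity check
#'
#' Cascading the identified inverse model with the simulated process
#' should approximate an identity map from the true unmeasured states to
#' their reconstructions. This check simulates a campaign (or reuses a
#' supplied one), pushes its measured signals through the feature pipeline
#' and the soft sensor, and reports the median relative deviation of the
#' reconstructed states from the simulated truth per target.
#'
#' @param model a fitted [soft_sensor()].
#' @param campaign a `ferm_campaign`, or a [campaign_config()] to simulate
#'   (with `seed`).
#' @param seed seed used when a config is supplied.
#' @param noisy whether a freshly simulated campaign carries sensor noise.
#' @param rel_floor guard on small true values.
#' @return List with `median_rel_err` (per target), `rel_err` series and
#'   the dataset used.
#' @export
cascade_identity_check <- function(model, campaign, seed = 1L,
                                   noisy = FALSE, rel_floor = 1e-6) {
  if (inherits(campaign, "campaign_config"))
    campaign <- generate_campaign(campaign, seed = seed, noisy = noisy)
  ds <- campaign$dataset
  truth <- do.call(rbind, campaign$truth)
  if (nrow(ds) != nrow(truth))
    stop("campaign dataset and truth tables are inconsistent")
  pred <- predict(model, ds)
  obs <- as.matrix(truth[, .TARGET_NAMES])
  rel <- abs(pred - obs) / pmax(abs(obs), rel_floor)
  rel[abs(obs) < rel_floor] <- NA_real_
  list(median_rel_err = apply(rel, 2, stats::median, na.rm = TRUE),
       rel_err = rel, dataset = ds)
}
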