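test_that("feature construction has the right shape and degenerates correctly", {
  camp <- tiny_campaign()
  ds <- camp$dataset
  expect_s3_class(ds, "soft_sensor_dataset")
  expect_equal(nrow(ds), 7)           # 28 h at 4 h spacing
  feat_cols <- c("x4", "x5", "x6", "x4_dot", "x4_ddot", "x5_dot",
                 paste0("u", 1:4), "Tw", "Sa", "Fa")
  expect_true(all(feat_cols %in% names(ds)))
  expect_false(anyNA(ds[, c(feat_cols, "x1", "x2", "x3")]))

  # constant-input trajectory: derivative features vanish
  n <- 21
  tr <- structure(data.frame(t_h = seq(0, 10, by = 0.5), X_gL = 5, S_gL = 2,
                             E_UmL = 1, CL = 40, H_molL = 2e-6, V_L = 30,
                             fC_Lh = 0.1, fN_Lh = 0, fM_Lh = 0, fA_Lh = 0,
                             Tw_C = 30, Sa_rpm = 300, Fa_Lmin = 60),
                  class = c("ferm_trajectory", "data.frame"))
  f <- build_features(tr)
  expect_equal(f$x4_dot, rep(0, n))
  expect_equal(f$x4_ddot, rep(0, n))
  expect_equal(f$x4, rep(40, n))

  expect_error(build_features(tr[, -5]), "CL")
})

test_that("derivative features track the analytic derivative of an exponential DO relaxation", {
  # abiotic relaxation CL(t) = CL* + (CL0 - CL*) exp(-KLa t), sampled at 0.5 h
  KLa <- 0.3; CL0 <- 20; CLs <- 100
  t <- seq(0, 24, by = 0.5)
  tr <- structure(data.frame(t_h = t, X_gL = 0, S_gL = 5, E_UmL = 0,
                             CL = CLs + (CL0 - CLs) * exp(-KLa * t),
                             H_molL = 1e-6, V_L = 30, fC_Lh = 0, fN_Lh = 0,
                             fM_Lh = 0, fA_Lh = 0, Tw_C = 30, Sa_rpm = 300,
                             Fa_Lmin = 60),
                  class = c("ferm_trajectory", "data.frame"))
  f <- build_features(tr, filter_cfg = list(D = Inf, m = 1L))
  d1 <- -KLa * (CL0 - CLs) * exp(-KLa * t)
  d2 <- KLa^2 * (CL0 - CLs) * exp(-KLa * t)
  expect_lt(max(abs(f$x4_dot - d1) / abs(d1)), 1e-3)
  expect_lt(max(abs(f$x4_ddot - d2) / abs(d2)), 1e-2)
})

test_that("fitting is deterministic and achieves near-zero error on noise-free data", {
  camp <- default_campaign(noisy = FALSE)
  m1 <- suppressWarnings(soft_sensor(camp$dataset, epochs = 3000, seed = 1))
  ev <- evaluate_soft_sensor(m1)
  expect_lt(max(ev$mse["train", ]), 1e-3)
  m2 <- suppressWarnings(soft_sensor(camp$dataset, epochs = 3000, seed = 1))
  expect_identical(coef(m1), coef(m2))
  expect_identical(m1$loss, m2$loss)
})

test_that("shuffled-target control shows no skill while the true fit does", {
  camp <- default_campaign(noisy = FALSE)
  for (s in 1:5) {
    perm <- camp$dataset
    set.seed(s)
    idx <- sample(nrow(perm))
    perm[, c("x1", "x2", "x3")] <- perm[idx, c("x1", "x2", "x3")]
    mt <- suppressWarnings(soft_sensor(camp$dataset, epochs = 600, seed = s))
    mp <- suppressWarnings(soft_sensor(perm, epochs = 600, seed = s))
    et <- evaluate_soft_sensor(mt)
    ep <- evaluate_soft_sensor(mp)
    expect_true(all(et$mse["test", ] < ep$mse["test", ]))
  }
  # permuted-control test error is on the order of the target variance
  expect_gt(min(ep$mse["test", ]), 0.01)
})

test_that("prediction round-trips the normalisation and enforces the feature contract", {
  camp <- default_campaign(noisy = FALSE)
  model <- suppressWarnings(soft_sensor(camp$dataset, epochs = 500, seed = 2))
  ds <- camp$dataset
  pred <- predict(model, ds)
  # round-trip identity: denormalise(normalised prediction) = prediction
  Xn <- normalize_channels(as.matrix(ds[, model$feature_names]),
                           stats = model$feature_stats)$data
  pn <- sapply(c("x1", "x2", "x3"), function(k)
    drop(fcnn_forward(coef(model)[[k]], t(Xn))$Yhat))
  expect_equal(unname(denormalize_channels(pn, model$target_stats)),
               unname(pred), tolerance = 1e-12)
  # stored residuals are reproduced
  expect_equal(residuals(model),
               as.matrix(ds[, c("x1", "x2", "x3")]) - pred,
               ignore_attr = TRUE)
  # removing the second-derivative feature must be refused
  expect_error(predict(model, ds[, setdiff(names(ds), "x4_ddot")]),
               "x4_ddot")
})

test_that("a model trained on constant targets predicts that constant", {
  camp <- tiny_campaign()
  ds <- camp$dataset
  ds[, c("x1", "x2", "x3")] <- rep(c(7, 3, 1), each = nrow(ds))
  model <- suppressWarnings(soft_sensor(ds, epochs = 4000, seed = 1,
                                        train_frac = 1))
  pred <- predict(model, ds)
  expect_equal(unname(colMeans(pred)), c(7, 3, 1), tolerance = 1e-2)
  expect_lt(max(apply(pred, 2, sd)), 1e-2)
})

test_that("evaluation matches brute-force recomputation and guards small targets", {
  camp <- default_campaign(noisy = FALSE)
  ds <- camp$dataset
  ds$split <- "train"
  stats <- normalize_channels(as.matrix(ds[, c("x1", "x2", "x3")]))$stats
  # constant predictor at the target mean: MSE equals population variance
  obs <- normalize_channels(as.matrix(ds[, c("x1", "x2", "x3")]),
                            stats = stats)$data
  const <- matrix(colMeans(as.matrix(ds[, c("x1", "x2", "x3")])),
                  nrow(ds), 3, byrow = TRUE,
                  dimnames = list(NULL, c("x1", "x2", "x3")))
  ev <- suppressWarnings(evaluate_predictions(const, ds, stats,
                                              interp_min = NA))
  popvar <- function(v) mean((v - mean(v))^2)
  for (k in 1:3)
    expect_equal(unname(ev$mse["train", k]), popvar(obs[, k]),
                 tolerance = 1e-10)
  # perfect predictor: zero error everywhere
  perfect <- as.matrix(ds[, c("x1", "x2", "x3")])
  ev0 <- suppressWarnings(evaluate_predictions(perfect, ds, stats,
                                               interp_min = NA))
  expect_equal(max(ev0$mse["train", ]), 0)
  expect_equal(max(ev0$median_rel_err), 0)
  # tiny true values are flagged and excluded from the medians
  ds2 <- ds
  ds2$x3 <- 1e-9
  ev2 <- suppressWarnings(evaluate_predictions(perfect, ds2, stats,
                                               interp_min = NA))
  expect_true(all(ev2$guarded[, "x3"]))
  expect_true(is.na(ev2$median_rel_err[["x3"]]))
  # 30-min display interpolation covers the assay span
  ev3 <- suppressWarnings(evaluate_predictions(perfect, ds, stats,
                                               interp_min = 30))
  expect_equal(median(diff(ev3$curves$t_h)), 0.5)
})

test_that("the trained cascade approximates the identity map, an untrained one does not", {
  camp <- default_campaign(noisy = FALSE)
  model <- suppressWarnings(soft_sensor(camp$dataset, epochs = 3000, seed = 1))
  cc <- cascade_identity_check(model, camp)
  expect_lt(max(cc$median_rel_err), 0.05)
  # negative control: untrained (random) networks deviate far more
  raw <- model
  for (k in c("x1", "x2", "x3"))
    raw$networks[[k]] <- init_network(c(length(model$feature_names),
                                        model$config$hidden, 1), seed = 99)
  cc0 <- cascade_identity_check(raw, camp)
  expect_gt(min(cc0$median_rel_err / cc$median_rel_err), 10)
  # held-out batch from the same kinetics: finite deviation, no crash
  cfg2 <- campaign_config(jitter_frac = 0)
  cc2 <- cascade_identity_check(model, cfg2, seed = 77, noisy = FALSE)
  expect_true(all(is.finite(cc2$median_rel_err)))
})

test_that("online correction is a no-op at zero epochs and adapts to a regime shift", {
  shift <- make_fixture("regime-shift", seed = 5)
  ds <- shift$dataset
  t_shift <- shift$manifest$t_shift
  pre <- ds[ds$t_h <= t_shift, ]
  post <- ds[ds$t_h > t_shift, ]
  pre$split <- "train"
  model <- suppressWarnings(soft_sensor(pre, epochs = 2000, seed = 3,
                                        train_frac = 1))
  # k = 0 epochs: model unchanged
  m0 <- online_correct(model, post[1:2, ], epochs = 0)
  expect_identical(coef(m0), coef(model))
  expect_warning(online_correct(model, post[0, ]), "no new")
  # correcting on the first post-shift assays improves the later ones
  later <- post[3:nrow(post), ]
  err <- function(m) {
    p <- predict(m, later)
    mean(abs(p - as.matrix(later[, c("x1", "x2", "x3")])) /
           pmax(abs(as.matrix(later[, c("x1", "x2", "x3")])), 1e-6))
  }
  e_pre <- err(model)
  mc <- online_correct(model, post[1:2, ], epochs = 200, window = 8)
  expect_lt(err(mc), e_pre)
  # re-presenting a training row keeps its loss at numerical zero once the
  # correction has re-converged (Adam perturbs before settling)
  row1 <- pre[nrow(pre), ]
  l_before <- mean((predict(model, row1) -
                      as.matrix(row1[, c("x1", "x2", "x3")]))^2)
  expect_lt(l_before, 1e-8)
  mr <- online_correct(model, row1, epochs = 200, window = 8)
  l_after <- mean((predict(mr, row1) -
                     as.matrix(row1[, c("x1", "x2", "x3")]))^2)
  expect_lt(l_after, 1e-8)
})

test_that("Adam-trained sensors dominate fixed-rate descent at matched budgets", {
  camp <- default_campaign(noisy = TRUE)
  wins_train <- 0L; wins_test <- 0L
  for (s in 1:5) {
    ma <- suppressWarnings(soft_sensor(camp$dataset, epochs = 800, seed = s,
                                       optimizer = "adam"))
    ms <- suppressWarnings(soft_sensor(camp$dataset, epochs = 800, seed = s,
                                       optimizer = "sgd"))
    ea <- evaluate_soft_sensor(ma)$mse
    es <- evaluate_soft_sensor(ms)$mse
    # Table-2-style aggregate MSE per dataset (mean over the three targets)
    if (mean(ea["train", ]) <= mean(es["train", ])) wins_train <- wins_train + 1L
    if (mean(ea["test", ]) <= mean(es["test", ])) wins_test <- wins_test + 1L
  }
  expect_gte(wins_train, 4L)
  expect_gte(wins_test, 4L)
})
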