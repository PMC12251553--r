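# Seeded generator of synthetic methanol-induction campaigns. The generator
# defines the study conditions every test runs under: a 240 h induction
# phase, near-constant feed profiles with bounded ramps, dense on-line
# logging, 4-hourly offline assays (60 pairs per batch) and Gaussian sensor
# noise at typical instrument accuracies (DO 0.5% of reading, pH 0.02,
# flows 2% of setpoint).

#' Sensor and assay noise specification
#'
#' Standard deviations for the measured channels. DO and flow noise are
#' relative (fraction of the reading/setpoint), pH noise is additive in pH
#' units and mapped to hydrogen-ion concentration through the local slope,
#' volume noise is additive in litres. Offline assays of cell, substrate
#' and enzyme concentration get relative noise; enzyme readings below the
#' chromatographic detection floor are reported at the floor.
#'
#' @param sd_DO_frac relative DO noise (default 0.005, i.e. 0.5%).
#' @param sd_pH additive pH noise (default 0.02).
#' @param sd_flow_frac relative feed-rate noise (default 0.02).
#' @param sd_V additive volume noise in L.
#' @param assay_frac relative offline assay noise for the three targets.
#' @param E_floor reporting floor for the enzyme assay (U/mL).
#' @return Named list of class `noise_spec`.
#' @export
noise_spec <- function(sd_DO_frac = 0.005, sd_pH = 0.02, sd_flow_frac = 0.02,
                       sd_V = 0.1, assay_frac = 0.02, E_floor = 0.01) {
  ns <- list(sd_DO_frac = sd_DO_frac, sd_pH = sd_pH,
             sd_flow_frac = sd_flow_frac, sd_V = sd_V,
             assay_frac = assay_frac, E_floor = E_floor)
  if (any(unlist(ns) < 0)) stop("noise standard deviations must be >= 0")
  class(ns) <- "noise_spec"
  ns
}

#' Campaign configuration
#'
#' Defines a multi-batch induction campaign: durations and grids, initial
#' state at induction onset (the batch and glycerol phases are summarised
#' by this state, since they only set the biomass available for
#' induction), the substrate setpoint the methanol feed is sized for,
#' bounded feed ramps, noise levels and optional batch-to-batch kinetic
#' jitter.
#'
#' @param n_batches number of batches.
#' @param induction_h induction duration (h, default 240).
#' @param offline_interval_h offline assay interval (h, default 4).
#' @param dense_step_h on-line logging step (h, default 0.5).
#' @param dt integrator step (h).
#' @param x0 initial [state_vector()] at induction onset.
#' @param env an [env_vector()] of campaign-constant environment settings.
#' @param S_set substrate setpoint (g/L) the methanol feed is sized for
#'   (about 1% methanol).
#' @param base_feeds named levels for the non-carbon feeds (L/h).
#' @param ramp_frac maximum relative feed ramp over the phase (default
#'   0.05, i.e. within +/-5% of the level).
#' @param noise a [noise_spec()].
#' @param kinetics a [kinetic_params()] list.
#' @param config a [model_config()].
#' @param jitter_frac batch-to-batch relative jitter on `mu_max` and
#'   `Y_XS` (default 0.10), uniform on `[-jitter, +jitter]`; 0 disables.
#' @return Object of class `campaign_config`.
#' @export
campaign_config <- function(n_batches = 1L, induction_h = 240,
                            offline_interval_h = 4, dense_step_h = 0.5,
                            dt = 0.02,
                            x0 = state_vector(60, 8, 1, 40, 2e-6, 50),
                            env = env_vector(30, 300, 60),
                            S_set = 8,
                            base_feeds = c(fN = 0.02, fM = 0.01, fA = 0.004),
                            ramp_frac = 0.05, noise = noise_spec(),
                            kinetics = kinetic_params(),
                            config = model_config(), jitter_frac = 0.10) {
  if (induction_h / offline_interval_h < 10)
    stop("campaign must yield at least 10 offline samples")
  if (offline_interval_h %% dense_step_h > 1e-9 &&
      abs(offline_interval_h %% dense_step_h - dense_step_h) > 1e-9)
    stop("offline grid must be nested in the dense grid")
  structure(list(n_batches = as.integer(n_batches),
                 induction_h = induction_h,
                 offline_interval_h = offline_interval_h,
                 dense_step_h = dense_step_h, dt = dt, x0 = x0, env = env,
                 S_set = S_set, base_feeds = base_feeds,
                 ramp_frac = ramp_frac, noise = noise, kinetics = kinetics,
                 config = config, jitter_frac = jitter_frac),
            class = "campaign_config")
}

#' Near-constant feed profile for one batch
#'
#' The methanol feed level is sized to the campaign-average substrate
#' demand `nu(x) * X * V / (S_C - S_set)`, estimated from a coarse pilot
#' simulation at the initial-demand level. Because uptake is
#' growth-dominated and therefore responds to substrate excursions, a
#' constant feed at the average demand holds the substrate within a
#' moderate band around its setpoint over the whole induction. The
#' remaining feeds sit at their configured levels. Each feed receives a
#' seeded linear ramp bounded by `ramp_frac` of its level (zero ramp
#' amplitude gives exactly constant feeds).
#'
#' @param cfg a [campaign_config()].
#' @param seed integer seed for the ramp draws.
#' @param rates optional [rate_laws()] used for sizing (defaults to the
#'   configured kinetics).
#' @return Function `t -> feed_vector` (L/h), with attribute `levels`.
#' @export
generate_feed_profile <- function(cfg, seed = 1L, rates = NULL) {
  if (is.null(rates)) rates <- default_rate_laws(cfg$kinetics)
  if (any(cfg$base_feeds < 0)) stop("feed levels must be non-negative")
  u1_0 <- rates$nu(cfg$x0) * cfg$x0[["X"]] * cfg$x0[["V"]] /
    (cfg$config$S_C - cfg$S_set)
  if (u1_0 < 0) stop("feed levels must be non-negative")
  # pilot run at the initial-demand level, then resize to average demand
  pilot_feeds <- function(t) c(fC = u1_0, cfg$base_feeds[c("fN", "fM", "fA")])
  pilot <- simulate_fermentation(cfg$x0, pilot_feeds, function(t) cfg$env,
                                 seq(0, cfg$induction_h, length.out = 61),
                                 rates, cfg$config, dt = min(0.05, cfg$dt * 5))
  ps <- trajectory_states(pilot)
  u1 <- mean(vapply(seq_len(nrow(ps)), function(i)
    rates$nu(ps[i, ]) * ps[i, "X"] * ps[i, "V"], numeric(1))) /
    (cfg$config$S_C - cfg$S_set)
  # head-room so that even the lowest ramped feed covers the average demand
  u1 <- u1 / (1 - cfg$ramp_frac)
  levels <- c(fC = unname(u1), cfg$base_feeds[c("fN", "fM", "fA")])
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  slopes <- stats::runif(4, -cfg$ramp_frac, cfg$ramp_frac)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  Tdur <- cfg$induction_h
  f <- function(t) {
    # linear ramp from -s to +s across the phase, clipped at non-negative
    fac <- 1 + slopes * (2 * pmin(pmax(t, 0), Tdur) / Tdur - 1)
    u <- pmax(levels * fac, 0)
    names(u) <- c("fC", "fN", "fM", "fA")
    u
  }
  attr(f, "levels") <- levels
  attr(f, "slopes") <- slopes
  f
}

jitter_kinetics <- function(kin, frac, seed) {
  if (frac <= 0) return(kin)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  kin$mu_max <- kin$mu_max * (1 + stats::runif(1, -frac, frac))
  kin$Y_XS <- kin$Y_XS * (1 + stats::runif(1, -frac, frac))
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  kin
}

add_sensor_noise <- function(traj, ns, seed) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  n <- nrow(traj)
  traj$CL <- traj$CL * (1 + stats::rnorm(n, sd = ns$sd_DO_frac))
  pH <- -log10(traj$H_molL) + stats::rnorm(n, sd = ns$sd_pH)
  traj$H_molL <- 10^(-pH)
  traj$V_L <- traj$V_L + stats::rnorm(n, sd = ns$sd_V)
  for (col in c("fC_Lh", "fN_Lh", "fM_Lh", "fA_Lh"))
    traj[[col]] <- traj[[col]] * (1 + stats::rnorm(n, sd = ns$sd_flow_frac))
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  traj
}

#' Generate a synthetic induction campaign
#'
#' Simulates each batch with (optionally jittered) kinetics, overlays
#' sensor noise on the dense measured channels, draws 4-hourly offline
#' assays with assay noise, and assembles the soft-sensor dataset. A 240 h
#' induction at a 4 h interval yields exactly 60 offline pairs per batch.
#'
#' @param cfg a [campaign_config()].
#' @param seed master integer seed; all batch-level draws derive from it.
#' @param noisy overlay sensor/assay noise (set `FALSE` for a noise-free
#'   campaign whose targets equal the simulated states exactly).
#' @return Object of class `ferm_campaign`: lists `trajectories` (clean),
#'   `measured` (noisy dense logs), `offline` (assay tables), a combined
#'   `dataset` (see [build_features()]), `truth` (clean states at offline
#'   times) and a `manifest` of seeds and configuration.
#' @export
generate_campaign <- function(cfg, seed = 1L, noisy = TRUE) {
  t_dense <- seq(0, cfg$induction_h, by = cfg$dense_step_h)
  t_off <- seq(cfg$offline_interval_h, cfg$induction_h,
               by = cfg$offline_interval_h)
  env_fun <- function(t) cfg$env
  trajectories <- list(); measured <- list(); offline <- list()
  truth <- list(); datasets <- list()
  for (b in seq_len(cfg$n_batches)) {
    bseed <- seed + 7919L * (b - 1L)
    kin <- jitter_kinetics(cfg$kinetics, cfg$jitter_frac, bseed + 1L)
    rates <- default_rate_laws(kin)
    # the feed profile is the campaign's recipe: its ramp draw is shared
    # across batches (only kinetics jitter and noise are batch-specific)
    feed_fun <- generate_feed_profile(cfg, seed = seed + 2L, rates = rates)
    traj <- tryCatch(
      simulate_fermentation(cfg$x0, feed_fun, env_fun, t_dense, rates,
                            cfg$config, dt = cfg$dt),
      error = function(e) stop(sprintf("batch %d (seed %d) failed: %s",
                                       b, bseed, conditionMessage(e))))
    meas <- if (noisy) add_sensor_noise(traj, cfg$noise, bseed + 3L) else traj

    ioff <- match(round(t_off, 9), round(traj$t_h, 9))
    stopifnot(!anyNA(ioff))
    tr_states <- trajectory_states(traj)[ioff, , drop = FALSE]
    off <- data.frame(t_h = t_off, x1 = tr_states[, "X"],
                      x2 = tr_states[, "S"], x3 = tr_states[, "E"])
    if (noisy && cfg$noise$assay_frac > 0) {
      old <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv)
      set.seed(bseed + 4L)
      for (col in c("x1", "x2", "x3"))
        off[[col]] <- off[[col]] *
          (1 + stats::rnorm(nrow(off), sd = cfg$noise$assay_frac))
      if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    }
    off$x3 <- pmax(off$x3, cfg$noise$E_floor)

    ds <- build_features(meas, offline = off)
    ds$batch <- b
    trajectories[[b]] <- traj
    measured[[b]] <- meas
    offline[[b]] <- off
    truth[[b]] <- data.frame(t_h = t_off, x1 = tr_states[, "X"],
                             x2 = tr_states[, "S"], x3 = tr_states[, "E"])
    datasets[[b]] <- ds
  }
  dataset <- do.call(rbind, datasets)
  class(dataset) <- c("soft_sensor_dataset", "data.frame")
  structure(list(trajectories = trajectories, measured = measured,
                 offline = offline, dataset = dataset, truth = truth,
                 manifest = list(seed = seed, noisy = noisy, cfg = cfg)),
            class = "ferm_campaign")
}

#' @export
print.ferm_campaign <- function(x, ...) {
  cat(sprintf("Synthetic campaign: %d batch(es), %d offline pairs each, %s\n",
              length(x$trajectories), nrow(x$offline[[1]]),
              if (x$manifest$noisy) "with sensor noise" else "noise-free"))
  invisible(x)
}

#' Small deterministic fixtures for tests and examples
#'
#' * `"tiny"` - a 28 h induction with 7 offline pairs, noise-free.
#' * `"tiny-noisy"` - the same campaign with sensor and assay noise.
#' * `"regime-shift"` - a 48 h noise-free campaign whose maximum specific
#'   growth rate steps up by 50% at t = 24 h (for online-correction
#'   experiments); the step time is recorded in the manifest.
#'
#' @param name fixture name.
#' @param seed integer seed.
#' @return A `ferm_campaign` (single batch).
#' @export
make_fixture <- function(name = c("tiny", "tiny-noisy", "regime-shift"),
                         seed = 1L) {
  name <- match.arg(name)
  if (name %in% c("tiny", "tiny-noisy")) {
    # deliberately below campaign scale: 28 h, 7 offline pairs
    cfg <- campaign_config(n_batches = 1L, induction_h = 240,
                           offline_interval_h = 4, jitter_frac = 0)
    cfg$induction_h <- 28
    return(generate_campaign(cfg, seed = seed, noisy = name == "tiny-noisy"))
  }
  # regime shift: simulate two segments and stitch
  cfg <- campaign_config(n_batches = 1L, induction_h = 48,
                         offline_interval_h = 4, jitter_frac = 0)
  t_shift <- 24
  rates1 <- default_rate_laws(cfg$kinetics)
  kin2 <- cfg$kinetics; kin2$mu_max <- kin2$mu_max * 1.5
  rates2 <- default_rate_laws(kin2)
  feed_fun <- generate_feed_profile(cfg, seed = seed, rates = rates1)
  env_fun <- function(t) cfg$env
  t1 <- seq(0, t_shift, by = cfg$dense_step_h)
  t2 <- seq(t_shift, cfg$induction_h, by = cfg$dense_step_h)
  tr1 <- simulate_fermentation(cfg$x0, feed_fun, env_fun, t1, rates1,
                               cfg$config, dt = cfg$dt)
  x_mid <- trajectory_states(tr1)[nrow(tr1), ]
  tr2 <- simulate_fermentation(x_mid, feed_fun, env_fun, t2, rates2,
                               cfg$config, dt = cfg$dt)
  traj <- rbind(tr1, tr2[-1, ])
  class(traj) <- c("ferm_trajectory", "data.frame")
  t_off <- seq(cfg$offline_interval_h, cfg$induction_h,
               by = cfg$offline_interval_h)
  ioff <- match(round(t_off, 9), round(traj$t_h, 9))
  st <- trajectory_states(traj)[ioff, , drop = FALSE]
  off <- data.frame(t_h = t_off, x1 = st[, "X"], x2 = st[, "S"],
                    x3 = st[, "E"])
  ds <- build_features(traj, offline = off)
  ds$batch <- 1L
  class(ds) <- c("soft_sensor_dataset", "data.frame")
  structure(list(trajectories = list(traj), measured = list(traj),
                 offline = list(off), dataset = ds,
                 truth = list(off),
                 manifest = list(seed = seed, noisy = FALSE, cfg = cfg,
                                 t_shift = t_shift)),
            class = "ferm_campaign")
}
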