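#' @keywords internal
"_PACKAGE"

# State ordering used throughout: x1..x6 = (X, S, E, CL, H, V).
.STATE_NAMES <- c("X", "S", "E", "CL", "H", "V")
.FEED_NAMES  <- c("fC", "fN", "fM", "fA")
.ENV_NAMES   <- c("Tw", "Sa", "Fa")

#' Construct a six-state fermentation state vector
#'
#' States are ordered as in the grey-box balance model: biomass `X` (g/L),
#' methanol `S` (g/L), inulinase `E` (U/mL), dissolved oxygen `CL`
#' (percent saturation by default; units are declared in the model config),
#' hydrogen-ion concentration `H` (mol/L) and broth volume `V` (L).
#'
#' @param X,S,E,CL,H,V scalar state values in the units above.
#' @return Named numeric vector of length 6.
#' @export
#' @examples
#' x0 <- state_vector(X = 60, S = 8, E = 1, CL = 40, H = 2e-6, V = 50)
state_vector <- function(X, S, E, CL, H, V) {
  x <- c(X = X, S = S, E = E, CL = CL, H = H, V = V)
  validate_state(x)
  x
}

validate_state <- function(x) {
  if (length(x) != 6L || !is.numeric(x))
    stop("state must be a numeric vector of length 6 (X, S, E, CL, H, V)")
  if (is.null(names(x))) names(x) <- .STATE_NAMES
  if (!all(is.finite(x))) stop("state contains non-finite values")
  if (x[["V"]] <= 0) stop("broth volume V must be positive")
  invisible(x)
}

#' Construct a feed-rate vector
#'
#' Feed rates for methanol (`fC`), ammonia water (`fN`), phosphate (`fM`)
#' and antifoam (`fA`). Plant logs record feeds in L/min; the model works
#' in hours, so rates are converted to L/h at ingestion.
#'
#' @param fC,fN,fM,fA non-negative feed rates.
#' @param units `"L/h"` (default, model units) or `"L/min"`.
#' @return Named numeric vector of length 4 in L/h.
#' @export
feed_vector <- function(fC = 0, fN = 0, fM = 0, fA = 0,
                        units = c("L/h", "L/min")) {
  units <- match.arg(units)
  u <- c(fC = fC, fN = fN, fM = fM, fA = fA)
  if (any(!is.finite(u))) stop("feed rates must be finite")
  if (any(u < 0)) stop("feed rates must be non-negative")
  if (units == "L/min") u <- u * 60
  u
}

#' Construct an environment vector
#'
#' Auxiliary measured quantities that do not enter the balance equations but
#' are part of the extended soft-sensor feature set: temperature `Tw` (deg C),
#' agitation speed `Sa` (rpm) and inlet airflow `Fa` (L/min).
#'
#' @param Tw,Sa,Fa scalar values; `Sa` and `Fa` must be non-negative.
#' @return Named numeric vector of length 3.
#' @export
env_vector <- function(Tw = 30, Sa = 300, Fa = 60) {
  if (Sa < 0 || Fa < 0) stop("Sa and Fa must be non-negative")
  c(Tw = Tw, Sa = Sa, Fa = Fa)
}

#' Model configuration for the grey-box balance equations
#'
#' Holds the physical coefficients of the six balance equations: feed
#' methanol concentration `S_C` (g/L), enzyme degradation constant `K_P`
#' (1/h), phosphate/antifoam coefficients `K_M`, `K_A` (signed; the printed
#' model adds them, set negative to treat them as inhibition), oxygen
#' transfer coefficient `K_La` (1/h) with saturation level `C_L_star`,
#' acid/base equivalent concentrations of the four feeds (`S_f`, `S_m`,
#' `S_n`, `S_a`, mol/L-equivalent) and the 6 x 4 dilution coefficient
#' matrix `A` (all ones by default, in which case the per-state dilution
#' term is exactly `(x_j / V) * dV/dt`).
#'
#' @param S_C feed methanol concentration (g/L).
#' @param K_P enzyme degradation constant (1/h).
#' @param K_M,K_A signed phosphate/antifoam coefficients in the enzyme
#'   balance.
#' @param K_La oxygen volumetric mass-transfer coefficient (1/h).
#' @param C_L_star oxygen saturation concentration (same units as `CL`).
#' @param S_f,S_m,S_n,S_a acid/base equivalent concentrations of the
#'   methanol, phosphate, ammonia and antifoam feeds.
#' @param A 6 x 4 dilution coefficient matrix.
#' @param nonneg_clip floor states at zero after each integration step.
#' @param literal_substrate_inflow use the literally printed substrate
#'   inflow term `S_C / V` instead of the mass-balanced `S_C * u1 / V`.
#' @return An object of class `ferm_config`.
#' @export
model_config <- function(S_C = 780, K_P = 0.005, K_M = 0.01, K_A = 0.01,
                         K_La = 1.6, C_L_star = 100,
                         S_f = 1e-6, S_m = 2e-6, S_n = 5e-6, S_a = 1e-6,
                         A = matrix(1, 6, 4), nonneg_clip = TRUE,
                         literal_substrate_inflow = FALSE) {
  if (K_La < 0) stop("K_La must be non-negative")
  if (C_L_star <= 0) stop("C_L_star must be positive")
  if (!is.matrix(A) || !identical(dim(A), c(6L, 4L)) || !all(is.finite(A)))
    stop("A must be a finite 6 x 4 matrix")
  structure(list(S_C = S_C, K_P = K_P, K_M = K_M, K_A = K_A, K_La = K_La,
                 C_L_star = C_L_star, S_f = S_f, S_m = S_m, S_n = S_n,
                 S_a = S_a, A = A, nonneg_clip = isTRUE(nonneg_clip),
                 literal_substrate_inflow = isTRUE(literal_substrate_inflow)),
            class = "ferm_config")
}

#' Volume balance right-hand side
#'
#' In fed-batch operation without broth removal the volume grows at the sum
#' of the four feed rates: `dV/dt = fC + fN + fM + fA`.
#'
#' @param feeds a [feed_vector()] (L/h).
#' @return Volume rate of change (L/h).
#' @export
volume_rhs <- function(feeds) {
  if (any(!is.finite(feeds))) stop("feed rates must be finite")
  if (any(feeds < 0)) stop("feed rates must be non-negative")
  sum(feeds)
}

#' Full six-state balance right-hand side
#'
#' Evaluates the grey-box model derivatives at one state. Each concentration
#' balance carries a formation/consumption term proportional to biomass
#' through its specific rate, plus inflow terms, minus a dilution term
#' `(x_j / V) * sum_i(a_ji * u_i)` from volume growth.
#'
#' @param state a [state_vector()].
#' @param feeds a [feed_vector()] (L/h).
#' @param rates a [rate_laws()] bundle of specific rates.
#' @param config a [model_config()].
#' @return Named numeric vector of the six time derivatives (units/h).
#' @export
state_rhs <- function(state, feeds, rates, config) {
  validate_state(state)
  x <- state
  u <- feeds
  V <- x[["V"]]
  dil <- (config$A[1:5, , drop = FALSE] %*% u)[, 1] / V  # per-state dilution rate

  r <- vapply(c("mu", "nu", "rho", "eta", "gamma"),
              function(nm) {
                val <- rates[[nm]](x)
                if (!is.finite(val))
                  stop(sprintf("rate law '%s' returned a non-finite value", nm))
                val
              }, numeric(1))

  s_in <- if (config$literal_substrate_inflow) config$S_C / V
          else config$S_C * u[["fC"]] / V

  c(X  = r[["mu"]] * x[["X"]] - x[["X"]] * dil[1],
    S  = -r[["nu"]] * x[["X"]] + s_in - x[["S"]] * dil[2],
    E  = r[["rho"]] * x[["X"]] - config$K_P * x[["E"]] +
         (config$K_M * u[["fM"]] + config$K_A * u[["fA"]]) / V -
         x[["E"]] * dil[3],
    CL = -r[["eta"]] * x[["X"]] + config$K_La * (config$C_L_star - x[["CL"]]) -
         x[["CL"]] * dil[4],
    H  = r[["gamma"]] * x[["X"]] - x[["H"]] * dil[5] +
         (config$S_f * u[["fC"]] - config$S_m * u[["fM"]] -
          config$S_n * u[["fN"]] - config$S_a * u[["fA"]]) / V,
    V  = sum(u))
}

#' Simulate the fermentation model on a time grid
#'
#' Integrates the balance equations with a fixed-step classical Runge-Kutta
#' scheme (deterministic and therefore exactly reproducible). Between
#' consecutive output times the solver takes equal substeps no longer than
#' `dt`. If `nonneg_clip` is set in the config, states are floored at zero
#' after each substep and the number of clipped components is recorded in
#' the `clips` attribute of the result.
#'
#' @param x0 initial [state_vector()].
#' @param feed_profile function of time returning a [feed_vector()] (L/h).
#' @param env_profile function of time returning an [env_vector()].
#' @param t_grid strictly increasing output times (h), first element is the
#'   initial time.
#' @param rates a [rate_laws()] bundle.
#' @param config a [model_config()].
#' @param dt maximum integration step (h).
#' @return A `ferm_trajectory`: a data frame with columns `t_h`, `X_gL`,
#'   `S_gL`, `E_UmL`, `CL`, `H_molL`, `V_L`, `fC_Lh`, `fN_Lh`, `fM_Lh`,
#'   `fA_Lh`, `Tw_C`, `Sa_rpm`, `Fa_Lmin`.
#' @export
#' @examples
#' rl <- default_rate_laws()
#' tr <- simulate_fermentation(
#'   state_vector(60, 8, 1, 40, 2e-6, 50),
#'   function(t) feed_vector(0.04, 0.002, 0.001, 0.0005),
#'   function(t) env_vector(), t_grid = seq(0, 2, by = 0.5),
#'   rates = rl, config = model_config())
simulate_fermentation <- function(x0, feed_profile, env_profile, t_grid,
                                  rates, config, dt = 0.01) {
  validate_state(x0)
  if (length(t_grid) < 1L || any(diff(t_grid) <= 0))
    stop("t_grid must be strictly increasing")
  if (dt <= 0) stop("dt must be positive")

  n <- length(t_grid)
  states <- matrix(NA_real_, n, 6, dimnames = list(NULL, .STATE_NAMES))
  feeds  <- matrix(NA_real_, n, 4, dimnames = list(NULL, .FEED_NAMES))
  envs   <- matrix(NA_real_, n, 3, dimnames = list(NULL, .ENV_NAMES))
  x <- x0
  states[1, ] <- x
  feeds[1, ]  <- feed_profile(t_grid[1])
  envs[1, ]   <- env_profile(t_grid[1])
  clips <- 0L

  rhs <- function(t, x) state_rhs(x, feed_profile(t), rates, config)

  for (i in seq_len(n - 1L)) {
    span <- t_grid[i + 1L] - t_grid[i]
    nsub <- max(1L, ceiling(span / dt - 1e-9))
    h <- span / nsub
    t <- t_grid[i]
    for (s in seq_len(nsub)) {
      k1 <- rhs(t, x)
      k2 <- rhs(t + h / 2, x + h / 2 * k1)
      k3 <- rhs(t + h / 2, x + h / 2 * k2)
      k4 <- rhs(t + h, x + h * k3)
      x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      if (!all(is.finite(x)))
        stop(sprintf("integrator failure at t = %.6g h (non-finite state)", t))
      if (config$nonneg_clip && any(x < 0)) {
        clips <- clips + sum(x < 0)
        x[x < 0] <- 0
      }
      t <- t + h
    }
    states[i + 1L, ] <- x
    feeds[i + 1L, ]  <- feed_profile(t_grid[i + 1L])
    envs[i + 1L, ]   <- env_profile(t_grid[i + 1L])
  }
  if (clips > 0L)
    warning(sprintf("%d negative state component(s) clipped to zero", clips))

  out <- data.frame(t_h = t_grid,
                    X_gL = states[, "X"], S_gL = states[, "S"],
                    E_UmL = states[, "E"], CL = states[, "CL"],
                    H_molL = states[, "H"], V_L = states[, "V"],
                    fC_Lh = feeds[, "fC"], fN_Lh = feeds[, "fN"],
                    fM_Lh = feeds[, "fM"], fA_Lh = feeds[, "fA"],
                    Tw_C = envs[, "Tw"], Sa_rpm = envs[, "Sa"],
                    Fa_Lmin = envs[, "Fa"])
  structure(out, clips = clips, class = c("ferm_trajectory", "data.frame"))
}

#' Extract the state matrix from a trajectory
#'
#' @param traj a `ferm_trajectory`.
#' @return Numeric matrix with columns `X`, `S`, `E`, `CL`, `H`, `V`.
#' @export
trajectory_states <- function(traj) {
  m <- as.matrix(traj[, c("X_gL", "S_gL", "E_UmL", "CL", "H_molL", "V_L")])
  colnames(m) <- .STATE_NAMES
  m
}

#' @export
print.ferm_trajectory <- function(x, ...) {
  cat(sprintf("Fermentation trajectory: %d time points, t = %.3g .. %.4g h\n",
              nrow(x), x$t_h[1], x$t_h[nrow(x)]))
  cat(sprintf("  final state: X = %.3g g/L, S = %.3g g/L, E = %.3g U/mL, ",
              x$X_gL[nrow(x)], x$S_gL[nrow(x)], x$E_UmL[nrow(x)]))
  cat(sprintf("CL = %.3g, pH = %.3g, V = %.3g L\n",
              x$CL[nrow(x)], -log10(x$H_molL[nrow(x)]), x$V_L[nrow(x)]))
  invisible(x)
}
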