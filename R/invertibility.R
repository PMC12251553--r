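# Local invertibility of the measurable-output map. The soft sensor rests
# on the claim that the time derivatives of the measurable outputs
# (z1, z2, z3) = (CL, H, V) carry enough independent information to pin
# down the unmeasured states (X, S, E). Operationally this is a rank
# condition: the 3x3 Jacobian of (z1dd, z1d, z2d) with respect to
# (x1, x2, x3) must have full rank at the operating point. All derivatives
# here are numerical (central differences), both along the flow and across
# states; the printed symbolic factorisations of this Jacobian are not
# reconstructable and are replaced by numerical diagnostics.

rk4_arc <- function(state, feeds, rates, config, span, nsub = 4L) {
  h <- span / nsub
  x <- state
  rhs <- function(x) state_rhs(x, feeds, rates, config)
  for (s in seq_len(nsub)) {
    k1 <- rhs(x)
    k2 <- rhs(x + h / 2 * k1)
    k3 <- rhs(x + h / 2 * k2)
    k4 <- rhs(x + h * k3)
    x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  x
}

#' Time derivatives of the measurable outputs along the flow
#'
#' Computes the first derivatives of dissolved oxygen (`z1_dot`) and
#' hydrogen-ion concentration (`z2_dot`) directly from the balance
#' equations, and the second derivative of dissolved oxygen (`z1_ddot`) by
#' a central finite difference of `z1_dot` along a short simulated arc with
#' the feeds held constant.
#'
#' @param state a [state_vector()].
#' @param feeds a [feed_vector()] (L/h), held constant over the arc.
#' @param rates a [rate_laws()] bundle.
#' @param config a [model_config()].
#' @param h_t half-width of the flow arc (h) used for the second
#'   derivative.
#' @return List with `z` (`z1`, `z2`, `z3` = `CL`, `H`, `V`), `z1_dot`,
#'   `z1_ddot`, `z2_dot`.
#' @export
output_derivatives <- function(state, feeds, rates, config, h_t = 1e-3) {
  if (h_t <= 0) stop("h_t must be positive")
  validate_state(state)
  xdot <- state_rhs(state, feeds, rates, config)
  xp <- rk4_arc(state, feeds, rates, config, h_t)
  xm <- rk4_arc(state, feeds, rates, config, -h_t)
  z1d_p <- state_rhs(xp, feeds, rates, config)[["CL"]]
  z1d_m <- state_rhs(xm, feeds, rates, config)[["CL"]]
  z1_ddot <- (z1d_p - z1d_m) / (2 * h_t)
  if (!is.finite(z1_ddot))
    stop("finite-difference estimate of the second output derivative is not finite; reduce h_t")
  list(z = c(z1 = state[["CL"]], z2 = state[["H"]], z3 = state[["V"]]),
       z1_dot = xdot[["CL"]], z1_ddot = z1_ddot, z2_dot = xdot[["H"]])
}

#' Numerical rank by singular-value thresholding
#'
#' Counts singular values above `tol_factor` times the largest. With
#' `equilibrate = TRUE` (the default used by the invertibility test) the
#' matrix rows are first divided by their largest absolute entry, which
#' leaves the rank unchanged in exact arithmetic but stops physically
#' tiny rows (the hydrogen-ion balance lives at 1e-6 mol/L while
#' dissolved oxygen lives at tens of percent) from drowning below the
#' threshold.
#'
#' @param J numeric matrix.
#' @param tol_factor relative singular-value threshold.
#' @param equilibrate divide each row by its max absolute entry first.
#' @return List with `rank`, `singular_values`, `tol`.
#' @export
numerical_rank <- function(J, tol_factor = 1e-8, equilibrate = TRUE) {
  Js <- J
  if (equilibrate) {
    rs <- apply(abs(Js), 1, max)
    rs[rs == 0] <- 1
    Js <- Js / rs
  }
  sv <- tryCatch(svd(Js, nu = 0, nv = 0)$d,
                 error = function(e) stop("singular-value computation failed: ",
                                          conditionMessage(e)))
  tol <- max(sv) * tol_factor
  list(rank = sum(sv > tol), singular_values = sv, tol = tol)
}

#' Numerical Jacobian of the output derivatives w.r.t. the unmeasured states
#'
#' Builds the 3x3 matrix `J = d(z1_ddot, z1_dot, z2_dot) / d(x1, x2, x3)`
#' by central finite differences (step `h` in scaled state units), then
#' judges invertibility by singular-value thresholding of the scaled
#' Jacobian (columns in units of the state scales, rows equilibrated; see
#' [numerical_rank()]): the rank counts singular values above
#' `tol_factor * max(sigma)` and the operating point is declared
#' invertible when the rank is 3.
#'
#' `det_diagnostic` is a heuristic product-form proxy for the determinant
#' condition of the theory: the determinant of the scaled Jacobian times
#' the normalised growth-coupling factor `d(eta)/d(x1)`, so it vanishes
#' both when the Jacobian is singular and when the oxygen-uptake rate does
#' not respond to biomass.
#'
#' @param state,feeds,rates,config as in [output_derivatives()].
#' @param h relative finite-difference step for the state perturbations.
#' @param h_t flow-arc half width passed to [output_derivatives()].
#' @param tol_factor relative singular-value threshold for the rank.
#' @return Object of class `jacobian_report`: `J`, `singular_values`,
#'   `rank`, `tol`, `invertible`, `det_diagnostic`, `g_terms` (numerically
#'   evaluated gradients of `eta` and `gamma` and the biomass coupling).
#' @export
jacobian_outputs <- function(state, feeds, rates, config, h = 1e-4,
                             h_t = 1e-3, tol_factor = 1e-8) {
  validate_state(state)
  f <- function(x) {
    od <- output_derivatives(x, feeds, rates, config, h_t = h_t)
    c(od$z1_ddot, od$z1_dot, od$z2_dot)
  }
  J <- matrix(NA_real_, 3, 3,
              dimnames = list(c("z1_ddot", "z1_dot", "z2_dot"),
                              c("x1", "x2", "x3")))
  scales <- pmax(abs(state[1:3]), 1)
  for (j in 1:3) {
    step <- h * scales[j]
    xp <- state; xp[j] <- xp[j] + step
    xm <- state; xm[j] <- xm[j] - step
    J[, j] <- (f(xp) - f(xm)) / (2 * step)
  }
  Jcol <- sweep(J, 2, scales, "*")   # columns in scaled (dimensionless) state units
  nr <- numerical_rank(Jcol, tol_factor = tol_factor, equilibrate = TRUE)
  sv <- nr$singular_values
  tol <- nr$tol
  rank <- nr$rank
  eta_grad <- rates$grad("eta", state)
  gamma_grad <- rates$grad("gamma", state)
  eta_val <- rates$eta(state)
  # normalised coupling factor in [0, 1]; zero iff d(eta)/d(x1) = 0
  den <- abs(eta_grad[[1]] * state[["X"]]) + abs(eta_val)
  coupling <- if (den > 0) abs(eta_grad[[1]] * state[["X"]]) / den else 0
  rs <- apply(abs(Jcol), 1, max); rs[rs == 0] <- 1
  structure(list(J = J, J_scaled = Jcol / rs,
                 singular_values = sv, rank = rank, tol = tol,
                 invertible = rank == 3L,
                 det_diagnostic = det(Jcol / rs) * coupling,
                 g_terms = list(eta_grad = eta_grad[1:3],
                                gamma_grad = gamma_grad[1:3],
                                eta = eta_val, gamma = rates$gamma(state),
                                coupling = coupling)),
            class = "jacobian_report")
}

#' @export
print.jacobian_report <- function(x, ...) {
  cat("Output-derivative Jacobian w.r.t. (X, S, E):\n")
  print(signif(x$J, 4))
  cat(sprintf("singular values: %s\nrank = %d (tol %.3g) -> %s\n",
              paste(signif(x$singular_values, 4), collapse = ", "),
              x$rank, x$tol,
              if (x$invertible) "locally invertible" else "NOT invertible"))
  invisible(x)
}

#' Scan a trajectory for local invertibility
#'
#' Evaluates [jacobian_outputs()] at every `stride`-th time point of a
#' simulated or logged trajectory and summarises the fraction of operating
#' points at which the rank condition holds.
#'
#' @param traj a `ferm_trajectory`.
#' @param rates,config model components used to rebuild the derivatives.
#' @param stride sampling stride along the trajectory (>= 1).
#' @param ... passed to [jacobian_outputs()].
#' @return List of class `invertibility_scan`: `t_h`, `reports`, `ranks`,
#'   `fraction_invertible`.
#' @export
invertibility_scan <- function(traj, rates, config, stride = 10L, ...) {
  if (!is.data.frame(traj) || nrow(traj) == 0L)
    stop("trajectory is empty")
  stride <- max(1L, as.integer(stride))
  idx <- seq(1L, nrow(traj), by = stride)
  states <- trajectory_states(traj)
  reports <- lapply(idx, function(i) {
    st <- states[i, ]
    fe <- c(fC = traj$fC_Lh[i], fN = traj$fN_Lh[i],
            fM = traj$fM_Lh[i], fA = traj$fA_Lh[i])
    jacobian_outputs(st, fe, rates, config, ...)
  })
  ranks <- vapply(reports, `[[`, integer(1), "rank")
  structure(list(t_h = traj$t_h[idx], reports = reports, ranks = ranks,
                 fraction_invertible = mean(ranks == 3L)),
            class = "invertibility_scan")
}

#' @export
print.invertibility_scan <- function(x, ...) {
  cat(sprintf("Invertibility scan: %d operating points, %.1f%% with rank 3\n",
              length(x$ranks), 100 * x$fraction_invertible))
  invisible(x)
}
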