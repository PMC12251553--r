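#' Bundle specific-rate laws
#'
#' The grey-box balances leave the five specific rates (growth `mu`,
#' substrate uptake `nu`, enzyme production `rho`, oxygen uptake `eta`,
#' proton release `gamma`) unspecified; any state-dependent functional form
#' can be plugged in here. Each law maps a [state_vector()] to a scalar
#' rate. Gradients with respect to the state are taken by central finite
#' differences unless analytic gradients are supplied in `grads` (functions
#' returning a length-6 vector).
#'
#' @param mu,nu,rho,eta,gamma functions `state -> scalar`.
#' @param grads optional named list of gradient functions.
#' @param params parameter list retained for reference.
#' @return An object of class `rate_laws`.
#' @export
rate_laws <- function(mu, nu, rho, eta, gamma, grads = NULL, params = NULL) {
  laws <- list(mu = mu, nu = nu, rho = rho, eta = eta, gamma = gamma)
  stopifnot(all(vapply(laws, is.function, logical(1))))
  laws$params <- params
  laws$grad <- function(which, state, h = 1e-6) {
    if (!is.null(grads[[which]])) return(grads[[which]](state))
    f <- laws[[which]]
    g <- numeric(6)
    for (j in 1:6) {
      step <- h * max(abs(state[j]), 1e-3)
      xp <- state; xp[j] <- xp[j] + step
      xm <- state; xm[j] <- xm[j] - step
      g[j] <- (f(xp) - f(xm)) / (2 * step)
    }
    names(g) <- names(state)
    g
  }
  class(laws) <- "rate_laws"
  laws
}

#' Default kinetic parameter set
#'
#' Fixture-scale parameters for a high-density methanol-induction culture.
#' They are illustrative values chosen to produce realistic trajectory
#' shapes (slow growth, declining dissolved oxygen, accumulating enzyme),
#' not estimates of any particular plant.
#'
#' @param mu_max maximum specific growth rate (1/h).
#' @param K_S substrate half-saturation constant (g/L).
#' @param K_i substrate inhibition constant (g/L); `Inf` disables.
#' @param K_O oxygen half-saturation constant (CL units).
#' @param X_max crowding capacity (g/L); `Inf` disables.
#' @param K_E product-burden constant (U/mL); growth slows as the
#'   recombinant product accumulates; `Inf` disables.
#' @param Y_XS biomass yield on substrate (g/g); `m_S` maintenance uptake
#'   (g substrate/(g cell h)).
#' @param alpha,beta growth-associated and constitutive enzyme production
#'   coefficients (Luedeking-Piret form).
#' @param Y_XO biomass yield on oxygen; `m_O` maintenance oxygen uptake.
#' @param g_max,K_H proton release scale (mol H+/(g cell h)) and its own
#'   substrate half-saturation (g/L).
#' @param m_S,m_O maintenance coefficients, see above.
#' @return Named list of kinetic parameters.
#' @export
kinetic_params <- function(mu_max = 0.01, K_S = 6, K_i = 60, K_O = 8,
                           X_max = 150, K_E = 300,
                           Y_XS = 0.3, m_S = 0.002,
                           alpha = 2, beta = 0.001,
                           Y_XO = 0.005, m_O = 1.2,
                           g_max = 1e-10, K_H = 2) {
  p <- list(mu_max = mu_max, K_S = K_S, K_i = K_i, K_O = K_O, X_max = X_max,
            K_E = K_E, Y_XS = Y_XS, m_S = m_S, alpha = alpha, beta = beta,
            Y_XO = Y_XO, m_O = m_O, g_max = g_max, K_H = K_H)
  if (p$Y_XS <= 0 || p$Y_XO <= 0) stop("yields Y_XS and Y_XO must be positive")
  if (p$K_S <= 0 || p$K_O <= 0 || p$K_H <= 0)
    stop("saturation constants must be positive")
  p
}

#' Default specific-rate laws
#'
#' Growth follows a Monod term with substrate inhibition
#' (`S / (K_S + S + S^2/K_i)`), oxygen limitation (`CL / (K_O + CL)`),
#' logistic crowding (`1 - X/X_max`) and a product-burden factor
#' (`1 / (1 + E/K_E)`) reflecting the metabolic cost of recombinant
#' protein expression. Substrate and oxygen uptake are yield-plus-
#' maintenance couplings to growth; enzyme production is Luedeking-Piret
#' (growth-associated plus constitutive); proton release carries its own
#' substrate saturation `g_max * S / (K_H + S)` so that acidification is
#' tied to methanol oxidation rather than strictly to growth. The burden
#' and proton terms give all three unmeasured states an independent
#' signature in the measurable outputs, which is what makes the
#' inverse-system construction well posed (see the methods vignette).
#' Analytic state gradients are attached for use as diagnostics and test
#' oracles.
#'
#' @param params a [kinetic_params()] list.
#' @return A [rate_laws()] object.
#' @export
default_rate_laws <- function(params = kinetic_params()) {
  p <- params
  mu <- function(x) {
    s <- x[["S"]] / (p$K_S + x[["S"]] + x[["S"]]^2 / p$K_i)
    o <- x[["CL"]] / (p$K_O + x[["CL"]])
    crowd <- if (is.finite(p$X_max)) max(0, 1 - x[["X"]] / p$X_max) else 1
    burden <- if (is.finite(p$K_E)) 1 / (1 + x[["E"]] / p$K_E) else 1
    p$mu_max * s * o * crowd * burden
  }
  nu <- function(x) mu(x) / p$Y_XS + p$m_S
  rho <- function(x) p$alpha * mu(x) + p$beta
  eta <- function(x) mu(x) / p$Y_XO + p$m_O
  gam <- function(x) p$g_max * x[["S"]] / (p$K_H + x[["S"]])

  mu_grad <- function(x) {
    S <- x[["S"]]; CL <- x[["CL"]]; X <- x[["X"]]; E <- x[["E"]]
    den <- p$K_S + S + S^2 / p$K_i
    s <- S / den
    o <- CL / (p$K_O + CL)
    crowd <- if (is.finite(p$X_max)) 1 - X / p$X_max else 1
    if (crowd < 0) return(numeric(6))
    burden <- if (is.finite(p$K_E)) 1 / (1 + E / p$K_E) else 1
    m <- p$mu_max * s * o * crowd * burden
    ds <- (den - S * (1 + 2 * S / p$K_i)) / den^2       # d s / d S
    g <- numeric(6)
    g[1] <- if (is.finite(p$X_max)) -p$mu_max * s * o * burden / p$X_max else 0
    g[2] <- p$mu_max * ds * o * crowd * burden
    g[3] <- if (is.finite(p$K_E)) -m / (p$K_E * (1 + E / p$K_E)) else 0
    g[4] <- p$mu_max * s * crowd * burden * p$K_O / (p$K_O + CL)^2
    names(g) <- .STATE_NAMES
    g
  }
  gam_grad <- function(x) {
    g <- numeric(6)
    g[2] <- p$g_max * p$K_H / (p$K_H + x[["S"]])^2
    names(g) <- .STATE_NAMES
    g
  }
  grads <- list(
    mu = mu_grad,
    nu = function(x) mu_grad(x) / p$Y_XS,
    rho = function(x) p$alpha * mu_grad(x),
    eta = function(x) mu_grad(x) / p$Y_XO,
    gamma = gam_grad)

  rate_laws(mu, nu, rho, eta, gam, grads = grads, params = p)
}

#' Degenerate constant-rate laws
#'
#' Specific rates that do not depend on the state at all. Useful as a
#' negative control: with constant oxygen-uptake and proton-release rates
#' the measurable outputs carry no independent information about the
#' substrate and enzyme states and the invertibility test must fail.
#'
#' @param mu,nu,rho,eta,gamma constant rate values.
#' @return A [rate_laws()] object with zero analytic gradients.
#' @export
constant_rate_laws <- function(mu = 0, nu = 0, rho = 0, eta = 0, gamma = 0) {
  zero6 <- function(x) structure(numeric(6), names = .STATE_NAMES)
  rate_laws(function(x) mu, function(x) nu, function(x) rho,
            function(x) eta, function(x) gamma,
            grads = list(mu = zero6, nu = zero6, rho = zero6,
                         eta = zero6, gamma = zero6))
}
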