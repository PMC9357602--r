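#' Delayed reaction--diffusion model specifications
#'
#' Three two-species kinetics with a gene-expression delay are supported, all
#' in nondimensional form on the unit interval:
#' \describe{
#'   \item{\code{"LI"}}{the ligand-internalisation Schnakenberg
#'     (activator-depleted) variant. The delay acts only on the activator's
#'     autocatalytic term: \eqn{u_t = (\epsilon^2/L^2) u_{xx} + a - u - 2u^2v +
#'     3\mathcal{F}}, \eqn{v_t = (1/L^2) v_{xx} + b - u^2 v}, with
#'     \eqn{\mathcal{F}} the kernel-weighted delayed value of \eqn{u^2 v}.}
#'   \item{\code{"GM1"}}{Gierer--Meinhardt with both arguments of the
#'     activator's \eqn{u^2/v} term delayed, and the inhibitor production
#'     \eqn{u^2} delayed.}
#'   \item{\code{"GM2"}}{as GM1 but with the inhibitor entering \eqn{u^2/v}
#'     instantaneously; only \eqn{u^2} is delayed.}
#' }
#' \eqn{a, b} are kinetic feed parameters, \eqn{\epsilon^2} the
#' activator/inhibitor diffusion ratio, and \eqn{L^2} the nondimensional
#' domain-size scaling.
#'
#' @param kinetics one of \code{"LI"}, \code{"GM1"}, \code{"GM2"}.
#' @param a,b kinetic parameters; the steady state must be positive, which
#'   requires \code{a + b > 0} for LI and \code{b > 0} for the GM variants.
#' @param eps2 diffusion ratio \eqn{\epsilon^2 > 0} (default 0.001).
#' @param L2 domain scaling \eqn{L^2 > 0} (default 4.5).
#' @return an object of class \code{"rd_model"}.
#' @examples
#' m <- rd_model("LI", a = 0.1, b = 0.9)
#' steady_state(m)
#' @export
rd_model <- function(kinetics = c("LI", "GM1", "GM2"), a, b,
                     eps2 = 0.001, L2 = 4.5) {
  kinetics <- match.arg(kinetics)
  if (!is.finite(a) || !is.finite(b) || a < 0)
    stop("`a` must be finite and >= 0, `b` finite")
  if (kinetics == "LI" && a + b <= 0)
    stop("LI model needs a + b > 0 for a positive steady state")
  if (kinetics != "LI" && b <= 0)
    stop("GM models need b > 0 for a positive steady state")
  if (eps2 <= 0 || L2 <= 0) stop("`eps2` and `L2` must be > 0")
  structure(list(kinetics = kinetics, a = a, b = b, eps2 = eps2, L2 = L2),
            class = "rd_model")
}

#' @export
print.rd_model <- function(x, ...) {
  ss <- steady_state(x)
  cat("<rd_model>", x$kinetics, " a =", x$a, " b =", x$b,
      " eps2 =", x$eps2, " L2 =", x$L2, "\n")
  cat("  steady state (u*, v*) = (", ss[1], ",", ss[2], ")\n")
  invisible(x)
}

#' Homogeneous steady state
#'
#' LI: \eqn{(u_\star, v_\star) = (a + b,\; b/(a+b)^2)}. GM1/GM2:
#' \eqn{((a+1)/b,\; ((a+1)/b)^2)}.
#'
#' @param model an \code{\link{rd_model}}.
#' @return named numeric vector \code{c(u = , v = )}, both components > 0.
#' @export
steady_state <- function(model) {
  stopifnot(inherits(model, "rd_model"))
  if (model$kinetics == "LI") {
    u <- model$a + model$b
    c(u = u, v = model$b / u^2)
  } else {
    u <- (model$a + 1) / model$b
    c(u = u, v = u^2)
  }
}

#' Delayed-step kinetics F and G
#'
#' The reaction steps carrying the gene-expression delay, evaluated on
#' (possibly lagged) concentrations. For LI, \eqn{F = u^2 v} (no delayed G);
#' for GM1, \eqn{F = u^2/v} and \eqn{G = u^2}; for GM2, \eqn{F = G = u^2}
#' (the inhibitor in \eqn{u^2/v} is instantaneous and is applied inside
#' \code{\link{kinetic_rhs}}).
#'
#' @param model an \code{\link{rd_model}}.
#' @param u,v concentrations (vectors allowed).
#' @return list with components \code{F} and \code{G} (\code{G} is \code{NULL}
#'   for LI).
#' @export
delayed_kinetics <- function(model, u, v) {
  switch(model$kinetics,
    LI = list(F = u^2 * v, G = NULL),
    GM1 = list(F = u^2 / v, G = u^2),
    GM2 = list(F = u^2, G = u^2))
}

#' Reaction right-hand sides with the delayed terms supplied
#'
#' Evaluates the kinetic (non-diffusive) part of the model with the
#' kernel-averaged delayed values passed in, so the same kinetics serve the
#' linear analysis and both the fixed- and distributed-delay simulators.
#'
#' @param model an \code{\link{rd_model}}.
#' @param u,v instantaneous concentrations.
#' @param F_val,G_val kernel-averaged delayed reaction values as produced by
#'   \code{\link{delayed_kinetics}} under the kernel integral. \code{G_val} is
#'   ignored for LI.
#' @return list with \code{du} and \code{dv}, the reaction rates.
#' @export
kinetic_rhs <- function(model, u, v, F_val, G_val = NULL) {
  switch(model$kinetics,
    LI = list(du = model$a - u - 2 * u^2 * v + 3 * F_val,
              dv = model$b - u^2 * v),
    GM1 = list(du = model$a - model$b * u + F_val,
               dv = G_val - v),
    GM2 = {
      if (any(v == 0)) stop("GM2 ratio term u_delayed^2 / v hit v = 0")
      list(du = model$a - model$b * u + F_val / v,
           dv = G_val - v)
    })
}

## instantaneous (J) and delayed (D) Jacobians of the kinetics at the steady
## state; the delayed block collects (df/dF)(dF/du) etc.
kinetic_jacobians <- function(model) {
  ss <- steady_state(model)
  u <- ss[["u"]]; v <- ss[["v"]]
  switch(model$kinetics,
    LI = list(J = matrix(c(-1 - 4 * u * v, -2 * u^2,
                           -2 * u * v, -u^2), 2, 2, byrow = TRUE),
              D = matrix(c(6 * u * v, 3 * u^2, 0, 0), 2, 2, byrow = TRUE)),
    GM1 = list(J = matrix(c(-model$b, 0, 0, -1), 2, 2, byrow = TRUE),
               D = matrix(c(2 * u / v, -u^2 / v^2, 2 * u, 0), 2, 2,
                          byrow = TRUE)),
    GM2 = list(J = matrix(c(-model$b, -u^2 / v^2, 0, -1), 2, 2, byrow = TRUE),
               D = matrix(c(2 * u / v, 0, 2 * u, 0), 2, 2, byrow = TRUE)))
}

#' Coefficients of the transcendental dispersion relation
#'
#' For wavenumber \eqn{k} the characteristic equation of the linearised model
#' is \deqn{\lambda^2 + \alpha_k \lambda + \beta_k + (\gamma_k \lambda +
#' \delta_k) E(\lambda) + \chi_k E(\lambda)^2 = 0,} with \eqn{E} the kernel
#' transform (\code{\link{kernel_laplace}}). The coefficients depend only on
#' the model parameters, assembled from the instantaneous and delayed
#' Jacobians at the steady state plus the diffusive contributions
#' \eqn{(\epsilon^2/L^2)k^2\pi^2} and \eqn{(1/L^2)k^2\pi^2}. \eqn{\chi_k = 0}
#' for LI and GM2.
#'
#' @param model an \code{\link{rd_model}}.
#' @param k integer wavenumber(s), vectorised.
#' @return data frame with columns \code{k, alpha, beta, gamma, delta, chi}.
#' @export
dispersion_coefficients <- function(model, k) {
  stopifnot(all(k >= 0), all(k == round(k)))
  jd <- kinetic_jacobians(model)
  J <- jd$J; D <- jd$D
  du <- model$eps2 / model$L2 * (k * pi)^2
  dv <- 1 / model$L2 * (k * pi)^2
  data.frame(
    k = k,
    alpha = du + dv - J[1, 1] - J[2, 2],
    beta = (du - J[1, 1]) * (dv - J[2, 2]) - J[1, 2] * J[2, 1],
    gamma = rep(-D[1, 1] - D[2, 2], length(k)),
    delta = -D[2, 2] * (du - J[1, 1]) - D[1, 1] * (dv - J[2, 2]) -
      J[1, 2] * D[2, 1] - J[2, 1] * D[1, 2],
    chi = rep(D[1, 1] * D[2, 2] - D[1, 2] * D[2, 1], length(k)))
}

## vectorised coefficient assembly over (a, b) vectors for a fixed k.
## Degenerate parameter points (undefined steady state) yield NA coefficients
## and are excluded downstream.
dispersion_coefficients_grid <- function(kinetics, a, b, eps2, L2, k) {
  if (kinetics == "LI") {
    us <- a + b
    us[us <= 0] <- NA_real_
    vs <- b / us^2
    J11 <- -1 - 4 * us * vs; J12 <- -2 * us^2
    J21 <- -2 * us * vs; J22 <- -us^2
    D11 <- 6 * us * vs; D12 <- 3 * us^2; D21 <- 0 * us; D22 <- 0 * us
  } else {
    bb <- ifelse(b > 0, b, NA_real_)
    us <- (a + 1) / bb
    vs <- us^2
    J11 <- -bb + 0 * us; J22 <- -1 + 0 * us
    D11 <- 2 * us / vs; D21 <- 2 * us; D22 <- 0 * us
    if (kinetics == "GM1") {
      J12 <- 0 * us; J21 <- 0 * us; D12 <- -us^2 / vs^2
    } else {
      J12 <- -us^2 / vs^2; J21 <- 0 * us; D12 <- 0 * us
    }
  }
  du <- eps2 / L2 * (k * pi)^2
  dv <- 1 / L2 * (k * pi)^2
  list(alpha = du + dv - J11 - J22,
       beta = (du - J11) * (dv - J22) - J12 * J21,
       gamma = -D11 - D22,
       delta = -D22 * (du - J11) - D11 * (dv - J22) - J12 * D21 - J21 * D12,
       chi = D11 * D22 - D12 * D21)
}
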