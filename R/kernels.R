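#' Delay-kernel specifications
#'
#' A delay kernel is the probability density of gene-expression delay times
#' entering the distributed-delay reaction--diffusion model. Three families are
#' supported:
#' \describe{
#'   \item{\code{"dirac"}}{a fixed delay \eqn{\tau}; the density is
#'     \eqn{\delta(s-\tau)}.}
#'   \item{\code{"gaussian"}}{a symmetric Gaussian with mean \eqn{\tau} and
#'     standard deviation \eqn{\sigma}, truncated to
#'     \eqn{[\tau - n\sigma, \tau + n\sigma]} and renormalised.}
#'   \item{\code{"skew_gaussian"}}{a skew-normal with location \eqn{\mu},
#'     scale \eqn{\omega} and skew factor \eqn{\rho}, truncated to
#'     \eqn{[\mu - n\omega, \mu + n\omega]} and renormalised. Its mean
#'     \eqn{\tau} is computed from the closed-form truncated skew-normal mean
#'     and stored on the object.}
#' }
#' The truncation window must contain strictly positive delays only, so
#' \eqn{\sigma < \tau/n} (equivalently \eqn{\omega < \mu/n}); the largest
#' admissible spread is \eqn{\sigma_{\max} = \tau/n}.
#'
#' @param family one of \code{"dirac"}, \code{"gaussian"},
#'   \code{"skew_gaussian"}.
#' @param tau mean delay (dirac and gaussian families), nondimensional time,
#'   must be positive (zero is allowed for the dirac family and denotes the
#'   undelayed model).
#' @param sigma standard deviation of the gaussian family.
#' @param mu,omega,rho location, scale and skew factor of the skew family.
#' @param n truncation half-width multiplier (default 3).
#' @return an object of class \code{"delay_kernel"} with fields
#'   \code{family}, \code{tau} (the mean delay for every family), the family
#'   parameters, and the truncation window \code{tau1}, \code{tau2}.
#' @examples
#' delay_kernel("gaussian", tau = 1, sigma = 0.2)
#' delay_kernel("skew_gaussian", mu = 1, omega = 0.3, rho = 10)
#' @export
delay_kernel <- function(family = c("dirac", "gaussian", "skew_gaussian"),
                         tau = NULL, sigma = NULL, mu = NULL, omega = NULL,
                         rho = NULL, n = 3) {
  family <- match.arg(family)
  if (n <= 0 || n != round(n)) stop("`n` must be a positive integer")
  k <- switch(family,
    dirac = {
      if (is.null(tau) || !is.finite(tau) || tau < 0)
        stop("dirac kernel needs a finite mean delay `tau` >= 0")
      list(family = family, tau = tau, sigma = 0, n = n,
           tau1 = tau, tau2 = tau)
    },
    gaussian = {
      if (is.null(tau) || is.null(sigma)) stop("gaussian kernel needs `tau` and `sigma`")
      if (sigma < 0) stop("`sigma` must be >= 0")
      if (sigma == 0)
        return(delay_kernel("dirac", tau = tau, n = n))
      if (tau - n * sigma <= 0)
        stop("truncation bound tau1 = tau - ", n, "*sigma must be > 0 ",
             "(positive delays only); require sigma < tau/", n)
      list(family = family, tau = tau, sigma = sigma, n = n,
           tau1 = tau - n * sigma, tau2 = tau + n * sigma)
    },
    skew_gaussian = {
      if (is.null(mu) || is.null(omega) || is.null(rho))
        stop("skew_gaussian kernel needs `mu`, `omega` and `rho`")
      if (omega <= 0) stop("`omega` must be > 0")
      if (mu - n * omega <= 0)
        stop("truncation bound tau1 = mu - ", n, "*omega must be > 0 ",
             "(positive delays only); require omega < mu/", n)
      tau_mean <- skew_trunc_mean(mu, omega, rho, n)
      list(family = family, tau = tau_mean, mu = mu, omega = omega,
           rho = rho, n = n, tau1 = mu - n * omega, tau2 = mu + n * omega)
    })
  structure(k, class = "delay_kernel")
}

#' @export
print.delay_kernel <- function(x, ...) {
  cat("<delay_kernel> family:", x$family, "\n")
  cat("  mean delay tau =", format(x$tau), "\n")
  if (x$family == "gaussian") cat("  sigma =", x$sigma, " n =", x$n, "\n")
  if (x$family == "skew_gaussian")
    cat("  mu =", x$mu, " omega =", x$omega, " rho =", x$rho, " n =", x$n, "\n")
  cat("  truncation window [", x$tau1, ",", x$tau2, "]\n")
  invisible(x)
}

#' Standard normal cumulative distribution function
#'
#' Thin validated wrapper used throughout the kernel machinery; equal to
#' \eqn{(1 + \mathrm{erf}(x/\sqrt 2))/2}.
#'
#' @param x numeric vector, finite.
#' @return probabilities in \[0, 1\].
#' @export
std_normal_cdf <- function(x) {
  if (!all(is.finite(x))) stop("`x` must be finite")
  stats::pnorm(x)
}

#' Owen's T function
#'
#' \eqn{T(x, \rho) = \frac{1}{2\pi}\int_0^{\rho}
#'   \frac{e^{-x^2(1+s^2)/2}}{1+s^2}\,ds}, evaluated by composite Simpson
#' quadrature. Antisymmetric in \eqn{\rho}. Used in the cdf of the skew-normal
#' distribution, \eqn{\Psi(x, \rho) = \Phi(x) - 2T(x, \rho)}, which enters the
#' truncation constant of the skew kernel.
#'
#' @param x,rho finite numerics (scalars).
#' @param nodes odd number of Simpson nodes (default 100001).
#' @return the value of the integral.
#' @examples
#' owens_t(0, 1)   # arctan(1) / (2*pi) = 1/8
#' @export
owens_t <- function(x, rho, nodes = 100001L) {
  if (!is.finite(x) || !is.finite(rho)) stop("`x` and `rho` must be finite")
  if (rho == 0) return(0)
  if (nodes %% 2L == 0L) nodes <- nodes + 1L
  s <- seq(0, rho, length.out = nodes)
  f <- exp(-0.5 * x^2 * (1 + s^2)) / (1 + s^2)
  simpson_sum(f, s[2] - s[1]) / (2 * pi)
}

## composite Simpson on equally spaced samples (odd length)
simpson_sum <- function(f, h) {
  n <- length(f)
  w <- rep(c(2, 4), length.out = n)
  w[1] <- 1; w[n] <- 1
  sum(w * f) * h / 3
}

## Simpson nodes and weights on [a, b] with an odd node count
simpson_rule <- function(a, b, nodes = 51L) {
  if (nodes %% 2L == 0L) nodes <- nodes + 1L
  s <- seq(a, b, length.out = nodes)
  h <- (b - a) / (nodes - 1L)
  w <- rep(c(2, 4), length.out = nodes)
  w[1] <- 1; w[nodes] <- 1
  list(s = s, w = w * h / 3)
}

## skew-normal cdf Psi(x, rho) = Phi(x) - 2 T(x, rho)
skew_normal_cdf <- function(x, rho, nodes = 100001L) {
  stats::pnorm(x) - 2 * owens_t(x, rho, nodes)
}

## truncation constant of the skew kernel over standardized window [-n, n]
skew_trunc_const <- function(rho, n = 3) {
  1 / (skew_normal_cdf(n, rho) - skew_normal_cdf(-n, rho))
}

## closed-form mean of the skew-normal truncated to [mu - n*omega, mu + n*omega].
## Derived by integrating s*K_S by parts; the boundary terms carry the
## standardized untruncated density 2 phi(z) Phi(rho z) and the skew correction
## integrates to a difference of normal cdfs at rho_hat * z.
skew_trunc_mean <- function(mu, omega, rho, n = 3) {
  al <- -n; be <- n
  rho_hat <- sqrt(1 + rho^2)
  psi_c <- skew_trunc_const(rho, n)
  bracket <- 2 * stats::dnorm(al) * stats::pnorm(rho * al) -
    2 * stats::dnorm(be) * stats::pnorm(rho * be) +
    (2 * rho / (rho_hat * sqrt(2 * pi))) *
      (stats::pnorm(rho_hat * be) - stats::pnorm(rho_hat * al))
  mu + omega * psi_c * bracket
}

#' Kernel probability density
#'
#' Evaluates the (truncated, renormalised) delay density at delay \code{s}.
#' Outside the truncation window the density is 0 by convention, so quadrature
#' nodes may straddle the boundary harmlessly. The dirac family has no density;
#' requesting it is an error.
#'
#' @param kernel a \code{\link{delay_kernel}}.
#' @param s numeric vector of delays.
#' @return nonnegative densities integrating to 1 over
#'   \code{[kernel$tau1, kernel$tau2]}.
#' @export
kernel_pdf <- function(kernel, s) {
  stopifnot(inherits(kernel, "delay_kernel"))
  if (kernel$family == "dirac")
    stop("the dirac kernel is a point mass and has no density")
  out <- numeric(length(s))
  inside <- s >= kernel$tau1 & s <= kernel$tau2
  if (kernel$family == "gaussian") {
    phi_c <- 1 / (stats::pnorm(kernel$n) - stats::pnorm(-kernel$n))
    z <- (s[inside] - kernel$tau) / kernel$sigma
    out[inside] <- phi_c * stats::dnorm(z) / kernel$sigma
  } else {
    psi_c <- skew_trunc_const(kernel$rho, kernel$n)
    z <- (s[inside] - kernel$mu) / kernel$omega
    out[inside] <- psi_c / kernel$omega * sqrt(2 / pi) *
      exp(-z^2 / 2) * stats::pnorm(kernel$rho * z)
  }
  out
}

#' Mean delay of a kernel
#'
#' For the dirac and gaussian families the mean is the \code{tau} parameter
#' (symmetric truncation preserves the mean); for the skew family it is the
#' truncated skew-normal closed form stored at construction.
#'
#' @param kernel a \code{\link{delay_kernel}}.
#' @return the mean delay, nondimensional time.
#' @export
kernel_mean <- function(kernel) {
  stopifnot(inherits(kernel, "delay_kernel"))
  kernel$tau
}

#' Solve for the skew-kernel location given a target mean
#'
#' Inverts the truncated skew-normal mean relation: finds \eqn{\mu} such that
#' the kernel with scale \eqn{\omega} and skew \eqn{\rho} has mean \code{tau}.
#' The scale may be given explicitly, or coupled to the location as a fraction
#' of its admissible maximum \eqn{\omega_{\max} = \mu/n}; in the coupled case
#' the mean relation and the coupling are solved jointly as one scalar root
#' problem in \eqn{\mu}.
#'
#' @param tau target mean delay, > 0.
#' @param rho skew factor.
#' @param omega explicit scale (exclusive with \code{omega_fraction}).
#' @param omega_fraction fraction \eqn{c \in (0, 1)} so that
#'   \eqn{\omega = c\,\mu/n}.
#' @param n truncation half-width multiplier.
#' @param tol absolute tolerance on the mean residual (default 1e-10).
#' @return list with \code{mu}, \code{omega} and the achieved \code{mean}.
#' @examples
#' location_from_mean(1, rho = 10, omega_fraction = 0.99)
#' @export
location_from_mean <- function(tau, rho, omega = NULL, omega_fraction = NULL,
                               n = 3, tol = 1e-10) {
  if (tau <= 0) stop("`tau` must be > 0")
  if (is.null(omega) == is.null(omega_fraction))
    stop("give exactly one of `omega` or `omega_fraction`")
  if (!is.null(omega_fraction) &&
      (omega_fraction <= 0 || omega_fraction >= 1))
    stop("`omega_fraction` must lie in (0, 1)")
  om_of_mu <- if (is.null(omega)) {
    function(mu) omega_fraction * mu / n
  } else {
    function(mu) omega
  }
  resid <- function(mu) skew_trunc_mean(mu, om_of_mu(mu), rho, n) - tau
  lo <- tau * 1e-2
  hi <- tau * 1e2
  if (!is.null(omega)) lo <- max(lo, n * omega * (1 + 1e-9))
  flo <- resid(lo); fhi <- resid(hi)
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0)
    stop("no sign change of the mean residual in the bracket [",
         signif(lo, 4), ", ", signif(hi, 4), "]")
  mu <- stats::uniroot(resid, c(lo, hi), tol = tol / 10)$root
  om <- om_of_mu(mu)
  list(mu = mu, omega = om, mean = skew_trunc_mean(mu, om, rho, n))
}

#' Maximum admissible skew-kernel scale for a given mean delay
#'
#' The positive-delay constraint \eqn{\mu - n\omega > 0} bounds the scale by
#' \eqn{\omega_{\max} = \mu/n}. Because the location \eqn{\mu} itself depends
#' on \eqn{\omega} through the mean relation, \eqn{\omega_{\max}} is defined by
#' the joint solve at the boundary coupling \eqn{\omega = \mu/n} (approached
#' from inside; the mean equation remains regular at the boundary).
#'
#' @inheritParams location_from_mean
#' @return list with \code{mu} and \code{omega_max}.
#' @export
skew_omega_max <- function(tau, rho, n = 3, tol = 1e-10) {
  if (tau <= 0) stop("`tau` must be > 0")
  resid <- function(mu) skew_trunc_mean(mu, mu / n, rho, n) - tau
  mu <- stats::uniroot(resid, c(tau * 1e-2, tau * 1e2), tol = tol / 10)$root
  list(mu = mu, omega_max = mu / n)
}

#' Laplace-type transform of a delay kernel
#'
#' Computes \eqn{E(\lambda) = \int_{\tau_1}^{\tau_2} K(s)\,e^{-\lambda s} ds},
#' the term through which the delay distribution enters the dispersion
#' relation. The dirac family returns \eqn{e^{-\lambda\tau}} exactly. The
#' gaussian family uses the error-function closed form for real \eqn{\lambda}
#' and composite Simpson quadrature for complex \eqn{\lambda}; the skew family
#' is always evaluated by quadrature.
#'
#' @param kernel a \code{\link{delay_kernel}}.
#' @param lam growth rate, real or complex, vectorised.
#' @param nodes Simpson node count for the quadrature path (default 201).
#' @return complex (or numeric, if \code{lam} is real and the closed form or
#'   dirac path applies) vector of transform values.
#' @examples
#' kernel_laplace(delay_kernel("dirac", tau = 1), 1)  # exp(-1)
#' @export
kernel_laplace <- function(kernel, lam, nodes = 201L) {
  stopifnot(inherits(kernel, "delay_kernel"))
  if (!all(is.finite(Re(lam)) & is.finite(Im(lam))))
    stop("`lam` must be finite")
  if (kernel$family == "dirac") return(exp(-lam * kernel$tau))
  if (kernel$family == "gaussian" && is.numeric(lam))
    return(gaussian_laplace_closed(kernel$tau, kernel$sigma, kernel$n, lam))
  q <- simpson_rule(kernel$tau1, kernel$tau2, nodes)
  wk <- q$w * kernel_pdf(kernel, q$s)
  drop(exp(outer(lam, q$s, function(l, s) -l * s)) %*% wk)
}

## erf via the normal cdf
erf_real <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

## closed-form transform of the truncated Gaussian kernel, real lambda:
## (Phi_c/2) exp(lam (lam sigma^2 - 2 tau)/2) [erf((lam sigma^2 + s - tau)/(sqrt(2) sigma))]
## evaluated between the truncation bounds.
gaussian_laplace_closed <- function(tau, sigma, n, lam) {
  phi_c <- 1 / (stats::pnorm(n) - stats::pnorm(-n))
  pref <- exp(lam * (lam * sigma^2 - 2 * tau) / 2)
  hi <- erf_real((lam * sigma^2 + n * sigma) / (sqrt(2) * sigma))
  lo <- erf_real((lam * sigma^2 - n * sigma) / (sqrt(2) * sigma))
  phi_c / 2 * pref * (hi - lo)
}

## transform evaluator used by the rootfinding engine: returns a function
## lam -> list(E, dE) with dE the lambda-derivative, vectorised over complex
## lam. `frac` scales every location/scale parameter, for delay continuation.
kernel_transform_fun <- function(kernel, frac = 1, nodes = 101L) {
  if (kernel$family == "dirac" || frac == 0) {
    tt <- kernel$tau * frac
    return(function(lam) {
      E <- exp(-lam * tt)
      list(E = E, dE = -tt * E)
    })
  }
  k <- if (frac == 1) kernel else scale_kernel(kernel, frac)
  q <- simpson_rule(k$tau1, k$tau2, nodes)
  wk <- q$w * kernel_pdf(k, q$s)
  s <- q$s
  function(lam) {
    M <- exp(outer(lam, s, function(l, ss) -l * ss))
    list(E = drop(M %*% wk), dE = drop(M %*% (-s * wk)))
  }
}

## shrink a kernel towards zero delay, scaling location and scale together
scale_kernel <- function(kernel, frac) {
  switch(kernel$family,
    dirac = delay_kernel("dirac", tau = kernel$tau * frac, n = kernel$n),
    gaussian = delay_kernel("gaussian", tau = kernel$tau * frac,
                            sigma = kernel$sigma * frac, n = kernel$n),
    skew_gaussian = delay_kernel("skew_gaussian", mu = kernel$mu * frac,
                                 omega = kernel$omega * frac,
                                 rho = kernel$rho, n = kernel$n))
}

## fast real-axis transform for the rootfinding engine's real-root scan
kernel_laplace_real <- function(kernel, lam, nodes = 101L) {
  switch(kernel$family,
    dirac = exp(-lam * kernel$tau),
    gaussian = gaussian_laplace_closed(kernel$tau, kernel$sigma, kernel$n, lam),
    skew_gaussian = {
      q <- simpson_rule(kernel$tau1, kernel$tau2, nodes)
      wk <- q$w * kernel_pdf(kernel, q$s)
      drop(exp(outer(lam, q$s, function(l, s) -l * s)) %*% wk)
    })
}
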