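#' Random initial conditions around the steady state
#'
#' Multiplicative Gaussian perturbation of the homogeneous steady state:
#' \eqn{u_0 = u_\star(1 + r_u(x))}, \eqn{v_0 = v_\star(1 + r_v(x))} with
#' \eqn{r_u, r_v} iid zero-mean normals of standard deviation
#' \code{sigma_IC} per grid point. The generator is seeded locally (the
#' caller's RNG state is restored) with R's Mersenne-Twister, so equal seeds
#' give bit-identical fields.
#'
#' @param model an \code{\link{rd_model}}.
#' @param grid an \code{\link{spatial_grid}}.
#' @param sigma_IC perturbation standard deviation, >= 0.
#' @param seed integer seed.
#' @return list with fields \code{u}, \code{v} and attributes recording
#'   \code{sigma_IC}, \code{seed} and the RNG algorithm.
#' @export
random_ic <- function(model, grid, sigma_IC, seed) {
  if (sigma_IC < 0) stop("`sigma_IC` must be >= 0")
  ss <- steady_state(model)
  r <- with_local_seed(seed, {
    list(ru = stats::rnorm(grid$m, 0, sigma_IC),
         rv = stats::rnorm(grid$m, 0, sigma_IC))
  })
  structure(list(u = ss[["u"]] * (1 + r$ru), v = ss[["v"]] * (1 + r$rv)),
            sigma_IC = sigma_IC, seed = seed, rng_kind = "Mersenne-Twister")
}

## run code under a fixed seed, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

#' Deterministic structured initial condition (synthetic surrogate)
#'
#' A smooth, deterministic low-mode perturbation of the steady state, standing
#' in for the single-mode initial data used in earlier ligand-internalisation
#' studies whose exact algebraic form is defined in external appendices. The
#' two species are perturbed out of phase:
#' \eqn{u_0 = u_\star(1 + A\cos(k\pi x))},
#' \eqn{v_0 = v_\star(1 - A\cos(k\pi x))}. This is a labelled surrogate for
#' qualitative robustness studies, not a reproduction of the original
#' functions.
#'
#' @param model an \code{\link{rd_model}}.
#' @param grid an \code{\link{spatial_grid}}.
#' @param amplitude perturbation amplitude \eqn{A > 0}.
#' @param mode integer cosine mode \eqn{k} (default 1).
#' @return list with fields \code{u}, \code{v}.
#' @export
structured_ic_surrogate <- function(model, grid, amplitude, mode = 1L) {
  if (amplitude <= 0) stop("`amplitude` must be > 0")
  ss <- steady_state(model)
  pert <- amplitude * cos(mode * pi * grid$x)
  list(u = ss[["u"]] * (1 + pert), v = ss[["v"]] * (1 - pert))
}

#' History functions for the pre-initial interval
#'
#' Builds the history \eqn{h(t)} for \eqn{t \in [-\tau_2, 0]} required to
#' start the delay system. \code{"constant"} returns the initial fields for
#' every past time. \code{"oscillatory"} returns the steady state modulated as
#' \eqn{(1 + r(x)\sin(w t))} with \eqn{r(x)} a seeded Gaussian field of
#' standard deviation \code{r_scale}; at \eqn{t = 0} it equals the steady
#' state exactly.
#'
#' @param ic initial fields (used by the constant kind).
#' @param kind \code{"constant"} or \code{"oscillatory"}.
#' @param model required for the oscillatory kind (steady state).
#' @param grid required for the oscillatory kind.
#' @param r_scale standard deviation of the spatial modulation field.
#' @param w temporal angular frequency.
#' @param seed seed for the modulation field.
#' @return function \code{h(t)} returning \code{list(u =, v =)}.
#' @export
history_function <- function(ic = NULL, kind = c("constant", "oscillatory"),
                             model = NULL, grid = NULL, r_scale = 0.01,
                             w = 1, seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "constant") {
    if (is.null(ic)) stop("constant history needs `ic`")
    u <- ic$u; v <- ic$v
    return(function(t) list(u = u, v = v))
  }
  if (is.null(model) || is.null(grid))
    stop("oscillatory history needs `model` and `grid`")
  ss <- steady_state(model)
  r <- with_local_seed(seed, stats::rnorm(grid$m, 0, r_scale))
  function(t) {
    f <- 1 + r * sin(w * t)
    list(u = ss[["u"]] * f, v = ss[["v"]] * f)
  }
}

## ---- named scenario presets -------------------------------------------------

preset_registry <- function() {
  li <- list(kinetics = "LI", a = 0.1, b = 0.9, eps2 = 0.001, L2 = 4.5)
  li_small <- list(kinetics = "LI", a = 0.4, b = 1.8, eps2 = 0.001, L2 = 0.2)
  gm <- list(kinetics = "GM2", a = 0.75, b = 0.5, eps2 = 0.001, L2 = 4.5)
  base <- list(m = 200L, bc = "neumann", history = "constant",
               ic = "random", t_end = 100, dt_out = 0.25)
  mk <- function(model, kernel, sigma_IC, threshold, ...) {
    utils::modifyList(c(base, list(model = model, kernel = kernel,
                                   sigma_IC = sigma_IC,
                                   threshold = threshold)),
                      list(...))
  }
  list(
    li_fixed_tau1 = mk(li, list(family = "dirac", tau = 1), 0.01, 0.1),
    li_fixed_tau16 = mk(li, list(family = "dirac", tau = 16), 0.01, 0.1,
                        t_end = 500),
    li_gaussian_tau1 = mk(li, list(family = "gaussian", tau = 1,
                                   sigma = 0.99 / 3), 0.01, 0.1),
    li_skew_tau01 = mk(utils::modifyList(li, list(eps2 = 0.01)),
                       list(family = "skew_gaussian_mean", tau = 0.1,
                            rho = 10, omega_fraction = 0.99), 0.01, 0.1),
    li_linear_regime = mk(li_small, list(family = "dirac", tau = 0.2),
                          1e-5, 0.1, t_end = 60),
    li_sweep = mk(li, list(family = "dirac", tau = 1), 1e-5, 0.1,
                  tau_grid = seq(1, 16, by = 1), t_end = 600),
    gm1_sweep = mk(utils::modifyList(gm, list(kinetics = "GM1")),
                   list(family = "dirac", tau = 0.5), 0.001, 10,
                   tau_grid = seq(0.1, 1, by = 0.1), t_end = 300),
    gm2_sweep = mk(gm, list(family = "dirac", tau = 1), 0.001, 10,
                   tau_grid = seq(1, 16, by = 1), t_end = 600),
    li_mixed_bc = mk(li, list(family = "dirac", tau = 1), 0.01, 0.1,
                     bc = "mixed"),
    li_oscillatory_history = mk(li, list(family = "dirac", tau = 1), 0.01,
                                0.1, history = "oscillatory", w = 1,
                                r_scale = 0.01),
    li_structured_ic = mk(li, list(family = "dirac", tau = 1), 0.1, 0.1,
                          ic = "structured_surrogate"))
}

#' Named scenario presets
#'
#' Frozen parameter blocks for the simulated regimes studied in the package:
#' the ligand-internalisation base point (a, b) = (0.1, 0.9) with fixed,
#' symmetric-Gaussian and skewed kernels, the small-domain linear-theory
#' regime (L^2 = 0.2), the Gierer--Meinhardt sweep regimes at
#' (a, b) = (0.75, 0.5), mixed boundary conditions, and oscillatory or
#' structured initial data. Presets serialise round-trip identically through
#' the pipeline config format.
#'
#' @param name preset name; see \code{\link{list_presets}}.
#' @return a scenario list (model, kernel, initial-condition and run
#'   settings).
#' @export
scenario_preset <- function(name) {
  reg <- preset_registry()
  if (!name %in% names(reg))
    stop("unknown preset '", name, "'; see list_presets()")
  reg[[name]]
}

#' @rdname scenario_preset
#' @export
list_presets <- function() names(preset_registry())
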