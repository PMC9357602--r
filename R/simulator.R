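#' Uniform spatial grid on the unit interval
#'
#' @param m number of equally spaced points including both endpoints
#'   (default 500).
#' @return object of class \code{"rd_grid"} with fields \code{m}, \code{x},
#'   \code{dx}.
#' @export
spatial_grid <- function(m = 500L) {
  if (m < 3) stop("`m` must be >= 3")
  x <- seq(0, 1, length.out = m)
  structure(list(m = as.integer(m), x = x, dx = x[2] - x[1]),
            class = "rd_grid")
}

#' Discrete Laplacian operators for the two species
#'
#' Builds the three-point-stencil Laplacian as a pair of apply-functions, one
#' per species, honouring the boundary conditions. Homogeneous Neumann
#' boundaries use reflected ghost points, giving the second-order boundary row
#' \eqn{2(f_2 - f_1)/dx^2}; the mixed case clamps the activator to zero at
#' both boundaries (homogeneous Dirichlet; its boundary rate is zero) while
#' the inhibitor keeps Neumann conditions.
#'
#' @param grid an \code{\link{spatial_grid}}.
#' @param bc \code{"neumann"} (both species) or \code{"mixed"} (Dirichlet for
#'   the activator, Neumann for the inhibitor).
#' @return list with functions \code{u} and \code{v}, each mapping a field
#'   vector to its discrete Laplacian.
#' @export
laplacian_op <- function(grid, bc = c("neumann", "mixed")) {
  bc <- match.arg(bc)
  m <- grid$m; dx2 <- grid$dx^2
  lap_neumann <- function(f) {
    c(2 * (f[2] - f[1]),
      f[seq.int(3, m)] - 2 * f[seq.int(2, m - 1)] + f[seq.int(1, m - 2)],
      2 * (f[m - 1] - f[m])) / dx2
  }
  lap_dirichlet <- function(f) {
    ## boundary values are held at 0; boundary rows are zero rates
    c(0,
      (f[seq.int(3, m)] - 2 * f[seq.int(2, m - 1)] + f[seq.int(1, m - 2)]) / dx2,
      0)
  }
  list(u = if (bc == "mixed") lap_dirichlet else lap_neumann,
       v = lap_neumann)
}

#' Kernel-averaged delayed reaction terms
#'
#' Evaluates \eqn{\mathcal{F}(t) = \int_{\tau_1}^{\tau_2} K(s) F(u(t-s),
#' v(t-s)) ds} (and \eqn{\mathcal{G}} where the model has one) for every grid
#' point. A dirac kernel reduces to a single lagged lookup; distributed
#' kernels use composite Simpson quadrature with fixed nodes across the
#' truncation window.
#'
#' @param state_at function of one time argument returning
#'   \code{list(u =, v =)} field vectors; it must cover
#'   \code{[t - tau2, t - tau1]}.
#' @param kernel a \code{\link{delay_kernel}}.
#' @param t current time.
#' @param model an \code{\link{rd_model}}.
#' @param nq Simpson node count over the truncation window (default 51).
#' @return list with fields \code{F} and \code{G} (\code{G} is \code{NULL}
#'   for LI).
#' @export
delayed_term <- function(state_at, kernel, t, model, nq = 51L) {
  if (kernel$family == "dirac") {
    st <- state_at(t - kernel$tau)
    return(delayed_kinetics(model, st$u, st$v))
  }
  q <- simpson_rule(kernel$tau1, kernel$tau2, nq)
  wk <- q$w * kernel_pdf(kernel, q$s)
  wk <- wk / sum(wk)  # discrete normalisation: constant histories are exact
  accF <- 0; accG <- 0
  has_g <- model$kinetics != "LI"
  for (j in seq_along(q$s)) {
    st <- state_at(t - q$s[j])
    fg <- delayed_kinetics(model, st$u, st$v)
    accF <- accF + wk[j] * fg$F
    if (has_g) accG <- accG + wk[j] * fg$G
  }
  list(F = accF, G = if (has_g) accG else NULL)
}

#' Simulate the delayed reaction--diffusion model
#'
#' Method-of-lines solution: three-point Laplacian on a uniform grid, the
#' delayed reaction integral by Simpson quadrature over the kernel window
#' (a single lagged lookup for a fixed delay), and time integration by the
#' stiff solver of \pkg{deSolve} (\code{\link[deSolve]{dede}}, with an
#' internally generated banded Jacobian; the solver maintains the dense
#' solution history that the lagged lookups interpolate). The history on
#' \eqn{[-\tau_2, 0]} is taken from \code{history}; by default it is constant
#' and equal to the initial fields.
#'
#' @param model an \code{\link{rd_model}}.
#' @param kernel a \code{\link{delay_kernel}}.
#' @param ic list with fields \code{u} and \code{v} of length \code{grid$m}
#'   (e.g. from \code{\link{random_ic}}).
#' @param t_end final time, > 0.
#' @param grid an \code{\link{spatial_grid}} (default 500 points).
#' @param bc boundary conditions, \code{"neumann"} or \code{"mixed"}.
#' @param history \code{NULL} for a constant history equal to \code{ic}, or a
#'   function \code{h(t)} returning \code{list(u =, v =)} for \eqn{t \le 0}
#'   (see \code{\link{history_function}}).
#' @param dt_out output sampling interval (default \code{t_end/400}).
#' @param nq Simpson nodes for the distributed-delay integral (default 51).
#' @param stop_threshold if non-\code{NULL}, terminate integration early once
#'   \eqn{\max_x |u - u_\star|} exceeds this value (used by time-to-pattern
#'   sweeps so runs stop shortly after patterning begins).
#' @param atol,rtol solver tolerances.
#' @param include_reaction internal switch used by conservation tests;
#'   \code{FALSE} integrates pure diffusion.
#' @return object of class \code{"rd_sim"}: \code{x}, \code{t}, matrices
#'   \code{u}, \code{v} (time by space), the model/kernel/bc metadata and the
#'   steady state.
#' @export
simulate_rd <- function(model, kernel, ic, t_end, grid = spatial_grid(),
                        bc = c("neumann", "mixed"), history = NULL,
                        dt_out = NULL, nq = 51L, stop_threshold = NULL,
                        atol = 1e-9, rtol = 1e-8, include_reaction = TRUE) {
  bc <- match.arg(bc)
  if (t_end <= 0) stop("`t_end` must be > 0")
  m <- grid$m
  if (length(ic$u) != m || length(ic$v) != m)
    stop("initial fields must have length grid$m = ", m)
  ss <- steady_state(model)
  lap <- laplacian_op(grid, bc)
  iu <- seq.int(1L, 2L * m, by = 2L); iv <- iu + 1L
  u0 <- ic$u; v0 <- ic$v
  if (bc == "mixed") u0[c(1L, m)] <- 0
  if (is.null(history)) {
    hfun <- function(t) list(u = u0, v = v0)
  } else {
    hfun <- history
  }
  y0 <- numeric(2L * m); y0[iu] <- u0; y0[iv] <- v0

  max_lag <- kernel$tau2
  state_at <- function(tq) {
    if (tq <= 0) {
      hfun(tq)
    } else {
      yl <- deSolve::lagvalue(tq)
      list(u = yl[iu], v = yl[iv])
    }
  }
  delayed <- kernel$tau2 > 0
  rhs <- function(t, y, parms) {
    u <- y[iu]; v <- y[iv]
    if (include_reaction) {
      fg <- if (delayed) {
        delayed_term(state_at, kernel, t, model, nq)
      } else {
        delayed_kinetics(model, u, v)
      }
      kin <- kinetic_rhs(model, u, v, fg$F, fg$G)
      du <- model$eps2 / model$L2 * lap$u(u) + kin$du
      dv <- 1 / model$L2 * lap$v(v) + kin$dv
    } else {
      du <- model$eps2 / model$L2 * lap$u(u)
      dv <- 1 / model$L2 * lap$v(v)
    }
    if (bc == "mixed") du[c(1L, m)] <- 0
    dy <- numeric(2L * m); dy[iu] <- du; dy[iv] <- dv
    list(dy)
  }
  blowup_cap <- 1e6
  rootfunc <- function(t, y, parms) {
    g1 <- blowup_cap - max(abs(y))
    if (is.null(stop_threshold)) {
      g1
    } else {
      c(g1, max(abs(y[iu] - ss[["u"]])) - stop_threshold)
    }
  }
  if (is.null(dt_out)) dt_out <- t_end / 400
  times <- seq(0, t_end, by = dt_out)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  out <- if (delayed) {
    deSolve::dede(y0, times, rhs, parms = NULL, jactype = "bandint",
                  bandup = 2L, banddown = 2L, rootfunc = rootfunc,
                  control = list(mxhist = 1e5), atol = atol, rtol = rtol)
  } else {
    deSolve::lsodar(y0, times, rhs, parms = NULL, jactype = "bandint",
                    bandup = 2L, banddown = 2L, rootfunc = rootfunc,
                    atol = atol, rtol = rtol)
  }
  tt <- out[, 1]
  U <- out[, 1L + iu, drop = FALSE]
  V <- out[, 1L + iv, drop = FALSE]
  if (anyNA(U) || anyNA(V) || any(!is.finite(U)) || any(!is.finite(V)))
    stop("simulation produced non-finite fields near t = ", max(tt))
  nlast <- length(tt)
  if (tt[nlast] < t_end &&
      max(abs(U[nlast, ]), abs(V[nlast, ])) >= 0.99 * blowup_cap)
    stop("blow-up guard triggered: |u| or |v| exceeded ", blowup_cap,
         " at t = ", signif(tt[nlast], 6))
  structure(list(x = grid$x, t = tt, u = U, v = V, model = model,
                 kernel = kernel, bc = bc, grid = grid,
                 steady_state = ss,
                 terminated_early = tt[length(tt)] < t_end),
            class = "rd_sim")
}

#' @export
print.rd_sim <- function(x, ...) {
  cat("<rd_sim>", x$model$kinetics, "kernel:", x$kernel$family,
      " m =", x$grid$m, " t in [0,", max(x$t), "]",
      if (x$terminated_early) "(terminated at threshold)" else "", "\n")
  invisible(x)
}
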