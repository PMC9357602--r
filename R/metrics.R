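#' Time to pattern formation
#'
#' The first time \eqn{T^\star} at which the activator's maximal deviation
#' from the homogeneous steady state exceeds a threshold:
#' \eqn{\max_x |u(T^\star, x) - u_\star| > u_{T^\star}}. The crossing is
#' refined by linear interpolation between the bracketing output samples.
#'
#' @param sim an \code{\link{simulate_rd}} result.
#' @param threshold amplitude threshold \eqn{u_{T^\star} > 0}.
#' @param u_star steady-state activator value (default: taken from the
#'   simulation's model).
#' @return the crossing time, or \code{NA_real_} (with attribute
#'   \code{reached = FALSE}) if the trajectory never crosses.
#' @export
time_to_pattern <- function(sim, threshold, u_star = NULL) {
  stopifnot(inherits(sim, "rd_sim"))
  if (threshold <= 0) stop("`threshold` must be > 0")
  if (!length(sim$t)) stop("empty simulation")
  if (is.null(u_star)) u_star <- sim$steady_state[["u"]]
  dev <- apply(abs(sim$u - u_star), 1, max)
  above <- dev > threshold
  if (above[1]) return(structure(0, reached = TRUE))
  if (!any(above)) return(structure(NA_real_, reached = FALSE))
  i <- which(above)[1]
  t0 <- sim$t[i - 1]; t1 <- sim$t[i]
  d0 <- dev[i - 1]; d1 <- dev[i]
  structure(t0 + (threshold - d0) / (d1 - d0) * (t1 - t0), reached = TRUE)
}

#' Cosine-mode amplitudes of a spatial profile
#'
#' Coefficients of the \eqn{\cos(k\pi x)} Neumann eigenbasis, computed by a
#' type-I discrete cosine transform (FFT of the even reflection of the
#' profile). Normalised so that a pure input \eqn{A\cos(k\pi x)} returns
#' amplitude \eqn{A} at index \eqn{k}.
#'
#' @param field numeric profile sampled on a uniform grid including both
#'   endpoints.
#' @param grid optional \code{\link{spatial_grid}} (only its length is used).
#' @return numeric vector of amplitudes \eqn{A_0, A_1, \ldots, A_{m-1}}.
#' @export
mode_amplitudes <- function(field, grid = NULL) {
  m <- length(field)
  if (!is.null(grid) && grid$m != m)
    stop("field length does not match grid$m")
  if (m < 3) stop("need at least 3 samples")
  y <- c(field, field[seq.int(m - 1, 2)])
  co <- Re(stats::fft(y)) / (2 * (m - 1))
  A <- co[seq_len(m)]
  A[seq.int(2, m - 1)] <- 2 * A[seq.int(2, m - 1)]
  A
}

## inverse of mode_amplitudes: rebuild the profile from cosine amplitudes
modes_to_field <- function(A, x = seq(0, 1, length.out = length(A))) {
  k <- seq_along(A) - 1
  drop(cos(outer(x, k * pi)) %*% A)
}

#' Linear-theory predicted time to pattern
#'
#' From the exponential-growth approximation \eqn{A_k(T) \approx A_k(0)
#' e^{\lambda_k T}} of the dominant mode: \eqn{T = \ln(A_T/A_0)/\Re(\lambda_k)}.
#' The real part sets the amplitude growth; in the small-domain Turing regime
#' the dominant root is real.
#'
#' @param lambda_k dominant growth rate (complex allowed), with
#'   \eqn{\Re(\lambda_k) > 0}.
#' @param A0,A_T dominant-mode amplitudes at time 0 and at the threshold
#'   crossing; require \eqn{A_T \ge A_0 > 0}.
#' @return the predicted time.
#' @export
predicted_time_to_pattern <- function(lambda_k, A0, A_T) {
  if (Re(lambda_k) <= 0) stop("mode is not growing: Re(lambda_k) <= 0")
  if (!(A0 > 0) || A_T < A0) stop("need A_T >= A0 > 0")
  log(A_T / A0) / Re(lambda_k)
}

#' Count spikes in a spatial profile
#'
#' Counts concentration peaks of the final pattern. The profile on \eqn{[0,1]}
#' with Neumann boundaries is half a period of its even periodic extension, so
#' peaks are detected on that extension (boundary peaks are then whole peaks,
#' not half-peaks, and the count is independent of the pattern's phase).
#' A peak is a strict circular local maximum whose prominence (height above
#' the higher of the two flanking valleys) exceeds
#' \code{prominence_fraction} of the field's range.
#'
#' @param field numeric profile on a uniform grid.
#' @param prominence_fraction fraction of \code{max - min} in (0, 1)
#'   (default 0.2).
#' @return integer spike count (0 for a flat field).
#' @export
count_spikes <- function(field, prominence_fraction = 0.2) {
  if (prominence_fraction <= 0 || prominence_fraction >= 1)
    stop("`prominence_fraction` must be in (0, 1)")
  m <- length(field)
  rng <- max(field) - min(field)
  if (rng <= 0) return(0L)
  y <- c(field, field[seq.int(m - 1, 2)])  # even periodic extension
  n <- length(y)
  idx <- seq_len(n)
  nxt <- c(idx[-1], 1L); prv <- c(n, idx[-n])
  is_max <- y > y[nxt] & y > y[prv]
  peaks <- which(is_max)
  if (!length(peaks)) return(0L)
  prom_ok <- vapply(peaks, function(p) {
    ## walk both directions to the nearest strictly higher sample, tracking
    ## the lowest valley on the way; prominence = peak - max(valleys)
    valley <- function(dirn) {
      lo <- y[p]; i <- p
      for (step in seq_len(n)) {
        i <- if (dirn > 0) (i %% n) + 1L else ((i - 2L) %% n) + 1L
        if (y[i] > y[p]) break
        lo <- min(lo, y[i])
      }
      lo
    }
    (y[p] - max(valley(1L), valley(-1L))) > prominence_fraction * rng
  }, logical(1))
  sum(prom_ok)
}

#' Sweep the mean delay and fit the time-to-pattern law
#'
#' Runs one simulation per mean delay with identical (seeded) initial
#' perturbations, measures the time to pattern, and fits an ordinary
#' least-squares line \eqn{T^\star = \beta_0 + \beta_1 \tau}. Delays whose run
#' never crosses the threshold within \code{t_max} are flagged and excluded
#' from the fit.
#'
#' @param model an \code{\link{rd_model}}.
#' @param tau_grid increasing positive mean delays.
#' @param sigma_IC perturbation standard deviation for the initial condition.
#' @param threshold time-to-pattern threshold.
#' @param seed RNG seed shared by all runs.
#' @param kernel_family \code{"dirac"} (default) or \code{"gaussian"}.
#' @param sigma_fraction spread as a fraction of \eqn{\sigma_{\max}} when
#'   \code{kernel_family = "gaussian"}.
#' @param grid an \code{\link{spatial_grid}} (default 200 points, the
#'   desk-scale resolution used throughout the package tests).
#' @param t_max per-run time cap; runs terminate early at the threshold.
#' @param dt_out output sampling interval.
#' @param ... further arguments to \code{\link{simulate_rd}}.
#' @return list of class \code{"tau_sweep"}: \code{table} (tau, T_star,
#'   reached), \code{slope}, \code{intercept}, \code{r_squared},
#'   \code{excluded} (delays without patterning).
#' @export
tau_sweep <- function(model, tau_grid, sigma_IC, threshold, seed,
                      kernel_family = c("dirac", "gaussian"),
                      sigma_fraction = 0.5, grid = spatial_grid(200L),
                      t_max = 600, dt_out = 0.25, ...) {
  kernel_family <- match.arg(kernel_family)
  stopifnot(all(diff(tau_grid) > 0), all(tau_grid > 0))
  if (length(tau_grid) < 2)
    stop("tau_grid of length ", length(tau_grid),
         ": need at least 2 delays for a linear fit")
  ic <- random_ic(model, grid, sigma_IC, seed)
  rows <- lapply(tau_grid, function(tau) {
    kern <- if (kernel_family == "dirac") {
      delay_kernel("dirac", tau = tau)
    } else {
      delay_kernel("gaussian", tau = tau, sigma = sigma_fraction * tau / 3)
    }
    sim <- simulate_rd(model, kern, ic, t_end = t_max, grid = grid,
                       stop_threshold = threshold * 1.02, dt_out = dt_out,
                       ...)
    ts <- time_to_pattern(sim, threshold)
    data.frame(tau = tau, T_star = as.numeric(ts),
               reached = isTRUE(attr(ts, "reached")))
  })
  tab <- do.call(rbind, rows)
  keep <- tab[tab$reached, , drop = FALSE]
  if (nrow(keep) < 2)
    stop("fewer than 2 patterning delays; cannot fit the T-tau law")
  fit <- stats::lm(T_star ~ tau, data = keep)
  structure(list(table = tab,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 excluded = tab$tau[!tab$reached]),
            class = "tau_sweep")
}

#' @export
print.tau_sweep <- function(x, ...) {
  cat("<tau_sweep>", nrow(x$table), "delays; slope =", format(x$slope),
      " R^2 =", format(x$r_squared), "\n")
  if (length(x$excluded))
    cat("  non-patterning delays excluded:",
        paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}
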