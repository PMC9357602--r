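#' Residual of the transcendental characteristic equation
#'
#' Evaluates \eqn{\mathcal{D}_k(\lambda) = \lambda^2 + \alpha_k\lambda +
#' \beta_k + (\gamma_k\lambda + \delta_k)E(\lambda) + \chi_k E(\lambda)^2}
#' for the given model, kernel and wavenumber. A value of (numerically) zero
#' identifies a growth rate \eqn{\lambda_k} of the perturbation mode
#' \eqn{\cos(k\pi x)}.
#'
#' @param model an \code{\link{rd_model}}.
#' @param kernel a \code{\link{delay_kernel}}.
#' @param k integer wavenumber (scalar).
#' @param lam complex (or real) growth rate, vectorised.
#' @param nodes Simpson node count for the kernel transform (the gaussian
#'   family uses its error-function closed form when \code{lam} is real).
#' @return complex residual values.
#' @export
characteristic_residual <- function(model, kernel, k, lam, nodes = 1001L) {
  cf <- dispersion_coefficients(model, k)
  E <- if (is.numeric(lam) || all(Im(lam) == 0)) {
    kernel_laplace_real(kernel, Re(lam), nodes)
  } else {
    kernel_transform_fun(kernel, 1, nodes)(as.complex(lam))$E
  }
  lam^2 + cf$alpha * lam + cf$beta + (cf$gamma * lam + cf$delta) * E +
    cf$chi * E^2
}

## ---- vectorised rightmost-root engine --------------------------------------
##
## Strategy (per wavenumber k, simultaneously over a vector of parameter
## points): the two roots of the zero-delay quadratic are continued in the
## kernel's mean delay (all location/scale parameters scaled together) in
## steps of at most `cont_step`, with a damped complex Newton correction at
## each step; branches that leave a floor Re(lambda) < `floor_re` are frozen
## (they cannot contend for the rightmost root, which is additionally guarded
## by the real-axis scan). A sign-change scan of the real-valued residual on
## [scan_lo, scan_hi] followed by bisection catches real roots born away from
## the continued branches. Only roots whose final residual passes a scaled
## tolerance are kept.
grid_rightmost_k <- function(cf, kernel, cont_step = 0.05, nodes = 101L,
                             scan_lo = -20, scan_hi = 20, scan_step = 0.05,
                             floor_re = -30, newton_tol = 1e-10,
                             accept_tol = 1e-8, max_iter = 80L) {
  n <- length(cf$alpha)
  ok <- is.finite(cf$alpha) & is.finite(cf$beta)
  A <- cf$alpha + cf$gamma
  B <- cf$beta + cf$delta + cf$chi
  disc <- as.complex(A^2 - 4 * B)
  ## the imaginary nudge lets Newton leave the real axis when a continued
  ## real pair collides and becomes complex
  roots <- list((-A + sqrt(disc)) / 2 + 1e-6i, (-A - sqrt(disc)) / 2 - 1e-6i)
  resid <- list(rep(0, n), rep(0, n))
  tau <- kernel$tau
  scale <- pmax(1, abs(cf$beta) + abs(cf$delta))
  if (tau > 0 && any(ok)) {
    nsteps <- max(1L, ceiling(tau / cont_step))
    for (j in seq_len(nsteps)) {
      Ef <- kernel_transform_fun(kernel, j / nsteps, nodes)
      for (br in 1:2) {
        lam <- roots[[br]]
        act <- which(ok & Re(lam) > floor_re & is.finite(Re(lam)))
        if (!length(act)) next
        la <- lam[act]
        al <- cf$alpha[act]; be <- cf$beta[act]; ga <- cf$gamma[act]
        de <- cf$delta[act]; ch <- cf$chi[act]; sc <- scale[act]
        for (it in seq_len(max_iter)) {
          e <- Ef(la)
          Dv <- la^2 + al * la + be + (ga * la + de) * e$E + ch * e$E^2
          dD <- 2 * la + al + ga * e$E + (ga * la + de) * e$dE +
            2 * ch * e$E * e$dE
          step <- Dv / dD
          bad <- !is.finite(step)
          step[bad] <- 0
          sm <- Mod(step)
          step <- step * pmin(1, 2 / pmax(sm, 1e-300))
          la <- la - step
          mm <- Mod(Dv) / sc
          if (max(mm[!bad], 0) < newton_tol) break
        }
        e <- Ef(la)
        Dv <- la^2 + al * la + be + (ga * la + de) * e$E + ch * e$E^2
        fail <- !is.finite(Dv) | Mod(Dv) >= accept_tol * sc
        la[fail] <- complex(real = -Inf)
        lam[act] <- la
        roots[[br]] <- lam
        if (j == nsteps) {
          rs <- resid[[br]]
          rs[act] <- Mod(Dv)
          rs[act][fail] <- NA_real_
          resid[[br]] <- rs
        }
      }
    }
  }
  pick2 <- Re(roots[[2]]) > Re(roots[[1]])
  pick2[is.na(pick2)] <- FALSE
  root_best <- roots[[1]]; res_best <- resid[[1]]
  root_best[pick2] <- roots[[2]][pick2]
  res_best[pick2] <- resid[[2]][pick2]

  ## real-axis sign-change scan + bisection
  kern_final <- if (tau > 0) kernel else scale_kernel(kernel, 0)
  lamg <- seq(scan_lo, scan_hi, by = scan_step)
  Ev <- kernel_laplace_real(kern_final, lamg, nodes)
  Dm <- outer(rep(1, n), lamg^2) + outer(cf$alpha, lamg) + cf$beta +
    sweep(outer(cf$gamma, lamg), 2, Ev, `*`) +
    cf$delta * rep(Ev, each = n) + cf$chi * rep(Ev^2, each = n)
  sg <- sign(Dm)
  chg <- sg[, -1, drop = FALSE] * sg[, -ncol(sg), drop = FALSE] < 0
  idx <- apply(chg, 1, function(z) {
    w <- which(z)
    if (length(w)) max(w) else NA_integer_
  })
  has <- which(!is.na(idx) & ok)
  if (length(has)) {
    lo <- lamg[idx[has]]; hi <- lamg[idx[has] + 1]
    al <- cf$alpha[has]; be <- cf$beta[has]; ga <- cf$gamma[has]
    de <- cf$delta[has]; ch <- cf$chi[has]
    d_re <- function(l) {
      E <- kernel_laplace_real(kern_final, l, nodes)
      l^2 + al * l + be + (ga * l + de) * E + ch * E^2
    }
    flo <- d_re(lo)
    for (it in 1:52) {
      mid <- (lo + hi) / 2
      fm <- d_re(mid)
      left <- flo * fm < 0
      hi[left] <- mid[left]
      lo[!left] <- mid[!left]
      flo[!left] <- fm[!left]
    }
    mid <- (lo + hi) / 2
    better <- Re(root_best[has]) < mid | is.na(res_best[has])
    upd <- has[better]
    root_best[upd] <- as.complex(mid[better])
    res_best[upd] <- abs(d_re(mid))[better]
  }
  root_best[!ok] <- NA_complex_
  res_best[!ok] <- NA_real_
  list(root = root_best, re = Re(root_best), residual = res_best)
}

#' Rightmost root of the dispersion relation at one wavenumber
#'
#' Finds the root of \eqn{\mathcal{D}_k} with maximal real part by homotopy
#' continuation from the zero-delay quadratic roots plus a sign-change scan of
#' the real axis (see the package vignette for the strategy and its
#' validation). Fails loudly if no candidate root passes the residual
#' tolerance.
#'
#' @inheritParams characteristic_residual
#' @param cont_step maximal continuation step in mean delay (default 0.05).
#' @param scan_step resolution of the real-axis scan (default 0.01).
#' @param accept_tol residual acceptance tolerance, scaled by the coefficient
#'   magnitude.
#' @return list with \code{lambda} (complex), \code{residual} and \code{k}.
#' @export
rightmost_root <- function(model, kernel, k, nodes = 101L, cont_step = 0.05,
                           scan_step = 0.01, accept_tol = 1e-8) {
  cf <- dispersion_coefficients_grid(model$kinetics, model$a, model$b,
                                     model$eps2, model$L2, k)
  out <- grid_rightmost_k(cf, kernel, cont_step = cont_step, nodes = nodes,
                          scan_step = scan_step, accept_tol = accept_tol)
  if (!is.finite(out$re) || is.na(out$residual))
    stop("rightmost-root search failed at k = ", k,
         " (no candidate passed the residual tolerance; last iterate Re = ",
         signif(out$re, 6), ")")
  list(lambda = out$root, residual = out$residual, k = k)
}

#' Maximal growth rate over a wavenumber range
#'
#' Computes the rightmost root of the dispersion relation for every integer
#' wavenumber \eqn{k \in [0, k_{\max}]} and records the maximal real part and
#' its arg-max wavenumber (ties broken towards the smallest k).
#'
#' @inheritParams rightmost_root
#' @param k_max largest wavenumber scanned (default 50).
#' @return object of class \code{"dispersion_result"}: a list with
#'   \code{table} (data frame of k, Re, Im, residual), \code{max_re},
#'   \code{argmax_k}, \code{lambda_max}.
#' @examples
#' m <- rd_model("LI", 0.1, 0.9)
#' \donttest{max_growth_rate(m, delay_kernel("dirac", tau = 0))}
#' @export
max_growth_rate <- function(model, kernel, k_max = 50L, nodes = 101L,
                            cont_step = 0.05, scan_step = 0.05) {
  stopifnot(k_max >= 1)
  ks <- 0:k_max
  rows <- lapply(ks, function(k) {
    cf <- dispersion_coefficients_grid(model$kinetics, model$a, model$b,
                                       model$eps2, model$L2, k)
    out <- grid_rightmost_k(cf, kernel, cont_step = cont_step, nodes = nodes,
                            scan_step = scan_step)
    if (!is.finite(out$re) || is.na(out$residual))
      stop("rightmost-root search failed at k = ", k)
    data.frame(k = k, re = Re(out$root), im = Im(out$root),
               residual = out$residual)
  })
  tab <- do.call(rbind, rows)
  i <- which.max(tab$re)  # which.max returns the first (smallest k) on ties
  structure(list(table = tab, max_re = tab$re[i], argmax_k = tab$k[i],
                 lambda_max = complex(real = tab$re[i], imaginary = tab$im[i]),
                 model = model, kernel = kernel),
            class = "dispersion_result")
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat("<dispersion_result> max Re(lambda_k) =", format(x$max_re),
      "at k =", x$argmax_k, "over k in [0,", max(x$table$k), "]\n")
  invisible(x)
}

## max over k of Re(lambda_k) for a vector of (a, b) points, plus the k = 0
## value, vectorised. The workhorse behind the Turing-space operations.
growth_rate_field <- function(kinetics, a, b, eps2, L2, kernel, k_max = 50L,
                              nodes = 101L, cont_step = 0.05,
                              scan_step = 0.05) {
  n <- length(a)
  best <- rep(-Inf, n); bestk <- rep(0L, n)
  best_nz <- rep(-Inf, n)
  re0 <- rep(NA_real_, n)
  for (k in 0:k_max) {
    cf <- dispersion_coefficients_grid(kinetics, a, b, eps2, L2, k)
    out <- grid_rightmost_k(cf, kernel, cont_step = cont_step, nodes = nodes,
                            scan_step = scan_step)
    re <- out$re
    if (k == 0L) re0 <- re
    upd <- which(!is.na(re) & re > best + 1e-14)
    best[upd] <- re[upd]; bestk[upd] <- k
    if (k > 0L) {
      updz <- which(!is.na(re) & re > best_nz + 1e-14)
      best_nz[updz] <- re[updz]
    }
  }
  best[!is.finite(best)] <- NA_real_
  best_nz[!is.finite(best_nz)] <- NA_real_
  list(max_re = best, argmax_k = bestk, max_re_nonzero = best_nz,
       re_lambda0 = re0)
}

#' Turing-space scan over the kinetic parameter plane
#'
#' Evaluates \eqn{\max_k \Re(\lambda_k)} on a uniform (a, b) grid and extracts
#' the two marginal-stability contours: the homogeneous line
#' \eqn{\Re(\lambda_0) = 0} and the inhomogeneous line
#' \eqn{\max_{k\neq 0}\Re(\lambda_k) = 0}. The Turing space is the region
#' between them where the homogeneous mode is stable but some spatial mode
#' grows. Grid points with a degenerate steady state (e.g. \eqn{a = b = 0})
#' are carried as \code{NA}.
#'
#' @param kinetics model family, or an \code{\link{rd_model}} whose
#'   \code{a, b} are ignored.
#' @param kernel a \code{\link{delay_kernel}}.
#' @param a_grid,b_grid uniform grids with at least 2 points each.
#' @param eps2,L2 diffusion ratio and domain scaling (taken from
#'   \code{kinetics} if it is a model object).
#' @param k_max largest wavenumber.
#' @param ... engine tuning passed to the rootfinder.
#' @return object of class \code{"turing_scan"}: grids, matrices
#'   \code{max_re}, \code{max_re_nonzero}, \code{re_lambda0},
#'   \code{argmax_k} (a-index by b-index), the two contours as data frames of
#'   (a, b) points, and \code{turing_cells}, the number of grid points inside
#'   the Turing region.
#' @export
turing_space_scan <- function(kinetics, kernel, a_grid, b_grid,
                              eps2 = 0.001, L2 = 4.5, k_max = 50L, ...) {
  if (inherits(kinetics, "rd_model")) {
    eps2 <- kinetics$eps2; L2 <- kinetics$L2
    kinetics <- kinetics$kinetics
  }
  if (length(a_grid) < 2 || length(b_grid) < 2)
    stop("grids need at least 2 points each")
  G <- expand.grid(a = a_grid, b = b_grid)
  fld <- growth_rate_field(kinetics, G$a, G$b, eps2, L2, kernel,
                           k_max = k_max, ...)
  na_ <- length(a_grid); nb <- length(b_grid)
  shape <- function(v) matrix(v, na_, nb)
  M <- shape(fld$max_re); Mnz <- shape(fld$max_re_nonzero)
  M0 <- shape(fld$re_lambda0)
  turing <- !is.na(M0) & !is.na(Mnz) & M0 < 0 & Mnz > 0
  structure(list(
    a = a_grid, b = b_grid, kinetics = kinetics, eps2 = eps2, L2 = L2,
    kernel = kernel, max_re = M, max_re_nonzero = Mnz, re_lambda0 = M0,
    argmax_k = shape(fld$argmax_k),
    contour_k0 = zero_contour(a_grid, b_grid, M0),
    contour_knz = zero_contour(a_grid, b_grid, Mnz),
    turing_cells = sum(turing)),
    class = "turing_scan")
}

#' @export
print.turing_scan <- function(x, ...) {
  cat("<turing_scan>", x$kinetics, "on", length(x$a), "x", length(x$b),
      "grid; Turing region:", x$turing_cells, "grid points\n")
  invisible(x)
}

## zero-level contour points by linear interpolation of sign changes along
## grid rows and columns; returns a data.frame of (a, b) points
zero_contour <- function(a_grid, b_grid, M) {
  pts <- list()
  na_ <- length(a_grid); nb <- length(b_grid)
  for (j in seq_len(nb)) {
    col <- M[, j]
    i <- which(!is.na(col[-na_]) & !is.na(col[-1]) & col[-na_] * col[-1] < 0)
    if (length(i)) {
      t0 <- col[i] / (col[i] - col[i + 1])
      pts[[length(pts) + 1]] <- data.frame(
        a = a_grid[i] + t0 * (a_grid[i + 1] - a_grid[i]), b = b_grid[j])
    }
  }
  for (i in seq_len(na_)) {
    row <- M[i, ]
    j <- which(!is.na(row[-nb]) & !is.na(row[-1]) & row[-nb] * row[-1] < 0)
    if (length(j)) {
      t0 <- row[j] / (row[j] - row[j + 1])
      pts[[length(pts) + 1]] <- data.frame(
        a = a_grid[i], b = b_grid[j] + t0 * (b_grid[j + 1] - b_grid[j]))
    }
  }
  if (!length(pts)) return(data.frame(a = numeric(0), b = numeric(0)))
  do.call(rbind, pts)
}

#' Hausdorff distance between two point sets
#'
#' Used to compare marginal-stability contours across delays: two contours
#' "coincide at plotting resolution" when their Hausdorff distance is below
#' one grid cell.
#'
#' @param p,q data frames with columns \code{a}, \code{b}.
#' @return the symmetric Hausdorff distance.
#' @export
hausdorff_distance <- function(p, q) {
  if (!nrow(p) || !nrow(q)) return(Inf)
  d2 <- outer(p$a, q$a, "-")^2 + outer(p$b, q$b, "-")^2
  sqrt(max(min(apply(d2, 1, min)), min(apply(d2, 2, min))))
}

#' Distributed-vs-fixed growth-rate discrepancy over a parameter window
#'
#' For each spread fraction \eqn{c}, compares \eqn{\max_k \Re(\lambda_k)}
#' between a symmetric Gaussian kernel with \eqn{\sigma = c\,\sigma_{\max}}
#' (\eqn{\sigma_{\max} = \tau/n}) and the fixed-delay kernel with the same
#' mean, and reports the maximal absolute difference over the (a, b) grid.
#'
#' @param kinetics model family (or an \code{\link{rd_model}} template).
#' @param tau mean delay.
#' @param sigma_fractions fractions of \eqn{\sigma_{\max}} in (0, 1).
#' @param a_window,b_window ranges of the scan window.
#' @param grid_shape integer c(na, nb) grid dimensions (default c(71, 101)).
#' @param eps2,L2,k_max,... as in \code{\link{turing_space_scan}}.
#' @param n truncation half-width multiplier.
#' @return named numeric vector of maximal absolute discrepancies, one per
#'   fraction.
#' @export
distributed_vs_fixed_discrepancy <- function(kinetics, tau, sigma_fractions,
                                             a_window = c(0, 1.4),
                                             b_window = c(0, 2),
                                             grid_shape = c(71L, 101L),
                                             eps2 = 0.001, L2 = 4.5,
                                             k_max = 50L, n = 3, ...) {
  if (inherits(kinetics, "rd_model")) {
    eps2 <- kinetics$eps2; L2 <- kinetics$L2
    kinetics <- kinetics$kinetics
  }
  stopifnot(all(sigma_fractions > 0), all(sigma_fractions < 1), tau > 0)
  a_grid <- seq(a_window[1], a_window[2], length.out = grid_shape[1])
  b_grid <- seq(b_window[1], b_window[2], length.out = grid_shape[2])
  G <- expand.grid(a = a_grid, b = b_grid)
  fixed <- growth_rate_field(kinetics, G$a, G$b, eps2, L2,
                             delay_kernel("dirac", tau = tau, n = n),
                             k_max = k_max, ...)$max_re
  out <- vapply(sigma_fractions, function(cfr) {
    kern <- delay_kernel("gaussian", tau = tau, sigma = cfr * tau / n, n = n)
    dist <- growth_rate_field(kinetics, G$a, G$b, eps2, L2, kern,
                              k_max = k_max, ...)$max_re
    max(abs(dist - fixed), na.rm = TRUE)
  }, numeric(1))
  names(out) <- paste0("sigma_frac_", sigma_fractions)
  out
}

#' Maximal growth rate against mean delay for a skewed kernel
#'
#' For each mean delay \eqn{\tau} on a grid, solves the location
#' \eqn{\mu(\tau)} with the scale coupled as \eqn{\omega = c\,\omega_{\max}}
#' (\eqn{\omega_{\max} = \mu/n}) and computes \eqn{\max_k\Re(\lambda_k)} with
#' the resulting skew kernel; the \eqn{\tau = 0} entry is the undelayed value.
#'
#' @param model an \code{\link{rd_model}}.
#' @param rho skew factor.
#' @param omega_fraction coupling fraction \eqn{c \in (0,1)}.
#' @param tau_grid increasing nonnegative mean delays.
#' @param k_max,... engine settings.
#' @return data frame with columns \code{tau}, \code{max_re},
#'   \code{argmax_k}.
#' @export
skew_growth_curve <- function(model, rho, omega_fraction, tau_grid,
                              k_max = 50L, ...) {
  stopifnot(all(diff(tau_grid) > 0), all(tau_grid >= 0))
  rows <- lapply(tau_grid, function(tau) {
    kern <- if (tau == 0) {
      delay_kernel("dirac", tau = 0)
    } else {
      lm_ <- location_from_mean(tau, rho, omega_fraction = omega_fraction)
      delay_kernel("skew_gaussian", mu = lm_$mu, omega = lm_$omega, rho = rho)
    }
    g <- growth_rate_field(model$kinetics, model$a, model$b, model$eps2,
                           model$L2, kern, k_max = k_max, ...)
    data.frame(tau = tau, max_re = g$max_re, argmax_k = g$argmax_k)
  })
  do.call(rbind, rows)
}
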