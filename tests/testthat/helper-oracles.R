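# Shared independent oracles used across the suite.

# composite Simpson quadrature of a function (odd node count)
simpson_quad <- function(f, a, b, n = 10001L) {
  if (n %% 2L == 0L) n <- n + 1L
  s <- seq(a, b, length.out = n)
  h <- s[2] - s[1]
  w <- rep(c(2, 4), length.out = n)
  w[1] <- 1; w[n] <- 1
  sum(w * f(s)) * h / 3
}

# rightmost root of the zero-delay quadratic
# lambda^2 + (alpha+gamma) lambda + (beta+delta+chi) = 0
quadratic_rightmost <- function(cf) {
  A <- cf$alpha + cf$gamma
  B <- cf$beta + cf$delta + cf$chi
  disc <- as.complex(A^2 - 4 * B)
  r <- cbind((-A + sqrt(disc)) / 2, (-A - sqrt(disc)) / 2)
  r[cbind(seq_len(nrow(r)), max.col(Re(r)))]
}

# central finite-difference Jacobians of the kinetics at the steady state,
# independent of the closed-form Table assembly
fd_jacobians <- function(model, h = 1e-6) {
  ss <- steady_state(model)
  u <- ss[["u"]]; v <- ss[["v"]]
  # full rhs with the delayed arguments (ud, vd) held separate
  rhs <- function(u_, v_, ud, vd) {
    fg <- delayed_kinetics(model, ud, vd)
    kin <- kinetic_rhs(model, u_, v_, fg$F, fg$G)
    c(kin$du, kin$dv)
  }
  J <- D <- matrix(0, 2, 2)
  for (j in 1:2) {
    du_ <- c(u + h, v)[j]; dv_ <- c(u, v + h)[j]
    up <- if (j == 1) c(u + h, v) else c(u, v + h)
    dn <- if (j == 1) c(u - h, v) else c(u, v - h)
    J[, j] <- (rhs(up[1], up[2], u, v) - rhs(dn[1], dn[2], u, v)) / (2 * h)
    D[, j] <- (rhs(u, v, up[1], up[2]) - rhs(u, v, dn[1], dn[2])) / (2 * h)
  }
  list(J = J, D = D)
}

# dispersion coefficients assembled generically from finite-difference
# Jacobians (the oracle for the closed-form Table columns)
fd_dispersion_coefficients <- function(model, k) {
  jd <- fd_jacobians(model)
  J <- jd$J; D <- jd$D
  du <- model$eps2 / model$L2 * (k * pi)^2
  dv <- 1 / model$L2 * (k * pi)^2
  list(alpha = du + dv - J[1, 1] - J[2, 2],
       beta = (du - J[1, 1]) * (dv - J[2, 2]) - J[1, 2] * J[2, 1],
       gamma = -D[1, 1] - D[2, 2],
       delta = -D[2, 2] * (du - J[1, 1]) - D[1, 1] * (dv - J[2, 2]) -
         J[1, 2] * D[2, 1] - J[2, 1] * D[1, 2],
       chi = D[1, 1] * D[2, 2] - D[1, 2] * D[2, 1])
}

# random admissible model parameters for property sweeps
random_model <- function(kinetics) {
  if (kinetics == "LI") {
    rd_model("LI", a = runif(1, 0, 1.4), b = runif(1, 0.05, 2))
  } else {
    rd_model(kinetics, a = runif(1, 0, 1), b = runif(1, 0.1, 4))
  }
}
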