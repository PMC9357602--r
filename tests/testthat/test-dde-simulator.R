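test_that("Laplacian operators: constants, discrete eigenfunctions, mixed case", {
  g <- spatial_grid(50)
  lap <- laplacian_op(g, "neumann")
  expect_equal(lap$u(rep(2.7, g$m)), rep(0, g$m))
  # cos(k pi x) is an eigenfunction of the Neumann stencil with eigenvalue
  # -(2/dx^2)(1 - cos(k pi dx))
  for (k in c(1, 3, 7)) {
    f <- cos(k * pi * g$x)
    eig <- -(2 / g$dx^2) * (1 - cos(k * pi * g$dx))
    expect_equal(lap$u(f), eig * f, tolerance = 1e-10)
    expect_equal(eig, -(k * pi)^2, tolerance = 0.05 * (k * pi)^2)
  }
  # mixed case: clamped activator; interior of sin(pi x) gives -pi^2 sin(pi x)
  lapm <- laplacian_op(g, "mixed")
  f <- sin(pi * g$x)
  out <- lapm$u(f)
  expect_identical(out[c(1, g$m)], c(0, 0))
  interior <- 2:(g$m - 1)
  expect_equal(out[interior], -pi^2 * f[interior], tolerance = 2e-3)
  # discrete conservation: trapezoid-weighted sum of the Neumann Laplacian
  # vanishes for any field
  set.seed(5)
  w <- c(0.5, rep(1, g$m - 2), 0.5) * g$dx
  f <- rnorm(g$m)
  expect_lt(abs(sum(w * lap$u(f))), 1e-10)
})

test_that("delayed terms: constant history, pure lags, transform consistency", {
  m <- rd_model("LI", 0.1, 0.9)
  g <- spatial_grid(10)
  ss <- steady_state(m)
  const_state <- function(t) list(u = rep(ss[["u"]], g$m),
                                  v = rep(ss[["v"]], g$m))
  for (kern in list(delay_kernel("dirac", tau = 1),
                    delay_kernel("gaussian", tau = 1, sigma = 0.2),
                    delay_kernel("skew_gaussian", mu = 1, omega = 0.2,
                                 rho = 6))) {
    ft <- delayed_term(const_state, kern, t = 5, m, nq = 51)
    expect_equal(ft$F, rep(ss[["u"]]^2 * ss[["v"]], g$m), tolerance = 1e-8)
  }
  # exponential test field: dirac gives the lagged value, a distributed
  # kernel reproduces the kernel transform  E(lambda)
  lam <- 0.8
  gm <- rd_model("GM2", 0.75, 0.5)  # F = u^2: quadratic in u
  exp_state <- function(t) list(u = rep(exp(lam * t), g$m),
                                v = rep(1, g$m))
  kd <- delay_kernel("dirac", tau = 0.5)
  expect_equal(delayed_term(exp_state, kd, t = 2, gm)$F,
               rep(exp(2 * lam * (2 - 0.5)), g$m), tolerance = 1e-12)
  kg <- delay_kernel("gaussian", tau = 0.5, sigma = 0.1)
  # F(u(t-s)) = exp(2 lam (t-s)): integral = exp(2 lam t) E(2 lam)
  want <- exp(2 * lam * 2) * kernel_laplace(kg, 2 * lam)
  got <- delayed_term(exp_state, kg, t = 2, gm, nq = 501)$F[1]
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("the homogeneous steady state is preserved by every configuration", {
  g <- spatial_grid(40)
  for (kin in c("LI", "GM1", "GM2")) {
    m <- if (kin == "LI") rd_model(kin, 0.1, 0.9) else rd_model(kin, 0.75, 0.5)
    ss <- steady_state(m)
    ic <- list(u = rep(ss[["u"]], g$m), v = rep(ss[["v"]], g$m))
    for (kern in list(delay_kernel("dirac", tau = 0.5),
                      delay_kernel("gaussian", tau = 0.5, sigma = 0.1))) {
      sim <- simulate_rd(m, kern, ic, t_end = 2, grid = g, dt_out = 0.5)
      expect_lt(max(abs(sim$u - ss[["u"]])), 1e-6)
      expect_lt(max(abs(sim$v - ss[["v"]])), 1e-6)
    }
  }
  # mixed boundary conditions hold the activator at zero on the boundary
  m <- rd_model("LI", 0.1, 0.9)
  ic <- random_ic(m, g, 0.01, seed = 3)
  sim <- simulate_rd(m, delay_kernel("dirac", tau = 0.3), ic, t_end = 1,
                     grid = g, bc = "mixed", dt_out = 0.5)
  expect_true(all(sim$u[, c(1, g$m)] == 0))
})

test_that("pure Neumann diffusion conserves the spatial mean", {
  m <- rd_model("LI", 0.1, 0.9)
  g <- spatial_grid(60)
  ic <- random_ic(m, g, 0.1, seed = 9)
  sim <- simulate_rd(m, delay_kernel("dirac", tau = 0), ic, t_end = 1,
                     grid = g, dt_out = 0.25, include_reaction = FALSE,
                     atol = 1e-11, rtol = 1e-10)
  w <- c(0.5, rep(1, g$m - 2), 0.5) * g$dx
  mass <- drop(sim$u %*% w)
  expect_lt(max(abs(mass - mass[1])), 1e-8)
})

test_that("the simulated dominant-mode growth rate matches linear theory", {
  # small-domain regime: few unstable modes, clean exponential growth
  m <- rd_model("LI", 0.4, 1.8, eps2 = 0.001, L2 = 0.2)
  g <- spatial_grid(100)
  kern <- delay_kernel("dirac", tau = 0.2)
  ic <- random_ic(m, g, 1e-5, seed = 42)
  sim <- simulate_rd(m, kern, ic, t_end = 60, grid = g, dt_out = 0.25,
                     stop_threshold = 0.15)
  ss <- steady_state(m)
  amp <- t(apply(sim$u, 1, function(u) abs(mode_amplitudes(u - ss[["u"]]))))
  kdom <- which.max(amp[nrow(amp), 2:20])
  lam_pred <- unname(Re(rightmost_root(m, kern, kdom)$lambda))
  sel <- sim$t > 2 & amp[, kdom + 1] > 1e-7 & amp[, kdom + 1] < 0.02
  fit <- stats::lm(log(amp[sel, kdom + 1]) ~ sim$t[sel])
  expect_equal(unname(stats::coef(fit)[2]), lam_pred, tolerance = 0.05)
})

test_that("refining the grid and tolerances leaves the final field unchanged", {
  m <- rd_model("LI", 0.4, 1.8, eps2 = 0.001, L2 = 0.2)
  kern <- delay_kernel("dirac", tau = 0.2)
  t_end <- 30
  run <- function(mm, atol, rtol) {
    g <- spatial_grid(mm)
    ic <- list(u = steady_state(m)[["u"]] * (1 + 1e-3 * cos(pi * g$x)),
               v = rep(steady_state(m)[["v"]], mm))
    simulate_rd(m, kern, ic, t_end = t_end, grid = g, dt_out = t_end,
                atol = atol, rtol = rtol)
  }
  coarse <- run(80, 1e-9, 1e-8)
  fine <- run(160, 1e-10, 1e-9)
  u_c <- coarse$u[nrow(coarse$u), ]
  u_f <- fine$u[nrow(fine$u), seq(1, 160, by = 2)]
  expect_lt(max(abs(u_c - u_f)) / max(abs(u_f)), 0.01)
})

test_that("blow-up and bad input are reported, not returned", {
  m <- rd_model("LI", 0.1, 0.9)
  g <- spatial_grid(10)
  expect_error(simulate_rd(m, delay_kernel("dirac", tau = 1),
                           list(u = 1:5, v = 1:5), t_end = 1, grid = g),
               "length")
  expect_error(simulate_rd(m, delay_kernel("dirac", tau = 1),
                           random_ic(m, g, 0.01, 1), t_end = -1, grid = g),
               "t_end")
})
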