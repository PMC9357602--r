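test_that("zero-delay rightmost roots equal the quadratic-formula oracle", {
  set.seed(31)
  kern0 <- delay_kernel("dirac", tau = 0)
  for (kin in c("LI", "GM1", "GM2")) {
    for (i in 1:67) {
      m <- random_model(kin)
      k <- sample(0:30, 1)
      cf <- dispersion_coefficients(m, k)
      oracle <- quadratic_rightmost(cf)
      rr <- rightmost_root(m, kern0, k)
      expect_lt(abs(Re(rr$lambda) - Re(oracle)), 1e-10)
      expect_lt(rr$residual, 1e-8)
    }
  }
})

test_that("the characteristic residual reduces to the quadratic at zero delay", {
  m <- rd_model("LI", 0.1, 0.9)
  kern0 <- delay_kernel("dirac", tau = 0)
  cf <- dispersion_coefficients(m, 10)
  lam <- c(-3 + 2i, 0.4 + 0i, -0.1 - 1i)
  expect_equal(characteristic_residual(m, kern0, 10, lam),
               lam^2 + (cf$alpha + cf$gamma) * lam +
                 (cf$beta + cf$delta + cf$chi), tolerance = 1e-12)
  # the two explicit quadratic roots at k = 10 are residual-zero
  r <- quadratic_rightmost(cf)
  expect_lt(Mod(characteristic_residual(m, kern0, 10, r)), 1e-8)
})

test_that("solver roots satisfy the residual invariant with delay", {
  m <- rd_model("LI", 0.1, 0.9)
  for (kern in list(delay_kernel("dirac", tau = 0.6),
                    delay_kernel("gaussian", tau = 0.6, sigma = 0.15))) {
    for (k in c(0L, 4L, 9L)) {
      rr <- rightmost_root(m, kern, k)
      res <- Mod(characteristic_residual(m, kern, k, rr$lambda,
                                         nodes = 2001L))
      expect_lt(res, 1e-6)
      expect_lt(rr$residual, 1e-8)
    }
  }
})

test_that("the rightmost root is continuous in the delay", {
  m <- rd_model("LI", 0.1, 0.9)
  taus <- seq(0, 1, by = 0.05)
  re <- vapply(taus, function(tau) {
    Re(rightmost_root(m, delay_kernel("dirac", tau = tau), 4)$lambda)
  }, numeric(1))
  # no jumps: each increment bounded by a small multiple of its predecessor
  d <- abs(diff(re))
  expect_true(all(d[-1] < 3 * d[-length(d)] + 1e-6))
  expect_true(all(diff(re) < 0))  # delay only slows the growth here
})

test_that("max growth rate flags the Turing-unstable and stable LI points", {
  kern0 <- delay_kernel("dirac", tau = 0)
  g1 <- max_growth_rate(rd_model("LI", 0.1, 0.9), kern0, k_max = 50)
  expect_gt(g1$max_re, 0)
  expect_gt(g1$argmax_k, 0)
  expect_true(all(g1$table$residual < 1e-8))
  g2 <- max_growth_rate(rd_model("LI", 1.4, 0.1), kern0, k_max = 50)
  expect_lt(g2$max_re, 0)
})

test_that("symmetric-kernel discrepancy shrinks with the spread and with its limit", {
  # coarse desk-scale grid; the ordering across spread fractions is the claim
  disc <- distributed_vs_fixed_discrepancy(
    "LI", tau = 0.2, sigma_fractions = c(0.99, 0.2, 0.1),
    grid_shape = c(8L, 11L))
  expect_true(all(diff(unname(disc)) < 0))
  expect_lt(disc[["sigma_frac_0.1"]], disc[["sigma_frac_0.99"]] / 10)
})

test_that("Turing scans: region counts respond to delay as the kinetics dictate", {
  a_gm <- seq(0, 1, length.out = 9)
  b_gm <- seq(0.05, 4, length.out = 13)
  kern0 <- delay_kernel("dirac", tau = 0)
  kern03 <- delay_kernel("dirac", tau = 0.3)
  s1_0 <- turing_space_scan("GM1", kern0, a_gm, b_gm)
  s1_d <- turing_space_scan("GM1", kern03, a_gm, b_gm)
  expect_lt(s1_d$turing_cells, s1_0$turing_cells)  # GM1: delay shrinks it
  s2_0 <- turing_space_scan("GM2", kern0, a_gm, b_gm)
  s2_d <- turing_space_scan("GM2", kern03, a_gm, b_gm)
  expect_gt(s2_d$turing_cells, s2_0$turing_cells)  # GM2: delay expands it
  # scan invariants inside the Turing region
  inside <- !is.na(s1_0$re_lambda0) & s1_0$re_lambda0 < 0 &
    !is.na(s1_0$max_re_nonzero) & s1_0$max_re_nonzero > 0
  expect_identical(sum(inside), s1_0$turing_cells)
})

test_that("the LI inhomogeneous marginal contour does not move with delay", {
  a_g <- seq(0, 1.4, length.out = 15)
  b_g <- seq(0, 2, length.out = 21)
  cell <- sqrt(diff(a_g)[1]^2 + diff(b_g)[1]^2)
  scans <- lapply(c(0, 0.5, 1.5), function(tau) {
    turing_space_scan("LI", delay_kernel("dirac", tau = tau), a_g, b_g)
  })
  for (s in scans[-1]) {
    expect_lt(hausdorff_distance(scans[[1]]$contour_knz, s$contour_knz), cell)
  }
})

test_that("skew growth curves collapse to the symmetric and undelayed limits", {
  m <- rd_model("LI", 0.1, 0.9)
  taus <- c(0, 0.2, 0.4)
  base <- vapply(taus, function(tau) {
    kern <- if (tau == 0) delay_kernel("dirac", tau = 0) else
      delay_kernel("gaussian", tau = tau, sigma = 0.99 * tau / 3)
    max_growth_rate(m, kern, k_max = 12)$max_re
  }, numeric(1))
  cur0 <- skew_growth_curve(m, rho = 0, omega_fraction = 0.99,
                            tau_grid = taus, k_max = 12)
  expect_equal(cur0$max_re, base, tolerance = 1e-6)
  # tau -> 0 endpoint of any skew curve is the undelayed growth rate
  cur <- skew_growth_curve(m, rho = 10, omega_fraction = 0.99,
                           tau_grid = c(0, 0.1), k_max = 12)
  expect_equal(cur$max_re[1], base[1], tolerance = 1e-10)
})
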