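test_that("standard normal cdf has the symmetry and quadrature-checked values", {
  expect_equal(std_normal_cdf(0), 0.5)
  x <- c(0.3, 1.1, 2.7)
  expect_equal(std_normal_cdf(-x) + std_normal_cdf(x), rep(1, 3))
  # frozen value from 1e6-node composite Simpson of the Gaussian pdf
  expect_equal(std_normal_cdf(1.96), 0.9750021049, tolerance = 1e-9)
  expect_error(std_normal_cdf(Inf), "finite")
})

test_that("Owen's T matches its closed-form special cases and quadrature", {
  expect_identical(owens_t(0.7, 0), 0)
  expect_equal(owens_t(0, 1), 1 / 8, tolerance = 1e-12)
  # frozen value from 1e6-node composite Simpson of the defining integral
  expect_equal(owens_t(1, 1), 0.066741882166, tolerance = 1e-9)
  for (x in c(-1.3, 0.4, 2)) {
    for (rho in c(0.5, 3, 10)) {
      expect_equal(owens_t(x, -rho), -owens_t(x, rho), tolerance = 1e-10)
    }
  }
})

test_that("kernel construction enforces the positive-delay truncation window", {
  expect_error(delay_kernel("gaussian", tau = 1, sigma = 0.4), "tau1")
  expect_error(delay_kernel("skew_gaussian", mu = 1, omega = 0.5, rho = 2),
               "tau1")
  # sigma_max = tau/3 boundary: just inside is fine, the boundary is not
  expect_s3_class(delay_kernel("gaussian", tau = 1, sigma = 1 / 3 - 1e-9),
                  "delay_kernel")
  expect_error(delay_kernel("gaussian", tau = 1, sigma = 1 / 3))
  # sigma = 0 collapses to the dirac family
  expect_identical(delay_kernel("gaussian", tau = 2, sigma = 0)$family,
                   "dirac")
})

test_that("kernel pdf is normalised, truncated, and matches the closed density", {
  # truncation constant for n = 3: 1 / (Phi(3) - Phi(-3))
  k <- delay_kernel("gaussian", tau = 1, sigma = 0.2)
  phi_c <- 1 / (pnorm(3) - pnorm(-3))
  expect_equal(kernel_pdf(k, 1), phi_c / (0.2 * sqrt(2 * pi)),
               tolerance = 1e-12)
  expect_equal(phi_c, 1.0027071047, tolerance = 1e-9)
  expect_identical(kernel_pdf(k, c(0.1, 2)), c(0, 0))  # outside the window
  # normalisation across random admissible kernels of both families
  set.seed(11)
  for (i in 1:20) {
    tau <- runif(1, 0.3, 5)
    frac <- runif(1, 0.05, 0.95)
    kg <- delay_kernel("gaussian", tau = tau, sigma = frac * tau / 3)
    expect_lt(abs(simpson_quad(function(s) kernel_pdf(kg, s),
                               kg$tau1, kg$tau2) - 1), 1e-8)
    rho <- runif(1, -12, 12)
    ks <- delay_kernel("skew_gaussian", mu = tau, omega = frac * tau / 3,
                       rho = rho)
    expect_lt(abs(simpson_quad(function(s) kernel_pdf(ks, s),
                               ks$tau1, ks$tau2) - 1), 1e-8)
  }
})

test_that("zero skew reduces the skew kernel to the symmetric one", {
  kg <- delay_kernel("gaussian", tau = 1.5, sigma = 0.3)
  ks <- delay_kernel("skew_gaussian", mu = 1.5, omega = 0.3, rho = 0)
  s <- seq(kg$tau1, kg$tau2, length.out = 41)
  expect_equal(kernel_pdf(ks, s), kernel_pdf(kg, s), tolerance = 1e-8)
  expect_equal(kernel_mean(ks), 1.5, tolerance = 1e-12)
  lam <- c(-0.7, 0, 1.2)
  expect_equal(Re(kernel_laplace(ks, as.complex(lam), nodes = 801)),
               kernel_laplace(kg, lam), tolerance = 1e-8)
})

test_that("kernel means: dirac and gaussian give tau, skew matches quadrature", {
  expect_identical(kernel_mean(delay_kernel("dirac", tau = 1)), 1)
  expect_identical(kernel_mean(delay_kernel("gaussian", tau = 2, sigma = 0.5)),
                   2)
  # frozen value: 1e5-node Simpson of s * K_S for (mu, omega, rho) = (1, 0.3, 10)
  ks <- delay_kernel("skew_gaussian", mu = 1, omega = 0.3, rho = 10)
  expect_equal(kernel_mean(ks), 1.236155907190, tolerance = 1e-9)
  # closed form equals direct quadrature across a sweep
  set.seed(7)
  for (i in 1:12) {
    mu <- runif(1, 0.5, 3)
    om <- runif(1, 0.05, 0.3) * mu
    rho <- runif(1, -15, 15)
    k <- delay_kernel("skew_gaussian", mu = mu, omega = om, rho = rho)
    mq <- simpson_quad(function(s) s * kernel_pdf(k, s), k$tau1, k$tau2,
                       n = 100001L)
    expect_equal(kernel_mean(k), mq, tolerance = 1e-6)
  }
})

test_that("location_from_mean inverts the mean relation", {
  # symmetric case: mu = tau for any admissible omega
  r0 <- location_from_mean(2, rho = 0, omega = 0.1)
  expect_equal(r0$mu, 2, tolerance = 1e-9)
  # round trip through the kernel mean, explicit and coupled scale
  for (rho in c(-10, 3, 10)) {
    r <- location_from_mean(1, rho = rho, omega_fraction = 0.99)
    k <- delay_kernel("skew_gaussian", mu = r$mu, omega = r$omega, rho = rho)
    expect_equal(kernel_mean(k), 1, tolerance = 1e-9)
    r2 <- location_from_mean(0.7, rho = rho, omega = 0.05)
    k2 <- delay_kernel("skew_gaussian", mu = r2$mu, omega = 0.05, rho = rho)
    expect_equal(kernel_mean(k2), 0.7, tolerance = 1e-9)
  }
  expect_error(location_from_mean(1, 1, omega = 0.1, omega_fraction = 0.5),
               "exactly one")
})

test_that("kernel transform: normalisation, dirac closed form, quadrature oracle", {
  kd <- delay_kernel("dirac", tau = 1)
  kg <- delay_kernel("gaussian", tau = 1, sigma = 0.2)
  ks <- delay_kernel("skew_gaussian", mu = 1, omega = 0.2, rho = -5)
  for (k in list(kd, kg, ks)) expect_equal(Re(kernel_laplace(k, 0)), 1,
                                           tolerance = 1e-8)
  expect_equal(kernel_laplace(kd, 1), exp(-1))
  # frozen value: 1e6-node Simpson of K_N(s) e^(-s)
  expect_equal(kernel_laplace(kg, 1), 0.375106951850, tolerance = 1e-9)
  # closed form on the real axis agrees with the quadrature path
  lam <- c(-2, -0.5, 0.8, 3)
  expect_equal(kernel_laplace(kg, lam),
               Re(kernel_laplace(kg, as.complex(lam), nodes = 2001)),
               tolerance = 1e-9)
})

test_that("the gaussian transform approaches the fixed-delay limit monotonically", {
  lam <- 1.3
  target <- exp(-lam * 1)
  sig <- 0.3 / 2^(0:5)
  err <- vapply(sig, function(s) {
    abs(kernel_laplace(delay_kernel("gaussian", tau = 1, sigma = s), lam) -
          target)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[length(err)], 1e-3)
})

test_that("maximal admissible spreads at unit mean delay", {
  # symmetric kernel: sigma_max = tau/3 exactly
  expect_lt(abs(1 / 3 - 0.3333), 5e-5)
  expect_error(delay_kernel("gaussian", tau = 1, sigma = 1 / 3))
  # skewed kernel: joint solve of the mean relation with omega = mu/3;
  # both skew signs reported (positive skew pulls the location below the
  # mean, so its omega_max is the smaller of the two)
  wp <- skew_omega_max(1, 10)
  wm <- skew_omega_max(1, -10)
  expect_equal(kernel_mean(delay_kernel("skew_gaussian", mu = wp$mu,
                                        omega = wp$omega_max * (1 - 1e-9),
                                        rho = 10)), 1, tolerance = 1e-6)
  expect_lt(wp$omega_max, 1 / 3)
  expect_gt(wm$omega_max, 1 / 3)
})
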