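test_that("piecewise-linear rate follows its three branches", {
  F <- ref_rate(0.4)
  expect_equal(evaluate_rate(F, 0.2), 0.2)
  expect_equal(evaluate_rate(F, -1), 0)
  expect_equal(evaluate_rate(F, 1.0), 0.4)
  # vectorised, bounded, F(0) = 0, monotone
  a <- seq(-2, 2, by = 0.01)
  v <- evaluate_rate(F, a)
  expect_true(all(v >= 0 & v <= 0.4))
  expect_equal(evaluate_rate(F, 0), 0)
  expect_true(all(diff(v) >= 0))
  # unit slope at 0+
  expect_equal(evaluate_rate(F, 1e-9) / 1e-9, 1)
})

test_that("tanh and sigmoid rates have the advertised shape", {
  expect_equal(evaluate_rate(firing_rate("tanh"), 0), 0)
  expect_equal(evaluate_rate(firing_rate("tanh"), 0.7), tanh(0.7))
  S <- firing_rate("sigmoid", kappa = 0.4)
  expect_equal(evaluate_rate(S, 0.4), 1) # half height at threshold
  expect_gt(evaluate_rate(S, 0), 0) # not absorbing-state compatible
  a <- seq(-3, 3, by = 0.05)
  expect_true(all(diff(evaluate_rate(S, a)) > 0))
})

test_that("rate evaluation rejects non-finite activity", {
  expect_error(evaluate_rate(ref_rate(), NaN), "finite")
})

test_that("Gaussian kernel value, evenness and mass", {
  w <- ref_kernel()
  expect_equal(kernel_value(w, 0), 1.2 / sqrt(2 * pi), tolerance = 1e-12)
  x <- seq(0.1, 5, by = 0.37)
  expect_equal(kernel_value(w, x), kernel_value(w, -x))
  expect_true(all(kernel_value(w, seq(-10, 10, 0.1)) >= 0))
  # quadrature oracle: mass over [-10 sigma, 10 sigma] recovers W0
  m <- stats::integrate(function(y) kernel_value(w, y), -10, 10,
                        rel.tol = 1e-12)$value
  expect_equal(m, 1.2, tolerance = 1e-8)
})

test_that("wrapped periodic kernel has period L and mass W0 over one period", {
  L <- 12
  w <- weight_kernel(1.2, 1, form = "periodic_wrapped_gaussian", period = L)
  x <- seq(-3, 3, by = 0.4)
  expect_equal(kernel_value(w, x), kernel_value(w, x + L), tolerance = 1e-12)
  m <- stats::integrate(function(y) kernel_value(w, y), 0, L,
                        rel.tol = 1e-10, subdivisions = 400)$value
  expect_equal(m, 1.2, tolerance = 1e-6)
})

test_that("homogeneous fixed points: piecewise linear cases", {
  fp <- homogeneous_fixed_points(ref_rate(0.4), 1.2)
  expect_equal(fp$a_star, c(0, 0.4), tolerance = 1e-10)
  expect_equal(fp$stability, c("unstable", "stable"))
  # each root satisfies the fixed-point equation
  expect_true(all(abs(fp$a_star -
                        evaluate_rate(ref_rate(0.4), 1.2 * fp$a_star)) < 1e-10))
  # subcritical mass: only the origin, now stable
  fp2 <- homogeneous_fixed_points(ref_rate(0.4), 0.5)
  expect_equal(fp2$a_star, 0)
  expect_equal(fp2$stability, "stable")
})

test_that("tanh nonzero fixed point matches a bisection oracle", {
  q0_oracle <- bisect(function(q) q - tanh(1.2 * q), 0.1, 1)
  fp <- homogeneous_fixed_points(firing_rate("tanh"), 1.2)
  expect_equal(max(fp$a_star), q0_oracle, tolerance = 1e-9)
  expect_equal(q0_oracle, 0.6585, tolerance = 1e-3)
})

test_that("heterogeneity modulation factors", {
  expect_equal(modulation(het_none(), c(-5, 0, 5)), c(1, 1, 1))
  h <- het_slow_linear(0.01, offset = 10)
  expect_equal(modulation(h, c(10, 20)), c(1, 1.1))
  hp <- het_periodic(0.5, c(`1` = 0.5, `-1` = 0.5))
  u <- seq(0, 3, by = 0.21)
  expect_equal(modulation(hp, u), 1 + cos(u / 0.5), tolerance = 1e-12)
  # one-sided coefficient input is completed by conjugation
  hp2 <- het_periodic(0.5, c(`1` = 0.5))
  expect_equal(modulation(hp2, u), modulation(hp, u))
  expect_warning(het_periodic(0.5, c(`1` = 0.8, `-1` = 0.8)), "positive")
})

test_that("tabulated slow profiles interpolate and extend flat with warning", {
  tab <- data.frame(x = c(0, 1, 2), f = c(0, 1, 0))
  h <- het_slow(0.1, tab)
  expect_equal(modulation(h, 0.5), 1 + 0.1 * 0.5)
  expect_warning(v <- modulation(h, 5), "flat")
  expect_equal(v, 1.0) # boundary value f = 0
})

test_that("model config round-trips exactly", {
  cfg <- list(
    kernel = list(form = "gaussian", W0 = 1.2, sigma = 1),
    rate = list(form = "piecewise_linear", kappa = 0.4),
    het = list(kind = "slow", beta = 0.005,
               profile = list(type = "linear", offset = 10)),
    tau = 1
  )
  m <- model_from_config(cfg)
  expect_identical(model_to_config(m), cfg)
  # periodic heterogeneity too
  cfg2 <- list(kernel = list(form = "gaussian", W0 = 1.2, sigma = 1),
               rate = list(form = "tanh"),
               het = list(kind = "periodic", eps = 0.5,
                          coeffs = list(`1` = 0.5, `-1` = 0.5)),
               tau = 2)
  m2 <- model_from_config(cfg2)
  rt <- model_to_config(m2)
  expect_equal(rt$het$coeffs[["1"]], 0.5)
  expect_equal(rt$tau, 2)
  expect_error(model_from_config(c(cfg, list(bogus = 1))), "unknown key")
})
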