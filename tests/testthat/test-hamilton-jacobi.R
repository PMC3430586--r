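test_that("Hamiltonian values and symmetry", {
  w <- ref_kernel()
  expect_equal(hj_hamiltonian(0, 0, w), 0.2)
  # at the minimal-speed momentum, H = c0 lambda0 (front-locus identity)
  d <- minimal_speed(w)
  expect_equal(hj_hamiltonian(d$lambda0, 0, w), d$c0 * d$lambda0,
               tolerance = 1e-10)
  p <- seq(0.1, 1.5, by = 0.17)
  expect_equal(hj_hamiltonian(p, 0, w), hj_hamiltonian(-p, 0, w))
})

test_that("homogeneous BVP: constant momentum, linear path, conserved energy", {
  w <- ref_kernel()
  b <- solve_hamilton_bvp(w, x = 3, t = 5)
  expect_lt(max(abs(b$path$P - b$p0)), 1e-9)
  expect_equal(b$path$X, 3 * b$path$s / 5, tolerance = 1e-8)
  expect_lt(b$energy_drift, 1e-8)
  # p0 solves W'(p) = x / t
  expect_equal(kernel_transform_prime(w, b$p0), 3 / 5, tolerance = 1e-9)
  # endpoint condition
  expect_equal(b$path$X[nrow(b$path)], 3, tolerance = 1e-8)
})

test_that("energy is conserved along heterogeneous BVP paths", {
  w <- ref_kernel()
  f <- function(x) sin(0.3 * x)
  fp <- function(x) 0.3 * cos(0.3 * x)
  for (beta in c(0.05, 0.2)) {
    b <- solve_hamilton_bvp(w, x = 3, t = 5,
                            J = function(x) 1 + beta * f(x),
                            Jprime = function(x) beta * fp(x))
    expect_lt(b$energy_drift, 1e-8)
  }
})

test_that("BVP momentum matches first-order perturbation theory at O(beta^2)", {
  w <- ref_kernel()
  f <- function(x) sin(0.3 * x)
  fp <- function(x) 0.3 * cos(0.3 * x)
  x_end <- 3; t_end <- 5
  betas <- c(1e-1, 1e-2, 1e-3)
  errs <- vapply(betas, function(beta) {
    b <- solve_hamilton_bvp(w, x_end, t_end,
                            J = function(x) 1 + beta * f(x),
                            Jprime = function(x) beta * fp(x))
    pert <- first_order_momentum(w, f, x_end, t_end, b$path$s)
    max(abs(b$path$P - (pert$lambda + beta * pert$p1)))
  }, numeric(1))
  slope <- stats::coef(stats::lm(log(errs) ~ log(betas)))[2]
  expect_gt(slope, 1.8)
  expect_lt(slope, 2.2)
})

test_that("sign of the first-order response flips with the modulation gradient", {
  w <- ref_kernel()
  beta <- 1e-3
  f <- function(x) sin(0.3 * x)
  fp <- function(x) 0.3 * cos(0.3 * x)
  bp <- solve_hamilton_bvp(w, 3, 5, J = function(x) 1 + beta * f(x),
                           Jprime = function(x) beta * fp(x))
  bm <- solve_hamilton_bvp(w, 3, 5, J = function(x) 1 - beta * f(x),
                           Jprime = function(x) -beta * fp(x))
  lam <- first_order_momentum(w, f, 3, 5, bp$path$s)$lambda
  dev_p <- bp$path$P - lam
  dev_m <- bm$path$P - lam
  expect_lt(max(abs(dev_p + dev_m)), 10 * beta^2)
})

test_that("action G: homogeneous closed form, front locus, positivity ahead", {
  w <- ref_kernel()
  d <- minimal_speed(w)
  # closed form with lambda solving W'(lambda) = x/t
  expect_equal(action_G(w, 3, 5), action_G_homogeneous(w, 3, 5),
               tolerance = 1e-8)
  # on the front locus x = c0 t the action vanishes
  expect_lt(abs(action_G_homogeneous(w, d$c0 * 7, 7)), 1e-10)
  # ahead of the front G > 0
  expect_gt(action_G_homogeneous(w, d$c0 * 7 + 1, 7), 0)
  # heterogeneous action matches the first-order closed form to O(beta^2)
  beta <- 1e-3
  f <- function(x) sin(0.3 * x)
  lam <- first_order_momentum(w, f, 3, 5, 0)$lambda
  Fint <- stats::integrate(f, 0, 3, rel.tol = 1e-12)$value
  G1 <- 5 - kernel_transform(w, lam) * 5 + lam * 3 -
    beta * kernel_transform(w, lam) * (5 / 3) * Fint
  Gh <- action_G(w, 3, 5, J = function(x) 1 + beta * f(x),
                 Jprime = function(x) beta * 0.3 * cos(0.3 * x))
  expect_lt(abs(Gh - G1), 10 * beta^2)
})

test_that("minimal speed from the front-locus condition equals dispersion", {
  w <- ref_kernel()
  d <- minimal_speed(w)
  # minimise (W(lambda) - 1)/lambda via the HJ identity xdot = H(p)/p
  c_hj <- stats::optimize(function(l) hj_hamiltonian(l, 0, w) / l,
                          c(0.05, 3), tol = 1e-12)$objective
  expect_equal(c_hj, d$c0, tolerance = 1e-8)
})

test_that("perturbed front position: trivial, quadratic and quadrature routes", {
  w <- ref_kernel()
  d <- minimal_speed(w)
  # beta = 0 reduces to uniform motion
  expect_equal(perturbed_front_position(w, 0, function(y) y, c(1, 5, 10),
                                        l = 10),
               10 + d$c0 * c(1, 5, 10))
  # linear profile: quadrature route equals the closed parabola
  t_grid <- seq(0, 40, by = 5)
  f_lin <- function(y) y - 10
  eps2 <- 0.005
  expect_equal(perturbed_front_position(w, eps2, f_lin, t_grid, l = 10),
               front_position_parabola(w, eps2, t_grid, l = 10),
               tolerance = 1e-10)
  # quadratic coefficient equals eps2 c0 (c0 lambda0 + 1) / (2 lambda0)
  co <- eps2 * d$c0 * (d$c0 * d$lambda0 + 1) / (2 * d$lambda0)
  x2 <- front_position_parabola(w, eps2, 2, l = 10)
  x1 <- front_position_parabola(w, eps2, 1, l = 10)
  x0 <- front_position_parabola(w, eps2, 0, l = 10)
  expect_equal((x2 - 2 * x1 + x0) / 1, 2 * co, tolerance = 1e-10)
})

test_that("instantaneous speed: constants and finite-difference consistency", {
  w <- ref_kernel()
  d <- minimal_speed(w)
  expect_equal(instantaneous_speed(w, 0, function(y) y, 7), d$c0)
  shift <- instantaneous_speed(w, 0.01, function(y) rep(1, length(y)), 3) - d$c0
  expect_equal(shift, 0.01 * kernel_transform(w, d$lambda0) / d$lambda0,
               tolerance = 1e-12)
  # d/dt of the position prediction matches the speed formula
  f <- function(y) sin(0.2 * y)
  beta <- 0.01
  h <- 1e-4
  for (tt in c(5, 12)) {
    fd <- (perturbed_front_position(w, beta, f, tt + h) -
             perturbed_front_position(w, beta, f, tt - h)) / (2 * h)
    expect_equal(fd, instantaneous_speed(w, beta, f, tt), tolerance = 1e-6)
  }
})
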