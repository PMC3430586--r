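test_that("reduced vector field: deterministic line and fixed points", {
  sys <- tanh_system()
  # p = 0: coordinate equation is the scalar neural field, momentum is frozen
  d <- reduced_rhs(sys, 0.3, 0)
  expect_equal(d$qdot, -0.3 + tanh(1.2 * 0.3))
  expect_equal(d$pdot, 0)
  # the metastable state is a fixed point
  q0 <- max(homogeneous_fixed_points(firing_rate("tanh"), 1.2)$a_star)
  d0 <- reduced_rhs(sys, q0, 0)
  expect_lt(abs(d0$qdot), 1e-10)
  expect_lt(abs(d0$pdot), 1e-10)
  expect_error(reduced_rhs(sys, -0.1, 0), "non-negative")
})

test_that("reduced vector field matches the Hamiltonian gradient", {
  sys <- tanh_system()
  h <- 1e-6
  for (pt in list(c(0.3, -0.2), c(0.5, 0.1), c(0.1, -0.35))) {
    q <- pt[1]; p <- pt[2]
    d <- reduced_rhs(sys, q, p)
    dHdp <- (reduced_hamiltonian(sys, q, p + h) -
               reduced_hamiltonian(sys, q, p - h)) / (2 * h)
    dHdq <- (reduced_hamiltonian(sys, q + h, p) -
               reduced_hamiltonian(sys, q - h, p)) / (2 * h)
    expect_equal(d$qdot, dHdp, tolerance = 1e-6)
    expect_equal(d$pdot, -dHdq, tolerance = 1e-6)
  }
})

test_that("fluctuational fixed point: closed form across noise exponents", {
  fps <- reduced_fixed_points(tanh_system(beta = 1, s = 0.5))
  expect_equal(fps$p_magnitude[fps$name == "P"], 0.4, tolerance = 1e-14)
  expect_equal(fps$p[fps$name == "P"], -0.4, tolerance = 1e-14) # signed
  # both Hamilton right-hand sides vanish at every listed fixed point
  sys <- tanh_system()
  for (i in seq_len(nrow(fps))) {
    d <- reduced_rhs(sys, fps$q[i], fps$p[i])
    expect_lt(abs(d$qdot), 1e-10)
    expect_lt(abs(d$pdot), 1e-10)
  }
  # beta scaling and the s < 1/2 degenerate case
  expect_equal(reduced_fixed_points(tanh_system(beta = 2, s = 0.5))$p_magnitude[3],
               0.1)
  expect_equal(reduced_fixed_points(tanh_system(s = 0.25))$p[3], 0)
  expect_error(reduced_fixed_points(tanh_system(s = 0.75)), "fluctuational")
})

test_that("zero-energy branch: endpoints, limit, and H = 0 identity", {
  sys <- tanh_system()
  q0 <- max(homogeneous_fixed_points(firing_rate("tanh"), 1.2)$a_star)
  expect_equal(zero_energy_branch(sys, q0), 0, tolerance = 1e-12)
  # q -> 0 limit approaches p_e = -0.4
  expect_equal(zero_energy_branch(sys, 1e-10), -0.4, tolerance = 1e-8)
  qs <- seq(0.05, q0, length.out = 40)
  ps <- zero_energy_branch(sys, qs)
  expect_lt(max(abs(reduced_hamiltonian(sys, qs, ps))), 1e-12)
  expect_error(zero_energy_branch(sys, 2 * q0), "q must lie")
  expect_error(zero_energy_branch(sys, 0), "q must lie")
})

test_that("action per unit length: Simpson oracle and two-route agreement", {
  q0 <- bisect(function(q) q - tanh(1.2 * q), 0.1, 1)
  # independent Simpson oracle of the branch integral, s = 1/2:
  # integrand 2 (tanh(1.2 q) - q)/q with limit 0.4 at q = 0
  f_half <- function(q) ifelse(q == 0, 0.4, 2 * (tanh(1.2 * q) - q) / q)
  oracle_half <- simpson(f_half, 0, q0, n = 4000)
  act <- action_along_optimal_path(tanh_system(s = 0.5))
  expect_equal(act$S0_over_L, oracle_half, tolerance = 1e-8)
  expect_lt(abs(act$S0_quadrature - act$S0_trajectory), 1e-6)
  expect_equal(act$path_type, "Q+ -> P")
  # s = 1/4: integrand 2 (tanh(1.2 q) - q)/sqrt(q), vanishing at 0
  f_quarter <- function(q) ifelse(q == 0, 0, 2 * (tanh(1.2 * q) - q) / sqrt(q))
  oracle_quarter <- simpson(f_quarter, 0, q0, n = 4000)
  act4 <- action_along_optimal_path(tanh_system(s = 0.25))
  expect_equal(act4$S0_over_L, oracle_quarter, tolerance = 1e-6)
  expect_equal(act4$path_type, "Q+ -> Q-")
  # quadrupling beta divides the action by 16; doubling by 4
  act_b2 <- action_along_optimal_path(tanh_system(beta = 2, s = 0.5))
  expect_equal(act_b2$S0_over_L, act$S0_over_L / 4, tolerance = 1e-10)
})

test_that("action barrier shrinks to zero as invasion becomes marginal", {
  S <- vapply(c(1.05, 1.1, 1.2, 1.5),
              function(w) action_along_optimal_path(tanh_system(W0 = w))$S0_over_L,
              numeric(1))
  expect_true(all(diff(S) > 0)) # increasing in W0, hence decreasing toward W0 = 1
  expect_lt(S[1], 0.05)
  expect_true(all(S > 0))
})

test_that("log extinction time arithmetic and scaling", {
  expect_equal(extinction_time(0.15, 0.1), 15)
  expect_equal(extinction_time(0.15, 0.05), 60) # quadruples when eps halves
  expect_lt(extinction_time(0.15, 100), 1e-4)
  act <- action_along_optimal_path(tanh_system())
  expect_equal(extinction_time(act, 0.1), act$S0_over_L * 100)
})

test_that("constant-energy contours: E = 0 recovery and Vieta root structure", {
  sys <- tanh_system()
  q0 <- max(homogeneous_fixed_points(firing_rate("tanh"), 1.2)$a_star)
  ct0 <- constant_energy_contours(sys, 0, q_range = c(0.05, q0), n = 60)
  lower <- ct0[ct0$branch == "lower", ]
  upper <- ct0[ct0$branch == "upper", ]
  expect_lt(max(abs(upper$p)), 1e-12) # trivial root p = 0
  expect_equal(lower$p, zero_energy_branch(sys, lower$q), tolerance = 1e-10)
  # Vieta: product of roots = -2 E / g^2
  for (e in c(-0.01, 0.02)) {
    ct <- constant_energy_contours(sys, e, q_range = c(0.1, 0.6), n = 30)
    pr <- ct$p[ct$branch == "lower"] * ct$p[ct$branch == "upper"]
    g2 <- ct$q[ct$branch == "lower"]
    expect_equal(pr, -2 * e / g2, tolerance = 1e-10)
  }
  # small-|E| contours hug the zero-energy branches: sup distance ~ O(E)
  es <- c(2e-4, 1e-4, 5e-5, 2.5e-5) # small enough for the linear regime
  dist <- vapply(es, function(e) {
    ct <- constant_energy_contours(sys, e, q_range = c(0.3, 0.5), n = 20)
    max(abs(ct$p[ct$branch == "upper"])) # distance to the p = 0 branch
  }, numeric(1))
  slope <- stats::coef(stats::lm(log(dist) ~ log(es)))[2]
  expect_equal(unname(slope), 1, tolerance = 0.1)
})

test_that("phase portrait assembles branches and plots", {
  pp <- phase_portrait(tanh_system())
  expect_setequal(unique(pp$zero_energy$branch),
                  c("p = 0", "q = 0", "activation"))
  expect_s3_class(autoplot(pp), "ggplot")
})

test_that("field Hamilton equations: deterministic and x-independent reductions", {
  g <- periodic_grid(16, 65)
  m <- model_spec(ref_kernel(), firing_rate("tanh"))
  q <- 0.4 + 0.1 * sin(2 * pi * g$x / 16)
  # p = 0: coordinate flow is the deterministic field, momentum stays zero
  d <- field_hamilton_rhs(q, rep(0, g$N), m, g)
  drive <- convolve_weights(q, m$kernel, g)
  expect_equal(d$qdot, -q + tanh(drive), tolerance = 1e-12)
  expect_true(all(d$pdot == 0))
  # x-independent fields reduce to the scalar system at every node
  sys <- tanh_system()
  dr <- reduced_rhs(sys, 0.3, -0.2)
  df <- field_hamilton_rhs(rep(0.3, g$N), rep(-0.2, g$N), m, g,
                           g = list(beta = 1, s = 0.5))
  expect_equal(df$qdot, rep(dr$qdot, g$N), tolerance = 1e-10)
  expect_equal(df$pdot, rep(dr$pdot, g$N), tolerance = 1e-10)
})

test_that("field Hamilton IVP conserves the energy functional", {
  g <- periodic_grid(16, 65)
  m <- model_spec(ref_kernel(), firing_rate("tanh"))
  q0f <- 0.6586 + 0.05 * sin(2 * pi * g$x / 16)
  p0f <- 0.01 * cos(2 * pi * g$x / 16)
  sol <- integrate_field_hamilton(m, g, q0f, p0f, T = 10)
  expect_lt(sol$energy_drift, 1e-6)
})
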