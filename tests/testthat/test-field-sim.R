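test_that("nonlocal drive recovers the kernel mass in the interior", {
  g <- small_grid(-20, 20, 0.2)
  w <- ref_kernel()
  s <- convolve_weights(rep(1, g$N), w, g)
  mid <- which(abs(g$x) < 5) # > 8 sigma from both edges
  expect_true(all(abs(s[mid] - 1.2) < 1e-6))
  # truncation: boundary node misses roughly half the mass
  expect_lt(s[1], 1.2)
  expect_equal(s[1], 0.6 + kernel_value(w, 0) * g$dx / 2, tolerance = 1e-2)
})

test_that("banded and fft paths agree with the dense direct-sum oracle", {
  set.seed(11)
  for (bc in c("free", "periodic")) {
    g <- if (bc == "periodic") periodic_grid(25, 125) else small_grid(-12, 13, 0.2)
    a <- runif(g$N)
    w <- ref_kernel()
    s_dense <- convolve_weights(a, w, g, method = "dense")
    s_band <- convolve_weights(a, w, g, method = "banded")
    s_fft <- convolve_weights(a, w, g, method = "fft")
    expect_lt(max(abs(s_band - s_dense)), 1e-10)
    expect_lt(max(abs(s_fft - s_dense)), 1e-10)
  }
})

test_that("banded path preserves compact support exactly", {
  g <- small_grid(-40, 40, 0.2)
  a <- numeric(g$N)
  a[g$x < 0] <- 0.3
  s <- convolve_weights(a, ref_kernel(), g, method = "banded")
  far <- g$x > 8 + g$dx # beyond the kernel band from any active node
  expect_true(all(s[far] == 0))
})

test_that("slow and periodic modulations enter the drive as J(x') factors", {
  g <- small_grid(-20, 20, 0.2)
  w <- ref_kernel()
  a <- exp(-g$x^2 / 8)
  h <- het_slow_linear(0.01, offset = 0)
  s_mod <- convolve_weights(a, w, g, h)
  s_ref <- convolve_weights(a * modulation(h, g$x), w, g)
  expect_equal(s_mod, s_ref, tolerance = 1e-14)
})

test_that("uniform nontrivial state is a fixed point of the dynamics", {
  g <- periodic_grid(25, 125)
  m <- ref_model()
  traj <- simulate_field(m, g, rep(0.4, g$N), T = 2, dt = 0.02)
  expect_lt(max(abs(traj$values - 0.4)), 1e-10)
  # trivial state too
  traj0 <- simulate_field(m, g, rep(0, g$N), T = 1, dt = 0.02)
  expect_true(all(traj0$values == 0))
})

test_that("trajectories stay non-negative and kappa-bounded", {
  g <- small_grid(-20, 20, 0.2)
  m <- ref_model()
  a0 <- pmin(front_initial_condition(g, l = 0), 0.4) # start within [0, kappa]
  traj <- simulate_field(m, g, a0, T = 5, dt = 0.02)
  expect_true(all(traj$values >= 0))
  expect_true(all(traj$values <= 0.4 * (1 + 1e-6)))
})

test_that("halving dt changes the solution by a small amount", {
  g <- small_grid(-15, 15, 0.25)
  m <- ref_model()
  a0 <- front_initial_condition(g, l = 0)
  t1 <- simulate_field(m, g, a0, T = 10, dt = 0.02, sample_times = 10)
  t2 <- simulate_field(m, g, a0, T = 10, dt = 0.01, sample_times = 10)
  expect_lt(max(abs(t1$values - t2$values)), 1e-3)
})

test_that("translation invariance on a periodic homogeneous domain", {
  g <- periodic_grid(30, 151)
  m <- ref_model()
  bump <- function(x) 0.3 * exp(-((x - 8) %% 30 - 15)^2 / 2)
  shift_nodes <- 17
  a0 <- bump(g$x)
  a0s <- c(a0[(g$N - shift_nodes + 1):g$N], a0[1:(g$N - shift_nodes)])
  t1 <- simulate_field(m, g, a0, T = 3, dt = 0.02, sample_times = 3)
  t2 <- simulate_field(m, g, a0s, T = 3, dt = 0.02, sample_times = 3)
  v1s <- c(t1$values[1, (g$N - shift_nodes + 1):g$N],
           t1$values[1, 1:(g$N - shift_nodes)])
  expect_lt(max(abs(t2$values[1, ] - v1s)), 1e-10)
})

test_that("steady state: periodic domain is uniform at a0 = F(W0 a0)", {
  g <- periodic_grid(25, 125)
  ss <- steady_state(ref_model(), g)
  expect_lt(ss$residual, 1e-10)
  expect_lt(max(abs(ss$a - 0.4)), 1e-10)
  # tanh rate: bulk value is the nonzero root of q = tanh(1.2 q)
  m2 <- model_spec(ref_kernel(), firing_rate("tanh"))
  ss2 <- steady_state(m2, g)
  q0 <- bisect(function(q) q - tanh(1.2 * q), 0.1, 1)
  expect_lt(max(abs(ss2$a - q0)), 1e-8)
})

test_that("steady state: Dirichlet domain has a kappa bulk and boundary layers", {
  g <- grid_1d(0, 25, 251, bc = "dirichlet_zero")
  ss <- steady_state(ref_model(), g)
  expect_lt(ss$residual, 1e-10)
  bulk <- g$x > 8 & g$x < 17
  expect_lt(max(abs(ss$a[bulk] - 0.4)), 1e-8)
  expect_equal(ss$a[1], 0)
  # the profile dips near the edges (nonlocal truncation)
  expect_lt(ss$a[10], 0.4)
})

test_that("front tracking recovers an exact translation speed", {
  g <- small_grid(-10, 40, 0.1)
  times <- seq(0, 10, by = 0.5)
  # per-sample displacement c dt = 0.4 is a whole number of grid cells, so
  # the interpolation error is identical at every time and cancels exactly
  c_true <- 0.8
  prof <- function(x) 0.4 / (1 + exp(2 * x))
  vals <- t(vapply(times, function(tt) prof(g$x - c_true * tt),
                   numeric(g$N)))
  traj <- structure(list(times = times, values = vals, grid = g,
                         model = ref_model(), scheme = "euler", dt = 0.5),
                    class = "nf_trajectory")
  ft <- track_front(traj, levels = c(0.1, 0.2, 0.3))
  expect_equal(ft$speed, c_true, tolerance = 1e-10)
  # level offsets are constant in time: the profile translates rigidly
  wide <- matrix(ft$positions$X, nrow = length(times))
  offsets <- wide - wide[, 1]
  expect_lt(max(abs(sweep(offsets, 2, offsets[1, ]))), 1e-9)
})

test_that("levels never crossed are flagged missing", {
  g <- small_grid(-10, 10, 0.2)
  vals <- matrix(0.1, 2, g$N) # flat field, no crossing
  traj <- structure(list(times = c(0, 1), values = vals, grid = g,
                         model = ref_model(), scheme = "euler", dt = 1),
                    class = "nf_trajectory")
  ft <- track_front(traj, levels = 0.3)
  expect_true(all(is.na(ft$positions$X)))
  expect_true(is.na(ft$speed))
})

test_that("pulsating simulation: mean speed near Hill prediction, periodic gait", {
  het <- het_periodic(0.5, c(`1` = 0.5, `-1` = 0.5))
  m <- ref_model(het = het)
  g <- grid_1d(-20, 60, 801)
  traj <- simulate_field(m, g, front_initial_condition(g, l = 0), T = 40,
                         dt = 0.02, sample_times = seq(0, 40, by = 0.5))
  ft <- track_front(traj, 0.2, window = c(25, 40))
  c_hill <- pulsating_minimal_speed(
    hill_problem(ref_kernel(), 0.5, c(`1` = 0.5, `-1` = 0.5), M = 8))$c0
  expect_lt(abs(ft$speed - c_hill) / c_hill, 0.15)
  # instantaneous speed oscillates around the mean
  X <- ft$mean_position$X_mean
  tt <- ft$mean_position$t
  sel <- tt >= 25
  inst <- diff(X[sel]) / diff(tt[sel])
  expect_gt(max(inst) - min(inst), 0.02)
})

test_that("invalid inputs are rejected", {
  g <- small_grid(-10, 10, 0.2)
  m <- ref_model()
  expect_error(simulate_field(m, g, rep(-0.1, g$N), T = 1, dt = 0.02),
               "non-negative")
  expect_error(simulate_field(m, g, rep(0.1, g$N), T = 1, dt = 0.5),
               "dt")
})
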