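# shared fixtures: the reference parameter set W0 = 1.2, sigma = 1,
# kappa = 0.4 used throughout, plus small grids sized for fast tests

ref_kernel <- function(W0 = 1.2, sigma = 1) weight_kernel(W0, sigma)

ref_rate <- function(kappa = 0.4) firing_rate("piecewise_linear", kappa = kappa)

ref_model <- function(W0 = 1.2, sigma = 1, kappa = 0.4, het = het_none()) {
  model_spec(weight_kernel(W0, sigma), ref_rate(kappa), het = het)
}

tanh_system <- function(W0 = 1.2, beta = 1, s = 0.5) {
  reduced_system(firing_rate("tanh"), W0 = W0, beta = beta, s = s)
}

small_grid <- function(x_lo = -20, x_hi = 20, dx = 0.2, bc = "free") {
  grid_1d(x_lo, x_hi, round((x_hi - x_lo) / dx) + 1, bc = bc)
}

# periodic grid with an odd node count so the wrapped kernel band covers
# the period exactly
periodic_grid <- function(L = 25, N = 125) grid_1d(0, L, N, bc = "periodic")

# independent bisection root finder (oracle; deliberately not uniroot)
bisect <- function(f, lo, hi, tol = 1e-13, maxit = 200) {
  flo <- f(lo)
  for (i in seq_len(maxit)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (fm == 0 || (hi - lo) / 2 < tol) return(mid)
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  (lo + hi) / 2
}

# composite Simpson quadrature (oracle; deliberately not integrate())
simpson <- function(f, a, b, n = 2000) {
  if (n %% 2 == 1) n <- n + 1
  x <- seq(a, b, length.out = n + 1)
  w <- c(1, rep(c(4, 2), length.out = n - 1), 1)
  sum(w * f(x)) * (b - a) / n / 3
}
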