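#' Full-field extinction Hamilton equations
#'
#' Right-hand sides of the canonical Hamilton equations obtained by
#' extremising the weak-noise action of the stochastic neural field:
#' `dq/dt = dH/dp = -q + F(w * q) + p g^2(q)` and
#' `dp/dt = -dH/dq = p - integral F'( (w * q)(y) ) w(y - x) p(y) dy
#'          - p^2 g(q) g'(q)`.
#' The momentum equation carries the canonical minus sign, which is what
#' conserves the energy functional along trajectories. Note the transposed
#' kernel (`w(y - x)` inside the `y` integral); for an even kernel the
#' transpose equals the original convolution. With `p = 0` the coordinate
#' equation reduces exactly to the deterministic neural field and
#' `dp/dt = 0`; for `x`-independent fields both equations reduce to
#' [reduced_rhs()] at every node.
#'
#' @param q,p Fields on the grid.
#' @param model An [model_spec()] (smooth rate recommended; the kernel must
#'   be even).
#' @param grid A [grid_1d()].
#' @param g Noise-factor parameters, a list with `beta` and `s`
#'   (`g(q) = beta q^s`).
#' @return A list with `qdot`, `pdot`.
#' @export
field_hamilton_rhs <- function(q, p, model, grid, g = list(beta = 1, s = 0.5)) {
  stopifnot(length(q) == grid$N, length(p) == grid$N)
  drive <- convolve_weights(q, model$kernel, grid, model$het)
  Fd <- evaluate_rate(model$rate, drive)
  Fpd <- rate_prime(model$rate, drive)
  gq <- g$beta * pmax(q, 0)^g$s
  gg <- ifelse(q == 0 & 2 * g$s - 1 > 0, 0,
               g$beta^2 * g$s * pmax(q, 0)^(2 * g$s - 1))
  p2gg <- ifelse(p == 0, 0, p^2 * gg)
  # even kernel: the transposed operator is the same banded convolution
  qdot <- -q + Fd + p * gq^2
  pdot <- p - convolve_weights(Fpd * p, model$kernel, grid, model$het) - p2gg
  list(qdot = qdot, pdot = pdot)
}

#' Energy functional of the field Hamilton system
#'
#' `H[q, p] = integral p(x) [ -q + F(w * q) + p g^2(q) / 2 ] dx`, evaluated
#' by the rectangle rule on the grid (spectrally accurate on a periodic
#' domain).
#'
#' @inheritParams field_hamilton_rhs
#' @return Energy value.
#' @export
field_hamiltonian <- function(q, p, model, grid, g = list(beta = 1, s = 0.5)) {
  drive <- convolve_weights(q, model$kernel, grid, model$het)
  Fd <- evaluate_rate(model$rate, drive)
  gq <- g$beta * pmax(q, 0)^g$s
  sum(p * (-q + Fd + 0.5 * p * gq^2)) * grid$dx
}

#' Integrate the field Hamilton equations as an initial-value problem
#'
#' Adaptive integration (deSolve, `lsoda`) of the coupled `(q, p)` fields,
#' recording the energy `H[q, p]` along the run; the drift
#' `max |H(t) - H(0)|` diagnoses the discretisation (the spatially
#' discretised system is exactly Hamiltonian, so the drift is controlled by
#' the integrator tolerance).
#'
#' @inheritParams field_hamilton_rhs
#' @param q0,p0 Initial fields.
#' @param T Horizon.
#' @param n_save Saved snapshots.
#' @param rtol,atol Integrator tolerances.
#' @return A list with `times`, `q` and `p` (time-by-node matrices),
#'   `energy` (per snapshot), `energy_drift`.
#' @export
integrate_field_hamilton <- function(model, grid, q0, p0, T, g = list(beta = 1, s = 0.5),
                                     n_save = 41, rtol = 1e-10, atol = 1e-12) {
  N <- grid$N
  rhs <- function(t, y, parms) {
    d <- field_hamilton_rhs(y[1:N], y[(N + 1):(2 * N)], model, grid, g)
    list(c(d$qdot, d$pdot))
  }
  sol <- deSolve::ode(c(q0, p0), times = seq(0, T, length.out = n_save),
                      func = rhs, parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  qm <- sol[, 2:(N + 1), drop = FALSE]
  pm <- sol[, (N + 2):(2 * N + 1), drop = FALSE]
  en <- vapply(seq_len(nrow(sol)), function(i)
    field_hamiltonian(qm[i, ], pm[i, ], model, grid, g), numeric(1))
  list(times = sol[, 1], q = qm, p = pm, energy = en,
       energy_drift = max(abs(en - en[1])))
}
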