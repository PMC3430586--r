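#' Reduced extinction Hamiltonian system
#'
#' For spatially uniform fields the weak-noise Hamiltonian per unit length
#' is
#' `H/L = p [ -q + F(W0 q) + p g^2(q) / 2 ]`
#' with multiplicative-noise factor `g(q) = beta q^s`. The firing rate must
#' satisfy `F(0) = 0` with unit slope at the origin (the scale convention
#' under which the fluctuational momentum takes its closed form).
#'
#' @param rate A [firing_rate()] with `F(0) = 0` (piecewise linear or tanh).
#' @param W0 Synaptic mass (`W0 > 1` for a metastable active state).
#' @param beta,s Noise-factor parameters, `g(q) = beta q^s` with `beta > 0`
#'   and `0 < s <= 1`.
#' @return An object of class `"nf_reduced"`.
#' @examples
#' reduced_system(firing_rate("tanh"), W0 = 1.2, beta = 1, s = 0.5)
#' @export
reduced_system <- function(rate, W0, beta = 1, s = 0.5) {
  stopifnot(inherits(rate, "nf_rate"), W0 > 0, beta > 0, s > 0, s <= 1)
  if (rate$form == "sigmoid")
    stop("sigmoid rate has F(0) > 0: no absorbing state", call. = FALSE)
  structure(list(rate = rate, W0 = W0, beta = beta, s = s),
            class = "nf_reduced")
}

reduced_g <- function(sys, q) sys$beta * q^sys$s
reduced_gprime <- function(sys, q) sys$beta * sys$s * q^(sys$s - 1)

#' Reduced Hamiltonian and its vector field
#'
#' `reduced_hamiltonian` evaluates `H/L`; `reduced_rhs` evaluates the
#' canonical Hamilton equations
#' `qdot = dH/dp = -q + F(W0 q) + p g^2(q)` and
#' `pdot = -dH/dq = p - W0 F'(W0 q) p - p^2 g(q) g'(q)`.
#' The canonical sign of the momentum equation is what makes the energy a
#' constant of motion and the metastable state `Q+` a saddle of the full
#' `(q, p)` flow (with the opposite sign `Q+` would be a stable node and
#' the energy would drift).
#' On the deterministic line `p = 0` the flow reduces to the scalar neural
#' field dynamics and `pdot = 0`.
#'
#' @param sys A [reduced_system()].
#' @param q Activity coordinate (`q >= 0`).
#' @param p Conjugate momentum.
#' @return `reduced_rhs`: list with `qdot`, `pdot`; `reduced_hamiltonian`:
#'   numeric.
#' @export
reduced_rhs <- function(sys, q, p) {
  stopifnot(inherits(sys, "nf_reduced"))
  if (any(q < 0)) stop("q must be non-negative", call. = FALSE)
  Fq <- evaluate_rate(sys$rate, sys$W0 * q)
  Fp <- rate_prime(sys$rate, sys$W0 * q)
  g <- reduced_g(sys, q)
  # p^2 g g' = p^2 beta^2 s q^{2s-1}: finite at q = 0 for s >= 1/2
  gg <- ifelse(q == 0 & 2 * sys$s - 1 > 0, 0,
               sys$beta^2 * sys$s * q^(2 * sys$s - 1))
  # at q = 0 with s < 1/2 the factor g g' diverges but p vanishes there on
  # any admissible path; define p^2 g g' = 0 when p = 0
  p2gg <- ifelse(p == 0, 0, p^2 * gg)
  list(qdot = -q + Fq + p * g^2,
       pdot = p - sys$W0 * Fp * p - p2gg)
}

#' @rdname reduced_rhs
#' @export
reduced_hamiltonian <- function(sys, q, p) {
  Fq <- evaluate_rate(sys$rate, sys$W0 * q)
  p * (-q + Fq) + 0.5 * p^2 * reduced_g(sys, q)^2
}

#' Fixed points of the reduced phase plane
#'
#' `Q+ = (q0, 0)` with `q0 = F(W0 q0)` the metastable active state,
#' `Q- = (0, 0)` the deterministic zero state, and the fluctuational fixed
#' point `P = (0, p_e)` with
#' `p_e = -2 (W0 - 1) lim_{q -> 0} q / g^2(q)`:
#' `|p_e| = 2 (W0 - 1) / beta^2` for `s = 1/2`, `p_e = 0` for `s < 1/2`,
#' and no finite fluctuational fixed point for `s > 1/2` (an error).
#' The signed value is negative for `W0 > 1`; magnitudes are reported
#' alongside with the sign convention recorded.
#'
#' @param sys A [reduced_system()].
#' @return A tibble with columns `name`, `q`, `p`, `p_magnitude`.
#' @examples
#' reduced_fixed_points(reduced_system(firing_rate("tanh"), 1.2, beta = 1, s = 0.5))
#' @export
reduced_fixed_points <- function(sys) {
  stopifnot(inherits(sys, "nf_reduced"))
  if (sys$W0 <= 1)
    stop("W0 <= 1: no metastable active state", call. = FALSE)
  fp <- homogeneous_fixed_points(sys$rate, sys$W0)
  q0 <- max(fp$a_star)
  if (sys$s > 0.5)
    stop("s > 1/2: q / g^2(q) diverges as q -> 0, no finite fluctuational ",
         "fixed point", call. = FALSE)
  p_e <- if (sys$s == 0.5) -2 * (sys$W0 - 1) / sys$beta^2 else 0
  tibble::tibble(
    name = c("Q+", "Q-", "P"),
    q = c(q0, 0, 0),
    p = c(0, 0, p_e),
    p_magnitude = abs(c(0, 0, p_e))
  )
}

#' Nontrivial zero-energy branch
#'
#' Setting `H/L = 0` and dividing out the trivial root `p = 0` gives the
#' activation branch
#' `p(q) = 2 [q - F(W0 q)] / g^2(q)`, defined on `0 < q <= q0`; it vanishes
#' at `q0` and approaches the fluctuational momentum `p_e` as `q -> 0`.
#' The optimal (most probable) path to extinction runs along this branch.
#'
#' @param sys A [reduced_system()].
#' @param q Activity values in `(0, q0]`.
#' @return Signed momentum values `p(q)` (negative for `W0 > 1`).
#' @export
zero_energy_branch <- function(sys, q) {
  stopifnot(inherits(sys, "nf_reduced"))
  q0 <- max(homogeneous_fixed_points(sys$rate, sys$W0)$a_star)
  if (any(q <= 0 | q > q0 * (1 + 1e-12)))
    stop("q must lie in (0, q0]", call. = FALSE)
  Fq <- evaluate_rate(sys$rate, sys$W0 * q)
  2 * (q - Fq) / reduced_g(sys, q)^2
}

#' Action per unit length along the optimal extinction path
#'
#' Computes `S0 / L = |integral p dq|` along the nontrivial zero-energy
#' branch from the metastable state `Q+ = (q0, 0)` down to the absorbing
#' line, by two independent routes that must agree to `route_tol`:
#' adaptive quadrature of the branch formula in `q`, and time integration
#' of the Hamilton equations along the heteroclinic connection accumulating
#' `integral p qdot dt`. The path terminates at the fluctuational fixed
#' point `P = (0, p_e)` for `s = 1/2` and at the origin `Q-` for `s < 1/2`.
#'
#' @param sys A [reduced_system()] with `s <= 1/2`.
#' @param route_tol Required agreement between the two routes.
#' @return An object of class `"nf_extinction"`: `S0_over_L`, `path_type`,
#'   `S0_quadrature`, `S0_trajectory`, `quadrature_error`, `q0`, `p_e`,
#'   `sign_convention`.
#' @examples
#' action_along_optimal_path(reduced_system(firing_rate("tanh"), 1.2, 1, 0.5))
#' @export
action_along_optimal_path <- function(sys, route_tol = 1e-6) {
  stopifnot(inherits(sys, "nf_reduced"))
  if (sys$W0 <= 1) stop("W0 <= 1: no invasion barrier", call. = FALSE)
  if (sys$s > 0.5) stop("s > 1/2: no finite fluctuational fixed point",
                        call. = FALSE)
  fps <- reduced_fixed_points(sys)
  q0 <- fps$q[fps$name == "Q+"]
  p_e <- fps$p[fps$name == "P"]
  # route 1: adaptive quadrature of |p(q)| with the analytic q -> 0 limit
  integrand <- function(q) {
    v <- 2 * (evaluate_rate(sys$rate, sys$W0 * q) - q) / reduced_g(sys, q)^2
    # endpoint limit: 2 (W0 - 1) / beta^2 for s = 1/2, 0 for s < 1/2
    at0 <- if (sys$s == 0.5) 2 * (sys$W0 - 1) / sys$beta^2 else 0
    ifelse(q == 0, at0, v)
  }
  quad <- stats::integrate(integrand, 0, q0, rel.tol = 1e-12,
                           abs.tol = 1e-14, subdivisions = 500L)
  S_quad <- quad$value
  # route 2: Hamilton flow along the heteroclinic, started just off Q+
  delta <- 1e-8 * q0
  q_start <- q0 - delta
  rhs <- function(t, y, parms) {
    q <- max(y[1], 1e-300)
    p <- zero_energy_branch(sys, min(q, q0))
    d <- reduced_rhs(sys, q, p)
    list(c(d$qdot, p * d$qdot))
  }
  root_fn <- function(t, y, parms) y[1] - 1e-10 * q0
  sol <- deSolve::lsodar(c(q_start, 0), times = c(0, 1e4), func = rhs,
                         rootfunc = root_fn, rtol = 1e-11, atol = 1e-13)
  S_traj <- abs(sol[nrow(sol), 3])
  # endpoint corrections: [q0 - delta, q0] where |p| <= |p'(q0)| delta,
  # and the residual tail below the root cutoff bounded by |p_e| * cutoff
  tail_bound <- abs(p_e) * 1e-10 * q0 + 2 * delta^2 / reduced_g(sys, q0)^2
  if (abs(S_quad - S_traj) > route_tol + tail_bound)
    stop(sprintf(paste0("quadrature (%.10f) and trajectory (%.10f) routes ",
                        "disagree beyond %.1e"),
                 S_quad, S_traj, route_tol), call. = FALSE)
  structure(
    list(S0_over_L = S_quad,
         path_type = if (sys$s == 0.5) "Q+ -> P" else "Q+ -> Q-",
         S0_quadrature = S_quad, S0_trajectory = S_traj,
         quadrature_error = quad$abs.error,
         quadrature_subdivisions = quad$subdivisions,
         q0 = q0, p_e = p_e,
         sign_convention = "branch momentum p(q) < 0 for W0 > 1; S0/L reported as magnitude |integral p dq|"),
    class = "nf_extinction"
  )
}

#' @export
print.nf_extinction <- function(x, ...) {
  cat("<nf_extinction> S0/L =", format(x$S0_over_L, digits = 8),
      " path", x$path_type, "\n  routes: quadrature",
      format(x$S0_quadrature, digits = 10), "| trajectory",
      format(x$S0_trajectory, digits = 10), "\n")
  invisible(x)
}

#' @export
glance.nf_extinction <- function(x, ...) {
  tibble::tibble(S0_over_L = x$S0_over_L, path_type = x$path_type,
                 S0_quadrature = x$S0_quadrature,
                 S0_trajectory = x$S0_trajectory,
                 quadrature_error = x$quadrature_error,
                 q0 = x$q0, p_e = x$p_e)
}

#' Log extinction time in the weak-noise limit
#'
#' `ln tau_e = S0/L / epsilon^2`, up to pre-exponential factors.
#'
#' @param result An `nf_extinction` (or a number `S0/L`).
#' @param epsilon Noise strength (`> 0`).
#' @return `ln tau_e`.
#' @examples
#' extinction_time(0.15, 0.1) # 15
#' @export
extinction_time <- function(result, epsilon) {
  stopifnot(epsilon > 0)
  S <- if (inherits(result, "nf_extinction")) result$S0_over_L else result
  S / epsilon^2
}

#' Constant-energy contours of the reduced phase plane
#'
#' For each energy `E` and activity `q`, solves the quadratic
#' `g^2(q) p^2 / 2 + [F(W0 q) - q] p - E = 0` for the two momentum roots;
#' complex pairs are skipped. `E = 0` recovers the `p = 0` line and the
#' nontrivial activation branch exactly.
#'
#' @param sys A [reduced_system()].
#' @param E Energies.
#' @param q_range Range of `q` sampled.
#' @param n Number of `q` samples.
#' @return A tibble with columns `E`, `branch` (`"lower"`, `"upper"`),
#'   `q`, `p`.
#' @export
constant_energy_contours <- function(sys, E, q_range = NULL, n = 400) {
  stopifnot(inherits(sys, "nf_reduced"))
  if (is.null(q_range)) {
    q0 <- max(homogeneous_fixed_points(sys$rate, sys$W0)$a_star)
    q_range <- c(1e-4, 1.3 * q0)
  }
  qs <- seq(q_range[1], q_range[2], length.out = n)
  out <- purrr::map_dfr(E, function(e) {
    g2 <- reduced_g(sys, qs)^2
    b <- evaluate_rate(sys$rate, sys$W0 * qs) - qs
    disc <- b^2 + 2 * g2 * e
    ok <- disc >= 0
    sq <- sqrt(pmax(disc, 0))
    tibble::tibble(
      E = e,
      branch = rep(c("lower", "upper"), each = sum(ok)),
      q = rep(qs[ok], 2),
      p = c((-b[ok] - sq[ok]) / g2[ok], (-b[ok] + sq[ok]) / g2[ok])
    )
  })
  out
}

#' Phase portrait of the reduced extinction system
#'
#' Assembles fixed points, the zero-energy branches, and optional
#' constant-energy contours into one plottable object.
#'
#' @param sys A [reduced_system()].
#' @param E Additional energies to contour (default a small symmetric set).
#' @param n Samples per branch.
#' @return An object of class `"nf_portrait"` with tibbles `fixed_points`,
#'   `zero_energy`, `contours`.
#' @export
phase_portrait <- function(sys, E = c(-0.02, -0.005, 0.005, 0.02), n = 400) {
  fps <- reduced_fixed_points(sys)
  q0 <- fps$q[fps$name == "Q+"]
  qs <- seq(q0 * 1e-6, q0, length.out = n)
  zero <- dplyr::bind_rows(
    tibble::tibble(branch = "p = 0", q = seq(0, 1.3 * q0, length.out = n),
                   p = 0),
    tibble::tibble(branch = "q = 0", q = 0,
                   p = seq(min(fps$p) * 1.2, abs(min(fps$p)) * 0.2,
                           length.out = n)),
    tibble::tibble(branch = "activation", q = qs,
                   p = zero_energy_branch(sys, qs))
  )
  structure(
    list(fixed_points = fps, zero_energy = zero,
         contours = constant_energy_contours(sys, E, n = n), sys = sys),
    class = "nf_portrait"
  )
}

#' @export
autoplot.nf_portrait <- function(object, ...) {
  ggplot2::ggplot() +
    ggplot2::geom_path(data = object$contours,
                       ggplot2::aes(.data$q, .data$p,
                                    group = interaction(.data$E, .data$branch)),
                       colour = "grey60", linewidth = 0.3) +
    ggplot2::geom_path(data = object$zero_energy,
                       ggplot2::aes(.data$q, .data$p, group = .data$branch),
                       linewidth = 0.9) +
    ggplot2::geom_point(data = object$fixed_points,
                        ggplot2::aes(.data$q, .data$p), size = 2) +
    ggplot2::labs(x = "q", y = "p") +
    ggplot2::theme_minimal()
}
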