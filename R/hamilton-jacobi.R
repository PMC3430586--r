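#' Derivatives of the symmetrised kernel transform
#'
#' Analytic `W'(p)` and `W''(p)` for the Gaussian kernel,
#' `W(p) = W0 exp(p^2 sigma^2 / 2)`.
#'
#' @param kernel A [weight_kernel()].
#' @param p Momentum (decay rate).
#' @return Derivative values.
#' @export
kernel_transform_prime <- function(kernel, p) {
  if (!kernel$form %in% c("gaussian", "periodic_wrapped_gaussian"))
    stop("analytic transform derivatives require a Gaussian kernel",
         call. = FALSE)
  s2 <- kernel$sigma^2
  kernel$W0 * s2 * p * exp(p^2 * s2 / 2)
}

#' @rdname kernel_transform_prime
#' @export
kernel_transform_second <- function(kernel, p) {
  s2 <- kernel$sigma^2
  kernel$W0 * s2 * exp(p^2 * s2 / 2) * (1 + s2 * p^2)
}

# invert W'(lambda) = v for lambda > 0 (W' is increasing there)
invert_transform_prime <- function(kernel, v) {
  stopifnot(v > 0)
  f <- function(l) kernel_transform_prime(kernel, l) - v
  hi <- 1 / kernel$sigma
  while (f(hi) < 0) hi <- hi * 2
  stats::uniroot(f, c(1e-12, hi), tol = 1e-14)$root
}

#' Sharp-interface Hamiltonian for slowly modulated weights
#'
#' Under the hyperbolic rescaling the front becomes the zero level set of an
#' action `G(x, t)` obeying `dG/dt + H(dG/dx, x) = 0` with
#' `H(p, x) = -1 + W(p) J(x)`, where `W` is the symmetrised Laplace
#' transform of the kernel and `J` the slow synaptic modulation.
#'
#' @param p Conjugate momentum (leading-edge decay rate).
#' @param x Position.
#' @param kernel A [weight_kernel()].
#' @param J Modulation function of position (default homogeneous, `J = 1`).
#' @return Energy `H(p, x)`.
#' @examples
#' hj_hamiltonian(0, 0, weight_kernel(1.2, 1)) # W0 - 1 = 0.2
#' @export
hj_hamiltonian <- function(p, x, kernel, J = NULL) {
  Jx <- if (is.null(J)) 1 else J(x)
  -1 + kernel_transform(kernel, p) * Jx
}

#' Solve the Hamilton boundary-value problem by shooting
#'
#' Integrates the characteristic equations
#' `dX/ds = J(X) W'(P)`, `dP/ds = -J'(X) W(P)` with `X(0) = 0`, and
#' root-finds on the initial momentum `P(0)` so that `X(t) = x`. Since
#' `dX/ds` increases with `P` along positive momenta the boundary residual
#' is monotone in `P(0)` and the shooting root is unique; if several sign
#' changes are detected they are all reported rather than silently choosing
#' one.
#'
#' @param kernel A [weight_kernel()].
#' @param x Endpoint position `X(t) = x > 0`.
#' @param t Horizon (`t > 0`).
#' @param J,Jprime Modulation and its derivative (default homogeneous).
#'   `Jprime` is computed by central differences when omitted.
#' @param p_bracket Initial-momentum search interval (default
#'   `[0.1 lambda0, 10 lambda0]`).
#' @param n_save Number of saved path samples.
#' @param rtol,atol Integrator tolerances.
#' @return An object of class `"nf_hjpath"`: `path` (tibble `s, X, P`),
#'   `p0`, `E` (conserved energy), `energy_drift`,
#'   `action_integral` (`integral P dX`), `x`, `t`.
#' @export
solve_hamilton_bvp <- function(kernel, x, t, J = NULL, Jprime = NULL,
                               p_bracket = NULL, n_save = 201,
                               rtol = 1e-11, atol = 1e-12) {
  stopifnot(t > 0, x > 0)
  homogeneous <- is.null(J)
  if (homogeneous) {
    J <- function(z) rep(1, length(z))
    Jprime <- function(z) rep(0, length(z))
  } else if (is.null(Jprime)) {
    h <- 1e-6
    Jfun <- J
    Jprime <- function(z) (Jfun(z + h) - Jfun(z - h)) / (2 * h)
  }
  rhs <- function(s, y, parms) {
    X <- y[1]; P <- y[2]
    dX <- J(X) * kernel_transform_prime(kernel, P)
    dP <- -Jprime(X) * kernel_transform(kernel, P)
    list(c(dX, dP, P * dX))
  }
  shoot <- function(p0) {
    deSolve::ode(c(0, p0, 0), times = c(0, t), func = rhs, parms = NULL,
                 method = "ode45", rtol = rtol, atol = atol)[2, 2] - x
  }
  # X(t; p0) is increasing in p0 (dX/ds = J W'(P) and P moves with p0), so
  # bracket locally around the homogeneous solution W'(p) = x/t and expand
  # geometrically; a wide log-grid scan would probe momenta where W' is
  # astronomically large and the characteristics become needlessly stiff
  if (is.null(p_bracket)) {
    p_guess <- invert_transform_prime(kernel, x / t)
    p_bracket <- c(0.7 * p_guess, 1.4 * p_guess)
  }
  lo <- p_bracket[1]; hi <- p_bracket[2]
  r_lo <- shoot(lo); r_hi <- shoot(hi)
  n_expand <- 0L
  while (r_lo > 0 && n_expand < 60L) {
    hi <- lo; r_hi <- r_lo
    lo <- lo * 0.7
    r_lo <- shoot(lo)
    n_expand <- n_expand + 1L
  }
  while (r_hi < 0 && n_expand < 60L) {
    lo <- hi; r_lo <- r_hi
    hi <- hi * 1.4
    r_hi <- shoot(hi)
    n_expand <- n_expand + 1L
  }
  if (r_lo > 0 || r_hi < 0)
    stop(sprintf(paste0("shooting failed to bracket the endpoint: residuals ",
                        "%g and %g for p(0) in [%g, %g]"),
                 r_lo, r_hi, lo, hi), call. = FALSE)
  p0 <- stats::uniroot(shoot, c(lo, hi), f.lower = r_lo, f.upper = r_hi,
                       tol = 1e-13)$root
  sol <- deSolve::ode(c(0, p0, 0), times = seq(0, t, length.out = n_save),
                      func = rhs, parms = NULL, method = "ode45",
                      rtol = rtol, atol = atol)
  path <- tibble::tibble(s = sol[, 1], X = sol[, 2], P = sol[, 3])
  H <- -1 + kernel_transform(kernel, path$P) * J(path$X)
  E <- H[1]
  structure(
    list(path = path, p0 = p0, E = E,
         energy_drift = max(abs(H - E)),
         action_integral = unname(sol[nrow(sol), 4]),
         x = x, t = t),
    class = "nf_hjpath"
  )
}

#' @export
print.nf_hjpath <- function(x, ...) {
  cat("<nf_hjpath> x =", x$x, " t =", x$t, " p0 =", format(x$p0, digits = 8),
      " E =", format(x$E, digits = 8),
      " energy drift =", format(x$energy_drift, digits = 3), "\n")
  invisible(x)
}

#' @export
tidy.nf_hjpath <- function(x, ...) x$path

#' Action of the sharp-interface front
#'
#' `G(x, t) = -E(x, t) t + integral_0^t P dX`, computed from the shooting
#' solution of the Hamilton boundary-value problem. The front locus is
#' `G(x(t), t) = 0`; `G > 0` ahead of the front. In the homogeneous case
#' the closed form is `G = t - W(lambda) t + lambda x` with `lambda` solving
#' `W'(lambda) = x / t` (see [action_G_homogeneous()]).
#'
#' @inheritParams solve_hamilton_bvp
#' @return Action value `G(x, t)`.
#' @export
action_G <- function(kernel, x, t, J = NULL, Jprime = NULL, ...) {
  b <- solve_hamilton_bvp(kernel, x, t, J = J, Jprime = Jprime, ...)
  -b$E * t + b$action_integral
}

#' @rdname action_G
#' @export
action_G_homogeneous <- function(kernel, x, t) {
  lambda <- invert_transform_prime(kernel, x / t)
  t - kernel_transform(kernel, lambda) * t + lambda * x
}

#' First-order perturbative momentum under weak slow modulation
#'
#' For `J(x) = 1 + beta f(x)` with `beta << 1` the characteristic momentum
#' expands as `P(s) = lambda + beta p1(s) + O(beta^2)` with
#' `p1(s) = -W(lambda) (t/x) f(x s / t) + A1` and the constant `A1` fixed by
#' the endpoint conditions,
#' `A1 = (W(lambda) t / x^2 - 1 / (t W''(lambda))) integral_0^x f(y) dy`,
#' where `lambda` solves `W'(lambda) = x/t`.
#'
#' @param kernel A [weight_kernel()].
#' @param f Profile function of the modulation.
#' @param x,t Endpoint and horizon.
#' @param s Internal times at which to evaluate `p1`.
#' @return A list with `lambda` (zeroth order) and `p1` (values at `s`).
#' @export
first_order_momentum <- function(kernel, f, x, t, s) {
  lambda <- invert_transform_prime(kernel, x / t)
  W <- kernel_transform(kernel, lambda)
  Wpp <- kernel_transform_second(kernel, lambda)
  Fx <- stats::integrate(f, 0, x, rel.tol = 1e-12)$value
  A1 <- (W * t / x^2 - 1 / (t * Wpp)) * Fx
  list(lambda = lambda, p1 = -W * (t / x) * f(x * s / t) + A1)
}

#' Perturbed front position under weak slow modulation
#'
#' First-order prediction for the front location with modulation
#' `J = 1 + beta f`:
#' `x(t) = l + c0 t + beta W(lambda0) / (c0 lambda0) integral_0^{c0 t} f(y) dy`,
#' where `(lambda0, c0)` is the homogeneous minimal-speed pair. For the
#' linear profile `f(y) = y - l` this reduces exactly to the closed
#' quadratic of [front_position_parabola()].
#'
#' @param kernel A [weight_kernel()].
#' @param beta Modulation amplitude (`beta = 0` gives `l + c0 t`).
#' @param f Profile function.
#' @param t Time(s).
#' @param l Initial front position.
#' @return Predicted position(s).
#' @export
perturbed_front_position <- function(kernel, beta, f, t, l = 0) {
  disp <- minimal_speed(kernel)
  c0 <- disp$c0; l0 <- disp$lambda0
  W <- kernel_transform(kernel, l0)
  vapply(t, function(tt) {
    if (beta == 0 || tt == 0) return(l + c0 * tt)
    Fint <- stats::integrate(f, 0, c0 * tt, rel.tol = 1e-12)$value
    l + c0 * tt + beta * W / (c0 * l0) * Fint
  }, numeric(1))
}

#' Closed-form parabola for a linear heterogeneity
#'
#' For `J(x) = 1 + eps2 (x - l)` the perturbed front position is the
#' downward-opening-in-speed parabola
#' `x(t) = l + (c0 - eps2 l (c0 lambda0 + 1) / lambda0) t
#'          + eps2 c0 (c0 lambda0 + 1) / (2 lambda0) t^2`,
#' using `W(lambda0) = 1 + c0 lambda0`.
#'
#' @param kernel A [weight_kernel()].
#' @param eps2 Slope of the linear modulation.
#' @param t Time(s).
#' @param l Initial front position.
#' @return Predicted position(s).
#' @export
front_position_parabola <- function(kernel, eps2, t, l = 10) {
  disp <- minimal_speed(kernel)
  c0 <- disp$c0; l0 <- disp$lambda0
  l + (c0 - eps2 * l * (c0 * l0 + 1) / l0) * t +
    eps2 * c0 * (c0 * l0 + 1) / (2 * l0) * t^2
}

#' Instantaneous front speed under weak slow modulation
#'
#' `c(t) = c0 + beta W(lambda0) / lambda0 * f(eps_scale c0 t)`: the front
#' samples the modulation at its unperturbed location, with `eps_scale`
#' carrying the hyperbolic-rescaling bookkeeping (1 when `f` is expressed
#' in unscaled simulation coordinates).
#'
#' @inheritParams perturbed_front_position
#' @param eps_scale Rescaling factor inside the profile argument.
#' @return Speed(s) at `t`.
#' @export
instantaneous_speed <- function(kernel, beta, f, t, eps_scale = 1) {
  disp <- minimal_speed(kernel)
  c0 <- disp$c0; l0 <- disp$lambda0
  W <- kernel_transform(kernel, l0)
  c0 + beta * W / l0 * f(eps_scale * c0 * t)
}
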