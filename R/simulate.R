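#' Integrate the deterministic neural field
#'
#' Direct time stepping of
#' `tau da/dt = -a + F( integral w(x - x') J(x') a(x') dx' )`
#' on a [grid_1d()], with forward Euler (default, matching the reference
#' discretisation) or Heun's method. The trajectory is sampled at
#' `sample_times` (snapped to the step lattice).
#'
#' @param model An [model_spec()].
#' @param grid A [grid_1d()].
#' @param a0 Initial field (`a0 >= 0`), length `grid$N`, or a function of
#'   position.
#' @param T Final time.
#' @param dt Time step; must satisfy `dt <= 0.1 tau`.
#' @param sample_times Times at which to store the field (default ~50
#'   snapshots including 0 and T).
#' @param scheme `"euler"` or `"heun"`.
#' @param method Convolution path (see [convolve_weights()]).
#' @return An object of class `"nf_trajectory"`: `times`, `values`
#'   (time-by-node matrix), `grid`, `model`, `scheme`.
#' @examples
#' g <- grid_1d(-20, 20, 401)
#' m <- model_spec(weight_kernel(1.2, 1), firing_rate("piecewise_linear", kappa = 0.4))
#' traj <- simulate_field(m, g, front_initial_condition(g), T = 5, dt = 0.01)
#' @export
simulate_field <- function(model, grid, a0, T, dt,
                           sample_times = NULL,
                           scheme = c("euler", "heun"),
                           method = "banded") {
  scheme <- match.arg(scheme)
  stopifnot(inherits(model, "nf_model"), inherits(grid, "nf_grid"), T > 0)
  if (dt > 0.1 * model$tau + 1e-12)
    stop("dt must satisfy dt <= 0.1 * tau", call. = FALSE)
  if (grid$dx > model$kernel$sigma / 4)
    warning("grid spacing dx exceeds sigma/4; discretisation may be coarse",
            call. = FALSE)
  if (is.function(a0)) a0 <- a0(grid$x)
  stopifnot(length(a0) == grid$N)
  if (any(a0 < 0)) stop("initial field must be non-negative", call. = FALSE)
  if (is.null(sample_times))
    sample_times <- seq(0, T, length.out = min(51, round(T / dt) + 1))
  step_loop(model, grid, a0, T, dt, sample_times, scheme, method,
            noise = NULL)
}

# shared deterministic / stochastic stepping core; with noise = NULL the
# arithmetic is bitwise identical to the noiseless Langevin path
step_loop <- function(model, grid, a0, T, dt, sample_times, scheme, method,
                      noise) {
  n_steps <- round(T / dt)
  keep_idx <- unique(pmin(pmax(round(sample_times / dt), 0), n_steps))
  times <- keep_idx * dt
  values <- matrix(NA_real_, length(keep_idx), grid$N)
  a <- a0
  rate <- model$rate
  drive <- function(v) convolve_weights(v, model$kernel, grid, model$het,
                                        method = method)
  dirichlet <- grid$bc == "dirichlet_zero"
  if (dirichlet) a[c(1, grid$N)] <- 0
  stochastic <- !is.null(noise) && noise$epsilon > 0
  if (stochastic) {
    sq <- noise_step_factor(noise, grid, dt)
    n_clamped <- 0L
  }
  ki <- 1L
  for (i in 0:n_steps) {
    if (ki <= length(keep_idx) && i == keep_idx[ki]) {
      values[ki, ] <- a
      ki <- ki + 1L
    }
    if (i == n_steps) break
    f1 <- (-a + evaluate_rate(rate, drive(a))) / model$tau
    if (scheme == "euler") {
      a_new <- a + dt * f1
    } else {
      ap <- a + dt * f1
      f2 <- (-ap + evaluate_rate(rate, drive(ap))) / model$tau
      a_new <- a + dt * (f1 + f2) / 2
    }
    if (stochastic) {
      a_new <- a_new + noise$epsilon * noise_g(noise, a) * sq(grid$N)
      neg <- a_new < 0
      if (any(neg)) {
        n_clamped <- n_clamped + sum(neg)
        a_new[neg] <- 0
      }
    }
    if (dirichlet) a_new[c(1, grid$N)] <- 0
    if (any(!is.finite(a_new)) || max(a_new) > 1e6)
      stop(sprintf("field blow-up at step %d (t = %.4f): max |a| = %g",
                   i + 1, (i + 1) * dt, max(abs(a_new[is.finite(a_new)]), 0)),
           call. = FALSE)
    a <- a_new
  }
  out <- structure(
    list(times = times, values = values, grid = grid, model = model,
         scheme = scheme, dt = dt),
    class = "nf_trajectory"
  )
  if (stochastic) {
    out$noise <- noise
    out$n_clamped <- n_clamped
    out$clamp_fraction <- n_clamped / (n_steps * grid$N)
  }
  out
}

#' Sigmoidal front initial condition
#'
#' The steep sigmoid `a(x, 0) = 0.5 / (1 + exp(eta (x - l)))`: activity
#' approximately 0.5 for `x << l` decaying steeply to 0 for `x >> l`, so the
#' front invades rightward from `l`. (For leading-edge decay steeper than
#' the selected rate `lambda0` the invasion front is pulled at the minimal
#' speed.)
#'
#' @param grid A [grid_1d()] (or a numeric vector of positions).
#' @param l Initial front position.
#' @param eta Steepness.
#' @return Initial field values.
#' @export
front_initial_condition <- function(grid, l = 10, eta = 5) {
  x <- if (inherits(grid, "nf_grid")) grid$x else grid
  0.5 / (1 + exp(eta * (x - l)))
}

#' @export
print.nf_trajectory <- function(x, ...) {
  cat("<nf_trajectory>", length(x$times), "snapshots x", x$grid$N,
      "nodes, t in [", min(x$times), ",", max(x$times), "], scheme =",
      x$scheme, "\n")
  invisible(x)
}

#' @export
tidy.nf_trajectory <- function(x, ...) {
  tibble::tibble(
    t = rep(x$times, each = x$grid$N),
    x = rep(x$grid$x, length(x$times)),
    a = as.vector(t(x$values))
  )
}

#' @export
autoplot.nf_trajectory <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$a,
                                   group = .data$t, colour = .data$t)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "x", y = "a(x, t)", colour = "t") +
    ggplot2::theme_minimal()
}

#' Steady state of the neural field on a bounded domain
#'
#' Solves the fixed-point equation `a(x) = F( integral w(x - x') a(x') dx' )`
#' by damped fixed-point iteration started from the uniform nontrivial state.
#' On a periodic domain the solution is uniform, `a = a0` with
#' `a0 = F(W0 a0)`; with Dirichlet boundaries it is uniform in the bulk with
#' boundary layers at the edges.
#'
#' @param model An [model_spec()] (`W0 > 1` for a nontrivial state).
#' @param grid A [grid_1d()].
#' @param damping Iteration damping in (0, 1].
#' @param tol Sup-norm residual tolerance.
#' @param max_iter Iteration cap.
#' @return A list with `a` (the field), `residual`, `iterations`,
#'   `residual_history`.
#' @export
steady_state <- function(model, grid, damping = 0.5, tol = 1e-10,
                         max_iter = 10000) {
  stopifnot(inherits(model, "nf_model"), inherits(grid, "nf_grid"))
  fp <- homogeneous_fixed_points(model$rate, model$kernel$W0)
  a0 <- max(fp$a_star)
  if (a0 <= 0)
    stop("W0 <= 1: only the trivial steady state exists", call. = FALSE)
  a <- rep(a0, grid$N)
  dirichlet <- grid$bc == "dirichlet_zero"
  if (dirichlet) a[c(1, grid$N)] <- 0
  hist <- numeric(0)
  for (it in seq_len(max_iter)) {
    Fa <- evaluate_rate(model$rate,
                        convolve_weights(a, model$kernel, grid, model$het))
    if (dirichlet) Fa[c(1, grid$N)] <- 0
    res <- max(abs(Fa - a))
    hist <- c(hist, res)
    if (res < tol)
      return(list(a = a, residual = res, iterations = it,
                  residual_history = hist))
    a <- a + damping * (Fa - a)
  }
  stop(sprintf(paste0("steady state not converged in %d iterations ",
                      "(last residuals: %s)"),
               max_iter,
               paste(format(utils::tail(hist, 3), digits = 3), collapse = ", ")),
       call. = FALSE)
}
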