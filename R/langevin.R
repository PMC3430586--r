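#' Ito Langevin simulation of the stochastic neural field
#'
#' Euler-Maruyama integration of
#' `dA = [-A + F(w * A)] dt + epsilon g(A) dW(x, t)` with the Ito
#' interpretation. The zero-activity state is exactly invariant
#' (`g(0) = 0` and the update never creates activity from nothing);
#' negative excursions are clamped to zero to preserve the absorbing
#' property in discrete time, and the clamp count is recorded. With
#' `epsilon = 0` the trajectory is bitwise identical to
#' [simulate_field()] with the same stepping.
#'
#' @inheritParams simulate_field
#' @param noise An [noise_spec()].
#' @return An `nf_trajectory` with additional elements `noise`,
#'   `n_clamped`, `clamp_fraction`.
#' @export
simulate_langevin <- function(model, grid, noise, a0, T, dt,
                              sample_times = NULL, method = "banded") {
  stopifnot(inherits(model, "nf_model"), inherits(grid, "nf_grid"),
            inherits(noise, "nf_noise"))
  if (dt > 0.1 * model$tau + 1e-12)
    stop("dt must satisfy dt <= 0.1 * tau", call. = FALSE)
  if (is.function(a0)) a0 <- a0(grid$x)
  if (any(a0 < 0)) stop("initial field must be non-negative", call. = FALSE)
  if (model$rate$form == "sigmoid")
    stop("sigmoid rate has F(0) > 0: incompatible with an absorbing state",
         call. = FALSE)
  if (is.null(sample_times))
    sample_times <- seq(0, T, length.out = min(51, round(T / dt) + 1))
  step_loop(model, grid, a0, T, dt, sample_times, scheme = "euler",
            method = method, noise = noise)
}

#' Ensemble front-wandering statistics
#'
#' Runs `n_trials` independent Langevin simulations, tracks level-set front
#' positions `X_z(t)` for the given levels, averages first over levels and
#' then across trials, and fits a power law to the growth of the
#' across-trial variance of the level-averaged positions. Trials in which
#' the front is lost (no level crossed at some sample time: extinction or a
#' boundary hit) are excluded and counted.
#'
#' Per-trial seeds are derived from `seed` with the L'Ecuyer-CMRG stream
#' splitting scheme, so trials are reproducible and independent; the caller
#' RNG state is restored on exit.
#'
#' The variance exponent is fitted on `fit_window` (default: the last half
#' decade of time, `[T / sqrt(10), T]`, after discarding a transient of
#' `0.2 T`), and its confidence interval is obtained by bootstrap over
#' trials (resampling whole trials, which accounts for the strong temporal
#' correlation of the ensemble variance estimates).
#'
#' @inheritParams simulate_langevin
#' @param n_trials Number of trials (`>= 2`).
#' @param levels Level values `z` used for tracking.
#' @param seed Master seed.
#' @param sample_times Times at which positions are recorded.
#' @param fit_window Length-2 window for the power-law fit.
#' @param n_boot Bootstrap resamples for the exponent CI.
#' @return An object of class `"nf_ensemble"`: `stats` (tibble
#'   `t, mean, var, n_effective`), `exponent`, `exponent_stderr`,
#'   `exponent_ci`, `fit` (per [fit_power_law()]), `positions`
#'   (time-by-trial matrix), `n_excluded`, `clamp_fraction`,
#'   `noise_convention`.
#' @export
ensemble_front_statistics <- function(model, grid, noise, a0, T, dt,
                                      n_trials, levels, seed = 1,
                                      sample_times = NULL,
                                      fit_window = NULL, n_boot = 200,
                                      method = "banded") {
  stopifnot(n_trials >= 2, length(levels) >= 1)
  if (is.null(sample_times)) sample_times <- seq(T / 50, T, length.out = 50)
  sample_times <- sample_times[sample_times > 0]
  old_kind <- RNGkind()
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit({
    RNGkind(old_kind[1], old_kind[2], old_kind[3])
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  RNGkind("L'Ecuyer-CMRG")
  set.seed(seed)
  stream <- get(".Random.seed", globalenv())
  pos <- matrix(NA_real_, length(sample_times), n_trials)
  clamp_frac <- numeric(n_trials)
  for (k in seq_len(n_trials)) {
    stream <- parallel::nextRNGStream(stream)
    assign(".Random.seed", stream, globalenv())
    traj <- simulate_langevin(model, grid, noise, a0, T, dt,
                              sample_times = sample_times, method = method)
    ft <- track_front(traj, levels)
    pos[, k] <- ft$mean_position$X_mean[match(round(sample_times / dt),
                                              round(traj$times / dt))]
    clamp_frac[k] <- traj$clamp_fraction %||% 0
  }
  lost <- apply(pos, 2, function(p) any(is.na(p)))
  n_excluded <- sum(lost)
  if (n_trials - n_excluded < 2)
    stop("fewer than 2 trials retain a tracked front", call. = FALSE)
  keep <- pos[, !lost, drop = FALSE]
  stats_tbl <- tibble::tibble(
    t = sample_times,
    mean = rowMeans(keep),
    var = apply(keep, 1, stats::var),
    n_effective = ncol(keep)
  )
  if (is.null(fit_window))
    fit_window <- c(max(0.2 * T, T / sqrt(10)), T)
  in_win <- stats_tbl$t >= fit_window[1] & stats_tbl$t <= fit_window[2]
  if (all(stats_tbl$var[in_win] == 0)) {
    # deterministic ensemble: zero wandering, no exponent to fit
    return(structure(
      list(stats = stats_tbl, exponent = NA_real_,
           exponent_stderr = NA_real_, exponent_ci = c(NA_real_, NA_real_),
           fit = NULL, positions = keep, levels = levels,
           n_trials = n_trials, n_excluded = n_excluded,
           fit_window = fit_window, clamp_fraction = mean(clamp_frac),
           noise_convention = noise$convention, seed = seed),
      class = "nf_ensemble"
    ))
  }
  fit <- fit_power_law(stats_tbl$t, stats_tbl$var, fit_window)
  boot_exp <- function(m) {
    v <- apply(m, 1, stats::var)
    ok <- v > 0
    f <- tryCatch(fit_power_law(stats_tbl$t[ok], v[ok], fit_window),
                  error = function(e) NULL)
    if (is.null(f)) NA_real_ else f$exponent
  }
  bs <- vapply(seq_len(n_boot), function(i)
    boot_exp(keep[, sample.int(ncol(keep), replace = TRUE), drop = FALSE]),
    numeric(1))
  bs <- bs[is.finite(bs)]
  mean_clamp <- mean(clamp_frac)
  if (mean_clamp > 1e-3)
    warning(sprintf("clamping fraction %.2g exceeds 0.1%% of node-steps: discretisation may be too coarse",
                    mean_clamp), call. = FALSE)
  structure(
    list(stats = stats_tbl,
         exponent = fit$exponent,
         exponent_stderr = stats::sd(bs),
         exponent_ci = stats::quantile(bs, c(0.025, 0.975), names = FALSE),
         fit = fit,
         positions = keep,
         levels = levels,
         n_trials = n_trials, n_excluded = n_excluded,
         fit_window = fit_window,
         clamp_fraction = mean_clamp,
         noise_convention = noise$convention,
         seed = seed),
    class = "nf_ensemble"
  )
}

#' @export
print.nf_ensemble <- function(x, ...) {
  cat("<nf_ensemble>", ncol(x$positions), "trials (", x$n_excluded,
      "excluded ),", nrow(x$stats), "times\n")
  cat("  variance exponent =", format(x$exponent, digits = 4),
      " bootstrap 95% CI [", format(x$exponent_ci[1], digits = 3), ",",
      format(x$exponent_ci[2], digits = 3), "] on window [",
      x$fit_window[1], ",", x$fit_window[2], "]\n")
  invisible(x)
}

#' @export
tidy.nf_ensemble <- function(x, ...) x$stats

#' @export
glance.nf_ensemble <- function(x, ...) {
  tibble::tibble(exponent = x$exponent, stderr = x$exponent_stderr,
                 ci_lo = x$exponent_ci[1], ci_hi = x$exponent_ci[2],
                 r_squared = x$fit$r_squared,
                 n_trials = x$n_trials, n_excluded = x$n_excluded,
                 window_lo = x$fit_window[1], window_hi = x$fit_window[2],
                 clamp_fraction = x$clamp_fraction)
}

#' @export
autoplot.nf_ensemble <- function(object, ...) {
  df <- object$stats
  pred <- exp(object$fit$intercept + object$fit$exponent * log(df$t))
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$var)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = pred), linetype = 2) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "t", y = expression(sigma[X]^2 * (t)),
                  subtitle = sprintf("fitted exponent %.3f [%.2f, %.2f]",
                                     object$exponent, object$exponent_ci[1],
                                     object$exponent_ci[2])) +
    ggplot2::theme_minimal()
}

#' Power-law fit of variance growth
#'
#' Least-squares slope of `log(variance)` against `log(time)` on a window.
#'
#' @param times,variance Numeric vectors.
#' @param window Length-2 time window.
#' @return A list with `exponent`, `stderr`, `r_squared`, `intercept`,
#'   `window`, `n`.
#' @examples
#' fit_power_law(1:100, sqrt(1:100), c(10, 100))$exponent # 0.5
#' @export
fit_power_law <- function(times, variance, window) {
  stopifnot(length(times) == length(variance), length(window) == 2)
  sel <- times >= window[1] & times <= window[2]
  if (sum(sel) < 3)
    stop("fewer than 3 points in the fit window", call. = FALSE)
  if (any(variance[sel] <= 0))
    stop("nonpositive variance in the fit window", call. = FALSE)
  lt <- log(times[sel]); lv <- log(variance[sel])
  fit <- stats::lm(lv ~ lt)
  sm <- summary(fit)
  list(exponent = unname(stats::coef(fit)[2]),
       stderr = sm$coefficients[2, 2],
       r_squared = sm$r.squared,
       intercept = unname(stats::coef(fit)[1]),
       window = window, n = sum(sel))
}
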