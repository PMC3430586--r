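#' Reference experiment presets
#'
#' Bound experiment configurations reproducing the reference study setups:
#'
#' * `"fig2"`: dispersion curves and minimal speeds, Gaussian kernel,
#'   `W0 in {1.2, 1.5, 2, 2.5, 3}`, `sigma = 1`.
#' * `"fig3a"`/`"fig3b"`: Dirichlet steady states, `L = 5` / `L = 25`,
#'   `W0 = 1.2`, `kappa = 0.4`.
#' * `"fig4a"`/`"fig4b"`: pulsating fronts, `K(x) = cos(x/eps)` with
#'   `eps = 0.5` / `0.8`, `W0 = 1.2`, `kappa = 0.4`.
#' * `"fig5"`: homogeneous pulled front, domain `[-100, 100]`, `dx = 0.1`,
#'   `dt = 0.01`, sigmoidal initial front at `l = 10`.
#' * `"fig6"`/`"fig7"`: linear slow heterogeneity `1 + eps2 (x - l)` with
#'   `eps2 = 0.005` / `0.01` (the hyperbolic-rescaling bookkeeping puts the
#'   squared small parameter on the unscaled slope).
#' * `"fig8"`: stochastic wandering, `epsilon = 0.005`, `g(A) = A`,
#'   `kappa = 0.8`, at a reduced ensemble scale (96 trials, `T = 200`,
#'   `dx = 0.2`, `dt = 0.02`, levels in `(0.5 kappa, 0.95 kappa)`).
#' * `"fig9a"`/`"fig9b"`: extinction phase plane, tanh rate, `W0 = 1.2`,
#'   `g(q) = q^s` with `s = 1/2` / `1/4`.
#'
#' @param name Preset name.
#' @return An experiment config list (see [run_experiment()]).
#' @export
figure_preset <- function(name = c("fig2", "fig3a", "fig3b", "fig4a", "fig4b",
                                   "fig5", "fig6", "fig7", "fig8",
                                   "fig9a", "fig9b")) {
  name <- match.arg(name)
  pl_model <- function(kappa = 0.4, het = NULL) {
    m <- list(kernel = list(form = "gaussian", W0 = 1.2, sigma = 1),
              rate = list(form = "piecewise_linear", kappa = kappa),
              tau = 1)
    if (!is.null(het)) m$het <- het
    m
  }
  cfg <- switch(name,
    fig2 = list(kind = "dispersion",
                model = pl_model(),
                dispersion = list(W0_values = c(1.2, 1.5, 2, 2.5, 3))),
    fig3a = list(kind = "steady_state", model = pl_model(),
                 grid = list(x_lo = 0, x_hi = 5, dx = 0.05,
                             bc = "dirichlet_zero")),
    fig3b = list(kind = "steady_state", model = pl_model(),
                 grid = list(x_lo = 0, x_hi = 25, dx = 0.05,
                             bc = "dirichlet_zero")),
    fig4a = list(kind = "pulsating",
                 model = pl_model(het = list(kind = "periodic", eps = 0.5,
                                             coeffs = list(`1` = 0.5, `-1` = 0.5))),
                 hill = list(M = 16)),
    fig4b = list(kind = "pulsating",
                 model = pl_model(het = list(kind = "periodic", eps = 0.8,
                                             coeffs = list(`1` = 0.5, `-1` = 0.5))),
                 hill = list(M = 16)),
    fig5 = list(kind = "simulate", model = pl_model(),
                grid = list(x_lo = -100, x_hi = 100, dx = 0.1, bc = "free"),
                run = list(T = 50, dt = 0.01, l = 10, eta = 5),
                track = list(levels = 0.2, window = c(40, 50))),
    fig6 = list(kind = "hj", model = pl_model(
                  het = list(kind = "slow", beta = 0.005,
                             profile = list(type = "linear", offset = 10))),
                grid = list(x_lo = -100, x_hi = 100, dx = 0.1, bc = "free"),
                run = list(T = 40, dt = 0.01, l = 10, eta = 5),
                track = list(levels = 0.2)),
    fig7 = list(kind = "hj", model = pl_model(
                  het = list(kind = "slow", beta = 0.01,
                             profile = list(type = "linear", offset = 10))),
                grid = list(x_lo = -100, x_hi = 100, dx = 0.1, bc = "free"),
                run = list(T = 40, dt = 0.01, l = 10, eta = 5),
                track = list(levels = 0.2)),
    fig8 = list(kind = "wander", model = pl_model(kappa = 0.8),
                grid = list(x_lo = 0, x_hi = 250, dx = 0.2, bc = "free"),
                noise = list(epsilon = 0.005, g_form = "linear"),
                run = list(T = 200, dt = 0.02, l = 20, eta = 5,
                           trials = 96,
                           levels = list(frac_lo = 0.5, frac_hi = 0.95,
                                         n = 8))),
    fig9a = list(kind = "extinction",
                 extinction = list(rate = "tanh", W0 = 1.2, beta = 1,
                                   s = 0.5, epsilon = 0.1)),
    fig9b = list(kind = "extinction",
                 extinction = list(rate = "tanh", W0 = 1.2, beta = 1,
                                   s = 0.25, epsilon = 0.1))
  )
  cfg$preset <- name
  cfg
}

#' Read and validate an experiment config
#'
#' Configs are YAML (or JSON) with a top-level `kind` in
#' `{dispersion, simulate, steady_state, pulsating, hj, wander, extinction}`
#' and blocks as produced by [figure_preset()]. Unknown keys are rejected;
#' defaults (`tau = 1`, `dx = 0.1 sigma`) are filled in and echoed.
#'
#' @param path File path.
#' @return Validated config list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

#' @rdname load_config
#' @param config Config list.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}

validate_config <- function(cfg) {
  kinds <- c("dispersion", "simulate", "steady_state", "pulsating", "hj",
             "wander", "extinction")
  check_keys(cfg, c("kind", "preset", "model", "grid", "noise", "run",
                    "track", "hill", "dispersion", "extinction"), "experiment")
  if (is.null(cfg$kind) || !cfg$kind %in% kinds)
    stop("config `kind` must be one of: ", paste(kinds, collapse = ", "),
         call. = FALSE)
  if (!is.null(cfg$model)) {
    # fills defaults and checks keys/values
    m <- model_from_config(cfg$model)
    cfg$model$tau <- cfg$model$tau %||% 1
    if (!is.null(cfg$grid)) {
      check_keys(cfg$grid, c("x_lo", "x_hi", "dx", "N", "bc"), "grid")
      if (is.null(cfg$grid$dx) && is.null(cfg$grid$N))
        cfg$grid$dx <- 0.1 * m$kernel$sigma
    }
  }
  if (!is.null(cfg$noise))
    check_keys(cfg$noise, c("epsilon", "g_form", "gamma", "beta", "s",
                            "corr_len"), "noise")
  if (!is.null(cfg$run))
    check_keys(cfg$run, c("T", "dt", "l", "eta", "trials", "levels", "seed"),
               "run")
  cfg
}

config_grid <- function(gc) {
  if (!is.null(gc$N))
    grid_1d(gc$x_lo, gc$x_hi, gc$N, bc = gc$bc %||% "free")
  else {
    N <- round((gc$x_hi - gc$x_lo) / gc$dx) + 1
    grid_1d(gc$x_lo, gc$x_hi, N, bc = gc$bc %||% "free")
  }
}
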