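#' Firing-rate functions
#'
#' Constructs the nonlinear activation function `F` of the neural field.
#' Three forms are supported:
#'
#' * `"piecewise_linear"`: `F(a) = 0` for `a <= 0`, `a` for `0 < a <= kappa`,
#'   and `kappa` for `a > kappa`. The slope at `0+` is exactly 1, so the zero
#'   state is linearly unstable whenever the synaptic mass `W0 > 1`.
#' * `"tanh"`: `F(a) = tanh(a)`; smooth, with `F(0) = 0` and `F'(0) = 1`.
#' * `"sigmoid"`: `F(a) = height / (1 + exp(-gain (a - threshold)))`. Note
#'   that `F(0) > 0`, so this form is incompatible with an absorbing zero
#'   state; it is supported for fixed-point analysis only and rejected by the
#'   stochastic and extinction modules.
#'
#' @param form One of `"piecewise_linear"`, `"tanh"`, `"sigmoid"`.
#' @param kappa Activity ceiling (required for `"piecewise_linear"`; used as
#'   the default sigmoid threshold).
#' @param gain,threshold,height Sigmoid parameters; defaults give
#'   `2 / (1 + exp(-2 (a - kappa)))`.
#' @return An object of class `"nf_rate"`.
#' @examples
#' F <- firing_rate("piecewise_linear", kappa = 0.4)
#' evaluate_rate(F, c(-1, 0.2, 1)) # 0, 0.2, 0.4
#' @export
firing_rate <- function(form = c("piecewise_linear", "tanh", "sigmoid"),
                        kappa = NULL, gain = 2, threshold = NULL, height = 2) {
  form <- match.arg(form)
  if (form == "piecewise_linear") {
    if (is.null(kappa) || !is.finite(kappa) || kappa <= 0)
      stop("piecewise_linear rate requires a positive `kappa`", call. = FALSE)
  }
  if (form == "sigmoid") {
    if (is.null(threshold)) {
      if (is.null(kappa))
        stop("sigmoid rate requires `threshold` (or `kappa`)", call. = FALSE)
      threshold <- kappa
    }
  }
  structure(
    list(form = form, kappa = kappa, gain = gain,
         threshold = threshold, height = height),
    class = "nf_rate"
  )
}

#' Evaluate a firing-rate function
#'
#' @param rate An [firing_rate()] object.
#' @param a Activity values (finite numeric vector).
#' @return `F(a)`, vectorised over `a`.
#' @export
evaluate_rate <- function(rate, a) {
  stopifnot(inherits(rate, "nf_rate"))
  if (any(!is.finite(a))) stop("activity values must be finite", call. = FALSE)
  switch(rate$form,
    piecewise_linear = pmin(pmax(a, 0), rate$kappa),
    tanh = tanh(a),
    sigmoid = rate$height / (1 + exp(-rate$gain * (a - rate$threshold))),
    stop("unknown firing-rate form: ", rate$form, call. = FALSE)
  )
}

#' Derivative of a firing-rate function
#'
#' For the piecewise-linear form the derivative at the kinks `a = 0` and
#' `a = kappa` is taken from the right and left respectively (`side`
#' selects one-sided values at the kinks for stability classification).
#'
#' @param rate An [firing_rate()] object.
#' @param a Activity values.
#' @param side `"right"`, `"left"`, or `"both"` (kink convention).
#' @return `F'(a)`.
#' @export
rate_prime <- function(rate, a, side = c("right", "left")) {
  stopifnot(inherits(rate, "nf_rate"))
  side <- match.arg(side)
  switch(rate$form,
    piecewise_linear = {
      k <- rate$kappa
      if (side == "right") as.numeric(a >= 0 & a < k)
      else as.numeric(a > 0 & a <= k)
    },
    tanh = 1 / cosh(a)^2,
    sigmoid = {
      e <- exp(-rate$gain * (a - rate$threshold))
      rate$height * rate$gain * e / (1 + e)^2
    }
  )
}

#' @export
print.nf_rate <- function(x, ...) {
  cat("<nf_rate>", x$form)
  if (!is.null(x$kappa)) cat("  kappa =", x$kappa)
  if (x$form == "sigmoid")
    cat("  gain =", x$gain, " threshold =", x$threshold, " height =", x$height)
  cat("\n")
  invisible(x)
}

#' Homogeneous fixed points of the neural field
#'
#' Solves `a* = F(W0 a*)` by a dense sign-change scan followed by bisection,
#' and classifies stability from the sign of the derivative of the spatially
#' uniform dynamics `da/dt = -a + F(W0 a)`. At a kink of the piecewise-linear
#' rate one-sided derivatives are used, and `"marginal"` is reported when
#' they disagree. The zero state is classified by its right derivative (the
#' field is constrained to `a >= 0`).
#'
#' @param rate An [firing_rate()] object with `F(0) = 0`.
#' @param W0 Total synaptic mass (positive).
#' @param a_max Upper end of the root scan (default `max(2 kappa, 2)`).
#' @param n_scan Number of scan points.
#' @param tol Bisection tolerance.
#' @return A tibble with columns `a_star` and `stability`
#'   (`"stable"`, `"unstable"`, `"marginal"`).
#' @examples
#' homogeneous_fixed_points(firing_rate("piecewise_linear", kappa = 0.4), 1.2)
#' @export
homogeneous_fixed_points <- function(rate, W0, a_max = NULL, n_scan = 4096,
                                     tol = 1e-12) {
  stopifnot(inherits(rate, "nf_rate"), W0 > 0)
  if (is.null(a_max)) a_max <- max(2 * (rate$kappa %||% 1), 2)
  h <- function(a) -a + evaluate_rate(rate, W0 * a)
  grid <- seq(0, a_max, length.out = n_scan)
  hv <- h(grid)
  roots <- numeric(0)
  if (abs(hv[1]) < tol) roots <- c(roots, grid[1])
  sgn <- sign(hv)
  for (i in seq_len(n_scan - 1)) {
    if (sgn[i] == 0 && grid[i] > 0) {
      roots <- c(roots, grid[i])
    } else if (sgn[i] * sgn[i + 1] < 0) {
      r <- stats::uniroot(h, c(grid[i], grid[i + 1]), tol = tol)$root
      roots <- c(roots, r)
    }
  }
  roots <- sort(unique(round(roots / tol) * tol))
  # drop duplicates closer than scan resolution
  if (length(roots) > 1)
    roots <- roots[c(TRUE, diff(roots) > a_max / n_scan / 2)]
  classify <- function(a) {
    dr <- -1 + W0 * rate_prime(rate, W0 * a, side = "right")
    dl <- -1 + W0 * rate_prime(rate, W0 * a, side = "left")
    if (a == 0) return(if (dr > 0) "unstable" else if (dr < 0) "stable" else "marginal")
    if (sign(dr) != sign(dl)) return("marginal")
    if (dr > 0) "unstable" else if (dr < 0) "stable" else "marginal"
  }
  tibble::tibble(
    a_star = roots,
    stability = vapply(roots, classify, character(1))
  )
}
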