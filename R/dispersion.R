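#' Symmetrised Laplace transform of the weight kernel
#'
#' `W(lambda) = integral w(y) exp(-lambda y) dy`, which for an even kernel
#' equals the sum of the two one-sided Laplace transforms. For a Gaussian
#' kernel the closed form is `W0 exp(lambda^2 sigma^2 / 2)`, valid for any
#' finite (possibly complex) `lambda`. For other kernels a numerical
#' quadrature fallback is used (real `lambda` only) and the quadrature error
#' estimate is attached as an attribute.
#'
#' @param kernel A [weight_kernel()].
#' @param lambda Decay rate; numeric or complex.
#' @param quadrature Force the quadrature path (used for cross-checks).
#' @return `W(lambda)`; real and `>= W0` for real `lambda` (Gaussian).
#' @export
kernel_transform <- function(kernel, lambda, quadrature = FALSE) {
  stopifnot(inherits(kernel, "nf_kernel"))
  if (!quadrature && kernel$form %in% c("gaussian", "periodic_wrapped_gaussian")) {
    # wrapped form shares the transform of its Gaussian generator
    out <- kernel$W0 * exp(lambda^2 * kernel$sigma^2 / 2)
    if (is.complex(lambda) && all(Im(lambda) == 0)) out <- Re(out)
    return(out)
  }
  if (is.complex(lambda))
    stop("quadrature transform supports real lambda only", call. = FALSE)
  vapply(lambda, function(l) {
    q <- stats::integrate(function(y) kernel_value(kernel, y) * exp(-l * y),
                          -12 * kernel$sigma, 12 * kernel$sigma,
                          rel.tol = 1e-12, abs.tol = 1e-14,
                          subdivisions = 400L)
    structure(q$value, abs_error = q$abs.error)
    q$value
  }, numeric(1))
}

#' Linear-spreading dispersion relation
#'
#' The speed of an exponential leading edge `exp(-lambda xi)`:
#' `c(lambda) = (W(lambda) - 1) / lambda`. For `W0 > 1` this is a positive
#' unimodal function of `lambda > 0`, diverging at both ends; its minimum is
#' the pulled-front speed.
#'
#' @param kernel A [weight_kernel()].
#' @param lambda Positive decay rate(s).
#' @return Speeds `c(lambda)`.
#' @examples
#' dispersion_speed(weight_kernel(1.2, 1), 1) # (1.2 exp(0.5) - 1) / 1
#' @export
dispersion_speed <- function(kernel, lambda) {
  if (any(lambda <= 0)) stop("lambda must be positive", call. = FALSE)
  (kernel_transform(kernel, lambda) - 1) / lambda
}

#' Minimal pulled-front speed
#'
#' Minimises the dispersion relation `c(lambda)` over `lambda > 0`. A coarse
#' logarithmic grid scan guards against spurious local minima before Brent
#' minimisation to `tol`. The result records consistency residuals of the
#' implicit minimiser condition
#' `lambda0^2 = (W0 - exp(-lambda0^2 sigma^2 / 2)) / (sigma^2 W0)` and of the
#' quadratic relation
#' `lambda0 = (-1/c0 + sqrt(1/c0^2 + 4/sigma^2)) / 2`.
#'
#' @param kernel A [weight_kernel()] with `W0 > 1`.
#' @param bracket Search interval for `lambda` (default
#'   `c(1e-3, 10/sigma)`).
#' @param n_curve Number of curve samples returned.
#' @param tol Minimisation tolerance.
#' @return An object of class `"nf_dispersion"` with elements `lambda0`,
#'   `c0`, `curve` (tibble of `(lambda, c)`), and `diagnostics`.
#' @examples
#' minimal_speed(weight_kernel(1.2, 1))
#' @export
minimal_speed <- function(kernel, bracket = NULL, n_curve = 200, tol = 1e-10) {
  stopifnot(inherits(kernel, "nf_kernel"))
  if (kernel$W0 <= 1)
    stop("W0 <= 1: zero state is not invaded, no positive minimal speed",
         call. = FALSE)
  if (is.null(bracket)) bracket <- c(1e-3, 10 / kernel$sigma)
  cfun <- function(l) dispersion_speed(kernel, l)
  lg <- exp(seq(log(bracket[1]), log(bracket[2]), length.out = 200))
  cg <- cfun(lg)
  i0 <- which.min(cg)
  lo <- lg[max(1, i0 - 1)]; hi <- lg[min(length(lg), i0 + 1)]
  opt <- stats::optimize(cfun, c(lo, hi), tol = tol)
  lambda0 <- opt$minimum
  c0 <- opt$objective
  # polish the minimiser on the stationarity condition
  # lambda W'(lambda) - W(lambda) + 1 = 0 (exact derivative of the Gaussian
  # transform), since a bracketed minimiser alone is only sqrt(eps)-accurate
  polish <- tryCatch({
    gfun <- function(l) l * kernel_transform_prime(kernel, l) -
      kernel_transform(kernel, l) + 1
    wlo <- lambda0 * 0.9; whi <- lambda0 * 1.1
    while (gfun(wlo) > 0) wlo <- wlo * 0.9
    while (gfun(whi) < 0) whi <- whi * 1.1
    stats::uniroot(gfun, c(wlo, whi), tol = 1e-15)$root
  }, error = function(e) NULL)
  if (!is.null(polish)) {
    lambda0 <- polish
    c0 <- cfun(lambda0)
  }
  s2 <- kernel$sigma^2
  res13 <- lambda0^2 - (kernel$W0 - exp(-lambda0^2 * s2 / 2)) / (s2 * kernel$W0)
  res15 <- lambda0 - 0.5 * (-1 / c0 + sqrt(1 / c0^2 + 4 / s2))
  curve <- tibble::tibble(
    lambda = exp(seq(log(bracket[1]), log(bracket[2]), length.out = n_curve))
  )
  curve$c <- cfun(curve$lambda)
  structure(
    list(lambda0 = lambda0, c0 = c0, curve = curve,
         kernel = kernel,
         diagnostics = list(bracket = c(lo, hi),
                            minimizer_residual = res13,
                            quadratic_residual = res15)),
    class = "nf_dispersion"
  )
}

#' @export
print.nf_dispersion <- function(x, ...) {
  cat("<nf_dispersion> lambda0 =", format(x$lambda0, digits = 8),
      " c0 =", format(x$c0, digits = 8), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.nf_dispersion <- function(x, ...) x$curve

#' @export
glance.nf_dispersion <- function(x, ...) {
  tibble::tibble(
    lambda0 = x$lambda0, c0 = x$c0,
    W0 = x$kernel$W0, sigma = x$kernel$sigma,
    minimizer_residual = x$diagnostics$minimizer_residual,
    quadratic_residual = x$diagnostics$quadratic_residual
  )
}

#' @export
autoplot.nf_dispersion <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$lambda, .data$c)) +
    ggplot2::geom_line() +
    ggplot2::annotate("point", x = object$lambda0, y = object$c0) +
    ggplot2::labs(x = expression(lambda), y = expression(c(lambda)),
                  subtitle = sprintf("minimum c0 = %.4f at lambda0 = %.4f",
                                     object$c0, object$lambda0)) +
    ggplot2::theme_minimal()
}
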