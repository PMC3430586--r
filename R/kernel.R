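#' Synaptic weight kernels
#'
#' A Gaussian footprint `w(x) = W0 / sqrt(2 pi sigma^2) exp(-x^2 / 2 sigma^2)`
#' with total mass `W0 = integral of w`, or its periodic wrapping
#' `w(x) = sum_n w0(x + n L)` on a domain of period `L`.
#'
#' @param W0 Total synaptic mass, `W0 > 0`. Invasion of the zero state
#'   requires `W0 > 1`.
#' @param sigma Spatial range of the kernel, `sigma > 0`.
#' @param form `"gaussian"` or `"periodic_wrapped_gaussian"`.
#' @param period Domain period `L` (required for the wrapped form).
#' @return An object of class `"nf_kernel"`.
#' @examples
#' w <- weight_kernel(W0 = 1.2, sigma = 1)
#' kernel_value(w, 0) # 1.2 / sqrt(2*pi)
#' @export
weight_kernel <- function(W0, sigma = 1,
                          form = c("gaussian", "periodic_wrapped_gaussian"),
                          period = NULL) {
  form <- match.arg(form)
  stopifnot(is.finite(W0), W0 > 0, is.finite(sigma), sigma > 0)
  if (form == "periodic_wrapped_gaussian" &&
      (is.null(period) || period <= 0))
    stop("wrapped kernel requires a positive `period`", call. = FALSE)
  structure(list(W0 = W0, sigma = sigma, form = form, period = period),
            class = "nf_kernel")
}

#' Evaluate a weight kernel
#'
#' @param kernel A [weight_kernel()] object.
#' @param x Displacements.
#' @param n_wrap Number of image terms on each side for the wrapped form
#'   (the Gaussian tail beyond `n_wrap` periods is negligible for
#'   `n_wrap * period > 10 sigma`).
#' @return Weight density `w(x)`, vectorised.
#' @export
kernel_value <- function(kernel, x, n_wrap = NULL) {
  stopifnot(inherits(kernel, "nf_kernel"))
  g <- function(y) kernel$W0 / sqrt(2 * pi * kernel$sigma^2) *
    exp(-y^2 / (2 * kernel$sigma^2))
  if (kernel$form == "gaussian") return(g(x))
  L <- kernel$period
  if (is.null(n_wrap)) n_wrap <- ceiling(10 * kernel$sigma / L) + 1
  s <- g(x)
  for (n in seq_len(n_wrap)) s <- s + g(x + n * L) + g(x - n * L)
  s
}

#' @export
print.nf_kernel <- function(x, ...) {
  cat("<nf_kernel>", x$form, " W0 =", x$W0, " sigma =", x$sigma)
  if (!is.null(x$period)) cat(" period =", x$period)
  cat("\n")
  invisible(x)
}
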