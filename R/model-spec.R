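#' Neural field model specification
#'
#' Bundles the synaptic kernel, firing rate, heterogeneity and time constant
#' of the activity equation
#' `tau da/dt = -a + F( integral w(x - x') J(x') a(x') dx' )`.
#' This object is the single source of model truth consumed by the
#' simulation, dispersion and extinction modules.
#'
#' @param kernel A [weight_kernel()].
#' @param rate A [firing_rate()].
#' @param het An `nf_het` heterogeneity (default [het_none()]).
#' @param tau Time constant, `tau > 0` (default 1).
#' @return An object of class `"nf_model"`.
#' @examples
#' model_spec(weight_kernel(1.2, 1), firing_rate("piecewise_linear", kappa = 0.4))
#' @export
model_spec <- function(kernel, rate, het = het_none(), tau = 1) {
  stopifnot(inherits(kernel, "nf_kernel"), inherits(rate, "nf_rate"),
            inherits(het, "nf_het"), is.finite(tau), tau > 0)
  structure(list(kernel = kernel, rate = rate, het = het, tau = tau),
            class = "nf_model")
}

#' @export
print.nf_model <- function(x, ...) {
  cat("<nf_model> tau =", x$tau, "\n  ")
  print(x$kernel)
  cat("  ")
  print(x$rate)
  cat("  ")
  print(x$het)
  invisible(x)
}

#' Serialise a model specification to a plain config list
#'
#' The returned list maps one-to-one onto the YAML/JSON config block
#' (`kernel{form, W0, sigma}, rate{form, kappa, ...}, het{kind, ...}, tau`)
#' and round-trips exactly through [model_from_config()]. Slow
#' heterogeneities are serialisable when built from a linear profile
#' (`profile: linear` with an `offset`, meaning `f(x) = x - offset`) or a
#' table; arbitrary profile functions cannot be echoed and raise an error.
#'
#' @param model An `nf_model`.
#' @return A named list.
#' @export
model_to_config <- function(model) {
  stopifnot(inherits(model, "nf_model"))
  k <- model$kernel
  kernel <- list(form = k$form, W0 = k$W0, sigma = k$sigma)
  if (!is.null(k$period)) kernel$period <- k$period
  r <- model$rate
  rate <- switch(r$form,
    piecewise_linear = list(form = r$form, kappa = r$kappa),
    tanh = list(form = r$form),
    sigmoid = list(form = r$form, gain = r$gain, threshold = r$threshold,
                   height = r$height)
  )
  h <- model$het
  het <- switch(h$kind,
    none = list(kind = "none"),
    slow = {
      if (!is.null(h$f_table)) {
        list(kind = "slow", beta = h$beta,
             profile = list(type = "table",
                            x = h$f_table$x, f = h$f_table$f))
      } else if (!is.null(attr(h, "linear_offset"))) {
        list(kind = "slow", beta = h$beta,
             profile = list(type = "linear",
                            offset = attr(h, "linear_offset")))
      } else {
        stop("slow heterogeneity with an arbitrary profile function cannot ",
             "be serialised; use a linear or tabulated profile", call. = FALSE)
      }
    },
    periodic = list(kind = "periodic", eps = h$eps,
                    coeffs = as.list(stats::setNames(Re(h$coeffs),
                                                     names(h$coeffs))))
  )
  list(kernel = kernel, rate = rate, het = het, tau = model$tau)
}

#' Build a model specification from a config list
#'
#' Inverse of [model_to_config()]; unknown keys are rejected.
#'
#' @param config A named list with blocks `kernel`, `rate`, `het` (optional)
#'   and `tau` (optional, default 1).
#' @return An `nf_model`.
#' @export
model_from_config <- function(config) {
  check_keys(config, c("kernel", "rate", "het", "tau"), "model")
  kc <- config$kernel
  check_keys(kc, c("form", "W0", "sigma", "period"), "kernel")
  kernel <- weight_kernel(W0 = kc$W0, sigma = kc$sigma %||% 1,
                          form = kc$form %||% "gaussian", period = kc$period)
  rc <- config$rate
  check_keys(rc, c("form", "kappa", "gain", "threshold", "height"), "rate")
  rate <- firing_rate(form = rc$form, kappa = rc$kappa,
                      gain = rc$gain %||% 2, threshold = rc$threshold,
                      height = rc$height %||% 2)
  hc <- config$het %||% list(kind = "none")
  check_keys(hc, c("kind", "beta", "profile", "eps", "coeffs"), "het")
  het <- switch(hc$kind %||% "none",
    none = het_none(),
    slow = {
      pr <- hc$profile
      check_keys(pr, c("type", "offset", "x", "f"), "het$profile")
      if (identical(pr$type, "linear")) {
        het_slow_linear(hc$beta, offset = pr$offset)
      } else if (identical(pr$type, "table")) {
        het_slow(hc$beta, data.frame(x = unlist(pr$x), f = unlist(pr$f)))
      } else stop("unknown slow profile type: ", pr$type, call. = FALSE)
    },
    periodic = het_periodic(hc$eps, unlist(hc$coeffs)),
    stop("unknown heterogeneity kind: ", hc$kind, call. = FALSE)
  )
  model_spec(kernel, rate, het, tau = config$tau %||% 1)
}

#' Slow linear heterogeneity `J(x) = 1 + beta (x - offset)`
#'
#' Convenience constructor for the linear profile `f(x) = x - offset`; this
#' form is serialisable through [model_to_config()].
#'
#' @param beta Amplitude.
#' @param offset Position at which the modulation crosses 1.
#' @return An `nf_het`.
#' @export
het_slow_linear <- function(beta, offset = 0) {
  h <- het_slow(beta, f = function(x) x - offset)
  attr(h, "linear_offset") <- offset
  h
}

check_keys <- function(block, allowed, where) {
  if (is.null(block)) return(invisible(NULL))
  bad <- setdiff(names(block), allowed)
  if (length(bad))
    stop("unknown key(s) in ", where, " config: ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(NULL)
}
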