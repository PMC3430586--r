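#' Synaptic heterogeneities
#'
#' Spatial modulation of the synaptic weights. Two kinds:
#'
#' * `het_slow(beta, f)`: a slow, non-periodic modulation
#'   `J(x) = 1 + beta f(x)`, with `f` a function or a two-column table
#'   (`x`, `f`) that is interpolated linearly and extended flat beyond its
#'   range (with a warning).
#' * `het_periodic(eps, coeffs)`: a periodic modulation `1 + K(x / eps)`
#'   of period `2 pi eps`, with `K(u) = sum_l K_l exp(i l u)` given by its
#'   Fourier coefficients. Coefficients are supplied as a (possibly complex)
#'   vector named by integer mode index `l`; reality of the modulation
#'   requires `K_{-l} = Conj(K_l)` (missing negative modes are filled in by
#'   conjugation).
#'
#' `het_none()` is the homogeneous case `J(x) = 1`.
#'
#' @param beta Amplitude of the slow modulation.
#' @param f Profile: a function of position, or a data frame with columns
#'   `x` and `f`.
#' @param eps Period parameter (period `2 pi eps`).
#' @param coeffs Named vector of Fourier coefficients, names are mode
#'   indices, e.g. `c("1" = 0.5, "-1" = 0.5)` for `K(u) = cos(u)`.
#' @return An object of class `"nf_het"`.
#' @name heterogeneity
NULL

#' @rdname heterogeneity
#' @export
het_none <- function() {
  structure(list(kind = "none"), class = "nf_het")
}

#' @rdname heterogeneity
#' @export
het_slow <- function(beta, f) {
  if (is.data.frame(f)) {
    stopifnot(all(c("x", "f") %in% names(f)))
    tab <- f[order(f$x), ]
    fn <- function(x) {
      if (any(x < min(tab$x) | x > max(tab$x)))
        warning("slow-heterogeneity profile extended flat outside its table",
                call. = FALSE)
      stats::approx(tab$x, tab$f, xout = x, rule = 2)$y
    }
  } else {
    stopifnot(is.function(f))
    fn <- f
  }
  structure(list(kind = "slow", beta = beta, f = fn, f_table = if (is.data.frame(f)) f),
            class = "nf_het")
}

#' @rdname heterogeneity
#' @export
het_periodic <- function(eps, coeffs) {
  stopifnot(eps > 0, length(coeffs) > 0, !is.null(names(coeffs)))
  l <- as.integer(names(coeffs))
  if (any(is.na(l))) stop("coefficient names must be integer mode indices",
                          call. = FALSE)
  cf <- as.complex(coeffs)
  names(cf) <- names(coeffs)
  # fill missing conjugate modes; check consistency of those present
  for (i in seq_along(l)) {
    nm <- as.character(-l[i])
    if (!nm %in% names(cf)) {
      cf[nm] <- Conj(cf[i])
    } else if (Mod(cf[nm] - Conj(cf[i])) > 1e-12) {
      stop("K_{-l} must equal Conj(K_l) for a real modulation", call. = FALSE)
    }
  }
  h <- structure(list(kind = "periodic", eps = eps, coeffs = cf),
                 class = "nf_het")
  # positivity of 1 + K(u)
  u <- seq(0, 2 * pi, length.out = 512)
  if (min(1 + het_periodic_K(h, u)) <= 0)
    warning("periodic modulation 1 + K(x/eps) is not positive everywhere",
            call. = FALSE)
  h
}

het_periodic_K <- function(het, u) {
  l <- as.integer(names(het$coeffs))
  v <- rep(0 + 0i, length(u))
  for (i in seq_along(l)) v <- v + het$coeffs[i] * exp(1i * l[i] * u)
  Re(v)
}

#' Evaluate the synaptic modulation factor
#'
#' Returns the multiplicative factor applied to the weights at source
#' position `x`: 1 for no heterogeneity, `1 + beta f(x)` for a slow
#' modulation, `1 + K(x / eps)` for a periodic one.
#'
#' @param het An `nf_het` object.
#' @param x Positions.
#' @return Numeric vector of modulation factors.
#' @export
modulation <- function(het, x) {
  stopifnot(inherits(het, "nf_het"))
  switch(het$kind,
    none = rep(1, length(x)),
    slow = 1 + het$beta * het$f(x),
    periodic = 1 + het_periodic_K(het, x / het$eps)
  )
}

#' @export
print.nf_het <- function(x, ...) {
  cat("<nf_het>", x$kind)
  if (x$kind == "slow") cat("  beta =", x$beta)
  if (x$kind == "periodic")
    cat("  eps =", x$eps, " modes:", paste(names(x$coeffs), collapse = ","))
  cat("\n")
  invisible(x)
}
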