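#' Hill-matrix problem for pulsating fronts
#'
#' In a medium with a `2 pi eps`-periodic weight modulation `1 + K(x/eps)`
#' the leading edge of a pulsating front satisfies a nonlocal Hill equation.
#' Expanding the periodic amplitude in Fourier modes truncated at `|m| <= M`
#' gives the matrix eigenproblem
#' `(1 + c lambda) P_m = W(lambda - i m / eps) [ P_m + sum_l K_l P_{m-l} ]`.
#'
#' @param kernel A [weight_kernel()].
#' @param eps Modulation period parameter (period `2 pi eps`).
#' @param coeffs Fourier coefficients of `K`, named by integer mode index
#'   (e.g. `c("1" = 0.5, "-1" = 0.5)` for `K(u) = cos u`). Missing negative
#'   modes are filled in by conjugation.
#' @param M Truncation: largest retained `|mode index|`, `M >= 1`.
#' @return An object of class `"nf_hill"`.
#' @export
hill_problem <- function(kernel, eps, coeffs, M = 16) {
  stopifnot(inherits(kernel, "nf_kernel"), eps > 0, M >= 1)
  het <- het_periodic(eps, coeffs) # validates K_{-l} = Conj(K_l)
  structure(list(kernel = kernel, eps = eps, coeffs = het$coeffs, M = as.integer(M)),
            class = "nf_hill")
}

hill_matrix <- function(problem, lambda) {
  M <- problem$M
  m <- -M:M
  Wm <- kernel_transform(problem$kernel,
                         as.complex(lambda) - 1i * m / problem$eps)
  n <- 2 * M + 1
  A <- matrix(0 + 0i, n, n)
  l_idx <- as.integer(names(problem$coeffs))
  for (i in seq_len(n)) {
    A[i, i] <- Wm[i]
    for (j in seq_len(n)) {
      d <- m[i] - m[j]
      hit <- which(l_idx == d)
      if (length(hit)) A[i, j] <- A[i, j] + Wm[i] * problem$coeffs[hit]
    }
  }
  A
}

#' Pulsating-front dispersion relation
#'
#' Builds the truncated Hill matrix at decay rate `lambda` and returns the
#' mean front speed `c = (mu - 1) / lambda`, where `mu` is the eigenvalue of
#' largest real part (the branch that connects continuously to the
#' homogeneous transform `W(lambda)` as the modulation amplitude vanishes).
#' An error is raised if the leading eigenvalue has a relative imaginary
#' part above `1e-8`, or if two distinct eigenvalues tie for largest real
#' part within tolerance (selection ambiguity), in which case both values
#' are reported.
#'
#' @param problem A [hill_problem()].
#' @param lambda Positive decay rate.
#' @return Mean speed `c(lambda)`.
#' @export
pulsating_dispersion <- function(problem, lambda) {
  stopifnot(inherits(problem, "nf_hill"))
  if (lambda <= 0) stop("lambda must be positive", call. = FALSE)
  ev <- eigen(hill_matrix(problem, lambda), only.values = TRUE)$values
  ord <- order(Re(ev), decreasing = TRUE)
  mu <- ev[ord[1]]
  if (length(ev) > 1) {
    mu2 <- ev[ord[2]]
    if (abs(Re(mu) - Re(mu2)) < 1e-10 * max(1, abs(mu)) &&
        Mod(mu - mu2) > 1e-8 * max(1, abs(mu)))
      stop(sprintf(paste0("ambiguous eigenvalue selection: ",
                          "%s and %s tie for largest real part"),
                   format(mu), format(mu2)), call. = FALSE)
  }
  if (abs(Im(mu)) > 1e-8 * abs(mu))
    stop("leading Hill eigenvalue has non-negligible imaginary part: ",
         format(mu), call. = FALSE)
  (Re(mu) - 1) / lambda
}

#' Minimal mean speed of a pulsating front
#'
#' Minimises the Hill-matrix dispersion over `lambda` and verifies
#' truncation convergence by recomputing at double the truncation: the
#' result is accepted when `|c0(M) - c0(2M)| < tol_M`.
#'
#' @param problem A [hill_problem()].
#' @param bracket `lambda` search interval (default `c(1e-3, 10/sigma)`).
#' @param tol Minimisation tolerance.
#' @param tol_M Truncation-convergence tolerance.
#' @return A list with `lambda0`, `c0`, and a `convergence` report
#'   (`c0_M`, `c0_2M`, `delta`, truncations used).
#' @export
pulsating_minimal_speed <- function(problem, bracket = NULL, tol = 1e-10,
                                    tol_M = 1e-6) {
  stopifnot(inherits(problem, "nf_hill"))
  if (is.null(bracket)) bracket <- c(1e-3, 10 / problem$kernel$sigma)
  minimise <- function(pb) {
    lg <- exp(seq(log(bracket[1]), log(bracket[2]), length.out = 60))
    cg <- vapply(lg, function(l) pulsating_dispersion(pb, l), numeric(1))
    i0 <- which.min(cg)
    stats::optimize(function(l) pulsating_dispersion(pb, l),
                    c(lg[max(1, i0 - 1)], lg[min(length(lg), i0 + 1)]),
                    tol = tol)
  }
  o1 <- minimise(problem)
  p2 <- problem; p2$M <- 2L * problem$M
  o2 <- minimise(p2)
  delta <- abs(o1$objective - o2$objective)
  if (delta >= tol_M)
    stop(sprintf(paste0("pulsating minimal speed not converged in truncation: ",
                        "c0(M=%d) = %.10f, c0(M=%d) = %.10f, delta = %.3g"),
                 problem$M, o1$objective, p2$M, o2$objective, delta),
         call. = FALSE)
  list(lambda0 = o2$minimum, c0 = o2$objective,
       convergence = list(M = problem$M, c0_M = o1$objective,
                          M2 = p2$M, c0_2M = o2$objective, delta = delta))
}
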