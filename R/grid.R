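#' One-dimensional simulation grid
#'
#' Uniform grid on `[x_lo, x_hi]` with `N` nodes. For non-periodic boundary
#' conditions both endpoints are nodes and `dx = (x_hi - x_lo) / (N - 1)`;
#' for a periodic domain the right endpoint is identified with the left and
#' `dx = (x_hi - x_lo) / N`.
#'
#' Boundary conditions:
#' * `"free"`: the nonlocal integral is truncated at the domain edge (no
#'   ghost mass outside).
#' * `"dirichlet_zero"`: as `"free"`, with the field pinned to 0 on the
#'   two boundary nodes.
#' * `"periodic"`: displacements wrap; the kernel is wrapped onto the
#'   period.
#'
#' @param x_lo,x_hi Domain endpoints.
#' @param N Number of nodes (`N >= 16`).
#' @param bc One of `"free"`, `"dirichlet_zero"`, `"periodic"`.
#' @return An object of class `"nf_grid"` with elements `x` (node
#'   positions), `dx`, `N`, `bc`.
#' @export
grid_1d <- function(x_lo, x_hi, N, bc = c("free", "dirichlet_zero", "periodic")) {
  bc <- match.arg(bc)
  N <- as.integer(N)
  stopifnot(x_hi > x_lo, N >= 16)
  if (bc == "periodic") {
    dx <- (x_hi - x_lo) / N
    x <- x_lo + (0:(N - 1)) * dx
  } else {
    dx <- (x_hi - x_lo) / (N - 1)
    x <- seq(x_lo, x_hi, length.out = N)
  }
  structure(list(x = x, dx = dx, N = N, bc = bc, x_lo = x_lo, x_hi = x_hi),
            class = "nf_grid")
}

#' @export
print.nf_grid <- function(x, ...) {
  cat("<nf_grid>", x$N, "nodes on [", x$x_lo, ",", x$x_hi, "] dx =",
      format(x$dx), " bc =", x$bc, "\n")
  invisible(x)
}
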