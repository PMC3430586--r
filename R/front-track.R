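#' Level-set front tracking
#'
#' For each stored time and level value `z`, finds the position `X_z(t)`
#' where the activity profile crosses `z` downward (the front decays to the
#' right). Crossing positions are linearly interpolated between bracketing
#' nodes; when a level is crossed more than once the rightmost crossing is
#' taken (the invasion front is the rightmost interface); a level never
#' crossed at a time is marked missing.
#'
#' The mean front position averages `X_z(t)` over levels, and a front speed
#' is fitted by least squares on the mean position over `window` (default:
#' the last half of the tracked times).
#'
#' @param traj An `nf_trajectory`.
#' @param levels Level values `z`.
#' @param window Length-2 time window for the speed fit.
#' @return An object of class `"nf_fronttrack"` with elements `positions`
#'   (tibble `t, z, X`), `mean_position` (tibble `t, X_mean, n_levels`),
#'   `speed`, `speed_stderr`, `window`, `levels`.
#' @export
track_front <- function(traj, levels, window = NULL) {
  stopifnot(inherits(traj, "nf_trajectory"), length(levels) >= 1)
  times <- traj$times
  x <- traj$grid$x
  N <- traj$grid$N
  pos <- matrix(NA_real_, length(times), length(levels))
  for (i in seq_along(times)) {
    a <- traj$values[i, ]
    for (j in seq_along(levels)) {
      z <- levels[j]
      idx <- which(a[-N] >= z & a[-1] < z)
      if (length(idx)) {
        k <- max(idx) # rightmost downward crossing
        pos[i, j] <- x[k] + (a[k] - z) / (a[k] - a[k + 1]) * traj$grid$dx
      }
    }
  }
  mean_pos <- rowMeans(pos, na.rm = TRUE)
  n_levels <- rowSums(!is.na(pos))
  mean_pos[n_levels == 0] <- NA_real_
  if (is.null(window))
    window <- c(min(times) + diff(range(times)) / 2, max(times))
  sel <- times >= window[1] & times <= window[2] & !is.na(mean_pos)
  if (sum(sel) >= 2) {
    fit <- stats::lm(mean_pos[sel] ~ times[sel])
    speed <- unname(stats::coef(fit)[2])
    speed_se <- summary(fit)$coefficients[2, 2]
  } else {
    speed <- NA_real_
    speed_se <- NA_real_
  }
  structure(
    list(
      positions = tibble::tibble(
        t = rep(times, length(levels)),
        z = rep(levels, each = length(times)),
        X = as.vector(pos)
      ),
      mean_position = tibble::tibble(t = times, X_mean = mean_pos,
                                     n_levels = n_levels),
      speed = speed, speed_stderr = speed_se,
      window = window, levels = levels
    ),
    class = "nf_fronttrack"
  )
}

#' @export
print.nf_fronttrack <- function(x, ...) {
  cat("<nf_fronttrack>", length(x$levels), "levels,",
      nrow(x$mean_position), "times; fitted speed =",
      format(x$speed, digits = 6), "on window [",
      x$window[1], ",", x$window[2], "]\n")
  invisible(x)
}

#' @export
tidy.nf_fronttrack <- function(x, ...) x$positions

#' @export
glance.nf_fronttrack <- function(x, ...) {
  tibble::tibble(speed = x$speed, speed_stderr = x$speed_stderr,
                 window_lo = x$window[1], window_hi = x$window[2],
                 n_levels = length(x$levels))
}

#' @export
autoplot.nf_fronttrack <- function(object, ...) {
  ggplot2::ggplot(object$positions,
                  ggplot2::aes(.data$t, .data$X, group = .data$z,
                               colour = factor(.data$z))) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_line(data = object$mean_position,
                       ggplot2::aes(.data$t, .data$X_mean),
                       inherit.aes = FALSE, linewidth = 1) +
    ggplot2::labs(x = "t", y = expression(X[z](t)), colour = "level z") +
    ggplot2::theme_minimal()
}
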