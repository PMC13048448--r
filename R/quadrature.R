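# Newton-Cotes quadrature on the package's uniform age grids.
#
# All lifetime integrals are truncated at a_max (where survivorship falls below
# the truncation tolerance) and evaluated by composite Simpson rules; tails
# int_a^{a_max} are accumulated from the old-age end so that small values are
# sums of small positive increments rather than differences of large ones.

#' Composite Simpson weights on a uniform grid
#'
#' @param n number of grid points (odd).
#' @param h grid spacing.
#' @return numeric vector of quadrature weights such that `sum(w * y)`
#'   approximates the integral of `y` over the grid.
#' @keywords internal
simpson_weights <- function(n, h) {
  stopifnot(n >= 3L, n %% 2L == 1L)
  w <- rep(c(2, 4), length.out = n)
  w[1L] <- 1
  w[n] <- 1
  w * h / 3
}

#' Cumulative integral on a uniform grid (local-parabola rule)
#'
#' Third-order accurate cumulative quadrature: Simpson increments over point
#' pairs, with the mid-pair value from the same interpolating parabola.
#'
#' @param y integrand values on the grid (odd length).
#' @param h grid spacing.
#' @return vector of the same length; element k approximates the integral from
#'   the first grid point to grid point k.
#' @keywords internal
cumquad <- function(y, h) {
  n <- length(y)
  stopifnot(n %% 2L == 1L, n >= 3L)
  out <- numeric(n)
  io <- seq(1L, n - 2L, by = 2L)
  out[io + 2L] <- cumsum(h / 3 * (y[io] + 4 * y[io + 1L] + y[io + 2L]))
  out[io + 1L] <- out[io] + h / 12 * (5 * y[io] + 8 * y[io + 1L] - y[io + 2L])
  out
}

#' Tail integrals int_a^{a_max} y on a uniform grid
#'
#' @inheritParams cumquad
#' @return vector of the same length; element k approximates the integral from
#'   grid point k to the last grid point.
#' @keywords internal
tailquad <- function(y, h) {
  rev(cumquad(rev(y), h))
}

# Central finite-difference step, relative to the argument scale.
fd_step <- function(x, rel) {
  rel * pmax(1, abs(x))
}
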