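# Internal helpers shared across modules.

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop_invalid("'%s' must be finite numeric", name)
  invisible(x)
}

check_positive <- function(x, name, strict = TRUE) {
  check_finite(x, name)
  if (strict && any(x <= 0)) stop_invalid("'%s' must be > 0", name)
  if (!strict && any(x < 0)) stop_invalid("'%s' must be >= 0", name)
  invisible(x)
}

#' Mass of a centred 2D Gaussian inside an annulus
#'
#' For a normalized 2D Gaussian of standard deviation `sigma`, returns the
#' probability mass contained between radii `r1` and `r2`,
#' `exp(-r1^2/(2 sigma^2)) - exp(-r2^2/(2 sigma^2))`.  This closed form is the
#' workhorse for annulus-averaged radial dose values.
#'
#' @param r1,r2 inner and outer radii (mm), vectorized.
#' @param sigma Gaussian standard deviation (mm).
#' @return annulus mass (dimensionless, in `[0, 1]`).
#' @export
gauss_annulus_mass <- function(r1, r2, sigma) {
  check_positive(sigma, "sigma")
  exp(-r1^2 / (2 * sigma^2)) - exp(-r2^2 / (2 * sigma^2))
}

# Bilinear interpolation into matrix `z` (rows ~ x_axis, cols ~ y_axis) with
# edge clamping; xq/yq vectorized (recycled to common length).
bilinear_clamped <- function(x_axis, y_axis, z, xq, yq) {
  n <- max(length(xq), length(yq))
  xq <- rep_len(pmin(pmax(xq, x_axis[1]), x_axis[length(x_axis)]), n)
  yq <- rep_len(pmin(pmax(yq, y_axis[1]), y_axis[length(y_axis)]), n)
  ix <- findInterval(xq, x_axis, rightmost.closed = TRUE)
  iy <- findInterval(yq, y_axis, rightmost.closed = TRUE)
  ix <- pmin(pmax(ix, 1L), length(x_axis) - 1L)
  iy <- pmin(pmax(iy, 1L), length(y_axis) - 1L)
  if (length(x_axis) == 1L) ix <- rep_len(1L, n)
  if (length(y_axis) == 1L) iy <- rep_len(1L, n)
  x0 <- x_axis[ix]; y0 <- y_axis[iy]
  dx <- if (length(x_axis) > 1L) (xq - x0) / (x_axis[ix + 1L] - x0) else 0
  dy <- if (length(y_axis) > 1L) (yq - y0) / (y_axis[iy + 1L] - y0) else 0
  ix1 <- pmin(ix + 1L, length(x_axis))
  iy1 <- pmin(iy + 1L, length(y_axis))
  z[cbind(ix, iy)]   * (1 - dx) * (1 - dy) +
  z[cbind(ix1, iy)]  * dx       * (1 - dy) +
  z[cbind(ix, iy1)]  * (1 - dx) * dy +
  z[cbind(ix1, iy1)] * dx       * dy
}

# Cumulative trapezoidal integral of y over x, same length as x, starting at 0.
cumtrapz1 <- function(x, y) {
  n <- length(x)
  c(0, cumsum((y[-1] + y[-n]) / 2 * diff(x)))
}
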