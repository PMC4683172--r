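# Halo parameterizations: the analytic Soukup model for the dose fraction and
# width of the large-angle (nuclear) component, the tabulated lookup container
# shared by both parameterizations, and the bilinear table lookup.

# Substitute the past-Bragg-peak hold: beyond the peak both u and sigma_LA
# keep the value they have at the peak depth.
hold_depth <- function(r0, z_we) pmin(z_we, r0)

#' Soukup halo fraction u(R0, z_WE)
#'
#' Analytic fit to Monte-Carlo simulations of nuclear interaction products in
#' water, giving the share of the integral dose at water-equivalent depth
#' `z_we` deposited by the halo of a beam with Bragg-peak depth `r0`:
#' \deqn{u = 0.052\,\ln\!\Big(1.13 + \frac{z}{11.2 - 0.023 R_0}\Big)
#'   + 0.35\,\frac{0.0017 R_0^2 - R_0}{(R_0+3)^2 - z^2}
#'   - 1.61\times 10^{-9}\, z\,(R_0+3)^2}
#' with \eqn{z = \min(z_{WE}, R_0)} (past the Bragg peak the value at the
#' peak depth is held).  Where the right-hand side is negative the fraction
#' is set to 0; the result is clamped to `[0, 1]`.
#'
#' @param r0 Bragg-peak depth in water (mm), > 0.
#' @param z_we water-equivalent depth (mm), >= 0; vectorized.
#' @param clamp if `FALSE`, return the raw analytic right-hand side (no
#'   clamping to `[0, 1]`); the past-peak hold is always applied.
#' @return halo fraction (dimensionless).
#' @export
soukup_halo_fraction <- function(r0, z_we, clamp = TRUE) {
  check_positive(r0, "r0"); check_positive(z_we, "z_we", strict = FALSE)
  z <- hold_depth(r0, z_we)
  u <- 0.052 * log(1.13 + z / (11.2 - 0.023 * r0)) +
    0.35 * (0.0017 * r0^2 - r0) / ((r0 + 3)^2 - z^2) -
    1.61e-9 * z * (r0 + 3)^2
  if (clamp) u <- pmin(pmax(u, 0), 1)
  u
}

#' Soukup large-angle width sigma_LA(R0, z_WE)
#'
#' Companion analytic fit for the standard deviation of the halo Gaussian:
#' \deqn{\sigma_{LA} = 2.85 + 0.0014 R_0 \ln(z + 3) + 0.06 z
#'   - 7.4\times10^{-5} z^2 - \frac{0.22 R_0}{(z - R_0 - 5)^2}}
#' with \eqn{z = \min(z_{WE}, R_0)} (the same past-peak hold as for the halo
#' fraction is applied to the width), clamped at 0 from below.
#'
#' @inheritParams soukup_halo_fraction
#' @return large-angle width (mm).
#' @export
soukup_sigma_la <- function(r0, z_we) {
  check_positive(r0, "r0"); check_positive(z_we, "z_we", strict = FALSE)
  z <- hold_depth(r0, z_we)
  s <- 2.85 + 0.0014 * r0 * log(z + 3) + 0.06 * z - 7.4e-5 * z^2 -
    0.22 * r0 / (z - r0 - 5)^2
  pmax(s, 0)
}

#' Halo parameterization tables
#'
#' 2D tables of the halo fraction `u` and the squared large-angle width
#' `sigma_LA^2` over (Bragg-peak depth, water-equivalent depth), the form in
#' which the dose engine consumes any halo model.  `sigma_LA^2` (not
#' `sigma_LA`) is stored and interpolated, matching the quadrature use in the
#' halo kernel width.
#'
#' @param r0_axis Bragg-peak depths indexing rows (mm), strictly increasing.
#' @param depth_axis water-equivalent depths indexing columns (mm),
#'   strictly increasing, covering `[0, max_wepl_fraction * max(r0_axis)]`.
#' @param u_table matrix of halo fractions in `[0, 1]`.
#' @param sigma_la_sq_table matrix of squared widths (mm^2), >= 0.
#' @param hold_fraction fraction of R0 beyond which each row is constant.
#' @param max_wepl_fraction largest `z_WE / R0` ever evaluated (default 1.05).
#' @param model label, one of `"soukup"`, `"direct"`, `"single"`, `"custom"`.
#' @return an object of class `halo_parameterization`.
#' @export
halo_parameterization <- function(r0_axis, depth_axis, u_table,
                                  sigma_la_sq_table, hold_fraction = 1,
                                  max_wepl_fraction = 1.05,
                                  model = "custom") {
  check_positive(r0_axis, "r0_axis")
  check_positive(depth_axis, "depth_axis", strict = FALSE)
  u_table <- as.matrix(u_table); sigma_la_sq_table <- as.matrix(sigma_la_sq_table)
  if (length(r0_axis) > 1 && any(diff(r0_axis) <= 0))
    stop_invalid("r0_axis must be strictly increasing")
  if (any(diff(depth_axis) <= 0))
    stop_invalid("depth_axis must be strictly increasing")
  if (!all(dim(u_table) == c(length(r0_axis), length(depth_axis))) ||
      !all(dim(u_table) == dim(sigma_la_sq_table)))
    stop_invalid("halo tables: inconsistent dimensions")
  if (any(u_table < 0 | u_table > 1)) stop_invalid("u must lie in [0, 1]")
  if (any(sigma_la_sq_table < 0)) stop_invalid("sigma_LA^2 must be >= 0")
  for (i in seq_along(r0_axis)) {
    past <- depth_axis > hold_fraction * r0_axis[i]
    if (sum(past) > 1) {
      if (diff(range(u_table[i, past])) > 1e-9 ||
          diff(range(sigma_la_sq_table[i, past])) > 1e-6)
        stop_invalid("rows must be constant past hold_fraction * R0")
    }
  }
  structure(list(r0_axis = r0_axis, depth_axis = depth_axis,
                 u_table = u_table, sigma_la_sq_table = sigma_la_sq_table,
                 hold_fraction = hold_fraction,
                 max_wepl_fraction = max_wepl_fraction, model = model),
            class = "halo_parameterization")
}

#' @export
print.halo_parameterization <- function(x, ...) {
  cat(sprintf("<halo_parameterization> model '%s': %d x %d (R0 x depth), hold at %.2f*R0\n",
              x$model, length(x$r0_axis), length(x$depth_axis), x$hold_fraction))
  invisible(x)
}

#' Tabulate the Soukup parameterization for a beamline
#'
#' Evaluates [soukup_halo_fraction] and [soukup_sigma_la] on a regular
#' (R0, depth) grid so that the engine's bilinear lookup can treat both
#' parameterizations uniformly.
#'
#' @param beamline a [beamline_table].
#' @param depth_axis water-equivalent depth nodes (mm); defaults to a 1 mm
#'   grid covering `[0, 1.05 * max(R0)]`.
#' @return a [halo_parameterization] with `model = "soukup"`.
#' @export
build_soukup_tables <- function(beamline, depth_axis = NULL) {
  if (!inherits(beamline, "beamline_table") || length(beamline$r0) == 0)
    stop_invalid("'beamline' must be a non-empty beamline_table")
  r0 <- beamline$r0
  if (is.null(depth_axis)) depth_axis <- seq(0, ceiling(1.05 * max(r0)), by = 1)
  if (max(depth_axis) < 1.05 * max(r0) - 1e-9)
    stop_invalid("depth_axis must cover [0, 1.05 * max(R0)]")
  u <- t(vapply(r0, function(r) soukup_halo_fraction(r, depth_axis),
                numeric(length(depth_axis))))
  sla <- t(vapply(r0, function(r) soukup_sigma_la(r, depth_axis)^2,
                  numeric(length(depth_axis))))
  halo_parameterization(r0, depth_axis, u, sla, hold_fraction = 1,
                        model = "soukup")
}

#' Constant-u halo tables
#'
#' Convenience constructor for degenerate parameterizations (e.g. `u == 0`
#' for the single-Gaussian reduction, or `u == 1` to route all dose through
#' the halo path in tests).
#'
#' @param beamline a [beamline_table].
#' @param u constant halo fraction in `[0, 1]`.
#' @param sigma_la constant large-angle width (mm).
#' @return a [halo_parameterization].
#' @export
build_constant_tables <- function(beamline, u, sigma_la = 6) {
  r0 <- beamline$r0
  depth_axis <- c(0, 1.05 * max(r0))
  nr <- length(r0); nc <- length(depth_axis)
  halo_parameterization(r0, depth_axis,
                        matrix(u, nr, nc), matrix(sigma_la^2, nr, nc),
                        hold_fraction = 1,
                        model = if (u == 0) "single" else "custom")
}

#' Bilinear halo-table lookup
#'
#' Interpolates `u` and `sigma_LA^2` bilinearly in (R0, depth); queries
#' outside the table clamp to the nearest edge, consistent with the
#' hold-constant semantics past the Bragg peak.
#'
#' @param params a [halo_parameterization].
#' @param r0 Bragg-peak depth(s) of the queried beam (mm).
#' @param z_we water-equivalent depth(s) (mm).
#' @return list with components `u` and `sigma_la_sq`, each the length of
#'   the (recycled) query vectors.
#' @export
lookup_halo <- function(params, r0, z_we) {
  if (!inherits(params, "halo_parameterization"))
    stop_invalid("'params' must be a halo_parameterization")
  list(
    u = bilinear_clamped(params$r0_axis, params$depth_axis, params$u_table,
                         r0, z_we),
    sigma_la_sq = bilinear_clamped(params$r0_axis, params$depth_axis,
                                   params$sigma_la_sq_table, r0, z_we)
  )
}
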