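# Widths of the primary Gaussian: multiple-Coulomb-scattering growth of the
# computational pencil beam (CPB) width with depth, and the quadrature rules
# combining air, scattering and large-angle components.

PROTON_MASS_MEV <- 938.272
X0_WATER_MM <- 360.8  # radiation length of water

#' Scattering-model parameters
#'
#' The two free parameters of the primary-width growth model: the scattering
#' energy constant `E_S` (MeV) of the Highland-type scattering power and the
#' empirical width correction `delta` (mm).  The single-Gaussian defaults are
#' 14.1 MeV and 0.21 mm; with a double-Gaussian beam model both must be
#' recalibrated against the primary contribution alone (see
#' [calibrate_scattering]).
#'
#' @param e_s scattering energy constant (MeV), > 0.
#' @param delta empirical width correction (mm), >= 0.
#' @export
scattering_params <- function(e_s = 14.1, delta = 0.21) {
  check_positive(e_s, "e_s"); check_positive(delta, "delta", strict = FALSE)
  structure(list(e_s = e_s, delta = delta), class = "scattering_params")
}

#' @export
print.scattering_params <- function(x, ...) {
  cat(sprintf("<scattering_params> E_S = %.2f MeV, delta = %.3f mm\n",
              x$e_s, x$delta))
  invisible(x)
}

# p*v (MeV) of a proton with residual range r_res (mm water), Bragg-Kleeman.
proton_pv_from_range <- function(r_res) {
  e <- (pmax(r_res, 0.05) / BK_ALPHA_MM)^(1 / BK_P)
  e * (e + 2 * PROTON_MASS_MEV) / (e + PROTON_MASS_MEV)
}

#' Multiple-scattering width of the computational pencil beam
#'
#' Grows the CPB width from zero at the surface by Fermi-Eyges integration of
#' a Highland-type scattering power `T(t) = (E_S / (p v))^2 / X0` along the
#' water-equivalent path,
#' \deqn{\sigma_{MCS}^2(z) = \int_0^z (z - t)^2\, T(t)\, dt,}
#' with the proton momentum-velocity product from the residual
#' Bragg-Kleeman range, plus the empirical additive correction
#' `delta * z_WE / R0` (so `delta` has units mm and vanishes at the surface).
#' The in-air width at the surface is *not* included here; it is added in
#' quadrature by [total_pb_sigma].  Past the Bragg peak the width is held at
#' its peak-depth value.
#'
#' @param energy beam energy (MeV); must be present in `beamline`.
#' @param z_we water-equivalent depth(s) (mm), each `<= 1.05 * R0`.
#' @param scattering a [scattering_params].
#' @param beamline a [beamline_table].
#' @return sigma_CPB (mm), same length as `z_we`; monotone non-decreasing.
#' @export
primary_sigma <- function(energy, z_we, scattering, beamline) {
  check_positive(z_we, "z_we", strict = FALSE)
  i <- beamline_energy_index(beamline, energy)
  r0 <- beamline$r0[i]
  if (any(z_we > 1.05 * r0 + 1e-9))
    stop_invalid("z_we exceeds 1.05 * R0 (%.1f mm)", 1.05 * r0)
  sig <- primary_sigma_fun(r0, scattering)
  sig(z_we)
}

# Returns a vectorized function sigma_CPB(z_we) for a beam of range r0,
# precomputing the Fermi-Eyges moment integrals on a fine grid.
primary_sigma_fun <- function(r0, scattering) {
  h <- min(0.5, r0 / 400)
  t <- seq(0, r0, by = h)
  tp <- (scattering$e_s / proton_pv_from_range(r0 - t))^2 / X0_WATER_MM
  m0 <- cumtrapz1(t, tp)          # int T
  m1 <- cumtrapz1(t, t * tp)      # int t T
  m2 <- cumtrapz1(t, t^2 * tp)    # int t^2 T
  f0 <- stats::approxfun(t, m0, rule = 2)
  f1 <- stats::approxfun(t, m1, rule = 2)
  f2 <- stats::approxfun(t, m2, rule = 2)
  function(z_we) {
    z <- pmin(z_we, r0)
    s2 <- pmax(z^2 * f0(z) - 2 * z * f1(z) + f2(z), 0)
    sqrt(s2) + scattering$delta * pmin(z_we, r0) / r0
  }
}

#' Halo kernel width (quadrature sum)
#'
#' `sigma_HPB = sqrt(sigma_PB^2 + sigma_LA^2)`: the halo pencil beam carries
#' the full primary width plus the large-angle component in quadrature.
#'
#' @param sigma_pb total primary width (mm), >= 0.
#' @param sigma_la large-angle width (mm), >= 0.
#' @export
hpb_sigma <- function(sigma_pb, sigma_la) {
  check_positive(sigma_pb, "sigma_pb", strict = FALSE)
  check_positive(sigma_la, "sigma_la", strict = FALSE)
  sqrt(sigma_pb^2 + sigma_la^2)
}

#' Total primary width
#'
#' `sigma_PB = sqrt(sigma_air^2 + sigma_CPB^2)`: in-air width at the surface
#' added in quadrature to the multiple-scattering growth.
#'
#' @param sigma_air in-air width at the surface (mm), >= 0.
#' @param sigma_cpb multiple-scattering width (mm), >= 0.
#' @export
total_pb_sigma <- function(sigma_air, sigma_cpb) {
  check_positive(sigma_air, "sigma_air", strict = FALSE)
  check_positive(sigma_cpb, "sigma_cpb", strict = FALSE)
  sqrt(sigma_air^2 + sigma_cpb^2)
}
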