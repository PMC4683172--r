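# Beamline data: per-energy Bragg-peak depth, integral depth-dose curves and
# in-air beam width at the patient surface.

# Bragg-Kleeman range-energy relation in water, R [mm] = 0.022 * E^1.77.
BK_ALPHA_MM <- 0.022
BK_P <- 1.77

#' Convert proton energy to Bragg-peak depth in water
#'
#' Bragg-Kleeman relation `R0 = 0.022 * E^1.77` (R0 in mm, E in MeV).
#' @param energy beam energy (MeV).
#' @export
energy_to_r0 <- function(energy) {
  check_positive(energy, "energy")
  BK_ALPHA_MM * energy^BK_P
}

#' @rdname energy_to_r0
#' @param r0 Bragg-peak depth in water (mm).
#' @export
r0_to_energy <- function(r0) {
  check_positive(r0, "r0")
  (r0 / BK_ALPHA_MM)^(1 / BK_P)
}

#' Beamline table
#'
#' Container for the per-energy machine data the dose engine consumes: the
#' Bragg-peak depth in water `R0(E)`, a sampled integral depth-dose curve
#' `I_IDD(E, z_WE)` (laterally integrated dose, dose x mm^2, arbitrary
#' scale) on a common water-equivalent depth grid, and the in-air beam width
#' at the patient surface `sigma_air(E)`.
#'
#' @param energies nominal beam energies (MeV), strictly increasing.
#' @param r0 Bragg-peak depth in water per energy (mm), strictly increasing.
#' @param idd matrix of IDD samples, `length(energies)` rows, one column per
#'   node of `z_grid`.
#' @param z_grid regular water-equivalent depth grid for `idd` (mm).
#' @param sigma_air in-air width at the surface per energy (mm), > 0.
#' @return an object of class `beamline_table`.
#' @export
beamline_table <- function(energies, r0, idd, z_grid, sigma_air) {
  check_positive(energies, "energies"); check_positive(r0, "r0")
  check_positive(sigma_air, "sigma_air"); check_finite(z_grid, "z_grid")
  idd <- as.matrix(idd)
  if (any(diff(r0) <= 0)) stop_invalid("R0 must be strictly increasing with energy")
  if (length(energies) != length(r0) || length(energies) != length(sigma_air) ||
      nrow(idd) != length(energies) || ncol(idd) != length(z_grid))
    stop_invalid("beamline_table: inconsistent dimensions")
  if (any(idd < 0)) stop_invalid("IDD samples must be >= 0")
  peak_z <- z_grid[apply(idd, 1L, which.max)]
  if (any(abs(peak_z - r0) > 3))
    stop_invalid("IDD argmax deviates from R0 by more than 3 mm")
  structure(list(energies = energies, r0 = r0, idd = idd, z_grid = z_grid,
                 sigma_air = sigma_air),
            class = "beamline_table")
}

#' @export
print.beamline_table <- function(x, ...) {
  cat(sprintf("<beamline_table> %d energies, R0 %.1f-%.1f mm, depth grid %d nodes\n",
              length(x$energies), min(x$r0), max(x$r0), length(x$z_grid)))
  invisible(x)
}

# Index of the beamline energy (exact match within tolerance), or error.
beamline_energy_index <- function(beamline, energy, tol = 1e-6) {
  i <- which(abs(beamline$energies - energy) <= tol * max(1, energy))
  if (length(i) != 1L)
    stop_invalid("energy %.4g MeV not present in beamline table", energy)
  i
}

# I_IDD(E, z_WE) by linear interpolation along depth; 0 outside the grid.
beamline_idd_at <- function(beamline, energy_index, z_we) {
  stats::approx(beamline$z_grid, beamline$idd[energy_index, ], xout = z_we,
                rule = 1, yleft = 0, yright = 0)$y -> v
  v[is.na(v)] <- 0
  v
}

#' Synthetic beamline table
#'
#' Builds a [beamline_table] from a set of Bragg-peak depths using the
#' analytic Bragg curve of [analytic_idd], the Bragg-Kleeman range-energy
#' relation, and a smooth in-air width model
#' `sigma_air = 3.3 - 0.004 * R0 + 270 / (R0 + 70)` mm (wider spots at low
#' energy, as scanning nozzles deliver).
#'
#' @param r0 Bragg-peak depths in water (mm), strictly increasing.
#' @param z_step depth grid step for the IDD curves (mm).
#' @return a [beamline_table].
#' @export
make_synthetic_beamline <- function(r0, z_step = 1) {
  check_positive(r0, "r0")
  r0 <- sort(r0)
  z_grid <- seq(0, 1.05 * max(r0) + z_step, by = z_step)
  idd <- t(vapply(r0, function(r) analytic_idd(r, z_grid), numeric(length(z_grid))))
  sigma_air <- 3.3 - 0.004 * r0 + 270 / (r0 + 70)
  beamline_table(energies = r0_to_energy(r0), r0 = r0, idd = idd,
                 z_grid = z_grid, sigma_air = sigma_air)
}
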