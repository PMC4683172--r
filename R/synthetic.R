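# Synthetic ground truth: analytic Bragg curves, two-Gaussian beams with
# known parameters, pseudo-Monte-Carlo radial profiles, and phantoms.  These
# stand in for the Monte-Carlo reference data a clinical commissioning would
# use, so the fitting pipeline and dose engine are testable end to end.

#' Analytic integral depth-dose curve
#'
#' A smooth Bragg-curve stand-in peaking exactly at `r0`: a slowly rising
#' plateau `1 + 0.45 (z/R0)^3` plus a Gaussian peak of width `0.022 R0` and
#' amplitude 2.8, with a Gaussian distal falloff of width `0.0176 R0` and
#' hard zero beyond `1.05 R0`.  The peak width corresponds to range
#' straggling (about 1.2% of range) plus a typical beam momentum spread,
#' which is what makes spread-out Bragg peaks with conventional layer
#' spacings flat.  All shape scales are proportional to `r0`, so curves for
#' different ranges are rescaled copies of each other.
#'
#' @param r0 Bragg-peak depth (mm), > 0.
#' @param z_grid depths at which to sample (mm).
#' @return IDD samples (dose x mm^2, arbitrary scale), same length as
#'   `z_grid`.
#' @export
analytic_idd <- function(r0, z_grid) {
  check_positive(r0, "r0"); check_finite(z_grid, "z_grid")
  sp <- 0.022 * r0
  sd_ <- 0.0176 * r0
  peak_val <- 1 + 0.45 + 2.8
  v <- ifelse(z_grid <= r0,
              1 + 0.45 * (z_grid / r0)^3 + 2.8 * exp(-(z_grid - r0)^2 / (2 * sp^2)),
              peak_val * exp(-(z_grid - r0)^2 / (2 * sd_^2)))
  v[z_grid > 1.05 * r0 | z_grid < 0] <- 0
  v
}

#' Ground-truth beam with known double-Gaussian structure
#'
#' Defines smooth depth curves for the halo fraction, the total primary width
#' and the large-angle width of a beam with Bragg-peak depth `r0`.  The halo
#' fraction rises with depth and the widths grow smoothly, loosely emulating
#' what direct fits to Monte-Carlo profiles produce; the profile at every
#' depth is *exactly* a sum of two Gaussians, so fits recover the parameters
#' exactly in the noiseless limit (the non-Gaussian "aura" of neutral
#' secondaries is deliberately not simulated).
#'
#' @param r0 Bragg-peak depth (mm).
#' @param u_surface,u_peak halo fraction at the surface and at the peak.
#' @param u_power shape exponent of the halo-fraction rise.
#' @param sla_surface,sla_peak large-angle width at surface / peak (mm).
#' @param sla_power shape exponent of the width growth.
#' @param sigma_air in-air width at the surface (mm); default from the
#'   synthetic beamline width model.
#' @param scattering a [scattering_params] driving the primary-width growth.
#' @return an object of class `ground_truth_beam` with function fields
#'   `u_true(z)`, `sigma_pb_true(z)`, `sigma_la_true(z)`, `idd_true(z)`.
#' @export
make_ground_truth_beam <- function(r0, u_surface = 0.05, u_peak = 0.25,
                                   u_power = 1.5, sla_surface = 8,
                                   sla_peak = 12, sla_power = 1.2,
                                   sigma_air = NULL,
                                   scattering = scattering_params(13.0, 0.05)) {
  check_positive(r0, "r0")
  if (u_surface < 0 || u_peak > 1 || u_peak < 0 || u_surface > 1)
    stop_invalid("u must lie in [0, 1]")
  if (is.null(sigma_air)) sigma_air <- 3.3 - 0.004 * r0 + 270 / (r0 + 70)
  mcs <- primary_sigma_fun(r0, scattering)
  u_true <- function(z) {
    f <- (pmin(z, r0) / r0)^u_power
    u_surface + (u_peak - u_surface) * f
  }
  sigma_la_true <- function(z) {
    f <- (pmin(z, r0) / r0)^sla_power
    sla_surface + (sla_peak - sla_surface) * f
  }
  sigma_pb_true <- function(z) total_pb_sigma(sigma_air, mcs(z))
  idd_true <- function(z) analytic_idd(r0, z)
  structure(list(r0 = r0, sigma_air = sigma_air,
                 u_true = u_true, sigma_pb_true = sigma_pb_true,
                 sigma_la_true = sigma_la_true, idd_true = idd_true),
            class = "ground_truth_beam")
}

#' @export
print.ground_truth_beam <- function(x, ...) {
  cat(sprintf("<ground_truth_beam> R0 = %.0f mm, u(BP) = %.3f, sigma_LA(BP) = %.2f mm\n",
              x$r0, x$u_true(x$r0), x$sigma_la_true(x$r0)))
  invisible(x)
}

#' Radial dose profile
#'
#' Binned radial dose at a fixed water-equivalent depth: the mean dose in
#' each annulus `[r_i, r_{i+1})`.  This is the unit of data the fitting
#' pipeline consumes.
#'
#' @param bin_edges ascending radii starting at 0 (mm).
#' @param dose mean dose per annulus (arbitrary dose units), >= 0.
#' @param depth water-equivalent depth of the profile (mm).
#' @param r0 Bragg-peak depth of the parent beam (mm).
#' @param sd estimated per-bin standard deviation (same units as `dose`).
#' @export
radial_profile <- function(bin_edges, dose, depth, r0, sd = NULL) {
  check_finite(bin_edges, "bin_edges")
  if (bin_edges[1] < 0 || any(diff(bin_edges) <= 0))
    stop_invalid("bin_edges must be non-negative and strictly increasing")
  if (length(dose) != length(bin_edges) - 1L)
    stop_invalid("length(dose) must equal length(bin_edges) - 1")
  if (any(dose < 0)) stop_invalid("dose must be >= 0")
  if (is.null(sd)) sd <- rep(0, length(dose))
  if (any(sd < 0)) stop_invalid("sd must be >= 0")
  structure(list(bin_edges = bin_edges, dose = dose, depth = depth, r0 = r0,
                 sd = sd),
            class = "radial_profile")
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf("<radial_profile> R0 = %.0f mm, depth %.1f mm, %d bins to %.0f mm\n",
              x$r0, x$depth, length(x$dose), max(x$bin_edges)))
  invisible(x)
}

# Annulus areas pi*(r2^2 - r1^2) of a profile.
profile_bin_areas <- function(profile) {
  e <- profile$bin_edges
  pi * diff(e^2)
}

# Bin-center radii.
profile_bin_centers <- function(profile) {
  e <- profile$bin_edges
  (e[-1] + e[-length(e)]) / 2
}

#' Pseudo-Monte-Carlo radial profile from a ground-truth beam
#'
#' The noiseless bin value is the exact annulus average of
#' `D(r) = I_IDD * [(1-u) G(r; sigma_PB) + u G(r; sigma_HPB)]` with
#' `sigma_HPB` from the quadrature rule, computed from closed-form annulus
#' Gaussian masses.  Statistical noise is emulated by multiplying each bin by
#' `1 + noise_level * xi` with standard-normal `xi` (a Monte-Carlo-like
#' relative error); `sd` is set to `noise_level` times the bin value.
#'
#' @param beam a [make_ground_truth_beam] object.
#' @param depth water-equivalent depth (mm), `<= 1.05 * R0`.
#' @param bin_edges radial bin edges (mm); default 0.5 mm bins to 100 mm.
#' @param noise_level relative noise (default 0.02); 0 gives the exact model.
#' @param seed RNG seed for reproducible noise.
#' @return a [radial_profile].
#' @export
radial_profile_from_truth <- function(beam, depth,
                                      bin_edges = seq(0, 100, by = 0.5),
                                      noise_level = 0.02, seed = NULL) {
  if (!inherits(beam, "ground_truth_beam")) stop_invalid("'beam' must be a ground_truth_beam")
  if (depth > 1.05 * beam$r0 + 1e-9)
    stop_invalid("depth %.1f mm exceeds 1.05 * R0", depth)
  u <- beam$u_true(depth)
  s_pb <- beam$sigma_pb_true(depth)
  s_hpb <- hpb_sigma(s_pb, beam$sigma_la_true(depth))
  idd <- beam$idd_true(depth)
  r1 <- bin_edges[-length(bin_edges)]; r2 <- bin_edges[-1]
  area <- pi * (r2^2 - r1^2)
  d <- idd * ((1 - u) * gauss_annulus_mass(r1, r2, s_pb) +
              u * gauss_annulus_mass(r1, r2, s_hpb)) / area
  if (noise_level > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    d <- pmax(d * (1 + noise_level * stats::rnorm(length(d))), 0)
  }
  radial_profile(bin_edges, d, depth, beam$r0, sd = noise_level * d)
}

#' Phantom grid of relative stopping power
#'
#' @param kind `"water"` (all ones) or `"slab"` (ones with a contiguous
#'   z-range replaced by `slab_rsp`).
#' @param dims integer triple of voxel counts (x, y, z).
#' @param spacing voxel spacing (mm), scalar or triple.
#' @param origin position of the first voxel centre (mm).
#' @param slab_rsp relative stopping power of the slab.
#' @param slab_range depth range (mm, along z measured from the phantom
#'   surface) occupied by the slab.
#' @return an object of class `phantom_grid` with fields `rsp` (3D array),
#'   `spacing`, `origin`.
#' @export
make_phantom <- function(kind = c("water", "slab"), dims = c(60, 60, 60),
                         spacing = 1, origin = NULL, slab_rsp = 1,
                         slab_range = NULL) {
  kind <- match.arg(kind)
  dims <- as.integer(dims)
  check_positive(dims, "dims")
  spacing <- rep_len(as.numeric(spacing), 3L)
  check_positive(spacing, "spacing")
  if (is.null(origin)) origin <- c(0, 0, spacing[3] / 2)
  rsp <- array(1, dim = dims)
  if (kind == "slab") {
    if (is.null(slab_range)) stop_invalid("'slab_range' required for a slab phantom")
    check_positive(slab_rsp, "slab_rsp", strict = FALSE)
    zc <- origin[3] + (seq_len(dims[3]) - 1L) * spacing[3]
    sel <- zc >= slab_range[1] & zc < slab_range[2]
    if (!any(sel) || slab_range[1] < 0 || slab_range[2] > dims[3] * spacing[3])
      stop_invalid("slab_range outside the phantom grid")
    rsp[, , sel] <- slab_rsp
  }
  structure(list(rsp = rsp, spacing = spacing, origin = origin),
            class = "phantom_grid")
}

#' @export
print.phantom_grid <- function(x, ...) {
  cat(sprintf("<phantom_grid> %d x %d x %d voxels @ %.1f x %.1f x %.1f mm\n",
              dim(x$rsp)[1], dim(x$rsp)[2], dim(x$rsp)[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}
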