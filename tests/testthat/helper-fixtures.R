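# Shared fixtures, built in code.  Heavier objects are memoised so the suite
# pays for them once.

.fix <- new.env(parent = emptyenv())

fix_beamline <- function() {
  if (is.null(.fix$bl)) .fix$bl <- make_synthetic_beamline(c(70, 131, 220))
  .fix$bl
}

fix_soukup <- function() {
  if (is.null(.fix$soukup)) .fix$soukup <- build_soukup_tables(fix_beamline())
  .fix$soukup
}

# Profiles from the three reference beams on a given depth schedule.
fix_profiles <- function(noise = 0, seedbase = NULL,
                         fracs = seq(0.02, 1.04, by = 0.02)) {
  prs <- list()
  r0s <- c(70, 131, 220)
  for (i in seq_along(r0s)) {
    beam <- make_ground_truth_beam(r0s[i])
    for (fi in seq_along(fracs)) {
      prs[[length(prs) + 1L]] <- radial_profile_from_truth(
        beam, fracs[fi] * r0s[i], noise_level = noise,
        seed = if (is.null(seedbase)) NULL else seedbase + i * 1000L + fi)
    }
  }
  prs
}

# Relative RMS of a recovered depth curve against the generating truth.
rel_rms <- function(est, truth) sqrt(mean((est - truth)^2)) / sqrt(mean(truth^2))

# Recovery errors (u, sigma_LA) of a direct-model build against the
# ground-truth beams, per R0.
recovery_errors <- function(dm) {
  out <- NULL
  for (r0 in c(70, 131, 220)) {
    beam <- make_ground_truth_beam(r0)
    z <- seq(0, r0, by = 2)
    lk <- lookup_halo(dm$halo, r0, z)
    out <- rbind(out, data.frame(
      r0 = r0,
      u = rel_rms(lk$u, beam$u_true(z)),
      sigma_la = rel_rms(sqrt(lk$sigma_la_sq), beam$sigma_la_true(z))))
  }
  out
}

# Brute-force direct summation of the double-Gaussian dose model over every
# voxel of a water phantom: the independent oracle for the engine.  Uses
# cell-integrated Gaussians (mean dose per voxel), no BEV, no kernel
# superposition, no truncation.
brute_force_dose <- function(layer, phantom, beamline, halo, scattering,
                             truncation) {
  gm <- function(dx, s, h) stats::pnorm(dx + h / 2, sd = s) -
    stats::pnorm(dx - h / 2, sd = s)
  dims <- dim(phantom$rsp)
  gx <- phantom$origin[1] + (seq_len(dims[1]) - 1) * phantom$spacing[1]
  gy <- phantom$origin[2] + (seq_len(dims[2]) - 1) * phantom$spacing[2]
  ei <- which.min(abs(beamline$energies - layer$energy))
  r0 <- beamline$r0[ei]; sa <- beamline$sigma_air[ei]
  ax <- seq(min(layer$spots$x) - 40, max(layer$spots$x) + 40, by = 1)
  ay <- seq(min(layer$spots$y) - 40, max(layer$spots$y) + 40, by = 1)
  cp <- split_sub_pbs(layer$spots, sa, ax, ay, truncation = truncation)
  nz <- cp$W != 0
  cx <- rep(cp$xs, times = length(cp$ys))[as.vector(nz)]
  cy <- rep(cp$ys, each = length(cp$xs))[as.vector(nz)]
  cw <- cp$W[nz]
  sfun <- function(z) primary_sigma(layer$energy, z, scattering, beamline)
  dose <- array(0, dim = dims)
  for (k in seq_len(dims[3])) {
    zwe <- phantom$origin[3] + (k - 1) * phantom$spacing[3]
    if (zwe > 1.05 * r0) next
    idd <- stats::approx(beamline$z_grid, beamline$idd[ei, ], xout = zwe,
                         yleft = 0, yright = 0)$y
    lk <- lookup_halo(halo, r0, zwe)
    scpb <- max(sfun(zwe), 1e-9)
    spb <- sqrt(sa^2 + scpb^2)
    shpb <- sqrt(spb^2 + lk$sigma_la_sq)
    pl <- matrix(0, dims[1], dims[2])
    for (i in seq_along(cw))
      pl <- pl + cw[i] * (1 - lk$u) * idd *
        outer(gm(gx - cx[i], scpb, 1), gm(gy - cy[i], scpb, 1))
    for (i in seq_len(nrow(layer$spots)))
      pl <- pl + layer$spots$w[i] * lk$u * idd *
        outer(gm(gx - layer$spots$x[i], shpb, 1),
              gm(gy - layer$spots$y[i], shpb, 1))
    dose[, , k] <- pl
  }
  dose
}

# Small dose_grid from an array.
as_dose_grid <- function(arr, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  structure(list(dose = arr, spacing = spacing, origin = origin),
            class = "dose_grid")
}

# Isotropic 3D Gaussian field on an n^3 grid.
gaussian_field <- function(n, centre, sigma) {
  x <- (0:(n - 1))
  r2 <- outer((x - centre[1])^2, outer((x - centre[2])^2, (x - centre[3])^2,
                                       "+"), "+")
  array(exp(-r2 / (2 * sigma^2)), dim = c(n, n, n))
}
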