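# Parameterization fitting: per-depth Gaussian fits, the direct pipeline,
# Soukup primary-width extraction, scattering recalibration.

test_that("single-Gaussian fit recovers an exact Gaussian profile", {
  beam <- make_ground_truth_beam(131, u_surface = 0, u_peak = 0)
  pr <- radial_profile_from_truth(beam, 40, noise_level = 0)
  f <- fit_single_gaussian(pr)
  expect_equal(f$sigma, beam$sigma_pb_true(40), tolerance = 1e-8)
  expect_equal(f$amplitude, sum(pr$dose * pi * diff(pr$bin_edges^2)),
               tolerance = 1e-3)
  # on a two-Gaussian profile the single width lands between the components
  beam2 <- make_ground_truth_beam(131)
  pr2 <- radial_profile_from_truth(beam2, 40, noise_level = 0)
  f2 <- fit_single_gaussian(pr2)
  s_pb <- beam2$sigma_pb_true(40)
  s_hpb <- hpb_sigma(s_pb, beam2$sigma_la_true(40))
  expect_gt(f2$sigma, s_pb)
  expect_lt(f2$sigma, s_hpb)
})

test_that("double-Gaussian fit recovers noiseless parameters to 1e-4 relative", {
  beam <- make_ground_truth_beam(220)
  for (frac in c(0.1, 0.5, 1.0)) {
    d <- frac * 220
    f <- fit_double_gaussian(radial_profile_from_truth(beam, d, noise_level = 0))
    expect_true(f$converged)
    expect_equal(f$u, beam$u_true(d), tolerance = 1e-4)
    expect_equal(f$sigma_pb, beam$sigma_pb_true(d), tolerance = 1e-4)
    expect_equal(f$sigma_hpb,
                 hpb_sigma(beam$sigma_pb_true(d), beam$sigma_la_true(d)),
                 tolerance = 1e-4)
  }
})

test_that("double-Gaussian fit respects the single-Gaussian limit and ordering", {
  beam0 <- make_ground_truth_beam(131, u_surface = 0, u_peak = 0)
  pr <- radial_profile_from_truth(beam0, 60, noise_level = 0)
  f <- fit_double_gaussian(pr)
  expect_lte(f$u, 0.01)
  # swapped width initialization converges to the same sorted solution
  beam <- make_ground_truth_beam(131)
  pr2 <- radial_profile_from_truth(beam, 60, noise_level = 0)
  fa <- fit_double_gaussian(pr2, init = list(sigma1 = 4, sigma2 = 12))
  fb <- fit_double_gaussian(pr2, init = list(sigma1 = 12, sigma2 = 4))
  expect_equal(fa$sigma_pb, fb$sigma_pb, tolerance = 1e-6)
  expect_equal(fa$u, fb$u, tolerance = 1e-6)
  expect_gte(fa$sigma_hpb, fa$sigma_pb)
  expect_error(fit_double_gaussian(
    radial_profile(seq(0, 10, 1), rep(0, 10), 5, 131)), "zero")
})

test_that("ring-area weighting makes the shape parameters scale-invariant", {
  beam <- make_ground_truth_beam(131)
  pr <- radial_profile_from_truth(beam, 60, noise_level = 0)
  pr5 <- radial_profile(pr$bin_edges, 5 * pr$dose, pr$depth, pr$r0)
  f1 <- fit_double_gaussian(pr)
  f5 <- fit_double_gaussian(pr5)
  expect_equal(f5$u, f1$u, tolerance = 1e-7)
  expect_equal(f5$sigma_pb, f1$sigma_pb, tolerance = 1e-7)
  expect_equal(f5$sigma_hpb, f1$sigma_hpb, tolerance = 1e-7)
  expect_equal(f5$amplitude, 5 * f1$amplitude, tolerance = 1e-6)
})

test_that("halving the bin width changes noiseless fit parameters by < 0.1%", {
  beam <- make_ground_truth_beam(131)
  f1 <- fit_double_gaussian(radial_profile_from_truth(
    beam, 60, bin_edges = seq(0, 100, by = 0.5), noise_level = 0))
  f2 <- fit_double_gaussian(radial_profile_from_truth(
    beam, 60, bin_edges = seq(0, 100, by = 0.25), noise_level = 0))
  expect_equal(f2$u, f1$u, tolerance = 1e-3)
  expect_equal(f2$sigma_pb, f1$sigma_pb, tolerance = 1e-3)
  expect_equal(f2$sigma_hpb, f1$sigma_hpb, tolerance = 1e-3)
})

test_that("direct pipeline holds its curves past 102% of the Bragg-peak depth", {
  prs <- fix_profiles(noise = 0, fracs = c(0.02, seq(0.1, 1, 0.1), 1.02, 1.04))
  dm <- build_direct_model(prs)
  expect_identical(dm$halo$model, "direct")
  for (r0 in c(70, 131, 220)) {
    at102 <- lookup_halo(dm$halo, r0, 1.02 * r0)
    at104 <- lookup_halo(dm$halo, r0, 1.04 * r0)
    expect_equal(at104$u, at102$u, tolerance = 1e-9)
    expect_equal(at104$sigma_la_sq, at102$sigma_la_sq, tolerance = 1e-9)
  }
  # tables stay inside their domains
  expect_true(all(dm$halo$u_table >= 0 & dm$halo$u_table <= 1))
  expect_true(all(dm$halo$sigma_la_sq_table >= 0))
  # raw primary widths are returned for the calibration step
  expect_true(all(c("r0", "depth", "sigma_pb") %in% names(dm$sigma_pb)))
  expect_error(build_direct_model(prs[1:4]), "cover")
})

test_that("Soukup-consistent fixture returns the true primary width", {
  bl <- fix_beamline()
  tabs <- fix_soukup()
  prs <- list()
  for (i in seq_along(bl$r0)) {
    r0 <- bl$r0[i]
    beam <- make_ground_truth_beam(
      r0, u_surface = soukup_halo_fraction(r0, 0),
      u_peak = soukup_halo_fraction(r0, r0), u_power = 1,
      sigma_air = bl$sigma_air[i])
    # halo exactly as the tables describe it
    beam$u_true <- function(z) soukup_halo_fraction(r0, z)
    beam$sigma_la_true <- function(z) soukup_sigma_la(r0, z)
    for (frac in c(0.2, 0.5, 0.8, 1.0))
      prs[[length(prs) + 1L]] <- radial_profile_from_truth(beam, frac * r0,
                                                           noise_level = 0)
  }
  ex <- extract_sigma_pb_soukup(prs, tabs)
  for (row in seq_len(nrow(ex))) {
    beam <- make_ground_truth_beam(ex$r0[row],
      sigma_air = bl$sigma_air[match(ex$r0[row], bl$r0)])
    expect_equal(ex$sigma_pb[row], beam$sigma_pb_true(ex$depth[row]),
                 tolerance = 1e-3)
  }
  expect_true(all(ex$iterations <= 2))
})

test_that("with a zero-halo table the extraction reduces to the single fit", {
  bl <- fix_beamline()
  tab0 <- build_constant_tables(bl, 0, 0)
  beam <- make_ground_truth_beam(131, u_surface = 0, u_peak = 0)
  pr <- radial_profile_from_truth(beam, 60, noise_level = 0)
  ex <- extract_sigma_pb_soukup(list(pr), tab0)
  expect_equal(ex$sigma_pb, fit_single_gaussian(pr)$sigma, tolerance = 1e-9)
})

test_that("scattering calibration recovers known E_S and delta", {
  bl <- fix_beamline()
  true <- scattering_params(13.0, 0.05)
  tb <- do.call(rbind, lapply(seq_along(bl$r0), function(i) {
    z <- seq(0.1, 1, length.out = 10) * bl$r0[i]
    data.frame(r0 = bl$r0[i], depth = z,
               sigma_pb = total_pb_sigma(
                 bl$sigma_air[i], primary_sigma(bl$energies[i], z, true, bl)))
  }))
  cal <- calibrate_scattering(tb, bl)
  expect_equal(cal$e_s, 13.0, tolerance = 0.01)
  expect_equal(cal$delta, 0.05, tolerance = 0.01)
  # a delta = 0 truth yields essentially zero fitted correction
  tb0 <- tb
  sp0 <- scattering_params(13.0, 0)
  for (i in seq_along(bl$r0)) {
    rows <- tb0$r0 == bl$r0[i]
    tb0$sigma_pb[rows] <- total_pb_sigma(
      bl$sigma_air[i], primary_sigma(bl$energies[i], tb0$depth[rows], sp0, bl))
  }
  expect_lte(calibrate_scattering(tb0, bl)$delta, 0.01)
  # 2% noise on the widths still pins E_S to 5% when the calibration spans
  # a full energy ladder (the E_S/delta split needs the energy lever arm)
  bl2 <- make_synthetic_beamline(seq(60, 240, by = 10))
  tb2 <- do.call(rbind, lapply(seq_along(bl2$r0), function(i) {
    z <- seq(0.1, 1, length.out = 15) * bl2$r0[i]
    data.frame(r0 = bl2$r0[i], depth = z,
               sigma_pb = total_pb_sigma(
                 bl2$sigma_air[i], primary_sigma(bl2$energies[i], z, true, bl2)))
  }))
  set.seed(7)
  tb2$sigma_pb <- tb2$sigma_pb * (1 + 0.02 * rnorm(nrow(tb2)))
  expect_equal(calibrate_scattering(tb2, bl2)$e_s, 13.0, tolerance = 0.05)
  expect_error(calibrate_scattering(tb[tb$r0 == 70, ], bl), ">= 2 energies")
})

test_that("entry-width factor is applied per model kind", {
  expect_identical(entry_width_factor("direct"), 0.97)
  expect_identical(entry_width_factor("soukup"), 1.0)
  expect_error(entry_width_factor("pedroni"))
})
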