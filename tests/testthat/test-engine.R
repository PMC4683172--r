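# Dose engine: splitting, raytracing, deposit, kernel superposition,
# BEV -> global transform, plan orchestration.

test_that("sub-PB splitting conserves each spot's weight on the fine lattice", {
  xs <- seq(-20, 20, by = 1)
  spots <- data.frame(x = c(-3, 0, 3), y = c(0, 0, 3), w = c(1, 2.5, 0.25))
  cp <- split_sub_pbs(spots, sigma_entry = 3.2, xs, xs)
  expect_equal(sum(cp$W), sum(spots$w), tolerance = 1e-12)
  # a width far below the lattice spacing degenerates to the nearest site
  cp0 <- split_sub_pbs(data.frame(x = 0.2, y = -0.3, w = 2),
                       sigma_entry = 0.01, xs, xs)
  expect_equal(max(cp0$W), 2)
  expect_equal(sum(cp0$W != 0), 1)
  expect_error(split_sub_pbs(spots, 0, xs, xs), "> 0")
})

test_that("fine lattice is nine times denser than the spot lattice", {
  cfg <- engine_config()  # 1 mm CPB, 3 mm PB
  ax <- halodose:::bev_axes(c(-6, 6), c(-6, 6), cfg, margin = 10)
  nf <- length(ax$x$fine) * length(ax$y$fine)
  nc <- length(ax$x$coarse) * length(ax$y$coarse)
  expect_equal((cfg$pb_spacing / cfg$cpb_spacing)^2, 9)
  # node-count ratio approaches 9 (exact up to the shared boundary row)
  expect_equal(nf / nc, 9, tolerance = 0.25)
  # every coarse node is a fine node
  expect_true(all(ax$x$coarse %in% ax$x$fine))
})

test_that("one halo pencil beam per spot, same position and weight", {
  layer <- list(energy = 100,
                spots = data.frame(x = seq(-15, 15, by = 3), y = 0, w = 1:11))
  h <- assign_hpbs(layer)
  expect_identical(nrow(h), 11L)
  expect_identical(h$x, layer$spots$x)
  expect_identical(h$w, layer$spots$w)
})

test_that("raytracing returns geometric depth in water and shifts with a slab", {
  w <- make_phantom("water", dims = c(20, 20, 50), spacing = 1)
  rt <- raytrace_wepl(w, 10, 10, cap = 40)
  expect_equal(rt$z_we, rt$z)
  expect_identical(rt$active, rt$z_we <= 40)
  s <- make_phantom("slab", dims = c(20, 20, 50), spacing = 1, slab_rsp = 2,
                    slab_range = c(10, 20))
  rts <- raytrace_wepl(s, 10, 10)
  downstream <- rts$z > 20
  expect_equal(rts$z_we[downstream], rts$z[downstream] + 10)
  expect_message(mi <- raytrace_wepl(w, 500, 500), "misses")
  expect_true(all(mi$z_we == 0))
})

test_that("deposit splits the integral dose exactly between primary and halo", {
  bl <- fix_beamline()
  tab <- fix_soukup()
  sp <- scattering_params(13.8, 0)
  ph <- make_phantom("water", dims = c(61, 61, 80), spacing = 1)
  layer <- list(energy = bl$energies[1],
                spots = data.frame(x = c(27, 30, 33), y = rep(30, 3), w = c(1, 2, 1)))
  bev <- deposit_layer(layer, ph, bl, tab, sp, engine_config())
  i <- which.min(abs(bl$energies - layer$energy))
  zwe <- 0.5 + (bev$fine$z_index - 1)
  expected <- sum(layer$spots$w) *
    approx(bl$z_grid, bl$idd[i, ], xout = zwe, yleft = 0, yright = 0)$y
  got <- apply(bev$fine$Q, 3, sum) + apply(bev$coarse$Q, 3, sum)
  expect_equal(got, expected, tolerance = 1e-12)
  # complementary limits: all-halo and no-halo tables
  tab1 <- build_constant_tables(bl, 1, 6)
  bev1 <- deposit_layer(layer, ph, bl, tab1, sp, engine_config())
  expect_true(all(bev1$fine$Q == 0))
  expect_equal(apply(bev1$coarse$Q, 3, sum), expected, tolerance = 1e-12)
  tab0 <- build_constant_tables(bl, 0, 0)
  bev0 <- deposit_layer(layer, ph, bl, tab0, sp, engine_config())
  expect_true(all(bev0$coarse$Q == 0))
})

test_that("kernel superposition conserves plane sums and counts operations", {
  bev <- list(xs = seq(-15, 15, 1), ys = seq(-15, 15, 1), spacing = 1,
              z_index = 1L,
              Q = array(0, dim = c(31, 31, 1)), sigma = list(2.5))
  bev$Q[16, 16, 1] <- 3.7
  ks <- kernel_superposition(bev, 3.5)
  expect_equal(sum(ks$Q), 3.7, tolerance = 1e-12)
  # sigma = 0 keeps the dose in its own cell
  bev0 <- bev; bev0$sigma <- list(0)
  expect_identical(kernel_superposition(bev0, 3.5)$Q, bev0$Q)
  # operation counts scale quadratically with sigma / spacing
  bev2 <- bev; bev2$sigma <- list(5)
  r <- kernel_superposition(bev2, 3.5)$ops / ks$ops
  expect_gt(r, 3.4); expect_lt(r, 4.7)
})

test_that("aligned BEV planes copy into the global grid and keep their integral", {
  ph <- make_phantom("water", dims = c(21, 21, 5), spacing = 1)
  Q <- array(0, dim = c(21, 21, 2))
  set.seed(3)
  Q[5:17, 5:17, ] <- runif(13 * 13 * 2)
  bev <- list(xs = 0:20, ys = 0:20, spacing = 1, z_index = c(2L, 4L), Q = Q)
  dose <- bev_to_global(bev, NULL, ph)
  expect_identical(dose[, , 2], Q[, , 1])
  expect_identical(dose[, , 3], matrix(0, 21, 21))
  expect_equal(sum(dose), sum(Q), tolerance = 1e-12)
})

test_that("plan orchestration validates directions and energies", {
  bl <- fix_beamline()
  ph <- make_phantom("water", dims = c(21, 21, 10), spacing = 2)
  sp <- scattering_params()
  bad <- make_single_spot_plan(bl$energies[1], isocenter = c(20, 20))
  bad$fields[[1]]$direction <- c(1, 0, 0)
  expect_error(compute_plan_dose(bad, ph, bl, fix_soukup(), sp),
               "normally incident")
  missing_e <- make_single_spot_plan(57.5, isocenter = c(20, 20))
  expect_error(compute_plan_dose(missing_e, ph, bl, fix_soukup(), sp),
               "not present")
})

test_that("single-spot dose reproduces the closed-form two-Gaussian profile", {
  bl <- fix_beamline()
  tab <- fix_soukup()
  sp <- scattering_params(13.8, 0)
  ph <- make_phantom("water", dims = c(81, 81, 180), spacing = 1)
  plan <- make_single_spot_plan(bl$energies[3], isocenter = c(40, 40))
  run <- compute_plan_dose(plan, ph, bl, tab, sp, engine_config())
  k <- 151
  zwe <- 0.5 + (k - 1)
  idd <- approx(bl$z_grid, bl$idd[3, ], xout = zwe)$y
  lk <- lookup_halo(tab, 220, zwe)
  s_pb <- total_pb_sigma(bl$sigma_air[3],
                         primary_sigma(bl$energies[3], zwe, sp, bl))
  s_hpb <- sqrt(s_pb^2 + lk$sigma_la_sq)
  r <- 0:25
  closed <- idd * ((1 - lk$u) * exp(-r^2 / (2 * s_pb^2)) / (2 * pi * s_pb^2) +
                   lk$u * exp(-r^2 / (2 * s_hpb^2)) / (2 * pi * s_hpb^2))
  eng <- run$dose$dose[41:66, 41, k]
  expect_lt(max(abs(eng - closed)) / max(closed), 0.01)
})
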