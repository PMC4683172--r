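# Beam physics: analytic halo parameterization, width models, table lookup.

# Independent second transcription of the halo-fraction and large-angle
# width fits, written with different groupings (log1p, factored difference
# of squares) so a transcription slip in either copy shows up.
u_oracle <- function(r0, z_we) {
  z <- pmin(z_we, r0)
  denom_log <- 11.2 - 0.023 * r0
  t1 <- 0.052 * log1p(0.13 + z / denom_log)
  dd <- (r0 + 3 - z) * (r0 + 3 + z)
  t2 <- 0.35 * 0.0017 * r0 * r0 / dd - 0.35 * r0 / dd
  t3 <- -(1.61e-9) * z * (r0 + 3) * (r0 + 3)
  pmin(pmax(t1 + t2 + t3, 0), 1)
}

sla_oracle <- function(r0, z_we) {
  z <- pmin(z_we, r0)
  v <- 2.85 + 0.0014 * r0 * log(z + 3) + 0.06 * z - 7.4e-5 * z * z -
    0.22 * r0 / ((z - r0 - 5) * (z - r0 - 5))
  pmax(v, 0)
}

test_that("halo-fraction and width evaluators agree with an independent transcription", {
  for (r0 in c(70, 131, 220)) {
    z <- seq(0, 1.05 * r0, length.out = 400)
    expect_equal(soukup_halo_fraction(r0, z), u_oracle(r0, z),
                 tolerance = 1e-12)
    expect_equal(soukup_sigma_la(r0, z), sla_oracle(r0, z),
                 tolerance = 1e-12)
  }
})

test_that("halo fraction clamps to zero where the analytic expression is negative", {
  # scan for a grid point with a negative raw value
  grid <- expand.grid(r0 = seq(10, 250, by = 5), frac = seq(0, 1, by = 0.05))
  raw <- mapply(function(r, f) soukup_halo_fraction(r, f * r, clamp = FALSE),
                grid$r0, grid$frac)
  expect_true(any(raw < 0))
  neg <- which(raw < 0)[1]
  expect_identical(soukup_halo_fraction(grid$r0[neg],
                                        grid$frac[neg] * grid$r0[neg]), 0)
  # and the clamped values are a valid fraction everywhere
  clamped <- mapply(function(r, f) soukup_halo_fraction(r, f * r),
                    grid$r0, grid$frac)
  expect_true(all(clamped >= 0 & clamped <= 1))
  expect_true(all(mapply(function(r, f) soukup_sigma_la(r, f * r),
                         grid$r0, grid$frac) >= 0))
})

test_that("both halo curves hold their Bragg-peak value past the peak", {
  for (r0 in c(70, 220)) {
    expect_identical(soukup_halo_fraction(r0, r0 + 50),
                     soukup_halo_fraction(r0, r0))
    expect_identical(soukup_sigma_la(r0, r0 + 50), soukup_sigma_la(r0, r0))
  }
})

test_that("non-finite inputs are rejected", {
  expect_error(soukup_halo_fraction(NaN, 10), "finite")
  expect_error(soukup_sigma_la(220, Inf), "finite")
})

test_that("large-angle width dwarfs the primary width at mid-range depths", {
  bl <- fix_beamline()
  sp <- scattering_params(13.8, 0)
  z <- seq(0.3 * 220, 0.7 * 220, by = 5)
  s_pb <- total_pb_sigma(bl$sigma_air[3],
                         primary_sigma(bl$energies[3], z, sp, bl))
  expect_true(all(soukup_sigma_la(220, z) >= 2 * s_pb))
})

test_that("quadrature width rules behave algebraically", {
  expect_equal(hpb_sigma(3, 4), 5)
  expect_equal(hpb_sigma(2.7, 0), 2.7)
  expect_equal(hpb_sigma(0, 6.1), 6.1)
  expect_equal(total_pb_sigma(3.3, 0), 3.3)
  expect_equal(total_pb_sigma(0, 1.7), 1.7)
  # nesting composes quadratically
  a <- 2.1; cc <- 1.3; l <- 7.9
  expect_equal(hpb_sigma(total_pb_sigma(a, cc), l)^2, a^2 + cc^2 + l^2)
  # sigma_HPB dominates both of its components
  expect_true(hpb_sigma(3, 4) >= 4 && hpb_sigma(3, 4) >= 3)
  expect_error(hpb_sigma(-1, 2), ">= 0")
})

test_that("multiple-scattering width grows from zero, scales with E_S, stays monotone", {
  bl <- fix_beamline()
  sp0 <- scattering_params(14.1, 0)
  expect_equal(primary_sigma(bl$energies[2], 0, sp0, bl), 0)
  z <- seq(0, 131, by = 1)
  s1 <- primary_sigma(bl$energies[2], z, sp0, bl)
  s2 <- primary_sigma(bl$energies[2], z, scattering_params(28.2, 0), bl)
  expect_equal(s2, 2 * s1, tolerance = 1e-12)
  for (i in seq_along(bl$energies)) {
    zz <- seq(0, 1.05 * bl$r0[i], length.out = 300)
    sig <- primary_sigma(bl$energies[i], zz, scattering_params(13.8, 0.05), bl)
    expect_true(all(diff(sig) >= -1e-12))
  }
  expect_error(primary_sigma(bl$energies[2], 1.06 * 131, sp0, bl), "1.05")
})

test_that("tabulated Soukup model round-trips through the lookup", {
  bl1 <- make_synthetic_beamline(131)
  tab <- build_soukup_tables(bl1)
  expect_identical(nrow(tab$u_table), 1L)
  # node values equal direct evaluation
  expect_equal(tab$u_table[1, ], soukup_halo_fraction(131, tab$depth_axis))
  expect_equal(tab$sigma_la_sq_table[1, ], soukup_sigma_la(131, tab$depth_axis)^2)
  lk <- lookup_halo(tab, 131, tab$depth_axis[5])
  expect_identical(lk$u, tab$u_table[1, 5])
  # midpoint query is the arithmetic mean of the two nodes
  mid <- (tab$depth_axis[7] + tab$depth_axis[8]) / 2
  expect_equal(lookup_halo(tab, 131, mid)$u,
               mean(tab$u_table[1, 7:8]), tolerance = 1e-12)
  # depth queries beyond the table clamp to the last node
  expect_equal(lookup_halo(tab, 131, 1e4)$u,
               tab$u_table[1, ncol(tab$u_table)])
})

test_that("bilinear lookup matches a direct formula on random interior queries", {
  tab <- fix_soukup()
  set.seed(11)
  r0q <- runif(50, min(tab$r0_axis), max(tab$r0_axis))
  zq <- runif(50, min(tab$depth_axis), max(tab$depth_axis))
  direct <- function(m, xa, ya, x, y) {
    i <- findInterval(x, xa); j <- findInterval(y, ya)
    i <- pmin(i, length(xa) - 1L); j <- pmin(j, length(ya) - 1L)
    tx <- (x - xa[i]) / (xa[i + 1] - xa[i]); ty <- (y - ya[j]) / (ya[j + 1] - ya[j])
    m[cbind(i, j)] * (1 - tx) * (1 - ty) + m[cbind(i + 1, j)] * tx * (1 - ty) +
      m[cbind(i, j + 1)] * (1 - tx) * ty + m[cbind(i + 1, j + 1)] * tx * ty
  }
  lk <- lookup_halo(tab, r0q, zq)
  expect_equal(lk$u, direct(tab$u_table, tab$r0_axis, tab$depth_axis, r0q, zq),
               tolerance = 1e-12)
  expect_equal(lk$sigma_la_sq,
               direct(tab$sigma_la_sq_table, tab$r0_axis, tab$depth_axis, r0q, zq),
               tolerance = 1e-12)
})

test_that("beamline and halo-table constructors enforce their invariants", {
  expect_error(beamline_table(c(100, 90), c(70, 60),
                              matrix(1, 2, 3), c(0, 1, 2), c(3, 3)),
               "increasing")
  bl <- fix_beamline()
  expect_error(build_soukup_tables(bl, depth_axis = seq(0, 100, 1)), "cover")
  expect_error(halo_parameterization(c(70, 131), c(0, 50, 100),
                                     matrix(2, 2, 3), matrix(1, 2, 3)),
               "\\[0, 1\\]")
})
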