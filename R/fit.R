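# Parameterization fitting: single- and double-Gaussian fits to radial dose
# profiles with ring-area weighting, the direct double-Gaussian pipeline
# (fit -> rearrange the quadrature rule -> smoothing splines -> hold), the
# iterative primary-width extraction under the Soukup halo model, and the
# recalibration of the scattering parameters E_S and delta.

# Residual function factory: annulus-averaged k-Gaussian mixture model with
# ring-area weights pi*(r2^2 - r1^2) applied to the squared residuals.
ring_weighted_residuals <- function(profile) {
  r1 <- profile$bin_edges[-length(profile$bin_edges)]
  r2 <- profile$bin_edges[-1]
  area <- pi * (r2^2 - r1^2)
  sw <- sqrt(area)
  list(r1 = r1, r2 = r2, area = area, sw = sw, dose = profile$dose)
}

#' Ring-area-weighted single-Gaussian fit of a radial profile
#'
#' Least-squares fit of an annulus-averaged normalized 2D Gaussian
#' `A * G(r; sigma)` to a radial profile, weighting each bin's squared
#' residual by the full ring area `pi (r_{i+1}^2 - r_i^2)` so the sparse
#' large-radius dose is not ignored.
#'
#' @param profile a [radial_profile] with at least 3 positive bins.
#' @return list with `sigma` (mm), `amplitude` (integral dose), `converged`,
#'   `residual_norm`.
#' @export
fit_single_gaussian <- function(profile) {
  w <- ring_weighted_residuals(profile)
  if (sum(w$dose > 0) < 3L) stop_invalid("need >= 3 positive bins")
  rc <- (w$r1 + w$r2) / 2
  total <- sum(w$dose * w$area)
  sigma0 <- sqrt(max(sum(w$dose * w$area * rc^2) / total / 2, 0.01))
  fn <- function(p) {
    pred <- p[1] * gauss_annulus_mass(w$r1, w$r2, p[2]) / w$area
    w$sw * (pred - w$dose)
  }
  fit <- minpack.lm::nls.lm(par = c(total, sigma0), fn = fn,
                            lower = c(0, 0.05), upper = c(Inf, 500),
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  list(sigma = fit$par[2], amplitude = fit$par[1],
       converged = fit$info %in% 1:3,
       residual_norm = sqrt(sum(fn(fit$par)^2) / sum((w$sw * w$dose)^2)))
}

#' Ring-area-weighted double-Gaussian fit of a radial profile
#'
#' Simultaneously fits the amplitude `A`, halo fraction `u` and the two
#' widths of the model
#' `A * [(1-u) G(r; sigma_PB) + u G(r; sigma_HPB)]`
#' (annulus-averaged) by bounded Levenberg-Marquardt least squares with
#' ring-area weights.  The constraint `sigma_HPB >= sigma_PB` is built into
#' the parameterization (`sigma_HPB = sigma_PB + ds`, `ds >= 0`), which also
#' removes the label-switching ambiguity; `u` is bounded to `[0, 1]` and the
#' widths to `[0.1, 200]` mm.  Initialization: `sigma_PB` from a
#' single-Gaussian fit, `sigma_HPB = 3 sigma_PB`, `u = 0.1`.
#'
#' @param profile a [radial_profile] with at least 6 positive bins.
#' @param init optional list overriding the initialization; any of
#'   `sigma1`, `sigma2`, `u`, `amplitude` (widths are sorted internally).
#' @return list with `depth`, `sigma_pb`, `sigma_hpb`, `u`, `amplitude`,
#'   `converged`, `residual_norm`.
#' @export
fit_double_gaussian <- function(profile, init = NULL) {
  w <- ring_weighted_residuals(profile)
  if (all(w$dose == 0)) stop_invalid("degenerate profile: all bins zero")
  if (sum(w$dose > 0) < 6L) stop_invalid("need >= 6 positive bins")
  sg <- fit_single_gaussian(profile)
  p0 <- c(A = sg$amplitude, u = 0.1, s1 = sg$sigma, ds = 2 * sg$sigma)
  if (!is.null(init)) {
    if (!is.null(init$sigma1) || !is.null(init$sigma2)) {
      ss <- sort(c(init$sigma1 %||% sg$sigma, init$sigma2 %||% 3 * sg$sigma))
      p0["s1"] <- ss[1]; p0["ds"] <- ss[2] - ss[1]
    }
    if (!is.null(init$u)) p0["u"] <- init$u
    if (!is.null(init$amplitude)) p0["A"] <- init$amplitude
  }
  fn <- function(p) {
    pred <- p[1] * ((1 - p[2]) * gauss_annulus_mass(w$r1, w$r2, p[3]) +
                    p[2] * gauss_annulus_mass(w$r1, w$r2, p[3] + p[4])) / w$area
    w$sw * (pred - w$dose)
  }
  run <- function(par) minpack.lm::nls.lm(
    par = par, fn = fn, lower = c(0, 0, 0.1, 0), upper = c(Inf, 1, 200, 200),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  fit <- run(p0)
  if (fit$par[2] > 0.5) {
    # Degenerate mixture mode: the "halo" absorbed the primary.  Prefer the
    # physical low-u branch when it fits the data comparably well.
    alt <- run(c(fit$par[1], 0.08, fit$par[3] + fit$par[4],
                 2 * (fit$par[3] + fit$par[4])))
    if (sqrt(sum(fn(alt$par)^2)) <= 1.05 * sqrt(sum(fn(fit$par)^2)))
      fit <- alt
  }
  p <- fit$par
  se <- fit_param_se(fn, p)
  list(depth = profile$depth, sigma_pb = unname(p[3]),
       sigma_hpb = unname(p[3] + p[4]), u = unname(p[2]),
       amplitude = unname(p[1]), converged = fit$info %in% 1:3,
       residual_norm = sqrt(sum(fn(p)^2) / sum((w$sw * w$dose)^2)),
       se_u = se$u, se_sigma_la = se$sigma_la)
}

# Standard errors of u and sigma_LA = sqrt((s1+ds)^2 - s1^2) from the
# weighted-least-squares covariance at the solution (delta method).
fit_param_se <- function(fn, p) {
  out <- list(u = NA_real_, sigma_la = NA_real_)
  jac <- tryCatch(pracma::jacobian(fn, p), error = function(e) NULL)
  if (is.null(jac)) return(out)
  r <- fn(p)
  s2 <- sum(r^2) / max(length(r) - length(p), 1L)
  cv <- tryCatch(solve(crossprod(jac)) * s2, error = function(e) NULL)
  if (is.null(cv) || any(!is.finite(diag(cv)))) return(out)
  out$u <- sqrt(max(cv[2, 2], 0))
  s1 <- p[3]; ds <- p[4]
  sla2 <- (s1 + ds)^2 - s1^2
  if (sla2 > 1e-6) {
    # gradient of sigma_la wrt (s1, ds)
    g <- c(ds / sqrt(sla2), (s1 + ds) / sqrt(sla2))
    v <- g[1]^2 * cv[3, 3] + g[2]^2 * cv[4, 4] + 2 * g[1] * g[2] * cv[3, 4]
    out$sigma_la <- sqrt(max(v, 0))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Cubic penalized-regression smoother for the raw depth curves: abscissa
# sqrt(z / R0) (halo depth curves rise steeply near the surface, and the
# square-root stretch resolves that curvature), inverse-variance weights
# from the per-depth fit standard errors, roughness chosen by REML.  A
# second pass re-estimates the residual scale locally (running MAD) and
# bisquare-downweights outlying depth points, since the asymptotic fit
# standard errors understate the error of occasional near-degenerate fits.
smooth_depth_curve <- function(z, y, se, r0, z_eval) {
  x <- sqrt(pmax(z, 0) / r0)
  w <- 1 / pmax(se, 1e-4)^2
  w[!is.finite(w)] <- stats::median(w[is.finite(w)])
  w <- w / mean(w)
  k <- max(5L, min(8L, length(x) - 2L))
  dat <- data.frame(y = y, x = x)
  g1 <- mgcv::gam(y ~ s(x, k = k, bs = "cr"), data = dat, weights = w,
                  method = "REML")
  r <- y - stats::fitted(g1)
  n <- length(r)
  if (n >= 12L) {
    s_loc <- vapply(seq_len(n), function(i) {
      j <- max(1L, i - 5L):min(n, i + 5L)
      stats::mad(r[j])
    }, numeric(1))
    s_loc <- pmax(s_loc, 1e-6)
    rb <- pmin(abs(r) / (4.685 * s_loc), 1)
    w2 <- (1 - rb^2)^2 / s_loc^2
    w2[!is.finite(w2)] <- 0
    if (mean(w2) > 0) {
      g1 <- mgcv::gam(y ~ s(x, k = k, bs = "cr"), data = dat,
                      weights = w2 / mean(w2), method = "REML")
    }
  }
  as.numeric(stats::predict(g1, data.frame(x = sqrt(pmax(z_eval, 0) / r0))))
}

#' Direct double-Gaussian parameterization from radial profiles
#'
#' The full direct pipeline: per depth, a ring-area-weighted double-Gaussian
#' fit; the large-angle width from the quadrature rule,
#' `sigma_LA = sqrt(sigma_HPB^2 - sigma_PB^2)`; penalized cubic splines
#' (inverse-variance weighted, roughness by REML, on a square-root depth
#' abscissa that resolves the steep near-surface rise) through the raw
#' `u(z)` and `sigma_LA(z)` points to suppress fit noise; and a hold past
#' `hold_fraction * R0` (default 102% of the Bragg-peak depth), beyond which
#' the two-charged-Gaussian picture breaks down and the fits chase the aura
#' of neutral secondaries.  Fits at depths beyond the hold are computed but
#' excluded from the splines.
#'
#' @param profiles list of [radial_profile]s covering, for each beam,
#'   depths from the surface to at least `hold_fraction * R0`.
#' @param depth_axis output depth nodes (mm); default 1 mm grid to
#'   `1.05 * max(R0)`.
#' @param hold_fraction fraction of R0 at which the curves are frozen.
#' @return list with `halo` (a [halo_parameterization], `model = "direct"`),
#'   `sigma_pb` (data.frame `r0`, `depth`, `sigma_pb` of raw primary widths
#'   for [calibrate_scattering]), and `fits` (raw per-depth results).
#' @export
build_direct_model <- function(profiles, depth_axis = NULL,
                               hold_fraction = 1.02) {
  r0s <- vapply(profiles, function(p) p$r0, numeric(1))
  groups <- sort(unique(r0s))
  if (is.null(depth_axis))
    # include each beam's hold depth as a node so the hold is exact under
    # linear interpolation
    depth_axis <- sort(unique(c(seq(0, ceiling(1.05 * max(groups)), by = 1),
                                hold_fraction * groups)))
  u_tab <- matrix(0, length(groups), length(depth_axis))
  sla_tab <- matrix(0, length(groups), length(depth_axis))
  pb_rows <- list(); all_fits <- list()
  for (g in seq_along(groups)) {
    r0 <- groups[g]
    prs <- profiles[r0s == r0]
    depths <- vapply(prs, function(p) p$depth, numeric(1))
    o <- order(depths); prs <- prs[o]; depths <- depths[o]
    if (min(depths) > 0.05 * r0 || max(depths) < hold_fraction * r0 - 1e-9)
      stop_invalid("profiles for R0 = %.0f mm must cover [0, %.2f * R0]",
                   r0, hold_fraction)
    fits <- lapply(prs, fit_double_gaussian)
    u_raw <- vapply(fits, `[[`, numeric(1), "u")
    s_pb <- vapply(fits, `[[`, numeric(1), "sigma_pb")
    s_hpb <- vapply(fits, `[[`, numeric(1), "sigma_hpb")
    se_u <- vapply(fits, `[[`, numeric(1), "se_u")
    se_s <- vapply(fits, `[[`, numeric(1), "se_sigma_la")
    sla_raw <- sqrt(pmax(s_hpb^2 - s_pb^2, 0))
    # Spline inputs: inside the hold range, excluding fits that collapsed
    # into the degenerate high-u mixture mode (preference for a limited
    # halo fraction).
    keep <- depths <= hold_fraction * r0 + 1e-9 & u_raw <= 0.5
    if (sum(keep) < 4L) stop_invalid("need >= 4 usable depths within the hold range")
    hold_z <- min(hold_fraction * r0, max(depths[keep]))
    z_eval <- pmin(pmax(depth_axis, min(depths)), hold_z)
    u_tab[g, ] <- pmin(pmax(
      smooth_depth_curve(depths[keep], u_raw[keep], se_u[keep], r0, z_eval), 0), 1)
    sla_tab[g, ] <- pmax(
      smooth_depth_curve(depths[keep], sla_raw[keep], se_s[keep], r0, z_eval), 0)^2
    pb_rows[[g]] <- data.frame(r0 = r0, depth = depths[keep],
                               sigma_pb = s_pb[keep])
    all_fits[[g]] <- fits
  }
  halo <- halo_parameterization(groups, depth_axis, u_tab, sla_tab,
                                hold_fraction = hold_fraction,
                                model = "direct")
  list(halo = halo, sigma_pb = do.call(rbind, pb_rows), fits = all_fits)
}

#' Primary-width extraction under the Soukup halo model
#'
#' For each profile, computes the halo radial dose predicted by the Soukup
#' tables (halo fraction times the profile's integral dose, spread with the
#' halo kernel width from the quadrature rule and the current primary width),
#' subtracts it from the total profile, and fits the remainder with a single
#' Gaussian to obtain `sigma_PB`.  Because the halo kernel itself depends on
#' `sigma_PB`, the procedure iterates, but the large-angle width dominates
#' the quadrature sum so it converges essentially after one pass.  Negative
#' remainder bins are floored at 0 and counted.
#'
#' @param profiles list of [radial_profile]s.
#' @param tables a [halo_parameterization] (normally from
#'   [build_soukup_tables]).
#' @param tol relative change in `sigma_PB` below which iteration stops.
#' @param max_iter iteration cap.
#' @return data.frame with columns `r0`, `depth`, `sigma_pb`, `iterations`,
#'   `n_floored`.
#' @export
extract_sigma_pb_soukup <- function(profiles, tables, tol = 0.005,
                                    max_iter = 5L) {
  rows <- lapply(profiles, function(pr) {
    w <- ring_weighted_residuals(pr)
    total <- sum(pr$dose * w$area)
    lk <- lookup_halo(tables, pr$r0, pr$depth)
    s_pb <- fit_single_gaussian(pr)$sigma
    it <- 0L; n_floored <- 0L
    repeat {
      it <- it + 1L
      s_hpb <- sqrt(s_pb^2 + lk$sigma_la_sq)
      halo <- total * lk$u * gauss_annulus_mass(w$r1, w$r2, s_hpb) / w$area
      rem <- pr$dose - halo
      n_floored <- sum(rem < 0)
      rem <- pmax(rem, 0)
      s_new <- fit_single_gaussian(
        radial_profile(pr$bin_edges, rem, pr$depth, pr$r0))$sigma
      done <- abs(s_new - s_pb) / s_pb < tol || it >= max_iter
      s_pb <- s_new
      if (done) break
    }
    data.frame(r0 = pr$r0, depth = pr$depth, sigma_pb = s_pb,
               iterations = it, n_floored = n_floored)
  })
  do.call(rbind, rows)
}

#' Recalibrate the scattering parameters E_S and delta
#'
#' Joint least-squares fit of the primary-width growth model to extracted
#' `sigma_PB(z)` values over all energies and depths.  The in-air surface
#' width enters in quadrature on the model side (residuals are formed in
#' total-width space, `sqrt(sigma_air^2 + sigma_MCS^2) - sigma_PB`): this
#' is equivalent at the optimum to removing `sigma_air` from the data in
#' quadrature, but does not amplify measurement noise where the scattering
#' component is small.  `E_S` and `delta` are the only free parameters.
#'
#' @param sigma_pb_table data.frame with columns `r0`, `depth`, `sigma_pb`
#'   (as returned by [build_direct_model] or [extract_sigma_pb_soukup]);
#'   at least 2 energies with at least 3 depths each.
#' @param beamline a [beamline_table] supplying `sigma_air` per energy
#'   (matched by nearest R0).
#' @param start starting [scattering_params].
#' @return the fitted [scattering_params].
#' @export
calibrate_scattering <- function(sigma_pb_table, beamline,
                                 start = scattering_params()) {
  tb <- sigma_pb_table
  groups <- unique(tb$r0)
  if (length(groups) < 2L || any(table(tb$r0) < 3L))
    stop_invalid("need sigma_PB at >= 2 energies with >= 3 depths each")
  idx <- vapply(groups, function(r) which.min(abs(beamline$r0 - r)), integer(1))
  obs <- list(); z <- list(); r0v <- list(); s_air <- list()
  for (g in seq_along(groups)) {
    rows <- tb$r0 == groups[g]
    obs[[g]] <- tb$sigma_pb[rows]
    z[[g]] <- tb$depth[rows]
    r0v[[g]] <- beamline$r0[idx[g]]
    s_air[[g]] <- beamline$sigma_air[idx[g]]
  }
  fn <- function(p) {
    sp <- scattering_params(p[1], p[2])
    unlist(lapply(seq_along(groups), function(g)
      total_pb_sigma(s_air[[g]], primary_sigma_fun(r0v[[g]], sp)(z[[g]])) -
        obs[[g]]))
  }
  fit <- minpack.lm::nls.lm(par = c(start$e_s, start$delta), fn = fn,
                            lower = c(1, 0), upper = c(100, 5),
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  scattering_params(fit$par[1], fit$par[2])
}

#' Entry-width correction factor
#'
#' For the direct parameterization the halo fraction at the surface is
#' non-zero, so the in-air width describes primary and halo together and the
#' primary entry width must be reduced; a single factor of 0.97 is applied
#' across energies.  The Soukup model has essentially no surface halo, so no
#' correction is applied.  The factor scales only the width used to
#' distribute weights over the computational pencil beams, never the
#' scattering growth with depth.
#'
#' @param model_kind `"soukup"`, `"direct"` or `"single"`.
#' @return the multiplicative factor applied to the in-air width.
#' @export
entry_width_factor <- function(model_kind) {
  switch(match.arg(model_kind, c("soukup", "direct", "single")),
         direct = 0.97, soukup = 1.0, single = 1.0)
}
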