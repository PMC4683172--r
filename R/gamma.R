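# Dose comparison tooling: 3D gamma index with passing rates above a dose
# threshold, dose-difference maps, and radial profile extraction.

#' Gamma-index criteria
#'
#' @param dose_percent dose-difference criterion, % of the normalization dose.
#' @param dist_mm distance-to-agreement criterion, mm.
#' @param threshold_percent voxels of the reference below this % of the
#'   normalization dose are excluded from evaluation.
#' @param normalization `"max_dose"` (global maximum of the reference) or
#'   `"prescription"` (user-supplied value).
#' @param prescription prescription dose (required when
#'   `normalization = "prescription"`).
#' @export
gamma_criteria <- function(dose_percent = 2, dist_mm = 2,
                           threshold_percent = 10,
                           normalization = c("max_dose", "prescription"),
                           prescription = NULL) {
  check_positive(dose_percent, "dose_percent")
  check_positive(dist_mm, "dist_mm")
  check_positive(threshold_percent, "threshold_percent")
  normalization <- match.arg(normalization)
  if (normalization == "prescription") check_positive(prescription, "prescription")
  structure(list(dose_percent = dose_percent, dist_mm = dist_mm,
                 threshold_percent = threshold_percent,
                 normalization = normalization, prescription = prescription),
            class = "gamma_criteria")
}

# Trilinear upsampling of a 3D array by integer factor m: input nodes stay
# at output indices (i-1)*m + 1, with linear interpolation between them.
upsample_axis <- function(a, axis, m) {
  n <- dim(a)[axis]
  if (m == 1L || n == 1L) return(a)
  nq <- (n - 1L) * m + 1L
  pos <- 1 + (seq_len(nq) - 1) / m
  k0 <- pmin(floor(pos), n - 1L)
  fr <- pos - k0
  d <- dim(a); d[axis] <- nq
  out <- array(0, dim = d)
  for (q in seq_len(nq)) {
    lo <- k0[q]; f <- fr[q]
    sl <- switch(axis,
                 (1 - f) * a[lo, , ] + f * a[lo + 1L, , ],
                 (1 - f) * a[, lo, ] + f * a[, lo + 1L, ],
                 (1 - f) * a[, , lo] + f * a[, , lo + 1L])
    switch(axis, out[q, , ] <- sl, out[, q, ] <- sl, out[, , q] <- sl)
  }
  out
}

upsample3 <- function(a, m) {
  upsample_axis(upsample_axis(upsample_axis(a, 1L, m), 2L, m), 3L, m)
}

#' 3D global gamma index
#'
#' For every reference voxel above the dose threshold, searches a sphere of
#' radius `3 * dist_mm` around it (on the evaluated dose upsampled 3x by
#' trilinear interpolation) for
#' \deqn{\gamma = \min_r \sqrt{(\Delta D/\delta D)^2 + (\Delta r/\delta r)^2}}
#' with the dose difference taken relative to the normalization dose
#' (global gamma).  Offsets are visited in order of increasing distance with
#' per-voxel early termination, so well-matched voxels cost almost nothing.
#' Gamma values above 3 are reported as found (the search radius caps them
#' near `3 * dist_mm / delta_r`).
#'
#' @param eval_dose,ref_dose `dose_grid` objects on the same geometry.
#' @param criteria a [gamma_criteria].
#' @return list with `gamma` (array, `NA` below threshold), `passing_rate`
#'   (% of evaluated voxels with gamma <= 1), `n_evaluated`.
#' @export
gamma_index <- function(eval_dose, ref_dose, criteria = gamma_criteria()) {
  if (!isTRUE(all.equal(dim(eval_dose$dose), dim(ref_dose$dose))) ||
      !isTRUE(all.equal(eval_dose$spacing, ref_dose$spacing)))
    stop_invalid("gamma_index requires matching grid geometries")
  d_ref <- ref_dose$dose
  norm <- if (criteria$normalization == "max_dose") max(d_ref) else criteria$prescription
  if (norm <= 0) stop_invalid("normalization dose must be > 0")
  dd <- criteria$dose_percent / 100 * norm
  dr <- criteria$dist_mm
  mask <- d_ref >= criteria$threshold_percent / 100 * norm
  n_eval <- sum(mask)
  if (n_eval == 0L) stop_invalid("no voxels above the evaluation threshold")
  m <- 3L
  up <- upsample3(eval_dose$dose, m)
  h <- eval_dose$spacing / m
  rad <- 3 * dr
  ko <- expand.grid(i = seq(-ceiling(rad / h[1]), ceiling(rad / h[1])),
                    j = seq(-ceiling(rad / h[2]), ceiling(rad / h[2])),
                    k = seq(-ceiling(rad / h[3]), ceiling(rad / h[3])))
  r2 <- (ko$i * h[1])^2 + (ko$j * h[2])^2 + (ko$k * h[3])^2
  keep <- r2 <= rad^2
  ko <- ko[keep, ]; r2 <- r2[keep]
  o <- order(r2); ko <- ko[o, ]; r2 <- r2[o]
  idx <- which(mask, arr.ind = TRUE)
  ui <- (idx[, 1] - 1L) * m + 1L
  uj <- (idx[, 2] - 1L) * m + 1L
  uk <- (idx[, 3] - 1L) * m + 1L
  refv <- d_ref[mask]
  g2 <- rep(Inf, n_eval)
  du <- dim(up)
  act <- seq_len(n_eval)
  for (t in seq_len(nrow(ko))) {
    dist2 <- r2[t] / dr^2
    act <- act[g2[act] > dist2]
    if (!length(act)) break
    ii <- ui[act] + ko$i[t]; jj <- uj[act] + ko$j[t]; kk <- uk[act] + ko$k[t]
    ok <- ii >= 1L & ii <= du[1] & jj >= 1L & jj <= du[2] & kk >= 1L & kk <= du[3]
    if (!any(ok)) next
    a <- act[ok]
    ev <- up[cbind(ii[ok], jj[ok], kk[ok])]
    cand <- ((ev - refv[a]) / dd)^2 + dist2
    g2[a] <- pmin(g2[a], cand)
  }
  gam <- array(NA_real_, dim = dim(d_ref))
  gam[mask] <- sqrt(g2)
  list(gamma = gam, passing_rate = 100 * mean(g2 <= 1),
       n_evaluated = n_eval)
}

#' Dose-difference map
#'
#' `(eval - ref) / normalization * 100` per voxel.
#'
#' @param eval_dose,ref_dose `dose_grid` objects on the same geometry.
#' @param normalization scalar normalization dose; default the reference
#'   maximum.
#' @return 3D array of percent differences.
#' @export
dose_difference_map <- function(eval_dose, ref_dose, normalization = NULL) {
  if (!isTRUE(all.equal(dim(eval_dose$dose), dim(ref_dose$dose))))
    stop_invalid("dose grids must have matching dimensions")
  if (is.null(normalization)) normalization <- max(ref_dose$dose)
  if (!is.numeric(normalization) || normalization == 0)
    stop_invalid("normalization dose must be non-zero")
  (eval_dose$dose - ref_dose$dose) / normalization * 100
}

#' Radial profile of a dose grid
#'
#' Annulus-averaged dose around a beam axis at a given depth plane: voxels
#' of the plane are binned by their lateral distance from `(axis_x, axis_y)`
#' and averaged per annulus.
#'
#' @param dose a `dose_grid`.
#' @param axis_x,axis_y lateral axis position (mm, global frame).
#' @param depth depth of the plane (mm along z from the grid origin); the
#'   nearest plane is used.
#' @param bin_edges radial bin edges (mm).
#' @return a [radial_profile] (with `r0` set to `NA`).
#' @export
radial_profile_of_dose <- function(dose, axis_x, axis_y, depth,
                                   bin_edges = seq(0, 50, by = 1)) {
  d <- dim(dose$dose)
  gx <- dose$origin[1] + (seq_len(d[1]) - 1) * dose$spacing[1]
  gy <- dose$origin[2] + (seq_len(d[2]) - 1) * dose$spacing[2]
  gz <- dose$origin[3] + (seq_len(d[3]) - 1) * dose$spacing[3]
  if (axis_x < gx[1] || axis_x > gx[d[1]] || axis_y < gy[1] || axis_y > gy[d[2]])
    stop_invalid("axis lies outside the dose grid")
  k <- which.min(abs(gz - depth))
  rr <- sqrt(outer((gx - axis_x)^2, (gy - axis_y)^2, `+`))
  plane <- dose$dose[, , k]
  bin <- findInterval(rr, bin_edges, rightmost.closed = TRUE)
  sel <- bin >= 1 & bin <= length(bin_edges) - 1
  means <- tapply(plane[sel], factor(bin[sel], levels = seq_len(length(bin_edges) - 1L)),
                  mean)
  v <- as.numeric(means)
  v[is.na(v)] <- 0
  radial_profile(bin_edges, pmax(v, 0), depth = gz[k], r0 = NA_real_)
}
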