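# Spot-scanning plans: energy layers of lateral spot positions and weights.

#' Spot-scanning plan
#'
#' A plan is a list of fields; each field has a beam direction (the engine
#' supports normal incidence, direction `c(0, 0, 1)`), a lateral isocenter
#' offset (mm, added to the spot coordinates to place them in the global
#' frame), and a list of energy layers, each an energy (MeV) plus a
#' data.frame of spot positions `x`, `y` (mm, on the scanning plane) and
#' weights `w` (arbitrary MU-like units).
#'
#' @param fields list of fields as described above.
#' @return an object of class `plan_spec`.
#' @export
plan_spec <- function(fields) {
  for (f in fields) {
    if (length(f$layers) < 1L) stop_invalid("field with no energy layers")
    for (ly in f$layers) {
      if (!is.data.frame(ly$spots) || nrow(ly$spots) < 1L)
        stop_invalid("every layer needs >= 1 spot")
      if (any(ly$spots$w < 0)) stop_invalid("spot weights must be >= 0")
      check_positive(ly$energy, "energy")
    }
  }
  structure(list(fields = fields), class = "plan_spec")
}

#' @export
print.plan_spec <- function(x, ...) {
  nl <- sum(vapply(x$fields, function(f) length(f$layers), integer(1)))
  ns <- sum(vapply(x$fields, function(f)
    sum(vapply(f$layers, function(l) nrow(l$spots), integer(1))), integer(1)))
  cat(sprintf("<plan_spec> %d field(s), %d layer(s), %d spot(s)\n",
              length(x$fields), nl, ns))
  invisible(x)
}

# Check all plan energies exist in the beamline table.
validate_plan_energies <- function(plan, beamline) {
  for (f in plan$fields) for (ly in f$layers)
    beamline_energy_index(beamline, ly$energy)
  invisible(TRUE)
}

new_field <- function(layers, isocenter = c(0, 0)) {
  list(direction = c(0, 0, 1), isocenter = isocenter, layers = layers)
}

#' Single-spot plan
#'
#' @param energy beam energy (MeV).
#' @param x,y lateral spot position (mm, relative to the isocenter).
#' @param w spot weight.
#' @param isocenter lateral offset `c(x, y)` placing the field (mm).
#' @return a [plan_spec] with one field, one layer, one spot.
#' @export
make_single_spot_plan <- function(energy, x = 0, y = 0, w = 1,
                                  isocenter = c(0, 0)) {
  plan_spec(list(new_field(
    list(list(energy = energy, spots = data.frame(x = x, y = y, w = w))),
    isocenter = isocenter)))
}

#' Square-field single-layer plan
#'
#' Spots on a `spot_spacing` lattice covering a square of the given side,
#' centred on the isocenter, all with equal weight.
#'
#' @param energy beam energy (MeV).
#' @param side side length of the square field (mm).
#' @param spot_spacing lateral spot spacing (mm, default 3).
#' @param w per-spot weight.
#' @inheritParams make_single_spot_plan
#' @export
make_square_field_plan <- function(energy, side, spot_spacing = 3, w = 1,
                                   isocenter = c(0, 0)) {
  half <- floor(side / 2 / spot_spacing) * spot_spacing
  pos <- seq(-half, half, by = spot_spacing)
  g <- expand.grid(x = pos, y = pos)
  plan_spec(list(new_field(
    list(list(energy = energy, spots = data.frame(x = g$x, y = g$y, w = w))),
    isocenter = isocenter)))
}

#' Cubic-target plan with depth-weighted layers
#'
#' A single normally incident field of `n_layers` energy layers whose
#' Bragg-peak depths span the target depth range, with spots on a
#' `spot_spacing` lattice covering a square of side `side`.  Layer weights
#' are obtained by non-negative least squares so that the summed central-axis
#' integral depth dose is flat across the target (a simple spread-out Bragg
#' peak weighting).
#'
#' @param beamline a [beamline_table] whose ranges cover `depth_range`.
#' @param side target side length (mm, default 100).
#' @param depth_range depth interval `c(proximal, distal)` of the target (mm).
#' @param n_layers number of energy layers (default 20).
#' @param spot_spacing lateral spot spacing (mm, default 3).
#' @inheritParams make_single_spot_plan
#' @export
make_cubic_target_plan <- function(beamline, side = 100,
                                   depth_range = c(100, 200), n_layers = 20,
                                   spot_spacing = 3, isocenter = c(0, 0)) {
  r0_want <- seq(depth_range[1], depth_range[2], length.out = n_layers)
  idx <- vapply(r0_want, function(r) which.min(abs(beamline$r0 - r)), integer(1))
  if (anyDuplicated(idx))
    stop_invalid("beamline energy ladder too coarse for %d distinct layers", n_layers)
  zq <- seq(depth_range[1] + 2, depth_range[2] - 2, by = 2)
  a <- vapply(idx, function(i) beamline_idd_at(beamline, i, zq),
              numeric(length(zq)))
  wl <- pracma::lsqnonneg(a, rep(1, length(zq)))$x
  wl <- wl / max(wl)
  half <- floor(side / 2 / spot_spacing) * spot_spacing
  pos <- seq(-half, half, by = spot_spacing)
  g <- expand.grid(x = pos, y = pos)
  layers <- lapply(seq_along(idx), function(k)
    list(energy = beamline$energies[idx[k]],
         spots = data.frame(x = g$x, y = g$y, w = wl[k])))
  plan_spec(list(new_field(layers, isocenter = isocenter)))
}
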