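# File dialects: JSON plans, raw float32 volumes with a JSON header for
# phantoms and dose grids (a deliberately minimal dialect; no DICOM), CSV
# halo tables and beamline tables, and the deterministic fixture writer.

#' Save / load a spot-scanning plan (JSON)
#'
#' @param plan a [plan_spec].
#' @param path file path.
#' @export
save_plan <- function(plan, path) {
  fields <- lapply(plan$fields, function(f)
    list(direction = f$direction, isocenter = f$isocenter,
         layers = lapply(f$layers, function(ly)
           list(energy = ly$energy,
                spots = list(x = ly$spots$x, y = ly$spots$y, w = ly$spots$w)))))
  jsonlite::write_json(list(fields = fields), path, auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}

#' @rdname save_plan
#' @export
load_plan <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (is.null(j$fields)) stop_invalid("%s: not a plan file (no 'fields')", path)
  fields <- lapply(j$fields, function(f) {
    layers <- lapply(f$layers, function(ly) {
      if (is.null(ly$energy) || is.null(ly$spots))
        stop_invalid("%s: layer missing 'energy' or 'spots'", path)
      list(energy = ly$energy,
           spots = data.frame(x = unlist(ly$spots$x), y = unlist(ly$spots$y),
                              w = unlist(ly$spots$w)))
    })
    list(direction = unlist(f$direction), isocenter = unlist(f$isocenter),
         layers = layers)
  })
  plan_spec(fields)
}

# Shared raw float32 volume dialect -------------------------------------

write_volume <- function(arr, spacing, origin, path) {
  header <- list(dims = dim(arr), spacing = spacing, origin = origin,
                 dtype = "float32", byte_order = "little", order = "fortran")
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(paste0(path, ".raw"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(arr), con, size = 4L, endian = "little")
  invisible(path)
}

read_volume <- function(path) {
  hpath <- paste0(path, ".json")
  if (!file.exists(hpath)) stop_invalid("missing header file %s", hpath)
  h <- jsonlite::read_json(hpath, simplifyVector = TRUE)
  n <- prod(h$dims)
  rawpath <- paste0(path, ".raw")
  v <- readBin(rawpath, what = "numeric", n = n + 1L, size = 4L,
               endian = "little")
  if (length(v) != n)
    stop_invalid("%s: %d float32 values, header dims %s imply %d",
                 rawpath, length(v), paste(h$dims, collapse = "x"), n)
  list(arr = array(v, dim = h$dims), spacing = h$spacing, origin = h$origin)
}

#' Save / load a phantom (raw float32 + JSON header)
#'
#' @param phantom a [make_phantom] grid.
#' @param path file path stem (writes `<path>.raw` and `<path>.json`).
#' @export
save_phantom <- function(phantom, path) {
  write_volume(phantom$rsp, phantom$spacing, phantom$origin, path)
}

#' @rdname save_phantom
#' @export
load_phantom <- function(path) {
  v <- read_volume(path)
  structure(list(rsp = v$arr, spacing = v$spacing, origin = v$origin),
            class = "phantom_grid")
}

#' Save / load a dose grid (raw float32 + JSON header)
#'
#' @param dose a `dose_grid`.
#' @param path file path stem.
#' @export
save_dose <- function(dose, path) {
  write_volume(dose$dose, dose$spacing, dose$origin, path)
}

#' @rdname save_dose
#' @export
load_dose <- function(path) {
  v <- read_volume(path)
  structure(list(dose = v$arr, spacing = v$spacing, origin = v$origin),
            class = "dose_grid")
}

#' Save / load halo parameterization tables (CSV)
#'
#' Long-format CSV with columns `r0`, `z_we`, `u`, `sigma_la_sq` and comment
#' header lines carrying the model name and hold fraction.
#'
#' @param params a [halo_parameterization].
#' @param path file path.
#' @export
save_halo_tables <- function(params, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# model=%s", params$model),
               sprintf("# hold_fraction=%.17g", params$hold_fraction),
               sprintf("# max_wepl_fraction=%.17g", params$max_wepl_fraction)),
             con)
  g <- expand.grid(z_we = params$depth_axis, r0 = params$r0_axis)
  df <- data.frame(r0 = g$r0, z_we = g$z_we,
                   u = as.vector(t(params$u_table)),
                   sigma_la_sq = as.vector(t(params$sigma_la_sq_table)))
  utils::write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname save_halo_tables
#' @export
load_halo_tables <- function(path) {
  hdr <- readLines(path, n = 10L)
  meta <- function(key, default) {
    ln <- grep(sprintf("^# %s=", key), hdr, value = TRUE)
    if (length(ln)) as.character(sub(sprintf("^# %s=", key), "", ln[1])) else default
  }
  df <- utils::read.csv(path, comment.char = "#")
  r0_axis <- sort(unique(df$r0))
  depth_axis <- sort(unique(df$z_we))
  key <- match(paste(df$r0, df$z_we), paste(
    rep(r0_axis, each = length(depth_axis)), rep(depth_axis, length(r0_axis))))
  u <- matrix(NA_real_, length(r0_axis), length(depth_axis))
  s <- matrix(NA_real_, length(r0_axis), length(depth_axis))
  u[cbind((key - 1) %/% length(depth_axis) + 1, (key - 1) %% length(depth_axis) + 1)] <- df$u
  s[cbind((key - 1) %/% length(depth_axis) + 1, (key - 1) %% length(depth_axis) + 1)] <- df$sigma_la_sq
  halo_parameterization(r0_axis, depth_axis, u, s,
                        hold_fraction = as.numeric(meta("hold_fraction", "1")),
                        max_wepl_fraction = as.numeric(meta("max_wepl_fraction", "1.05")),
                        model = meta("model", "custom"))
}

#' Save / load a beamline table (CSV)
#'
#' Long-format CSV: one row per (energy, depth node) with the scalar columns
#' repeated.
#'
#' @param beamline a [beamline_table].
#' @param path file path.
#' @export
save_beamline <- function(beamline, path) {
  nE <- length(beamline$energies); nz <- length(beamline$z_grid)
  df <- data.frame(energy = rep(beamline$energies, each = nz),
                   r0 = rep(beamline$r0, each = nz),
                   sigma_air = rep(beamline$sigma_air, each = nz),
                   z = rep(beamline$z_grid, nE),
                   idd = as.vector(t(beamline$idd)))
  utils::write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname save_beamline
#' @export
load_beamline <- function(path) {
  df <- utils::read.csv(path)
  energies <- unique(df$energy)
  z_grid <- sort(unique(df$z))
  idd <- matrix(NA_real_, length(energies), length(z_grid))
  r0 <- numeric(length(energies)); s_air <- numeric(length(energies))
  for (i in seq_along(energies)) {
    rows <- df[df$energy == energies[i], ]
    rows <- rows[order(rows$z), ]
    idd[i, ] <- rows$idd
    r0[i] <- rows$r0[1]; s_air[i] <- rows$sigma_air[1]
  }
  beamline_table(energies, r0, idd, z_grid, s_air)
}

#' Save / load radial profiles (CSV)
#'
#' Long format: `r0`, `depth`, `r_lo`, `r_hi`, `dose`, `sd`; one profile per
#' (r0, depth) pair.
#'
#' @param profiles list of [radial_profile]s.
#' @param path file path.
#' @export
save_profiles <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    e <- p$bin_edges
    data.frame(r0 = p$r0, depth = p$depth, r_lo = e[-length(e)], r_hi = e[-1],
               dose = p$dose, sd = p$sd)
  })
  utils::write.table(format(do.call(rbind, rows), digits = 17,
                            scientific = TRUE, trim = TRUE),
                     path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname save_profiles
#' @export
load_profiles <- function(path) {
  df <- utils::read.csv(path)
  out <- list()
  for (key in unique(paste(df$r0, df$depth))) {
    rows <- df[paste(df$r0, df$depth) == key, ]
    rows <- rows[order(rows$r_lo), ]
    out[[length(out) + 1L]] <- radial_profile(
      c(rows$r_lo, rows$r_hi[nrow(rows)]), rows$dose, rows$depth[1],
      rows$r0[1], sd = rows$sd)
  }
  out
}

#' Write a deterministic fixture set
#'
#' Packages the synthetic ground truth into files: a beamline with
#' Bragg-peak depths 70, 131 and 220 mm, the Soukup halo tables, pseudo-MC
#' radial profiles for the three beams, water and slab phantoms, a
#' single-spot plan and a 20-layer cubic-target plan, plus a manifest with
#' md5 checksums of every written file.
#'
#' @param seed RNG seed controlling the profile noise.
#' @param out_dir output directory (created if missing).
#' @param noise_level relative noise of the pseudo-MC profiles.
#' @return invisibly, the manifest as a named list of checksums.
#' @export
make_fixtures <- function(seed, out_dir, noise_level = 0.02) {
  if (!dir.exists(out_dir))
    if (!dir.create(out_dir, recursive = TRUE))
      stop_invalid("cannot create output directory %s", out_dir)
  r0s <- c(70, 131, 220)
  bl <- make_synthetic_beamline(seq(60, 240, by = 5))
  save_beamline(bl, file.path(out_dir, "beamline.csv"))
  save_halo_tables(build_soukup_tables(bl),
                   file.path(out_dir, "soukup_tables.csv"))
  profiles <- list()
  for (i in seq_along(r0s)) {
    beam <- make_ground_truth_beam(r0s[i])
    for (frac in c(0.02, seq(0.1, 1.0, by = 0.1), 1.02, 1.04)) {
      profiles[[length(profiles) + 1L]] <- radial_profile_from_truth(
        beam, frac * r0s[i], noise_level = noise_level,
        seed = seed + i * 1000L + round(frac * 100))
    }
  }
  save_profiles(profiles, file.path(out_dir, "profiles.csv"))
  save_phantom(make_phantom("water", dims = c(60, 60, 80), spacing = 2),
               file.path(out_dir, "phantom_water"))
  save_phantom(make_phantom("slab", dims = c(60, 60, 80), spacing = 2,
                            slab_rsp = 2, slab_range = c(40, 60)),
               file.path(out_dir, "phantom_slab"))
  bl220 <- bl$energies[which.min(abs(bl$r0 - 220))]
  save_plan(make_single_spot_plan(bl220, isocenter = c(59, 59)),
            file.path(out_dir, "plan_single_spot.json"))
  save_plan(make_cubic_target_plan(bl, side = 100,
                                   depth_range = c(100, 200), n_layers = 20,
                                   isocenter = c(59, 59)),
            file.path(out_dir, "plan_cubic_target.json"))
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  sums <- tools::md5sum(file.path(out_dir, files))
  manifest <- as.list(stats::setNames(unname(sums), files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}
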