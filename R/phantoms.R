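#' 2D projected iron-concentration phantom
#'
#' A phantom is a 2D map of projected iron amount per pixel (mol Fe), on a
#' FOV-centered Cartesian grid: rows index the travel axis `z` (row 1 at the
#' lowest z), columns index the deflection axis `x`. All generators in this
#' module are deterministic.
#'
#' @param grid numeric matrix of non-negative iron amounts (mol Fe per pixel).
#' @param pixel_size pixel edge length in m.
#' @param origin length-2 FOV-centered offset of the grid center in m.
#' @param label free-text label.
#' @return An object of class `mpi_phantom`.
#' @export
phantom <- function(grid, pixel_size, origin = c(0, 0), label = "") {
  if (!is.matrix(grid) || !is.numeric(grid)) stop("grid must be a numeric matrix")
  if (any(!is.finite(grid)) || any(grid < 0))
    stop("grid values must be finite and non-negative")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be positive")
  structure(list(grid = grid, pixel_size = pixel_size,
                 origin = as.numeric(origin), label = label),
            class = "mpi_phantom")
}

#' @export
print.mpi_phantom <- function(x, ...) {
  cat(sprintf("<mpi_phantom> '%s': %d x %d px at %g mm, total %.4g mol Fe\n",
              x$label, nrow(x$grid), ncol(x$grid), 1000 * x$pixel_size,
              sum(x$grid)))
  invisible(x)
}

#' @export
plot.mpi_phantom <- function(x, ...) {
  co <- pixel_coords(x)
  graphics::image(co$x, co$z, t(x$grid), asp = 1, xlab = "x [m]",
                  ylab = "z [m]", main = x$label, useRaster = TRUE, ...)
  invisible(x)
}

#' Pixel-center coordinates of a phantom grid
#'
#' @param ph an [phantom()] (or any object with `grid`, `pixel_size`,
#'   `origin`).
#' @return List with `x` (column centers) and `z` (row centers) in m.
#' @export
pixel_coords <- function(ph) {
  nr <- nrow(ph$grid); nc <- ncol(ph$grid)
  list(x = (seq_len(nc) - (nc + 1) / 2) * ph$pixel_size + ph$origin[1],
       z = (seq_len(nr) - (nr + 1) / 2) * ph$pixel_size + ph$origin[2])
}

# Internal: physical extent (m) of the grid.
phantom_extent <- function(ph) {
  list(x = ncol(ph$grid) * ph$pixel_size, z = nrow(ph$grid) * ph$pixel_size)
}

# Internal: empty FOV-covering grid for a scanner config.
.empty_grid <- function(config, pixel_size) {
  nc <- round(config$fov_x / pixel_size) + 1L
  nr <- round(config$fov_z / pixel_size) + 1L
  matrix(0, nr, nc)
}

#' Iron amount of a diluted tracer volume
#'
#' Converts a dilution of the stock tracer into mol of iron:
#' `(c_stock / dilution_factor) * volume_ml / molar_mass`, with the
#' milligram-to-gram conversion applied.
#'
#' @param c_stock stock iron concentration in mg/ml.
#' @param dilution_factor dilution factor (e.g. 100 for a 1:100 dilution).
#' @param volume_ml sample volume in ml.
#' @param molar_mass molar mass of iron in g/mol.
#' @return Iron amount in mol.
#' @export
#' @examples
#' dilution_to_mol(8.5, 100, 1)  # ~1.5e-6 mol (1.5 umol)
dilution_to_mol <- function(c_stock = 8.5, dilution_factor = 1, volume_ml = 1,
                            molar_mass = 55.845) {
  if (c_stock <= 0 || molar_mass <= 0) stop("c_stock and molar_mass must be positive")
  if (dilution_factor <= 0) stop("dilution_factor must be positive")
  if (volume_ml < 0) stop("volume_ml must be non-negative")
  (c_stock / dilution_factor) * volume_ml / 1000 / molar_mass
}

#' Tracer dose limit for a reference person
#'
#' @param mg_per_kg dose limit per body mass, mg Fe / kg.
#' @param body_mass_kg body mass in kg.
#' @return Total allowed iron dose in mg.
#' @export
#' @examples
#' dose_limit(2.5, 80)  # 200 mg
dose_limit <- function(mg_per_kg = 2.5, body_mass_kg = 80) {
  if (mg_per_kg < 0 || body_mass_kg <= 0)
    stop("arguments must be positive (mg_per_kg may be 0)")
  mg_per_kg * body_mass_kg
}

#' Point-like sample phantom
#'
#' A uniform disc (an Eppendorf cap seen in projection) carrying a total iron
#' amount of `iron_mol`, exactly conserved on the grid.
#'
#' @param position length-2 `c(x, z)` center in m; must lie inside the FOV.
#' @param iron_mol total iron amount in mol.
#' @param sample_diameter disc diameter in m.
#' @param config a [scanner_config()] fixing the FOV.
#' @param pixel_size grid pixel size in m.
#' @param volume_ml nominal sample volume in ml (metadata only).
#' @return An [phantom()].
#' @export
#' @examples
#' ph <- point_sample(c(0.01, 0), iron_mol = dilution_to_mol(8.5, 800, 1))
#' sum(ph$grid)  # equals the requested amount
point_sample <- function(position, iron_mol, sample_diameter = 0.009,
                         config = scanner_config(), pixel_size = 0.001,
                         volume_ml = 1) {
  if (length(position) != 2 || any(!is.finite(position)))
    stop("position must be finite c(x, z)")
  if (abs(position[1]) > config$fov_x / 2 || abs(position[2]) > config$fov_z / 2)
    stop("position lies outside the FOV")
  if (iron_mol < 0) stop("iron_mol must be non-negative")
  grid <- .empty_grid(config, pixel_size)
  ph <- phantom(grid, pixel_size,
                label = sprintf("point sample %.3g mol Fe", iron_mol))
  co <- pixel_coords(ph)
  d2 <- outer(co$z - position[2], co$x - position[1],
              function(a, b) a^2 + b^2)
  mask <- d2 <= (sample_diameter / 2)^2
  if (!any(mask)) {   # disc smaller than one pixel: use the nearest pixel
    mask[which.min(d2)] <- TRUE
  }
  grid[mask] <- iron_mol / sum(mask)
  ph$grid <- grid
  ph
}

#' Vessel geometry specification
#'
#' Describes a tubular vessel along a polyline path, with an optional
#' cosine-tapered stenosis (fractional lumen narrowing over a finite length),
#' an optional spherical aneurysm bulge, and an optional perpendicular branch
#' segment (the scenario that produces the orientation-dependent
#' pseudo-stenosis artifact).
#'
#' @param parent_diameter lumen diameter of the parent vessel in m.
#' @param path 2-column matrix of `(x, z)` polyline vertices in m; default a
#'   straight segment along `z` through the FOV center.
#' @param stenosis_grade fractional diameter narrowing in `[0, 1]` (0 = none).
#' @param stenosis_length taper length in m.
#' @param stenosis_position position of the stenosis center as a fraction of
#'   the path arclength.
#' @param aneurysm_diameter diameter of the spherical bulge in m (0 = none).
#' @param aneurysm_position bulge center as a fraction of path arclength.
#' @param branch optional list with `position` (fraction of arclength),
#'   `length` (m) and `diameter` (m) of a branch perpendicular to the path.
#' @return An object of class `vessel_spec`.
#' @export
vessel_spec <- function(parent_diameter = 0.010,
                        path = cbind(x = c(0, 0), z = c(-0.048, 0.048)),
                        stenosis_grade = 0, stenosis_length = 0.030,
                        stenosis_position = 0.5,
                        aneurysm_diameter = 0, aneurysm_position = 0.5,
                        branch = NULL) {
  if (parent_diameter <= 0) stop("parent_diameter must be positive")
  if (stenosis_grade < 0 || stenosis_grade > 1)
    stop("stenosis_grade must lie in [0, 1]")
  if (stenosis_length <= 0) stop("stenosis_length must be positive")
  if (aneurysm_diameter < 0) stop("aneurysm_diameter must be non-negative")
  path <- as.matrix(path)
  if (ncol(path) != 2 || nrow(path) < 2) stop("path must be an n x 2 polyline, n >= 2")
  if (!is.null(branch)) {
    if (!all(c("position", "length", "diameter") %in% names(branch)))
      stop("branch needs 'position', 'length' and 'diameter'")
  }
  structure(list(parent_diameter = parent_diameter, path = path,
                 stenosis_grade = stenosis_grade,
                 stenosis_length = stenosis_length,
                 stenosis_position = stenosis_position,
                 aneurysm_diameter = aneurysm_diameter,
                 aneurysm_position = aneurysm_position,
                 branch = branch),
            class = "vessel_spec")
}

# Internal: arclength s of the projection onto a polyline and perpendicular
# distance u, for points (px, pz). Returns list(s, u, total_length).
.polyline_su <- function(path, px, pz) {
  nseg <- nrow(path) - 1L
  seg_len <- sqrt(diff(path[, 1])^2 + diff(path[, 2])^2)
  cum0 <- c(0, cumsum(seg_len))
  best_u <- rep(Inf, length(px))
  best_s <- rep(0, length(px))
  for (i in seq_len(nseg)) {
    ax <- path[i, 1]; az <- path[i, 2]
    dx <- path[i + 1, 1] - ax; dz <- path[i + 1, 2] - az
    L2 <- dx * dx + dz * dz
    tpar <- pmin(pmax(((px - ax) * dx + (pz - az) * dz) / L2, 0), 1)
    qx <- ax + tpar * dx; qz <- az + tpar * dz
    d <- sqrt((px - qx)^2 + (pz - qz)^2)
    upd <- d < best_u
    best_u[upd] <- d[upd]
    best_s[upd] <- cum0[i] + tpar[upd] * seg_len[i]
  }
  list(s = best_s, u = best_u, total_length = cum0[nseg + 1L])
}

# Internal: mol Fe per pixel column of chord thickness (m) filled at
# concentration conc mg/ml, for pixel edge px (m). mg/ml == kg/m^3 == 1000 g/m^3.
.chord_to_mol <- function(chord, conc, px, molar_mass = 55.845) {
  chord * px * px * conc * 1000 / molar_mass
}

# Internal: local lumen diameter along arclength with cosine-tapered stenosis.
.lumen_diameter <- function(spec, s, total_length) {
  d <- rep(spec$parent_diameter, length(s))
  if (spec$stenosis_grade > 0) {
    sc <- spec$stenosis_position * total_length
    rel <- (s - sc) / (spec$stenosis_length / 2)
    inside <- abs(rel) <= 1
    w <- numeric(length(s))
    w[inside] <- 0.5 * (1 + cos(pi * rel[inside]))
    d <- spec$parent_diameter * (1 - spec$stenosis_grade * w)
  }
  d
}

#' Projected vessel phantom
#'
#' Builds the x-z projection of a fluid-filled tube along the specified path
#' using the analytic chord-thickness model: a pixel at perpendicular distance
#' `u` from the centerline of a tube with local lumen diameter `d` carries a
#' projected fluid column of `2 * sqrt((d/2)^2 - u^2)`. Within the stenosis
#' the lumen diameter is `parent_diameter * (1 - grade)` at the center of a
#' smooth cosine taper; an aneurysm adds a spherical bulge; a branch adds a
#' perpendicular tube segment.
#'
#' @param spec a [vessel_spec()].
#' @param fill_concentration iron concentration of the filling in mg/ml.
#' @param config a [scanner_config()].
#' @param pixel_size grid pixel size in m.
#' @return An [phantom()] in mol Fe per pixel.
#' @export
#' @examples
#' ph <- vessel_phantom(vessel_spec(stenosis_grade = 0.7), pixel_size = 0.002)
vessel_phantom <- function(spec, fill_concentration = 8.5,
                           config = scanner_config(), pixel_size = 0.001) {
  stopifnot(inherits(spec, "vessel_spec"))
  if (fill_concentration < 0) stop("fill_concentration must be non-negative")
  if (any(abs(spec$path[, 1]) > config$fov_x / 2 + 1e-12) ||
      any(abs(spec$path[, 2]) > config$fov_z / 2 + 1e-12))
    stop("vessel path exits the grid")
  grid <- .empty_grid(config, pixel_size)
  ph <- phantom(grid, pixel_size, label = "vessel")
  co <- pixel_coords(ph)
  pz <- rep(co$z, times = length(co$x))
  px <- rep(co$x, each = length(co$z))
  su <- .polyline_su(spec$path, px, pz)
  d <- .lumen_diameter(spec, su$s, su$total_length)
  half <- d / 2
  chord <- 2 * sqrt(pmax(half^2 - su$u^2, 0))

  if (spec$aneurysm_diameter > 0) {
    ctr <- .point_at_arclength(spec$path, spec$aneurysm_position * su$total_length)
    rr2 <- (px - ctr[1])^2 + (pz - ctr[2])^2
    sph <- 2 * sqrt(pmax((spec$aneurysm_diameter / 2)^2 - rr2, 0))
    chord <- pmax(chord, sph)
  }
  if (!is.null(spec$branch)) {
    br <- .branch_path(spec$path, spec$branch)
    sub <- .polyline_su(br, px, pz)
    bch <- 2 * sqrt(pmax((spec$branch$diameter / 2)^2 - sub$u^2, 0))
    chord <- pmax(chord, bch)
  }
  ph$grid <- matrix(.chord_to_mol(chord, fill_concentration, pixel_size),
                    nrow(grid), ncol(grid))
  ph$label <- sprintf("vessel (grade %.2f)", spec$stenosis_grade)
  ph
}

# Internal: point on polyline at arclength s.
.point_at_arclength <- function(path, s) {
  seg_len <- sqrt(diff(path[, 1])^2 + diff(path[, 2])^2)
  cum0 <- c(0, cumsum(seg_len))
  s <- min(max(s, 0), cum0[length(cum0)])
  i <- findInterval(s, cum0, all.inside = TRUE)
  f <- (s - cum0[i]) / seg_len[i]
  c(path[i, 1] + f * (path[i + 1, 1] - path[i, 1]),
    path[i, 2] + f * (path[i + 1, 2] - path[i, 2]))
}

# Internal: perpendicular branch polyline at a fraction of the parent path.
.branch_path <- function(path, branch) {
  seg_len <- sqrt(diff(path[, 1])^2 + diff(path[, 2])^2)
  total <- sum(seg_len)
  s <- branch$position * total
  p0 <- .point_at_arclength(path, s)
  # direction of the containing segment
  cum0 <- c(0, cumsum(seg_len))
  i <- findInterval(s, cum0, all.inside = TRUE)
  dir <- c(path[i + 1, 1] - path[i, 1], path[i + 1, 2] - path[i, 2])
  dir <- dir / sqrt(sum(dir^2))
  perp <- c(-dir[2], dir[1])
  rbind(p0, p0 + perp * branch$length)
}

#' Time-varying phantom sequence
#'
#' @param frames list of [phantom()]s sharing one grid geometry.
#' @param frame_rate frames per second.
#' @param flow_profile numeric vector of the pulsatile velocity (m/s) sampled
#'   over the sequence.
#' @return An object of class `dynamic_phantom`.
#' @export
dynamic_phantom <- function(frames, frame_rate = 4, flow_profile = numeric(0)) {
  if (!length(frames) || !all(vapply(frames, inherits, TRUE, "mpi_phantom")))
    stop("frames must be a non-empty list of phantoms")
  dims <- vapply(frames, function(f) dim(f$grid), integer(2))
  if (any(dims != dims[, 1]))
    stop("all frames must share the grid geometry")
  structure(list(frames = frames, frame_rate = frame_rate,
                 flow_profile = flow_profile),
            class = "dynamic_phantom")
}

#' @export
print.dynamic_phantom <- function(x, ...) {
  cat(sprintf("<dynamic_phantom> %d frames at %g fps, peak flow %.3g m/s\n",
              length(x$frames), x$frame_rate,
              if (length(x$flow_profile)) max(x$flow_profile) else NA))
  invisible(x)
}

# Internal: displaced arclength under a rectified-sinusoid pulsatile profile
# v(t) = peak * |sin(pi * pulse_freq * t)| integrated from 0 to t (closed form).
.pulsatile_displacement <- function(t, peak, pulse_freq = 1) {
  tau <- t * pulse_freq
  whole <- floor(tau)
  fracp <- tau - whole
  (peak / pulse_freq) * (2 * whole + (1 - cos(pi * fracp))) / pi
}

#' Traveling tracer bolus under pulsatile flow
#'
#' Generates a frame sequence of a bolus advancing along the vessel path. The
#' velocity follows a rectified sinusoid at `pulse_freq` (default 1 Hz) scaled
#' to `peak_velocity`; the bolus occupies a contiguous arclength window whose
#' length follows from the bolus volume and the local lumen, and total iron is
#' conserved until the bolus reaches the end of the path, after which it
#' decreases.
#'
#' @param spec a [vessel_spec()].
#' @param bolus_volume_ml injected volume in ml.
#' @param bolus_iron total injected iron in mol (default: 1 ml of undiluted
#'   8.5 mg/ml stock).
#' @param peak_velocity peak pulsatile velocity in m/s.
#' @param frame_rate frames per second.
#' @param n_frames number of frames.
#' @param pulse_freq pulse frequency in 1/s.
#' @param profile `"pulsatile"` (rectified sinusoid, the default) or
#'   `"constant"` (steady flow at `peak_velocity`).
#' @param config a [scanner_config()].
#' @param pixel_size grid pixel size in m.
#' @return A [dynamic_phantom()]; its `flow_profile` samples the velocity at
#'   1 ms resolution over the sequence.
#' @export
bolus_sequence <- function(spec, bolus_volume_ml = 1,
                           bolus_iron = dilution_to_mol(8.5, 1, 1),
                           peak_velocity = 0.5, frame_rate = 4, n_frames = 8,
                           pulse_freq = 1, profile = c("pulsatile", "constant"),
                           config = scanner_config(), pixel_size = 0.001) {
  stopifnot(inherits(spec, "vessel_spec"))
  profile <- match.arg(profile)
  if (peak_velocity <= 0) stop("peak_velocity must be positive")
  area <- pi * (spec$parent_diameter / 2)^2
  bolus_len <- bolus_volume_ml * 1e-6 / area

  grid <- .empty_grid(config, pixel_size)
  ph0 <- phantom(grid, pixel_size, label = "bolus")
  co <- pixel_coords(ph0)
  pz <- rep(co$z, times = length(co$x))
  px <- rep(co$x, each = length(co$z))
  su <- .polyline_su(spec$path, px, pz)
  d <- .lumen_diameter(spec, su$s, su$total_length)
  chord <- 2 * sqrt(pmax((d / 2)^2 - su$u^2, 0))

  window_weight <- function(s0, s1) {
    w <- chord
    w[su$s < s0 | su$s > s1] <- 0
    w
  }
  # Normalization is frozen at the last frame whose window is fully interior,
  # so total iron is conserved exactly until the bolus reaches the path end
  # and decreases as it is truncated afterwards.
  frames <- vector("list", n_frames)
  scale_i <- NA_real_
  for (i in seq_len(n_frames)) {
    t_i <- (i - 1) / frame_rate
    adv <- if (profile == "constant") peak_velocity * t_i else
      .pulsatile_displacement(t_i, peak_velocity, pulse_freq)
    w <- window_weight(adv, adv + bolus_len)
    if (adv + bolus_len <= su$total_length + 1e-12 && sum(w) > 0)
      scale_i <- bolus_iron / sum(w)
    if (is.na(scale_i)) scale_i <- 0
    g <- matrix(w * scale_i, nrow(grid), ncol(grid))
    frames[[i]] <- phantom(g, pixel_size,
                           label = sprintf("bolus frame %d (t = %.2f s)", i, t_i))
  }
  tt <- seq(0, n_frames / frame_rate, by = 1e-3)
  vel <- if (profile == "constant") rep(peak_velocity, length(tt)) else
    peak_velocity * abs(sin(pi * pulse_freq * tt))
  dynamic_phantom(frames, frame_rate, flow_profile = vel)
}

#' Marker phantom for MPI-visible instruments
#'
#' A guidewire carries one point-like marker at its tip; a balloon catheter
#' carries two markers separated by `marker_spacing` along the device axis.
#'
#' @param kind `"guidewire"` or `"balloon"`.
#' @param tip_position length-2 `c(x, z)` of the tip marker in m.
#' @param marker_iron iron per marker in mol.
#' @param marker_spacing distance between the two balloon markers in m.
#' @param marker_diameter marker disc diameter in m.
#' @param axis length-2 device axis direction (normalized internally).
#' @param config a [scanner_config()].
#' @param pixel_size grid pixel size in m.
#' @return An [phantom()].
#' @export
#' @examples
#' instrument_phantom("balloon", c(0, -0.02))
instrument_phantom <- function(kind = c("guidewire", "balloon"),
                               tip_position, marker_iron = 2e-5,
                               marker_spacing = 0.037,
                               marker_diameter = 0.004,
                               axis = c(0, 1),
                               config = scanner_config(), pixel_size = 0.001) {
  kind <- match.arg(kind)
  axis <- axis / sqrt(sum(axis^2))
  centers <- list(tip_position)
  if (kind == "balloon")
    centers <- c(centers, list(tip_position + axis * marker_spacing))
  for (ctr in centers) {
    if (abs(ctr[1]) > config$fov_x / 2 || abs(ctr[2]) > config$fov_z / 2)
      stop("marker position lies outside the FOV")
  }
  out <- NULL
  for (ctr in centers) {
    p <- point_sample(ctr, iron_mol = marker_iron,
                      sample_diameter = marker_diameter,
                      config = config, pixel_size = pixel_size)
    out <- if (is.null(out)) p else { out$grid <- out$grid + p$grid; out }
  }
  out$label <- sprintf("%s markers", kind)
  out
}

# 5 x 7 bitmap glyphs for the lettering phantom.
.glyphs <- list(
  "i" = c("..X..",
          ".....",
          ".XX..",
          "..X..",
          "..X..",
          "..X..",
          ".XXX."),
  "I" = c("XXXXX",
          "..X..",
          "..X..",
          "..X..",
          "..X..",
          "..X..",
          "XXXXX"),
  "M" = c("X...X",
          "XX.XX",
          "X.X.X",
          "X.X.X",
          "X...X",
          "X...X",
          "X...X"),
  "P" = c("XXXX.",
          "X...X",
          "X...X",
          "XXXX.",
          "X....",
          "X....",
          "X...."),
  " " = c(".....", ".....", ".....", ".....", ".....", ".....", ".....")
)

#' Lettering phantom
#'
#' Deterministic binary glyph map (5 x 7 bitmap font, upscaled to about 60%
#' of the FOV width), uniform concentration, as a structured test
#' distribution for the imaging chain.
#'
#' @param text text to render; supported characters: `i`, `I`, `M`, `P` and
#'   space.
#' @param total_iron total iron over the lettering in mol.
#' @param width_frac lettering width as a fraction of the FOV width.
#' @param config a [scanner_config()].
#' @param pixel_size grid pixel size in m.
#' @return An [phantom()].
#' @export
#' @examples
#' ph <- lettering_phantom("iMPI", pixel_size = 0.002)
lettering_phantom <- function(text = "iMPI", total_iron = 1e-5,
                              width_frac = 0.6,
                              config = scanner_config(), pixel_size = 0.001) {
  chars <- strsplit(text, "")[[1]]
  bad <- setdiff(chars, names(.glyphs))
  if (length(bad))
    stop("unsupported characters: ", paste(unique(bad), collapse = ", "),
         " (supported: ", paste(names(.glyphs), collapse = ""), ")")
  if (total_iron <= 0) stop("total_iron must be positive")
  glyph_w <- 5L; glyph_h <- 7L; gap <- 1L
  w_small <- length(chars) * (glyph_w + gap) - gap
  small <- matrix(0L, glyph_h, w_small)
  for (i in seq_along(chars)) {
    g <- .glyphs[[chars[i]]]
    bits <- do.call(rbind, lapply(g, function(row)
      as.integer(strsplit(row, "")[[1]] == "X")))
    small[, (i - 1L) * (glyph_w + gap) + seq_len(glyph_w)] <- bits
  }
  small <- small[glyph_h:1, , drop = FALSE]  # row 1 = lowest z

  grid <- .empty_grid(config, pixel_size)
  scale <- max(1L, floor(width_frac * ncol(grid) / w_small))
  big <- small[rep(seq_len(nrow(small)), each = scale),
               rep(seq_len(ncol(small)), each = scale), drop = FALSE]
  if (nrow(big) > nrow(grid) || ncol(big) > ncol(grid))
    stop("lettering does not fit the grid; reduce width_frac or text length")
  r0 <- floor((nrow(grid) - nrow(big)) / 2)
  c0 <- floor((ncol(grid) - ncol(big)) / 2)
  grid[r0 + seq_len(nrow(big)), c0 + seq_len(ncol(big))] <- big
  grid <- grid * (total_iron / sum(grid))
  phantom(grid, pixel_size, label = sprintf("lettering '%s'", text))
}
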