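#' Scanner configuration for a traveling-FFL projection MPI system
#'
#' Collects all drive and geometry parameters of the field generator: the two
#' low-frequency channels (CH1/CH2, saddle-coil pairs driven 90 degrees out of
#' phase) that generate a field-free line (FFL) traveling along the scanner
#' axis `z`, and the deflection channel (CH3) that steers the FFL sinusoidally
#' along `x` so that the FFL paints 2D projections of the tracer distribution
#' in the x-z plane.
#'
#' The default frequencies (`f1 = f2 = 60` Hz, `f3 = 2480` Hz) make one 50 ms
#' acquisition window commensurate with both drives: it contains exactly
#' 3 periods of `f1` and 124 periods of `f3`, so the FFL trajectory repeats
#' every 50 ms and every harmonic sideband `n*f3 + k*f1` falls exactly on a
#' 20 Hz FFT bin of the window.
#'
#' The gradient scales linearly with the CH1/2 current: the operating gradient
#' stored in `$gradient` equals `gradient_full * I_ch12 / I_ch12_full`
#' (0.24 T/m at the default operating currents).
#'
#' @param f1,f2 drive frequencies of CH1 and CH2 in Hz; must be equal.
#' @param f3 deflection frequency of CH3 in Hz; must exceed `f1`.
#' @param phase12 CH1-CH2 phase shift in radians (default `pi/2`), which turns
#'   the two standing fields into a traveling wave.
#' @param gradient_full FFL gradient at full current, T/m.
#' @param I_ch12_full,I_ch3_full full-power channel currents, A.
#' @param I_ch12,I_ch3 operating channel currents, A.
#' @param fov_x,fov_z field-of-view extents in m (deflection axis x,
#'   travel axis z).
#' @param ffl_spacing distance in m between adjacent traveling FFLs of
#'   opposite gradient polarity; default one FOV length, i.e. exactly one FFL
#'   crosses the FOV per half period of `f1`.
#' @param x_max peak FFL deflection in m; at most `fov_x / 2`.
#' @param B_pp peak-to-peak drive amplitude in T (safety bookkeeping).
#' @param T_acq acquisition window in s.
#' @param dt_burst burst duty cycle in s (one frame incl. overhead).
#' @param fs sampling rate in samples/s. Must satisfy `fs > 2 * n_max * f3`.
#' @param ramp_time transient settle delay in s between waveform start and the
#'   beginning of the acquisition window.
#' @param n_max highest drive-field harmonic retained anywhere downstream;
#'   sets the Nyquist requirement on `fs`.
#'
#' @return An object of class `scanner_config`: a validated list of the above
#'   plus `gradient` (operating gradient, T/m) and `commensurate` (logical,
#'   TRUE when `T_acq * f1` and `T_acq * f3` are both integers).
#' @export
#' @examples
#' cfg <- scanner_config()
#' cfg$gradient            # 0.24 T/m at 110/165 of full current
#' cfg$T_acq * cfg$f3      # 124 deflection periods per acquisition
scanner_config <- function(f1 = 60, f2 = f1, f3 = 2480, phase12 = pi / 2,
                           gradient_full = 0.36,
                           I_ch12_full = 165, I_ch3_full = 110,
                           I_ch12 = 110, I_ch3 = 75,
                           fov_x = 0.11, fov_z = 0.12,
                           ffl_spacing = fov_z, x_max = fov_x / 2,
                           B_pp = 0.070,
                           T_acq = 0.050, dt_burst = 0.060,
                           fs = 496000, ramp_time = 0.010,
                           n_max = 25) {
  num_ok <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in c("f1", "f2", "f3", "phase12", "gradient_full", "I_ch12_full",
               "I_ch3_full", "I_ch12", "I_ch3", "fov_x", "fov_z",
               "ffl_spacing", "x_max", "B_pp", "T_acq", "dt_burst", "fs",
               "ramp_time", "n_max")) {
    if (!num_ok(get(nm))) stop("'", nm, "' must be a finite numeric scalar")
  }
  if (f1 != f2) stop("f1 and f2 must be equal (traveling-wave condition)")
  if (f3 <= f1) stop("f3 must exceed f1")
  if (f1 <= 0 || fs <= 0 || T_acq <= 0) stop("frequencies, fs and T_acq must be positive")
  if (gradient_full <= 0) stop("gradient_full must be positive")
  if (I_ch12 <= 0 || I_ch12_full <= 0 || I_ch3 <= 0 || I_ch3_full <= 0)
    stop("currents must be positive")
  if (I_ch12 > I_ch12_full || I_ch3 > I_ch3_full)
    stop("operating currents may not exceed full-power currents")
  if (fov_x <= 0 || fov_z <= 0 || ffl_spacing <= 0)
    stop("FOV extents and ffl_spacing must be positive")
  if (x_max > fov_x / 2 + 1e-12)
    stop("x_max must not exceed fov_x / 2")
  if (dt_burst < T_acq) stop("dt_burst must be at least T_acq")
  if (ramp_time < 0) stop("ramp_time must be non-negative")
  if (n_max < 1) stop("n_max must be at least 1")
  if (fs <= 2 * n_max * f3)
    stop(sprintf(
      "fs = %g S/s violates the Nyquist requirement fs > 2 * n_max * f3 = %g Hz",
      fs, 2 * n_max * f3))

  int_tol <- 1e-9
  commensurate <- abs(T_acq * f1 - round(T_acq * f1)) < int_tol &&
    abs(T_acq * f3 - round(T_acq * f3)) < int_tol

  structure(list(
    f1 = f1, f2 = f2, f3 = f3, phase12 = phase12,
    gradient_full = gradient_full,
    I_ch12_full = I_ch12_full, I_ch3_full = I_ch3_full,
    I_ch12 = I_ch12, I_ch3 = I_ch3,
    gradient = gradient_full * I_ch12 / I_ch12_full,
    fov_x = fov_x, fov_z = fov_z,
    ffl_spacing = ffl_spacing, x_max = x_max,
    B_pp = B_pp, T_acq = T_acq, dt_burst = dt_burst,
    fs = fs, ramp_time = ramp_time, n_max = n_max,
    commensurate = commensurate
  ), class = "scanner_config")
}

#' @export
print.scanner_config <- function(x, ...) {
  cat("<scanner_config>\n")
  cat(sprintf("  drive: f1 = f2 = %g Hz, f3 = %g Hz, phase12 = %.3f rad\n",
              x$f1, x$f3, x$phase12))
  cat(sprintf("  currents: CH1/2 %g A (full %g A), CH3 %g A (full %g A)\n",
              x$I_ch12, x$I_ch12_full, x$I_ch3, x$I_ch3_full))
  cat(sprintf("  gradient: %.3f T/m operating (%.2f T/m at full current)\n",
              x$gradient, x$gradient_full))
  cat(sprintf("  FOV: %g x %g cm (x, z), x_max = %g cm, FFL spacing = %g cm\n",
              100 * x$fov_x, 100 * x$fov_z, 100 * x$x_max, 100 * x$ffl_spacing))
  cat(sprintf("  acquisition: %g ms at %g kS/s (%d samples), burst %g ms, ramp %g ms\n",
              1000 * x$T_acq, x$fs / 1000, round(x$T_acq * x$fs),
              1000 * x$dt_burst, 1000 * x$ramp_time))
  cat(sprintf("  commensurate: %s (T_acq * f1 = %g, T_acq * f3 = %g)\n",
              x$commensurate, x$T_acq * x$f1, x$T_acq * x$f3))
  invisible(x)
}

# Internal: traveling-wave FFL state at absolute waveform times t (vector).
# The wave advances one ffl_spacing per half period of f1; two FFLs of
# opposite gradient polarity are ffl_spacing apart, so the polarity of the
# FFL crossing the FOV alternates between consecutive z-passes.
.ffl_state <- function(config, t) {
  phase <- 2 * config$f1 * t            # passes since t = 0 (1 pass = 1/(2 f1))
  pass_index <- floor(phase)
  frac <- phase - pass_index
  sign <- 1 - 2 * (pass_index %% 2)     # +1 on even passes
  z <- -config$fov_z / 2 + frac * config$ffl_spacing
  x <- config$x_max * sin(2 * pi * config$f3 * t)
  sweep <- ifelse(cos(2 * pi * config$f3 * t) >= 0, 1L, -1L)
  list(x = x, z = z, sign = sign, sweep = sweep, pass_index = pass_index)
}

#' Time-resolved FFL position
#'
#' Evaluates the idealized traveling-wave trajectory: the FFL deflects
#' sinusoidally along `x` at the CH3 frequency, `x(t) = x_max sin(2 pi f3 t)`,
#' while its `z` position advances linearly with the traveling-wave phase
#' `2 pi f1 t`, wrapping by one `ffl_spacing` every half period of `f1` with
#' alternating gradient polarity.
#'
#' @param config a [scanner_config()].
#' @param t time(s) in seconds since waveform start; non-negative and finite.
#' @return A data frame with one row per time point and columns `t`, `x`, `z`
#'   (m), `sign` (gradient polarity, +-1), `G` (local gradient magnitude,
#'   T/m) and `pass_index` (which z-sweep).
#' @export
#' @examples
#' ffl_position(scanner_config(), c(0, 0.0125, 0.025))
ffl_position <- function(config, t) {
  stopifnot(inherits(config, "scanner_config"))
  if (!is.numeric(t) || any(!is.finite(t))) stop("t must be finite numeric")
  if (any(t < 0)) stop("t must be non-negative")
  st <- .ffl_state(config, t)
  data.frame(t = t, x = st$x, z = st$z, sign = st$sign,
             G = config$gradient, pass_index = st$pass_index)
}

#' Idealized field magnitude near the traveling FFL
#'
#' Local analytic model of the encoding field: the field vanishes exactly on
#' each FFL and grows linearly with perpendicular distance (in the x-z plane)
#' from it, with slope equal to the operating gradient `G` and sign given by
#' the polarity of the nearest FFL. Along the travel axis the signed value is
#' a triangle wave with zeros on the FFLs, so the field is continuous and
#' piecewise linear between adjacent FFLs of opposite polarity.
#'
#' @param config a [scanner_config()].
#' @param r a length-2 numeric `c(x, z)` or an n x 2 matrix of positions in m
#'   (FOV-centered coordinates). Positions must lie within a bounding box of
#'   twice the FOV.
#' @param t scalar time in s.
#' @return Signed field value(s) in T; `abs()` gives the magnitude
#'   `G * distance-to-FFL`.
#' @export
#' @examples
#' cfg <- scanner_config()
#' field_at(cfg, c(0.01, 0), 0)   # 1 cm from the t = 0 FFL foot point
field_at <- function(config, r, t) {
  stopifnot(inherits(config, "scanner_config"))
  if (is.null(dim(r))) r <- matrix(r, ncol = 2)
  if (ncol(r) != 2) stop("r must be c(x, z) or an n x 2 matrix")
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0)
    stop("t must be a finite non-negative scalar")
  if (any(abs(r[, 1]) > config$fov_x) || any(abs(r[, 2]) > config$fov_z))
    stop("positions must lie within twice the FOV")
  st <- .ffl_state(config, t)
  dx <- r[, 1] - st$x
  dz0 <- r[, 2] - st$z
  j <- round(dz0 / config$ffl_spacing)
  dz <- dz0 - j * config$ffl_spacing
  sgn <- st$sign * (1 - 2 * (abs(j) %% 2))   # polarity of the nearest FFL
  out <- sgn * ifelse(dz >= 0, 1, -1) * config$gradient * sqrt(dx^2 + dz^2)
  as.numeric(out)
}

#' Gradient at a fractional drive current
#'
#' The FFL gradient scales linearly with the CH1/2 current, so a system run
#' at a fraction of full power produces that same fraction of the full-power
#' gradient (e.g. 0.36 T/m at full current gives about 0.25 T/m at 70%).
#'
#' @param config a [scanner_config()].
#' @param fraction fraction of full current in `[0, 1]`.
#' @return Gradient in T/m.
#' @export
#' @examples
#' gradient_at_fraction(scanner_config(), 0.70)  # ~0.25 T/m
gradient_at_fraction <- function(config, fraction) {
  stopifnot(inherits(config, "scanner_config"))
  if (!is.numeric(fraction) || any(!is.finite(fraction)))
    stop("fraction must be finite numeric")
  if (any(fraction < 0 | fraction > 1)) stop("fraction must lie in [0, 1]")
  config$gradient_full * fraction
}

#' Build the acquisition sequence: FFL trajectory plus drive waveforms
#'
#' Samples the FFL trajectory at `fs` over one acquisition window of length
#' `T_acq`, starting `ramp_time` after waveform start (the transient settle
#' delay), and attaches the three sampled drive-current waveforms. Each sample
#' is labeled with `line_index` (which `1/f3` deflection period within the
#' acquisition), `pass_index` (which z-sweep of the traveling wave, fixing the
#' FFL polarity) and `sweep` (deflection direction, +1 while `x` increases).
#'
#' At the default frequency ratio (`f3/f1 = 124/3`) the window holds exactly
#' 124 complete lines spread over 3 `f1` periods and the trajectory repeats
#' with period `T_acq`; an incommensurate `T_acq` is allowed but flagged
#' non-repeating.
#'
#' @param config a [scanner_config()].
#' @return An object of class `mpi_trajectory`: list with `t` (absolute time,
#'   s), `x`, `z`, `sign`, `sweep`, `line_index`, `pass_index` (per sample),
#'   `waveforms` (data frame of CH1/CH2/CH3 currents in A at the same
#'   samples), `config` and `commensurate`.
#' @export
#' @examples
#' traj <- make_sequence(scanner_config(fs = 49600))
#' length(unique(traj$line_index))   # 124 lines per acquisition
make_sequence <- function(config) {
  stopifnot(inherits(config, "scanner_config"))
  if (config$fs <= 2 * config$n_max * config$f3)
    stop(sprintf(
      "fs = %g S/s violates the Nyquist requirement fs > 2 * n_max * f3 = %g Hz",
      config$fs, 2 * config$n_max * config$f3))
  n <- round(config$T_acq * config$fs)
  t0 <- config$ramp_time
  t <- t0 + (seq_len(n) - 1) / config$fs
  st <- .ffl_state(config, t)
  line_index <- floor((t - t0) * config$f3 + 1e-9)
  if (!config$commensurate)
    warning("T_acq is not commensurate with f1 and f3; trajectory does not repeat")
  waveforms <- data.frame(
    t = t,
    ch1 = config$I_ch12 * sin(2 * pi * config$f1 * t),
    ch2 = config$I_ch12 * sin(2 * pi * config$f2 * t + config$phase12),
    ch3 = config$I_ch3 * sin(2 * pi * config$f3 * t)
  )
  structure(list(
    t = t, x = st$x, z = st$z, sign = st$sign, sweep = st$sweep,
    line_index = line_index, pass_index = st$pass_index,
    waveforms = waveforms, config = config,
    commensurate = config$commensurate
  ), class = "mpi_trajectory")
}

#' @export
print.mpi_trajectory <- function(x, ...) {
  cat("<mpi_trajectory>\n")
  cat(sprintf("  %d samples over %g ms at %g kS/s (acquisition starts at %g ms)\n",
              length(x$t), 1000 * x$config$T_acq, x$config$fs / 1000,
              1000 * x$config$ramp_time))
  cat(sprintf("  %d deflection lines, %d z-passes, repeating: %s\n",
              length(unique(x$line_index)), length(unique(x$pass_index)),
              x$commensurate))
  invisible(x)
}

#' Export a trajectory as delimited text
#'
#' Writes one row per sample with columns `t, x, z, sign, sweep, line_index,
#' pass_index`.
#'
#' @param traj an [make_sequence()] trajectory.
#' @param path output file path (CSV).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "mpi_trajectory"))
  df <- data.frame(t = traj$t, x = traj$x, z = traj$z, sign = traj$sign,
                   sweep = traj$sweep, line_index = traj$line_index,
                   pass_index = traj$pass_index)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
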