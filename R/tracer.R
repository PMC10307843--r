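#' Tracer magnetization model
#'
#' Static Langevin description of a superparamagnetic nanoparticle ensemble.
#' The applied field `B` enters through the dimensionless argument
#' `xi = beta * B`; the equilibrium magnetization fraction is the Langevin
#' function [langevin()]. Relaxation dynamics (Neel/Brownian) are not modeled.
#'
#' The default `beta` is calibrated so that at a 0.25 T/m gradient a voxel's
#' magnetization leaves saturation only once the FFL approaches within about
#' 2 mm (`xi = 5` at that distance), consistent with a spatial resolution on
#' the order of 5 mm.
#'
#' @param beta Langevin argument scale in 1/T.
#' @param m_sat saturation signal moment per mol of iron (arbitrary units).
#' @param name tracer label.
#' @param c_stock stock iron concentration in mg/ml.
#' @param molar_mass_fe molar mass of iron in g/mol.
#' @return An object of class `tracer_model`.
#' @export
#' @examples
#' tracer_model()
tracer_model <- function(beta = 1e4, m_sat = 1, name = "Perimag",
                         c_stock = 8.5, molar_mass_fe = 55.845) {
  if (!is.numeric(beta) || length(beta) != 1 || !is.finite(beta) || beta <= 0)
    stop("beta must be a positive scalar")
  if (!is.numeric(m_sat) || m_sat <= 0) stop("m_sat must be positive")
  if (!is.numeric(c_stock) || c_stock <= 0) stop("c_stock must be positive")
  if (!is.numeric(molar_mass_fe) || molar_mass_fe <= 0)
    stop("molar_mass_fe must be positive")
  structure(list(beta = beta, m_sat = m_sat, name = name,
                 c_stock = c_stock, molar_mass_fe = molar_mass_fe),
            class = "tracer_model")
}

#' @export
print.tracer_model <- function(x, ...) {
  cat(sprintf("<tracer_model> %s: beta = %g 1/T, m_sat = %g /mol, stock %g mg/ml\n",
              x$name, x$beta, x$m_sat, x$c_stock))
  invisible(x)
}

#' Measurement noise model
#'
#' White Gaussian noise plus optional fixed-frequency narrowband interference
#' lines (emulating background pickup from active hardware in an unshielded
#' environment). All randomness is fixed by `seed`.
#'
#' @param sigma_white standard deviation of the white noise (signal units).
#' @param interference_lines optional data frame or list with elements
#'   `frequency` (Hz) and `amplitude`.
#' @param seed integer RNG seed.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma_white = 0, interference_lines = NULL, seed = 1L) {
  if (!is.numeric(sigma_white) || sigma_white < 0)
    stop("sigma_white must be non-negative")
  if (!is.null(interference_lines)) {
    interference_lines <- as.data.frame(interference_lines)
    if (!all(c("frequency", "amplitude") %in% names(interference_lines)))
      stop("interference_lines needs 'frequency' and 'amplitude'")
  }
  structure(list(sigma_white = sigma_white,
                 interference_lines = interference_lines,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Langevin function
#'
#' `L(xi) = coth(xi) - 1/xi`, the equilibrium magnetization fraction of a
#' superparamagnetic ensemble. Odd, strictly increasing, bounded by +-1, with
#' `L'(0) = 1/3`. The removable singularity at 0 is evaluated via the series
#' `xi/3 - xi^3/45` for tiny arguments.
#'
#' @param xi dimensionless argument(s); must be finite.
#' @return Magnetization fraction(s) in `(-1, 1)`.
#' @export
#' @examples
#' langevin(c(0, 1, 50))
langevin <- function(xi) {
  if (!is.numeric(xi) || any(!is.finite(xi))) stop("xi must be finite numeric")
  out <- numeric(length(xi))
  small <- abs(xi) < 1e-5
  xs <- xi[small]
  out[small] <- xs / 3 - xs^3 / 45
  xl <- xi[!small]
  out[!small] <- 1 / tanh(xl) - 1 / xl
  out
}

#' A single induced-voltage acquisition
#'
#' Container for one acquisition window of the receive signal.
#'
#' @param samples numeric vector of induced voltage samples (arbitrary units).
#' @param fs sampling rate, S/s.
#' @param t0 start time, s.
#' @param duration window length, s; `length(samples)` must equal
#'   `round(duration * fs)`.
#' @return An object of class `signal_frame`.
#' @export
signal_frame <- function(samples, fs, t0 = 0, duration = length(samples) / fs) {
  if (!is.numeric(samples) || any(!is.finite(samples)))
    stop("samples must be finite numeric")
  if (length(samples) != round(duration * fs))
    stop("length(samples) must equal round(duration * fs)")
  structure(list(samples = as.numeric(samples), fs = fs, t0 = t0,
                 duration = duration), class = "signal_frame")
}

#' @export
print.signal_frame <- function(x, ...) {
  cat(sprintf("<signal_frame> %d samples, %g ms at %g kS/s, t0 = %g ms, rms = %.3g\n",
              length(x$samples), 1000 * x$duration, x$fs / 1000, 1000 * x$t0,
              sqrt(mean(x$samples^2))))
  invisible(x)
}

# Internal: magnetization time course of point amounts at (xs, zs).
# Around the FFL the encoding field is quadrupolar: |B| = G * rho with
# rho the in-plane distance to the line, and the receive coil picks up the
# transverse magnetization component, giving the geometric factor dz/rho.
# Returns total receive-direction magnetization per time sample.
.magnetization <- function(traj, tracer, xs, zs, amounts) {
  cfg <- traj$config
  n <- length(traj$t)
  m <- numeric(n)
  if (length(xs) == 0) return(m)
  beta_g <- tracer$beta * cfg$gradient
  for (i in seq_along(xs)) {
    dx <- xs[i] - traj$x
    dz0 <- zs[i] - traj$z
    j <- round(dz0 / cfg$ffl_spacing)
    dz <- dz0 - j * cfg$ffl_spacing
    sgn <- traj$sign * (1 - 2 * (abs(j) %% 2))
    rho <- sqrt(dx * dx + dz * dz)
    geo <- dz / rho
    geo[rho == 0] <- 0
    m <- m + (amounts[i] * tracer$m_sat) * sgn * geo * langevin(beta_g * rho)
  }
  m
}

#' Simulate the induced receive signal for a phantom
#'
#' Forward model of signal formation: every tracer voxel carries a Langevin
#' magnetization in the local FFL encoding field; the receive coil (assumed
#' homogeneously sensitive over the FOV) measures `s = -dM/dt`, evaluated by
#' central finite differences along the sample axis. The model is exactly
#' linear in the phantom concentration map. Optional seeded noise is added
#' after signal formation.
#'
#' @param phantom an [phantom()] whose grid covers the FOV.
#' @param traj a trajectory from [make_sequence()].
#' @param tracer a [tracer_model()].
#' @param noise optional [noise_model()]; `NULL` for a noise-free frame.
#' @return A [signal_frame()] of `round(T_acq * fs)` samples.
#' @export
#' @examples
#' cfg <- scanner_config(fs = 49600)
#' traj <- make_sequence(cfg)
#' ph <- point_sample(c(0.01, 0), iron_mol = 1.5e-6, config = cfg,
#'                    pixel_size = 0.004)
#' fr <- simulate_frame(ph, traj, tracer_model())
simulate_frame <- function(phantom, traj, tracer, noise = NULL) {
  stopifnot(inherits(phantom, "mpi_phantom"), inherits(traj, "mpi_trajectory"),
            inherits(tracer, "tracer_model"))
  cfg <- traj$config
  ext <- phantom_extent(phantom)
  if (ext$x < cfg$fov_x - 1e-9 || ext$z < cfg$fov_z - 1e-9)
    stop("phantom grid does not cover the FOV")
  if (!is.null(noise) && !inherits(noise, "noise_model"))
    stop("noise must be a noise_model or NULL")

  nz <- which(phantom$grid != 0)
  co <- pixel_coords(phantom)
  idx <- arrayInd(nz, dim(phantom$grid))
  m <- .magnetization(traj, tracer,
                      xs = co$x[idx[, 2]], zs = co$z[idx[, 1]],
                      amounts = phantom$grid[nz])
  n <- length(m)
  s <- numeric(n)
  if (n >= 3) {
    s[2:(n - 1)] <- -(m[3:n] - m[1:(n - 2)]) * cfg$fs / 2
    s[1] <- -(m[2] - m[1]) * cfg$fs
    s[n] <- -(m[n] - m[n - 1]) * cfg$fs
  }
  if (!is.null(noise)) {
    set.seed(noise$seed)
    if (noise$sigma_white > 0)
      s <- s + stats::rnorm(n, sd = noise$sigma_white)
    if (!is.null(noise$interference_lines)) {
      for (i in seq_len(nrow(noise$interference_lines))) {
        s <- s + noise$interference_lines$amplitude[i] *
          cos(2 * pi * noise$interference_lines$frequency[i] * traj$t)
      }
    }
  }
  signal_frame(s, fs = cfg$fs, t0 = cfg$ramp_time, duration = cfg$T_acq)
}

#' Frequency of a harmonic sideband
#'
#' The deflection drive at `f3` mixes with the traveling wave at `f1`, so the
#' particle signal appears at combination frequencies `n * f3 + k * f1`
#' (e.g. the first sideband of the 5th harmonic, `5 * f3 + 2 * f1`, lies at
#' 12,520 Hz for the default drives).
#'
#' @param config a [scanner_config()].
#' @param n harmonic order of `f3` (integer, `n >= 1`).
#' @param k sideband order of `f1` (integer, may be negative).
#' @return Frequency in Hz.
#' @export
#' @examples
#' harmonic_freq(scanner_config(), 5, 2)  # 12520
harmonic_freq <- function(config, n, k = 0) {
  stopifnot(inherits(config, "scanner_config"))
  if (any(n < 1)) stop("n must be >= 1")
  n * config$f3 + k * config$f1
}

# Internal: FFT bin index (1-based) of frequency f for a frame of duration T.
.bin_of <- function(f, duration) round(f * duration) + 1L

#' Sideband decomposition of a signal frame
#'
#' Reads the complex amplitude of every harmonic sideband `n * f3 + k * f1`
#' (for `n = 1..n_max`, `|k| <= k_max`) directly off the FFT of the frame.
#' This requires the frame duration to be commensurate with both drives so
#' that each sideband falls exactly on an FFT bin. A per-band SNR is estimated
#' as the band magnitude divided by the median magnitude of the 20 nearest
#' bins that belong to no sideband of the evaluated set.
#'
#' @param frame a [signal_frame()].
#' @param config the [scanner_config()] the frame was acquired with.
#' @param n_max highest harmonic order evaluated.
#' @param k_max largest sideband order `|k|` evaluated.
#' @return An object of class `mpi_spectrum`: a list with `components` (data
#'   frame of `n`, `k`, `frequency`, complex `amplitude`, `magnitude`, `snr`),
#'   `noise_floor` (median per-band floor) and the window metadata.
#' @export
spectrum_of <- function(frame, config, n_max = 7, k_max = 20) {
  stopifnot(inherits(frame, "signal_frame"), inherits(config, "scanner_config"))
  dur <- frame$duration
  off1 <- config$f1 * dur - round(config$f1 * dur)
  off3 <- config$f3 * dur - round(config$f3 * dur)
  if (abs(off1) > 1e-6 || abs(off3) > 1e-6)
    stop(sprintf(paste0(
      "frame duration is not commensurate with the drives: ",
      "f1 and f3 fall %.4g and %.4g bins off the FFT grid"), off1, off3))
  n_samp <- length(frame$samples)
  x <- stats::fft(frame$samples)
  nyq_bin <- floor(n_samp / 2)

  comp <- expand.grid(k = -k_max:k_max, n = seq_len(n_max))
  comp$frequency <- comp$n * config$f3 + comp$k * config$f1
  comp <- comp[comp$frequency > 0 & comp$frequency < frame$fs / 2, ]
  comp$bin <- .bin_of(comp$frequency, dur)
  # one bin may be reachable by several (n, k); keep the smallest |k|
  comp <- comp[order(comp$bin, abs(comp$k), comp$k), ]
  comp <- comp[!duplicated(comp$bin), ]
  comp <- comp[order(comp$n, comp$k), ]

  sideband_bins <- unique(comp$bin)
  candidate <- setdiff(seq(2L, nyq_bin), sideband_bins)
  mag_all <- Mod(x) * 2 / n_samp

  floor_of <- function(bin) {
    nb <- candidate[order(abs(candidate - bin))][seq_len(min(20L, length(candidate)))]
    stats::median(mag_all[nb])
  }
  floors <- vapply(comp$bin, floor_of, numeric(1))
  amp <- x[comp$bin] * 2 / n_samp
  comp_out <- data.frame(n = comp$n, k = comp$k, frequency = comp$frequency,
                         magnitude = Mod(amp),
                         snr = ifelse(floors > 0, Mod(amp) / floors, Inf))
  comp_out$amplitude <- amp
  structure(list(components = comp_out,
                 noise_floor = stats::median(floors),
                 duration = dur, fs = frame$fs,
                 f1 = config$f1, f3 = config$f3),
            class = "mpi_spectrum")
}

#' @export
print.mpi_spectrum <- function(x, ...) {
  cat(sprintf("<mpi_spectrum> %d sidebands (f3 = %g Hz, f1 = %g Hz), noise floor %.3g\n",
              nrow(x$components), x$f3, x$f1, x$noise_floor))
  top <- x$components[order(-x$components$magnitude), ][seq_len(min(5, nrow(x$components))), ]
  for (i in seq_len(nrow(top)))
    cat(sprintf("  n = %2d, k = %+3d (%6g Hz): |A| = %.3g, SNR = %.2f\n",
                top$n[i], top$k[i], top$frequency[i], top$magnitude[i], top$snr[i]))
  invisible(x)
}

#' Keep only sidebands above an SNR threshold
#'
#' Peak-picking as used before reconstruction: components whose estimated SNR
#' falls below `snr_min` (default 2) are discarded.
#'
#' @param spec an [spectrum_of()] result.
#' @param snr_min minimum SNR retained.
#' @return A new `mpi_spectrum` containing only the retained components.
#' @export
pick_harmonics <- function(spec, snr_min = 2) {
  stopifnot(inherits(spec, "mpi_spectrum"))
  if (!is.numeric(snr_min) || length(snr_min) != 1 || snr_min < 0)
    stop("snr_min must be a non-negative scalar")
  spec$components <- spec$components[spec$components$snr >= snr_min, ]
  spec
}

# Internal: apply a frequency-domain mask to a frame. `keep` is a logical
# vector of length n whose TRUE entries must all lie in the DC..Nyquist half
# (1-based, bin 1 = DC); the conjugate-mirror bins are kept automatically so
# the output stays real.
.apply_bin_mask <- function(frame, keep) {
  n <- length(frame$samples)
  x <- stats::fft(frame$samples)
  full <- rep(FALSE, n)
  pos <- which(keep)
  full[pos] <- TRUE
  mirror <- n - pos + 2L
  mirror <- mirror[mirror >= 1L & mirror <= n]
  full[mirror] <- TRUE
  x[!full] <- 0
  out <- Re(stats::fft(x, inverse = TRUE)) / n
  signal_frame(out, fs = frame$fs, t0 = frame$t0, duration = frame$duration)
}

#' Remove the drive fundamentals from a frame
#'
#' Software emulation of the gradiometric receive chain: notches the exact
#' FFT bins of the CH3 fundamental `f3` and of the CH1/CH2 drives `f1 = f2`
#' (plus DC), leaving every other bin untouched.
#'
#' @param frame a [signal_frame()].
#' @param config the matching [scanner_config()].
#' @return The filtered [signal_frame()].
#' @export
filter_fundamental <- function(frame, config) {
  stopifnot(inherits(frame, "signal_frame"), inherits(config, "scanner_config"))
  n <- length(frame$samples)
  nyq_bin <- floor(n / 2)
  keep <- rep(FALSE, n)
  keep[seq_len(nyq_bin + 1L)] <- TRUE
  notch <- c(1L, .bin_of(config$f1, frame$duration),
             .bin_of(config$f2, frame$duration),
             .bin_of(config$f3, frame$duration))
  keep[notch[notch >= 1 & notch <= n]] <- FALSE
  .apply_bin_mask(frame, keep)
}

#' Band-select harmonic content of a frame
#'
#' Keeps only the frequency windows around the chosen deflection harmonics,
#' `|f - n * f3| <= k_max * f1` for `n` in `n_set`, zeroing everything else
#' (including DC and the drive region below `2 * f3 - k_max * f1` when
#' `n_set` starts at 2). This is the band selection used when building and
#' applying the image-based system matrix.
#'
#' @param frame a [signal_frame()].
#' @param config the matching [scanner_config()].
#' @param n_set integer vector of retained harmonic orders.
#' @param k_max sideband half-width of each window in units of `f1`.
#' @return The filtered [signal_frame()].
#' @export
filter_harmonics <- function(frame, config, n_set = 2:config$n_max, k_max = 20) {
  stopifnot(inherits(frame, "signal_frame"), inherits(config, "scanner_config"))
  if (any(n_set < 1)) stop("n_set must contain orders >= 1")
  n <- length(frame$samples)
  nyq_bin <- floor(n / 2)
  freqs <- (seq_len(nyq_bin + 1L) - 1L) / frame$duration
  keep_pos <- rep(FALSE, nyq_bin + 1L)
  for (h in n_set) {
    keep_pos <- keep_pos | (abs(freqs - h * config$f3) <= k_max * config$f1 + 1e-9)
  }
  keep_pos[1] <- FALSE  # DC
  keep <- rep(FALSE, n)
  keep[seq_len(nyq_bin + 1L)] <- keep_pos
  .apply_bin_mask(frame, keep)
}

#' Write / read a signal frame as delimited text
#'
#' Two-column CSV (`t`, `value`) with `fs`, `t0` and `duration` kept in
#' commented header lines so the frame round-trips exactly.
#'
#' @param frame a [signal_frame()].
#' @param path file path.
#' @return `write_signal_frame` returns `path` invisibly; `read_signal_frame`
#'   returns the [signal_frame()].
#' @export
write_signal_frame <- function(frame, path) {
  stopifnot(inherits(frame, "signal_frame"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs: %.10g", frame$fs), con)
  writeLines(sprintf("# t0: %.10g", frame$t0), con)
  writeLines(sprintf("# duration: %.10g", frame$duration), con)
  writeLines("t,value", con)
  t <- frame$t0 + (seq_along(frame$samples) - 1) / frame$fs
  writeLines(paste(format(t, digits = 12), format(frame$samples, digits = 17),
                   sep = ","), con)
  invisible(path)
}

#' @rdname write_signal_frame
#' @export
read_signal_frame <- function(path) {
  hdr <- readLines(path, n = 3)
  meta <- as.numeric(sub("^# [a-z0-9]+: ", "", hdr))
  df <- utils::read.csv(path, comment.char = "#")
  signal_frame(df$value, fs = meta[1], t0 = meta[2], duration = meta[3])
}
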