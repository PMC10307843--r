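# End-to-end experiment runner: configuration container, simulate and
# reconstruct drivers, demo and fixture generation. These functions are the
# programmatic surface behind the command-line script in inst/cli.

.log <- function(fmt, ...) {
  if (isTRUE(getOption("fflmpi.quiet", FALSE))) return(invisible(NULL))
  message(format(Sys.time(), "%H:%M:%OS1 "), sprintf(fmt, ...))
}

#' Full run configuration
#'
#' Bundles everything one experiment needs: scanner, tracer, noise, a named
#' phantom specification, reconstruction parameters, output directory and the
#' seed that fixes every stochastic element. Fully serializable to YAML.
#'
#' @param scanner a [scanner_config()].
#' @param tracer a [tracer_model()].
#' @param noise a [noise_model()] or `NULL`.
#' @param phantom_spec named list: `name` is one of `"dilution_series"`,
#'   `"point"`, `"vessel"`, `"bolus"`, `"instrument"`, `"lettering"`, plus
#'   generator arguments (e.g. `dilutions`, `position`, `stenosis_grade`,
#'   `kind`, `text`); `pixel_size` selects the phantom grid resolution.
#' @param recon list with `pixel_size`, `margin`, `n_set`, `k_max`,
#'   `lambda_reg`, `n_iter`, `shape`.
#' @param output_dir output directory (created on demand).
#' @param seed integer seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(scanner = scanner_config(),
                       tracer = tracer_model(),
                       noise = NULL,
                       phantom_spec = list(name = "point",
                                           position = c(0.012, 0.008),
                                           iron_mol = 1.5e-6,
                                           pixel_size = 0.001),
                       recon = list(pixel_size = 0.002, margin = 0.15,
                                    n_set = 2:12, k_max = 20,
                                    lambda_reg = 1e-3, n_iter = 10,
                                    shape = c(124, 128)),
                       output_dir = tempfile("fflmpi_run_"),
                       seed = 1L) {
  stopifnot(inherits(scanner, "scanner_config"), inherits(tracer, "tracer_model"))
  if (!is.null(noise)) stopifnot(inherits(noise, "noise_model"))
  if (is.null(phantom_spec$name)) stop("phantom_spec needs a 'name'")
  structure(list(scanner = scanner, tracer = tracer, noise = noise,
                 phantom_spec = phantom_spec, recon = recon,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "run_config")
}

# Internal: build the phantom(s) requested by a run_config.
# Returns a list of phantoms (one per frame).
.build_phantoms <- function(run) {
  ps <- run$phantom_spec
  px <- ps$pixel_size %||% 0.001
  cfg <- run$scanner
  switch(ps$name,
    dilution_series = {
      dil <- ps$dilutions %||% c(50, 100, 200, 400, 800)
      pos <- ps$position %||% c(0.012, 0.008)
      lapply(dil, function(f)
        point_sample(pos, iron_mol = dilution_to_mol(run$tracer$c_stock, f, 1,
                                                     run$tracer$molar_mass_fe),
                     config = cfg, pixel_size = px))
    },
    point = list(point_sample(ps$position %||% c(0.012, 0.008),
                              iron_mol = ps$iron_mol %||% 1.5e-6,
                              config = cfg, pixel_size = px)),
    vessel = {
      spec <- vessel_spec(stenosis_grade = ps$stenosis_grade %||% 0,
                          aneurysm_diameter = ps$aneurysm_diameter %||% 0)
      list(vessel_phantom(spec, config = cfg, pixel_size = px))
    },
    bolus = {
      spec <- vessel_spec(stenosis_grade = ps$stenosis_grade %||% 0)
      bolus_sequence(spec, n_frames = ps$n_frames %||% 8,
                     config = cfg, pixel_size = px)$frames
    },
    instrument = list(instrument_phantom(ps$kind %||% "balloon",
                                         ps$tip_position %||% c(0, -0.02),
                                         config = cfg, pixel_size = px)),
    lettering = list(lettering_phantom(ps$text %||% "iMPI",
                                       config = cfg, pixel_size = px)),
    stop("unknown phantom_spec name: ", ps$name)
  )
}

#' Simulate an experiment: phantoms to signal files
#'
#' Builds the phantoms named by the run configuration, generates the
#' trajectory, simulates one signal frame per phantom frame and writes
#' everything (trajectory CSV, signal CSVs, phantom TIFFs) into the output
#' directory. Re-running with the same configuration and seed reproduces the
#' files byte for byte.
#'
#' @param run a [run_config()].
#' @return Invisibly, a list with the written `signal_files`,
#'   `phantom_files`, `trajectory_file` and the in-memory objects.
#' @export
run_simulate <- function(run) {
  stopifnot(inherits(run, "run_config"))
  dir.create(run$output_dir, showWarnings = FALSE, recursive = TRUE)
  .log("simulate: phantom '%s' -> %s", run$phantom_spec$name, run$output_dir)
  phs <- .build_phantoms(run)
  traj <- make_sequence(run$scanner)
  traj_file <- file.path(run$output_dir, "trajectory.csv")
  write_trajectory(traj, traj_file)
  sig_files <- character(length(phs))
  ph_files <- character(length(phs))
  for (i in seq_along(phs)) {
    noise_i <- run$noise
    if (!is.null(noise_i)) noise_i$seed <- run$seed + i - 1L
    fr <- simulate_frame(phs[[i]], traj, run$tracer, noise_i)
    sig_files[i] <- file.path(run$output_dir, sprintf("signal_%03d.csv", i))
    ph_files[i] <- file.path(run$output_dir, sprintf("phantom_%03d.tiff", i))
    write_signal_frame(fr, sig_files[i])
    write_phantom(phs[[i]], ph_files[i])
    .log("simulate: frame %d / %d written", i, length(phs))
  }
  invisible(list(signal_files = sig_files, phantom_files = ph_files,
                 trajectory_file = traj_file, phantoms = phs, traj = traj))
}

#' Reconstruct simulated or recorded signal files
#'
#' Runs the processing chain (fundamental removal, harmonic band selection,
#' gridding, folding, Kaczmarz reconstruction) on each signal file and writes
#' raw, folded and reconstructed images as numbered 16-bit TIFFs.
#'
#' @param run a [run_config()].
#' @param signal_files signal CSVs from [run_simulate()]; defaults to all
#'   `signal_*.csv` in the output directory.
#' @param sm optional prebuilt [build_system_matrix()]; built on the fly
#'   (and cached as `system_matrix.rds` in the output directory) otherwise.
#' @return Invisibly, the list of written image files and the `recon_image`
#'   objects.
#' @export
run_reconstruct <- function(run, signal_files = NULL, sm = NULL) {
  stopifnot(inherits(run, "run_config"))
  if (is.null(signal_files))
    signal_files <- sort(list.files(run$output_dir, "^signal_.*\\.csv$",
                                    full.names = TRUE))
  if (!length(signal_files)) stop("no signal files to reconstruct")
  rc <- run$recon
  traj <- make_sequence(run$scanner)
  grid <- recon_grid(run$scanner, pixel_size = rc$pixel_size %||% 0.002,
                     margin = rc$margin %||% 0.15)
  sm_file <- file.path(run$output_dir, "system_matrix.rds")
  if (is.null(sm)) {
    if (file.exists(sm_file)) {
      sm <- load_system_matrix(sm_file, run$scanner, run$tracer)
      .log("reconstruct: reusing cached system matrix")
    } else {
      .log("reconstruct: building system matrix (%d columns)", grid$nr * grid$nc)
      sm <- build_system_matrix(traj, run$tracer, grid,
                                shape = rc$shape %||% c(124, 128),
                                n_set = rc$n_set %||% 2:12,
                                k_max = rc$k_max %||% 20)
      save_system_matrix(sm, sm_file)
    }
  } else {
    want <- .sm_fingerprint(run$scanner, run$tracer, sm$grid, sm$shape,
                            sm$n_set, sm$k_max)
    if (!identical(want, sm$build_params))
      stop("supplied system matrix does not match the run configuration")
  }
  out <- list(files = character(0), recons = list())
  for (i in seq_along(signal_files)) {
    fr <- read_signal_frame(signal_files[i])
    fr <- filter_fundamental(fr, run$scanner)
    fr <- filter_harmonics(fr, run$scanner, n_set = sm$n_set, k_max = sm$k_max)
    raw <- grid_raw(fr, traj, shape = sm$shape)
    folded <- fold(raw)
    rec <- reconstruct(folded, sm, lambda_reg = rc$lambda_reg %||% 1e-3,
                       n_iter = rc$n_iter %||% 10)
    base <- sub("\\.csv$", "", basename(signal_files[i]))
    f1 <- file.path(run$output_dir, paste0(base, "_raw.tiff"))
    f2 <- file.path(run$output_dir, paste0(base, "_folded.tiff"))
    f3 <- file.path(run$output_dir, paste0(base, "_recon.tiff"))
    write_image_tiff(raw$grid, f1, meta = list(kind = "raw"))
    write_image_tiff(folded$grid, f2, meta = list(kind = "folded"))
    write_image_tiff(rec$grid, f3, pixel_size = grid$pixel_size,
                    meta = list(kind = "recon"))
    out$files <- c(out$files, f1, f2, f3)
    out$recons[[i]] <- rec
    .log("reconstruct: frame %d / %d done (residual %.3g)", i,
         length(signal_files), rec$residual[length(rec$residual)])
  }
  invisible(out)
}

#' End-to-end demonstration on the lettering phantom
#'
#' Pushes the lettering phantom through the complete chain (simulation,
#' filtering, gridding, folding, system-matrix reconstruction) at a reduced
#' problem size and writes a phantom / raw / folded / reconstruction panel.
#' The demo is noise-free and therefore fully deterministic.
#'
#' @param output_dir output directory.
#' @return Invisibly, a list with the run objects and `ncc`, the normalized
#'   cross-correlation between the reconstruction and the phantom resampled
#'   on the reconstruction grid.
#' @export
run_demo <- function(output_dir = tempfile("fflmpi_demo_")) {
  cfg <- scanner_config(fs = 124000, n_max = 12)
  run <- run_config(scanner = cfg,
                    phantom_spec = list(name = "lettering", text = "iMPI",
                                        pixel_size = 0.002),
                    recon = list(pixel_size = 0.004, margin = 0.15,
                                 n_set = 2:10, k_max = 20,
                                 lambda_reg = 1e-3, n_iter = 10,
                                 shape = c(62, 64)),
                    output_dir = output_dir)
  sim <- run_simulate(run)
  rec <- run_reconstruct(run, sim$signal_files)
  r <- rec$recons[[1]]
  ph_r <- resample_phantom(sim$phantoms[[1]], r$recon_grid)
  ncc <- .ncc(r$grid, ph_r)
  .log("demo: normalized cross-correlation recon vs phantom = %.3f", ncc)
  invisible(list(run = run, sim = sim, rec = rec, ncc = ncc))
}

#' Resample a phantom onto a reconstruction grid
#'
#' Sums the phantom's per-pixel iron into the nearest reconstruction pixel
#' (amount-conserving for phantoms inside the grid).
#'
#' @param ph an [phantom()].
#' @param grid a [recon_grid()].
#' @return Matrix of dimensions `grid$nr x grid$nc`.
#' @export
resample_phantom <- function(ph, grid) {
  stopifnot(inherits(ph, "mpi_phantom"), inherits(grid, "recon_grid"))
  co <- pixel_coords(ph)
  nzi <- which(ph$grid != 0)
  out <- matrix(0, grid$nr, grid$nc)
  if (!length(nzi)) return(out)
  ij <- arrayInd(nzi, dim(ph$grid))
  ir <- pmin(pmax(round((co$z[ij[, 1]] - grid$z[1]) / grid$pixel_size) + 1, 1),
             grid$nr)
  ic <- pmin(pmax(round((co$x[ij[, 2]] - grid$x[1]) / grid$pixel_size) + 1, 1),
             grid$nc)
  idx <- (ic - 1) * grid$nr + ir
  acc <- rowsum(ph$grid[nzi], idx)
  out[as.integer(rownames(acc))] <- acc[, 1]
  out
}

# Internal: normalized cross-correlation of two equal-size arrays.
.ncc <- function(a, b) {
  a <- as.vector(a) - mean(a)
  b <- as.vector(b) - mean(b)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

#' Generate miniature test fixtures
#'
#' Writes a deterministic set of reduced-size assets for fast tests and
#' examples: a quarter-resolution point and lettering phantom, one noisy
#' signal frame and a small prebuilt system matrix.
#'
#' @param seed integer seed for the noisy frame.
#' @param dir output directory.
#' @return Invisibly, the list of written files.
#' @export
generate_fixtures <- function(seed = 1L, dir = tempfile("fflmpi_fixtures_")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- scanner_config(fs = 49600, n_max = 9)
  traj <- make_sequence(cfg)
  tr <- tracer_model()
  ph_pt <- point_sample(c(0.012, 0.008), 1.5e-6, config = cfg, pixel_size = 0.004)
  ph_tx <- lettering_phantom("iMPI", config = cfg, pixel_size = 0.004)
  fr <- simulate_frame(ph_pt, traj, tr, noise_model(sigma_white = 1e-4, seed = seed))
  grid <- recon_grid(cfg, pixel_size = 0.004, margin = 0.1)
  sm <- build_system_matrix(traj, tr, grid, shape = c(62, 64), n_set = 2:8,
                            k_max = 20)
  files <- c(point_phantom = file.path(dir, "point_phantom.tiff"),
             lettering_phantom = file.path(dir, "lettering_phantom.tiff"),
             noisy_frame = file.path(dir, "noisy_frame.csv"),
             system_matrix = file.path(dir, "system_matrix.rds"))
  write_phantom(ph_pt, files["point_phantom"])
  write_phantom(ph_tx, files["lettering_phantom"])
  write_signal_frame(fr, files["noisy_frame"])
  save_system_matrix(sm, files["system_matrix"])
  .log("fixtures: %d files in %s", length(files), dir)
  invisible(as.list(files))
}
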