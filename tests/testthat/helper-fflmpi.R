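# Shared reduced-size test context. The scanner keeps the paper-grade drive
# parameters (f1 = 60 Hz, f3 = 2480 Hz, 50 ms window) but samples at
# 49.6 kS/s and grids onto 62 x 64 raw images (31 x 32 sub-images) with a
# 4 mm reconstruction grid, which keeps every full-chain test in seconds.
# Expensive shared objects (trajectory, system matrix) are built once per
# test run and cached.

.test_cache <- new.env(parent = emptyenv())

test_config <- function() {
  scanner_config(fs = 49600, n_max = 9)
}

test_traj <- function() {
  if (is.null(.test_cache$traj)) .test_cache$traj <- make_sequence(test_config())
  .test_cache$traj
}

test_tracer <- function() tracer_model()

test_shape <- c(62L, 64L)
test_bands <- list(n_set = 2:8, k_max = 20)

# Base system matrix: 4 mm recon pixels, 10% overscan margin. The 4 mm pixel
# is deliberately coarser than half the PSF main lobe, so the build warns;
# the warning is acknowledged here once.
test_sm <- function() {
  if (is.null(.test_cache$sm)) {
    grid <- recon_grid(test_config(), pixel_size = 0.004, margin = 0.1)
    .test_cache$sm <- suppressWarnings(
      build_system_matrix(test_traj(), test_tracer(), grid,
                          shape = test_shape,
                          n_set = test_bands$n_set, k_max = test_bands$k_max))
  }
  .test_cache$sm
}

# Full processing chain: phantom -> filtered frame -> folded image.
test_folded <- function(ph, noise = NULL) {
  cfg <- test_config()
  fr <- simulate_frame(ph, test_traj(), test_tracer(), noise)
  fr <- filter_fundamental(fr, cfg)
  fr <- filter_harmonics(fr, cfg, n_set = test_bands$n_set,
                         k_max = test_bands$k_max)
  fold(grid_raw(fr, test_traj(), shape = test_shape))
}

test_recon <- function(ph, lambda_reg = 1e-3, n_iter = 10, noise = NULL) {
  reconstruct(test_folded(ph, noise), test_sm(), lambda_reg = lambda_reg,
              n_iter = n_iter)
}
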