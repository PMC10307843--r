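test_that("langevin has the textbook limits and shape", {
  expect_equal(langevin(0), 0)
  # coth(1) - 1 evaluated independently at high precision
  expect_equal(langevin(1), 1 / tanh(1) - 1, tolerance = 1e-14)
  expect_equal(round(langevin(1), 5), 0.31304)
  expect_gte(langevin(50), 0.97)
  expect_lt(langevin(50), 1)
  expect_equal(langevin(-50), -langevin(50))
  xi <- seq(-8, 8, by = 0.01)
  expect_equal(langevin(xi), -langevin(-xi))          # odd
  expect_true(all(diff(langevin(xi)) > 0))            # strictly increasing
  expect_true(all(abs(langevin(xi)) < 1))             # bounded
  h <- 1e-4
  expect_equal((langevin(h) - langevin(-h)) / (2 * h), 1 / 3, tolerance = 1e-6)
  expect_error(langevin(Inf), "finite")
})

test_that("simulate_frame is linear in the phantom and zero without tracer", {
  cfg <- test_config()
  traj <- test_traj()
  tr <- test_tracer()
  empty <- phantom(matrix(0, 31, 29), pixel_size = 0.004)
  expect_equal(simulate_frame(empty, traj, tr)$samples,
               rep(0, length(traj$t)))

  p1 <- point_sample(c(0.012, 0.008), 1e-6, config = cfg, pixel_size = 0.004)
  p2 <- point_sample(c(-0.02, -0.015), 2e-6, config = cfg, pixel_size = 0.004)
  f1 <- simulate_frame(p1, traj, tr)$samples
  f2 <- simulate_frame(p2, traj, tr)$samples
  doubled <- p1; doubled$grid <- 2 * p1$grid
  expect_equal(simulate_frame(doubled, traj, tr)$samples, 2 * f1,
               tolerance = 1e-12)
  mix <- p1; mix$grid <- 3 * p1$grid + 0.5 * p2$grid
  expect_equal(simulate_frame(mix, traj, tr)$samples, 3 * f1 + 0.5 * f2,
               tolerance = 1e-9)
})

test_that("noisy frames are reproducible from the seed", {
  cfg <- test_config()
  ph <- point_sample(c(0.012, 0.008), 1e-6, config = cfg, pixel_size = 0.004)
  nm <- noise_model(sigma_white = 1e-3,
                    interference_lines = data.frame(frequency = 5000,
                                                    amplitude = 1e-3),
                    seed = 99)
  a <- simulate_frame(ph, test_traj(), test_tracer(), nm)
  b <- simulate_frame(ph, test_traj(), test_tracer(), nm)
  expect_identical(a$samples, b$samples)
  c2 <- simulate_frame(ph, test_traj(), test_tracer(),
                       noise_model(sigma_white = 1e-3, seed = 100))
  expect_false(identical(a$samples, c2$samples))
})

test_that("a phantom that does not cover the FOV is rejected", {
  small <- phantom(matrix(1e-9, 5, 5), pixel_size = 0.004)
  expect_error(simulate_frame(small, test_traj(), test_tracer()),
               "cover the FOV")
})

test_that("harmonic_freq reproduces the sideband arithmetic", {
  cfg <- scanner_config()
  expect_identical(harmonic_freq(cfg, 5, 2), 12520)
  expect_identical(harmonic_freq(cfg, 1, 0), 2480)
  expect_identical(harmonic_freq(cfg, 3, 0), 7440)
  expect_error(harmonic_freq(cfg, 0, 1), "n must be")
})

test_that("spectrum_of recovers an injected tone and rejects bad durations", {
  cfg <- test_config()
  t <- (0:2479) / cfg$fs
  tone <- signal_frame(0.7 * cos(2 * pi * 12520 * t), fs = cfg$fs,
                       duration = cfg$T_acq)
  sp <- spectrum_of(tone, cfg, n_max = 6, k_max = 5)
  i <- which(sp$components$n == 5 & sp$components$k == 2)
  expect_equal(sp$components$magnitude[i], 0.7, tolerance = 0.01)

  bad <- signal_frame(rnorm(2331), fs = cfg$fs, duration = 0.047)
  expect_error(spectrum_of(bad, cfg), "bins off")
})

test_that("point-source energy concentrates in the harmonic sidebands", {
  cfg <- test_config()
  ph <- point_sample(c(0.012, 0.008), 1e-6, config = cfg, pixel_size = 0.004)
  fr <- filter_fundamental(simulate_frame(ph, test_traj(), test_tracer()), cfg)
  x2 <- Mod(stats::fft(fr$samples))^2
  nyq <- floor(length(x2) / 2)
  freqs <- (1:nyq) / fr$duration
  e <- x2[2:(nyq + 1)]
  keep <- rep(FALSE, nyq)
  for (h in 1:9)
    keep <- keep | (abs(freqs - h * cfg$f3) <= 20 * cfg$f1)
  expect_gte(sum(e[keep]) / sum(e), 0.95)
})

test_that("band SNR is about 1 on pure white noise", {
  cfg <- test_config()
  empty <- phantom(matrix(0, 31, 29), pixel_size = 0.004)
  msnr <- vapply(1:50, function(s) {
    fr <- simulate_frame(empty, test_traj(), test_tracer(),
                         noise_model(sigma_white = 1, seed = s))
    mean(spectrum_of(fr, cfg, n_max = 5, k_max = 5)$components$snr)
  }, numeric(1))
  # the band magnitude is Rayleigh: E|X| / median|X| = 1.065, so the mean
  # band SNR sits slightly above 1
  expect_gt(mean(msnr), 0.9)
  expect_lt(mean(msnr), 1.3)
})

test_that("pick_harmonics thresholds deterministically and nests", {
  cfg <- test_config()
  ph <- point_sample(c(0.012, 0.008), 2e-7, config = cfg, pixel_size = 0.004)
  fr <- simulate_frame(ph, test_traj(), test_tracer(),
                       noise_model(sigma_white = 5e-5, seed = 3))
  sp <- spectrum_of(filter_fundamental(fr, cfg), cfg, n_max = 6, k_max = 10)
  expect_identical(pick_harmonics(sp, 0)$components, sp$components)
  sizes <- vapply(c(0, 1, 2, 4, 8), function(thr)
    nrow(pick_harmonics(sp, thr)$components), integer(1))
  expect_true(all(diff(sizes) <= 0))
  prev <- sp
  for (thr in c(1, 2, 4)) {
    cur <- pick_harmonics(sp, thr)
    expect_true(all(cur$components$frequency %in% prev$components$frequency))
    prev <- cur
  }
  huge <- pick_harmonics(sp, 1e12)
  expect_equal(nrow(huge$components), 0)
})

test_that("filter_fundamental notches the drives and nothing else", {
  cfg <- test_config()
  t <- (0:2479) / cfg$fs
  f3tone <- signal_frame(sin(2 * pi * cfg$f3 * t), fs = cfg$fs,
                         duration = cfg$T_acq)
  out <- filter_fundamental(f3tone, cfg)
  expect_lt(sqrt(mean(out$samples^2)), 1e-10)

  probe <- signal_frame(cos(2 * pi * 12520 * t), fs = cfg$fs,
                        duration = cfg$T_acq)
  kept <- filter_fundamental(probe, cfg)
  expect_equal(sqrt(mean(kept$samples^2)), sqrt(mean(probe$samples^2)),
               tolerance = 0.01)

  # strong f3 feedthrough disappears without touching the particle bands
  ph <- point_sample(c(0.012, 0.008), 1e-6, config = cfg, pixel_size = 0.004)
  clean <- simulate_frame(ph, test_traj(), test_tracer())
  dirty <- clean
  dirty$samples <- dirty$samples + 50 * sin(2 * pi * cfg$f3 * test_traj()$t)
  spc <- spectrum_of(filter_fundamental(clean, cfg), cfg, n_max = 6, k_max = 5)
  spd <- spectrum_of(filter_fundamental(dirty, cfg), cfg, n_max = 6, k_max = 5)
  keep <- spc$components$magnitude > 1e-3 * max(spc$components$magnitude)
  expect_equal(spd$components$magnitude[keep], spc$components$magnitude[keep],
               tolerance = 0.02)
})

test_that("signal frames round-trip through delimited text", {
  cfg <- test_config()
  ph <- point_sample(c(0.012, 0.008), 1e-6, config = cfg, pixel_size = 0.004)
  fr <- simulate_frame(ph, test_traj(), test_tracer())
  path <- withr::local_tempfile(fileext = ".csv")
  write_signal_frame(fr, path)
  back <- read_signal_frame(path)
  expect_equal(back$samples, fr$samples)
  expect_equal(back$fs, fr$fs)
  expect_equal(back$t0, fr$t0)
})
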