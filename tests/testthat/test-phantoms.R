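test_that("dilution arithmetic matches the tracer bookkeeping", {
  expect_equal(dilution_to_mol(8.5, 100, 1, 55.845), 1.522e-6, tolerance = 1e-3)
  expect_equal(signif(dilution_to_mol(8.5, 100, 1, 55.845) * 1e6, 2), 1.5)
  expect_equal(dilution_to_mol(8.5, 50, 1, 55.845), 3.044e-6, tolerance = 1e-3)
  expect_equal(dilution_to_mol(5, 10, 0), 0)
  expect_error(dilution_to_mol(8.5, 0, 1), "dilution_factor")
  expect_error(dilution_to_mol(8.5, -5, 1), "dilution_factor")
})

test_that("dose limit is the per-kg product", {
  expect_equal(dose_limit(2.5, 80), 200)
  expect_equal(dose_limit(2.5, 85), 212.5)
  expect_equal(dose_limit(0, 70), 0)
})

test_that("point samples conserve iron and translate by whole pixels", {
  cfg <- test_config()
  iron <- dilution_to_mol(8.5, 800, 1)
  expect_equal(iron, 1.9025e-7, tolerance = 1e-4)
  ph <- point_sample(c(0.012, 0.008), iron, config = cfg, pixel_size = 0.002)
  expect_equal(sum(ph$grid), iron)

  ph2 <- point_sample(c(0.022, 0.008), iron, config = cfg, pixel_size = 0.002)
  shift <- round(0.01 / 0.002)
  expect_equal(ph2$grid[, (1 + shift):ncol(ph2$grid)],
               ph$grid[, 1:(ncol(ph$grid) - shift)])

  expect_error(point_sample(c(0.2, 0), 1e-6, config = cfg), "outside the FOV")
})

test_that("vessel projection follows the chord-thickness model", {
  cfg <- test_config()
  # uniform vessel: constant centerline profile along the path
  ph0 <- vessel_phantom(vessel_spec(stenosis_grade = 0), config = cfg,
                        pixel_size = 0.001)
  co <- pixel_coords(ph0)
  ic <- which.min(abs(co$x))
  rows <- which(abs(co$z) <= 0.03)
  center0 <- ph0$grid[rows, ic]
  expect_lt(diff(range(center0)) / mean(center0), 0.01)

  # 70% stenosis: centerline projected amount drops to ~30% of the parent
  ph7 <- vessel_phantom(vessel_spec(stenosis_grade = 0.7), config = cfg,
                        pixel_size = 0.001)
  ratio <- min(ph7$grid[rows, ic]) / mean(center0)
  expect_equal(ratio, 0.3, tolerance = 0.02)

  # narrowing is monotone in the grade
  mins <- vapply(c(0.35, 0.5, 0.7), function(g)
    min(vessel_phantom(vessel_spec(stenosis_grade = g), config = cfg,
                       pixel_size = 0.001)$grid[rows, ic]), numeric(1))
  expect_true(all(diff(mins) < 0))

  # aneurysm bulge: local maximum above the vessel baseline at the center
  pha <- vessel_phantom(vessel_spec(aneurysm_diameter = 0.02), config = cfg,
                        pixel_size = 0.001)
  irz <- which.min(abs(co$z))
  expect_gt(pha$grid[irz, ic], max(center0) * 1.5)

  expect_error(vessel_phantom(vessel_spec(path = cbind(c(0, 0), c(-0.2, 0.2))),
                              config = cfg), "exits the grid")
})

test_that("bolus advances with the flow profile and conserves iron", {
  cfg <- test_config()
  spec <- vessel_spec()
  iron <- dilution_to_mol(8.5, 1, 1)

  # constant profile: displacement after one frame is exactly v / frame_rate
  bs <- bolus_sequence(spec, bolus_iron = iron, peak_velocity = 0.06,
                       frame_rate = 4, n_frames = 3, profile = "constant",
                       config = cfg, pixel_size = 0.002)
  centroid_z <- function(ph) {
    co <- pixel_coords(ph)
    w <- rowSums(ph$grid)
    sum(co$z * w) / sum(w)
  }
  dz <- centroid_z(bs$frames[[2]]) - centroid_z(bs$frames[[1]])
  expect_lt(abs(dz - 0.06 / 4), 0.002)
  expect_equal(sum(bs$frames[[1]]$grid), iron, tolerance = 1e-12)
  expect_equal(sum(bs$frames[[2]]$grid), iron, tolerance = 0.02)

  # pulsatile displacement law against brute-force numeric integration
  for (tt in c(0.1, 0.25, 0.8, 1.3)) {
    tg <- seq(0, tt, length.out = 20001)
    num <- sum(0.5 * abs(sin(pi * tg))) * tt / (length(tg) - 1)
    expect_equal(fflmpi:::.pulsatile_displacement(tt, 0.5, 1), num,
                 tolerance = 1e-3)
  }
  # mean advance per frame at the stated peak and frame rate
  expect_equal(fflmpi:::.pulsatile_displacement(1, 0.5, 1),
               (2 / pi) * 0.5, tolerance = 1e-12)

  # pulsatile sequence: peak of the flow profile equals the configured peak
  bp <- bolus_sequence(spec, bolus_iron = iron, peak_velocity = 0.5,
                       frame_rate = 4, n_frames = 4,
                       config = cfg, pixel_size = 0.002)
  expect_equal(max(bp$flow_profile), 0.5, tolerance = 1e-6)
  # the bolus leaves the 9.6 cm path well before frame 4 at 50 cm/s peak
  expect_lt(sum(bp$frames[[4]]$grid), iron)
})

test_that("instrument markers sit where the device geometry says", {
  cfg <- test_config()
  bp <- instrument_phantom("balloon", c(0, -0.03), marker_iron = 1e-5,
                           config = cfg, pixel_size = 0.001)
  co <- pixel_coords(bp)
  prof <- rowSums(bp$grid)
  peaks <- which(prof > 0)
  # two clusters: their weighted centers are 37 mm apart (within one pixel)
  lower <- peaks[co$z[peaks] < -0.015]
  upper <- peaks[co$z[peaks] >= -0.015]
  c1 <- sum(co$z[lower] * prof[lower]) / sum(prof[lower])
  c2 <- sum(co$z[upper] * prof[upper]) / sum(prof[upper])
  expect_lt(abs((c2 - c1) - 0.037), 0.0011)  # one grid pixel
  expect_equal(sum(bp$grid), 2e-5, tolerance = 1e-12)

  gw <- instrument_phantom("guidewire", c(0.01, 0.02), marker_iron = 1e-5,
                           config = cfg, pixel_size = 0.001)
  nz <- which(gw$grid > 0, arr.ind = TRUE)
  # single connected marker: all nonzero pixels within one marker diameter
  expect_lt(max(dist(nz)) * 0.001, 0.005)
  doubled <- instrument_phantom("guidewire", c(0.01, 0.02), marker_iron = 2e-5,
                                config = cfg, pixel_size = 0.001)
  expect_equal(doubled$grid, 2 * gw$grid)

  expect_error(instrument_phantom("balloon", c(0, 0.05), config = cfg),
               "outside the FOV")
})

test_that("lettering phantom is deterministic and fits the FOV", {
  cfg <- test_config()
  a <- lettering_phantom("iMPI", config = cfg, pixel_size = 0.002)
  b <- lettering_phantom("iMPI", config = cfg, pixel_size = 0.002)
  expect_identical(a$grid, b$grid)
  expect_gt(sum(a$grid > 0), 0)
  expect_equal(sum(a$grid), 1e-5)
  co <- pixel_coords(a)
  nz <- which(a$grid > 0, arr.ind = TRUE)
  expect_lte(max(abs(co$x[nz[, 2]])), cfg$fov_x / 2)
  expect_lte(max(abs(co$z[nz[, 1]])), cfg$fov_z / 2)
  # lettering spans roughly 60% of the FOV width
  expect_gt(diff(range(co$x[nz[, 2]])), 0.3 * cfg$fov_x)
  expect_error(lettering_phantom("iMQI"), "unsupported")
})
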