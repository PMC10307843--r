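test_that("system-matrix columns are folded unit point responses", {
  sm <- test_sm()
  grid <- sm$grid
  # pick the recon pixel nearest the FOV center and rebuild its column by
  # running the public chain on a unit point phantom at that pixel
  ic <- which.min(abs(grid$x)); ir <- which.min(abs(grid$z))
  j <- (ic - 1) * grid$nr + ir
  # phantom grid with pixel centers aligned to the recon pixel centers
  ph <- phantom(matrix(0, 31, 29), pixel_size = 0.004,
                origin = c(grid$x[ic], grid$z[ir]) -
                  round(c(grid$x[ic], grid$z[ir]) / 0.004) * 0.004)
  co <- pixel_coords(ph)
  ph$grid[which.min(abs(co$z - grid$z[ir])),
          which.min(abs(co$x - grid$x[ic]))] <- 1
  fd <- test_folded(ph)
  expect_equal(as.vector(fd$grid), sm$A[, j], tolerance = 1e-10)
})

test_that("adjacent system-matrix columns are one-pixel shifts of each other", {
  sm <- test_sm()
  grid <- sm$grid
  ic <- which.min(abs(grid$x)); ir <- which.min(abs(grid$z))
  cols <- vapply(c(-1, 0, 1), function(d)
    sm$A[, (ic - 1) * grid$nr + ir + d], numeric(nrow(sm$A)))
  nzr <- test_shape[1] / 2
  imgs <- lapply(1:3, function(i) matrix(cols[, i], nzr, test_shape[2] / 2))
  # folded-image row pitch ~3.9 mm vs 4 mm recon pitch: the cross-correlation
  # peak between neighbors in z must sit at a one-row shift
  best_shift <- function(a, b) {
    sh <- -3:3
    cc <- vapply(sh, function(s) {
      ra <- max(1, 1 + s):min(nzr, nzr + s)
      rb <- ra - s
      sum(a[ra, ] * b[rb, ])
    }, numeric(1))
    sh[which.max(cc)]
  }
  expect_equal(abs(best_shift(imgs[[1]], imgs[[2]])), 1)
  expect_equal(abs(best_shift(imgs[[2]], imgs[[3]])), 1)
})

test_that("the forward operator reproduces folded data for on-grid phantoms", {
  sm <- test_sm()
  grid <- sm$grid
  # three-point phantom placed exactly on recon pixel centers
  pts <- list(c(11, 12, 1.0), c(20, 18, 0.5), c(15, 25, 2.0))  # (ir, ic, amt)
  ph <- phantom(matrix(0, 31, 29), pixel_size = 0.004,
                origin = c(grid$x[1] %% 0.004, grid$z[1] %% 0.004))
  co <- pixel_coords(ph)
  cvec <- numeric(ncol(sm$A))
  for (p in pts) {
    cvec[(p[2] - 1) * grid$nr + p[1]] <- p[3] * 1e-6
    ph$grid[which.min(abs(co$z - grid$z[p[1]])),
            which.min(abs(co$x - grid$x[p[2]]))] <- p[3] * 1e-6
  }
  fd <- test_folded(ph)
  expect_equal(as.vector(sm$A %*% cvec), as.vector(fd$grid), tolerance = 1e-9)
})

test_that("reconstruction is consistent, non-negative and damped by lambda", {
  sm <- test_sm()
  grid <- sm$grid
  j <- (18 - 1) * grid$nr + 16
  b <- structure(list(grid = matrix(sm$A[, j] * 1e-6, test_shape[1] / 2,
                                    test_shape[2] / 2)),
                 class = "folded_image")
  rec <- reconstruct(b, sm, lambda_reg = 1e-4, n_iter = 10)
  expect_true(all(rec$grid >= 0))
  expect_true(all(is.finite(rec$grid)))
  am <- which(rec$grid == max(rec$grid), arr.ind = TRUE)[1, ]
  expect_equal(unname(am), c(16, 18))

  crushed <- reconstruct(b, sm, lambda_reg = 1e6, n_iter = 10)
  expect_lt(sum(crushed$grid), 1e-3 * sum(rec$grid))

  small <- structure(list(grid = matrix(0, 5, 5)), class = "folded_image")
  expect_error(reconstruct(small, sm), "does not match")
})

test_that("two sources 3 cm apart resolve as two maxima at the right spots", {
  cfg <- test_config()
  sm <- test_sm()
  grid <- sm$grid
  ph <- phantom(matrix(0, 31, 29), pixel_size = 0.004,
                origin = c(grid$x[1] %% 0.004, grid$z[1] %% 0.004))
  co <- pixel_coords(ph)
  ir1 <- which.min(abs(grid$z + 0.015)); ir2 <- which.min(abs(grid$z - 0.015))
  ic <- which.min(abs(grid$x - 0.01))
  ph$grid[which.min(abs(co$z - grid$z[ir1])), which.min(abs(co$x - grid$x[ic]))] <- 1e-6
  ph$grid[which.min(abs(co$z - grid$z[ir2])), which.min(abs(co$x - grid$x[ic]))] <- 1e-6
  rec <- test_recon(ph)
  prof <- rec$grid[, ic]
  ord <- order(prof, decreasing = TRUE)
  top2 <- sort(ord[1:2])
  expect_lte(abs(top2[1] - ir1), 1)
  expect_lte(abs(top2[2] - ir2), 1)
})

test_that("overscan absorbs tracer just outside the FOV", {
  cfg <- test_config()
  traj <- test_traj()
  big <- phantom(matrix(0, 41, 33), pixel_size = 0.004)
  co <- pixel_coords(big)
  big$grid[which.min(abs(co$z + 0.065)), which.min(abs(co$x))] <- 1e-6
  fr <- filter_fundamental(simulate_frame(big, traj, test_tracer()), cfg)
  fr <- filter_harmonics(fr, cfg, n_set = test_bands$n_set,
                         k_max = test_bands$k_max)
  fd <- fold(grid_raw(fr, traj, shape = test_shape))
  spurious <- vapply(c(0, 0.15), function(m) {
    gg <- recon_grid(cfg, pixel_size = 0.004, margin = m)
    smm <- suppressWarnings(
      build_system_matrix(traj, test_tracer(), gg, shape = test_shape,
                          n_set = test_bands$n_set, k_max = test_bands$k_max))
    r <- reconstruct(fd, smm, 1e-3, 10)
    infx <- abs(gg$x) <= cfg$fov_x / 2
    infz <- abs(gg$z) <= cfg$fov_z / 2
    sum(r$grid[infz, infx])
  }, numeric(1))
  expect_lt(spurious[2], spurious[1])
})

test_that("multicontrast separates markers from extended filling", {
  cfg <- test_config()
  traj <- test_traj()
  grid <- test_sm()$grid
  mk <- instrument_phantom("balloon", c(0, -0.02), marker_iron = 2e-5,
                           config = cfg, pixel_size = 0.002)
  fillspec <- vessel_spec(parent_diameter = 0.009,
                          path = cbind(x = c(0, 0), z = c(-0.016, 0.013)))
  fill <- vessel_phantom(fillspec, config = cfg, pixel_size = 0.002)
  comp <- mk; comp$grid <- mk$grid + fill$grid
  fr <- simulate_frame(comp, traj, test_tracer())

  sm_hi <- suppressWarnings(build_system_matrix(traj, test_tracer(), grid,
                                                shape = test_shape,
                                                n_set = 5:8, k_max = 20))
  sm_lo <- suppressWarnings(build_system_matrix(traj, test_tracer(), grid,
                                                shape = test_shape,
                                                n_set = 2:3, k_max = 20))
  mc <- multicontrast_reconstruct(fr, traj, sm_hi,
                                  params_a = list(n_set = 5:8, k_max = 20),
                                  params_b = list(n_set = 2:3, k_max = 20,
                                                  sm = sm_lo))
  expect_true(all(mc$difference$grid >= 0))
  mask <- resample_phantom(mk, grid) > 0
  odds <- function(r) {
    f <- sum(r$grid[mask]) / sum(r$grid)
    f / (1 - f)
  }
  # markers carry relatively more weight in the high-harmonic reconstruction
  expect_gt(odds(mc$a) / odds(mc$b), 1.2)
})

test_that("multicontrast rejects identical parameter sets and clamps", {
  cfg <- test_config()
  traj <- test_traj()
  sm <- test_sm()
  mk <- instrument_phantom("balloon", c(0, -0.02), marker_iron = 2e-5,
                           config = cfg, pixel_size = 0.002)
  fr <- simulate_frame(mk, traj, test_tracer())
  expect_error(multicontrast_reconstruct(fr, traj, sm,
                                         params_a = list(lambda_reg = 1e-3),
                                         params_b = list(lambda_reg = 1e-3)),
               "identical")
  mc <- multicontrast_reconstruct(fr, traj, sm,
                                  params_a = list(lambda_reg = 1e-3),
                                  params_b = list(lambda_reg = 1.005e-3))
  # near-identical regularization: difference image is essentially empty
  expect_lt(sum(mc$difference$grid), 0.02 * sum(mc$a$grid))
  expect_true(all(mc$difference$grid >= 0))
})

test_that("stenosis grading reads the along-path attenuation", {
  # synthetic reconstructions with known profiles
  cfg <- test_config()
  gg <- recon_grid(cfg, pixel_size = 0.002, margin = 0)
  tube <- function(width_scale) {
    g <- matrix(0, gg$nr, gg$nc)
    for (i in seq_len(gg$nr)) {
      w <- width_scale(gg$z[i])
      g[i, abs(gg$x) <= 0.005] <- w
    }
    structure(list(grid = g, recon_grid = gg,
                   params = list(), residual = 0, converged = TRUE),
              class = "recon_image")
  }
  path <- cbind(x = c(0, 0), z = c(-0.048, 0.048))
  uniform <- tube(function(z) 1)
  expect_lt(stenosis_grade_from_image(uniform, path, 0.010), 0.1)
  occluded <- tube(function(z) ifelse(abs(z) < 0.01, 0, 1))
  expect_gte(stenosis_grade_from_image(occluded, path, 0.010), 0.9)
  empty <- tube(function(z) 0)
  expect_error(stenosis_grade_from_image(empty, path, 0.010), "empty profile")
  expect_error(stenosis_grade_from_image(uniform, cbind(c(0, 0), c(-1, 1)),
                                         0.010), "outside")
})

test_that("system matrices round-trip with fingerprint protection", {
  sm <- test_sm()
  path <- withr::local_tempfile(fileext = ".rds")
  save_system_matrix(sm, path)
  back <- load_system_matrix(path, test_config(), test_tracer())
  expect_equal(back$A, sm$A)
  other <- tracer_model(beta = 2e4)
  expect_error(load_system_matrix(path, test_config(), other), "fingerprint")
})
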