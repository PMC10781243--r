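# Whole-image beamformers: degeneracies, kernel-vs-reference equivalence,
# DMAS scaling laws, DCR-MVDR snapshots.

test_that("zero cube produces zero images for every beamformer", {
  geom <- fx_geom(8)
  cube <- analytic_cube(array(0i, c(3, 8, 64)), geom, plane_wave_angles(3, 5))
  grid <- image_grid(geom, c(-1e-3, 1e-3), c(1e-3, 2e-3))
  for (m in c("cpwc", "txmv", "tx-dmas")) {
    img <- switch(m, cpwc = beamform_cpwc(cube, grid),
                  txmv = beamform_txmv(cube, grid, L = 2, T = 1),
                  "tx-dmas" = beamform_tx_dmas(cube, grid, p = 2))
    expect_true(all(img$data == 0i), label = m)
  }
})

test_that("single-angle CPWC reduces to one-shot DAS", {
  cube <- fx_point_cube()
  one <- analytic_cube(cube$data[4, , , drop = FALSE], cube$geometry,
                       plane_wave_sequence(cube$sequence$angles[4],
                                           cube$sequence$t0[4]))
  grid <- fx_point_grid()
  img1 <- beamform_cpwc(one, grid)
  # per-pixel oracle through the echo-matrix route
  px <- c(grid$lateral_x[3], grid$axial_z[5])
  X <- build_echo_matrix(one, px, 1.75)
  expect_equal(img1$data[5, 3], cpwc_pixel(X), tolerance = 1e-10)
})

test_that("whole-image CPWC agrees with the per-pixel echo-matrix route", {
  cube <- fx_point_cube()
  grid <- pixel_grid(seq(-1e-3, 1e-3, length.out = 5),
                     seq(19.5e-3, 20.5e-3, length.out = 7))
  img <- beamform_cpwc(cube, grid)
  for (ix in c(1, 3, 5)) for (iz in c(1, 4, 7)) {
    X <- build_echo_matrix(cube, c(grid$lateral_x[ix], grid$axial_z[iz]), 1.75)
    expect_equal(img$data[iz, ix], cpwc_pixel(X), tolerance = 1e-10)
  }
})

test_that("degeneracy chain: DMAS p=1 is TxMV, TxMV L=1 is CPWC, Tx-DMAS p=1 is CPWC", {
  cube <- fx_point_cube()
  grid <- fx_point_grid()
  cp <- beamform_cpwc(cube, grid)
  tx <- beamform_txmv(cube, grid, L = 3, T = 4)
  dm1 <- beamform_txmv_dmas(cube, grid, p = 1, L = 3, T = 4)
  expect_equal(dm1$data, tx$data, tolerance = 1e-12)
  tx1 <- beamform_txmv(cube, grid, L = 1, T = 4)
  expect_equal(tx1$data, cp$data, tolerance = 1e-10)
  td1 <- beamform_tx_dmas(cube, grid, p = 1)
  expect_equal(td1$data, cp$data, tolerance = 1e-10)
})

test_that("TxMV kernel matches a per-pixel reference built from the MV primitives", {
  # reference route: covariance_forward on the axial snapshot family,
  # fb_average, diagonal_load, mv_weights, mv_output - per pixel
  cube <- fx_point_cube()
  grid <- pixel_grid(seq(-1.5e-3, 1.5e-3, length.out = 7),
                     seq(19.6e-3, 20.4e-3, length.out = 23))
  L <- 3; T <- 5; delta <- 0.1
  img <- beamform_txmv(cube, grid, L = L, T = T, delta = delta)
  nz <- length(grid$axial_z)
  for (ix in c(2, 4, 6)) for (iz in c(1, 12, 23)) {
    rows <- max(1, iz - T):min(nz, iz + T)
    fam <- t(vapply(rows, function(r) {
      X <- build_echo_matrix(cube, c(grid$lateral_x[ix], grid$axial_z[r]), 1.75)
      channel_sum(X)
    }, complex(7)))
    Rc <- covariance_forward(fam, L, T = T, n = which(rows == iz))
    Rl <- diagonal_load(fb_average(Rc), delta, L)
    w <- mv_weights(Rl)
    z <- fam[which(rows == iz), ]
    expect_equal(img$data[iz, ix], mv_output(z, w, L), tolerance = 1e-8)
  }
})

test_that("RxMV is distortionless, sharper than CPWC, and degenerates at L=1", {
  cube <- fx_point_cube()
  grid <- fx_point_grid()
  cp <- beamform_cpwc(cube, grid)
  rx <- beamform_rxmv(cube, grid)
  expect_equal(dim(rx$data), dim(cp$data))
  fw_cp <- fwhm_lateral(cp, 20e-3, 0)
  fw_rx <- fwhm_lateral(rx, 20e-3, 0)
  expect_lte(fw_rx, fw_cp)
  rx1 <- beamform_rxmv(cube, grid, L = 1)
  expect_equal(rx1$data, cp$data, tolerance = 1e-10)
})

test_that("DMAS root scaling keeps phase and obeys the magnitude law", {
  expect_equal(dmas_root_scale(4 * exp(1i * pi / 3), 2), 2 * exp(1i * pi / 3),
               tolerance = 1e-12)
  z <- rand_cplx(50, seed = 31)
  expect_equal(dmas_root_scale(z, 1), z, tolerance = 1e-12)
  for (p in c(1.5, 2, 2.5)) {
    zs <- dmas_root_scale(z, p)
    expect_equal(Mod(zs), Mod(z)^(1 / p), tolerance = 1e-12)
    expect_equal(Arg(zs), Arg(z), tolerance = 1e-12)
  }
  expect_equal(dmas_root_scale(0i, 2), 0i)
})

test_that("Tx-DMAS magnitude laws: single-angle 1/M^p scaling and constant input", {
  geom <- fx_geom(4)
  M <- 5
  # constant transmit-angle array: root then power cancel, output magnitude |c|
  nt <- 32
  c0 <- 2 * exp(0.7i)
  Z <- matrix(c0, 1, M)
  zs <- pwbeam:::.root_scale(Z, 2)
  y <- mean(zs)
  expect_equal(Mod(pwbeam:::.power_restore(y, 2)), Mod(c0), tolerance = 1e-12)
  # single nonzero angle of magnitude |c| -> output magnitude |c| / M^p
  z1 <- c(3 + 0i, rep(0i, M - 1))
  for (p in c(1, 2, 2.5)) {
    ys <- mean(pwbeam:::.root_scale(matrix(z1, 1), p))
    expect_equal(Mod(pwbeam:::.power_restore(ys, p)), 3 / M^p, tolerance = 1e-12)
  }
})

test_that("beamformers obey the DMAS global-scale magnitude law", {
  cube <- fx_point_cube()
  grid <- pixel_grid(seq(-1e-3, 1e-3, length.out = 5),
                     seq(19.7e-3, 20.3e-3, length.out = 9))
  lam <- 0.5 * exp(1.1i)
  scaled <- analytic_cube(cube$data * lam, cube$geometry, cube$sequence)
  cp <- beamform_cpwc(cube, grid); cps <- beamform_cpwc(scaled, grid)
  expect_equal(cps$data, lam * cp$data, tolerance = 1e-10)
  dm <- beamform_txmv_dmas(cube, grid, p = 2, L = 3, T = 3)
  dms <- beamform_txmv_dmas(scaled, grid, p = 2, L = 3, T = 3)
  expect_equal(Mod(dms$data), Mod(lam) * Mod(dm$data), tolerance = 1e-8)
})

test_that("DCR-MVDR snapshots equal the brute-force leave-one-out compounds", {
  X <- fx_random_echo(6, 10, n_masked = 3, seed = 41)
  S <- dcr_snapshots(X)
  act <- which(X$rx_mask)
  expect_equal(dim(S), c(6, length(act)))
  for (jj in seq_along(act)) {
    keep <- setdiff(act, act[jj])
    oracle <- rowMeans(X$values[, keep, drop = FALSE])
    expect_equal(S[, jj], oracle, tolerance = 1e-12)
  }
  # identical columns: every snapshot equals the full compound
  v <- rand_cplx(6, seed = 42)
  Xi <- fx_echo(matrix(v, 6, 8, byrow = FALSE))
  Si <- dcr_snapshots(Xi)
  expect_true(all(abs(Si - v) < 1e-12))
})

test_that("DCR-MVDR is distortionless on constant data and runs whole images", {
  geom <- fx_geom(8)
  sq <- plane_wave_angles(4, 5)
  cube <- analytic_cube(array(3 - 2i, c(4, 8, 64)), geom, sq)
  grid <- pixel_grid(0, 1.2e-3)  # delays inside the 64-sample window
  img <- beamform_dcr_mvdr(cube, grid, f_number = 0.2, delta = 1)
  expect_equal(img$data[1, 1], 3 - 2i, tolerance = 1e-8)

  cube2 <- fx_point_cube()
  grid2 <- pixel_grid(seq(-1e-3, 1e-3, length.out = 5),
                      seq(19.8e-3, 20.2e-3, length.out = 5))
  img2 <- beamform_dcr_mvdr(cube2, grid2, delta = 1)
  pk <- arrayInd(which.max(Mod(img2$data)), dim(img2$data))
  expect_equal(pk[1], 3, tolerance = 1.01)  # peak on the scatterer row
})

test_that("the registry dispatches every method name", {
  cube <- fx_point_cube()
  grid <- pixel_grid(seq(-0.5e-3, 0.5e-3, length.out = 3),
                     seq(19.9e-3, 20.1e-3, length.out = 3))
  for (m in c("cpwc", "rxmv", "txmv", "dcr-mvdr", "txmv-dmas", "tx-dmas",
              "txmv-admas")) {
    img <- switch(m,
                  txmv = beamform(cube, grid, m, L = 3, T = 2),
                  "txmv-dmas" = beamform(cube, grid, m, p = 2, L = 3, T = 2),
                  "txmv-admas" = beamform(cube, grid, m, L = 3, T = 2),
                  beamform(cube, grid, m))
    expect_s3_class(img, "pw_image")
    expect_equal(img$method, m)
    expect_equal(dim(img$data), c(3L, 3L))
  }
  expect_error(beamform(cube, grid, "nope"))
})
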