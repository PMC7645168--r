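test_that("ground-truth susceptibilities match the tissue table for all labels", {
  ph <- build_phantom(tiny_spec())
  tt <- tissue_table()
  rs <- roi_stats(ph$chi, ph$labels, tt)
  expect_equal(nrow(rs), nrow(tt))          # every label present
  expect_true(all(rs$sd == 0))
  expect_equal(rs$mean, tt$chi_ppb[match(rs$code, tt$code)])
  # spot values
  expect_equal(rs$mean[rs$name == "GP-L"], 180)
  expect_equal(rs$mean[rs$name == "WM"], 0)
  expect_equal(rs$mean[rs$name == "V"], 450)
})

test_that("sphere rasterization hits the analytic voxel count", {
  ph <- build_phantom(tiny_spec())
  tt <- tissue_table()
  vox_mm3 <- prod(ph$grid$voxel_size)
  for (nm in c("CMB1", "CMB2", "CaD2", "PG")) {
    r <- default_spheres()$radius_mm[default_spheres()$name == nm]
    n <- sum(ph$labels == tt$code[tt$name == nm])
    expect_lt(abs(n * vox_mm3 - 4 / 3 * pi * r^3) / (4 / 3 * pi * r^3), 0.15)
  }
})

test_that("overlapping spheres are rejected", {
  sp <- default_spheres()
  sp$cx[2] <- sp$cx[1] + 1; sp$cy[2] <- sp$cy[1]; sp$cz[2] <- sp$cz[1]
  expect_error(build_phantom(phantom_spec(spheres = sp)), "overlap")
})

test_that("R2* follows 20 + 0.125 chi except fixed-rate sphere inserts", {
  ph <- build_phantom(tiny_spec())
  tt <- tissue_table()
  r2s <- chi_to_r2star(ph$chi, ph$labels, tt)
  expect_equal(unique(r2s[ph$labels == tt$code[tt$name == "WM"]]), 20)
  expect_equal(unique(r2s[ph$labels == tt$code[tt$name == "GP-L"]]), 42.5)
  expect_equal(unique(r2s[ph$labels == tt$code[tt$name == "CMB1"]]), 40)
  expect_equal(unique(r2s[ph$labels == tt$code[tt$name == "PG"]]), 40)
})

test_that("Ernst magnitude limits and stationarity", {
  # TR >> T1, 90 degrees: S -> pd * exp(-TE R2*)
  s <- ernst_magnitude(pd = 0.8, T1_ms = 100, r2star = 25,
                       tr_s = 10, flip_deg = 90, te_s = 0.01)
  expect_equal(s, 0.8 * exp(-0.01 * 25), tolerance = 1e-6)
  # Ernst angle maximizes the signal over flip angle
  tr <- 25e-3; T1 <- 837
  e1 <- exp(-tr / (T1 * 1e-3))
  ernst <- acos(e1) * 180 / pi
  fas <- seq(1, 60, by = 0.5)
  sig <- vapply(fas, function(a)
    ernst_magnitude(1, T1, 0, tr, a, 0), numeric(1))
  expect_equal(fas[which.max(sig)], ernst, tolerance = 0.5)
  # hand-checked WM value at the high flip angle
  a <- 24 * pi / 180
  expected <- 0.73 * sin(a) * (1 - e1) / (1 - cos(a) * e1) * exp(-8.75e-3 * 20)
  expect_equal(ernst_magnitude(0.73, 837, 20, 25e-3, 24, 8.75e-3), expected)
  expect_error(ernst_magnitude(1, -5, 20, 25e-3, 24, 8.75e-3), "T1")
})

test_that("same seed gives a bit-identical dataset", {
  a <- simulate_stage(tiny_spec(), snr = 10, seed = 42)
  b <- simulate_stage(tiny_spec(), snr = 10, seed = 42)
  expect_identical(a$echoes, b$echoes)
})

test_that("measured white-matter SNR matches the requested level", {
  ds0 <- tiny_noiseless()
  ds <- tiny_noisy()
  wm <- ds$labels == tissue_table()$code[tissue_table()$name == "WM"]
  for (nm in names(ds$echoes)) {
    noise <- ds$echoes[[nm]]$magnitude - ds0$echoes[[nm]]$magnitude
    snr_meas <- mean(ds0$echoes[[nm]]$magnitude[wm]) / stats::sd(noise[wm])
    expect_gt(snr_meas, 9); expect_lt(snr_meas, 11)
  }
})

test_that("structural reference has the expected GM/WM contrast sign", {
  ds <- tiny_noiseless()
  tt <- tissue_table()
  gm <- ds$labels == tt$code[tt$name == "GM"]
  wm <- ds$labels == tt$code[tt$name == "WM"]
  # GM T1 > WM T1 => lower GM signal at high flip angle, short TR
  expect_lt(mean(ds$structural[gm]), mean(ds$structural[wm]))
})

test_that("noise-free phase round-trips to the forward field away from wraps", {
  ds <- simulate_stage(tiny_spec(spheres = NULL), snr = Inf, seed = 3)
  K <- make_dipole_kernel(ds$grid)
  dB_true <- forward_field(ds$chi_gt, K)
  e <- ds$echoes$FAL_TE1
  phi_u <- unwrap_phase(e$phase, ds$grid$voxel_size, ds$brain_mask)
  dB <- phase_to_field(phi_u, e$te_s, ds$params$b0_T)
  expect_lt(max(abs((dB - dB_true)[ds$brain_mask])), 1e-6)
})
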