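test_that("temporal profile is the documented piecewise-linear ramp", {
  cfg <- deformation_config(t_onset = 10800, t_peak = 39000, t_return = 48000)
  expect_equal(temporal_profile(0, cfg), 0)
  expect_equal(temporal_profile(10800, cfg), 0)
  expect_equal(temporal_profile(39000, cfg), 1)
  expect_equal(temporal_profile((10800 + 39000) / 2, cfg), 0.5)
  expect_equal(temporal_profile(48000, cfg), 0)
  expect_equal(temporal_profile(43500, cfg), 0.5)
  tt <- seq(0, 50000, by = 100)
  s <- temporal_profile(tt, cfg)
  expect_true(all(s >= 0 & s <= 1))
  expect_lt(max(abs(diff(s))), 0.02)   # continuity at the breakpoints
})

test_that("the amplitude law is zero on the stem and A_tip at the top tips", {
  scene <- scene_model(lamppost = FALSE, spheres = FALSE)
  deform <- deformation_config(A_tip = 0.15)
  expect_equal(deformation_amplitude(scene, deform, rbind(c(0, 0, 0.2))),
               0, tolerance = 1e-12)
  top <- scene$tips[which.max(scene$tips$r * scene$tips$z), c("x", "y", "z")]
  expect_equal(deformation_amplitude(scene, deform, as.matrix(top)), 0.15)
  # amplitudes never exceed A_tip and grow with radius at fixed height
  r <- seq(0, scene$r_max, length.out = 20)
  amps <- deformation_amplitude(scene, deform, cbind(r, 0, scene$z_crown / 2))
  expect_true(all(diff(amps) >= 0))
  expect_lte(max(amps), 0.15)
})

test_that("scan sampling hits expected counts and surfaces", {
  scene <- cylinder_scene(radius = 0.05, length = 0.4)
  area <- 2 * pi * 0.05 * 0.4
  sc <- sample_scan(scene, deform = NULL, density = 1000,
                    stem_density = 10000 / area, sphere_density = 1000,
                    noise_sigma = 0, rng_seed = 1)
  expect_lt(abs(n_points(sc) - 10000), 4 * sqrt(10000))
  # noise-free points lie exactly on the cylinder surface
  rr <- sqrt(sc$coords[, 1]^2 + sc$coords[, 2]^2)
  expect_lt(max(abs(rr - 0.05)), 1e-12)
  expect_true(all(sc$coords[, 3] >= 0 & sc$coords[, 3] <= 0.4))
  expect_true(all(sc$true_disp_m == 0))
})

test_that("sphere components are recovered by the sphere-fit oracle", {
  scene <- scene_model(tree = FALSE, lamppost = FALSE)
  sc <- sample_scan(scene, deform = NULL, sphere_density = 60000,
                    noise_sigma = 0.001, rng_seed = 4)
  for (id in unique(sc$surface_id)) {
    pts <- sc$coords[sc$surface_id == id, , drop = FALSE]
    f <- fit_sphere(pts, fixed_radius = 0.099)
    true_ctr <- scene$surfaces[[which(vapply(scene$surfaces, `[[`, "",
                                             "id") == id)]]$center
    expect_lt(sqrt(sum((f$center - true_ctr)^2)), 0.001)
  }
})

test_that("dropout and occlusion remove points as configured", {
  scene <- scene_model(lamppost = FALSE, spheres = FALSE)
  base <- sample_scan(scene, s = 0, density = 5000, stem_density = 5000,
                      noise_sigma = 0, rng_seed = 7)
  dropped <- sample_scan(scene, s = 0, density = 5000, stem_density = 5000,
                         noise_sigma = 0, dropout = 0.4, rng_seed = 7)
  expect_equal(n_points(dropped) / n_points(base), 0.6, tolerance = 0.03)

  occ <- sample_scan(scene, s = 0, density = 5000, stem_density = 5000,
                     noise_sigma = 0, occlusion = c(0, pi / 2), rng_seed = 7)
  az <- atan2(occ$coords[, 2], occ$coords[, 1]) %% (2 * pi)
  expect_true(all(az >= pi / 2))
})

test_that("generated series carry exact, reproducible ground truth", {
  scene <- scene_model(lamppost = FALSE, spheres = FALSE)
  deform <- deformation_config(A_tip = 0.15)
  sim <- generate_time_series(scene, deform, n_dai = 4, interval_s = 14000,
                              master_seed = 12, density = 2000,
                              stem_density = 2000, noise_sigma = 0)
  # epoch 0 pre-onset: no imposed displacement anywhere
  expect_true(all(sim$dais$clouds[[1]]$true_disp_m == 0))
  # static components never move
  for (cl in sim$dais$clouds) {
    expect_true(all(cl$true_disp_m[cl$component == "stem"] == 0))
  }
  # per-point truth equals s * amplitude law at the undisplaced position
  cl3 <- sim$dais$clouds[[3]]
  moving <- cl3$component %in% c("branch", "blob", "tip_blob")
  base <- cl3$coords - outer(rep(1, n_points(cl3)), c(0, 0, 0))
  expect_true(all(cl3$true_disp_m[moving] <= 0.15 * sim$s[3] + 1e-12))
  # tip truth reaches s * A_tip for the extreme branch
  tt <- sim$tip_truth
  expect_equal(max(tt$true_disp_m[tt$dai == 2]), 0.15 * sim$s[3])
  expect_true(all(tt$true_disp_m[tt$dai == 0] == 0))

  rerun <- generate_time_series(scene, deform, n_dai = 4, interval_s = 14000,
                                master_seed = 12, density = 2000,
                                stem_density = 2000, noise_sigma = 0)
  expect_identical(sim$dais$clouds[[2]]$coords, rerun$dais$clouds[[2]]$coords)
})

test_that("lamppost ground truth is zero at every epoch", {
  scene <- scene_model(tree = FALSE, spheres = FALSE)
  sim <- generate_time_series(scene, deformation_config(), n_dai = 3,
                              master_seed = 2, density = 2000,
                              stem_density = 2000)
  for (cl in sim$dais$clouds) {
    expect_true(all(cl$component == "lamppost"))
    expect_true(all(cl$true_disp_m == 0))
  }
})

test_that("sparser scans lose more clusters to missing epochs", {
  scene <- scene_model(lamppost = FALSE, spheres = FALSE)
  miss_frac <- vapply(c(0, 0.55), function(dr) {
    sim <- generate_time_series(scene, NULL, n_dai = 4, master_seed = 31,
                                density = 25000, stem_density = 25000,
                                noise_sigma = 0.001, dropout = dr)
    tr <- track_sequence(sim$dais, cluster_params(min_size = 40, rng_seed = 31),
                         fparams = filter_params(iso_radius = 0.02))
    mean(tr$missing)
  }, numeric(1))
  expect_lte(miss_frac[1], miss_frac[2])
})
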