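test_that("geometry and acquisition validation behave", {
  expect_warning(scan_geometry(192L, 1.0, 60L), "rule of thumb")
  expect_silent(scan_geometry(64L, 1.0, 120L))
  expect_error(acquisition_spec(0), "tube current")
  acq <- acquisition_spec(100)
  expect_equal(acq$i0, acq$i0_ref / 5)
})

test_that("dose reduction factors follow the linear flux model", {
  expect_equal(dose_reduction_factor(acquisition_spec(100)), 5)
  expect_equal(dose_reduction_factor(acquisition_spec(50)), 10)
  expect_equal(dose_reduction_factor(acquisition_spec(25)), 20)
})

test_that("an all-air volume projects to a zero sinogram", {
  g <- grid_def(c(48L, 48L, 1L), 2)
  air <- image_volume(array(-1000, g$n), g$spacing, g$origin)
  sino <- forward_project(air, scan_geometry(96L, 1.5, 60L, quiet = TRUE))
  expect_equal(max(abs(sino$data)), 0)
  expect_identical(sino$provenance, "ideal")
})

test_that("projection of a centred disk matches the chord length", {
  img <- fx_disk_slice(radius = 30, hu_in = 0)
  geom <- fx_geometry()
  sino <- forward_project(img, geom)
  s_off <- (seq_len(geom$n_detectors) - (geom$n_detectors + 1) / 2) *
    geom$detector_pitch_mm
  chord <- ifelse(abs(s_off) < 30, 2 * 0.02 * sqrt(pmax(30^2 - s_off^2, 0)), 0)
  for (a in c(1L, 45L, 90L))
    expect_lt(max(abs(sino$data[, a, 1] - chord)), 2 * 0.02 * 1.5)
})

test_that("an off-centre disk traces a sinusoid across angles", {
  img <- fx_disk_slice(radius = 15, hu_in = 0, centre = c(20, 0))
  geom <- fx_geometry()
  sino <- forward_project(img, geom)
  s_off <- (seq_len(geom$n_detectors) - (geom$n_detectors + 1) / 2) *
    geom$detector_pitch_mm
  # intensity-weighted projection centroid equals the in-plane offset
  # projected on the detector axis: s(theta) = x0 cos(theta)
  trace <- apply(sino$data[, , 1], 2, function(p) sum(s_off * p) / sum(p))
  expect_lt(max(abs(trace - 20 * cos(geom$angles_rad))), 0.5)
})

test_that("support exceeding the detector span is refused", {
  g <- grid_def(c(96L, 96L, 1L), 3)  # 288 mm field of view
  img <- image_volume(array(0, g$n), g$spacing, g$origin)
  expect_error(forward_project(img, fx_geometry()), "detector span")
})

test_that("count noise vanishes in the high-flux limit", {
  geom <- scan_geometry(4L, 1, 2L, quiet = TRUE)
  sino <- lvdose:::new_sinogram(array(2, c(4, 2, 1)), geom, grid_def(), "ideal")
  acq <- acquisition_spec(500, i0_ref = 1e12, electronic_noise_sd = 0)
  noisy <- simulate_counts(sino, acq, seed = 1)
  expect_lt(max(abs(noisy$data - sino$data)), 1e-3)
})

test_that("log-domain variance matches the delta-method closed form", {
  geom <- scan_geometry(4L, 1, 2L, quiet = TRUE)
  n <- 1e4
  p0 <- 2
  sino <- lvdose:::new_sinogram(array(p0, c(n, 1, 1)), geom, grid_def(),
                                "ideal")
  acq <- acquisition_spec(500, i0_ref = 1e5, electronic_noise_sd = 10)
  noisy <- simulate_counts(sino, acq, seed = 2)
  nbar <- acq$i0 * exp(-p0)
  pred <- (nbar + 10^2) / nbar^2
  expect_lt(abs(var(as.numeric(noisy$data)) - pred) / pred, 0.1)
})

test_that("halving the tube current doubles the quantum-limited variance", {
  geom <- scan_geometry(4L, 1, 2L, quiet = TRUE)
  p0 <- 2
  sino <- lvdose:::new_sinogram(array(p0, c(1e4, 1, 1)), geom, grid_def(),
                                "ideal")
  v <- vapply(c(100, 50), function(mA) {
    acq <- acquisition_spec(mA, i0_ref = 2e5, electronic_noise_sd = 0)
    var(as.numeric(simulate_counts(sino, acq, seed = mA)$data))
  }, numeric(1))
  expect_lt(abs(v[2] / v[1] - 2), 0.2)
})

test_that("incremental injection reproduces a direct low-dose acquisition", {
  geom <- scan_geometry(4L, 1, 2L, quiet = TRUE)
  p0 <- 2
  ideal <- lvdose:::new_sinogram(array(p0, c(1e4, 1, 1)), geom, grid_def(),
                                 "ideal")
  acq_std <- acquisition_spec(500)
  acq_low <- acquisition_spec(100)
  std <- simulate_counts(ideal, acq_std, seed = 3)
  # same dose in = identical sinogram out
  same <- inject_incremental_noise(std, acq_std, acq_std, seed = 4)
  expect_identical(same$data, std$data)
  expect_error(inject_incremental_noise(std, acq_std, acquisition_spec(600)),
               "must not exceed")
  emul <- inject_incremental_noise(std, acq_std, acq_low, seed = 5)
  direct <- simulate_counts(ideal, acq_low, seed = 6)
  # zero-mean injection, and total variance matching the direct route
  expect_lt(abs(mean(emul$data) - mean(std$data)), 4 * sd(std$data) / 100)
  expect_lt(abs(var(as.numeric(emul$data)) / var(as.numeric(direct$data)) - 1),
            0.1)
  expect_lt(abs(mean(emul$data) - mean(direct$data)), 0.005)
})

test_that("FBP reconstructs air from a zero sinogram", {
  g <- grid_def(c(48L, 48L, 1L), 2)
  geom <- scan_geometry(96L, 1.5, 60L, quiet = TRUE)
  zero <- lvdose:::new_sinogram(array(0, c(96, 60, 1)), geom, g, "ideal")
  rec <- fbp_reconstruct(zero, g)
  expect_equal(range(rec$data), c(-1000, -1000))
})

test_that("project-then-reconstruct recovers a water cylinder", {
  img <- fx_disk_slice(radius = 30, hu_in = 0)
  geom <- fx_geometry()
  g <- lvdose:::grid_like(img)
  rec <- fbp_reconstruct(forward_project(img, geom), g)
  w <- lvdose:::voxel_world_coords(g)
  inside <- w[, 1]^2 + w[, 2]^2 <= 20^2
  expect_lt(abs(mean(rec$data[inside])), 10)
})

test_that("noise increases the reconstructed interior variability", {
  img <- fx_disk_slice(radius = 30, hu_in = 0)
  geom <- fx_geometry()
  g <- lvdose:::grid_like(img)
  ideal <- forward_project(img, geom)
  clean <- fbp_reconstruct(ideal, g)
  noisy <- fbp_reconstruct(simulate_counts(ideal, acquisition_spec(50),
                                           seed = 9), g)
  w <- lvdose:::voxel_world_coords(g)
  inside <- w[, 1]^2 + w[, 2]^2 <= 20^2
  expect_gt(sd(noisy$data[inside]), sd(clean$data[inside]))
})

test_that("the dose ladder shares one grid and degrades monotonically", {
  spec <- phantom_spec()
  g <- grid_def(c(48L, 48L, 48L), 3)
  vox <- voxelize_phase(spec, "ED", g)
  geom <- scan_geometry(112L, 1.4, 90L, quiet = TRUE)
  acq <- acquisition_spec(500)
  expect_error(emulate_dose_ladder(vox$image, geom, acq, c(100, 500)),
               "descending")
  expect_error(emulate_dose_ladder(vox$image, geom, acq, c(400, 100)),
               "standard")
  single <- emulate_dose_ladder(vox$image, geom, acq, 500, seed = 11)
  expect_length(single, 1L)
  ladder <- emulate_dose_ladder(vox$image, geom, acq,
                                c(500, 100, 50, 25, 10), seed = 11)
  expect_named(ladder, c("500", "100", "50", "25", "10"))
  for (v in ladder) expect_identical(dim(v$data), g$n)
  interior <- lvdose:::erode6(vox$labels$data == 1L)
  sds <- vapply(ladder, function(v) sd(v$data[interior]), numeric(1))
  expect_true(all(diff(sds) >= 0))
})

test_that("stochastic CT stages are reproducible from their seeds", {
  img <- fx_disk_slice(radius = 30, hu_in = 0)
  geom <- fx_geometry()
  ideal <- forward_project(img, geom)
  acq <- acquisition_spec(100)
  a <- simulate_counts(ideal, acq, seed = 21)
  b <- simulate_counts(ideal, acq, seed = 21)
  expect_identical(a$data, b$data)
})
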