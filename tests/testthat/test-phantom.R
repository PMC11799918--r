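test_that("phantom spec validation rejects degenerate anatomy", {
  expect_error(phantom_spec(endo_long_axis_mm = 52, epi_long_axis_mm = 52),
               "wall")
  expect_error(phantom_spec(endo_short_axis_mm = 40, endo_long_axis_mm = 30),
               "prolate")
  expect_error(phantom_spec(es_radial_scale = 0), "ES scales")
  expect_error(phantom_spec(es_radial_scale = 1.2), "ES scales")
  expect_error(phantom_spec(base_truncation_frac = 1), "base_truncation_frac")
  expect_error(phantom_spec(orientation = diag(c(1, 1, -1))), "rotation")
})

test_that("identical parameters and seed give identical specs", {
  s1 <- build_phantom_spec(target_ef_pct = 55, seed = 42)
  s2 <- build_phantom_spec(target_ef_pct = 55, seed = 42)
  expect_identical(s1, s2)
})

test_that("target-EF root finding matches numeric volume integration", {
  spec <- build_phantom_spec(target_ef_pct = 60)
  ed <- lvdose:::phase_geometry(spec, "ED")
  es <- lvdose:::phase_geometry(spec, "ES")
  f <- spec$base_truncation_frac
  edv <- oracle_trunc_volume(ed$endo_short, ed$endo_long, f)
  esv <- oracle_trunc_volume(es$endo_short, es$endo_long, f)
  expect_equal(100 * (edv - esv) / edv, 60, tolerance = 0.5 / 60)
  expect_equal(analytic_ground_truth(spec)$ef_pct, 60, tolerance = 1e-6)
  expect_error(build_phantom_spec(target_ef_pct = 95), "target_ef_pct")
})

test_that("analytic ground truth has the closed-form limits", {
  id <- phantom_spec(es_radial_scale = 1, es_long_scale = 1)
  gt <- analytic_ground_truth(id)
  expect_equal(gt$ef_pct, 0)
  expect_equal(gt$gls_pct, 0)
  expect_equal(unname(gt$cs_pct), c(0, 0, 0))
  expect_equal(unname(gt$wt_pct), c(0, 0, 0))
  # lengths scale linearly with the longitudinal scale
  long_only <- phantom_spec(es_radial_scale = 1, es_long_scale = 0.8,
                            wall_model = "fixed-thickness")
  expect_equal(analytic_ground_truth(long_only)$gls_pct, -20)
})

test_that("analytic EF agrees with a fine quadrature oracle", {
  spec <- phantom_spec()
  gt <- analytic_ground_truth(spec)
  ed <- lvdose:::phase_geometry(spec, "ED")
  es <- lvdose:::phase_geometry(spec, "ES")
  f <- spec$base_truncation_frac
  ef_num <- 100 * (1 - oracle_trunc_volume(es$endo_short, es$endo_long, f) /
                     oracle_trunc_volume(ed$endo_short, ed$endo_long, f))
  expect_equal(gt$ef_pct, ef_num, tolerance = 0.1 / gt$ef_pct)
})

test_that("ground-truth metrics are invariant under orientation", {
  set.seed(8)
  R <- lvdose:::random_rotation()
  a <- analytic_ground_truth(phantom_spec())
  b <- analytic_ground_truth(phantom_spec(orientation = R))
  expect_equal(a, b)
})

test_that("volume-preserving wall model conserves the myocardial shell", {
  spec <- phantom_spec()
  f <- spec$base_truncation_frac
  ed <- lvdose:::phase_geometry(spec, "ED")
  es <- lvdose:::phase_geometry(spec, "ES")
  v_myo <- function(g) {
    lvdose:::trunc_ellipsoid_volume(g$epi_short, g$epi_long,
                                    g$basal_height / g$epi_long) -
      lvdose:::trunc_ellipsoid_volume(g$endo_short, g$endo_long,
                                      g$basal_height / g$endo_long)
  }
  expect_equal(v_myo(ed), v_myo(es), tolerance = 1e-8)
  # and the ES wall is thicker than the ED wall (systolic thickening)
  expect_gt(es$epi_short - es$endo_short, ed$epi_short - ed$endo_short)
})

test_that("voxelized labels are valid and the cavity is enclosed", {
  fx <- fx_default_phantom()
  expect_true(all(fx$ed$labels$data %in% 0:2))
  expect_identical(cavity_exposure_count(fx$ed$labels), 0L)
  expect_identical(cavity_exposure_count(fx$es$labels), 0L)
  expect_true(same_grid <- identical(dim(fx$ed$labels$data),
                                     dim(fx$ed$image$data)))
})

test_that("voxel-counted cavity volume converges to the analytic value", {
  spec <- phantom_spec()
  gt <- analytic_ground_truth(spec)
  vol_at <- function(sp, n) {
    lab <- voxelize_phase(spec, "ED", grid_def(c(n, n, n), sp))$labels
    sum(lab$data == 2L) * sp^3 / 1000
  }
  v_coarse <- vol_at(1.5, 96L)
  v_fine <- vol_at(0.75, 168L)
  expect_lt(abs(v_coarse - gt$edv_ml) / gt$edv_ml, 0.02)
  expect_lt(abs(v_fine - gt$edv_ml) / gt$edv_ml, 0.02)
  expect_lt(abs(v_fine - gt$edv_ml), abs(v_coarse - gt$edv_ml))
})

test_that("a grid too small to contain the phantom is refused", {
  expect_error(voxelize_phase(phantom_spec(), "ED",
                              grid_def(c(32L, 32L, 32L), 1.5)),
               "half-extent")
})

test_that("cohort generation is reproducible and spans the EF range", {
  n <- 10L
  c1 <- generate_cohort(n, seed = 5)
  c2 <- generate_cohort(n, seed = 5)
  expect_identical(c1, c2)
  expect_length(c1, n)
  params <- t(vapply(c1, function(s)
    c(s$endo_short_axis_mm, s$endo_long_axis_mm), numeric(2)))
  expect_identical(nrow(unique(params)), n)
  ranges <- list(endo_short_axis_mm = c(20, 27),
                 endo_long_axis_mm = c(40, 50),
                 wall_thickness_mm = c(8, 12),
                 apex_wall_frac = c(0.6, 0.8),
                 target_ef_pct = c(20, 70))
  efs <- vapply(generate_cohort(n, ranges, seed = 6),
                function(s) analytic_ground_truth(s)$ef_pct, numeric(1))
  expect_true(all(efs >= 19.5 & efs <= 70.5))
  expect_error(generate_cohort(0), "n must be")
  expect_error(generate_cohort(3, list(endo_short_axis_mm = c(27, 20),
                                       endo_long_axis_mm = c(40, 50),
                                       wall_thickness_mm = c(8, 12),
                                       apex_wall_frac = c(0.6, 0.8),
                                       target_ef_pct = c(35, 70))),
               "invalid range")
})
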