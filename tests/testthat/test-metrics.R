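make_labels <- function(arr, sp = 2) label_volume(arr, sp)

test_that("Dice has its closed-form values and symmetry", {
  a <- array(0L, c(6L, 6L, 6L)); a[2:3, 2:3, 2:3] <- 1L
  b <- array(0L, c(6L, 6L, 6L)); b[3:4, 2:3, 2:3] <- 1L
  la <- make_labels(a); lb <- make_labels(b)
  expect_equal(dice(la, la, 1L), 1)
  expect_equal(dice(la, lb, 1L), 0.5)  # |A|=|B|=8, overlap 4
  disjoint <- make_labels(array(0L, c(6L, 6L, 6L)))
  expect_equal(dice(la, disjoint, 1L), 0)
  expect_equal(dice(disjoint, disjoint, 2L), 1)  # both empty
  expect_equal(dice(la, lb, 1L), dice(lb, la, 1L))
  expect_error(dice(la, make_labels(a, sp = 3), 1L), "same grid")
})

test_that("EF is volume arithmetic on the blood pool", {
  # EDV:ESV = 150:60 in 8 mm^3 voxels (1500 and 600 voxels)
  ed <- array(0L, c(20L, 20L, 20L)); ed[seq_len(1500L)] <- 2L
  es <- array(0L, c(20L, 20L, 20L)); es[seq_len(600L)] <- 2L
  led <- make_labels(ed); les <- make_labels(es)
  expect_equal(ejection_fraction(led, les), 60)
  expect_equal(ejection_fraction(led, led), 0)
  empty <- make_labels(array(0L, c(20L, 20L, 20L)))
  expect_error(ejection_fraction(empty, les), "zero EDV")
})

test_that("GLS follows the cavity-length ratio of the long-axis views", {
  ed <- fx_view_set(fx_long_view(80L), fx_long_view(80L))
  es <- fx_view_set(fx_long_view(64L), fx_long_view(64L))
  expect_equal(gls(ed, es), -20)
  expect_equal(gls(ed, ed), 0)
  missing <- structure(list(views = list("2CH" = fx_long_view(80L))),
                       class = "view_set")
  expect_error(gls(missing, es), "missing long-axis view")
})

test_that("CS follows the perimeter ratio of circular cavities", {
  ed <- fx_ring_view(25, 35)
  es <- fx_ring_view(20, 32)
  expect_equal(circumferential_strain(ed, es), -20, tolerance = 0.5 / 20)
  expect_equal(circumferential_strain(ed, ed), 0)
  empty <- fx_ring_view(25, 35)
  empty$blood_frac[] <- 0
  ob <- circumferential_strain(ed, empty)
  expect_equal(as.numeric(ob), -100)
  expect_true(attr(ob, "obliterated"))
  expect_error(circumferential_strain(empty, es), "empty blood pool")
})

test_that("uniform ring thickening gives identical spokes", {
  ed <- fx_ring_view(25, 35)   # 10 mm wall
  es <- fx_ring_view(20, 34)   # 14 mm wall
  wt <- wall_thickening(ed, es)
  expect_length(wt$spokes_pct, 16L)
  expect_equal(wt$avg_pct, 40, tolerance = 0.05)
  expect_lt(max(abs(wt$spokes_pct - 40)), 5)  # pixelated fixture quantization
  wt0 <- wall_thickening(ed, ed)
  expect_equal(wt0$avg_pct, 0, tolerance = 1e-6)
  expect_equal(unname(wt0$spokes_pct), rep(0, 16), tolerance = 1e-6)
})

test_that("rays failing to cross the ring are flagged, many are an error", {
  ed <- fx_ring_view(25, 35)
  # no myocardium at all: every ray exits into background
  bare <- fx_ring_view(25, 25.01)
  bare$myo_frac[] <- 0
  expect_error(wall_thickening(bare, bare), "spokes failed")
})

test_that("Pearson correlation matches hand arithmetic", {
  expect_equal(pearson(1:4, 1:4), 1)
  expect_equal(pearson(1:4, -(1:4)), -1)
  # x=[1,2,3,4], y=[2,1,4,3]: cov = 3/3, sd product = 5/3 -> rho = 0.6
  expect_equal(pearson(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_error(pearson(1:3, 1:4), "unequal")
  expect_error(pearson(1:2, 1:2), "at least 3")
  expect_error(pearson(c(1, 1, 1), 1:3), "constant")
})

test_that("an identity deformation yields near-zero metrics everywhere", {
  spec <- phantom_spec(es_radial_scale = 1, es_long_scale = 1)
  g <- grid_def(c(96L, 96L, 96L), 1.5)
  ed <- voxelize_phase(spec, "ED", g)
  es <- voxelize_phase(spec, "ES", g)
  m <- compute_all(ed$labels, es$labels)
  expect_lt(abs(m$ef_pct), 1)
  expect_lt(abs(m$gls_pct), 1)
  expect_lt(max(abs(m$cs_pct)), 1)
  expect_lt(max(abs(m$wt_avg_pct)), 1)
})

test_that("measured metrics recover the analytic ground truth", {
  spec <- phantom_spec()
  gt <- analytic_ground_truth(spec)
  g <- grid_def(c(168L, 168L, 168L), 0.75)
  ed <- voxelize_phase(spec, "ED", g)
  es <- voxelize_phase(spec, "ES", g)
  m <- compute_all(ed$labels, es$labels)
  expect_lt(abs(m$ef_pct - gt$ef_pct), 1)
  expect_lt(abs(m$gls_pct - gt$gls_pct), 1)
  expect_lt(max(abs(m$cs_pct - gt$cs_pct)), 1)
  expect_lt(max(abs(m$wt_avg_pct - gt$wt_pct)), 2)
  expect_identical(dim(m$wt_spokes_pct), c(16L, 3L))
})

test_that("metrics are equivariant under phantom rotation", {
  set.seed(17)
  R <- lvdose:::random_rotation()
  # 0.75 mm: at coarser grids the canonical pose is adversarial (basal
  # plane exactly on voxel centres), which tests alignment artefacts
  # rather than equivariance
  g <- grid_def(c(168L, 168L, 168L), 0.75)
  m0 <- {
    spec <- phantom_spec()
    compute_all(voxelize_phase(spec, "ED", g)$labels,
                voxelize_phase(spec, "ES", g)$labels)
  }
  m1 <- {
    spec <- phantom_spec(orientation = R)
    compute_all(voxelize_phase(spec, "ED", g)$labels,
                voxelize_phase(spec, "ES", g)$labels)
  }
  expect_lt(abs(m0$ef_pct - m1$ef_pct), 1)
  expect_lt(abs(m0$gls_pct - m1$gls_pct), 1)
  expect_lt(max(abs(m0$cs_pct - m1$cs_pct)), 1)
  expect_lt(max(abs(m0$wt_avg_pct - m1$wt_avg_pct)), 2)
})

test_that("ratio metrics are invariant to uniform spatial rescaling", {
  # the same voxel data at doubled spacing, with the view sampling scaled
  # alongside: EF/GLS/CS are pure ratios
  fx <- fx_default_phantom()
  ed2 <- label_volume(fx$ed$labels$data, fx$ed$labels$spacing * 2)
  es2 <- label_volume(fx$es$labels$data, fx$es$labels$spacing * 2)
  m1 <- compute_all(fx$ed$labels, fx$es$labels)
  m2 <- compute_all(ed2, es2, view_config(pixel_spacing_mm = 2,
                                          fov_mm = 320))
  expect_equal(m1$ef_pct, m2$ef_pct, tolerance = 1e-10)
  expect_lt(abs(m1$gls_pct - m2$gls_pct), 1)
  expect_lt(max(abs(m1$cs_pct - m2$cs_pct)), 1)
})
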