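test_that("generalized Dice loss matches an independent evaluation", {
  # 4-voxel, 2-class toy: reference class-1 = [1,1,0,0],
  # class-1 probabilities [0.8, 0.6, 0.3, 0.1]
  p1 <- c(0.8, 0.6, 0.3, 0.1)
  p <- cbind(1 - p1, p1)
  r <- cbind(c(0, 0, 1, 1), c(1, 1, 0, 0))
  eps <- 1e-5
  # independent arithmetic, written out term by term
  w0 <- 1 / (2 + eps)^2
  w1 <- 1 / (2 + eps)^2
  num <- w0 * (0.7 + 0.9) + w1 * (0.8 + 0.6)
  den <- w0 * (2 + 0.2 + 0.4 + 0.7 + 0.9) + w1 * (2 + 0.8 + 0.6 + 0.3 + 0.1)
  expect_equal(generalized_dice_loss(p, r), 1 - 2 * num / den,
               tolerance = 1e-12)
})

test_that("generalized Dice loss has the right extremes", {
  r <- cbind(c(1, 0), c(0, 1))
  expect_lt(generalized_dice_loss(r, r), 1e-4)
  wrong <- cbind(c(0, 1), c(1, 0))
  expect_equal(generalized_dice_loss(wrong, r), 1)
  expect_error(generalized_dice_loss(r[1, , drop = FALSE], r), "shapes")
  expect_error(generalized_dice_loss(cbind(c(2, 0), c(0, 1)), r), "sum to 1")
})

test_that("GDL is voxel-permutation invariant and monotone", {
  set.seed(3)
  p1 <- runif(20)
  p <- cbind(1 - p1, p1)
  r1 <- sample(0:1, 20, TRUE)
  r <- cbind(1 - r1, r1)
  perm <- sample(20)
  expect_equal(generalized_dice_loss(p, r),
               generalized_dice_loss(p[perm, ], r[perm, ]))
  # 2-voxel probe: loss strictly decreases as mass moves to the reference
  ref <- cbind(c(1, 0), c(0, 1))
  losses <- vapply(seq(0.1, 0.9, by = 0.1), function(q)
    generalized_dice_loss(cbind(c(q, 1 - q), c(1 - q, q)), ref), numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("GDL training gradient agrees with finite differences", {
  set.seed(4)
  p1 <- runif(12, 0.05, 0.95)
  p <- cbind(1 - p1, p1)
  r1 <- sample(0:1, 12, TRUE)
  r <- cbind(1 - r1, r1)
  g <- lvdose:::gdl_grad(p, r)
  eps <- 1e-6
  for (i in c(1L, 7L, 20L)) {
    pp <- p; pp[i] <- pp[i] + eps
    pm <- p; pm[i] <- pm[i] - eps
    fd <- (lvdose:::gdl_train(pp, r) - lvdose:::gdl_train(pm, r)) / (2 * eps)
    expect_equal(g[i], fd, tolerance = 1e-5)
  }
})

test_that("rule-based segmentation is exact on a noise-free phantom", {
  fx <- fx_default_phantom()
  seg <- rule_based_segment(fx$ed$image)
  # interior agreement: away from the (ambiguous) one-voxel boundary shell
  for (cls in 1:2) {
    interior <- lvdose:::erode6(fx$ed$labels$data == cls)
    expect_true(all(seg$data[interior] == cls))
  }
  expect_gte(dice(seg, fx$ed$labels, 1), 0.99)
  expect_gte(dice(seg, fx$ed$labels, 2), 0.99)
})

test_that("rule-based segmentation handles edge inputs", {
  g <- grid_def(c(16L, 16L, 16L), 2)
  bg <- image_volume(array(40, g$n), g$spacing, g$origin)
  expect_true(all(rule_based_segment(bg)$data == 0L))
  expect_error(rule_based_segment(bg, c(225, 70)), "increasing")
  expect_error(rule_observer(c(225, 70)), "increasing")
})

test_that("training selects cases per recipe and learns on a toy set", {
  set.seed(11)
  g <- grid_def(c(24L, 24L, 24L), 3)
  cases <- list()
  for (i in 1:2) {
    spec <- phantom_spec(endo_short_axis_mm = 18, endo_long_axis_mm = 28,
                         epi_short_axis_mm = 25, epi_long_axis_mm = 34)
    vox <- voxelize_phase(spec, if (i == 1) "ED" else "ES", g)
    img <- vox$image
    img$data <- img$data + array(rnorm(length(img$data), 0, 15), dim(img$data))
    cases[[i]] <- training_case(img, vox$labels, paste0("case", i), "SD")
    low <- img
    low$data <- low$data + array(rnorm(length(img$data), 0, 30),
                                 dim(img$data))
    cases[[i + 2]] <- training_case(low, vox$labels, paste0("case", i), "25")
  }
  cfg <- net_config(base_channels = 2L, patch_size = c(16L, 16L, 16L))
  rec <- train_recipe(learning_rate = 2e-2, batch_size = 2L, epochs = 6L,
                      batches_per_epoch = 4L, doses_included = "SD", seed = 2)
  obs <- train_observer(cfg, rec, cases)
  # dataset audit: the Standard recipe saw only standard-dose cases
  expect_true(all(obs$dataset_audit$dose == "SD"))
  expect_identical(nrow(obs$dataset_audit), 2L)
  # the Noise-Robust recipe additionally includes the low-dose cases
  rec_nr <- train_recipe(learning_rate = 2e-2, batch_size = 2L, epochs = 1L,
                         batches_per_epoch = 1L, doses_included = "all",
                         seed = 2)
  obs_nr <- train_observer(cfg, rec_nr, cases)
  expect_setequal(unique(obs_nr$dataset_audit$dose), c("SD", "25"))
  # learning sanity: the loss comes down
  expect_lt(obs$loss_history[length(obs$loss_history)], obs$loss_history[1])
  # reproducibility: identical recipe and data give an identical loss curve
  obs2 <- train_observer(cfg, rec, cases)
  expect_identical(obs$loss_history, obs2$loss_history)
  # dose filter with no survivors
  expect_error(train_observer(cfg, train_recipe(doses_included = "999"),
                              cases), "no training cases")
  # patch larger than the volume
  big <- net_config(base_channels = 2L, patch_size = c(64L, 64L, 64L))
  expect_error(train_observer(big, rec, cases), "larger than volume")

  # inference: grid metadata preserved, deterministic, valid labels
  seg1 <- segment_volume(obs, cases[[1]]$image)
  seg2 <- segment_volume(obs, cases[[1]]$image)
  expect_identical(seg1$data, seg2$data)
  expect_equal(seg1$spacing, cases[[1]]$image$spacing)
  expect_equal(seg1$origin, cases[[1]]$image$origin)
  expect_true(all(seg1$data %in% 0:2))
  expect_error(segment_volume(list(), cases[[1]]$image), "not a trained")
})
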