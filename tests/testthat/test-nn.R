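test_that("network configuration enforces its invariants", {
  expect_error(net_config(patch_size = c(20L, 20L, 20L)), "divisible")
  cfg <- net_config(base_channels = 2L, patch_size = c(16L, 16L, 16L))
  expect_identical(cfg$n_levels, 4L)
  expect_identical(cfg$n_classes, 3L)
})

test_that("backpropagation matches finite differences", {
  set.seed(1)
  cfg <- net_config(n_levels = 3L, base_channels = 2L,
                    patch_size = c(8L, 8L, 8L), ds_weights = c(1, 0.5))
  params <- lvdose:::nn_init_unet(cfg, seed = 2)
  x <- array(rnorm(512), c(8L, 8L, 8L))
  y <- array(sample(0:2, 512, TRUE), c(8L, 8L, 8L))
  ws <- lvdose:::cfg_head_weights(cfg)
  wsum <- sum(unlist(ws))
  loss_of <- function(par) {
    fw <- lvdose:::unet_forward(par, x, cfg)
    tot <- 0
    for (nm in names(fw$logits)) {
      ref <- lvdose:::one_hot(as.integer(
        lvdose:::downsample_labels(y, as.integer(nm))))
      pr <- lvdose:::softmax_rows(lvdose:::as_class_matrix(fw$logits[[nm]]))
      tot <- tot + ws[[nm]] * lvdose:::gdl_train(pr, ref)
    }
    tot / wsum
  }
  fw <- lvdose:::unet_forward(params, x, cfg, want_cache = TRUE)
  dlog <- list()
  for (nm in names(fw$logits)) {
    ref <- lvdose:::one_hot(as.integer(
      lvdose:::downsample_labels(y, as.integer(nm))))
    pr <- lvdose:::softmax_rows(lvdose:::as_class_matrix(fw$logits[[nm]]))
    gp <- (ws[[nm]] / wsum) * lvdose:::gdl_grad(pr, ref)
    dz <- pr * (gp - rowSums(gp * pr))
    dlog[[nm]] <- array(dz, dim(fw$logits[[nm]]))
  }
  gr <- lvdose:::nn_leaves(lvdose:::unet_backward(params, fw$cache, dlog, cfg))
  leaves <- lvdose:::nn_leaves(params)
  eps <- 1e-5
  set.seed(5)
  for (key in sample(names(leaves), 5)) {
    i <- sample(length(leaves[[key]]), 1)
    plus <- leaves; plus[[key]][i] <- plus[[key]][i] + eps
    minus <- leaves; minus[[key]][i] <- minus[[key]][i] - eps
    fd <- (loss_of(lvdose:::nn_assign_leaves(params, plus)) -
             loss_of(lvdose:::nn_assign_leaves(params, minus))) / (2 * eps)
    an <- gr[[key]][i]
    expect_lt(abs(fd - an), 1e-6 + 1e-3 * max(abs(fd), abs(an)))
  }
})

test_that("nearest upsampling and its adjoint are consistent", {
  x <- array(rnorm(2 * 2 * 2 * 3), c(2L, 2L, 2L, 3L))
  up <- lvdose:::upsample2_fwd(x)
  expect_identical(dim(up), c(4L, 4L, 4L, 3L))
  expect_equal(up[1, 1, 1, ], x[1, 1, 1, ])
  expect_equal(up[2, 2, 2, ], x[1, 1, 1, ])
  # adjoint test: <up(x), y> == <x, up^T(y)>
  y <- array(rnorm(length(up)), dim(up))
  down <- lvdose:::upsample2_bwd(y, dim(x))
  expect_equal(sum(up * y), sum(x * down))
})

test_that("forward inference is deterministic and shape-preserving", {
  cfg <- net_config(base_channels = 2L, patch_size = c(16L, 16L, 16L))
  params <- lvdose:::nn_init_unet(cfg, seed = 9)
  x <- array(rnorm(16^3), c(16L, 16L, 16L))
  f1 <- lvdose:::unet_forward(params, x, cfg)
  f2 <- lvdose:::unet_forward(params, x, cfg)
  expect_identical(f1$logits, f2$logits)
  expect_identical(dim(f1$logits[["1"]]), c(16L, 16L, 16L, 3L))
  expect_identical(dim(f1$logits[["2"]]), c(8L, 8L, 8L, 3L))
})
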