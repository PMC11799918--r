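#' Generalized Dice loss
#'
#' Multi-class Dice-based loss with inverse-squared class-volume weights:
#' `GDL = 1 - 2 (sum_l w_l sum_n r_ln p_ln) / (sum_l w_l sum_n (r_ln + p_ln))`
#' with `w_l = 1 / (sum_n r_ln + eps)^2`. Zero for a perfect prediction,
#' one when all probability mass sits on wrong classes.
#'
#' @param class_probabilities voxels-by-classes matrix (or array with the
#'   class as last dimension); rows must sum to 1.
#' @param one_hot_reference matching one-hot reference.
#' @param epsilon class-volume stabilizer.
#' @return scalar loss in [0, 1].
#' @export
generalized_dice_loss <- function(class_probabilities, one_hot_reference,
                                  epsilon = 1e-5) {
  p <- as_class_matrix(class_probabilities)
  r <- as_class_matrix(one_hot_reference)
  if (!all(dim(p) == dim(r)))
    stop("generalized_dice_loss: probability and reference shapes differ")
  if (max(abs(rowSums(p) - 1)) > 1e-4)
    stop("generalized_dice_loss: probabilities must sum to 1 per voxel")
  w <- gdl_weights(r, epsilon, clamp_empty = FALSE)
  num <- sum(w * colSums(r * p))
  den <- sum(w * colSums(r + p))
  1 - 2 * num / den
}

# Inverse-squared class-volume weights. For training, classes absent from
# a patch get the largest finite weight instead of the 1/eps^2 blow-up
# (the usual stabilization in generalized-Dice implementations): absent
# classes must still be suppressed, but with a bounded gradient scale.
gdl_weights <- function(r, epsilon = 1e-5, clamp_empty = TRUE) {
  n <- colSums(r)
  w <- 1 / (n + epsilon)^2
  if (clamp_empty && any(n == 0) && any(n > 0))
    w[n == 0] <- max(w[n > 0])
  w
}

as_class_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  d <- dim(x)
  matrix(x, prod(d[-length(d)]), d[length(d)])
}

# Training-side generalized Dice loss with clamped empty-class weights.
gdl_train <- function(p, r, epsilon = 1e-5) {
  w <- gdl_weights(r, epsilon)
  1 - 2 * sum(w * colSums(r * p)) / sum(w * colSums(r + p))
}

# Gradient of the (training-side) generalized Dice loss wrt probabilities.
gdl_grad <- function(p, r, epsilon = 1e-5) {
  w <- gdl_weights(r, epsilon)
  num <- sum(w * colSums(r * p))
  den <- sum(w * colSums(r + p))
  # d/dp_ln [1 - 2 num/den] = -2 (w_l r_ln den - num w_l) / den^2
  -2 * (sweep(r, 2, w, "*") * den - num *
          matrix(w, nrow(p), ncol(p), byrow = TRUE)) / den^2
}

one_hot <- function(labels_int, n_classes = 3L) {
  m <- matrix(0, length(labels_int), n_classes)
  m[cbind(seq_along(labels_int), labels_int + 1L)] <- 1
  m
}

#' Training recipe for the network observer
#'
#' The two training regimes of the study are expressed through
#' `doses_included`: the Standard observer trains on standard-dose volumes
#' only (`"SD"`), the Noise-Robust observer additionally on the emulated
#' low-dose volumes of the same cases.
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size patches per optimization step.
#' @param epochs training epochs.
#' @param batches_per_epoch optimization steps per epoch.
#' @param doses_included character vector of dose tags a training case
#'   must match (`"SD"`, `"100"`, ...), or `"all"`.
#' @param fg_bias probability that a sampled patch is centred on a
#'   foreground voxel.
#' @param lr_schedule `"cosine"` (decay to zero over the run; stabilizes
#'   the short, small-batch scaled-down trainings) or `"constant"`.
#' @param grad_clip clip the global gradient norm at this value before
#'   the optimizer step (`Inf` to disable); the generalized Dice loss
#'   produces occasional gradient spikes on patches with tiny classes.
#' @param seed RNG seed for initialization and patch sampling.
#' @return a `train_recipe`.
#' @export
train_recipe <- function(learning_rate = 5e-4, batch_size = 32L,
                         epochs = 200L, batches_per_epoch = 8L,
                         doses_included = "SD", fg_bias = 0.5,
                         lr_schedule = c("cosine", "constant"),
                         grad_clip = 1.0, seed = 1L) {
  if (learning_rate <= 0 || batch_size < 1 || epochs < 1 ||
      batches_per_epoch < 1)
    stop("train_recipe: learning rate, batch size and epochs must be positive")
  structure(list(optimizer = "adam", learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 batches_per_epoch = as.integer(batches_per_epoch),
                 doses_included = doses_included, fg_bias = fg_bias,
                 lr_schedule = match.arg(lr_schedule),
                 grad_clip = grad_clip, seed = seed),
            class = "train_recipe")
}

#' Bundle a training case
#'
#' @param image an [image_volume()].
#' @param labels the matching [label_volume()].
#' @param case_id case identifier.
#' @param dose dose tag (`"SD"` or the tube current as character).
#' @return a training-case list.
#' @export
training_case <- function(image, labels, case_id, dose = "SD") {
  if (!same_grid(image, labels))
    stop("training_case: image and labels are not on the same grid")
  list(image = image, labels = labels, case_id = case_id,
       dose = as.character(dose))
}

normalize_hu <- function(hu, centre = 150, scale = 200) (hu - centre) / scale

sample_patch <- function(case, patch, fg_bias) {
  d <- dim(case$image$data)
  if (any(d < patch))
    stop("train_observer: patch ", paste(patch, collapse = "x"),
         " larger than volume ", paste(d, collapse = "x"))
  fg <- case$fg_idx
  centre <- if (length(fg) && runif(1) < fg_bias) {
    i <- fg[sample.int(length(fg), 1L)]
    c((i - 1) %% d[1], ((i - 1) %/% d[1]) %% d[2],
      (i - 1) %/% (d[1] * d[2])) + 1
  } else {
    sapply(d, function(n) sample.int(n, 1L))
  }
  lo <- pmin(pmax(centre - patch %/% 2L, 1L), d - patch + 1L)
  hi <- lo + patch - 1L
  list(x = case$image$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]],
       y = case$labels$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]])
}

# Deep-supervision references: labels nearest-downsampled by 2^(l-1).
downsample_labels <- function(y, l) {
  if (l == 1L) return(y)
  s <- 2L^(l - 1L)
  d <- dim(y)
  y[seq(1L, d[1], s), seq(1L, d[2], s), seq(1L, d[3], s)]
}

#' Train a network observer
#'
#' Patch-based training of the residual 3D U-Net with the generalized Dice
#' loss, Adam, and (optionally) deep supervision: auxiliary losses at the
#' coarser decoder resolutions, combined with the configured weights.
#' Patches are sampled with a foreground bias; no data augmentation is
#' applied. Training is reproducible: a fixed (recipe, data) pair yields
#' an identical loss history.
#'
#' @param config a [net_config()].
#' @param recipe a [train_recipe()]; its `doses_included` selects which
#'   training cases participate (the dataset audit records the selection).
#' @param cases list of [training_case()]s.
#' @return an `lv_observer` (type `"unet"`) with the trained parameters,
#'   per-epoch loss history and a dataset audit table.
#' @export
train_observer <- function(config, recipe, cases) {
  keep <- if (identical(recipe$doses_included, "all")) seq_along(cases)
    else which(vapply(cases, function(cs) cs$dose %in% recipe$doses_included,
                      logical(1)))
  if (!length(keep)) stop("train_observer: no training cases after the ",
                          "dose filter (", paste(recipe$doses_included,
                                                 collapse = ","), ")")
  cases <- cases[keep]
  audit <- data.frame(
    case_id = vapply(cases, `[[`, character(1), "case_id"),
    dose = vapply(cases, `[[`, character(1), "dose"))
  for (i in seq_along(cases))
    cases[[i]]$fg_idx <- which(cases[[i]]$labels$data != 0L)
  params <- nn_init_unet(config, seed = derive_seed(recipe$seed, "init"))
  leaves <- nn_leaves(params)
  opt <- adam_init(leaves)
  ds_w <- if (config$deep_supervision)
    cfg_head_weights(config) else c("1" = 1)
  loss_history <- numeric(recipe$epochs)
  with_seed(derive_seed(recipe$seed, "sampling"), {
    for (ep in seq_len(recipe$epochs)) {
      lr <- if (recipe$lr_schedule == "cosine")
        recipe$learning_rate * 0.5 * (1 + cos(pi * (ep - 1) / recipe$epochs))
      else recipe$learning_rate
      # linear warmup over the first tenth of the run: the generalized
      # Dice loss is spiky early on and can kill a class irrecoverably
      warm <- ceiling(recipe$epochs / 10)
      if (ep <= warm) lr <- lr * ep / (warm + 1)
      ep_loss <- 0
      for (bt in seq_len(recipe$batches_per_epoch)) {
        gacc <- NULL
        bloss <- 0
        for (s in seq_len(recipe$batch_size)) {
          cs <- cases[[sample.int(length(cases), 1L)]]
          pt <- sample_patch(cs, config$patch_size, recipe$fg_bias)
          fw <- unet_forward(params, normalize_hu(pt$x), config,
                             want_cache = TRUE)
          dlog <- list()
          loss <- 0
          for (nm in names(fw$logits)) {
            l <- as.integer(nm)
            ref <- one_hot(as.integer(downsample_labels(pt$y, l)))
            z <- as_class_matrix(fw$logits[[nm]])
            p <- softmax_rows(z)
            loss <- loss + ds_w[[nm]] * gdl_train(p, ref)
            gp <- ds_w[[nm]] * gdl_grad(p, ref)
            dz <- p * (gp - rowSums(gp * p))
            dlog[[nm]] <- array(dz, dim(fw$logits[[nm]]))
          }
          bloss <- bloss + loss / sum(unlist(ds_w))
          gr <- nn_leaves(unet_backward(params, fw$cache, dlog, config))
          gacc <- if (is.null(gacc)) gr
            else mapply(`+`, gacc, gr, SIMPLIFY = FALSE)
        }
        gacc <- lapply(gacc, `/`, recipe$batch_size)
        if (is.finite(recipe$grad_clip)) {
          gn <- sqrt(sum(vapply(gacc, function(g) sum(g^2), numeric(1))))
          if (gn > recipe$grad_clip)
            gacc <- lapply(gacc, `*`, recipe$grad_clip / gn)
        }
        st <- adam_step(opt, leaves, gacc, lr)
        opt <- st$state
        leaves <- st$leaves
        params <- nn_assign_leaves(params, leaves)
        ep_loss <- ep_loss + bloss / recipe$batch_size
      }
      loss_history[ep] <- ep_loss / recipe$batches_per_epoch
    }
  })
  structure(list(type = "unet", params = params, config = config,
                 recipe = recipe, loss_history = loss_history,
                 dataset_audit = audit,
                 hu_norm = c(centre = 150, scale = 200)),
            class = "lv_observer")
}

cfg_head_weights <- function(config) {
  n <- min(length(config$ds_weights), config$n_levels - 1L)
  setNames(as.list(config$ds_weights[seq_len(n)]), as.character(seq_len(n)))
}

#' @export
print.lv_observer <- function(x, ...) {
  cat(sprintf("<lv_observer:%s>", x$type))
  if (x$type == "unet")
    cat(sprintf(" base_channels %d, %d epochs, final loss %.4f",
                x$config$base_channels, length(x$loss_history),
                x$loss_history[length(x$loss_history)]))
  cat("\n")
  invisible(x)
}

#' Segment a volume with an observer
#'
#' For the network observer: sliding-window inference (windows of the
#' training patch size, edge windows shifted inward), per-voxel softmax
#' averaging across overlaps, then argmax with ties broken toward the
#' lower class index. Deterministic. For the rule-based observer:
#' [rule_based_segment()].
#'
#' @param observer an `lv_observer` from [train_observer()] or
#'   [rule_observer()].
#' @param image an [image_volume()].
#' @param inference_patch window size for sliding-window inference;
#'   defaults to the training patch size (instance-norm feature statistics
#'   are window-size dependent, so matched windows are the safe choice).
#' @return a [label_volume()] on the input grid.
#' @export
segment_volume <- function(observer, image, inference_patch = NULL) {
  if (!inherits(observer, "lv_observer"))
    stop("segment_volume: not a trained observer")
  if (observer$type == "rule")
    return(rule_based_segment(image, observer$thresholds))
  d <- dim(image$data)
  div <- 2L^(observer$config$n_levels - 1L)
  patch <- if (is.null(inference_patch)) observer$config$patch_size
  else as.integer(rep_len(inference_patch, 3L))
  if (any(patch %% div != 0L))
    stop("segment_volume: inference patch must be divisible by ", div)
  if (any(d < patch))
    stop("segment_volume: volume ", paste(d, collapse = "x"),
         " smaller than the inference patch ", paste(patch, collapse = "x"))
  x <- normalize_hu(image$data, observer$hu_norm["centre"],
                    observer$hu_norm["scale"])
  starts <- lapply(1:3, function(ax) {
    s <- seq(1L, d[ax] - patch[ax] + 1L, by = patch[ax])
    unique(c(s, d[ax] - patch[ax] + 1L))
  })
  probs <- array(0, c(d, 3L))
  cnt <- array(0, d)
  for (i in starts[[1]]) for (j in starts[[2]]) for (k in starts[[3]]) {
    xi <- i:(i + patch[1] - 1L); yj <- j:(j + patch[2] - 1L)
    zk <- k:(k + patch[3] - 1L)
    fw <- unet_forward(observer$params, x[xi, yj, zk], observer$config)
    z <- as_class_matrix(fw$logits[["1"]])
    p <- array(softmax_rows(z), c(patch, 3L))
    probs[xi, yj, zk, ] <- probs[xi, yj, zk, , drop = FALSE] + p
    cnt[xi, yj, zk] <- cnt[xi, yj, zk] + 1
  }
  probs <- probs / as.numeric(cnt)
  lab <- max.col(matrix(probs, prod(d), 3L), ties.method = "first") - 1L
  label_volume(array(lab, d), image$spacing, image$origin)
}

#' Deterministic rule-based observer
#'
#' HU-threshold classification with largest-component cleanup and hole
#' filling - a fully reproducible stand-in observer, so measurement
#' stages can be exercised without network training.
#'
#' @param hu_thresholds ordered thresholds: below the first is background,
#'   between them myocardium, above the second blood pool.
#' @return an `lv_observer` of type `"rule"`.
#' @export
rule_observer <- function(hu_thresholds = c(background_myocardium = 70,
                                            myocardium_blood = 225)) {
  if (diff(hu_thresholds) <= 0)
    stop("rule_observer: thresholds must be strictly increasing ",
         "(background < myocardium < blood pool)")
  structure(list(type = "rule", thresholds = hu_thresholds),
            class = "lv_observer")
}

#' Rule-based multi-label segmentation
#'
#' Threshold classification (background / myocardium / blood pool in
#' increasing HU), then per-class largest connected component and filling
#' of enclosed background holes by their surrounding class majority.
#'
#' @param image an [image_volume()].
#' @param hu_thresholds as in [rule_observer()].
#' @return a [label_volume()].
#' @export
rule_based_segment <- function(image,
                               hu_thresholds = c(background_myocardium = 70,
                                                 myocardium_blood = 225)) {
  if (diff(hu_thresholds) <= 0)
    stop("rule_based_segment: thresholds must be strictly increasing ",
         "(background < myocardium < blood pool)")
  d <- dim(image$data)
  lab <- array(0L, d)
  lab[image$data >= hu_thresholds[1]] <- 1L
  lab[image$data >= hu_thresholds[2]] <- 2L
  # keep only the largest connected component of each foreground class
  for (cls in c(1L, 2L)) {
    cc <- cpp_label_components(lab == cls, d)
    if (max(cc) > 1L) {
      tab <- tabulate(cc[cc > 0L])
      lab[cc > 0L & cc != which.max(tab)] <- 0L
    }
  }
  # enclosed background pockets take the majority label of their boundary
  cc <- cpp_label_components(lab == 0L, d)
  if (max(cc) > 0L) {
    border <- unique(c(cc[1, , ], cc[d[1], , ], cc[, 1, ], cc[, d[2], ],
                       cc[, , 1], cc[, , d[3]]))
    hole_ids <- setdiff(seq_len(max(cc)), border[border > 0L])
    if (length(hole_ids)) {
      is_hole <- array(cc %in% hole_ids, d)
      votes <- matrix(0L, max(cc), 2L)  # boundary votes per class 1/2
      for (ax in 1:3) for (by in c(-1L, 1L)) {
        sh <- shift_array(lab, ax, by)
        sel <- is_hole & sh != 0L
        if (!any(sel)) next
        tb <- table(factor(cc[sel], levels = seq_len(max(cc))),
                    factor(sh[sel], levels = 1:2))
        votes <- votes + tb
      }
      maj <- ifelse(votes[, 2] > votes[, 1], 2L, 1L)
      maj[rowSums(votes) == 0L] <- 0L
      lab[is_hole] <- maj[cc[is_hole]]
    }
  }
  label_volume(lab, image$spacing, image$origin)
}

shift_array <- function(a, ax, by) {
  d <- dim(a)
  out <- array(if (is.logical(a)) FALSE else 0L, d)
  src <- dst <- lapply(d, seq_len)
  if (by > 0) { dst[[ax]] <- (1 + by):d[ax]; src[[ax]] <- 1:(d[ax] - by) }
  else { dst[[ax]] <- 1:(d[ax] + by); src[[ax]] <- (1 - by):d[ax] }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}
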