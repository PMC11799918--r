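# Minimal 3D convolutional network engine: forward and hand-derived
# backward passes for the residual U-Net observer. Arrays are (x, y, z, C);
# convolutions run as im2col gathers (C++) followed by BLAS GEMM.

conv_init <- function(k, c_in, c_out, stride = 1L) {
  fan_in <- k^3 * c_in
  list(W = matrix(rnorm(fan_in * c_out, 0, sqrt(2 / fan_in)), fan_in, c_out),
       b = rep(0, c_out), k = as.integer(k), stride = as.integer(stride))
}

conv_fwd <- function(p, x) {
  d <- dim(x)
  pad <- if (p$k == 3L) 1L else 0L
  cols <- cpp_im2col3(as.numeric(x), d, p$k, pad, p$stride)
  y <- cols %*% p$W
  y <- sweep(y, 2, p$b, "+")
  od <- (d[1:3] + 2L * pad - p$k) %/% p$stride + 1L
  array(y, c(od, ncol(p$W)))
}

conv_bwd <- function(p, x, dy) {
  d <- dim(x)
  pad <- if (p$k == 3L) 1L else 0L
  cols <- cpp_im2col3(as.numeric(x), d, p$k, pad, p$stride)
  dy2 <- matrix(dy, nrow(cols), ncol(p$W))
  dW <- crossprod(cols, dy2)
  db <- colSums(dy2)
  dx <- cpp_col2im3(dy2 %*% t(p$W), d, p$k, pad, p$stride)
  list(dx = array(dx, d), dW = dW, db = db)
}

# Feature normalization inside the blocks. "instance": per-channel over
# the window (statistics depend on the inference window); "channel":
# per-voxel over the channels (spatially local, so identical for any
# window size); "none": raw features.
inorm_fwd <- function(x, eps = 1e-5, norm = "instance") {
  if (norm == "none") return(list(y = x, none = TRUE))
  d <- dim(x)
  m <- matrix(x, prod(d[1:3]), d[4])
  if (norm == "channel") {
    mu <- rowMeans(m)
    v <- rowMeans(m^2) - mu^2
    inv <- 1 / sqrt(v + eps)
    xhat <- (m - mu) * inv
    return(list(y = array(xhat, d), xhat = xhat, inv = inv,
                channel = TRUE))
  }
  mu <- colMeans(m)
  v <- colMeans(m^2) - mu^2
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(m, 2, mu), 2, inv, "*")
  list(y = array(xhat, d), xhat = xhat, inv = inv)
}

inorm_bwd <- function(cache, dy) {
  if (isTRUE(cache$none)) return(dy)
  d <- dim(dy)
  g <- matrix(dy, prod(d[1:3]), d[4])
  if (isTRUE(cache$channel)) {
    t1 <- g - rowMeans(g)
    t2 <- cache$xhat * rowMeans(g * cache$xhat)
    return(array((t1 - t2) * cache$inv, d))
  }
  t1 <- sweep(g, 2, colMeans(g))
  t2 <- sweep(cache$xhat, 2, colMeans(g * cache$xhat), "*")
  array(sweep(t1 - t2, 2, cache$inv, "*"), d)
}

relu_fwd <- function(x) { x[x < 0] <- 0; x }
relu_bwd <- function(y, dy) { dy[y <= 0] <- 0; dy }

upsample2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2),
    rep(seq_len(d[3]), each = 2), , drop = FALSE]
}

upsample2_bwd <- function(dy, d_in) {
  d <- dim(dy)
  o1 <- seq(1L, d[1], 2L); o2 <- seq(1L, d[2], 2L); o3 <- seq(1L, d[3], 2L)
  acc <- array(0, c(d_in[1:3], d[4]))
  for (a in 0:1) for (b in 0:1) for (cc in 0:1)
    acc <- acc + dy[o1 + a, o2 + b, o3 + cc, , drop = FALSE]
  acc
}

res_block_init <- function(c_in, c_out) {
  list(conv1 = conv_init(3L, c_in, c_out),
       conv2 = conv_init(3L, c_out, c_out),
       short = if (c_in != c_out) conv_init(1L, c_in, c_out) else NULL)
}

res_block_fwd <- function(p, x, norm = "instance") {
  a <- conv_fwd(p$conv1, x)
  n1 <- inorm_fwd(a, norm = norm)
  h <- relu_fwd(n1$y)
  b <- conv_fwd(p$conv2, h)
  n2 <- inorm_fwd(b, norm = norm)
  s <- if (is.null(p$short)) x else conv_fwd(p$short, x)
  y <- relu_fwd(n2$y + s)
  list(y = y, cache = list(x = x, n1 = n1, h = h, n2 = n2, y = y))
}

res_block_bwd <- function(p, cache, dy) {
  dsum <- relu_bwd(cache$y, dy)
  db2 <- inorm_bwd(cache$n2, dsum)
  g2 <- conv_bwd(p$conv2, cache$h, db2)
  dh <- relu_bwd(cache$h, g2$dx)
  db1 <- inorm_bwd(cache$n1, dh)
  g1 <- conv_bwd(p$conv1, cache$x, db1)
  grads <- list(conv1 = list(dW = g1$dW, db = g1$db),
                conv2 = list(dW = g2$dW, db = g2$db))
  if (is.null(p$short)) {
    dx <- g1$dx + dsum
  } else {
    gs <- conv_bwd(p$short, cache$x, dsum)
    grads$short <- list(dW = gs$dW, db = gs$db)
    dx <- g1$dx + gs$dx
  }
  list(dx = dx, grads = grads)
}

#' Residual 3D U-Net configuration
#'
#' Four encoder-decoder levels with two residual blocks per level,
#' channel doubling per level, optional deep supervision (auxiliary
#' segmentation heads at the intermediate decoder resolutions), and a
#' three-class output (background, myocardium, blood pool).
#'
#' @param n_levels encoder-decoder levels.
#' @param residual_blocks_per_level residual blocks at each level.
#' @param base_channels channels at the finest level (doubled per level).
#'   The default is the desk-scale setting; 32 is the clinical-scale value.
#' @param deep_supervision attach auxiliary losses at coarser decoder
#'   levels.
#' @param ds_weights loss weights for decoder levels 1, 2, 3 (finest
#'   first); used as stated when deep supervision is on, otherwise only
#'   the first entry.
#' @param n_classes output classes (3).
#' @param patch_size training/inference patch; every dimension must be
#'   divisible by `2^(n_levels - 1)`.
#' @param norm feature normalization inside the blocks: `"instance"`
#'   (default; per-channel over the window, so inference should use the
#'   training window size), `"channel"` (per-voxel over channels) or
#'   `"none"`.
#' @return a `net_config` list.
#' @export
net_config <- function(n_levels = 4L, residual_blocks_per_level = 2L,
                       base_channels = 8L, deep_supervision = TRUE,
                       ds_weights = c(1, 0.5, 0.25), n_classes = 3L,
                       patch_size = c(64L, 64L, 32L),
                       norm = c("instance", "channel", "none")) {
  if (n_classes != 3L) stop("net_config: this observer is three-class")
  if (any(patch_size %% 2L^(n_levels - 1L) != 0L))
    stop("net_config: patch_size must be divisible by 2^(n_levels-1) = ",
         2L^(n_levels - 1L))
  structure(list(n_levels = as.integer(n_levels),
                 residual_blocks_per_level =
                   as.integer(residual_blocks_per_level),
                 base_channels = as.integer(base_channels),
                 deep_supervision = isTRUE(deep_supervision),
                 ds_weights = ds_weights, n_classes = 3L,
                 patch_size = as.integer(patch_size),
                 norm = match.arg(norm)),
            class = "net_config")
}

nn_init_unet <- function(cfg, in_channels = 1L, seed = 1L) {
  with_seed(seed, {
    L <- cfg$n_levels
    ch <- cfg$base_channels * 2L^(seq_len(L) - 1L)
    nb <- cfg$residual_blocks_per_level
    params <- list(stem = conv_init(3L, in_channels, ch[1]))
    params$enc <- lapply(seq_len(L), function(l) {
      p <- list()
      if (l > 1) p$down <- conv_init(3L, ch[l - 1], ch[l], stride = 2L)
      p$res <- c(list(res_block_init(ch[l], ch[l])),
                 lapply(seq_len(nb - 1), function(i)
                   res_block_init(ch[l], ch[l])))
      p
    })
    params$dec <- vector("list", L - 1L)
    for (l in seq_len(L - 1L)) {
      params$dec[[l]] <- list(
        up = conv_init(3L, ch[l + 1], ch[l]),
        res = c(list(res_block_init(2L * ch[l], ch[l])),
                lapply(seq_len(nb - 1), function(i)
                  res_block_init(ch[l], ch[l]))))
    }
    head_levels <- if (cfg$deep_supervision)
      seq_len(min(length(cfg$ds_weights), L - 1L)) else 1L
    # the finest head also sees the raw (normalized-HU) input: feature
    # normalization is window-relative, so an input skip restores the
    # absolute intensity cue the classes are defined by
    params$head <- setNames(
      lapply(head_levels, function(l)
        conv_init(1L, ch[l] + (l == 1L) * in_channels, cfg$n_classes)),
      as.character(head_levels))
    params
  })
}

unet_forward <- function(params, x, cfg, want_cache = FALSE) {
  if (length(dim(x)) == 3L) x <- array(x, c(dim(x), 1L))
  L <- cfg$n_levels
  norm <- if (is.null(cfg$norm)) "instance" else cfg$norm
  cache <- list(x = x)
  f <- conv_fwd(params$stem, x)
  nstem <- inorm_fwd(f, norm = norm)
  f <- relu_fwd(nstem$y)
  cache$stem <- list(n = nstem, y = f)
  skips <- vector("list", L)
  enc_cache <- vector("list", L)
  for (l in seq_len(L)) {
    ec <- list()
    if (l > 1) {
      dlast <- f
      f <- conv_fwd(params$enc[[l]]$down, f)
      nd <- inorm_fwd(f, norm = norm)
      f <- relu_fwd(nd$y)
      ec$down <- list(x = dlast, n = nd, y = f)
    }
    ec$res <- vector("list", length(params$enc[[l]]$res))
    for (i in seq_along(params$enc[[l]]$res)) {
      r <- res_block_fwd(params$enc[[l]]$res[[i]], f, norm)
      f <- r$y
      ec$res[[i]] <- r$cache
    }
    skips[[l]] <- f
    enc_cache[[l]] <- ec
  }
  cache$enc <- enc_cache
  dec_feats <- vector("list", L - 1L)
  dec_cache <- vector("list", L - 1L)
  for (l in rev(seq_len(L - 1L))) {
    dc <- list(d_in = dim(f))
    u <- upsample2_fwd(f)
    dc$u_in <- u
    u <- conv_fwd(params$dec[[l]]$up, u)
    nu <- inorm_fwd(u, norm = norm)
    u <- relu_fwd(nu$y)
    dc$up <- list(n = nu, y = u)
    z <- array(c(u, skips[[l]]), c(dim(u)[1:3], dim(u)[4] + dim(skips[[l]])[4]))
    dc$c_up <- dim(u)[4]
    f <- z
    dc$res <- vector("list", length(params$dec[[l]]$res))
    for (i in seq_along(params$dec[[l]]$res)) {
      r <- res_block_fwd(params$dec[[l]]$res[[i]], f, norm)
      f <- r$y
      dc$res[[i]] <- r$cache
    }
    dec_feats[[l]] <- f
    dec_cache[[l]] <- dc
  }
  cache$dec <- dec_cache
  logits <- lapply(names(params$head), function(nm) {
    l <- as.integer(nm)
    hin <- if (l == 1L)
      array(c(dec_feats[[1L]], x), c(dim(x)[1:3], dim(dec_feats[[1L]])[4] +
                                       dim(x)[4]))
    else dec_feats[[l]]
    conv_fwd(params$head[[nm]], hin)
  })
  names(logits) <- names(params$head)
  cache$dec_feats <- dec_feats
  list(logits = logits, cache = if (want_cache) cache else NULL)
}

zero_like <- function(p) rapply(p, function(x) x * 0, how = "replace",
                                classes = "ANY")

unet_backward <- function(params, cache, dlogits, cfg) {
  L <- cfg$n_levels
  grads <- list()
  ddec_feats <- vector("list", L - 1L)
  for (nm in names(params$head)) {
    l <- as.integer(nm)
    cf <- dim(cache$dec_feats[[l]])[4]
    hin <- if (l == 1L)
      array(c(cache$dec_feats[[1L]], cache$x),
            c(dim(cache$x)[1:3], cf + dim(cache$x)[4]))
    else cache$dec_feats[[l]]
    g <- conv_bwd(params$head[[nm]], hin, dlogits[[nm]])
    grads$head[[nm]] <- list(dW = g$dW, db = g$db)
    dfeat <- if (l == 1L) g$dx[, , , seq_len(cf), drop = FALSE] else g$dx
    ddec_feats[[l]] <- if (is.null(ddec_feats[[l]])) dfeat
      else ddec_feats[[l]] + dfeat
  }
  dskips <- vector("list", L)
  df_deeper <- NULL  # gradient flowing to the encoder output of level L
  grads$dec <- vector("list", L - 1L)
  for (l in seq_len(L - 1L)) {
    dc <- cache$dec[[l]]
    df <- ddec_feats[[l]]
    if (is.null(df)) df <- array(0, dim(cache$dec_feats[[l]]))
    for (i in rev(seq_along(params$dec[[l]]$res))) {
      r <- res_block_bwd(params$dec[[l]]$res[[i]], dc$res[[i]], df)
      grads$dec[[l]]$res[[i]] <- r$grads
      df <- r$dx
    }
    cu <- dc$c_up
    du <- df[, , , seq_len(cu), drop = FALSE]
    dskip <- df[, , , cu + seq_len(dim(df)[4] - cu), drop = FALSE]
    dskips[[l]] <- dskip
    du <- relu_bwd(dc$up$y, du)
    du <- inorm_bwd(dc$up$n, du)
    g <- conv_bwd(params$dec[[l]]$up, dc$u_in, du)
    grads$dec[[l]]$up <- list(dW = g$dW, db = g$db)
    ddeeper <- upsample2_bwd(g$dx, dc$d_in)
    if (l + 1L <= L - 1L) {
      ddec_feats[[l + 1L]] <- if (is.null(ddec_feats[[l + 1L]])) ddeeper
        else ddec_feats[[l + 1L]] + ddeeper
    } else df_deeper <- ddeeper
  }
  grads$enc <- vector("list", L)
  df <- df_deeper
  for (l in rev(seq_len(L))) {
    if (l < L) df <- df + dskips[[l]]
    ec <- cache$enc[[l]]
    for (i in rev(seq_along(params$enc[[l]]$res))) {
      r <- res_block_bwd(params$enc[[l]]$res[[i]], ec$res[[i]], df)
      grads$enc[[l]]$res[[i]] <- r$grads
      df <- r$dx
    }
    if (l > 1) {
      df <- relu_bwd(ec$down$y, df)
      df <- inorm_bwd(ec$down$n, df)
      g <- conv_bwd(params$enc[[l]]$down, ec$down$x, df)
      grads$enc[[l]]$down <- list(dW = g$dW, db = g$db)
      df <- g$dx
    }
  }
  df <- relu_bwd(cache$stem$y, df)
  df <- inorm_bwd(cache$stem$n, df)
  g <- conv_bwd(params$stem, cache$x, df)
  grads$stem <- list(dW = g$dW, db = g$db)
  grads
}

# Flatten nested parameter/gradient lists into named leaf lists (W/b
# matrices and vectors) for the optimizer.
nn_leaves <- function(p, prefix = "") {
  out <- list()
  nms <- names(p)
  if (is.null(nms)) nms <- as.character(seq_along(p))
  for (j in seq_along(p)) {
    nm <- if (nzchar(nms[j])) nms[j] else as.character(j)
    v <- p[[j]]
    if (is.null(v)) next
    key <- if (prefix == "") nm else paste0(prefix, ".", nm)
    if (is.list(v)) out <- c(out, nn_leaves(v, key))
    else if (nm %in% c("W", "b", "dW", "db")) {
      # gradients (dW/db) share keys with their parameters (W/b)
      leaf <- if (nm %in% c("dW", "db")) substring(nm, 2L) else nm
      key <- if (prefix == "") leaf else paste0(prefix, ".", leaf)
      out[[key]] <- v
    }
  }
  out
}

nn_assign_leaves <- function(p, leaves, prefix = "") {
  nms <- names(p)
  if (is.null(nms)) nms <- as.character(seq_along(p))
  for (j in seq_along(p)) {
    nm <- if (nzchar(nms[j])) nms[j] else as.character(j)
    v <- p[[j]]
    if (is.null(v)) next
    key <- if (prefix == "") nm else paste0(prefix, ".", nm)
    if (is.list(v)) p[[j]] <- nn_assign_leaves(v, leaves, key)
    else if (nm %in% c("W", "b") && !is.null(leaves[[key]]))
      p[[j]] <- leaves[[key]]
  }
  p
}

adam_init <- function(leaves) {
  list(m = lapply(leaves, function(x) x * 0),
       v = lapply(leaves, function(x) x * 0), t = 0L)
}

adam_step <- function(state, leaves, grad_leaves, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (key in names(leaves)) {
    g <- grad_leaves[[key]]
    if (is.null(g)) next
    state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * g
    state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * g^2
    leaves[[key]] <- leaves[[key]] -
      lr * (state$m[[key]] / bc1) / (sqrt(state$v[[key]] / bc2) + eps)
  }
  list(state = state, leaves = leaves)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}
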