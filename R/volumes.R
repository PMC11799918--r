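#' Voxel grid definition
#'
#' Defines a regular voxel grid. World coordinates follow
#' `world = origin + index0 * spacing` with 0-based indices, axis order
#' (x, y, z). By default the origin is chosen so the grid is centred on the
#' world origin, which is also the CT rotation axis used by the simulator.
#'
#' @param n integer vector of length 3, voxels per axis.
#' @param spacing numeric vector of length 3 (or scalar), voxel size in mm.
#' @param origin world position of voxel (0,0,0) in mm; `NULL` centres the
#'   grid on the world origin.
#' @return a `grid_def` list with fields `n`, `spacing`, `origin`.
#' @export
grid_def <- function(n = c(96L, 96L, 96L), spacing = 1.5, origin = NULL) {
  n <- as.integer(rep_len(n, 3L))
  spacing <- as.numeric(rep_len(spacing, 3L))
  if (any(n < 1L)) stop("grid_def: all grid dimensions must be >= 1")
  if (any(spacing <= 0)) stop("grid_def: spacing must be positive")
  if (is.null(origin)) origin <- -(n - 1) / 2 * spacing
  structure(list(n = n, spacing = spacing, origin = as.numeric(origin)),
            class = "grid_def")
}

new_volume <- function(data, spacing, origin, orientation, class) {
  spacing <- as.numeric(rep_len(spacing, 3L))
  if (any(spacing <= 0)) stop("volume spacing must be positive")
  if (length(dim(data)) != 3L) stop("volume data must be a 3D array")
  if (is.null(orientation)) orientation <- diag(3)
  structure(list(data = data, spacing = spacing,
                 origin = as.numeric(rep_len(origin, 3L)),
                 orientation = orientation),
            class = c(class, "lv_volume"))
}

#' HU image volume
#'
#' @param data 3D numeric array of Hounsfield units.
#' @param spacing,origin grid metadata in mm (see [grid_def()]).
#' @param orientation 3x3 direction-cosine matrix (identity for the
#'   axis-aligned grids produced by the simulator).
#' @return an `image_volume` object.
#' @export
image_volume <- function(data, spacing, origin = NULL, orientation = NULL) {
  if (!all(is.finite(data))) stop("image_volume: HU values must be finite")
  if (is.null(origin)) origin <- -(dim(data) - 1) / 2 * rep_len(spacing, 3L)
  new_volume(data, spacing, origin, orientation, "image_volume")
}

#' Multi-label segmentation volume
#'
#' Labels are 0 = background, 1 = myocardium, 2 = LV blood pool.
#'
#' @inheritParams image_volume
#' @param data 3D integer array with values in \{0, 1, 2\}.
#' @return a `label_volume` object.
#' @export
label_volume <- function(data, spacing, origin = NULL, orientation = NULL) {
  if (!all(data %in% 0:2)) stop("label_volume: labels must be in {0, 1, 2}")
  storage.mode(data) <- "integer"
  if (is.null(origin)) origin <- -(dim(data) - 1) / 2 * rep_len(spacing, 3L)
  new_volume(data, spacing, origin, orientation, "label_volume")
}

#' @export
print.lv_volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm, origin %s mm\n",
              class(x)[1L], paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' @export
dim.lv_volume <- function(x) dim(x$data)

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

#' Voxel volume in millilitres
#' @param vol an `lv_volume`.
#' @return scalar voxel volume in mL.
#' @export
voxel_volume_ml <- function(vol) prod(vol$spacing) / 1000

# World coordinates (mm) of every voxel centre, as an N x 3 matrix in
# column-major voxel order.
voxel_world_coords <- function(vol_or_grid) {
  g <- if (inherits(vol_or_grid, "grid_def")) vol_or_grid else
    grid_like(vol_or_grid)
  ax <- lapply(1:3, function(i) g$origin[i] + (seq_len(g$n[i]) - 1) * g$spacing[i])
  cbind(rep(ax[[1]], times = g$n[2] * g$n[3]),
        rep(rep(ax[[2]], each = g$n[1]), times = g$n[3]),
        rep(ax[[3]], each = g$n[1] * g$n[2]))
}

grid_like <- function(vol) grid_def(dim(vol$data), vol$spacing, vol$origin)

# Trilinear interpolation of a 3D array at world points (N x 3).
# Out-of-grid points return `fill`.
trilinear_sample <- function(vol, points, fill = 0) {
  d <- dim(vol$data)
  f <- sweep(sweep(points, 2, vol$origin), 2, vol$spacing, "/")  # 0-based
  i0 <- floor(f)
  a <- f - i0
  ok <- i0[, 1] >= 0 & i0[, 1] <= d[1] - 2 &
        i0[, 2] >= 0 & i0[, 2] <= d[2] - 2 &
        i0[, 3] >= 0 & i0[, 3] <= d[3] - 2
  out <- rep(fill, nrow(points))
  if (!any(ok)) return(out)
  i0 <- i0[ok, , drop = FALSE]; a <- a[ok, , drop = FALSE]
  idx <- function(dx, dy, dz)
    (i0[, 3] + dz) * d[1] * d[2] + (i0[, 2] + dy) * d[1] + i0[, 1] + dx + 1
  v <- as.numeric(vol$data)
  acc <- (1 - a[, 1]) * (1 - a[, 2]) * (1 - a[, 3]) * v[idx(0, 0, 0)] +
         a[, 1] * (1 - a[, 2]) * (1 - a[, 3]) * v[idx(1, 0, 0)] +
         (1 - a[, 1]) * a[, 2] * (1 - a[, 3]) * v[idx(0, 1, 0)] +
         a[, 1] * a[, 2] * (1 - a[, 3]) * v[idx(1, 1, 0)] +
         (1 - a[, 1]) * (1 - a[, 2]) * a[, 3] * v[idx(0, 0, 1)] +
         a[, 1] * (1 - a[, 2]) * a[, 3] * v[idx(1, 0, 1)] +
         (1 - a[, 1]) * a[, 2] * a[, 3] * v[idx(0, 1, 1)] +
         a[, 1] * a[, 2] * a[, 3] * v[idx(1, 1, 1)]
  out[ok] <- acc
  out
}

# Nearest-neighbour lookup of a 3D array at world points; out-of-grid -> fill.
nearest_sample <- function(vol, points, fill = 0L) {
  d <- dim(vol$data)
  f <- round(sweep(sweep(points, 2, vol$origin), 2, vol$spacing, "/"))
  ok <- f[, 1] >= 0 & f[, 1] <= d[1] - 1 &
        f[, 2] >= 0 & f[, 2] <= d[2] - 1 &
        f[, 3] >= 0 & f[, 3] <= d[3] - 1
  out <- rep(fill, nrow(points))
  if (!any(ok)) return(out)
  fi <- f[ok, , drop = FALSE]
  out[ok] <- vol$data[fi[, 3] * d[1] * d[2] + fi[, 2] * d[1] + fi[, 1] + 1]
  out
}

# Erode a logical mask by one voxel (6-neighbourhood).
erode6 <- function(mask) {
  d <- dim(mask)
  shift <- function(m, ax, by) {
    out <- array(FALSE, d)
    src <- dst <- lapply(d, seq_len)
    if (by > 0) { dst[[ax]] <- (1 + by):d[ax]; src[[ax]] <- 1:(d[ax] - by) }
    else { dst[[ax]] <- 1:(d[ax] + by); src[[ax]] <- (1 - by):d[ax] }
    out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    out
  }
  mask & shift(mask, 1, 1) & shift(mask, 1, -1) &
    shift(mask, 2, 1) & shift(mask, 2, -1) &
    shift(mask, 3, 1) & shift(mask, 3, -1)
}
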