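#' Estimate the LV long axis from a label volume
#'
#' The axis direction is the principal eigenvector of the blood pool's
#' second central moment tensor. The basal point is the centroid of the
#' cavity's uncovered (basal) face - blood voxels face-adjacent to
#' background; the apex is the myocardium voxel farthest from that point.
#' The direction is oriented apex -> base.
#'
#' @param labels a [label_volume()] containing blood-pool voxels.
#' @param min_anisotropy minimum ratio of the first to second moment
#'   eigenvalue; below it the axis is declared degenerate.
#' @return an `lv_axis` list: `direction` (unit, apex->base), `apex_mm`,
#'   `base_mm`, `length_mm`.
#' @export
estimate_long_axis <- function(labels, min_anisotropy = 1.2) {
  lab <- labels$data
  blood_idx <- which(lab == 2L)
  if (!length(blood_idx)) stop("estimate_long_axis: no blood-pool voxels")
  w <- voxel_world_coords(labels)
  bw <- w[blood_idx, , drop = FALSE]
  ctr <- colMeans(bw)
  mom <- crossprod(sweep(bw, 2, ctr)) / nrow(bw)
  eg <- eigen(mom, symmetric = TRUE)
  if (eg$values[1] / eg$values[2] < min_anisotropy)
    stop("estimate_long_axis: blood pool is nearly isotropic; ",
         "long axis is degenerate (eigenvalue ratio ",
         sprintf("%.3f", eg$values[1] / eg$values[2]), " < ",
         min_anisotropy, ")")
  axis <- eg$vectors[, 1]
  # basal face: blood voxels with a background face-neighbour
  d <- dim(lab)
  pad <- array(0L, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- lab
  bi <- which(lab == 2L, arr.ind = TRUE)
  exposed <- rep(FALSE, nrow(bi))
  for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)))
    exposed <- exposed |
      pad[cbind(bi[, 1] + 1 + o[1], bi[, 2] + 1 + o[2], bi[, 3] + 1 + o[3])] == 0L
  if (!any(exposed)) stop("estimate_long_axis: no basal opening found")
  face_pt <- colMeans(w[blood_idx[exposed], , drop = FALSE])
  myo_idx <- which(lab == 1L)
  if (!length(myo_idx)) stop("estimate_long_axis: no myocardium voxels")
  mw <- w[myo_idx, , drop = FALSE]
  dists <- sqrt(rowSums(sweep(mw, 2, face_pt)^2))
  apex_vox <- mw[which.max(dists), ]
  if (sum(axis * (face_pt - apex_vox)) < 0) axis <- -axis
  axis <- axis / sqrt(sum(axis^2))
  # sub-voxel apex/base localization along the axis by extent regression:
  # near the apex the epicardial cap volume grows quadratically with depth,
  # at the flat basal cut the cavity cross-section is constant, so the
  # sorted axial projections of shell/blood voxels extrapolate to the true
  # surface positions with far less quantization noise than any single
  # extreme voxel.
  vvol <- prod(labels$spacing)
  proj_shell <- c(w[myo_idx, , drop = FALSE] %*% axis, bw %*% axis)
  # regression windows scale with voxel size so several voxel layers
  # contribute at coarse resolutions
  t_apex <- extent_fit_quadratic(-proj_shell, vvol,
                                 window_mm = max(3, 2.5 * mean(labels$spacing)))
  t_base <- extent_fit_linear(bw %*% axis, vvol,
                              window_mm = max(2, 1.5 * mean(labels$spacing)))
  c_perp <- ctr - sum(ctr * axis) * axis
  apex_pt <- c_perp - t_apex * axis
  base_pt <- c_perp + t_base * axis
  len <- sum(axis * (base_pt - apex_pt))
  structure(list(direction = axis, apex_mm = apex_pt, base_mm = base_pt,
                 length_mm = len),
            class = "lv_axis")
}

#' View configuration
#'
#' @param sax_fractions positions of the basal/middle/apical short-axis
#'   planes as fractions of the apex-to-base length, measured from the apex.
#' @param long_axis_azimuths_deg in-plane azimuths of the two long-axis
#'   views about the LV axis (the phantom is axisymmetric; the 90-degree
#'   offset mirrors the approximately orthogonal clinical 2-CH/PLAX pair).
#' @param pixel_spacing_mm in-plane sampling pitch of each view.
#' @param fov_mm in-plane field of view of each view.
#' @param plane_mode `"per-phase"` (default): apex/base - hence SAX plane
#'   positions - are located from each phase's own labels, so strains
#'   compare corresponding material levels; `"ed-frame"`: the ED planes are
#'   reused verbatim for ES.
#' @return a `view_config` list.
#' @export
view_config <- function(sax_fractions = c(basal = 0.8, middle = 0.5,
                                          apical = 0.2),
                        long_axis_azimuths_deg = c("2CH" = 0, "PLAX" = 90),
                        pixel_spacing_mm = 1.0, fov_mm = 160,
                        plane_mode = c("per-phase", "ed-frame")) {
  if (any(sax_fractions <= 0 | sax_fractions >= 1))
    stop("view_config: sax_fractions must lie in (0, 1)")
  if (length(long_axis_azimuths_deg) != 2)
    stop("view_config: exactly two long-axis azimuths required")
  structure(list(sax_fractions = sax_fractions,
                 long_axis_azimuths_deg = long_axis_azimuths_deg,
                 pixel_spacing_mm = pixel_spacing_mm, fov_mm = fov_mm,
                 plane_mode = match.arg(plane_mode)),
            class = "view_config")
}

# Sub-voxel position of the maximum of a point cloud's projections, for a
# rounded (quadratically vanishing cross-section) end: cumulative count
# behind depth d is ~ d^2, so sorted depths are linear in sqrt(rank);
# the regression intercept is the surface position.
extent_fit_quadratic <- function(proj, voxel_vol, window_mm = 3) {
  hi <- max(proj)
  s <- sort(proj[proj > hi - window_mm], decreasing = TRUE)
  if (length(s) < 10) return(hi + 0.5 * voxel_vol^(1 / 3))
  i <- seq_along(s)
  stats::coef(stats::lm(s ~ sqrt(i - 0.5)))[[1]]
}

# Same for a flat cut end (constant cross-section): sorted depths are
# linear in rank.
extent_fit_linear <- function(proj, voxel_vol, window_mm = 2) {
  hi <- max(proj)
  s <- sort(proj[proj > hi - window_mm], decreasing = TRUE)
  if (length(s) < 10) return(hi + 0.5 * voxel_vol^(1 / 3))
  i <- seq_along(s)
  stats::coef(stats::lm(s ~ i))[[1]]
}

# Sub-voxel radius (mm) at which a trilinear indicator volume crosses 0.5
# along the ray origin + t*dir, t >= 0. NA if no crossing before max_mm.
ray_crossing_3d <- function(ind, origin, dir, max_mm, dt = NULL) {
  if (is.null(dt)) dt <- 0.25 * min(ind$spacing)
  tt <- seq(0, max_mm, by = dt)
  pts <- matrix(origin, length(tt), 3, byrow = TRUE) + tt %o% dir
  v <- trilinear_sample(ind, pts)
  if (v[1] < 0.5) return(NA_real_)
  k <- which(v < 0.5)[1]
  if (is.na(k)) return(NA_real_)
  tt[k - 1] + dt * (v[k - 1] - 0.5) / (v[k - 1] - v[k])
}

# Deterministic in-plane frame perpendicular to the axis.
axis_frame <- function(direction) {
  ref <- if (abs(direction[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- c(direction[2] * ref[3] - direction[3] * ref[2],
         direction[3] * ref[1] - direction[1] * ref[3],
         direction[1] * ref[2] - direction[2] * ref[1])
  u <- u / sqrt(sum(u^2))
  v <- c(direction[2] * u[3] - direction[3] * u[2],
         direction[3] * u[1] - direction[1] * u[3],
         direction[1] * u[2] - direction[2] * u[1])
  list(u = u, v = v)
}

sample_plane <- function(labels, image, centre, e1, e2, npix, sp,
                         axial_profile = FALSE, polar = FALSE) {
  off <- (seq_len(npix) - (npix + 1) / 2) * sp
  pts <- cbind(rep(off, times = npix), rep(off, each = npix))
  world <- matrix(centre, nrow(pts), 3, byrow = TRUE) +
    pts[, 1] %o% e1 + pts[, 2] %o% e2
  blood_ind <- indicator_volume(labels, 2L)
  lab <- matrix(nearest_sample(labels, world, fill = 0L), npix, npix)
  blood <- matrix(trilinear_sample(blood_ind, world), npix, npix)
  myo <- matrix(trilinear_sample(indicator_volume(labels, 1L), world), npix, npix)
  img <- if (!is.null(image))
    matrix(trilinear_sample(image, world, fill = -1000), npix, npix) else NULL
  out <- list(labels = lab, blood_frac = blood, myo_frac = myo, image = img)
  if (polar && any(blood >= 0.5)) {
    # fine polar boundary profiles (0.5-degree rays from the in-plane
    # blood centroid, sub-voxel crossings against the 3D indicators):
    # the basis for perimeter and wall-thickness measurements
    idx <- which(blood >= 0.5, arr.ind = TRUE)
    ctr_plane <- c(mean(off[idx[, 1]]), mean(off[idx[, 2]]))
    out$polar <- polar_trace(labels, centre + ctr_plane[1] * e1 +
                               ctr_plane[2] * e2, e1, e2,
                             rmax = abs(off[1]), ctr_plane = ctr_plane)
  }
  if (axial_profile && any(blood >= 0.5)) {
    # fine blood profile along e1 (0.2 mm steps), max over a small band of
    # lateral offsets around the in-plane cavity centroid: the view-grid
    # pitch is too coarse to localize the apical/basal cavity ends when the
    # source voxels are finer than the view pixels
    idx <- which(blood >= 0.5, arr.ind = TRUE)
    c2 <- mean(off[idx[, 2]])
    t_fine <- seq(off[1], off[npix], by = 0.2)
    prof <- rep(0, length(t_fine))
    for (s in c2 + (-2:2) * sp) {
      p <- matrix(centre, length(t_fine), 3, byrow = TRUE) +
        t_fine %o% e1 + s * matrix(e2, length(t_fine), 3, byrow = TRUE)
      prof <- pmax(prof, trilinear_sample(blood_ind, p))
    }
    out$axial_profile <- list(t_mm = t_fine, blood = prof)
  }
  out
}

# Radial boundary profiles of a short-axis cut: for rays at `n_rays`
# equally spaced angles from the centroid, the sub-voxel radius where the
# blood indicator drops below 0.5 (endocardium) and where the blood+myo
# shell indicator drops below 0.5 (epicardium), traced against the 3D
# label volume. NA where a ray finds no boundary; `ring` marks rays that
# leave the blood pool straight into background (no myocardial ring).
polar_trace <- function(labels, ctr_w, e1, e2, rmax, ctr_plane,
                        n_rays = 720L) {
  blood <- indicator_volume(labels, 2L)
  shell <- blood
  shell$data <- shell$data + indicator_volume(labels, 1L)$data
  dt <- 0.25 * min(labels$spacing)
  ang <- (seq_len(n_rays) - 1) * 2 * pi / n_rays
  rr <- seq(0, rmax, by = dt)
  dirs <- cos(ang) %o% e1 + sin(ang) %o% e2         # n_rays x 3
  pts <- matrix(rep(ctr_w, each = n_rays * length(rr)),
                n_rays * length(rr), 3)
  for (j in 1:3) pts[, j] <- pts[, j] + rep(dirs[, j], times = length(rr)) *
      rep(rr, each = n_rays)
  first_cross <- function(v) {
    # v: n_rays x n_r matrix of indicator samples along each ray
    below <- v < 0.5
    below[, 1] <- FALSE                              # centroid assumed inside
    k <- max.col(below, ties.method = "first")
    k[!below[cbind(seq_len(nrow(v)), k)]] <- NA      # no crossing
    r <- rep(NA_real_, nrow(v))
    ok <- !is.na(k) & k > 1
    kk <- k[ok]; i <- which(ok)
    v0 <- v[cbind(i, kk - 1L)]; v1 <- v[cbind(i, kk)]
    r[ok] <- rr[kk - 1L] + dt * (v0 - 0.5) / (v0 - v1)
    r
  }
  vb <- matrix(trilinear_sample(blood, pts), n_rays, length(rr))
  vs <- matrix(trilinear_sample(shell, pts), n_rays, length(rr))
  r_endo <- first_cross(vb)
  # epicardial crossing: search only beyond the endocardial radius
  vs_masked <- vs
  ri <- matrix(rep(rr, each = n_rays), n_rays, length(rr))
  vs_masked[which(ri <= r_endo)] <- 1
  r_epi <- first_cross(vs_masked)
  # a ray exits straight to background if the shell is already below 0.5
  # just outside the endocardial boundary
  half <- 0.5 * min(labels$spacing)
  just_out <- matrix(ctr_w, n_rays, 3, byrow = TRUE) +
    dirs * (r_endo + half)
  ring <- rep(FALSE, n_rays)
  ok <- !is.na(r_endo)
  ring[ok] <- trilinear_sample(shell, just_out[ok, , drop = FALSE]) >= 0.5
  list(angle_rad = ang, r_endo = r_endo, r_epi = r_epi, ring = ring,
       centroid_plane_mm = ctr_plane)
}

# cached 0/1 indicator volumes (cheap enough to rebuild; kept simple)
indicator_volume <- function(labels, class_id) {
  key <- paste0(".ind", class_id)
  if (!is.null(labels[[key]])) return(labels[[key]])
  image_volume(array(as.numeric(labels$data == class_id), dim(labels$data)),
               labels$spacing, labels$origin)
}

#' Resample a volume into the five cardiac measurement planes
#'
#' Produces one two-chamber (2CH) and one parasternal (PLAX) long-axis view
#' - planes containing the LV axis at the configured azimuths - and three
#' short-axis (SAX) views perpendicular to the axis at the configured
#' apex-to-base fractions. Labels are resampled nearest-neighbour; smooth
#' per-class indicator fields (trilinear) are carried alongside for
#' sub-voxel contour tracing; images (if given) are resampled trilinearly.
#'
#' @param labels a [label_volume()].
#' @param image optional matching [image_volume()].
#' @param lv_axis an `lv_axis` from [estimate_long_axis()].
#' @param config a [view_config()].
#' @return a `view_set`: named list of views
#'   (`2CH`, `PLAX`, `SAX_basal`, `SAX_middle`, `SAX_apical`), each carrying
#'   plane origin/axes, pixel spacing and resampled grids.
#' @export
resample_views <- function(labels, image = NULL, lv_axis,
                           config = view_config()) {
  sp <- config$pixel_spacing_mm
  npix <- 2L * floor(config$fov_mm / (2 * sp)) + 1L
  fr <- axis_frame(lv_axis$direction)
  views <- list()
  az <- config$long_axis_azimuths_deg
  mid <- (lv_axis$apex_mm + lv_axis$base_mm) / 2
  for (k in 1:2) {
    th <- az[k] * pi / 180
    e2 <- cos(th) * fr$u + sin(th) * fr$v
    pl <- sample_plane(labels, image, mid, lv_axis$direction, e2, npix, sp,
                       axial_profile = TRUE)
    views[[names(az)[k]]] <- c(list(
      kind = "long-axis", origin_mm = mid, e1 = lv_axis$direction, e2 = e2,
      normal = cos(th) * fr$v - sin(th) * fr$u,
      pixel_spacing_mm = sp, axis_coord_of_base = sum(
        lv_axis$direction * (lv_axis$base_mm - mid))), pl)
  }
  for (k in seq_along(config$sax_fractions)) {
    q <- config$sax_fractions[k]
    ctr <- lv_axis$apex_mm + q * lv_axis$length_mm * lv_axis$direction
    pl <- sample_plane(labels, image, ctr, fr$u, fr$v, npix, sp,
                       polar = TRUE)
    views[[paste0("SAX_", names(config$sax_fractions)[k])]] <- c(list(
      kind = "short-axis", origin_mm = ctr, e1 = fr$u, e2 = fr$v,
      normal = lv_axis$direction, fraction = unname(q),
      pixel_spacing_mm = sp), pl)
  }
  structure(list(views = views, axis = lv_axis, config = config),
            class = "view_set")
}
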