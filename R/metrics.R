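#' Dice overlap coefficient between two label volumes
#'
#' `2|A∩B| / (|A|+|B|)` for the voxels of `class_id`; defined as 1 when both
#' masks are empty.
#'
#' @param labels_a,labels_b [label_volume()]s on the same grid.
#' @param class_id label whose masks are compared (1 myocardium, 2 blood).
#' @return Dice coefficient in [0, 1].
#' @export
dice <- function(labels_a, labels_b, class_id) {
  if (!same_grid(labels_a, labels_b))
    stop("dice: label volumes are not on the same grid")
  a <- labels_a$data == class_id
  b <- labels_b$data == class_id
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) return(1.0)
  2 * sum(a & b) / (na + nb)
}

#' Ejection fraction from paired ED/ES label volumes
#'
#' `EF = 100 (EDV - ESV) / EDV`, with volumes taken as blood-pool voxel
#' counts times the voxel volume, in the native CT coordinate system.
#'
#' @param ed_labels,es_labels [label_volume()]s with identical spacing.
#' @return EF in percent.
#' @export
ejection_fraction <- function(ed_labels, es_labels) {
  if (max(abs(ed_labels$spacing - es_labels$spacing)) > 1e-6)
    stop("ejection_fraction: phases have different voxel spacing")
  edv <- sum(ed_labels$data == 2L) * prod(ed_labels$spacing)
  esv <- sum(es_labels$data == 2L) * prod(es_labels$spacing)
  if (edv <= 0) stop("ejection_fraction: no blood pool at ED (zero EDV)")
  100 * (edv - esv) / edv
}

# Bilinear interpolation inside a view's pixel grid; (s1, s2) are mm offsets
# along e1/e2 from the plane origin. Outside the grid -> 0.
plane_interp <- function(field, s1, s2, sp) {
  npix <- nrow(field)
  fi <- s1 / sp + (npix + 1) / 2
  fj <- s2 / sp + (npix + 1) / 2
  i0 <- floor(fi); j0 <- floor(fj)
  ok <- i0 >= 1 & i0 <= npix - 1 & j0 >= 1 & j0 <= npix - 1
  out <- numeric(length(s1))
  if (!any(ok)) return(out)
  i0 <- i0[ok]; j0 <- j0[ok]
  ai <- fi[ok] - i0; aj <- fj[ok] - j0
  id <- function(di, dj) (j0 + dj - 1) * npix + i0 + di
  f <- as.numeric(field)
  out[ok] <- (1 - ai) * (1 - aj) * f[id(0, 0)] + ai * (1 - aj) * f[id(1, 0)] +
    (1 - ai) * aj * f[id(0, 1)] + ai * aj * f[id(1, 1)]
  out
}

view_centroid <- function(view, thr = 0.5) {
  m <- view$blood_frac >= thr
  if (!any(m)) return(NULL)
  npix <- nrow(m); sp <- view$pixel_spacing_mm
  idx <- which(m, arr.ind = TRUE)
  c(mean(idx[, 1] - (npix + 1) / 2), mean(idx[, 2] - (npix + 1) / 2)) * sp
}

# Sub-pixel radius where `field` falls below 0.5 along the ray from `ctr`
# at angle `ang`, starting the search at radius r0. NA if no crossing.
ray_crossing <- function(view, field, ctr, ang, r0 = 0, dt = NULL) {
  sp <- view$pixel_spacing_mm
  if (is.null(dt)) dt <- 0.25 * sp
  rmax <- (nrow(field) / 2 - 1) * sp
  tt <- seq(r0, rmax, by = dt)
  v <- plane_interp(field, ctr[1] + tt * cos(ang), ctr[2] + tt * sin(ang), sp)
  if (v[1] < 0.5) return(NA_real_)
  k <- which(v < 0.5)[1]
  if (is.na(k)) return(NA_real_)
  tt[k - 1] + dt * (v[k - 1] - 0.5) / (v[k - 1] - v[k])
}

#' Global longitudinal strain from the two long-axis views
#'
#' Per view, `L` is the apex-to-basal-plane extent of the blood pool along
#' the LV axis within the plane; the view strain is
#' `100 (L_ES - L_ED) / L_ED`, and GLS is the mean over the 2-CH and PLAX
#' views. Lagrangian convention, ED reference, shortening negative.
#'
#' @param ed_views,es_views `view_set`s from [resample_views()].
#' @return GLS in percent.
#' @export
gls <- function(ed_views, es_views) {
  strain <- vapply(c("2CH", "PLAX"), function(key) {
    ved <- ed_views$views[[key]]; ves <- es_views$views[[key]]
    if (is.null(ved) || is.null(ves)) stop("gls: missing long-axis view ", key)
    len <- function(v) {
      # blood-indicator profile along the axis direction with sub-pixel
      # 0.5-crossings at the apical and basal cavity ends
      if (!is.null(v$axial_profile)) {
        prof <- v$axial_profile$blood; tv <- v$axial_profile$t_mm
      } else {
        prof <- apply(v$blood_frac, 1, max)
        tv <- (seq_along(prof) - (length(prof) + 1) / 2) * v$pixel_spacing_mm
      }
      inside <- which(prof >= 0.5)
      if (!length(inside)) stop("gls: empty blood pool in a long-axis view")
      lo <- min(inside); hi <- max(inside)
      step <- tv[2] - tv[1]
      e_lo <- if (lo > 1)
        tv[lo] - step * (prof[lo] - 0.5) / (prof[lo] - prof[lo - 1])
      else tv[lo] - step / 2
      e_hi <- if (hi < length(prof))
        tv[hi] + step * (prof[hi] - 0.5) / (prof[hi] - prof[hi + 1])
      else tv[hi] + step / 2
      e_hi - e_lo
    }
    100 * (len(ves) - len(ved)) / len(ved)
  }, numeric(1))
  mean(strain)
}

# Radial boundary profiles of a SAX view at n_rays angles: endocardial and
# epicardial radii plus a ring flag per ray. Uses the fine polar profiles
# stored by resample_views when present; otherwise traces the view's own
# pixel grids (hand-built views in tests).
sax_polar <- function(view, n_rays, smooth_deg = 0) {
  if (!is.null(view$polar)) {
    p <- view$polar
    stride <- length(p$angle_rad) / n_rays
    if (stride == round(stride)) {
      re <- p$r_endo; rp <- p$r_epi
      if (smooth_deg > 0) {
        hw <- max(1L, round(smooth_deg * length(p$angle_rad) / 360))
        re <- smooth_circular(re, hw); rp <- smooth_circular(rp, hw)
      }
      k <- 1 + (seq_len(n_rays) - 1) * stride
      return(list(angle_rad = p$angle_rad[k], r_endo = re[k],
                  r_epi = rp[k], ring = p$ring[k]))
    }
  }
  ctr <- view_centroid(view)
  if (is.null(ctr)) return(NULL)
  ang <- (seq_len(n_rays) - 1) * 2 * pi / n_rays
  sp <- view$pixel_spacing_mm
  shell <- view$blood_frac + view$myo_frac
  r_endo <- r_epi <- rep(NA_real_, n_rays)
  ring <- rep(FALSE, n_rays)
  for (k in seq_len(n_rays)) {
    r_endo[k] <- ray_crossing(view, view$blood_frac, ctr, ang[k])
    if (is.na(r_endo[k])) next
    ring[k] <- plane_interp(shell,
                            ctr[1] + (r_endo[k] + 0.5 * sp) * cos(ang[k]),
                            ctr[2] + (r_endo[k] + 0.5 * sp) * sin(ang[k]),
                            sp) >= 0.5
    r_epi[k] <- ray_crossing(view, shell, ctr, ang[k], r0 = r_endo[k])
  }
  list(angle_rad = ang, r_endo = r_endo, r_epi = r_epi, ring = ring)
}

# Circular moving average over a closed profile; NA samples are dropped
# from each window (all-NA windows stay NA).
smooth_circular <- function(x, half_width) {
  n <- length(x)
  acc <- numeric(n); cnt <- numeric(n)
  for (k in -half_width:half_width) {
    xs <- x[((seq_len(n) - 1 + k) %% n) + 1]
    ok <- !is.na(xs)
    acc[ok] <- acc[ok] + xs[ok]
    cnt <- cnt + ok
  }
  out <- acc / cnt
  out[cnt == 0] <- NA_real_
  out
}

# Endocardial perimeter of a SAX view: 360 radial rays (1 degree step) from
# the blood-pool centroid, sub-voxel boundary crossings, closed-polygon
# length. The radius profile is regularized by a +/-4 degree circular
# moving average before the polygon is measured: raw per-ray crossings
# carry ~0.1 mm voxel-grid jitter which would otherwise inflate the
# polygon length quadratically. NULL if the view holds no blood pool.
sax_perimeter <- function(view, n_rays = 360L) {
  if (is.null(view$polar) && is.null(view_centroid(view))) return(NULL)
  p <- sax_polar(view, n_rays)
  if (is.null(p)) return(NULL)
  r <- p$r_endo
  r[is.na(r)] <- 0
  hw <- max(1L, round(4 / (360 / n_rays)))
  r <- smooth_circular(r, hw)
  px <- r * cos(p$angle_rad); py <- r * sin(p$angle_rad)
  sum(sqrt(diff(c(px, px[1]))^2 + diff(c(py, py[1]))^2))
}

#' Circumferential strain in a short-axis view
#'
#' `CS = 100 (P_ES - P_ED) / P_ED` with P the endocardial contour perimeter
#' traced by 360 radial rays from the blood-pool centroid.
#' If the cavity is obliterated at ES the value is -100 with attribute
#' `obliterated = TRUE`.
#'
#' @param ed_sax,es_sax single SAX views (elements of a `view_set`).
#' @return CS in percent.
#' @export
circumferential_strain <- function(ed_sax, es_sax) {
  p_ed <- sax_perimeter(ed_sax)
  if (is.null(p_ed))
    stop("circumferential_strain: empty blood pool in the ED SAX view")
  p_es <- sax_perimeter(es_sax)
  if (is.null(p_es))
    return(structure(-100, obliterated = TRUE))
  100 * (p_es - p_ed) / p_ed
}

#' Radial wall thickening in a short-axis view
#'
#' Wall thickness is measured along `n_spokes` radial directions equally
#' spaced across 360 degrees from each phase's own blood-pool centroid:
#' `t = R_epi - R_endo` along the spoke, with sub-pixel boundary crossings.
#' Per spoke, `WT_k = 100 (t_ES - t_ED) / t_ED`; the average is the mean of
#' the valid spokes. A spoke whose ray fails to cross the myocardial ring is
#' flagged missing (NA); more than `max_missing` missing spokes is an error.
#'
#' @param ed_sax,es_sax single SAX views.
#' @param n_spokes number of radial directions (16).
#' @param max_missing maximum tolerated missing spokes.
#' @return list with `spokes_pct` (length `n_spokes`, NA = missing),
#'   `avg_pct`, and the raw per-phase thickness profiles in mm.
#' @export
wall_thickening <- function(ed_sax, es_sax, n_spokes = 16L, max_missing = 4L) {
  thick <- function(view) {
    if (is.null(view$polar) && is.null(view_centroid(view)))
      stop("wall_thickening: empty blood pool in a SAX view")
    p <- sax_polar(view, n_spokes, smooth_deg = 2)
    t <- p$r_epi - p$r_endo
    t[!p$ring] <- NA_real_  # ray exits straight into background: no ring
    t
  }
  t_ed <- thick(ed_sax); t_es <- thick(es_sax)
  wt <- 100 * (t_es - t_ed) / t_ed
  n_missing <- sum(is.na(wt))
  if (n_missing > max_missing)
    stop("wall_thickening: ", n_missing, " of ", n_spokes,
         " spokes failed to cross the myocardial ring")
  list(spokes_pct = wt, avg_pct = mean(wt, na.rm = TRUE),
       thickness_ed_mm = t_ed, thickness_es_mm = t_es)
}

#' Pearson correlation coefficient
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return product-moment correlation in [-1, 1].
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("pearson: unequal lengths")
  if (length(x) < 3) stop("pearson: need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) stop("pearson: constant vector")
  cor(x, y)
}

#' All functional metrics from a paired ED/ES segmentation
#'
#' Orchestrates the measurement pipeline: native-coordinate EF, long-axis
#' estimation, view resampling, GLS, per-level CS and 16-spoke WT. With the
#' default per-phase plane mode, apex/base (and hence SAX plane positions)
#' are located from each phase's own labels so strains compare
#' corresponding material levels.
#'
#' @param ed_labels,es_labels [label_volume()]s of the two phases.
#' @param config a [view_config()].
#' @return a `functional_metrics` list: `ef_pct`, `gls_pct`, `cs_pct`
#'   (named per SAX level), `wt_avg_pct`, `wt_spokes_pct` (16 x 3), the
#'   plane definitions used, and any obliteration flags.
#' @export
compute_all <- function(ed_labels, es_labels, config = view_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("compute_all [", name, "]: ", conditionMessage(e), call. = FALSE))
  }
  ef <- stage("ejection_fraction", ejection_fraction(ed_labels, es_labels))
  axis_ed <- stage("long_axis", estimate_long_axis(ed_labels))
  axis_es <- if (config$plane_mode == "per-phase")
    stage("long_axis", estimate_long_axis(es_labels)) else axis_ed
  ved <- stage("views", resample_views(ed_labels, NULL, axis_ed, config))
  ves <- stage("views", resample_views(es_labels, NULL, axis_es, config))
  g <- stage("gls", gls(ved, ves))
  lev <- names(config$sax_fractions)
  cs <- setNames(numeric(length(lev)), lev)
  wt_avg <- setNames(numeric(length(lev)), lev)
  wt_spokes <- matrix(NA_real_, 16L, length(lev),
                      dimnames = list(NULL, lev))
  obliterated <- logical(length(lev))
  for (k in seq_along(lev)) {
    key <- paste0("SAX_", lev[k])
    cs_k <- stage("circumferential_strain",
                  circumferential_strain(ved$views[[key]], ves$views[[key]]))
    obliterated[k] <- isTRUE(attr(cs_k, "obliterated"))
    cs[k] <- as.numeric(cs_k)
    if (obliterated[k]) {
      wt_avg[k] <- NA_real_
      next
    }
    wt_k <- stage("wall_thickening",
                  wall_thickening(ved$views[[key]], ves$views[[key]]))
    wt_avg[k] <- wt_k$avg_pct
    wt_spokes[, k] <- wt_k$spokes_pct
  }
  structure(list(ef_pct = ef, gls_pct = g, cs_pct = cs,
                 wt_avg_pct = wt_avg, wt_spokes_pct = wt_spokes,
                 obliterated = setNames(obliterated, lev),
                 planes = list(axis_ed = axis_ed, axis_es = axis_es,
                               config = config)),
            class = "functional_metrics")
}

#' @export
print.functional_metrics <- function(x, ...) {
  cat(sprintf("EF %.2f%%  GLS %.2f%%\n", x$ef_pct, x$gls_pct))
  cat("CS  (%):", paste(sprintf("%s %.2f", names(x$cs_pct), x$cs_pct),
                        collapse = "  "), "\n")
  cat("WT  (%):", paste(sprintf("%s %.2f", names(x$wt_avg_pct), x$wt_avg_pct),
                        collapse = "  "), "\n")
  invisible(x)
}
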