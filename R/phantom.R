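#' Parametric beating-LV phantom
#'
#' The phantom models the left ventricle as a truncated prolate-spheroid
#' shell in a canonical pose (long axis along +z, apex at negative z). The
#' endocardial and epicardial surfaces at end-diastole (ED) are coaxial
#' prolate spheroids; both are truncated by the basal plane, a plane
#' perpendicular to the long axis at `base_truncation_frac` times the
#' endocardial long semi-axis above the centre. End-systole (ES) scales the
#' endocardium radially by `es_radial_scale` and longitudinally by
#' `es_long_scale`; the epicardium follows either a myocardial
#' volume-preserving rule (the default, guaranteeing systolic wall
#' thickening) or a fixed-thickness rule. Because every surface is an
#' ellipsoid, cavity volumes, long-axis lengths, endocardial radii and wall
#' thicknesses - hence EF, GLS, CS and WT - have closed forms, giving each
#' phantom analytic ground-truth function metrics.
#'
#' @param endo_short_axis_mm,endo_long_axis_mm ED endocardial semi-axes (mm),
#'   long >= short (prolate).
#' @param epi_short_axis_mm,epi_long_axis_mm ED epicardial semi-axes (mm);
#'   must strictly exceed the endocardial ones (positive wall everywhere).
#' @param base_truncation_frac basal-plane height as a fraction of the
#'   endocardial long semi-axis, in (0, 1).
#' @param es_radial_scale,es_long_scale ES endocardial scale factors in
#'   (0, 1]; identity scales give ES geometry equal to ED.
#' @param wall_model `"volume-preserving"` (ES epicardium solved so the
#'   myocardial shell volume is conserved) or `"fixed-thickness"` (ED wall
#'   thickness kept at apex and equator).
#' @param orientation proper 3x3 rotation applied to the canonical pose,
#'   about the volume centre.
#' @param hu_map named HU values for `background`, `myocardium`,
#'   `blood_pool` (defaults 40 / 100 / 350: contrast-enhanced study).
#' @param seed integer recorded with the spec (used by cohort sampling).
#' @return a validated `phantom_spec` object.
#' @export
phantom_spec <- function(endo_short_axis_mm = 24, endo_long_axis_mm = 45,
                         epi_short_axis_mm = 34, epi_long_axis_mm = 52,
                         base_truncation_frac = 0.5,
                         es_radial_scale = 0.72, es_long_scale = 0.85,
                         wall_model = c("volume-preserving", "fixed-thickness"),
                         orientation = diag(3),
                         hu_map = c(background = 40, myocardium = 100,
                                    blood_pool = 350),
                         seed = NULL) {
  wall_model <- match.arg(wall_model)
  spec <- structure(list(
    endo_short_axis_mm = endo_short_axis_mm,
    endo_long_axis_mm = endo_long_axis_mm,
    epi_short_axis_mm = epi_short_axis_mm,
    epi_long_axis_mm = epi_long_axis_mm,
    base_truncation_frac = base_truncation_frac,
    es_radial_scale = es_radial_scale, es_long_scale = es_long_scale,
    wall_model = wall_model, orientation = orientation,
    hu_map = hu_map, seed = seed), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  ax <- c(spec$endo_short_axis_mm, spec$endo_long_axis_mm,
          spec$epi_short_axis_mm, spec$epi_long_axis_mm)
  if (any(!is.finite(ax)) || any(ax <= 0))
    stop("phantom_spec: all semi-axes must be positive")
  if (spec$endo_long_axis_mm < spec$endo_short_axis_mm ||
      spec$epi_long_axis_mm < spec$epi_short_axis_mm)
    stop("phantom_spec: long semi-axis must be >= short semi-axis (prolate)")
  if (spec$epi_short_axis_mm <= spec$endo_short_axis_mm ||
      spec$epi_long_axis_mm <= spec$endo_long_axis_mm)
    stop("phantom_spec: epicardial semi-axes must strictly exceed ",
         "endocardial semi-axes (zero or negative wall)")
  if (spec$base_truncation_frac <= 0 || spec$base_truncation_frac >= 1)
    stop("phantom_spec: base_truncation_frac must lie in (0, 1)")
  for (s in c(spec$es_radial_scale, spec$es_long_scale))
    if (!is.finite(s) || s <= 0 || s > 1)
      stop("phantom_spec: ES scales must lie in (0, 1]")
  R <- spec$orientation
  if (!is.matrix(R) || !all(dim(R) == c(3, 3)) ||
      max(abs(crossprod(R) - diag(3))) > 1e-6 || abs(det(R) - 1) > 1e-6)
    stop("phantom_spec: orientation must be a proper rotation ",
         "(orthonormal, determinant +1)")
  if (!all(c("background", "myocardium", "blood_pool") %in% names(spec$hu_map)))
    stop("phantom_spec: hu_map must name background, myocardium, blood_pool")
  es <- es_geometry(spec)
  if (es$epi_short <= es$endo_short || es$epi_long <= es$endo_long)
    stop("phantom_spec: ES wall is non-positive under wall_model '",
         spec$wall_model, "'")
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  gt <- analytic_ground_truth(x)
  cat(sprintf(paste0(
    "<phantom_spec> endo %gx%g mm, epi %gx%g mm, basal frac %g\n",
    "  ES scales radial %g / long %g (%s wall) -> EF %.1f%%, GLS %.1f%%\n"),
    x$endo_short_axis_mm, x$endo_long_axis_mm,
    x$epi_short_axis_mm, x$epi_long_axis_mm, x$base_truncation_frac,
    x$es_radial_scale, x$es_long_scale, x$wall_model, gt$ef_pct, gt$gls_pct))
  invisible(x)
}

# Volume of a prolate spheroid (semi-axes a, a, c) truncated at z <= f*c:
# V = pi a^2 c * K(f),  K(f) = f - f^3/3 + 2/3.
trunc_ellipsoid_K <- function(f) f - f^3 / 3 + 2 / 3

trunc_ellipsoid_volume <- function(a, c, f) pi * a^2 * c * trunc_ellipsoid_K(f)

# ES surface geometry implied by the spec's wall model. Basal plane height
# scales with the endocardial long axis (same truncation fraction in both
# phases), so the basal plane stays at the same material level.
es_geometry <- function(spec) {
  a <- spec$endo_short_axis_mm; c <- spec$endo_long_axis_mm
  A <- spec$epi_short_axis_mm;  C <- spec$epi_long_axis_mm
  f <- spec$base_truncation_frac
  sr <- spec$es_radial_scale; sl <- spec$es_long_scale
  a_es <- sr * a; c_es <- sl * c
  h_ed <- f * c; h_es <- sl * h_ed
  if (spec$wall_model == "volume-preserving") {
    C_es <- sl * C
    # myocardial shell volume conserved: solve the ES epicardial short axis
    Kg <- trunc_ellipsoid_K(h_ed / C)        # epi truncation fraction, both phases
    v_myo <- trunc_ellipsoid_volume(A, C, h_ed / C) -
      trunc_ellipsoid_volume(a, c, f)
    v_epi_es <- v_myo + trunc_ellipsoid_volume(a_es, c_es, f)
    A_es <- sqrt(v_epi_es / (pi * C_es * Kg))
  } else {
    A_es <- a_es + (A - a)
    C_es <- c_es + (C - c)
  }
  list(endo_short = a_es, endo_long = c_es,
       epi_short = A_es, epi_long = C_es,
       basal_height = h_es)
}

phase_geometry <- function(spec, phase = c("ED", "ES")) {
  phase <- match.arg(phase)
  if (phase == "ED")
    list(endo_short = spec$endo_short_axis_mm,
         endo_long = spec$endo_long_axis_mm,
         epi_short = spec$epi_short_axis_mm,
         epi_long = spec$epi_long_axis_mm,
         basal_height = spec$base_truncation_frac * spec$endo_long_axis_mm)
  else es_geometry(spec)
}

#' Closed-form ground-truth function metrics of a phantom
#'
#' EF from the truncated-ellipsoid cavity volumes at ED and ES; GLS from the
#' apex-to-basal-plane length (Lagrangian strain, ED reference, shortening
#' negative); CS per short-axis level from the endocardial cross-section
#' circumference; WT per level from the radial wall-thickness change.
#' Short-axis levels are placed at `sax_fractions` of the epicardial-apex to
#' basal-plane length, measured from the apex, matching the view module's
#' plane placement. All metrics are defined on the canonical pose and are
#' therefore invariant under the spec's orientation rotation.
#'
#' @param spec a [phantom_spec()].
#' @param sax_fractions named fractions in (0,1) for the basal/middle/apical
#'   short-axis levels (from apex).
#' @return list with `ef_pct`, `gls_pct`, `cs_pct` (per level), `wt_pct`
#'   (per level), and the per-phase cavity volumes in mL.
#' @export
analytic_ground_truth <- function(spec,
                                  sax_fractions = c(basal = 0.8, middle = 0.5,
                                                    apical = 0.2)) {
  ed <- phase_geometry(spec, "ED"); es <- phase_geometry(spec, "ES")
  f <- spec$base_truncation_frac
  edv <- trunc_ellipsoid_volume(ed$endo_short, ed$endo_long, f)
  esv <- trunc_ellipsoid_volume(es$endo_short, es$endo_long, f)
  ef <- 100 * (edv - esv) / edv
  # apex-to-basal-plane length of the cavity (endocardial apex)
  L_ed <- ed$endo_long + ed$basal_height
  L_es <- es$endo_long + es$basal_height
  gls <- 100 * (L_es - L_ed) / L_ed
  level <- function(g, q) {
    z <- -g$epi_long + unname(q) * (g$epi_long + g$basal_height)
    r_endo <- if (abs(z) < g$endo_long)
      g$endo_short * sqrt(1 - (z / g$endo_long)^2) else 0
    r_epi <- g$epi_short * sqrt(1 - (z / g$epi_long)^2)
    c(r_endo = r_endo, r_epi = r_epi)
  }
  cs <- wt <- setNames(numeric(length(sax_fractions)), names(sax_fractions))
  for (k in seq_along(sax_fractions)) {
    led <- level(ed, sax_fractions[k]); les <- level(es, sax_fractions[k])
    if (led["r_endo"] <= 0 || les["r_endo"] <= 0)
      stop("analytic_ground_truth: short-axis level '", names(sax_fractions)[k],
           "' misses the cavity; raise the fraction or thin the apex cap")
    cs[k] <- 100 * (les["r_endo"] - led["r_endo"]) / led["r_endo"]
    t_ed <- led["r_epi"] - led["r_endo"]; t_es <- les["r_epi"] - les["r_endo"]
    wt[k] <- 100 * (t_es - t_ed) / t_ed
  }
  list(ef_pct = ef, gls_pct = gls, cs_pct = cs, wt_pct = wt,
       edv_ml = edv / 1000, esv_ml = esv / 1000)
}

#' Voxelize one cardiac phase of a phantom
#'
#' Labels every grid voxel by analytic inside-tests on the rotated
#' ellipsoids (blood pool inside the endocardium, myocardium between the
#' surfaces, both below the basal plane) and maps labels to HU via the
#' spec's `hu_map`. The image is noise-free; dose-dependent degradation is
#' the CT simulator's job.
#'
#' @param spec a [phantom_spec()].
#' @param phase `"ED"` or `"ES"`.
#' @param grid a [grid_def()]; the rotation is applied about the grid centre.
#' @param body_radius_mm radius of the cylindrical soft-tissue "body"
#'   surrounding the LV (air, -1000 HU, outside). A compact body inside
#'   the scan field of view is what a CT acquisition sees; the default is
#'   90\% of the smaller in-plane half-extent. The body does not affect
#'   the labels (background class covers body and air alike).
#' @return list with `labels` ([label_volume()]) and `image`
#'   ([image_volume()]) on the same grid.
#' @export
voxelize_phase <- function(spec, phase = c("ED", "ES"),
                           grid = grid_def(), body_radius_mm = NULL) {
  phase <- match.arg(phase)
  g <- phase_geometry(spec, phase)
  half_extent <- grid$n * grid$spacing / 2
  need <- spec$epi_long_axis_mm
  if (need >= min(half_extent))
    stop(sprintf(paste0("voxelize_phase: grid half-extent (%.1f mm) cannot ",
                        "contain the phantom; need > %.1f mm per axis"),
                 min(half_extent), need))
  centre <- grid$origin + (grid$n - 1) / 2 * grid$spacing
  w <- voxel_world_coords(grid)
  p <- sweep(w, 2, centre) %*% spec$orientation  # R^-1 = t(R); (w-c) %*% R = t(R) (w-c)
  below <- p[, 3] <= g$basal_height
  in_endo <- (p[, 1]^2 + p[, 2]^2) / g$endo_short^2 +
    p[, 3]^2 / g$endo_long^2 <= 1
  in_epi <- (p[, 1]^2 + p[, 2]^2) / g$epi_short^2 +
    p[, 3]^2 / g$epi_long^2 <= 1
  lab <- integer(nrow(w))
  lab[in_epi & below] <- 1L
  lab[in_endo & below] <- 2L
  lab <- array(lab, grid$n)
  if (is.null(body_radius_mm))
    body_radius_mm <- 0.9 * min((grid$n * grid$spacing / 2)[1:2])
  in_body <- sweep(w[, 1:2], 2, centre[1:2])
  in_body <- in_body[, 1]^2 + in_body[, 2]^2 <= body_radius_mm^2
  hu <- array(ifelse(in_body, spec$hu_map[["background"]], -1000), grid$n)
  hu[lab == 1L] <- spec$hu_map[["myocardium"]]
  hu[lab == 2L] <- spec$hu_map[["blood_pool"]]
  list(labels = label_volume(lab, grid$spacing, grid$origin),
       image = image_volume(hu, grid$spacing, grid$origin))
}

#' Check that the myocardial shell encloses the blood pool
#'
#' Verifies that no blood-pool voxel is face-adjacent to background, except
#' across the open basal face (the truncation plane leaves the cavity
#' uncovered there by construction). Returns the number of violating voxels.
#'
#' @param labels a [label_volume()].
#' @param basal_dir unit vector (world) of the outward basal-face normal;
#'   blood voxels whose background neighbour lies within 60 degrees of this
#'   direction are attributed to the basal opening and not counted.
#' @return integer count of blood voxels touching background away from the
#'   basal face.
#' @export
cavity_exposure_count <- function(labels, basal_dir = c(0, 0, 1)) {
  lab <- labels$data; d <- dim(lab)
  basal_dir <- basal_dir / sqrt(sum(basal_dir^2))
  pad <- array(0L, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- lab
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  bad <- 0L
  blood <- which(lab == 2L, arr.ind = TRUE)
  for (k in seq_len(nrow(offs))) {
    o <- offs[k, ]
    cosang <- sum((labels$orientation %*% o) * basal_dir) / sqrt(sum(o^2))
    if (cosang > 0.05) next  # outward across the basal opening
    nb <- pad[cbind(blood[, 1] + 1 + o[1], blood[, 2] + 1 + o[2],
                    blood[, 3] + 1 + o[3])]
    bad <- bad + sum(nb == 0L)
  }
  bad
}

# Uniform random proper rotation (quaternion method).
random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# ES endocardial scales achieving a target EF. A single contractility knob
# s in (0, 1] drives both scales, with longitudinal shortening 60% of the
# radial shortening (physiological GLS/CS ratio); solved by 1-D root
# finding on the analytic truncated-ellipsoid EF.
solve_es_scales <- function(target_ef_pct, long_coupling = 0.6) {
  ef_of <- function(s) 100 * (1 - s^2 * (1 - long_coupling * (1 - s)))
  lo <- 0.05
  if (target_ef_pct <= ef_of(1) || target_ef_pct >= ef_of(lo))
    stop("solve_es_scales: target EF ", target_ef_pct,
         "% is unattainable for this deformation family")
  s <- uniroot(function(s) ef_of(s) - target_ef_pct, c(lo, 1),
               tol = 1e-10)$root
  c(es_radial_scale = s, es_long_scale = 1 - long_coupling * (1 - s))
}

#' Build a phantom spec, optionally solving the ES scales for a target EF
#'
#' With `target_ef_pct` given, the ES endocardial scale factors are solved
#' by 1-D root finding on the analytic cavity-volume formula so that the
#' phantom's analytic EF matches the target.
#'
#' @param ... parameters passed to [phantom_spec()].
#' @param target_ef_pct optional target ejection fraction in (5, 90).
#' @param seed integer recorded with the spec.
#' @return a `phantom_spec`.
#' @export
build_phantom_spec <- function(..., target_ef_pct = NULL, seed = NULL) {
  args <- list(...)
  if (!is.null(target_ef_pct)) {
    if (target_ef_pct <= 5 || target_ef_pct >= 90)
      stop("build_phantom_spec: target_ef_pct must lie in (5, 90)")
    sc <- solve_es_scales(target_ef_pct)
    args$es_radial_scale <- unname(sc["es_radial_scale"])
    args$es_long_scale <- unname(sc["es_long_scale"])
  }
  args$seed <- seed
  do.call(phantom_spec, args)
}

#' Generate a reproducible cohort of phantom specs
#'
#' Anatomy parameters are drawn uniformly from the given ranges, EF targets
#' uniformly from `target_ef_pct` (spanning normal and reduced function),
#' and each phantom receives a uniformly random orientation. The cohort is
#' bitwise reproducible from (`param_ranges`, `seed`).
#'
#' @param n number of phantoms (>= 1).
#' @param param_ranges named list of `c(lo, hi)` ranges for
#'   `endo_short_axis_mm`, `endo_long_axis_mm`, `wall_thickness_mm`,
#'   `apex_wall_frac` (apical wall as a fraction of the equatorial wall)
#'   and `target_ef_pct`.
#' @param seed integer RNG seed.
#' @param rotate if `FALSE`, all phantoms stay in the canonical pose.
#' @return list of `phantom_spec` objects.
#' @export
generate_cohort <- function(n,
                            param_ranges = list(
                              endo_short_axis_mm = c(20, 27),
                              endo_long_axis_mm = c(40, 50),
                              wall_thickness_mm = c(8, 12),
                              apex_wall_frac = c(0.6, 0.8),
                              target_ef_pct = c(35, 70)),
                            seed = 1L, rotate = TRUE) {
  if (n < 1) stop("generate_cohort: n must be >= 1")
  for (nm in names(param_ranges)) {
    r <- param_ranges[[nm]]
    if (length(r) != 2 || any(!is.finite(r)) || r[2] < r[1])
      stop("generate_cohort: invalid range for '", nm, "'")
  }
  draw <- function(nm) runif(1, param_ranges[[nm]][1], param_ranges[[nm]][2])
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    a <- draw("endo_short_axis_mm")
    c_ <- draw("endo_long_axis_mm")
    wt <- draw("wall_thickness_mm")
    af <- draw("apex_wall_frac")
    ef <- draw("target_ef_pct")
    R <- if (rotate) random_rotation() else diag(3)
    build_phantom_spec(endo_short_axis_mm = a, endo_long_axis_mm = c_,
                       epi_short_axis_mm = a + wt,
                       epi_long_axis_mm = c_ + af * wt,
                       orientation = R, target_ef_pct = ef,
                       seed = seed + i)
  })
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  expr
}
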