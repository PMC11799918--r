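#' Derive a stage seed from the global seed
#'
#' One global seed deterministically derives per-stage seeds by hashing the
#' stage name, so each pipeline stage is independently reproducible.
#'
#' @param global_seed integer.
#' @param stage character stage name.
#' @return integer seed in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(global_seed, stage) {
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(as.character(stage))) h <- (h * 131 + ch) %% m
  as.integer(1 + (h + (as.numeric(global_seed) %% m) * 7919) %% (m - 1))
}

#' Write a volume to a NIfTI file
#'
#' Spacing and origin are stored in the NIfTI header (sform); voxel data
#' are written as-is. Only axis-aligned grids are produced by this
#' package, so the direction matrix is the identity.
#'
#' @param vol an [image_volume()] or [label_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  xform <- rbind(cbind(diag(vol$spacing), vol$origin), c(0, 0, 0, 1))
  img <- RNifti::asNifti(vol$data)
  img <- RNifti::`sform<-`(img, structure(xform, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from a NIfTI file
#'
#' @param path NIfTI file path.
#' @param type `"image"` or `"label"` (integer-checked).
#' @return an [image_volume()] or [label_volume()].
#' @export
read_volume <- function(path, type = c("image", "label")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("read_volume: no such file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("read_volume: cannot read '",
                                           path, "': ",
                                           conditionMessage(e)))
  xf <- RNifti::xform(img)
  spacing <- sqrt(colSums(xf[1:3, 1:3]^2))
  origin <- xf[1:3, 4]
  arr <- array(as.numeric(img), dim(img)[1:3])
  if (type == "label") label_volume(array(as.integer(round(arr)), dim(arr)),
                                    spacing, origin)
  else image_volume(arr, spacing, origin)
}

default_config <- function() {
  list(
    seed = 1L,
    out_dir = "results",
    phantom = list(
      n = 10L,
      grid_n = c(96L, 96L, 96L),
      grid_spacing_mm = 1.5,
      rotate = TRUE,
      param_ranges = list(
        endo_short_axis_mm = c(20, 27),
        endo_long_axis_mm = c(40, 50),
        wall_thickness_mm = c(8, 12),
        apex_wall_frac = c(0.6, 0.8),
        target_ef_pct = c(35, 70))),
    ct_sim = list(
      n_detectors = 192L,
      detector_pitch_mm = 1.0,
      n_angles = 180L,
      ref_mA = 500,
      i0_ref = 3e5,
      electronic_noise_sd = 10,
      mu_water_per_mm = 0.020),
    segmenter = list(
      base_channels = 8L,
      patch_size = c(64L, 64L, 32L),
      learning_rate = 5e-4,
      batch_size = 32L,
      epochs = 200L,
      rule_thresholds = c(background_myocardium = 70,
                          myocardium_blood = 225)),
    views = list(
      sax_fractions = c(basal = 0.8, middle = 0.5, apical = 0.2),
      long_axis_azimuths_deg = c(0, 90),
      pixel_spacing_mm = 1.0,
      fov_mm = 160),
    study = list(
      doses_mA = c(500, 100, 50, 25, 10),
      threshold_metrics = c("ef", "gls", "cs"),
      threshold_tolerance_pp = 2.5))
}

merge_config <- function(defaults, overrides, path = character()) {
  for (key in names(overrides)) {
    here <- c(path, key)
    if (!key %in% names(defaults))
      stop("load_config: unknown key '", paste(here, collapse = "."),
           "'; valid keys here: ",
           paste(names(defaults), collapse = ", "))
    dv <- defaults[[key]]; ov <- overrides[[key]]
    if (is.list(dv) && !is.list(ov))
      stop("load_config: key '", paste(here, collapse = "."),
           "' must be a section")
    if (is.list(dv)) {
      # named sections merge recursively; unnamed lists are values
      if (length(names(dv)))
        defaults[[key]] <- merge_config(dv, ov, here)
      else defaults[[key]] <- ov
    } else {
      if (is.list(ov) || (is.numeric(dv) && !is.numeric(ov)) ||
          (is.character(dv) && !is.character(ov)))
        stop("load_config: type mismatch for key '",
             paste(here, collapse = "."), "'")
      defaults[[key]] <- ov
    }
  }
  defaults
}

#' Load a run configuration
#'
#' Reads a YAML configuration and merges it over the package defaults.
#' Unknown keys are rejected (typo guard); an absent or empty file yields
#' the complete default configuration, which is runnable as-is.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return nested configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("load_config: no such file: ", path)
  overrides <- yaml::read_yaml(path)
  if (is.null(overrides)) return(cfg)
  merge_config(cfg, overrides)
}
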