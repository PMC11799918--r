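#' Parallel-beam scan geometry
#'
#' A simplified per-axial-slice parallel-beam geometry: `n_detectors`
#' equispaced detector channels spanning the in-plane field of view and
#' `n_angles` projection angles uniformly covering \[0, 180) degrees. Every
#' axial slice of a volume is projected with the same geometry.
#'
#' @param n_detectors number of detector channels.
#' @param detector_pitch_mm channel spacing in mm.
#' @param n_angles number of projection angles over \[0, 180).
#' @param quiet suppress the angular-sampling advisory.
#' @return a `scan_geometry` list; `undersampled` flags geometries below
#'   the `n_angles >= n_detectors * pi / 2` rule of thumb (a warning, not
#'   an error - streak-prone but often acceptable for noise studies).
#' @export
scan_geometry <- function(n_detectors = 192L, detector_pitch_mm = 1.0,
                          n_angles = 180L, quiet = FALSE) {
  if (n_detectors < 2 || n_angles < 1 || detector_pitch_mm <= 0)
    stop("scan_geometry: invalid geometry parameters")
  undersampled <- n_angles < n_detectors * pi / 2
  if (undersampled && !quiet)
    warning(sprintf(paste0("scan_geometry: n_angles = %d is below the ",
                           "n_detectors*pi/2 ~ %.0f rule of thumb; ",
                           "expect mild angular-undersampling streaks"),
                    n_angles, n_detectors * pi / 2))
  structure(list(n_detectors = as.integer(n_detectors),
                 detector_pitch_mm = detector_pitch_mm,
                 n_angles = as.integer(n_angles),
                 angles_rad = (seq_len(n_angles) - 1) * pi / n_angles,
                 undersampled = undersampled),
            class = "scan_geometry")
}

#' X-ray acquisition specification
#'
#' The flux/noise model of the simulator: incident photons per detector
#' channel scale linearly with tube current,
#' `I0(mA) = i0_ref * mA / ref_mA`, quantum noise is Poisson in detected
#' counts, and detector readout adds zero-mean Gaussian electronic noise
#' (in counts).
#'
#' @param tube_current_mA tube current; dose is proportional to it.
#' @param i0_ref photons per ray at the reference tube current.
#' @param ref_mA reference tube current (the "standard" flux).
#' @param electronic_noise_sd electronic noise SD in counts.
#' @param mu_water_per_mm linear attenuation of water, 1/mm.
#' @param seed integer seed for the stochastic stages.
#' @return an `acquisition_spec` with derived field `i0`.
#' @export
acquisition_spec <- function(tube_current_mA, i0_ref = 3e5, ref_mA = 500,
                             electronic_noise_sd = 10,
                             mu_water_per_mm = 0.020, seed = NULL) {
  if (tube_current_mA <= 0) stop("acquisition_spec: tube current must be > 0")
  if (i0_ref <= 0) stop("acquisition_spec: i0_ref must be > 0")
  structure(list(tube_current_mA = tube_current_mA, i0_ref = i0_ref,
                 ref_mA = ref_mA,
                 i0 = i0_ref * tube_current_mA / ref_mA,
                 electronic_noise_sd = electronic_noise_sd,
                 mu_water_per_mm = mu_water_per_mm, seed = seed),
            class = "acquisition_spec")
}

#' Dose reduction factor of an acquisition relative to the reference
#'
#' Dose scales linearly with tube current at fixed kVp and rotation time,
#' so the reduction factor from the reference flux is `ref_mA / mA`.
#'
#' @param acq an [acquisition_spec()].
#' @return scalar reduction factor (e.g. 5 at 100 mA for a 500 mA
#'   reference).
#' @export
dose_reduction_factor <- function(acq) acq$ref_mA / acq$tube_current_mA

new_sinogram <- function(data, geometry, grid, provenance) {
  structure(list(data = data, geometry = geometry, grid = grid,
                 provenance = provenance),
            class = "sinogram_stack")
}

#' @export
print.sinogram_stack <- function(x, ...) {
  cat(sprintf("<sinogram_stack> %d det x %d angles x %d slices [%s]\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$provenance))
  invisible(x)
}

hu_to_mu <- function(hu, mu_water) pmax(mu_water * (1 + hu / 1000), 0)

#' Forward-project an HU volume into a sinogram stack
#'
#' HU are converted to linear attenuation `mu = mu_water (1 + HU/1000)`
#' (clamped at zero) and integrated along parallel rays slice by slice,
#' yielding dimensionless log-attenuation line integrals.
#'
#' @param image an [image_volume()]; in-plane grid centred on the rotation
#'   axis.
#' @param geometry a [scan_geometry()]; the detector span must cover the
#'   in-plane grid width.
#' @param mu_water_per_mm water attenuation used for the HU conversion.
#' @param step_mm ray sampling step (default half the in-plane voxel size).
#' @return a `sinogram_stack` with provenance `"ideal"`.
#' @export
forward_project <- function(image, geometry, mu_water_per_mm = 0.020,
                            step_mm = NULL) {
  d <- dim(image$data)
  span <- geometry$n_detectors * geometry$detector_pitch_mm
  support <- min(d[1] * image$spacing[1], d[2] * image$spacing[2])
  if (support > span)
    stop(sprintf(paste0("forward_project: phantom support (%.0f mm) exceeds ",
                        "the detector span (%.0f mm)"), support, span))
  if (is.null(step_mm)) step_mm <- 0.5 * min(image$spacing[1:2])
  mu <- hu_to_mu(image$data, mu_water_per_mm)
  sino <- cpp_forward_project(as.numeric(mu), dim(mu),
                              image$spacing[1], image$spacing[2],
                              geometry$n_detectors,
                              geometry$detector_pitch_mm,
                              geometry$angles_rad, step_mm)
  new_sinogram(sino, geometry, grid_like(image), "ideal")
}

#' Simulate noisy detector counts for a sinogram
#'
#' Per ray: `N = Poisson(I0 exp(-p)) + Normal(0, sd_e^2)`, counts floored
#' at 0.1 before the log (photon-starvation guard), and the noisy line
#' integral is `p' = ln(I0 / N)`. Reproducible from the seed.
#'
#' @param sinogram an ideal `sinogram_stack`.
#' @param acq an [acquisition_spec()].
#' @param seed overrides `acq$seed`.
#' @param count_floor minimum counts before the log.
#' @return a `sinogram_stack` with provenance `"noisy@<mA>"`.
#' @export
simulate_counts <- function(sinogram, acq, seed = NULL,
                            count_floor = 0.1) {
  if (acq$i0 <= 0) stop("simulate_counts: non-positive photon flux")
  seed <- if (!is.null(seed)) seed else acq$seed
  p <- sinogram$data
  n <- length(p)
  noisy <- with_seed(if (is.null(seed)) sample.int(2^31 - 1, 1) else seed, {
    counts <- rpois(n, acq$i0 * exp(-as.numeric(p)))
    if (acq$electronic_noise_sd > 0)
      counts <- counts + rnorm(n, 0, acq$electronic_noise_sd)
    counts
  })
  noisy <- pmax(noisy, count_floor)
  out <- array(log(acq$i0 / noisy), dim(p))
  new_sinogram(out, sinogram$geometry, sinogram$grid,
               sprintf("noisy@%gmA", acq$tube_current_mA))
}

# Delta-method variance of the log-domain projection value at mean counts
# nbar with electronic noise sd_e: var(ln(I0/N)) ~ (nbar + sd_e^2) / nbar^2.
log_domain_variance <- function(nbar, sd_e) (nbar + sd_e^2) / nbar^2

#' Emulate a low-dose sinogram from a measured standard-dose sinogram
#'
#' Adds zero-mean Gaussian noise per ray with variance equal to the
#' difference between the counts-model log-domain variances at the low and
#' standard doses, so the emulated sinogram's total noise matches a direct
#' acquisition at the low dose. The per-ray mean counts are estimated from
#' the measured standard-dose line integrals (all a real scanner has). The
#' Gaussian approximation of the Poisson difference thins at very low
#' counts; [simulate_counts()] provides the direct route for cross-checks.
#'
#' @param standard_sinogram measured (noisy) standard-dose `sinogram_stack`.
#' @param acq_standard,acq_low [acquisition_spec()]s; the low dose must not
#'   exceed the standard dose.
#' @param seed RNG seed.
#' @return a `sinogram_stack` with provenance `"emulated@<mA>"`.
#' @export
inject_incremental_noise <- function(standard_sinogram, acq_standard,
                                     acq_low, seed = NULL) {
  if (acq_low$tube_current_mA > acq_standard$tube_current_mA)
    stop("inject_incremental_noise: the emulated dose must not exceed ",
         "the standard dose")
  p <- as.numeric(standard_sinogram$data)
  nbar_std <- acq_standard$i0 * exp(-p)
  nbar_low <- acq_low$i0 * exp(-p)
  var_inc <- pmax(log_domain_variance(nbar_low, acq_low$electronic_noise_sd) -
                  log_domain_variance(nbar_std,
                                      acq_standard$electronic_noise_sd), 0)
  if (acq_low$tube_current_mA == acq_standard$tube_current_mA)
    return(new_sinogram(standard_sinogram$data, standard_sinogram$geometry,
                        standard_sinogram$grid,
                        standard_sinogram$provenance))
  noise <- with_seed(if (is.null(seed)) sample.int(2^31 - 1, 1) else seed,
                     rnorm(length(p), 0, sqrt(var_inc)))
  out <- array(p + noise, dim(standard_sinogram$data))
  new_sinogram(out, standard_sinogram$geometry, standard_sinogram$grid,
               sprintf("emulated@%gmA", acq_low$tube_current_mA))
}

# Apodized ramp filter: discrete Ram-Lak kernel built in the spatial
# domain (which keeps the correct low-frequency/DC response, unlike
# sampling |f| directly) and Hann-windowed in frequency.
ramp_hann_filter <- function(L, pitch) {
  n <- c(0:(L / 2), -(L / 2 - 1):-1)
  h <- ifelse(n == 0, 1 / (4 * pitch^2),
              ifelse(n %% 2L != 0L, -1 / (pi^2 * n^2 * pitch^2), 0))
  H <- Re(fft(h)) * pitch
  k <- 0:(L - 1)
  f <- pmin(k, L - k) / (L * pitch)
  f_ny <- 1 / (2 * pitch)
  H * 0.5 * (1 + cos(pi * f / f_ny))
}

#' Filtered back-projection reconstruction
#'
#' Per-slice parallel-beam FBP with a Hann-apodized ramp filter (the
#' simulator's surrogate for a clinical "standard" kernel); reconstructed
#' attenuation is converted back to HU.
#'
#' @param sinogram a `sinogram_stack`.
#' @param grid target [grid_def()]; slice count must match the sinogram.
#' @param mu_water_per_mm water attenuation for the HU conversion.
#' @return an [image_volume()].
#' @export
fbp_reconstruct <- function(sinogram, grid, mu_water_per_mm = 0.020) {
  sd <- dim(sinogram$data)
  if (grid$n[3] != sd[3])
    stop("fbp_reconstruct: grid slice count does not match the sinogram")
  geom <- sinogram$geometry
  n_det <- geom$n_detectors
  L <- nextn(2 * n_det, 2)
  H <- ramp_hann_filter(L, geom$detector_pitch_mm)
  # filter all (angle, slice) projections at once
  p <- matrix(sinogram$data, n_det, sd[2] * sd[3])
  pp <- rbind(p, matrix(0, L - n_det, ncol(p)))
  q <- Re(mvfft(mvfft(pp) * H, inverse = TRUE)) / L
  q <- array(q[seq_len(n_det), ], c(n_det, sd[2], sd[3]))
  vol <- cpp_backproject(as.numeric(q), dim(q), grid$n[1], grid$n[2],
                         grid$spacing[1], grid$spacing[2],
                         geom$detector_pitch_mm, geom$angles_rad)
  vol <- vol * pi / geom$n_angles
  hu <- 1000 * (vol / mu_water_per_mm - 1)
  image_volume(array(hu, grid$n), grid$spacing, grid$origin)
}

#' Emulate the dose ladder for one volume
#'
#' Implements the paired low-dose design: the standard-dose scan is
#' simulated directly (projection + counts noise + FBP); every lower dose
#' is emulated from that same standard-dose sinogram by incremental noise
#' injection, so all ladder volumes share the underlying anatomy and
#' standard-dose noise realization, then reconstructed on a common grid.
#'
#' @param image noise-free [image_volume()] (e.g. from [voxelize_phase()]).
#' @param geometry a [scan_geometry()].
#' @param acq_standard [acquisition_spec()] of the standard dose.
#' @param dose_list_mA descending tube currents; the first must equal the
#'   standard dose.
#' @param seed RNG seed (per-dose seeds are derived from it).
#' @return named list `"<mA>"` -> reconstructed [image_volume()].
#' @export
emulate_dose_ladder <- function(image, geometry, acq_standard,
                                dose_list_mA = c(500, 100, 50, 25, 10),
                                seed = 1L) {
  if (is.unsorted(rev(dose_list_mA), strictly = TRUE))
    stop("emulate_dose_ladder: dose list must be strictly descending")
  if (dose_list_mA[1] != acq_standard$tube_current_mA)
    stop("emulate_dose_ladder: first dose must be the standard tube current")
  grid <- grid_like(image)
  ideal <- forward_project(image, geometry, acq_standard$mu_water_per_mm)
  sino_std <- simulate_counts(ideal, acq_standard,
                              seed = derive_seed(seed, "standard-dose"))
  out <- list()
  out[[as.character(dose_list_mA[1])]] <-
    fbp_reconstruct(sino_std, grid, acq_standard$mu_water_per_mm)
  for (mA in dose_list_mA[-1]) {
    acq_low <- acquisition_spec(mA, i0_ref = acq_standard$i0_ref,
                                ref_mA = acq_standard$ref_mA,
                                electronic_noise_sd =
                                  acq_standard$electronic_noise_sd,
                                mu_water_per_mm =
                                  acq_standard$mu_water_per_mm)
    sino_low <- inject_incremental_noise(
      sino_std, acq_standard, acq_low,
      seed = derive_seed(seed, paste0("emulate-", mA)))
    out[[as.character(mA)]] <-
      fbp_reconstruct(sino_low, grid, acq_standard$mu_water_per_mm)
  }
  out
}
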