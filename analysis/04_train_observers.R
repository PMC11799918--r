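#!/usr/bin/env Rscript
# Trains the two network observers on a six-phantom training cohort:
#   Standard     - standard-dose volumes only
#   Noise-Robust - standard-dose plus the emulated low-dose ladder
# Both share the residual 3D U-Net architecture, generalized Dice loss
# with deep supervision, Adam, and the same seed; only the dataset
# differs. Runtime: ~10 min CPU for both. Writes loss histories to
# results/training_loss.csv and the observers to scratch/observers.rds
# (binary scratch; 05_dose_threshold.R retrains automatically if absent).

suppressPackageStartupMessages(library(lvdose))
seed <- 1L
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

geom <- scan_geometry(128L, 1.25, 120L, quiet = TRUE)
acq <- acquisition_spec(500)
grid <- grid_def(c(64L, 64L, 64L), 2.25)

train_cohort <- generate_cohort(6, seed = derive_seed(seed, "train-cohort"))
cases <- list()
for (i in seq_along(train_cohort)) for (ph in c("ED", "ES")) {
  vox <- voxelize_phase(train_cohort[[i]], ph, grid)
  ladder <- emulate_dose_ladder(vox$image, geom, acq, c(500, 100, 50, 25, 10),
                                seed = derive_seed(seed,
                                                   paste0("train-", i, ph)))
  for (ds in names(ladder))
    cases[[length(cases) + 1L]] <- training_case(
      ladder[[ds]], vox$labels, sprintf("train%d%s", i, ph),
      if (ds == "500") "SD" else ds)
}
message(length(cases), " training volumes prepared (6 cases x 2 phases x 5 doses)")

net <- net_config(base_channels = 4L, patch_size = c(16L, 16L, 16L))
mk <- function(doses) train_recipe(learning_rate = 1e-2, batch_size = 4L,
                                   epochs = 30L, batches_per_epoch = 10L,
                                   doses_included = doses,
                                   seed = derive_seed(seed, "training"))
observers <- list(standard = train_observer(net, mk("SD"), cases),
                  noise_robust = train_observer(net, mk("all"), cases))
for (nm in names(observers))
  message(sprintf("%-12s final loss %.4f (%d training volumes in audit)",
                  nm, tail(observers[[nm]]$loss_history, 1),
                  nrow(observers[[nm]]$dataset_audit)))

loss_tab <- do.call(rbind, lapply(names(observers), function(nm)
  data.frame(observer = nm,
             epoch = seq_along(observers[[nm]]$loss_history),
             loss = observers[[nm]]$loss_history)))
write.csv(loss_tab, "results/training_loss.csv", row.names = FALSE)
saveRDS(observers, "scratch/observers.rds")
message("Loss histories -> results/training_loss.csv; observers -> scratch/")
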