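#!/usr/bin/env Rscript
# Simulates example tracked ultrasound sweeps over one vertebra at the four
# depth x frequency settings of the acquisition grid, extracts their bone
# point clouds, and writes one sweep (frames + poses + sidecar) under
# results/sweeps/. The full 120-sweep grid is run by 04_run_study.R.

library(spinenav)

out <- "results/sweeps"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ph <- generate_phantom(phantom_config())
level <- 3L

rows <- list()
for (depth in c(5, 7)) for (freq in c(6, 12)) {
  cfg <- sweep_config(depth_cm = depth, frequency_mhz = freq, seed = 42L)
  sw <- simulate_sweep(ph, level, cfg)
  cl <- sweep_to_cloud(sw)
  rows[[length(rows) + 1]] <- data.frame(
    depth_cm = depth, frequency_mhz = freq,
    n_frames = length(sw$frames),
    image_px = sprintf("%dx%d", cfg$image_rows, cfg$n_cols),
    pixel_spacing_mm = round(cfg$pixel_spacing_mm, 4),
    echo_sigma_mm = cfg$echo_sigma_mm,
    cloud_points = nrow(cl$points))
  cat(sprintf("depth %g cm, %2g MHz: %d frames, %d bone points\n",
              depth, freq, length(sw$frames), nrow(cl$points)))
}
tab <- do.call(rbind, rows)
write.csv(tab, file.path(out, "example_sweeps.csv"), row.names = FALSE)

sw <- simulate_sweep(ph, level, sweep_config(depth_cm = 5, frequency_mhz = 12,
                                             seed = 42L))
write_sweep(sw, file.path(out, "example_L3_d5_f12"))
cat("Wrote example sweep to", file.path(out, "example_L3_d5_f12"), "\n")
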