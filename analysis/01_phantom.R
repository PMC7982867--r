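#!/usr/bin/env Rscript
# Builds the synthetic lumbosacral phantom that stands in for the specimen:
# six vertebrae (L1-L6) on a rigid frame with four fiducial spheres, CT-like
# volumes at 0.5 / 1 / 2 mm, a five-region labelmap per level and seven
# surface landmarks per vertebra. Writes the geometry tables (and NIfTI
# volumes when RNifti is available) under results/phantom/.

library(spinenav)

out <- "results/phantom"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- phantom_config()
cat("Generating phantom:", cfg$n_levels, "levels at",
    cfg$base_spacing_mm, "mm base spacing\n")
ph <- generate_phantom(cfg)
print(ph)

write_landmarks_csv(ph, file.path(out, "landmarks.csv"))
cat("Wrote", file.path(out, "landmarks.csv"), "\n")

apex <- t(vapply(ph$landmarks, function(m) m["spinous_apex", ], numeric(3)))
gaps <- rev(diff(rev(apex[, 3])))
cat("Measured successive spinous-process gaps (cranial to caudal, mm):\n ",
    paste(sprintf("%.2f", abs(diff(apex[, 3]))), collapse = ", "), "\n")
cat(sprintf("L1-L6 spinous distance: %.2f mm (configured %.2f mm)\n",
            abs(apex[1, 3] - apex[6, 3]), sum(cfg$inter_level_distances_mm)))

for (res in c(1, 2)) {
  v <- resample_ct(ph, res)
  cat(sprintf("CT at %g mm: %s voxels\n", res,
              paste(dim(v$data), collapse = " x ")))
  if (requireNamespace("RNifti", quietly = TRUE)) {
    write_volume_nifti(v, file.path(out, sprintf("ct_%gmm.nii.gz", res)))
  }
}
if (requireNamespace("RNifti", quietly = TRUE)) {
  write_volume_nifti(ph$ct, file.path(out, "ct_0.5mm.nii.gz"))
  write_volume_nifti(ph$labelmap, file.path(out, "labelmap_0.5mm.nii.gz"))
  cat("Wrote NIfTI volumes under", out, "\n")
}
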