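#!/usr/bin/env Rscript
# Error-propagation analysis: how an alignment error at one vertebra maps
# to its neighbours. Reads the study's long TRE table (04_run_study.R must
# have run), fits TRE against the cumulative spinous-process distances, and
# repeats the controlled-injection experiment over a range of angular
# errors to show the 2 sin(eps/2) lever-arm law.

library(spinenav)

out <- "results/propagation"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

gaps <- phantom_config()$inter_level_distances_mm
dist <- cumulative_level_distances(gaps)

long_path <- "results/study/results_long.csv"
if (file.exists(long_path)) {
  long <- read.csv(long_path)
  for (res in sort(unique(long$resolution_mm))) {
    sub <- long[long$resolution_mm == res & !is.na(long$tre_mm), ]
    pm <- propagation_matrix(sub)
    fit <- fit_tre_vs_distance(pm, dist)
    cat(sprintf("resolution %g mm: slope %.5f mm TRE per mm distance, intercept %.3f mm\n",
                res, fit$slope, fit$intercept))
    write.csv(pm, file.path(out, sprintf("propagation_%gmm.csv", res)))
  }
} else {
  cat("results/study/results_long.csv not found; run 04_run_study.R first.\n")
}

pos <- c(0, cumsum(rev(gaps)))
rows <- list()
for (eps in c(0.25, 0.5, 1, 2, 4)) {
  cells <- list()
  for (i in 1:6) {
    t_err <- perturb_transform(rt_identity(), eps, c(1, 0, 0),
                               pivot = c(0, 0, pos[i]))
    for (j in 1:6) {
      cells[[length(cells) + 1]] <- data.frame(
        acq_level = i, measured_level = j,
        tre_mm = compute_tre(t_err, rt_identity(), rbind(c(0, 0, pos[j]))))
    }
  }
  fit <- fit_tre_vs_distance(propagation_matrix(do.call(rbind, cells)), dist)
  rows[[length(rows) + 1]] <- data.frame(
    eps_deg = eps, slope = fit$slope,
    lever_arm_law = 2 * sin(eps / 2 * pi / 180),
    ratio = fit$slope / (2 * sin(eps / 2 * pi / 180)))
}
tab <- do.call(rbind, rows)
print(tab, digits = 5)
write.csv(tab, file.path(out, "lever_arm_scan.csv"), row.names = FALSE)
cat("Injected angular errors follow the 2 sin(eps/2) lever-arm law",
    "(ratios above are 1 to within numerical noise).\n")
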