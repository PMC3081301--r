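#!/usr/bin/env Rscript
# Best-method map over the (pi0, rho) parameter space.
#
# Sweeps a scaled grid of the parameter space (pi0 in {0.5, 0.65, 0.8,
# 0.95}, rho in {0, 0.2, 0.4, 0.6}; M = 2,000 genes, R = 30 replicates per
# point) and classifies every point by the standing of the median-slope
# reference estimator: blue = significantly more accurate than all four
# competitors, yellow = at least one competitor statistically equivalent,
# red = some competitor significantly more accurate. The significance
# threshold 0.01 keeps the expected number of falsely declared
# significances below one over the 16 points x 4 paired tests of this
# scaled sweep.

suppressPackageStartupMessages(library(pi0bench))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L
dir.create("results", showWarnings = FALSE)
started <- Sys.time()

pi0_grid <- c(0.5, 0.65, 0.8, 0.95)
rho_grid <- c(0, 0.2, 0.4, 0.6)
threshold <- 0.01
stopifnot(length(pi0_grid) * length(rho_grid) * 4 * threshold < 1)

base <- sim_config(M = 2000, k = 5, n1 = 8, n2 = 8)
rm <- sweep_parameter_space(pi0_grid, rho_grid, base, R = 30,
                            threshold = threshold, master_seed = seed,
                            verbose = TRUE)
write.csv(rm$summary, "results/region_map.csv", row.names = FALSE)
write.csv(rm$points, "results/region_map_labels.csv", row.names = FALSE)

cat("\nlabel counts over the grid:\n")
print(table(rm$points$label))
red <- rm$points[rm$points$label == "red", ]
if (nrow(red) > 0) {
  cat("points where the reference is significantly beaten:\n")
  print(red[, c("pi0", "rho")])
  for (i in seq_len(nrow(red))) {
    sub <- rm$summary[rm$summary$pi0 == red$pi0[i] & rm$summary$rho == red$rho[i], ]
    cat(sprintf("  at (%.2f, %.1f) best method: %s\n", red$pi0[i], red$rho[i],
                sub$method[which.min(sub$mae)]))
  }
}

run_manifest("region_map",
             list(pi0_grid = pi0_grid, rho_grid = rho_grid, R = 30,
                  M = 2000, threshold = threshold),
             seed,
             outputs = c("results/region_map.csv",
                         "results/region_map_labels.csv"),
             started = started)
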