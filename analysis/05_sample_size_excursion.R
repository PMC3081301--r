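#!/usr/bin/env Rscript
# Excursions into the sample-size dimension.
#
# The main benchmark fixes n = 8 arrays per condition. Here two
# representative points of the (pi0, rho) plane are re-run with n in
# {4, 6, 8, 12} to check whether the relative standing of the methods is an
# artefact of that choice: a mid-pi0 point where the median-slope reference
# dominates, and a high-pi0 point (pi0 = 0.95) where the BUM upper-bound
# method is expected to be competitive. Scaled: M = 2,000, R = 20.

suppressPackageStartupMessages(library(pi0bench))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L
dir.create("results", showWarnings = FALSE)
started <- Sys.time()

base <- sim_config(M = 2000, k = 5)
rows <- list()
for (pt in list(c(0.8, 0.2), c(0.95, 0.2))) {
  rm <- sweep_parameter_space(pi0_grid = pt[1], rho_grid = pt[2],
                              base_config = base, R = 20, threshold = 0.01,
                              master_seed = seed, n_grid = c(4, 6, 8, 12))
  rows[[length(rows) + 1]] <- rm$summary
  cat(sprintf("\n(pi0 = %.2f, rho = %.1f):\n", pt[1], pt[2]))
  for (n in c(4, 6, 8, 12)) {
    sub <- rm$summary[rm$summary$n == n, ]
    best <- sub[which.min(sub$mae), ]
    cat(sprintf("  n = %2d: best %s (MAE %.4f), label %s\n",
                n, best$method, best$mae, best$label))
  }
}
out <- do.call(rbind, rows)
write.csv(out, "results/sample_size_excursion.csv", row.names = FALSE)

run_manifest("sample_size_excursion",
             list(points = "(0.8, 0.2), (0.95, 0.2)", n = c(4, 6, 8, 12),
                  R = 20, M = 2000),
             seed, outputs = "results/sample_size_excursion.csv",
             started = started)
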