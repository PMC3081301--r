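#' Replicated in silico experiments at one parameter point
#'
#' Runs `R` independent replicate experiments of one simulation
#' configuration: each replicate simulates an expression study, computes
#' per-gene pooled-variance t-test p-values, and feeds the same p-value
#' vector to all five pi0 estimators — the shared data per replicate is what
#' makes the downstream paired comparisons valid. Per-replicate seeds are
#' drawn deterministically from `master_seed`, so the batch is reproducible
#' and replicates are mutually independent.
#'
#' @param config a [sim_config()]; its `seed` field is overridden per
#'   replicate.
#' @param R number of replicates (>= 2).
#' @param master_seed integer seed for the replicate seed stream.
#' @param methods estimator subset (default all five).
#' @return a `replicate_batch`: list with `estimates` (R x methods matrix,
#'   NA where an estimator failed), `truth` (the configured pi0), `seeds`,
#'   `config`, `R` and `n_failed` per method.
#' @examples
#' b <- run_replicates(sim_config(M = 200), R = 3, master_seed = 1)
#' dim(b$estimates)
#' @export
run_replicates <- function(config, R, master_seed, methods = methods_all) {
  stopifnot(inherits(config, "sim_config"), R >= 2)
  set.seed(as.integer(master_seed))
  seeds <- sample.int(2147483646L, R)
  est <- matrix(NA_real_, nrow = R, ncol = length(methods),
                dimnames = list(NULL, methods))
  for (j in seq_len(R)) {
    cfg <- config
    cfg$seed <- seeds[j]
    pv <- compute_pvalues(simulate_study(cfg))
    est[j, ] <- suppressWarnings(estimate_pi0_all(pv, methods))
  }
  n_failed <- colSums(is.na(est))
  if (any(n_failed > 0))
    warning(sprintf("estimator failures: %s",
                    paste(sprintf("%s=%d", methods[n_failed > 0],
                                  n_failed[n_failed > 0]), collapse = ", ")))
  structure(list(estimates = est, truth = config$pi0, seeds = seeds,
                 config = config, R = R, n_failed = n_failed),
            class = "replicate_batch")
}

#' @export
print.replicate_batch <- function(x, ...) {
  cat(sprintf("Replicate batch: R = %d at pi0 = %.2f, rho = %.2f (M = %d, n = %d+%d)\n",
              x$R, x$truth, x$config$rho, x$config$M, x$config$n1, x$config$n2))
  print(round(colMeans(x$estimates, na.rm = TRUE), 4))
  invisible(x)
}

#' Accuracy summary of a replicate batch
#'
#' Per method: mean absolute error MAE = mean(|pi0_hat - pi0|) over
#' replicates — the benchmark's primary accuracy measure — its standard
#' error, and the root mean squared error RMSE = sqrt(mean((pi0_hat -
#' pi0)^2)). RMSE weights large errors more and always satisfies
#' RMSE >= MAE.
#'
#' @param batch a [run_replicates()] result.
#' @return a data.frame with columns method, mae, mae_se, rmse, n_used.
#' @export
error_summary <- function(batch) {
  stopifnot(inherits(batch, "replicate_batch"))
  err <- abs(batch$estimates - batch$truth)
  data.frame(
    method = colnames(err),
    mae = colMeans(err, na.rm = TRUE),
    mae_se = apply(err, 2, function(e) {
      e <- e[!is.na(e)]
      stats::sd(e) / sqrt(length(e))
    }),
    rmse = sqrt(colMeans(err^2, na.rm = TRUE)),
    n_used = colSums(!is.na(err)),
    row.names = NULL
  )
}

#' Paired comparison of two methods' absolute errors
#'
#' A paired two-sided t-test on the per-replicate absolute-error differences
#' of two methods evaluated on the same simulated data sets. Degenerate
#' cases are handled explicitly: all differences exactly zero is a tie
#' (p = 1); zero variance with nonzero mean difference is reported as
#' p ~ 0 in favour of the method with lower error.
#'
#' @param errors_a,errors_b per-replicate absolute errors, same replicates.
#' @return list with `p` (two-sided p-value), `better` ("a", "b" or "tie")
#'   and `mean_diff` (mean of a - b).
#' @export
compare_methods_paired <- function(errors_a, errors_b) {
  ok <- !is.na(errors_a) & !is.na(errors_b)
  a <- errors_a[ok]; b <- errors_b[ok]
  if (length(a) < 2) stop("need at least 2 complete pairs")
  d <- a - b
  if (all(d == 0))
    return(list(p = 1, better = "tie", mean_diff = 0))
  # constant nonzero differences (up to rounding): t statistic degenerates
  if (stats::sd(d) <= 1e-10 * abs(mean(d)))
    return(list(p = .Machine$double.eps,
                better = if (mean(d) < 0) "a" else "b", mean_diff = mean(d)))
  tt <- stats::t.test(a, b, paired = TRUE)
  list(p = tt$p.value,
       better = if (mean(d) < 0) "a" else if (mean(d) > 0) "b" else "tie",
       mean_diff = mean(d))
}

#' Classify one parameter point by the reference method's standing
#'
#' Compares the reference estimator (ZG04 by default) with every other
#' method by paired t-tests on absolute errors. Three mutually exclusive
#' outcomes: `"blue"` — the reference has lower MAE than every other method
#' and all four comparisons are significant at `threshold`; `"red"` — some
#' method has lower MAE than the reference with p below `threshold`;
#' `"yellow"` — otherwise (at least one comparison is non-significant and no
#' method significantly beats the reference).
#'
#' @param batch a [run_replicates()] result containing the reference.
#' @param reference method name to compare against the rest.
#' @param threshold significance threshold for the paired tests.
#' @return list with `label`, `p_values` (named, reference vs each other
#'   method) and `better` (named direction per comparison).
#' @export
classify_grid_point <- function(batch, reference = "ZG04", threshold = 1e-5) {
  stopifnot(inherits(batch, "replicate_batch"))
  methods <- colnames(batch$estimates)
  if (!reference %in% methods) stop("reference method not in batch")
  err <- abs(batch$estimates - batch$truth)
  others <- setdiff(methods, reference)
  pvals <- numeric(length(others)); names(pvals) <- others
  better <- character(length(others)); names(better) <- others
  for (m in others) {
    cmp <- compare_methods_paired(err[, reference], err[, m])
    pvals[m] <- cmp$p
    better[m] <- switch(cmp$better, a = reference, b = m, "tie")
  }
  ref_beaten <- better != reference & better != "tie" & pvals < threshold
  ref_wins_all <- all(better == reference & pvals < threshold)
  label <- if (any(ref_beaten)) "red" else if (ref_wins_all) "blue" else "yellow"
  list(label = label, p_values = pvals, better = better,
       reference = reference, threshold = threshold)
}

#' Benchmark sweep over the (pi0, rho) parameter space
#'
#' Runs [run_replicates()] and [classify_grid_point()] at every point of a
#' pi0 x rho grid (optionally crossed with a set of per-condition sample
#' sizes, the sample-size excursions). Each point's seed is derived from the
#' master seed and the point's coordinates, so results do not depend on
#' evaluation order. The default threshold is chosen so that, over a full
#' grid of ~190 points with 4 tests each, fewer than one significance claim
#' is expected to be false.
#'
#' @param pi0_grid,rho_grid grid coordinates.
#' @param base_config a [sim_config()] supplying all other parameters.
#' @param R replicates per point.
#' @param threshold significance threshold for the paired tests.
#' @param master_seed integer master seed.
#' @param n_grid optional vector of per-condition sample sizes; default the
#'   base config's n1.
#' @param reference reference method for classification.
#' @param verbose print per-point progress.
#' @return a `region_map`: list with `summary` (tidy data.frame: pi0, rho,
#'   n, method, mae, mae_se, rmse, p_vs_reference, label) and `points`
#'   (one row per grid point with its label).
#' @export
sweep_parameter_space <- function(pi0_grid, rho_grid, base_config = sim_config(),
                                  R = 100, threshold = 1e-5, master_seed = 1,
                                  n_grid = NULL, reference = "ZG04",
                                  verbose = FALSE) {
  stopifnot(length(pi0_grid) >= 1, length(rho_grid) >= 1)
  if (is.null(n_grid)) n_grid <- base_config$n1
  grid <- expand.grid(pi0 = pi0_grid, rho = rho_grid, n = n_grid,
                      KEEP.OUT.ATTRS = FALSE)
  summary_rows <- vector("list", nrow(grid))
  point_rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cfg <- base_config
    cfg$pi0 <- grid$pi0[g]; cfg$rho <- grid$rho[g]
    cfg$n1 <- cfg$n2 <- as.integer(grid$n[g])
    seed_g <- derive_seed(master_seed, cfg$pi0, cfg$rho, cfg$n1)
    res <- tryCatch({
      batch <- run_replicates(cfg, R, seed_g)
      frac_failed <- max(batch$n_failed) / R
      cls <- classify_grid_point(batch, reference, threshold)
      label <- if (frac_failed > 0.1) "flagged" else cls$label
      es <- error_summary(batch)
      es$p_vs_reference <- ifelse(es$method == reference, NA_real_,
                                  cls$p_values[es$method])
      list(es = es, label = label)
    }, error = function(e) {
      warning(sprintf("grid point (pi0=%.2f, rho=%.2f, n=%d) failed: %s",
                      cfg$pi0, cfg$rho, cfg$n1, conditionMessage(e)),
              call. = FALSE)
      list(es = NULL, label = "missing")
    })
    if (!is.null(res$es)) {
      es <- res$es
      es$pi0 <- cfg$pi0; es$rho <- cfg$rho; es$n <- cfg$n1
      es$label <- res$label
      summary_rows[[g]] <- es[, c("pi0", "rho", "n", "method", "mae",
                                  "mae_se", "rmse", "p_vs_reference",
                                  "n_used", "label")]
    }
    point_rows[[g]] <- data.frame(pi0 = cfg$pi0, rho = cfg$rho, n = cfg$n1,
                                  label = res$label, seed = seed_g)
    if (verbose)
      message(sprintf("(pi0=%.2f, rho=%.2f, n=%d) -> %s",
                      cfg$pi0, cfg$rho, cfg$n1, res$label))
  }
  structure(list(summary = do.call(rbind, summary_rows),
                 points = do.call(rbind, point_rows),
                 reference = reference, threshold = threshold, R = R,
                 master_seed = master_seed),
            class = "region_map")
}

#' @export
print.region_map <- function(x, ...) {
  cat(sprintf("Region map: %d grid points, R = %d, reference = %s, threshold = %g\n",
              nrow(x$points), x$R, x$reference, x$threshold))
  print(table(x$points$label))
  invisible(x)
}
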