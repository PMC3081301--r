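# Replicated benchmark machinery: error summaries, paired comparisons,
# region labels and the parameter sweep.

# minimal hand-built batch for functions that only need estimates + truth
fake_batch <- function(est, truth) {
  structure(list(estimates = est, truth = truth, R = nrow(est),
                 config = sim_config(M = 10, pi0 = truth),
                 n_failed = colSums(is.na(est))),
            class = "replicate_batch")
}

test_that("MAE and RMSE match hand arithmetic and Jensen's inequality", {
  b <- fake_batch(cbind(A = c(0.7, 0.9), B = c(0.8, 0.6)), truth = 0.8)
  es <- error_summary(b)
  expect_equal(es$mae, c(0.1, 0.1))
  expect_equal(es$rmse[1], 0.1)
  expect_equal(es$rmse[2], sqrt(0.02))
  expect_true(all(es$rmse >= es$mae - 1e-12))

  exact <- fake_batch(cbind(A = rep(0.8, 3), B = rep(0.8, 3)), truth = 0.8)
  expect_equal(error_summary(exact)$mae, c(0, 0))
})

test_that("paired comparison matches a textbook paired t-test", {
  a <- c(0.05, 0.12, 0.08, 0.20, 0.03, 0.15, 0.09, 0.11, 0.07, 0.13)
  b <- c(0.09, 0.10, 0.12, 0.25, 0.08, 0.13, 0.15, 0.10, 0.11, 0.18)
  cmp <- compare_methods_paired(a, b)
  # independent closed-form computation of the paired t statistic
  d <- a - b
  tstat <- mean(d) / (sd(d) / sqrt(length(d)))
  p_oracle <- 2 * pt(-abs(tstat), length(d) - 1)
  expect_equal(cmp$p, p_oracle, tolerance = 1e-12)
  expect_equal(cmp$better, "a")

  expect_equal(compare_methods_paired(a, a),
               list(p = 1, better = "tie", mean_diff = 0))
  const <- compare_methods_paired(a, a + 0.05)
  expect_lt(const$p, 1e-10)
  expect_equal(const$better, "a")
})

test_that("region labels follow the three-outcome rule", {
  R <- 50; truth <- 0.8
  tie <- matrix(truth + 0.05, R, 5, dimnames = list(NULL, methods <-
    c("PM03", "PC04", "Ch04", "ST03", "ZG04")))
  expect_equal(classify_grid_point(fake_batch(tie, truth))$label, "yellow")

  blue <- tie; blue[, "ZG04"] <- truth          # reference errors all zero
  blue[, 1:4] <- truth + 0.2
  expect_equal(classify_grid_point(fake_batch(blue, truth))$label, "blue")

  red <- tie; red[, "PM03"] <- truth; red[, "ZG04"] <- truth + 0.2
  expect_equal(classify_grid_point(fake_batch(red, truth))$label, "red")

  # labels are a partition: always exactly one of the three
  set.seed(3)
  for (i in 1:5) {
    est <- matrix(pmin(1, pmax(0, truth + rnorm(R * 5, 0, 0.05))), R, 5,
                  dimnames = list(NULL, methods))
    lbl <- classify_grid_point(fake_batch(est, truth))$label
    expect_true(lbl %in% c("blue", "yellow", "red"))
  }
})

test_that("replicate batches are deterministic with the expected shape", {
  cfg <- sim_config(M = 200, pi0 = 0.8, rho = 0.2)
  b1 <- run_replicates(cfg, R = 3, master_seed = 7)
  b2 <- run_replicates(cfg, R = 3, master_seed = 7)
  expect_identical(b1$estimates, b2$estimates)
  expect_equal(dim(b1$estimates), c(3, 5))
  expect_equal(colnames(b1$estimates), c("PM03", "PC04", "Ch04", "ST03", "ZG04"))
  expect_true(all(b1$estimates >= 0 & b1$estimates <= 1, na.rm = TRUE))
})

test_that("every estimator sits near the upper boundary under the complete null", {
  b <- run_replicates(sim_config(M = 2000, pi0 = 1, rho = 0), R = 20,
                      master_seed = 11)
  expect_true(all(colMeans(b$estimates, na.rm = TRUE) >= 0.8))
})

test_that("a 1x1 sweep reduces to classify_grid_point and order does not matter", {
  cfg <- sim_config(M = 300)
  rm1 <- sweep_parameter_space(0.8, 0.2, cfg, R = 4, threshold = 0.01,
                               master_seed = 5)
  seed_pt <- rm1$points$seed[1]
  direct <- classify_grid_point(run_replicates(
    sim_config(M = 300, pi0 = 0.8, rho = 0.2), R = 4, seed_pt),
    threshold = 0.01)
  expect_equal(rm1$points$label, direct$label)

  fwd <- sweep_parameter_space(c(0.6, 0.9), c(0, 0.3), cfg, R = 3,
                               threshold = 0.01, master_seed = 5)
  rev <- sweep_parameter_space(c(0.9, 0.6), c(0.3, 0), cfg, R = 3,
                               threshold = 0.01, master_seed = 5)
  key <- function(x) x$points[order(x$points$pi0, x$points$rho), ]
  expect_equal(key(fwd)$label, key(rev)$label)
  expect_equal(key(fwd)$seed, key(rev)$seed)

  # tidy summary contract
  expect_true(all(c("pi0", "rho", "n", "method", "mae", "mae_se", "rmse",
                    "p_vs_reference", "label") %in% names(fwd$summary)))
  expect_true(all(fwd$summary$rmse >= fwd$summary$mae - 1e-12))
})
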