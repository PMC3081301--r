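# Simulator: block covariance, truth labelling, t-test p-values.

test_that("group covariance matrix matches its definition", {
  expect_equal(build_group_covariance(2, 0), diag(2))
  expect_equal(build_group_covariance(2, 0.5),
               matrix(c(1, 0.5, 0.5, 1), 2))
  # Cholesky factor of the k=2, rho=0.5 block: L = [[1,0],[0.5,sqrt(0.75)]]
  L <- t(chol(build_group_covariance(2, 0.5)))
  expect_equal(L, matrix(c(1, 0.5, 0, sqrt(0.75)), 2), tolerance = 1e-12)
  expect_equal(L %*% t(L), build_group_covariance(2, 0.5), tolerance = 1e-12)
  # sigma scales the whole matrix quadratically
  expect_equal(build_group_covariance(3, 0.4, sigma = 2),
               4 * build_group_covariance(3, 0.4))
})

test_that("covariance rejects correlations outside [0, 1)", {
  expect_error(build_group_covariance(2, -0.1), "rho")
  expect_error(build_group_covariance(2, 1), "rho")
  expect_error(build_group_covariance(2, 0.5, sigma = 0), "sigma")
})

test_that("config validation enforces the model's parameter ranges", {
  expect_error(sim_config(pi0 = 1.2), "pi0")
  expect_error(sim_config(rho = 1), "rho")
  expect_error(sim_config(n1 = 1), "arrays")
  expect_error(sim_config(sigma = -1), "sigma")
})

test_that("truth labels follow round(pi0 * M) and blocks never mix", {
  st <- simulate_study(sim_config(M = 10, pi0 = 0.8, seed = 1))
  expect_equal(sum(st$is_null), 8)
  expect_true(all(st$true_effect[st$is_null] == 0))
  expect_true(all(st$true_effect[!st$is_null] != 0))

  # blocks are homogeneous in null status, including remainder blocks
  st2 <- simulate_study(sim_config(M = 23, pi0 = 0.6, k = 5, seed = 2))
  expect_equal(sum(st2$is_null), 14)
  mixing <- tapply(st2$is_null, st2$block, function(z) length(unique(z)))
  expect_true(all(mixing == 1))
  expect_true(all(table(st2$block) <= 5))

  st3 <- simulate_study(sim_config(M = 12, pi0 = 1, seed = 3))
  expect_true(all(st3$is_null))
  expect_true(all(st3$true_effect == 0))
})

test_that("identical configs give bit-identical studies and p-values", {
  cfg <- sim_config(M = 60, pi0 = 0.7, rho = 0.5, seed = 99)
  a <- simulate_study(cfg); b <- simulate_study(cfg)
  expect_identical(a$values, b$values)
  expect_identical(compute_pvalues(a)$p, compute_pvalues(b)$p)
})

test_that("within-block sample correlation tracks the nominal rho", {
  rho <- 0.6
  st <- simulate_study(sim_config(M = 250, pi0 = 1, rho = rho, k = 5,
                                  n1 = 50, n2 = 50, seed = 5))
  per_block <- tapply(seq_len(250), st$block, function(idx) {
    cm <- cor(t(st$values[idx, ]))
    mean(cm[lower.tri(cm)])
  })
  se <- sd(per_block) / sqrt(length(per_block))
  expect_lt(abs(mean(per_block) - rho), 3 * se)
})

test_that("pooled t-test matches the hand-computed example", {
  study <- list(
    values = matrix(c(1, 2, 3, 2, 3, 4), nrow = 1),
    condition = factor(rep(c("control", "treatment"), each = 3),
                       levels = c("control", "treatment"))
  )
  pv <- compute_pvalues(study)
  # pooled variance 1, se = sqrt(2/3), t = 1/sqrt(2/3) = 1.2247, df = 4
  expect_equal(pv$df, 4)
  expect_equal(pv$t, sqrt(1.5), tolerance = 1e-6)
  expect_equal(pv$p, 2 * pt(-sqrt(1.5), 4), tolerance = 1e-10)
  expect_equal(round(pv$p, 4), 0.2879)
})

test_that("degenerate genes are flagged, identical samples give p = 1", {
  study <- list(
    values = matrix(c(1, 2, 3, 1, 2, 3,   # identical samples, nonzero var
                      5, 5, 5, 5, 5, 5),  # zero pooled variance, equal means
                    nrow = 2, byrow = TRUE),
    condition = factor(rep(c("control", "treatment"), each = 3),
                       levels = c("control", "treatment"))
  )
  pv <- compute_pvalues(study)
  expect_equal(pv$p, c(1, 1))
  expect_equal(pv$degenerate, c(FALSE, TRUE))

  bad <- study
  bad$values[2, 4:6] <- 7   # zero variance, unequal means
  expect_error(compute_pvalues(bad), "zero pooled variance")
})

test_that("complete-null p-values are uniform and size is respected", {
  pv <- compute_pvalues(simulate_study(sim_config(M = 5000, pi0 = 1,
                                                  rho = 0, seed = 17)))
  expect_gt(ks.test(pv$p, "punif")$p.value, 0.01)

  # marginal size is alpha even under strong block correlation; the SE is
  # replicate-based because correlation inflates the binomial variance
  for (alpha in c(0.01, 0.05)) {
    fracs <- vapply(1:8, function(r) {
      pvr <- compute_pvalues(simulate_study(sim_config(M = 5000, pi0 = 1,
                                                       rho = 0.6, seed = 20 + r)))
      mean(pvr$p < alpha)
    }, numeric(1))
    se <- sd(fracs) / sqrt(length(fracs))
    expect_lt(abs(mean(fracs) - alpha), 3 * se)
  }
})
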