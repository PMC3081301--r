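# The five pi0 estimators: frozen small examples, oracle cross-checks,
# and shared range/invariance properties.

test_that("ZG04 reproduces enumerated slopes on small inputs", {
  # uniform grid p_(i) = i/M: every chord to (1,1) has slope exactly 1
  M <- 1000
  est <- estimate_pi0_zg04(seq_len(M) / M)
  expect_equal(est$pi0_hat, 1)
  expect_true(all(abs(est$diagnostics$slopes - 1) < 1e-12))

  # brute-force enumeration: p = {0.1, 0.5, 0.6, 0.8}, defaults t1=0.5, t2=1
  # selected i: 2 (p=0.5) and 3 (p=0.6); i=1 below t1, i=4 excluded (i=M)
  # slopes: (1-2/4)/(1-0.5) = 1, (1-3/4)/(1-0.6) = 0.625; median = 0.8125
  est2 <- estimate_pi0_zg04(c(0.1, 0.5, 0.6, 0.8))
  expect_equal(sort(est2$diagnostics$slopes), c(0.625, 1))
  expect_equal(est2$pi0_hat, 0.8125)
})

test_that("ZG04 errors when no order statistic falls in range", {
  expect_error(estimate_pi0_zg04(c(0.1, 0.2, 0.3)), "widen")
  expect_error(estimate_pi0_zg04(c(0.3, 0.6), t1 = 0.7, t2 = 0.5), "t1")
})

test_that("ST03 tail fractions match direct counts", {
  # direct count: p = {0.01, 0.02, 0.6, 0.8} at lambda = 0.05 -> 2/(4*0.95)
  est <- estimate_pi0_st03(c(0.01, 0.02, 0.6, 0.8),
                           lambda_grid = c(0, 0.05, 0.5, 0.7, 0.9))
  expect_equal(est$diagnostics$pi0_lambda[1], 1)            # lambda = 0
  expect_equal(est$diagnostics$pi0_lambda[2], 2 / (4 * 0.95))

  # uniform grid M = 10: #\{p > 0.5\} = 5 -> 5/(10*0.5) = 1
  u10 <- seq(0.05, 0.95, by = 0.1)
  est2 <- estimate_pi0_st03(u10, lambda_grid = c(0, 0.25, 0.5, 0.75))
  expect_equal(est2$diagnostics$pi0_lambda[3], 1)

  expect_error(estimate_pi0_st03(runif(10), lambda_grid = c(0, 0.5, 0.9)),
               "at least 4")
})

test_that("PM03 likelihood optimum beats a grid-search oracle", {
  set.seed(31)
  for (rep in 1:3) {
    p <- generate_fixture("bum_mixture_pvalues", seed = 100 + rep,
                          M = 5000, w = 0.7, a = 0.2)
    est <- estimate_pi0_pm03(p)
    # coarse independent oracle over the (w, a) box
    ws <- seq(0.01, 0.99, length.out = 50)
    as <- seq(0.02, 1, length.out = 50)
    grid_best <- max(outer(ws, as, Vectorize(function(w, a)
      bum_loglik(pmax(p, 1e-10), w, a))))
    expect_gte(est$diagnostics$loglik, grid_best - 1e-6)
    # consistency: recovered parameters near the generating mixture
    expect_lt(abs(est$diagnostics$w - 0.7), 0.1)
    expect_lt(abs(est$diagnostics$a - 0.2), 0.1)
    expect_gte(est$pi0_hat, 0.7 - 0.05)
  }
})

test_that("PM03 reduces to pi0 = 1 on a uniform sample", {
  # fitted a -> 1 (or w -> 1): density at p = 1 is 1 for any mixing weight
  est <- estimate_pi0_pm03(generate_fixture("uniform_grid_pvalues", M = 1000))
  expect_equal(est$pi0_hat, 1, tolerance = 1e-3)
})

test_that("PC04 recovers the density floor of known mixtures", {
  # constant density: all spacings equal, smoothed minimum = 1
  est <- estimate_pi0_pc04(generate_fixture("uniform_grid_pvalues", M = 1000))
  expect_gte(est$pi0_hat, 0.98)

  # 0.5 Beta(0.1, 1) + 0.5 Uniform: density floor at p=1 is
  # 0.5 + 0.5*0.1 = 0.55
  set.seed(77)
  p <- c(rbeta(2500, 0.1, 1), runif(2500))
  est2 <- estimate_pi0_pc04(p)
  expect_lt(est2$pi0_hat, 1)
  expect_gte(est2$pi0_hat, 0.45)

  expect_error(estimate_pi0_pc04(c(0.2, 0.8)), "at least 3")
})

test_that("PC04 merges tied p-values instead of failing", {
  p <- c(0.1, 0.3, 0.3, 0.3, 0.5, 0.7, 0.9)
  est <- estimate_pi0_pc04(p)
  expect_true(est$pi0_hat >= 0 && est$pi0_hat <= 1)
})

test_that("Ch04 fits a monotone CDF whose derivative estimates the density floor", {
  est <- estimate_pi0_ch04(generate_fixture("uniform_grid_pvalues", M = 1000))
  expect_equal(est$pi0_hat, 1, tolerance = 0.02)
  # monotonicity: fitted density (CDF derivative) nonnegative everywhere
  expect_true(all(est$diagnostics$density >= -1e-8))

  # 0.8 Uniform + 0.2 Beta(0.2, 1): density minimum 0.8 + 0.2*0.2 = 0.84
  set.seed(41)
  p <- c(runif(8000), rbeta(2000, 0.2, 1))
  est2 <- estimate_pi0_ch04(p)
  expect_lt(abs(est2$pi0_hat - 0.84), 0.1)
  expect_true(all(est2$diagnostics$density >= -1e-8))

  expect_error(estimate_pi0_ch04(runif(10)), "at least")
})

test_that("all estimators stay in [0,1] and ignore input order", {
  set.seed(55)
  for (s in 1:4) {
    p <- generate_fixture("bum_mixture_pvalues", seed = s, M = 400,
                          w = 0.6, a = 0.3)
    ests <- estimate_pi0_all(p)
    expect_true(all(ests >= 0 & ests <= 1))
    shuffled <- estimate_pi0_all(sample(p))
    expect_equal(ests, shuffled, tolerance = 1e-10)
  }
})
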