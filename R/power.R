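#' Exact power of the two-sided pooled-variance two-sample t-test
#'
#' For a gene with true mean difference `d` (in units of sigma) measured on
#' `n1` control and `n2` treatment arrays, the t statistic follows a
#' noncentral t distribution with `n1 + n2 - 2` degrees of freedom and
#' noncentrality delta = d / (sigma * sqrt(1/n1 + 1/n2)). Power is the
#' probability that |t| exceeds the two-sided critical value.
#'
#' @param n1,n2 arrays per condition (>= 2).
#' @param alpha two-sided significance level in (0, 1).
#' @param d true mean difference.
#' @param sigma common within-condition standard deviation.
#' @return the rejection probability. Vectorised over `n1`/`n2`/`d`.
#' @examples
#' compute_power(8, 8, alpha = 0.01, d = 2)   # 0.826
#' @export
compute_power <- function(n1, n2 = n1, alpha = 0.01, d = 2, sigma = 1) {
  if (any(n1 < 2) || any(n2 < 2)) stop("need n1, n2 >= 2")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  if (sigma <= 0) stop("'sigma' must be positive")
  df <- n1 + n2 - 2
  ncp <- d / (sigma * sqrt(1 / n1 + 1 / n2))
  tcrit <- stats::qt(1 - alpha / 2, df)
  stats::pt(-tcrit, df, ncp) + 1 - stats::pt(tcrit, df, ncp)
}

#' Proportion of false positives (marginal FDR)
#'
#' Among genes declared significant, the expected proportion that are true
#' nulls. With a fraction pi0 of nulls rejected at rate alpha and the
#' remaining genes rejected at the test's power,
#' PFP = pi0 * alpha / (pi0 * alpha + (1 - pi0) * power).
#'
#' @param pi0 proportion of true null hypotheses.
#' @param alpha significance level.
#' @param power rejection probability for a differentially expressed gene.
#' @return the proportion of false positives, in [0, 1].
#' @examples
#' compute_pfp(0.8, 0.01, compute_power(8))   # 0.046
#' @export
compute_pfp <- function(pi0, alpha, power) {
  if (any(pi0 < 0 | pi0 > 1) || any(alpha < 0 | alpha > 1) ||
      any(power < 0 | power > 1))
    stop("all inputs must lie in [0, 1]")
  denom <- pi0 * alpha + (1 - pi0) * power
  if (any(denom == 0)) stop("no rejections expected: PFP undefined")
  pi0 * alpha / denom
}

#' Expected number of false positives
#'
#' With M simultaneous tests of which a fraction pi0 are true nulls, the
#' expected count of nulls with p < alpha is pi0 * alpha * M, regardless of
#' the correlation structure among the tests.
#'
#' @param M number of tests.
#' @param pi0 proportion of true nulls.
#' @param alpha significance level.
#' @return expected false-positive count.
#' @examples
#' expected_false_positives(10000, 1, 0.05)   # 500
#' @export
expected_false_positives <- function(M, pi0, alpha) {
  if (any(M < 1)) stop("need M >= 1")
  if (any(pi0 < 0 | pi0 > 1) || any(alpha < 0 | alpha > 1))
    stop("'pi0' and 'alpha' must lie in [0, 1]")
  pi0 * alpha * M
}

#' Power and PFP table over a range of sample sizes
#'
#' Tabulates the achievable power and resulting proportion of false
#' positives of the simulated study design as the per-condition sample size
#' grows, at fixed significance level, effect size and pi0.
#'
#' @param n vector of per-condition sample sizes (n1 = n2 = n).
#' @param alpha significance level.
#' @param d effect size.
#' @param pi0 proportion of true nulls used for the PFP column.
#' @param sigma common standard deviation.
#' @return a data.frame with columns n1, n2, alpha, d, power, pi0, pfp.
#' @examples
#' power_table()
#' @export
power_table <- function(n = 3:15, alpha = 0.01, d = 2, pi0 = 0.8, sigma = 1) {
  pow <- compute_power(n, n, alpha, d, sigma)
  data.frame(n1 = n, n2 = n, alpha = alpha, d = d, power = pow,
             pi0 = pi0, pfp = compute_pfp(pi0, alpha, pow))
}
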