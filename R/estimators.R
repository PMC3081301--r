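#' Estimators of the proportion of true null hypotheses
#'
#' Five p-value-based estimators of pi0 (the fraction of tests for which the
#' null hypothesis is true) behind a common interface. All take a vector of
#' p-values (or a `pvalue_set`) and return a `pi0_estimate` object holding
#' the method name, the estimate clipped to [0, 1], and method-specific fit
#' diagnostics.
#'
#' @name pi0-estimators
#' @seealso [estimate_pi0_all()] to run every method at once.
NULL

new_pi0_estimate <- function(method, pi0_hat, diagnostics = list()) {
  raw <- pi0_hat
  pi0_hat <- clip01(pi0_hat)
  diagnostics$clipped <- !identical(raw, pi0_hat)
  diagnostics$raw <- raw
  structure(list(method = method, pi0_hat = pi0_hat, diagnostics = diagnostics),
            class = "pi0_estimate")
}

#' @export
print.pi0_estimate <- function(x, ...) {
  cat(sprintf("%s estimate of pi0: %.4f%s\n", x$method, x$pi0_hat,
              if (isTRUE(x$diagnostics$clipped)) " (clipped to [0,1])" else ""))
  invisible(x)
}

#' Median-slope empirical-CDF estimator (ZG04)
#'
#' Sorts the p-values ascending and, for each order statistic p_(i) inside
#' the range [t1, t2], computes the slope of the chord connecting the
#' empirical-CDF point (p_(i), i/M) to the corner (1, 1):
#' s_i = (1 - i/M) / (1 - p_(i)). Under a pure uniform (all-null) sample each
#' chord has slope ~1; p-values from false nulls pile up near 0 and lower the
#' upper-tail chords towards pi0. The estimate is the median of the selected
#' slopes. The upper half of the p-value range (t1 = 0.5, t2 = 1) is the
#' default because it is the part least contaminated by non-null p-values,
#' and the median is used for robustness to extreme slopes.
#'
#' The index i = M is always excluded (its slope is identically 0 and carries
#' no information), as is any p_(i) = 1 (undefined slope).
#'
#' @param p numeric vector of p-values or a `pvalue_set`.
#' @param t1,t2 lower and upper bound of the p-value range used
#'   (0 < t1 < t2 <= 1).
#' @return a `pi0_estimate`; diagnostics hold the selected slopes.
#' @examples
#' estimate_pi0_zg04(runif(1000))
#' @export
estimate_pi0_zg04 <- function(p, t1 = 0.5, t2 = 1) {
  p <- as_pvalues(p)
  M <- length(p)
  if (M < 2) stop("need at least 2 p-values")
  if (!(t1 > 0 && t1 < t2 && t2 <= 1)) stop("need 0 < t1 < t2 <= 1")
  ps <- sort(p)
  i <- seq_len(M)
  sel <- ps >= t1 & ps <= t2 & ps < 1 & i < M
  if (!any(sel))
    stop("no p-value order statistics fall in [t1, t2]; widen the range")
  slopes <- (1 - i[sel] / M) / (1 - ps[sel])
  new_pi0_estimate("ZG04", stats::median(slopes),
                   list(slopes = slopes, n_slopes = sum(sel), t1 = t1, t2 = t2))
}

#' Lambda-tail spline estimator (ST03)
#'
#' For each tuning value lambda, the fraction of p-values above lambda,
#' rescaled by the width of the tail, pi0(lambda) = #\{p > lambda\} /
#' (M (1 - lambda)), is an estimate of pi0 that is biased upward for small
#' lambda (contaminated by alternatives) and noisy for large lambda. A
#' natural cubic smoothing spline with 3 degrees of freedom is fit to the
#' sequence of (lambda, pi0(lambda)) points and evaluated at the largest
#' lambda in the grid, extrapolating the trade-off towards lambda -> 1.
#'
#' @param p numeric vector of p-values or a `pvalue_set`.
#' @param lambda_grid strictly increasing tuning values in [0, 1);
#'   default 0, 0.01, ..., 0.95.
#' @param spline_df effective degrees of freedom of the smoothing spline.
#' @return a `pi0_estimate`; diagnostics hold the pointwise pi0(lambda).
#' @examples
#' estimate_pi0_st03(runif(1000))
#' @export
estimate_pi0_st03 <- function(p, lambda_grid = seq(0, 0.95, by = 0.01),
                              spline_df = 3) {
  p <- as_pvalues(p)
  M <- length(p)
  if (M < 2) stop("need at least 2 p-values")
  if (length(lambda_grid) < 4)
    stop("need at least 4 lambda values to fit the spline")
  if (is.unsorted(lambda_grid, strictly = TRUE) ||
      any(lambda_grid < 0) || any(lambda_grid >= 1))
    stop("'lambda_grid' must be strictly increasing within [0, 1)")
  pi0_lambda <- vapply(lambda_grid,
                       function(l) sum(p > l) / (M * (1 - l)), numeric(1))
  fit <- stats::smooth.spline(lambda_grid, pi0_lambda, df = spline_df)
  pi0 <- stats::predict(fit, x = max(lambda_grid))$y
  new_pi0_estimate("ST03", pi0,
                   list(lambda = lambda_grid, pi0_lambda = pi0_lambda,
                        spline_df = spline_df, eval_at = max(lambda_grid)))
}

# BUM negative log-likelihood on transformed parameters
# theta = (qlogis(w), qlogis(a)); density f(p) = w + (1-w) a p^(a-1).
bum_nll <- function(theta, logp) {
  w <- stats::plogis(theta[1])
  a <- stats::plogis(theta[2])
  -sum(log(w + (1 - w) * a * exp((a - 1) * logp)))
}

#' BUM log-likelihood
#'
#' Log-likelihood of the beta-uniform mixture density
#' f(p) = w + (1 - w) a p^(a - 1) for a sample of p-values. Exposed so that
#' fits can be compared against alternative optimisers.
#'
#' @param p p-values in (0, 1].
#' @param w mixing weight of the uniform component, in [0, 1].
#' @param a beta shape parameter, in (0, 1].
#' @return the summed log-likelihood.
#' @export
bum_loglik <- function(p, w, a) {
  p <- as_pvalues(p)
  sum(log(w + (1 - w) * a * p^(a - 1)))
}

#' Beta-uniform mixture upper-bound estimator (PM03)
#'
#' Fits the beta-uniform mixture (BUM) density
#' f(p) = w + (1 - w) a p^(a-1), with 0 < a <= 1 and 0 <= w <= 1, to the
#' observed p-values by maximum likelihood, and estimates pi0 by the fitted
#' density at p = 1, namely w + (1 - w) a. Because the beta component still
#' places some mass near p = 1, this value is an upper bound for pi0.
#'
#' Numerics: p-values are clipped to [1e-10, 1] (the density diverges at 0
#' when a < 1); the likelihood is maximised over logit-transformed
#' parameters from a 3 x 3 grid of starts, and the pure-uniform boundary
#' (w = 1, log-likelihood 0) is always included as a candidate, so a sample
#' indistinguishable from uniform yields exactly 1.
#'
#' @param p numeric vector of p-values or a `pvalue_set`.
#' @param starts matrix of (w, a) starting values for the multi-start
#'   optimisation; rows are starts.
#' @return a `pi0_estimate`; diagnostics hold the fitted `w`, `a` and the
#'   maximised log-likelihood.
#' @examples
#' pp <- c(rbeta(300, 0.2, 1), runif(700))
#' estimate_pi0_pm03(pp)
#' @export
estimate_pi0_pm03 <- function(p, starts = as.matrix(expand.grid(
                                w = c(0.1, 0.5, 0.9), a = c(0.1, 0.5, 0.9)))) {
  p <- as_pvalues(p)
  if (length(p) < 2) stop("need at least 2 p-values")
  p <- pmin(pmax(p, 1e-10), 1)
  logp <- log(p)

  best <- NULL
  n_ok <- 0L
  for (r in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(stats::qlogis(starts[r, ]), bum_nll, logp = logp,
                   method = "BFGS", control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    n_ok <- n_ok + 1L
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("BUM likelihood optimisation failed from every start")
  w <- stats::plogis(best$par[1])
  a <- stats::plogis(best$par[2])
  loglik <- -best$value
  # nested pure-uniform boundary: f == 1 everywhere, log-likelihood 0
  if (loglik < 0) {
    w <- 1; a <- 1; loglik <- 0
  }
  new_pi0_estimate("PM03", w + (1 - w) * a,
                   list(w = w, a = a, loglik = loglik, n_starts_ok = n_ok))
}

#' LOESS-smoothed spacing-density estimator (PC04)
#'
#' Estimates the p-value density from the spacings between consecutive order
#' statistics: with the sorted sample augmented by the boundary points 0 and
#' 1, a spacing of width d containing one point corresponds to a local
#' density of about 1 / (M d). These raw ordinates, placed at the interval
#' midpoints, are smoothed against the midpoints by local linear regression
#' (LOESS) weighted by the interval widths — a raw ordinate is informative
#' about the density over an interval proportional to its width, and the
#' weighting keeps the near-zero spike of tiny, wildly noisy spacings from
#' dominating the fit. pi0 is estimated by the minimum of the smoothed
#' density — the uniform "floor" of the mixture, attained where alternative
#' p-values are scarce. Tied p-values produce zero-width spacings; tied runs
#' are merged into the next positive spacing, which then carries the
#' combined count.
#'
#' @param p numeric vector of p-values or a `pvalue_set`.
#' @param span LOESS smoothing span.
#' @return a `pi0_estimate`; diagnostics hold midpoints, raw and smoothed
#'   ordinates.
#' @examples
#' estimate_pi0_pc04(runif(500))
#' @export
estimate_pi0_pc04 <- function(p, span = 0.3) {
  p <- as_pvalues(p)
  M <- length(p)
  if (M < 3) stop("need at least 3 p-values to form spacings")
  aug <- c(0, sort(p), 1)
  d <- diff(aug)
  pos <- d > 0
  if (!any(pos)) stop("all p-values identical; density undefined")
  # merge zero-width (tied) spacings into the following positive spacing
  grp <- rev(cumsum(rev(pos)))            # positive spacing each d belongs to
  counts <- tabulate(grp)[grp[pos]]       # spacings merged into each interval
  width <- d[pos]
  mid <- (aug[-length(aug)][pos] + aug[-1][pos]) / 2
  ord <- counts / (M * width)
  # loess warns verbosely about tiny neighbourhood radii for the midpoints
  # clustered near 0; harmless here, the fit is dominated by the weights
  fit <- suppressWarnings(
    stats::loess(ord ~ mid, span = span, degree = 1, weights = width,
                 control = stats::loess.control(surface = "direct")))
  grid <- seq(0, 1, length.out = 201)
  smoothed <- suppressWarnings(
    stats::predict(fit, newdata = data.frame(mid = grid)))
  new_pi0_estimate("PC04", min(smoothed, na.rm = TRUE),
                   list(mid = mid, raw = ord, grid = grid,
                        smoothed = smoothed, span = span))
}

# Interior knot sequence for the monotone CDF spline: geometric spacing
# near 0 where alternative p-values concentrate, uniform over the tail.
ch04_knots <- function(n_knots) {
  n_geo <- ceiling(n_knots / 2)
  geo <- exp(seq(log(1e-3), log(0.2), length.out = n_geo))
  uni <- seq(0.3, 0.9, length.out = n_knots - n_geo)
  sort(c(geo, uni))
}

# Exact solver for: minimize 1/2 g'Qg - b'g  s.t.  g >= 0, a'g = 1 (a > 0).
# Lawson-Hanson NNLS adapted for the single equality constraint: the outer
# loop adds the bound variable with the most negative reduced gradient, the
# inner loop steps from the current feasible point towards the
# equality-constrained solve on the free set, stopping at the first bound.
# Exact and deterministic for the small systems used here (a dozen
# variables).
solve_eqnnls <- function(Q, b, a, tol = 1e-10) {
  n <- length(b)
  Q <- Q + diag(1e-12 * max(diag(Q)), n)
  scale <- max(1, max(abs(b)))

  kkt_solve <- function(idx) {
    K <- rbind(cbind(Q[idx, idx, drop = FALSE], a[idx]), c(a[idx], 0))
    sol <- solve(K, c(b[idx], 1))
    list(z = sol[seq_along(idx)], mu = sol[length(sol)])
  }

  free <- rep(FALSE, n)
  free[n] <- TRUE
  g <- numeric(n)
  g[n] <- 1 / a[n]
  mu <- kkt_solve(n)$mu

  for (outer in seq_len(30 * n)) {
    red <- drop(Q %*% g - b) + mu * a
    cand <- which(!free & red < -tol * scale)
    if (length(cand) == 0) return(g)
    free[cand[which.min(red[cand])]] <- TRUE

    repeat {
      idx <- which(free)
      sol <- kkt_solve(idx)
      z <- numeric(n); z[idx] <- sol$z
      if (all(sol$z >= -tol)) {
        g <- pmax(z, 0); mu <- sol$mu
        break
      }
      # step towards z until the first free variable hits its bound
      blocking <- idx[sol$z < -tol]
      alpha <- min(g[blocking] / (g[blocking] - z[blocking]))
      g <- g + alpha * (z - g)
      hit <- free & (g <= tol)
      g[hit] <- 0
      free[hit] <- FALSE
      if (!any(free)) {          # numerical corner: restart from a vertex
        free[n] <- TRUE; g <- numeric(n); g[n] <- 1 / a[n]
        mu <- kkt_solve(n)$mu
        break
      }
    }
  }
  stop("constrained spline fit infeasible: active-set iteration did not settle")
}

#' Shape-constrained B-spline CDF estimator (Ch04)
#'
#' Fits a cubic B-spline approximation to the empirical CDF of the p-values
#' on [0, 1], constrained to pass through (0, 0) and (1, 1) and to have the
#' shape of a p-value mixture CDF: nondecreasing (it is a CDF) and concave
#' (the mixture density — uniform nulls plus alternatives piling up near
#' 0 — is nonincreasing). The knot sequence is concentrated near 0
#' (geometric placement), where the CDF bends sharply, plus uniformly spaced
#' tail knots. The fitted density is the first derivative of the CDF and
#' pi0 is estimated by its minimum over [0, 1]; under the concavity
#' constraint this is attained at p = 1, which makes the minimum a stable
#' functional rather than the minimum of a wiggly unconstrained fit.
#'
#' The shape constraints act on the spline coefficients: the derivative's
#' B-spline coefficients must be nonnegative and nonincreasing, which is
#' expressed as a nonnegative cone through cumulative sums. The resulting
#' least-squares problem is a convex quadratic over that cone with one
#' normalisation equality, solved exactly by a small active-set iteration.
#'
#' @param p numeric vector of p-values or a `pvalue_set`.
#' @param n_knots number of interior knots (default 10).
#' @return a `pi0_estimate`; diagnostics hold the knots, coefficients, and
#'   the fitted density over a fine grid.
#' @examples
#' estimate_pi0_ch04(runif(500))
#' @export
estimate_pi0_ch04 <- function(p, n_knots = 10) {
  p <- as_pvalues(p)
  M <- length(p)
  if (M < n_knots + 4) stop("need at least n_knots + 4 p-values")
  interior <- ch04_knots(n_knots)
  knots <- c(rep(0, 4), interior, rep(1, 4))
  nb <- n_knots + 4

  xs <- sort(p)
  ys <- (seq_len(M) - 0.5) / M
  B <- splines::splineDesign(knots, xs, ord = 4)

  # CDF coefficients from derivative "steps" g >= 0:
  # derivative coefficients d_j = sum_{l >= j} g_l are then nonnegative and
  # nonincreasing; CDF increments are wk_j * d_j, so c = A g is linear.
  wk <- (knots[(1:(nb - 1)) + 4] - knots[(1:(nb - 1)) + 1]) / 3
  cwk <- cumsum(wk)                       # cwk[nb-1] telescopes to 1
  A <- matrix(0, nb, nb - 1)
  for (i in 2:nb) A[i, ] <- cwk[pmin(i - 1, seq_len(nb - 1))]
  BA <- B %*% A
  g <- solve_eqnnls(crossprod(BA), drop(crossprod(BA, ys)), cwk)
  cc <- drop(A %*% g)
  cc <- cc / cc[nb]                       # CDF(1) = 1 exactly

  grid <- seq(0, 1, length.out = 401)
  Bd <- splines::splineDesign(knots, grid, ord = 4, derivs = 1)
  dens <- drop(Bd %*% cc)
  new_pi0_estimate("Ch04", min(dens),
                   list(knots = interior, coef = cc, grid = grid,
                        density = dens, steps = g))
}

#' Run all five pi0 estimators on one p-value set
#'
#' @param p numeric vector of p-values or a `pvalue_set`.
#' @param methods subset of `c("PM03", "PC04", "Ch04", "ST03", "ZG04")`.
#' @param on_error `"na"` records a failed estimator as NA with a warning;
#'   `"stop"` propagates the error.
#' @return named numeric vector of pi0 estimates (one per method).
#' @examples
#' estimate_pi0_all(runif(500))
#' @export
estimate_pi0_all <- function(p, methods = methods_all, on_error = c("na", "stop")) {
  on_error <- match.arg(on_error)
  methods <- match.arg(methods, methods_all, several.ok = TRUE)
  fns <- list(PM03 = estimate_pi0_pm03, PC04 = estimate_pi0_pc04,
              Ch04 = estimate_pi0_ch04, ST03 = estimate_pi0_st03,
              ZG04 = estimate_pi0_zg04)
  out <- vapply(methods, function(m) {
    if (on_error == "stop") return(fns[[m]](p)$pi0_hat)
    tryCatch(fns[[m]](p)$pi0_hat, error = function(e) {
      warning(sprintf("%s failed: %s", m, conditionMessage(e)), call. = FALSE)
      NA_real_
    })
  }, numeric(1))
  out
}
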