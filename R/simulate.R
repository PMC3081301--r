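#' Configuration of one in silico gene-expression experiment
#'
#' Bundles every knob of a simulated two-condition (control/treatment)
#' microarray study: `M` genes are measured on `n1 + n2` arrays; a fraction
#' `pi0` of genes are true nulls (identical means in both conditions) and the
#' remaining genes receive a per-gene treatment effect drawn from
#' Normal(`effect_mean`, `effect_sd`^2). Genes are grouped into blocks of `k`
#' with common pairwise correlation `rho`; blocks are mutually independent and
#' a block never mixes null and differentially expressed genes.
#'
#' @param M total number of genes (simultaneous tests).
#' @param pi0 proportion of true null genes, in [0, 1]. The number of nulls is
#'   `round(pi0 * M)`.
#' @param rho common within-block correlation, in [0, 1).
#' @param k block size (genes per correlated group), >= 1.
#' @param n1,n2 number of arrays in the control and treatment condition
#'   (each >= 2).
#' @param sigma within-condition standard deviation of expression (> 0).
#' @param effect_mean mean of the effect-size distribution for differentially
#'   expressed genes (the typical effect, default 2).
#' @param effect_sd standard deviation of the effect-size distribution.
#' @param seed integer RNG seed.
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(M = 100, pi0 = 0.8, rho = 0.3, seed = 1)
#' @export
sim_config <- function(M = 10000, pi0 = 0.8, rho = 0, k = 5,
                       n1 = 8, n2 = 8, sigma = 1,
                       effect_mean = 2, effect_sd = 0.5, seed = 1L) {
  stopifnot(is.numeric(M), length(M) == 1, M >= 1, M == round(M))
  if (!is.numeric(pi0) || pi0 < 0 || pi0 > 1)
    stop("'pi0' must lie in [0, 1]")
  if (!is.numeric(rho) || rho < 0 || rho >= 1)
    stop("'rho' must lie in [0, 1)")
  stopifnot(k >= 1, k == round(k))
  if (n1 < 2 || n2 < 2) stop("each condition needs at least 2 arrays")
  if (sigma <= 0) stop("'sigma' must be positive")
  if (effect_sd < 0) stop("'effect_sd' must be non-negative")
  structure(
    list(M = as.integer(M), pi0 = pi0, rho = rho, k = as.integer(k),
         n1 = as.integer(n1), n2 = as.integer(n2), sigma = sigma,
         effect_mean = effect_mean, effect_sd = effect_sd,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  M = %d genes, pi0 = %.3f (%d nulls), rho = %.2f, k = %d\n",
              x$M, x$pi0, round(x$pi0 * x$M), x$rho, x$k))
  cat(sprintf("  n1 = %d, n2 = %d arrays, sigma = %.2f, effect ~ N(%.2f, %.2f^2), seed = %d\n",
              x$n1, x$n2, x$sigma, x$effect_mean, x$effect_sd, x$seed))
  invisible(x)
}

config_digest <- function(config) {
  paste0("M", config$M, "_pi0", config$pi0, "_rho", config$rho,
         "_k", config$k, "_n", config$n1, "x", config$n2,
         "_s", config$sigma, "_d", config$effect_mean,
         "sd", config$effect_sd, "_seed", config$seed)
}

#' Equicorrelated block covariance matrix
#'
#' Covariance of the expression noise for one group of `k` correlated genes:
#' `sigma^2` on the diagonal and `rho * sigma^2` everywhere off it. For
#' `rho` in [0, 1) the matrix is symmetric positive definite, so its Cholesky
#' factor always exists and multivariate normal sampling is well defined.
#'
#' @param k block size (>= 1).
#' @param rho common pairwise correlation, in [0, 1). Negative values are
#'   rejected even when the matrix would remain positive definite, matching
#'   the correlation range the benchmark tunes over.
#' @param sigma standard deviation (> 0).
#' @return a `k` x `k` covariance matrix.
#' @examples
#' build_group_covariance(3, 0.5)
#' @export
build_group_covariance <- function(k, rho, sigma = 1) {
  stopifnot(k >= 1, k == round(k))
  if (!is.numeric(rho) || length(rho) != 1 || rho < 0 || rho >= 1)
    stop("'rho' must lie in [0, 1)")
  if (sigma <= 0) stop("'sigma' must be positive")
  sig2 <- sigma^2
  m <- matrix(rho * sig2, k, k)
  diag(m) <- sig2
  m
}

# Noise for `nb` independent blocks of size `s`, each column an array:
# one Cholesky factor, one big matrix product, rows ordered gene-within-block.
block_noise <- function(s, nb, ncol_total, rho, sigma) {
  z <- matrix(stats::rnorm(s * ncol_total * nb), nrow = s)
  if (s > 1 && rho > 0) {
    L <- t(chol(build_group_covariance(s, rho, sigma)))
    z <- L %*% z
  } else {
    z <- z * sigma
  }
  if (nb == 1) return(z)
  matrix(aperm(array(z, dim = c(s, ncol_total, nb)), c(1, 3, 2)),
         nrow = s * nb, ncol = ncol_total)
}

# Segment M genes into blocks of k; a remainder smaller than k is allowed.
segment_blocks <- function(m, k) {
  if (m == 0) return(integer(0))
  c(rep(k, m %/% k), if (m %% k > 0) m %% k)
}

#' Simulate a two-condition expression study with block-correlated genes
#'
#' Generates an `M` x `(n1 + n2)` matrix of expression values under the model
#' described in [sim_config()]: null genes have mean 0 in both conditions;
#' differentially expressed genes have control mean 0 and a treatment mean
#' drawn once per gene from Normal(`effect_mean`, `effect_sd`^2). Within each
#' block of `k` genes the noise across arrays is multivariate normal with the
#' equicorrelated covariance of [build_group_covariance()], sampled through
#' its Cholesky factor; blocks are mutually independent, and null and
#' differentially expressed genes are never placed in the same block. Arrays
#' are independent of one another: correlation acts across genes, not across
#' samples.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `expression_study`: a list with `values`
#'   (matrix), `condition` (factor per column), `is_null`, `true_effect`,
#'   `block` (block id per gene) and the originating `config`.
#' @examples
#' st <- simulate_study(sim_config(M = 20, pi0 = 0.5, seed = 7))
#' table(st$is_null)
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  M <- config$M
  M0 <- round(config$pi0 * M)
  M1 <- M - M0
  ntot <- config$n1 + config$n2
  condition <- factor(rep(c("control", "treatment"), c(config$n1, config$n2)),
                      levels = c("control", "treatment"))

  is_null <- c(rep(TRUE, M0), rep(FALSE, M1))
  true_effect <- numeric(M)
  if (M1 > 0)
    true_effect[!is_null] <- stats::rnorm(M1, config$effect_mean, config$effect_sd)

  # null blocks first, then blocks of differentially expressed genes
  sizes <- c(segment_blocks(M0, config$k), segment_blocks(M1, config$k))
  block <- rep(seq_along(sizes), sizes)

  noise <- matrix(0, nrow = M, ncol = ntot)
  runs <- rle(sizes)
  row0 <- 0L
  for (seg in seq_along(runs$lengths)) {
    s <- runs$values[seg]; nb <- runs$lengths[seg]
    rows <- row0 + seq_len(s * nb)
    noise[rows, ] <- block_noise(s, nb, ntot, config$rho, config$sigma)
    row0 <- row0 + s * nb
  }

  mu <- outer(true_effect, as.integer(condition == "treatment"))
  values <- mu + noise
  rownames(values) <- paste0("gene", seq_len(M))
  colnames(values) <- paste0(substr(as.character(condition), 1, 4), "_",
                             unlist(lapply(c(config$n1, config$n2), seq_len)))

  structure(
    list(values = values, condition = condition, is_null = is_null,
         true_effect = true_effect, block = block, config = config),
    class = "expression_study"
  )
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("Expression study: %d genes x %d arrays (%d null, %d DE), rho = %.2f, k = %d\n",
              nrow(x$values), ncol(x$values), sum(x$is_null), sum(!x$is_null),
              x$config$rho, x$config$k))
  invisible(x)
}

#' Per-gene two-sample t-test p-values
#'
#' Applies the pooled-variance (equal-variance) two-sample t-test to every
#' gene of a simulated study and returns the two-sided p-values. The test has
#' `n1 + n2 - 2` degrees of freedom. A gene with zero pooled variance is a
#' degenerate case with probability zero under the model: if its condition
#' means are also equal it is assigned p = 1 and flagged, otherwise an error
#' is raised.
#'
#' @param study an [simulate_study()] result, or any list with a `values`
#'   matrix and a `condition` factor with levels control/treatment.
#' @return an object of class `pvalue_set`: list with `p` (length-M vector in
#'   [0, 1]), `t` (test statistics), `df`, `degenerate` (logical flags) and a
#'   `config_digest` provenance string.
#' @examples
#' pv <- compute_pvalues(simulate_study(sim_config(M = 50, seed = 3)))
#' range(pv$p)
#' @export
compute_pvalues <- function(study) {
  x <- study$values[, study$condition == "control", drop = FALSE]
  y <- study$values[, study$condition == "treatment", drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  if (n1 < 2 || n2 < 2) stop("each condition needs at least 2 arrays")
  df <- n1 + n2 - 2
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  ss <- rowSums((x - m1)^2) + rowSums((y - m2)^2)
  sp2 <- ss / df
  degenerate <- sp2 == 0
  if (any(degenerate & (m1 != m2)))
    stop("zero pooled variance with unequal means: t statistic undefined")
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- ifelse(degenerate, 0, (m2 - m1) / se)
  p <- 2 * stats::pt(-abs(tstat), df)
  p[degenerate] <- 1
  structure(
    list(p = unname(p), t = unname(tstat), df = df, degenerate = degenerate,
         config_digest = if (!is.null(study$config)) config_digest(study$config) else NA_character_),
    class = "pvalue_set"
  )
}

#' @export
print.pvalue_set <- function(x, ...) {
  cat(sprintf("p-value set: %d tests, df = %d%s\n", length(x$p), x$df,
              if (any(x$degenerate)) sprintf(" (%d degenerate)", sum(x$degenerate)) else ""))
  invisible(x)
}

# Accept a pvalue_set or a bare numeric vector of p-values.
as_pvalues <- function(p) {
  if (inherits(p, "pvalue_set")) p <- p$p
  p <- as.numeric(p)
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must be in [0, 1] with no missing values")
  p
}

#' Write a simulated study and its truth labels to CSV
#'
#' The expression matrix goes to `<path>` (genes x arrays, header row of
#' condition labels) and the per-gene truth to `<path base>_truth.csv`
#' (gene id, is_null, true_effect).
#'
#' @param study an `expression_study`.
#' @param path output CSV path for the expression matrix.
#' @return invisibly, the two file paths written.
#' @export
write_study_csv <- function(study, path) {
  df <- as.data.frame(study$values)
  names(df) <- as.character(study$condition)
  utils::write.csv(cbind(gene = rownames(study$values), df), path,
                   row.names = FALSE)
  truth_path <- sub("\\.csv$", "_truth.csv", path)
  utils::write.csv(
    data.frame(gene = rownames(study$values), is_null = study$is_null,
               true_effect = study$true_effect),
    truth_path, row.names = FALSE)
  invisible(c(path, truth_path))
}
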