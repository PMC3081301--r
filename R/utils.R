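#' Clip a numeric vector to the unit interval
#'
#' Estimates of a proportion are forced into [0, 1]. Used by every estimator
#' so that downstream error summaries never see out-of-range values.
#'
#' @param x numeric vector.
#' @return `x` with values below 0 set to 0 and values above 1 set to 1.
#' @keywords internal
clip01 <- function(x) pmin(1, pmax(0, x))

#' Derive a deterministic per-point RNG seed
#'
#' Benchmark sweeps must be invariant to the order in which grid points are
#' evaluated, so each (pi0, rho, n) point gets its own seed derived from the
#' master seed and the coordinates, not from a shared RNG stream.
#'
#' @param master_seed integer master seed.
#' @param pi0,rho grid coordinates.
#' @param n sample size per condition.
#' @return a positive integer seed below 2^31.
#' @keywords internal
derive_seed <- function(master_seed, pi0, rho, n = 0L) {
  s <- (as.double(master_seed) + 100003 * round(pi0 * 1000) +
          10007 * round(rho * 1000) + 101 * as.double(n)) %% 2147483629
  as.integer(s) + 1L
}

methods_all <- c("PM03", "PC04", "Ch04", "ST03", "ZG04")

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
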