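#' Load and validate a simulation/benchmark configuration file
#'
#' Reads a YAML (or JSON) configuration, fills in the documented defaults
#' for any missing key, validates ranges, and rejects unknown keys. Keys at
#' the simulation level are those of [sim_config()]; the benchmark level
#' accepts `R`, `threshold`, `master_seed`, `pi0_grid`, `rho_grid` and
#' `n_grid`.
#'
#' @param path path to a YAML/JSON file. An empty file yields all defaults.
#' @return a list with elements `sim` (a validated [sim_config()]) and
#'   `benchmark` (a list of benchmark settings).
#' @examples
#' tf <- tempfile(fileext = ".yaml")
#' writeLines("pi0: 0.9\nrho: 0.3", tf)
#' load_config(tf)$sim$pi0
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("configuration must be a mapping of keys to values")

  sim_keys <- setdiff(names(formals(sim_config)), "")
  bench_keys <- c("R", "threshold", "master_seed", "pi0_grid", "rho_grid",
                  "n_grid")
  unknown <- setdiff(names(raw), c(sim_keys, bench_keys))
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))

  sim_args <- raw[intersect(names(raw), sim_keys)]
  sim <- do.call(sim_config, sim_args)
  bench_defaults <- list(R = 100, threshold = 1e-5, master_seed = 1,
                         pi0_grid = seq(0.05, 0.95, by = 0.05),
                         rho_grid = seq(0, 0.9, by = 0.1),
                         n_grid = NULL)
  bench <- utils::modifyList(bench_defaults,
                             raw[intersect(names(raw), bench_keys)])
  if (bench$R < 2) stop("configuration key 'R' must be >= 2")
  if (bench$threshold <= 0 || bench$threshold >= 1)
    stop("configuration key 'threshold' must be in (0, 1)")
  list(sim = sim, benchmark = bench)
}

#' Deterministic small data sets for testing and examples
#'
#' @param kind one of `"uniform_grid_pvalues"` (the exact grid
#'   p_(i) = (i - 0.5) / M), `"bum_mixture_pvalues"` (a seeded draw from the
#'   beta-uniform mixture w * U(0,1) + (1 - w) * Beta(a, 1)) or
#'   `"tiny_study"` (a 10-gene simulated study).
#' @param seed RNG seed for the random kinds.
#' @param M number of p-values / genes.
#' @param w,a mixture weight and beta shape for the BUM draw.
#' @return a numeric vector of p-values, or an `expression_study` for
#'   `"tiny_study"`.
#' @examples
#' generate_fixture("uniform_grid_pvalues", M = 4)
#' @export
generate_fixture <- function(kind = c("uniform_grid_pvalues",
                                      "bum_mixture_pvalues", "tiny_study"),
                             seed = 1L, M = 100, w = 0.7, a = 0.2) {
  kind <- match.arg(kind)
  switch(kind,
    uniform_grid_pvalues = (seq_len(M) - 0.5) / M,
    bum_mixture_pvalues = {
      set.seed(seed)
      is_unif <- stats::runif(M) < w
      ifelse(is_unif, stats::runif(M), stats::rbeta(M, a, 1))
    },
    tiny_study = simulate_study(sim_config(M = 10, pi0 = 0.5, rho = 0.5,
                                           k = 5, n1 = 4, n2 = 4,
                                           seed = seed))
  )
}

#' Write a p-value set to a single-column CSV
#'
#' @param p a `pvalue_set` or numeric vector.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_pvalues_csv <- function(p, path) {
  utils::write.csv(data.frame(p = as_pvalues(p)), path, row.names = FALSE)
  invisible(path)
}

#' Read p-values from a single-column CSV
#'
#' @param path CSV path with a header and one p-value per row.
#' @return numeric vector of p-values.
#' @export
read_pvalues_csv <- function(path) {
  df <- utils::read.csv(path)
  as_pvalues(df[[1]])
}

#' Run manifest for an analysis step
#'
#' Records what was run and with which inputs so a step can be re-executed
#' bit-for-bit: command name, resolved configuration, master seed, package
#' version, timestamps and MD5 digests of the output files.
#'
#' @param command short name of the analysis step.
#' @param config list of resolved settings.
#' @param master_seed integer seed used.
#' @param outputs character vector of output file paths.
#' @param started POSIXct start time.
#' @return the manifest as a list; written next to the first output as
#'   `<name>_manifest.json` when `outputs` is non-empty.
#' @export
run_manifest <- function(command, config, master_seed, outputs = character(0),
                         started = Sys.time()) {
  manifest <- list(
    command = command,
    config = config,
    master_seed = master_seed,
    package_version = as.character(utils::packageVersion("pi0bench")),
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(stats::setNames(
      as.character(tools::md5sum(outputs[file.exists(outputs)])),
      outputs[file.exists(outputs)]))
  )
  if (length(outputs) > 0) {
    path <- sub("\\.[a-zA-Z]+$", "_manifest.json", outputs[1])
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(manifest)
}
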