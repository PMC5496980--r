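# Config file handling. One dialect: YAML. A full run is described by
# three blocks -- vital_rates, disturbance, simulation -- and any block or
# key left out falls back to the packaged sperm whale reference case.

.sim_defaults <- function() {
  list(years = 100L, reps = 5000L, seed = 1L, total = 1665,
       sex_ratio_female = 0.5, threshold = NULL, rule = "final")
}

#' Path to the packaged sperm whale configuration
#'
#' The versioned reference fixture: the eleven vital-rate estimates for the
#' Gulf-of-Mexico female sperm whale population, the baseline disturbance
#' scenario, and the standard simulation controls.
#'
#' @return A file path inside the installed package.
#' @export
sperm_whale_config <- function()
  system.file("extdata", "sperm_whale.yaml", package = "poprecover",
              mustWork = TRUE)

#' Read and validate a model configuration
#'
#' Parses a YAML configuration with blocks `vital_rates`
#' (`sigma`, `gamma`, `b`), `disturbance` (`epsilon0`, `t_critical`,
#' `t_end`, `c1`, `c2`, `shape`, `target`, `tm_policy`) and `simulation`
#' (`years`, `reps`, `seed`, `total`, `sex_ratio_female`, `threshold`,
#' `rule`). Missing blocks or keys take the packaged sperm whale defaults.
#' Every invariant of every block is checked; all validation failures are
#' reported together, each naming the offending key.
#'
#' @param path path to a YAML file.
#' @return A list with components `rates` ([vital_rates()]), `scenario`
#'   ([disturbance()]), `sim` (simulation controls), and `model`
#'   (the assembled [recovery_model()]).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  errs <- character(0)
  grab <- function(expr) {
    tryCatch(expr, error = function(e) {
      errs <<- c(errs, conditionMessage(e)); NULL
    })
  }
  vr <- raw$vital_rates
  rates <- if (is.null(vr)) sperm_whale_rates() else grab(
    vital_rates(sigma = as.numeric(vr$sigma), gamma = as.numeric(vr$gamma),
                b = as.numeric(vr$b),
                advance_to = vr$advance_to))
  ds <- if (is.null(raw$disturbance)) list() else raw$disturbance
  scenario <- grab(disturbance(
    epsilon0 = ds$epsilon0 %||% 0,
    t_critical = ds$t_critical %||% 0,
    t_end = ds$t_end %||% ((ds$t_critical %||% 0) + 10),
    c1 = ds$c1 %||% 2, c2 = ds$c2 %||% 2,
    shape = ds$shape %||% "crf",
    target = ds$target %||% "survival",
    tm_policy = ds$tm_policy %||% "midpoint"))
  sim <- utils::modifyList(.sim_defaults(),
                           if (is.null(raw$simulation)) list() else raw$simulation)
  if (sim$years < 1) errs <- c(errs, "simulation$years must be >= 1")
  if (sim$reps < 1) errs <- c(errs, "simulation$reps must be >= 1")
  if (!is.null(sim$threshold) && sim$threshold <= 0)
    errs <- c(errs, "simulation$threshold must be positive")
  if (!sim$rule %in% c("final", "first_passage"))
    errs <- c(errs, "simulation$rule must be \"final\" or \"first_passage\"")
  if (length(errs))
    stop("invalid configuration (", path, "):\n  ",
         paste(errs, collapse = "\n  "))
  model <- recovery_model(rates, scenario, total = sim$total,
                          sex_ratio_female = sim$sex_ratio_female)
  list(rates = rates, scenario = scenario, sim = sim, model = model)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a model configuration
#'
#' Serializes a configuration (as returned by [read_config()], or a
#' [recovery_model()]) back to YAML. `read_config(write_config(x, p))`
#' reproduces `x`.
#'
#' @param config a list with `rates`, `scenario` and optionally `sim`
#'   components, or a `"recovery_model"`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_config <- function(config, path) {
  if (inherits(config, "recovery_model"))
    config <- list(rates = config$rates, scenario = config$scenario)
  r <- config$rates; s <- config$scenario
  out <- list(
    vital_rates = list(sigma = r$sigma, gamma = r$gamma, b = r$b,
                       advance_to = r$advance_to),
    disturbance = list(epsilon0 = s$epsilon0, t_critical = s$t_critical,
                       t_end = s$t_end, c1 = s$c1, c2 = s$c2,
                       shape = s$shape, target = s$target,
                       tm_policy = s$tm_policy))
  if (!is.null(config$sim)) out$simulation <- config$sim
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write replicate trajectories and a per-replicate summary to CSV
#'
#' Emits a long-format CSV (`replicate`, `year`, `total`) of the
#' total-abundance series of a [simulate.recovery_model()] result, and a
#' per-replicate summary CSV (`replicate`, `recovered`, `recovery_year`,
#' `extinct`, `final_total`).
#'
#' @param sim a `"pop_simulation"`.
#' @param file path of the trajectory CSV; the summary goes to the same
#'   path with a `_summary` suffix.
#' @return Invisibly, the two paths written.
#' @export
write_trajectories <- function(sim, file) {
  stopifnot(inherits(sim, "pop_simulation"))
  utils::write.csv(as.data.frame(sim), file, row.names = FALSE)
  fin <- sim$totals[, ncol(sim$totals)]
  summ <- data.frame(replicate = seq_len(nrow(sim$totals)),
                     recovered = fin >= sim$threshold,
                     recovery_year = sim$first_hit,
                     extinct = fin == 0L,
                     final_total = fin)
  sfile <- sub("(\\.[^.]+)?$", "_summary\\1", file)
  if (sfile == file) sfile <- paste0(file, "_summary")
  utils::write.csv(summ, sfile, row.names = FALSE)
  invisible(c(file, sfile))
}

#' Write a run manifest
#'
#' Records everything needed to re-run a result bit-identically with the
#' same package version: the resolved configuration, the master seed, the
#' package version and a timestamp. YAML, human-readable.
#'
#' @param config as for [write_config()].
#' @param seed the master seed of the run.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(config, seed, path) {
  if (inherits(config, "recovery_model"))
    config <- list(rates = config$rates, scenario = config$scenario)
  out <- list(
    package = "poprecover",
    version = as.character(utils::packageVersion("poprecover")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    config = list(
      vital_rates = list(sigma = config$rates$sigma,
                         gamma = config$rates$gamma, b = config$rates$b),
      disturbance = unclass(config$scenario),
      simulation = config$sim))
  yaml::write_yaml(out, path)
  invisible(path)
}
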