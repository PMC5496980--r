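#' Build a population recovery model
#'
#' Binds together the three ingredients of the nonautonomous projection
#' model: a pre-event vital-rate set, a disturbance scenario, and an
#' integer initial stage vector. The resulting object is the entry point
#' for deterministic projection ([predict()]), stochastic simulation
#' ([simulate()]), and Monte-Carlo endpoints ([recovery_probability()],
#' [mean_recovery_time()], [sweep_grid()]).
#'
#' When `n0` is not given it is derived from a census: the female share of
#' `total` is spread over the stable stage distribution of the pre-event
#' matrix via [initial_stages()]. The packaged defaults are the
#' Gulf-of-Mexico sperm whale reference case: 1665 whales, 1:1 sex ratio,
#' giving 832 females in stages (71, 173, 301, 148, 139).
#'
#' @param rates a [vital_rates()] object (default [sperm_whale_rates()]).
#' @param scenario a [disturbance()] object; `NULL` means no disturbance
#'   (a zero-magnitude scenario).
#' @param n0 integer initial stage vector; derived from `total` and
#'   `sex_ratio_female` when `NULL`.
#' @param total,sex_ratio_female census size and female share used when
#'   `n0` is `NULL`.
#' @return An object of class `"recovery_model"` with elements `rates`,
#'   `scenario`, `n0`, the pre-event `bundle`, `lambda` (asymptotic growth
#'   rate) and `stable_stage`.
#' @examples
#' m <- recovery_model(scenario = disturbance(0.05, t_critical = 10, t_end = 20))
#' m
#' coef(m)
#' @export
recovery_model <- function(rates = sperm_whale_rates(), scenario = NULL,
                           n0 = NULL, total = 1665, sex_ratio_female = 0.5) {
  stopifnot(inherits(rates, "vital_rates"))
  if (is.null(scenario))
    scenario <- disturbance(0, t_critical = 0, t_end = 0, shape = "srf")
  stopifnot(inherits(scenario, "disturbance"))
  bundle <- projection_matrices(rates)
  eig <- .dominant_eigen(bundle$A)
  if (is.null(n0))
    n0 <- initial_stages(total, sex_ratio_female, eig$w)
  if (length(n0) != rates$S || any(n0 < 0) || any(n0 != floor(n0)))
    stop("`n0` must be a nonnegative integer vector with one entry per stage")
  structure(
    list(rates = rates, scenario = scenario, n0 = as.integer(n0),
         bundle = bundle, lambda = eig$lambda, stable_stage = eig$w),
    class = "recovery_model")
}

#' @export
print.recovery_model <- function(x, ...) {
  cat("Population recovery model:", x$rates$S, "stages,",
      sum(x$n0), "individuals at year 0\n")
  cat(sprintf("  pre-event growth rate lambda = %.4f\n", x$lambda))
  if (x$scenario$epsilon0 > 0) print(x$scenario)
  else cat("  no disturbance\n")
  invisible(x)
}

#' @export
summary.recovery_model <- function(object, ...) {
  structure(list(model = object), class = "summary.recovery_model")
}

#' @export
print.summary.recovery_model <- function(x, ...) {
  m <- x$model
  print(m)
  cat(sprintf("  stable stage distribution: %s\n",
              paste(sprintf("%.4f", m$stable_stage), collapse = " ")))
  cat("  initial stage vector:", paste(m$n0, collapse = " "), "\n")
  cat("  projection matrix A:\n")
  print(round(m$bundle$A, 4))
  invisible(x)
}

#' @export
coef.recovery_model <- function(object, ...) {
  r <- object$rates
  c(stats::setNames(r$sigma, paste0("sigma", seq_len(r$S))),
    stats::setNames(r$gamma, paste0("gamma", seq_len(r$S))),
    b = r$b)
}

#' Deterministic nonautonomous projection
#'
#' Iterates the expected-value model \eqn{n(t) = A(\varepsilon(t))\,n(t-1)}
#' with real-valued abundances: the trajectory the stochastic model follows
#' on average. With no disturbance the total grows asymptotically at the
#' rate \eqn{\lambda} per year.
#'
#' @param object a [recovery_model()].
#' @param years horizon in years (default 100).
#' @param n0 starting vector (default: the model's integer initial vector;
#'   real values are allowed here).
#' @param ... unused.
#' @return An object of class `"pop_projection"`: a list with the
#'   `(years+1) x S` real matrix `counts` and the `totals` series.
#' @export
predict.recovery_model <- function(object, years = 100, n0 = object$n0, ...) {
  counts <- project_deterministic(n0, years, object$rates, object$scenario)
  structure(list(counts = counts, totals = rowSums(counts)),
            class = "pop_projection")
}

#' @export
print.pop_projection <- function(x, ...) {
  N <- length(x$totals) - 1L
  cat(sprintf("Deterministic projection over %d years: total %.1f -> %.1f\n",
              N, x$totals[1L], x$totals[N + 1L]))
  invisible(x)
}

#' Deterministic projection of the time-varying model
#'
#' Workhorse behind [predict.recovery_model()]: exact matrix iteration of
#' the time-varying projection model with real-valued abundances. The
#' matrix in force during year `t` is `matrix_at(rates, scenario, t)`.
#'
#' @param n0 numeric starting vector (need not be integer).
#' @param years horizon in years.
#' @param rates a [vital_rates()] object.
#' @param scenario a [disturbance()] object.
#' @return A `(years+1) x S` numeric matrix of abundances, rows labelled
#'   by year.
#' @export
project_deterministic <- function(n0, years, rates, scenario) {
  stopifnot(inherits(rates, "vital_rates"), inherits(scenario, "disturbance"),
            years >= 1, length(n0) == rates$S)
  S <- rates$S
  counts <- matrix(0, years + 1L, S,
                   dimnames = list(0:years, paste0("stage", seq_len(S))))
  counts[1L, ] <- n0
  n <- as.numeric(n0)
  for (t in seq_len(years)) {
    n <- drop(matrix_at(rates, scenario, t)$A %*% n)
    counts[t + 1L, ] <- n
  }
  counts
}

#' Simulate stochastic replicate trajectories
#'
#' Runs `nsim` independent demographic-stochasticity replicates of the
#' model and records the total-abundance series of each (full per-stage
#' paths are available through [simulate_trajectory()]).
#'
#' @param object a [recovery_model()].
#' @param nsim number of replicates.
#' @param seed integer seed (`NULL` uses the current RNG state).
#' @param years horizon in years (default 100).
#' @param ... unused.
#' @return An object of class `"pop_simulation"`: a list with `totals`
#'   (`nsim x (years+1)` integer matrix), `final` (`nsim x S` final stage
#'   counts), `first_hit` (first year each replicate's total reached the
#'   initial total, `NA` if never), and the threshold used.
#' @export
simulate.recovery_model <- function(object, nsim = 1, seed = NULL,
                                    years = 100, ...) {
  sim <- .simulate_totals(object$n0, years, object$rates, object$scenario,
                          reps = nsim, seed = seed)
  structure(c(sim, list(threshold = sum(object$n0), years = years)),
            class = "pop_simulation")
}

#' @export
print.pop_simulation <- function(x, ...) {
  K <- nrow(x$totals)
  cat("Stochastic simulation:", K, "replicates over", x$years, "years\n")
  fin <- x$totals[, x$years + 1L]
  cat(sprintf("  final total: median %.0f (range %d-%d)\n",
              stats::median(fin), min(fin), max(fin)))
  cat(sprintf("  at/above initial total (%d) at final year: %d of %d\n",
              x$threshold, sum(fin >= x$threshold), K))
  invisible(x)
}

#' @export
as.data.frame.pop_simulation <- function(x, ...) {
  K <- nrow(x$totals)
  yrs <- ncol(x$totals) - 1L
  data.frame(replicate = rep(seq_len(K), yrs + 1L),
             year = rep(0:yrs, each = K),
             total = as.vector(x$totals))
}

#' Plot replicate trajectories
#'
#' Draws the total-abundance series of each replicate, a dashed horizontal
#' line at the recovery threshold, and (optionally) the deterministic
#' expectation.
#'
#' @param x a `"pop_simulation"`.
#' @param model optional [recovery_model()]; when given, the deterministic
#'   trajectory is overlaid.
#' @param ... passed to [graphics::matplot()].
#' @return Invisibly, `x`.
#' @export
plot.pop_simulation <- function(x, model = NULL, ...) {
  yrs <- 0:(ncol(x$totals) - 1L)
  graphics::matplot(yrs, t(x$totals), type = "l", lty = 1,
                    col = grDevices::adjustcolor("steelblue", 0.5),
                    xlab = "years since event", ylab = "total females", ...)
  graphics::abline(h = x$threshold, lty = 2)
  if (!is.null(model)) {
    det <- predict(model, years = max(yrs))
    graphics::lines(yrs, det$totals, lwd = 2)
  }
  invisible(x)
}

#' @export
plot.recovery_model <- function(x, years = 100, nsim = 10, seed = NULL, ...) {
  sim <- simulate(x, nsim = nsim, seed = seed, years = years)
  plot(sim, model = x, ...)
}
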