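#' Monte-Carlo recovery probability
#'
#' Estimates \eqn{\Phi}, the probability that the population returns to its
#' pre-event size (or a chosen threshold) within `years`, by running `reps`
#' independent stochastic replicates. Under the default `"final"` rule a
#' replicate counts as recovered when its total abundance at the final year
#' is at or above the threshold, regardless of stage structure; extinct
#' replicates count as non-recovered. The `"first_passage"` rule instead
#' counts replicates whose total reaches the threshold at any year
#' \eqn{t \ge 1}.
#'
#' @param model a [recovery_model()].
#' @param years horizon N in years (default 100).
#' @param reps number of Monte-Carlo replicates K (default 5000).
#' @param threshold recovery threshold on the total female count (default:
#'   the model's initial total).
#' @param rule `"final"` or `"first_passage"`.
#' @param seed integer master seed for reproducibility.
#' @return An object of class `"endpoint_result"`: a list with `phi`
#'   (estimated probability), `recovered` and `extinct` counts, `reps`,
#'   `years`, `rule`, `threshold`, `seed`, the Monte-Carlo standard error
#'   `se`, and summary statistics of the first-passage recovery year among
#'   recovered, non-extinct replicates (`mean_recovery_time`,
#'   `sd_recovery_time`, `n_recovery_time`).
#' @examples
#' m <- recovery_model(scenario = disturbance(0.05, 10, 20))
#' recovery_probability(m, years = 100, reps = 200, seed = 1)
#' @export
recovery_probability <- function(model, years = 100, reps = 5000,
                                 threshold = NULL,
                                 rule = c("final", "first_passage"),
                                 seed = 1L) {
  stopifnot(inherits(model, "recovery_model"), years >= 1, reps >= 1)
  rule <- match.arg(rule)
  if (reps < 1000)
    warning("reps < 1000: Monte-Carlo error may exceed reporting precision")
  if (is.null(threshold)) threshold <- sum(model$n0)
  sim <- .simulate_totals(model$n0, years, model$rates, model$scenario,
                          reps, seed = seed, threshold = threshold)
  final_tot <- sim$totals[, years + 1L]
  extinct <- final_tot == 0L
  recovered <- if (rule == "final") final_tot >= threshold
               else !is.na(sim$first_hit)
  qual <- recovered & !extinct & !is.na(sim$first_hit)
  rt <- sim$first_hit[qual]
  phi <- mean(recovered)
  structure(
    list(phi = phi, recovered = sum(recovered), extinct = sum(extinct),
         reps = reps, years = years, rule = rule, threshold = threshold,
         seed = seed, se = sqrt(phi * (1 - phi) / reps),
         mean_recovery_time = if (length(rt)) mean(rt) else NA_real_,
         sd_recovery_time = if (length(rt) > 1) stats::sd(rt) else NA_real_,
         n_recovery_time = length(rt),
         scenario = model$scenario),
    class = "endpoint_result")
}

#' Mean first-passage recovery time
#'
#' The average first year at which the total abundance re-attains the
#' threshold, among replicates that do recover within the horizon and do
#' not go extinct. Replicates that never reach the threshold within
#' `years` are excluded and their count reported, not imputed.
#'
#' @inheritParams recovery_probability
#' @param years horizon cap in years (default 500, long enough that slow
#'   scenarios still register a recovery year).
#' @param reps replicate count (default 1000).
#' @return An `"endpoint_result"` (see [recovery_probability()]); `phi`
#'   here is the first-passage recovery fraction. Errors if no replicate
#'   qualifies.
#' @export
mean_recovery_time <- function(model, years = 500, reps = 1000,
                               threshold = NULL, seed = 1L) {
  res <- recovery_probability(model, years = years, reps = reps,
                              threshold = threshold, rule = "first_passage",
                              seed = seed)
  if (res$n_recovery_time == 0L)
    stop("no replicate recovered within ", years,
         " years; cannot estimate a mean recovery time")
  res
}

#' @export
print.endpoint_result <- function(x, ...) {
  cat(sprintf("Recovery endpoint (%s rule, threshold %d, K = %d, N = %d, seed %d)\n",
              x$rule, x$threshold, x$reps, x$years, x$seed))
  cat(sprintf("  Phi = %.4f  (recovered %d / %d, MC se %.4f)\n",
              x$phi, x$recovered, x$reps, x$se))
  cat(sprintf("  extinct replicates: %d\n", x$extinct))
  if (x$n_recovery_time > 0)
    cat(sprintf("  recovery year among %d recovered non-extinct replicates: mean %.1f (sd %.1f)\n",
                x$n_recovery_time, x$mean_recovery_time, x$sd_recovery_time))
  invisible(x)
}

#' @export
as.data.frame.endpoint_result <- function(x, ...) {
  data.frame(phi = x$phi, recovered = x$recovered, extinct = x$extinct,
             reps = x$reps, years = x$years, rule = x$rule,
             threshold = x$threshold, seed = x$seed, se = x$se,
             mean_recovery_time = x$mean_recovery_time,
             sd_recovery_time = x$sd_recovery_time,
             n_recovery_time = x$n_recovery_time)
}

#' Endpoint sweep over disturbance magnitude and duration
#'
#' Recomputes a recovery endpoint over a grid of `epsilon0` and/or
#' `t_critical` values (all other scenario fields taken from the model).
#' When `t_critical` varies, `t_end` keeps its offset from `t_critical`.
#' Each grid cell is seeded as `seed + cell index`, so cells are
#' reproducible independently of evaluation order.
#'
#' @param model a [recovery_model()] used as the template.
#' @param epsilon0,t_critical numeric vectors of axis values (default: the
#'   single value in the model's scenario).
#' @param what `"phi"` (recovery probability) or `"mrt"` (mean recovery
#'   time).
#' @inheritParams recovery_probability
#' @param reps replicates per cell (default 1000).
#' @return A data frame with one row per grid cell: the axis values and the
#'   fields of [as.data.frame.endpoint_result()].
#' @export
sweep_grid <- function(model, epsilon0 = NULL, t_critical = NULL,
                       what = c("phi", "mrt"),
                       years = 100, reps = 1000, threshold = NULL,
                       rule = c("final", "first_passage"), seed = 1L) {
  stopifnot(inherits(model, "recovery_model"))
  what <- match.arg(what)
  rule <- match.arg(rule)
  sc <- model$scenario
  if (is.null(epsilon0)) epsilon0 <- sc$epsilon0
  if (is.null(t_critical)) t_critical <- sc$t_critical
  offset <- sc$t_end - sc$t_critical
  grid <- expand.grid(epsilon0 = epsilon0, t_critical = t_critical,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    sci <- disturbance(epsilon0 = grid$epsilon0[i],
                       t_critical = grid$t_critical[i],
                       t_end = grid$t_critical[i] + offset,
                       c1 = sc$c1, c2 = sc$c2, shape = sc$shape,
                       target = sc$target, tm_policy = sc$tm_policy)
    mi <- recovery_model(model$rates, sci, n0 = model$n0)
    res <- if (what == "mrt")
      mean_recovery_time(mi, years = years, reps = reps,
                         threshold = threshold, seed = seed + i - 1L)
    else
      recovery_probability(mi, years = years, reps = reps,
                           threshold = threshold, rule = rule,
                           seed = seed + i - 1L)
    rows[[i]] <- cbind(grid[i, , drop = FALSE], as.data.frame(res))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
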