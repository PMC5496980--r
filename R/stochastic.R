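# Demographic stochasticity engine.
#
# Individual fates are multinomial: each of the n_j individuals of stage j
# independently lands in one of the S+1 fate categories given by column j of
# the fate matrix (stay, advance, die). Draws use the exact conditional
# binomial factorization of the multinomial, which vectorizes across
# replicate populations. Births are binomial with the per-parent fertility
# entry, independent of the parent's own transition that year.

# Multinomial fate draw for one stage across replicates.
# n: integer vector (one count per replicate); probs: S+1 fate probabilities.
# Returns a length(n) x (S+1) matrix of category counts.
.draw_fates <- function(n, probs) {
  K <- length(n)
  S1 <- length(probs)
  out <- matrix(0L, K, S1)
  rem_n <- as.integer(n)
  rem_p <- 1
  for (i in seq_len(S1 - 1L)) {
    p <- probs[i]
    if (p <= 0) next
    pc <- min(max(p / rem_p, 0), 1)
    x <- stats::rbinom(K, rem_n, pc)
    out[, i] <- x
    rem_n <- rem_n - x
    rem_p <- rem_p - p
  }
  out[, S1] <- rem_n  # remainder category (death row)
  out
}

# One projection step for K replicate populations held as a K x S integer
# matrix. Returns the K x S matrix at t+1; deaths are discarded.
.step_multi <- function(pop, bundle) {
  S <- ncol(pop)
  K <- nrow(pop)
  new <- matrix(0L, K, S)
  Uf <- bundle$U_fate
  for (j in seq_len(S)) {
    nj <- pop[, j]
    if (all(nj == 0L)) next
    fates <- .draw_fates(nj, Uf[, j])
    new <- new + fates[, seq_len(S), drop = FALSE]
  }
  Fm <- bundle$F
  for (j in seq_len(S)) {
    fj <- Fm[, j]
    dest <- which(fj > 0)
    for (i in dest) {
      if (fj[i] > 1)
        stop("fertility entry F[", i, ",", j, "] exceeds 1: at most one ",
             "birth per individual per year is assumed")
      new[, i] <- new[, i] + stats::rbinom(K, pop[, j], fj[i])
    }
  }
  new
}

#' One stochastic projection step
#'
#' Advances a stage-abundance vector one year under demographic
#' stochasticity: for each stage \eqn{j}, the \eqn{n_j} individuals are
#' assigned multinomially to the \eqn{S+1} fates of column \eqn{j} of the
#' fate matrix (deaths are discarded), and each of the \eqn{n_j} potential
#' parents independently produces a female offspring with probability given
#' by the fertility matrix. Transitions and births are independent.
#'
#' @param n integer vector of per-stage abundances.
#' @param bundle a `"matrix_bundle"` (from [projection_matrices()] or
#'   [matrix_at()]).
#' @return The integer abundance vector one year later. Expectation equals
#'   `bundle$A %*% n`.
#' @examples
#' m <- projection_matrices(sperm_whale_rates())
#' set.seed(1)
#' step_stochastic(c(71, 173, 301, 148, 139), m)
#' @export
step_stochastic <- function(n, bundle) {
  stopifnot(inherits(bundle, "matrix_bundle"))
  S <- ncol(bundle$A)
  if (length(n) != S) stop("`n` must have one count per stage")
  if (any(n < 0) || any(n != floor(n))) stop("`n` must be nonnegative integers")
  drop(.step_multi(matrix(as.integer(n), 1L, S), bundle))
}

#' Simulate one stochastic trajectory
#'
#' Runs the demographic-stochasticity model for `years` annual steps under
#' a disturbance scenario. The environment during year \eqn{t} (the step
#' from \eqn{t-1} to \eqn{t}) is the recovery function evaluated at
#' \eqn{t}, so a scenario with `t_critical = 10` exposes the population to
#' (essentially) the full reduction for its first ten years.
#'
#' @param n0 integer vector of initial per-stage abundances (year 0).
#' @param years horizon N (number of annual steps).
#' @param rates pre-event [vital_rates()].
#' @param scenario a [disturbance()] object.
#' @param seed optional integer seed; if `NULL` the current RNG state is
#'   used.
#' @param threshold recovery threshold on the total count (default: the
#'   initial total).
#' @return An object of class `"pop_trajectory"`: a list with the
#'   `(years+1) x S` integer matrix `counts` (rows labelled by year), the
#'   `totals` series, logical `recovered` and `extinct`, and
#'   `recovery_year` (first year `t >= 1` with total at or above the
#'   threshold, or `NA`).
#' @export
simulate_trajectory <- function(n0, years, rates, scenario, seed = NULL,
                                threshold = sum(n0)) {
  stopifnot(inherits(rates, "vital_rates"), inherits(scenario, "disturbance"),
            years >= 1)
  if (!is.null(seed)) set.seed(seed)
  S <- rates$S
  counts <- matrix(0L, years + 1L, S,
                   dimnames = list(0:years, paste0("stage", seq_len(S))))
  counts[1L, ] <- as.integer(n0)
  n <- matrix(as.integer(n0), 1L, S)
  for (t in seq_len(years)) {
    if (sum(n) > 0L)  # extinction is absorbing
      n <- .step_multi(n, matrix_at(rates, scenario, t))
    counts[t + 1L, ] <- n
  }
  totals <- rowSums(counts)
  hit <- which(totals[-1L] >= threshold)
  structure(
    list(counts = counts, totals = totals,
         recovered = totals[years + 1L] >= threshold,
         recovery_year = if (length(hit)) hit[1L] else NA_integer_,
         extinct = totals[years + 1L] == 0,
         threshold = threshold),
    class = "pop_trajectory")
}

#' @export
print.pop_trajectory <- function(x, ...) {
  N <- length(x$totals) - 1L
  cat("Stochastic trajectory over", N, "years:",
      x$totals[1L], "->", x$totals[N + 1L], "individuals\n")
  cat("  recovered (total >= ", x$threshold, " at final year): ",
      x$recovered, "\n", sep = "")
  if (!is.na(x$recovery_year))
    cat("  first year at/above threshold:", x$recovery_year, "\n")
  if (x$extinct) cat("  population went extinct\n")
  invisible(x)
}

#' @export
as.data.frame.pop_trajectory <- function(x, ...) {
  S <- ncol(x$counts)
  data.frame(year = rep(as.integer(rownames(x$counts)), S),
             stage = rep(seq_len(S), each = nrow(x$counts)),
             count = as.vector(x$counts))
}

# Internal: K replicate trajectories, tracking totals only.
# Returns list(totals = K x (years+1), first_hit = integer K (NA if never),
# final = K x S matrix).
.simulate_totals <- function(n0, years, rates, scenario, reps, seed = NULL,
                             threshold = sum(n0)) {
  if (!is.null(seed)) set.seed(seed)
  S <- length(n0)
  pop <- matrix(rep(as.integer(n0), each = reps), reps, S)
  totals <- matrix(0L, reps, years + 1L)
  totals[, 1L] <- sum(n0)
  first_hit <- rep(NA_integer_, reps)
  for (t in seq_len(years)) {
    pop <- .step_multi(pop, matrix_at(rates, scenario, t))
    tot <- rowSums(pop)
    totals[, t + 1L] <- tot
    hit <- is.na(first_hit) & tot >= threshold
    first_hit[hit] <- t
  }
  list(totals = totals, first_hit = first_hit, final = pop)
}
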