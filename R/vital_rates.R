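#' Define a stage-structured vital-rate set
#'
#' A vital-rate set holds per-stage annual survivorship probabilities
#' \eqn{\sigma_i}, per-stage transition probabilities \eqn{\gamma_i}, and an
#' annual fecundity \eqn{b} (female offspring per reproducing female per
#' year), together with the life-cycle wiring that turns them into a
#' projection matrix.
#'
#' The wiring is a "stay or advance" graph: an individual in stage \eqn{i}
#' survives with probability \eqn{\sigma_i} and, conditional on surviving,
#' advances to stage `advance_to[i]` with probability \eqn{\gamma_i} or stays
#' in stage \eqn{i} with probability \eqn{1-\gamma_i}. Reproduction places
#' \eqn{b} offspring per individual of stage `birth_from` into stage
#' `birth_to`.
#'
#' The default wiring is the five-stage female sperm whale life cycle:
#' calves (1) advance to juveniles (2), juveniles mature (3), mature females
#' give birth and become mothers (4), mothers wean and become resting
#' post-breeders (5), and post-breeders return to the mature stage (3) to
#' breed again. Fecundity flows from stage 3 to stage 1.
#'
#' @param sigma numeric vector of per-stage survivorships, all in \[0, 1\].
#' @param gamma numeric vector of per-stage transition probabilities, same
#'   length as `sigma`, all in \[0, 1\]. The last entry is the probability of
#'   the terminal stage returning to `advance_to[S]` (stage 3 in the default
#'   life cycle).
#' @param b annual fecundity in \[0, 1\] (at most one female birth per
#'   reproducing female per year).
#' @param advance_to integer vector: the destination stage of a transition
#'   out of each stage. Defaults to `c(2, 3, 4, 5, 3)` when `length(sigma)`
#'   is 5; must be supplied for other stage counts.
#' @param birth_from,birth_to stages producing and receiving newborns
#'   (defaults 3 and 1).
#'
#' @return An object of class `"vital_rates"`.
#' @seealso [projection_matrices()], [sperm_whale_rates()]
#' @examples
#' r <- sperm_whale_rates()
#' growth_rate(r)
#' @export
vital_rates <- function(sigma, gamma, b,
                        advance_to = NULL, birth_from = 3L, birth_to = 1L) {
  S <- length(sigma)
  if (S < 2L)
    stop("at least two stages are required (got ", S, ")")
  if (length(gamma) != S)
    stop("`gamma` must have the same length as `sigma` (", S, ")")
  bad <- function(x) any(!is.finite(x)) || any(x < 0) || any(x > 1)
  errs <- character(0)
  for (i in seq_len(S)) {
    if (bad(sigma[i])) errs <- c(errs, sprintf("sigma[%d] = %s is outside [0, 1]", i, format(sigma[i])))
    if (bad(gamma[i])) errs <- c(errs, sprintf("gamma[%d] = %s is outside [0, 1]", i, format(gamma[i])))
  }
  if (length(b) != 1L || bad(b)) errs <- c(errs, sprintf("b = %s is outside [0, 1]", format(b)))
  if (is.null(advance_to)) {
    if (S == 5L) advance_to <- c(2L, 3L, 4L, 5L, 3L)
    else stop("`advance_to` must be supplied when the stage count is not 5")
  }
  advance_to <- as.integer(advance_to)
  if (length(advance_to) != S || any(advance_to < 1L) || any(advance_to > S))
    errs <- c(errs, "`advance_to` must be a vector of valid stage indices, one per stage")
  if (birth_from < 1L || birth_from > S || birth_to < 1L || birth_to > S)
    errs <- c(errs, "`birth_from`/`birth_to` must be valid stage indices")
  if (length(errs))
    stop("invalid vital rates:\n  ", paste(errs, collapse = "\n  "))
  structure(
    list(sigma = as.numeric(sigma), gamma = as.numeric(gamma), b = as.numeric(b),
         S = S, advance_to = advance_to,
         birth_from = as.integer(birth_from), birth_to = as.integer(birth_to)),
    class = "vital_rates")
}

#' @export
print.vital_rates <- function(x, ...) {
  cat("Stage-structured vital rates (", x$S, " stages)\n", sep = "")
  tab <- rbind(sigma = x$sigma, gamma = x$gamma)
  colnames(tab) <- paste0("stage", seq_len(x$S))
  print(round(tab, 4))
  cat("fecundity b =", format(x$b), " (stage", x$birth_from, "-> stage",
      x$birth_to, ")\n")
  invisible(x)
}

#' Gulf-of-Mexico sperm whale vital rates
#'
#' The packaged reference parameterization of the five-stage female sperm
#' whale life cycle: survivorships 0.9070, 0.9424, 0.9777, 0.9777, 0.9777;
#' transition probabilities 0.4732, 0.1151, 0.2586, 0.4920, 0.4920; annual
#' fecundity 0.1250. The resulting projection matrix has asymptotic growth
#' rate about 1.0096 per year.
#'
#' @return A `"vital_rates"` object.
#' @export
sperm_whale_rates <- function() {
  vital_rates(sigma = c(0.9070, 0.9424, 0.9777, 0.9777, 0.9777),
              gamma = c(0.4732, 0.1151, 0.2586, 0.4920, 0.4920),
              b = 0.1250)
}
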