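#' Define a disturbance and environmental-recovery scenario
#'
#' A disaster reduces vital rates proportionally by `epsilon0` and the
#' environment then recovers. Two recovery shapes are supported:
#'
#' * `"crf"` (continuous recovery function): the reduction holds at
#'   `epsilon0` until `t_critical`, decays along a sigmoid over
#'   \[`t_critical`, `t_end`\], and is zero after `t_end`;
#' * `"srf"` (step recovery function): the reduction holds at `epsilon0`
#'   for `t < t_critical` and drops instantaneously to zero at
#'   `t_critical`.
#'
#' Lethal impacts (`target = "survival"`) scale adult survivorships by
#' \eqn{1-\varepsilon(t)} and juvenile survivorships (stages 1 and 2) by
#' \eqn{1 - c_j\varepsilon(t)} with amplification factors \eqn{c_j \ge 1},
#' reflecting the greater toxicant sensitivity of early stages. Sublethal
#' impacts (`target = "fecundity"`) scale fecundity by
#' \eqn{1-\varepsilon(t)}. `target = "both"` applies both at once (an
#' extension beyond the two canonical analyses, which treat them
#' separately). Transition probabilities \eqn{\gamma_i} are never altered.
#'
#' The sigmoid branch is \eqn{a/(1+e^{t-T_M}) - d} with \eqn{a, d} solved
#' so the branch equals `epsilon0` at `t_critical` and 0 at `t_end`.
#' `tm_policy` locates the inflection constant \eqn{T_M}: `"midpoint"`
#' (default) uses \eqn{(T_{Critical}+T_{End})/2}, placing the inflection
#' midway through the recovery window and giving the symmetric sigmoid
#' shape the model intends; `"literal"` uses \eqn{(T_{End}-T_{Critical})/2},
#' which for typical windows lies before the window and degenerates the
#' sigmoid into a near-step (retained for comparison; see the methods
#' vignette).
#'
#' @param epsilon0 peak proportional reduction, in \[0, 1\].
#' @param t_critical years of full reduction (nonnegative).
#' @param t_end year at which the environment has fully recovered
#'   (`>= t_critical`; default `t_critical + 10`). Ignored by `"srf"`.
#' @param c1,c2 juvenile amplification multipliers for stages 1 and 2
#'   (`>= 1`, and `c * epsilon0 <= 1` so perturbed rates stay in \[0, 1\]).
#' @param shape `"crf"` or `"srf"`.
#' @param target `"survival"`, `"fecundity"`, or `"both"`.
#' @param tm_policy `"midpoint"` or `"literal"`.
#' @return An object of class `"disturbance"`.
#' @examples
#' d <- disturbance(0.05, t_critical = 10, t_end = 20)
#' epsilon_at(d, 0:25)
#' @export
disturbance <- function(epsilon0, t_critical, t_end = t_critical + 10,
                        c1 = 2, c2 = 2,
                        shape = c("crf", "srf"),
                        target = c("survival", "fecundity", "both"),
                        tm_policy = c("midpoint", "literal")) {
  shape <- match.arg(shape)
  target <- match.arg(target)
  tm_policy <- match.arg(tm_policy)
  errs <- character(0)
  if (!is.finite(epsilon0) || epsilon0 < 0 || epsilon0 > 1)
    errs <- c(errs, sprintf("epsilon0 = %s is outside [0, 1]", format(epsilon0)))
  if (!is.finite(t_critical) || t_critical < 0)
    errs <- c(errs, "t_critical must be nonnegative")
  if (shape == "crf" && t_end < t_critical)
    errs <- c(errs, "t_end must be >= t_critical")
  for (nm in c("c1", "c2")) {
    cv <- get(nm)
    if (!is.finite(cv) || cv < 1)
      errs <- c(errs, sprintf("%s = %s must be >= 1", nm, format(cv)))
    else if (target != "fecundity" && cv * epsilon0 > 1 + 1e-12)
      errs <- c(errs, sprintf(
        "%s * epsilon0 = %s exceeds 1; juvenile survival would go negative",
        nm, format(cv * epsilon0)))
  }
  if (length(errs))
    stop("invalid disturbance scenario:\n  ", paste(errs, collapse = "\n  "))
  structure(
    list(epsilon0 = epsilon0, t_critical = t_critical, t_end = t_end,
         c1 = c1, c2 = c2, shape = shape, target = target,
         tm_policy = tm_policy),
    class = "disturbance")
}

#' @export
print.disturbance <- function(x, ...) {
  cat("Disturbance scenario (", toupper(x$shape), ", target: ", x$target,
      ")\n", sep = "")
  cat(sprintf("  epsilon0 = %g, t_critical = %g, t_end = %g\n",
              x$epsilon0, x$t_critical, x$t_end))
  if (x$target != "fecundity")
    cat(sprintf("  juvenile amplification c1 = %g, c2 = %g\n", x$c1, x$c2))
  if (x$shape == "crf")
    cat("  sigmoid inflection policy:", x$tm_policy, "\n")
  invisible(x)
}

#' Solve the sigmoid coefficients of a continuous recovery function
#'
#' The sigmoid branch \eqn{a/(1+e^{t-T_M}) - d} must equal `epsilon0` at
#' `t_critical` and 0 at `t_end`; this is a 2x2 linear system in
#' \eqn{(a, d)}, solved here exactly.
#'
#' @param scenario a [disturbance()] object with `shape = "crf"` and
#'   `t_end > t_critical`.
#' @return A list with elements `a`, `d` and `t_m`.
#' @export
sigmoid_coefficients <- function(scenario) {
  stopifnot(inherits(scenario, "disturbance"))
  if (scenario$shape != "crf")
    stop("sigmoid coefficients are defined only for the continuous recovery function")
  tc <- scenario$t_critical; te <- scenario$t_end
  if (te <= tc)
    stop("t_end must exceed t_critical for a sigmoid recovery (use shape = \"srf\" for an instantaneous one)")
  t_m <- switch(scenario$tm_policy,
                midpoint = (tc + te) / 2,
                literal  = (te - tc) / 2)
  # a / (1 + exp(t - t_m)) - d at t = tc equals epsilon0, at t = te equals 0
  M <- rbind(c(1 / (1 + exp(tc - t_m)), -1),
             c(1 / (1 + exp(te - t_m)), -1))
  sol <- solve(M, c(scenario$epsilon0, 0))
  list(a = sol[1], d = sol[2], t_m = t_m)
}

#' Evaluate the proportional vital-rate reduction at a time
#'
#' Evaluates the recovery function of a scenario: the magnitude
#' \eqn{\varepsilon(t)} by which targeted vital rates are proportionally
#' reduced during year `t`. Vectorized over `t`.
#'
#' @param scenario a [disturbance()] object.
#' @param t nonnegative time(s) in years since the event.
#' @return Reduction value(s) in \[0, 1\].
#' @export
epsilon_at <- function(scenario, t) {
  stopifnot(inherits(scenario, "disturbance"))
  if (any(t < 0)) stop("negative time passed to epsilon_at()")
  e0 <- scenario$epsilon0
  tc <- scenario$t_critical
  if (scenario$shape == "srf" || scenario$t_end <= tc)
    return(ifelse(t < tc, e0, 0))
  te <- scenario$t_end
  if (e0 == 0) return(rep(0, length(t)))
  cf <- sigmoid_coefficients(scenario)
  mid <- cf$a / (1 + exp(t - cf$t_m)) - cf$d
  out <- ifelse(t < tc, e0, ifelse(t > te, 0, mid))
  pmin(pmax(out, 0), 1)
}

#' Apply a proportional reduction to a vital-rate set
#'
#' Scales the targeted rates by the current reduction `eps`: adult
#' survivorships (stages 3 and up) by \eqn{1-\varepsilon}, juvenile
#' survivorships (stages 1 and 2) by \eqn{1 - c_j\varepsilon}, fecundity by
#' \eqn{1-\varepsilon}, according to the scenario's `target`. Transition
#' probabilities are unchanged.
#'
#' @param rates a [vital_rates()] object.
#' @param eps current reduction in \[0, 1\].
#' @param scenario a [disturbance()] object (supplies `c1`, `c2`, `target`).
#' @return A perturbed `"vital_rates"` object.
#' @export
perturb_rates <- function(rates, eps, scenario) {
  stopifnot(inherits(rates, "vital_rates"), inherits(scenario, "disturbance"))
  if (!is.finite(eps) || eps < 0 || eps > 1)
    stop("eps must be in [0, 1]")
  sigma <- rates$sigma
  b <- rates$b
  if (scenario$target %in% c("survival", "both")) {
    cj <- c(scenario$c1, scenario$c2, rep(1, rates$S - 2L))
    sigma <- rates$sigma * (1 - cj * eps)
    if (any(sigma < -1e-12))
      stop("perturbed survival is negative: c_j * eps exceeds 1")
    sigma <- pmax(sigma, 0)
  }
  if (scenario$target %in% c("fecundity", "both"))
    b <- rates$b * (1 - eps)
  vital_rates(sigma, rates$gamma, b, advance_to = rates$advance_to,
              birth_from = rates$birth_from, birth_to = rates$birth_to)
}

#' Time-varying projection matrices
#'
#' The matrix bundle in force during year `t` of a scenario: the recovery
#' function is evaluated at `t`, the vital rates perturbed accordingly, and
#' the matrices reassembled. After `t_end` (or from `t_critical` for the
#' step shape) the pre-event bundle is returned bit-identically.
#'
#' @param rates a [vital_rates()] object (pre-event rates).
#' @param scenario a [disturbance()] object.
#' @param t a single nonnegative time in years.
#' @return A `"matrix_bundle"`.
#' @export
matrix_at <- function(rates, scenario, t) {
  eps <- epsilon_at(scenario, t)
  projection_matrices(perturb_rates(rates, eps, scenario))
}
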