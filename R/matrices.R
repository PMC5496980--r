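#' Assemble the projection matrix and its decomposition
#'
#' Builds the annual projection matrix \eqn{A} from a vital-rate set, its
#' decomposition \eqn{A = U + F} into a transition-only part \eqn{U} and a
#' fertility-only part \eqn{F}, and the fate matrix: \eqn{U} with an
#' appended death row so that every column is a complete probability
#' distribution over the \eqn{S+1} possible fates (stay, advance, die) of
#' one individual.
#'
#' Entries of \eqn{U} are \eqn{P_i = \sigma_i(1-\gamma_i)} on the diagonal
#' (survive and stay) and \eqn{G_i = \sigma_i\gamma_i} on the advancement
#' arcs (survive and move); the death-row entry of column \eqn{i} is
#' \eqn{1 - (P_i + G_i) = 1 - \sigma_i}. \eqn{F} carries the single
#' fecundity entry \eqn{b}.
#'
#' @param rates a [vital_rates()] object.
#' @return An object of class `"matrix_bundle"`: a list with elements `A`,
#'   `U`, `F` (all \eqn{S \times S}) and `U_fate` (\eqn{(S+1) \times S},
#'   columns summing to exactly 1), plus the `rates` used.
#' @examples
#' m <- projection_matrices(sperm_whale_rates())
#' colSums(m$U_fate)
#' @export
projection_matrices <- function(rates) {
  stopifnot(inherits(rates, "vital_rates"))
  S <- rates$S
  P <- rates$sigma * (1 - rates$gamma)
  G <- rates$sigma * rates$gamma
  U <- matrix(0, S, S)
  for (j in seq_len(S)) {
    U[j, j] <- U[j, j] + P[j]
    U[rates$advance_to[j], j] <- U[rates$advance_to[j], j] + G[j]
  }
  Fm <- matrix(0, S, S)
  Fm[rates$birth_to, rates$birth_from] <- rates$b
  # death row: compensate accumulated rounding so each fate column sums to
  # exactly 1 (colSums accumulates in extended precision, so the residual
  # is fed back until it vanishes)
  U_fate <- rbind(U, 1 - colSums(U))
  for (k in 1:5) {
    resid <- 1 - colSums(U_fate)
    if (all(resid == 0)) break
    U_fate[S + 1L, ] <- U_fate[S + 1L, ] + resid
  }
  dimnames(U_fate) <- NULL
  structure(list(A = U + Fm, U = U, F = Fm, U_fate = U_fate, rates = rates),
            class = "matrix_bundle")
}

#' @export
print.matrix_bundle <- function(x, ...) {
  cat("Projection matrix bundle (", nrow(x$A), " stages)\nA:\n", sep = "")
  print(round(x$A, 4))
  cat("asymptotic growth rate:", format(growth_rate(x), digits = 6), "\n")
  invisible(x)
}

.dominant_eigen <- function(A) {
  ev <- eigen(A)
  i <- which.max(Mod(ev$values))
  lambda <- ev$values[i]
  if (abs(Im(lambda)) > 1e-8 * (1 + abs(Re(lambda))))
    stop("dominant eigenvalue is not real; the matrix has no simple dominant root")
  w <- ev$vectors[, i]
  if (max(abs(Im(w))) > 1e-8) stop("dominant eigenvector is not real")
  w <- Re(w)
  w <- w / sum(w)
  if (any(w < -1e-10))
    stop("dominant eigenvector has mixed signs after normalization")
  list(lambda = Re(lambda), w = pmax(w, 0) / sum(pmax(w, 0)))
}

#' Asymptotic annual growth rate
#'
#' The dominant eigenvalue (spectral radius) of the projection matrix:
#' the long-run multiplicative growth rate per year of the linear model.
#'
#' @param x a `"matrix_bundle"`, a `"vital_rates"` object, a plain
#'   nonnegative matrix, or a `"recovery_model"`.
#' @param ... unused.
#' @return A single real number.
#' @export
growth_rate <- function(x, ...) UseMethod("growth_rate")

#' @export
growth_rate.matrix <- function(x, ...) .dominant_eigen(x)$lambda

#' @export
growth_rate.matrix_bundle <- function(x, ...) .dominant_eigen(x$A)$lambda

#' @export
growth_rate.vital_rates <- function(x, ...)
  growth_rate(projection_matrices(x))

#' Stable stage distribution
#'
#' The dominant right eigenvector of the projection matrix, normalized to
#' sum to 1: the long-run proportion of individuals in each stage.
#'
#' @inheritParams growth_rate
#' @return A nonnegative probability vector of length \eqn{S}.
#' @export
stable_stage <- function(x, ...) UseMethod("stable_stage")

#' @export
stable_stage.matrix <- function(x, ...) .dominant_eigen(x)$w

#' @export
stable_stage.matrix_bundle <- function(x, ...) .dominant_eigen(x$A)$w

#' @export
stable_stage.vital_rates <- function(x, ...)
  stable_stage(projection_matrices(x))

#' Integer initial stage abundances
#'
#' Converts a total (both-sex) census into a female-only integer stage
#' vector: the female count is `floor(total * sex_ratio_female)` and each
#' stage receives its share of the stable (or supplied) stage distribution,
#' rounded half-up entry by entry. With the reference census of 1665 whales,
#' a 1:1 sex ratio and the reference stable distribution this gives 832
#' females in stages (71, 173, 301, 148, 139).
#'
#' @param total total census count (both sexes), nonnegative.
#' @param sex_ratio_female proportion of the census that is female.
#' @param dist probability vector over stages (sums to 1).
#' @return An integer vector of per-stage female abundances.
#' @export
initial_stages <- function(total, sex_ratio_female = 0.5, dist) {
  stopifnot(total >= 0, sex_ratio_female >= 0, sex_ratio_female <= 1)
  if (abs(sum(dist) - 1) > 1e-8)
    stop("`dist` must sum to 1")
  females <- floor(total * sex_ratio_female)
  as.integer(floor(females * dist + 0.5))  # round half-up per entry
}

#' Write the matrices of a bundle to CSV
#'
#' Writes `A`, `U`, `F` and `U_fate` as headered CSV files
#' (`A.csv`, `U.csv`, `F.csv`, `U_fate.csv`) under `dir`.
#'
#' @param bundle a `"matrix_bundle"`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_matrices <- function(bundle, dir) {
  stopifnot(inherits(bundle, "matrix_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- character(0)
  for (nm in c("A", "U", "F", "U_fate")) {
    m <- bundle[[nm]]
    colnames(m) <- paste0("stage", seq_len(ncol(m)))
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(m, p, row.names = FALSE)
    out <- c(out, p)
  }
  invisible(out)
}
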