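# Shared fixtures and independent oracles for the test suite.

whale <- sperm_whale_rates()
whale_bundle <- projection_matrices(whale)
whale_n0 <- c(71L, 173L, 301L, 148L, 139L)

# Table 1 values, kept literal so the tests do not depend on the fixture file.
WHALE_SIGMA <- c(0.9070, 0.9424, 0.9777, 0.9777, 0.9777)
WHALE_GAMMA <- c(0.4732, 0.1151, 0.2586, 0.4920, 0.4920)
WHALE_B <- 0.1250

# A random valid 5-stage vital-rate set (survivorships away from the
# boundaries so fate probabilities are well-conditioned).
random_rates <- function() {
  vital_rates(sigma = runif(5, 0.05, 0.95),
              gamma = runif(5, 0.05, 0.95),
              b = runif(1, 0, 1))
}

# Independent brute-force enumeration of the one-step outcome distribution
# for a tiny population. Works directly from the vital rates: each
# individual of stage j independently stays (sigma*(1-gamma)), advances
# (sigma*gamma) or dies, and each individual of the birth stage
# independently produces one stage-1 offspring with probability b.
# Returns a named numeric vector: outcome key "n1,n2,..." -> probability.
enumerate_step <- function(n, rates) {
  S <- rates$S
  P <- rates$sigma * (1 - rates$gamma)
  G <- rates$sigma * rates$gamma
  dist <- stats::setNames(1, paste(rep(0L, S), collapse = ","))
  convolve_option <- function(dist, options) {
    out <- new.env(parent = emptyenv())
    for (key in names(dist)) {
      base <- as.integer(strsplit(key, ",")[[1]])
      for (o in options) {
        v <- base + o$add
        k <- paste(v, collapse = ",")
        prev <- if (is.null(out[[k]])) 0 else out[[k]]
        out[[k]] <- prev + dist[[key]] * o$p
      }
    }
    vals <- as.list(out)
    stats::setNames(as.numeric(unlist(vals)), names(vals))
  }
  zero <- rep(0L, S)
  for (j in seq_len(S)) {
    stay <- zero; stay[j] <- 1L
    adv <- zero; adv[rates$advance_to[j]] <- 1L
    opts <- list(list(add = stay, p = P[j]),
                 list(add = adv, p = G[j]),
                 list(add = zero, p = 1 - rates$sigma[j]))
    for (i in seq_len(n[j])) dist <- convolve_option(dist, opts)
  }
  if (rates$b > 0) {
    birth <- zero; birth[rates$birth_to] <- 1L
    opts <- list(list(add = birth, p = rates$b),
                 list(add = zero, p = 1 - rates$b))
    for (i in seq_len(n[rates$birth_from])) dist <- convolve_option(dist, opts)
  }
  dist
}

# Chi-square statistic of observed outcome keys against an enumerated
# distribution, pooling outcomes with expected count < 5 into one category
# (dropped when its expected probability is zero). Returns the statistic
# and its degrees of freedom.
chisq_vs_enumeration <- function(keys, exact, K) {
  main <- names(exact)[exact * K >= 5]
  p_other <- 1 - sum(exact[main])
  obs <- tabulate(factor(keys, levels = main), nbins = length(main))
  expv <- exact[main] * K
  if (p_other > 1e-12) {
    obs <- c(obs, sum(!keys %in% main))
    expv <- c(expv, p_other * K)
  }
  list(stat = sum((obs - expv)^2 / expv), df = length(obs) - 1L)
}

# Draw K one-step outcomes of the stochastic engine from a fixed start,
# returned as a K x S matrix (uses the public one-year simulation surface).
draw_one_step <- function(n0, rates, K, seed) {
  m <- recovery_model(rates, n0 = n0)
  simulate(m, nsim = K, seed = seed, years = 1)$final
}
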