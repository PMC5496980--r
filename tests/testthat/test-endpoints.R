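test_that("recovery probability handles trivial and reproducible cases", {
  m <- recovery_model(whale, disturbance(0, 0, 0, shape = "srf"))
  # threshold zero is met by every replicate, recovered or not
  r0 <- suppressWarnings(
    recovery_probability(m, years = 5, reps = 50, threshold = 0, seed = 1))
  expect_equal(r0$phi, 1)
  # identical config + seed gives identical results including the tally
  sc <- disturbance(0.05, 10, 20)
  ms <- recovery_model(whale, sc)
  r1 <- recovery_probability(ms, years = 50, reps = 1000, seed = 4)
  r2 <- recovery_probability(ms, years = 50, reps = 1000, seed = 4)
  expect_identical(r1$recovered, r2$recovered)
  expect_identical(r1$phi, r2$phi)
  expect_equal(r1$recovered + (r1$reps - r1$recovered), r1$reps)
  expect_true(r1$phi >= 0 && r1$phi <= 1)
  # small replicate counts warn about Monte-Carlo error
  expect_warning(recovery_probability(ms, years = 5, reps = 10, seed = 1),
                 "Monte-Carlo")
})

test_that("phi is monotone in disturbance magnitude and duration", {
  # common random numbers: same master seed across grid points
  phis_eps <- vapply(c(0.02, 0.05, 0.08), function(e0) {
    m <- recovery_model(whale, disturbance(e0, 10, 20))
    recovery_probability(m, years = 100, reps = 1000, seed = 21)$phi
  }, numeric(1))
  expect_true(all(diff(phis_eps) <= 0.02))

  phis_tc <- vapply(c(5, 10, 20), function(tc) {
    m <- recovery_model(whale, disturbance(0.05, tc, tc + 10))
    recovery_probability(m, years = 100, reps = 1000, seed = 22)$phi
  }, numeric(1))
  expect_true(all(diff(phis_tc) <= 0.02))
})

test_that("step-function endpoints bound the sigmoid endpoint", {
  phi_of <- function(sc) recovery_probability(recovery_model(whale, sc),
                                              years = 100, reps = 1000,
                                              seed = 31)$phi
  for (e0 in c(0.05, 0.06)) {
    lo <- phi_of(disturbance(e0, 20, shape = "srf"))  # reduced until t_end
    mid <- phi_of(disturbance(e0, 10, 20, shape = "crf"))
    hi <- phi_of(disturbance(e0, 10, shape = "srf"))  # recovers at t_critical
    expect_lte(lo, mid + 0.03)
    expect_lte(mid, hi + 0.03)
  }
})

test_that("lethal impacts outweigh even total sublethal impacts", {
  surv <- recovery_model(whale, disturbance(0.06, 10, 20))
  fec <- recovery_model(whale, disturbance(1, 10, 20, target = "fecundity"))
  phi_s <- recovery_probability(surv, years = 100, reps = 1000, seed = 41)$phi
  phi_f <- recovery_probability(fec, years = 100, reps = 1000, seed = 41)$phi
  expect_lt(phi_s, phi_f)
  expect_equal(phi_f, 1)
})

test_that("mean recovery time uses first passage over qualifying replicates", {
  # certain survival-in-place plus certain birth per mature female:
  # the population grows every year, so every replicate first reaches the
  # starting total at t = 1
  grow <- vital_rates(rep(1, 5), rep(0, 5), 1)
  m <- recovery_model(grow, n0 = c(10L, 10L, 10L, 10L, 10L))
  r <- suppressWarnings(mean_recovery_time(m, years = 5, reps = 20, seed = 1))
  expect_equal(r$mean_recovery_time, 1)
  expect_equal(r$n_recovery_time, 20L)

  # no replicate can qualify when the threshold is unreachable
  frozen <- vital_rates(rep(1, 5), rep(0, 5), 0)
  mf <- recovery_model(frozen, n0 = c(10L, 0L, 0L, 0L, 0L))
  expect_error(suppressWarnings(
    mean_recovery_time(mf, years = 5, reps = 20, threshold = 50, seed = 1)),
    "no replicate")

  # the sigmoid mean recovery time falls between its two step-function bounds
  mrt_of <- function(sc) suppressWarnings(
    mean_recovery_time(recovery_model(whale, sc), years = 500, reps = 500,
                       seed = 51))$mean_recovery_time
  t_lo <- mrt_of(disturbance(0.05, 10, shape = "srf"))
  t_mid <- mrt_of(disturbance(0.05, 10, 20, shape = "crf"))
  t_hi <- mrt_of(disturbance(0.05, 20, shape = "srf"))
  expect_lte(t_lo, t_mid + 2)
  expect_lte(t_mid, t_hi + 2)

  # a harsher disturbance does not shorten the recovery (common seeds)
  t_worse <- suppressWarnings(
    mean_recovery_time(recovery_model(whale, disturbance(0.07, 10, 20)),
                       years = 500, reps = 500, seed = 51))$mean_recovery_time
  expect_gte(t_worse, t_mid - 2)
})

test_that("sweep grids cover the axes and reduce to single calls", {
  m <- recovery_model(whale, disturbance(0.05, 10, 20))
  g1 <- sweep_grid(m, years = 50, reps = 1000, seed = 61)
  expect_equal(nrow(g1), 1L)
  single <- recovery_probability(m, years = 50, reps = 1000, seed = 61)
  expect_equal(g1$phi, single$phi)

  g <- sweep_grid(m, t_critical = c(5, 10, 15, 20), years = 100,
                  reps = 1000, seed = 62)
  expect_equal(nrow(g), 4L)
  expect_equal(g$t_critical, c(5, 10, 15, 20))
  # t_end keeps its 10-year offset from t_critical
  # phi is non-increasing in the duration within Monte-Carlo noise
  expect_true(all(diff(g$phi) <= 0.03))
})
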