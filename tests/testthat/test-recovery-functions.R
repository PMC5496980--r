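test_that("sigmoid coefficients solve the boundary constraints", {
  # zero reduction forces zero coefficients
  cf0 <- sigmoid_coefficients(disturbance(0, 10, 20))
  expect_equal(cf0$a, 0)
  expect_equal(cf0$d, 0)

  # closed-form oracle for the 2x2 system, midpoint policy (t_m = 15):
  # a = eps0 / (f(tc) - f(te)), d = a * f(te) with f(x) = 1/(1+exp(x-15))
  f <- function(x) 1 / (1 + exp(x - 15))
  a_hand <- 0.05 / (f(10) - f(20))
  d_hand <- a_hand * f(20)
  cf <- sigmoid_coefficients(disturbance(0.05, 10, 20, tm_policy = "midpoint"))
  expect_equal(cf$t_m, 15)
  expect_equal(cf$a, a_hand, tolerance = 1e-10)
  expect_equal(cf$d, d_hand, tolerance = 1e-10)
  expect_equal(sigmoid_coefficients(disturbance(0.05, 10, 20,
                                                tm_policy = "literal"))$t_m, 5)

  # boundary constraints hold to 1e-12 for random valid scenarios,
  # under both inflection policies
  set.seed(7)
  for (i in 1:20) {
    tc <- runif(1, 0, 30)
    te <- tc + runif(1, 1, 25)
    e0 <- runif(1, 0.01, 0.5)
    for (pol in c("midpoint", "literal")) {
      d <- disturbance(e0, tc, te, tm_policy = pol)
      expect_lt(abs(epsilon_at(d, tc) - e0), 1e-12)
      expect_lt(abs(epsilon_at(d, te)), 1e-12)
    }
  }
})

test_that("recovery functions follow their branch definitions", {
  crf <- disturbance(0.05, 10, 20)
  srf <- disturbance(0.05, 10, shape = "srf")
  expect_equal(epsilon_at(crf, 0), 0.05)     # full reduction from the event
  expect_equal(epsilon_at(crf, 9.99), 0.05)
  expect_equal(epsilon_at(crf, 21), 0)       # fully recovered after t_end
  expect_equal(epsilon_at(srf, 9.99), 0.05)
  expect_equal(epsilon_at(srf, 10), 0)       # step drops at t_critical
  expect_error(epsilon_at(crf, -1), "negative")

  # a CRF with t_end = t_critical degenerates to the step function
  inst <- disturbance(0.3, 5, 5)
  expect_equal(epsilon_at(inst, c(4.9, 5)), c(0.3, 0))

  # monotone non-increasing over the recovery window for both policies
  tgrid <- seq(10, 20, by = 0.1)
  for (pol in c("midpoint", "literal")) {
    e <- epsilon_at(disturbance(0.05, 10, 20, tm_policy = pol), tgrid)
    expect_true(all(diff(e) <= 1e-12))
    expect_true(all(e >= 0 & e <= 0.05 + 1e-12))
  }
})

test_that("step functions bound the sigmoid pointwise", {
  e0 <- 0.07
  crf <- disturbance(e0, 10, 20)
  srf_lo <- disturbance(e0, 10, shape = "srf")   # recovers at t_critical
  srf_hi <- disturbance(e0, 20, shape = "srf")   # reduced until t_end
  tgrid <- seq(0, 30, by = 0.25)
  ec <- epsilon_at(crf, tgrid)
  expect_true(all(epsilon_at(srf_lo, tgrid) <= ec + 1e-12))
  expect_true(all(ec <= epsilon_at(srf_hi, tgrid) + 1e-12))
})

test_that("rate perturbation scales the targeted rates only", {
  sc <- disturbance(0.06, 10, 20, c1 = 2, c2 = 2)
  # no reduction leaves the rates untouched
  expect_equal(perturb_rates(whale, 0, sc), whale)
  p <- perturb_rates(whale, 0.05, sc)
  expect_equal(p$sigma[3], 0.9777 * 0.95)          # adult: 1 - eps
  expect_equal(p$sigma[1], 0.9070 * 0.90)          # juvenile: 1 - 2 eps
  expect_equal(p$sigma[2], 0.9424 * 0.90)
  expect_identical(p$gamma, whale$gamma)           # transitions untouched
  expect_equal(p$b, whale$b)                       # survival target only
  # full sublethal impact wipes out fecundity, survival untouched
  fec <- perturb_rates(whale, 1, disturbance(1, 10, target = "fecundity"))
  expect_equal(fec$b, 0)
  expect_identical(fec$sigma, whale$sigma)
  # "both" extension reduces both at once
  both <- perturb_rates(whale, 0.1, disturbance(0.1, 10, target = "both"))
  expect_equal(both$b, 0.1250 * 0.9)
  expect_equal(both$sigma[4], 0.9777 * 0.9)
  # violated c_j * eps <= 1 precondition is signalled
  expect_error(perturb_rates(whale, 0.6,
                             disturbance(0.1, 10, c1 = 2, c2 = 2)),
               "negative")
})

test_that("the time-varying matrix composes reduction and assembly", {
  sc <- disturbance(0.05, 10, 20, c1 = 2, c2 = 2)
  # after full recovery the pre-event bundle returns bit-identically
  expect_identical(matrix_at(whale, sc, 25)$A, whale_bundle$A)
  expect_identical(matrix_at(whale, disturbance(0, 0, 0, shape = "srf"),
                             3)$A, whale_bundle$A)
  # at t = t_critical the matrix matches an independently hand-built one
  eps <- epsilon_at(sc, 10)
  s <- WHALE_SIGMA * (1 - c(2, 2, 1, 1, 1) * eps)
  P <- s * (1 - WHALE_GAMMA); G <- s * WHALE_GAMMA
  A_hand <- matrix(0, 5, 5)
  diag(A_hand) <- P
  A_hand[2, 1] <- G[1]; A_hand[3, 2] <- G[2]; A_hand[4, 3] <- G[3]
  A_hand[5, 4] <- G[4]; A_hand[3, 5] <- G[5]
  A_hand[1, 3] <- WHALE_B
  expect_equal(matrix_at(whale, sc, 10)$A, A_hand)
  # perturbed fate columns still sum exactly to one
  for (t in c(0, 5, 10, 15, 20)) {
    expect_identical(colSums(matrix_at(whale, sc, t)$U_fate), rep(1, 5))
  }
})

test_that("scenario invariants are enforced at construction", {
  expect_error(disturbance(1.5, 10), "epsilon0")
  expect_error(disturbance(0.4, 10, c1 = 3), "c1")
  expect_error(disturbance(0.05, 10, t_end = 5), "t_end")
  expect_error(disturbance(0.05, -1), "t_critical")
  # c_j constraint not applied to fecundity-only scenarios
  expect_s3_class(disturbance(0.9, 10, c1 = 2, target = "fecundity"),
                  "disturbance")
})
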