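test_that("linear steady state is proportional to dose and epsilon-shifted", {
  p <- linearParams("slow")
  expect_equal(steadyStateLinear(p, 0.4)$H_eq, HEQ_STEP04_SLOW,
               tolerance = 1e-8)
  expect_equal(steadyStateLinear(p, 0)$H_eq, 0)
  # linearity in I with epsilon = 0
  I <- c(0.1, 0.25, 1, 4)
  expect_equal(steadyStateLinear(p, 2 * I)$H_eq,
               2 * steadyStateLinear(p, I)$H_eq)
  # perfect adaptation in the integral limit, for any dose
  p0 <- feedbackParams("linear", mu_prime = 0)
  expect_equal(steadyStateLinear(p0, c(0.1, 1, 10))$H_eq, rep(0, 3))
  expect_error(steadyStateLinear(nonlinearParams(), 0.1), "linear-family")
})

test_that("saturating-transcription closed form matches the exact root", {
  ts <- saturatingParams()           # epsilon = 0, K = 0.01
  Z <- derivedConstants(ts)$Z
  expect_equal(Z, 41.63, tolerance = 1e-3)
  I <- c(1e-4, 0.01, 0.1, 1, 10, 60)
  closed <- steadyStateNonlinear(ts, I, method = "saturating")
  exact <- steadyStateNonlinear(ts, I, method = "exact")
  expect_equal(closed$H_eq, exact$H_eq, tolerance = 1e-10)
  expect_equal(closed$A_eq, exact$A_eq, tolerance = 1e-10)

  # low-dose limit H ~ I K / Z
  low <- steadyStateNonlinear(ts, 0.1, method = "low_dose")
  expect_equal(low$H_eq, 0.1 * 0.01 / Z, tolerance = 1e-12)
  expect_equal(low$H_eq, 2.4e-5, tolerance = 0.02)
  expect_equal(low$H_eq, exact$H_eq[I == 0.1][1], tolerance = 0.01)

  # high-dose limit H ~ I - Z, approached from below as I/Z grows
  I_hi <- Z * c(3, 10, 50)
  gap <- abs(steadyStateNonlinear(ts, I_hi, method = "exact")$H_eq -
               (I_hi - Z))
  expect_true(all(diff(gap) < 0))
  expect_lt(gap[3] / Z, 1e-2)
  hi <- steadyStateNonlinear(ts, I_hi[3], method = "high_dose")
  expect_equal(hi$A_eq, ts$gamma * ts$gamma_prime / (ts$mu * ts$mu_prime))
})

test_that("nonlinear low-dose steady state is sublinear and flagged honestly", {
  nl <- nonlinearParams()
  sigma <- derivedConstants(nl)$sigma
  expect_equal(sigma, 2.4023e-6, tolerance = 1e-4)
  low <- steadyStateNonlinear(nl, 0, method = "low_dose")
  expect_equal(low$H_eq, (-sigma + sqrt(sigma^2 + 4 * sigma * 0.06)) / 2)
  expect_equal(low$H_eq, 3.80e-4, tolerance = 5e-3)
  exact <- steadyStateNonlinear(nl, 0, method = "exact")
  expect_equal(exact$H_eq, HEQ_NL_BASAL, tolerance = 1e-6)
  expect_equal(low$H_eq, exact$H_eq, tolerance = 0.05)
  expect_equal(low$A_eq, exact$A_eq, tolerance = 0.05)
  expect_true(low$valid)
  expect_false(steadyStateNonlinear(nl, 0.4, method = "low_dose")$valid)
  # epsilon = 0, I = 0 degenerates to the origin
  nl0 <- feedbackParams("nonlinear", epsilon = 0, beta = 10, gamma = 0.1,
                        gamma_prime = 0.005, mu = log(2) / 40,
                        mu_prime = log(2) / 100, K = 0.01, W = 0.01)
  expect_equal(steadyStateNonlinear(nl0, 0, method = "low_dose")$H_eq, 0)

  # sublinearity: H_eq / I and A_eq / I strictly decreasing on (0, 1]
  I <- seq(0.05, 1, length.out = 12)
  ss <- steadyStateNonlinear(nl, I, method = "exact")
  expect_true(all(diff(ss$H_eq / I) < 0))
  expect_true(all(diff(ss$A_eq / I) < 0))
})

test_that("integral feedback locks ramps onto a rate-proportional plateau", {
  p <- integralParams("fast")
  rr <- rampResponseIntegral(p, 1.1e-3, t = c(0, 1000))
  expect_equal(rr$H_plateau, 0.0115, tolerance = 2e-3)
  expect_equal(rampResponseIntegral(p, 2.2e-3)$H_plateau, 2 * rr$H_plateau)
  expect_equal(rampResponseIntegral(p, 0)$H_plateau, 0)

  # long-ramp simulation settles onto the plateau
  tr <- simulateModel(p, rampProtocol(1.1e-3, amplitude = 20,
                                      horizon = 20 / 1.1e-3))
  late <- tr$H[tr$time > 8000 & tr$time < 20 / 1.1e-3]
  expect_lt(max(abs(late / rr$H_plateau - 1)), 0.01)
  # and A grows linearly at alpha delta / beta
  lateA <- tr$A[tr$time > 8000 & tr$time < 20 / 1.1e-3]
  slopeA <- diff(range(lateA)) / diff(range(tr$time[tr$time > 8000 &
                                                      tr$time < 20 / 1.1e-3]))
  expect_equal(slopeA, p$alpha * 1.1e-3 / p$beta, tolerance = 0.01)
})

test_that("the maximal tolerable ramp rate separates adaptation from arrest", {
  p <- integralParams("fast")
  dm <- deltaMax(p, H_tox = 0.49)
  expect_equal(dm, 0.49 * 5 * 0.53 * 0.01 / (log(2) / 2.5), tolerance = 1e-12)
  expect_equal(dm, 0.0468, tolerance = 1e-3)
  expect_equal(deltaMax(p, 0), 0)
  # linear scaling in beta
  p2 <- integralParams("fast"); p2$beta <- 2 * p$beta
  expect_equal(deltaMax(p2, 0.49), 2 * dm)

  # simulated ramps: sub-threshold rate stays below H_tox, super exceeds it
  for (fac in c(0.9, 1.1)) {
    tr <- simulateModel(p, rampProtocol(fac * dm, amplitude = 100,
                                        horizon = 100 / (fac * dm)))
    late <- max(tr$H[tr$time > 1500])
    if (fac < 1) expect_lt(late, 0.49) else expect_gt(late, 0.49)
  }
})

test_that("linear-variant ramps grow at the quasi-static equilibrium rate", {
  p <- linearParams("slow")
  h <- rampResponseLinear(p, 1.1e-3, 2000)
  expect_equal(h, 0.163, tolerance = 2e-3)
  # the late-time growth rate equals dH_eq/dI times delta
  slope_eq <- diff(steadyStateLinear(p, c(0, 1))$H_eq)
  expect_equal(rampResponseLinear(p, 1.1e-3, 1) -
                 rampResponseLinear(p, 1.1e-3, 0), slope_eq * 1.1e-3)
  expect_equal(rampResponseLinear(p, 0, 2000), 0)

  # simulated late-time growth rate matches the closed form (< 2%); the
  # simulated value carries a constant feedback-delay offset, the rate does
  # not
  tr <- simulateModel(p, rampProtocol(1.1e-3, amplitude = 3,
                                      horizon = 3 / 1.1e-3))
  h_at <- function(tt) tr$H[which.min(abs(tr$time - tt))]
  slope_sim <- (h_at(2400) - h_at(1400)) / 1000
  expect_equal(slope_sim, slope_eq * 1.1e-3, tolerance = 0.02)
})

test_that("the absolute adaptation concentration balances the rate constants", {
  p <- linearParams("slow")
  Htox <- 0.54
  expect_equal(iAbs(p, Htox), Htox * (1 + 5 * 0.03 * 0.01 /
                                        (log(2) / 40 * log(2) / 100)))
  expect_equal(iAbs(p, Htox), 7.28, tolerance = 1e-3)
  # no scavenging: adaptation limit collapses onto the toxic level
  p0 <- linearParams("slow"); p0$beta <- 0
  expect_equal(iAbs(p0, Htox), Htox)
  expect_error(iAbs(integralParams("slow"), 0.5), "undefined")

  # slow-ramp asymptote, clipped at zero beyond I_abs
  d <- isoToleranceAsymptote(p, Htox, c(0, 7.28, 10))
  expect_equal(d[1], p$mu_prime * iAbs(p, Htox))
  expect_equal(d[3], 0)
})
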