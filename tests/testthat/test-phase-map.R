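test_that("toxicity calibration reproduces the dense-integration peak", {
  expect_equal(htox_of("slow"), HMAX_STEP06_SLOW, tolerance = 1e-6)
  expect_true(htox_of("slow") > 0.45 && htox_of("slow") < 0.60)
  # faster transcript turnover truncates the transient peak
  expect_equal(htox_of("fast"), HMAX_STEP06_FAST, tolerance = 1e-6)
  expect_lt(htox_of("fast"), htox_of("slow"))
  # without scavenging the step relaxes to its amplitude
  p0 <- linearParams("slow"); p0$beta <- 0
  expect_equal(calibrateHtox(p0, horizon = 2000), 0.6, tolerance = 1e-6)
})

test_that("peak stress grid is monotone in amplitude and in rate", {
  p <- linearParams("slow")
  pd <- hmaxGrid(p, I_values = c(0.2, 0.6, 2, 6),
                 delta_values = c(1e-4, 1e-3, 1e-2), H_tox = htox_of("slow"))
  M <- pd$H_max
  step_col <- vapply(pd$I, function(I) hmaxRamp(p, I, Inf), 0)
  full <- cbind(M, step = step_col)
  expect_true(all(apply(full, 2, diff) > -1e-9))    # nondecreasing in I
  expect_true(all(t(apply(full, 1, diff)) > -1e-9)) # nondecreasing in rate
  # quasi-static limit: the slowest ramps track the equilibrium curve from
  # above, offset by the rate-proportional feedback lag
  heq <- steadyStateLinear(p, pd$I)$H_eq
  expect_true(all(M[, 1] > heq))
  expect_lt(max(M[, 1] - heq), 5e-3)
  # step column equals the step-protocol peaks by construction
  expect_equal(unname(step_col[pd$I == 0.6]), htox_of("slow"),
               tolerance = 1e-6)
  df <- as.data.frame(pd)
  expect_true(all(df$adapted_bool == (df$H_max_mM < htox_of("slow"))))
})

test_that("adaptation boundary spans the step limit and the slow-ramp limit", {
  p <- linearParams("slow")
  Htox <- htox_of("slow")
  expect_equal(adaptationBoundary(p, Htox, Inf), 0.6, tolerance = 2e-3)
  I_slow <- adaptationBoundary(p, Htox, 1e-4)
  expect_equal(I_slow, iAbs(p, Htox), tolerance = 0.01)
  I_mid <- adaptationBoundary(p, Htox, 1e-2)
  expect_true(I_slow >= I_mid && I_mid >= 0.6 - 2e-3)

  # integral feedback has no amplitude limit below delta_max: open bound
  pi <- integralParams("fast")
  dm <- deltaMax(pi, 0.49)
  open <- adaptationBoundary(pi, 0.49, 0.5 * dm, I_range = c(0.01, 20))
  expect_true(isTRUE(attr(open, "open")))
})

test_that("slow ramping extends the adaptation limit more than tenfold", {
  for (set in c("slow", "fast")) {
    p <- linearParams(set)
    Htox <- htox_of(set)
    ratio <- adaptationBoundary(p, Htox, 1e-4) /
      adaptationBoundary(p, Htox, Inf)
    expect_gt(ratio, 10)
  }
})

test_that("the slow-ramp boundary slope is the protein dilution rate", {
  p <- linearParams("slow")
  Htox <- htox_of("slow")
  d1 <- p$mu_prime / 10; d2 <- p$mu_prime / 20
  I1 <- adaptationBoundary(p, Htox, d1, tol = 2e-4)
  I2 <- adaptationBoundary(p, Htox, d2, tol = 2e-4)
  slope <- (d1 - d2) / (I2 - I1)
  expect_equal(slope, p$mu_prime, tolerance = 0.1)
})

test_that("pretreatment leaves linear peaks unchanged but lowers nonlinear ones", {
  p <- linearParams("slow")
  res <- lapply(c(0, 0.2), function(I0)
    pretreatmentPeak(p, I0, delta_I = 0.6, t_challenge = 2000,
                     rtol = 1e-11, atol = 1e-14))
  inc <- vapply(res, function(r) r$H_max_challenge - r$H_eq_pre, 0)
  expect_lt(abs(inc[2] - inc[1]) / inc[1], 1e-8)
  # naive pretreatment reduces to the plain step peak
  expect_equal(res[[1]]$H_max_challenge, htox_of("slow"), tolerance = 1e-4)

  # nonlinear variant: the internal burst above the pretreatment baseline
  # shrinks strictly with the pretreatment level
  nl <- nonlinearParams()
  bursts <- vapply(c(0, 0.1, 0.2, 0.4), function(I0) {
    r <- pretreatmentPeak(nl, I0, delta_I = 0.1)
    r$H_max_challenge - r$H_eq_pre
  }, 0)
  expect_true(all(diff(bursts) < 0))
})

test_that("acquired tolerance shifts the challenge threshold only when scavenging saturates", {
  nl <- nonlinearParams()
  Htox_nl <- peakInternal(simulateModel(nl, stepProtocol(0.6, horizon = 600)))$H_max
  thr_naive <- toleranceThreshold(nl, 0, Htox_nl, dI_range = c(0.01, 4),
                                  tol = 5e-3)
  thr_pre <- toleranceThreshold(nl, 0.2, Htox_nl, dI_range = c(0.01, 4),
                                tol = 5e-3)
  expect_gt(thr_pre, thr_naive + 0.05)
  expect_equal(thr_naive, 0.6, tolerance = 0.05)

  p <- linearParams("slow")
  Htox <- htox_of("slow")
  lin_naive <- toleranceThreshold(p, 0, Htox, dI_range = c(0.01, 4),
                                  tol = 5e-3)
  lin_pre <- toleranceThreshold(p, 0.2, Htox, dI_range = c(0.01, 4),
                                tol = 5e-3)
  # superposition bounds the linear shift by the pretreatment equilibrium
  expect_lt(abs(lin_pre - lin_naive),
            steadyStateLinear(p, 0.2)$H_eq + 2e-2)

  expect_equal(as.character(fateCall(c(0.3, 0.7), 0.59)),
               c("adapted", "arrested"))
})
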