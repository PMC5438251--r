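test_that("a resting system under zero input stays identically at rest", {
  p <- linearParams("slow")
  tr <- simulateModel(p, constantProtocol(0, 500))
  expect_true(all(tr$H == 0) && all(tr$A == 0) && all(tr$A_mRNA == 0))
  pk <- peakInternal(tr)
  expect_equal(pk$H_max, 0)
})

test_that("step responses settle onto the closed-form equilibria", {
  p <- linearParams("slow")
  tr <- simulateModel(p, stepProtocol(0.4, horizon = 5000))
  expect_equal(tail(tr$H, 1), HEQ_STEP04_SLOW, tolerance = 1e-5)
  expect_equal(tail(tr$H, 1), steadyStateLinear(p, 0.4)$H_eq,
               tolerance = 1e-6)

  # perfect adaptation of the integral variant
  tri <- simulateModel(integralParams("fast"), stepProtocol(0.4, horizon = 5000))
  expect_lt(abs(tail(tri$H, 1)), 1e-6)
})

test_that("peak extraction matches the dense-integration oracle", {
  p <- linearParams("slow")
  tr <- simulateModel(p, stepProtocol(0.6, horizon = 1000))
  pk <- peakInternal(tr)
  expect_equal(pk$H_max, HMAX_STEP06_SLOW, tolerance = 1e-6)
  expect_true(pk$H_max > 0.45 && pk$H_max < 0.60)
  expect_lt(pk$H_max, 0.6)  # dH/dt <= alpha (I - H) bounds H below I

  expect_error(peakInternal(tr, window = c(500, 400)), "empty")
  expect_error(peakInternal(tr, window = c(-10, 50)), "span")
})

test_that("solver tolerances are converged on the peak benchmark", {
  p <- linearParams("slow")
  proto <- stepProtocol(0.6, horizon = 1000)
  h1 <- peakInternal(simulateModel(p, proto, rtol = 1e-8))$H_max
  h2 <- peakInternal(simulateModel(p, proto, rtol = 5e-9))$H_max
  expect_lt(abs(h2 / h1 - 1), 5e-4)
})

test_that("numeric steady states agree with the analytics across doses", {
  p <- linearParams("slow")
  for (I in c(0, 0.05, 0.4, 2, 10)) {
    ss <- steadyStateNumeric(p, I)
    cf <- steadyStateLinear(p, I)
    expect_equal(ss[["H"]], cf$H_eq, tolerance = 1e-8)
    expect_equal(ss[["A"]], cf$A_eq, tolerance = 1e-8)
  }
  expect_equal(unname(steadyStateNumeric(p, 0)), c(0, 0, 0))

  nl <- nonlinearParams()
  ss <- steadyStateNumeric(nl, 0)
  expect_equal(ss[["H"]], HEQ_NL_BASAL, tolerance = 1e-6)
  # cross-validate the root against long-horizon integration
  tr <- simulateModel(nl, constantProtocol(0, 4000),
                      initial = c(1e-4, 0, 0))
  expect_equal(tail(tr$H, 1), ss[["H"]], tolerance = 1e-6)

  # integral limit: H = 0 with scavenging matched to influx
  ssi <- steadyStateNumeric(integralParams("fast"), 0.4)
  expect_equal(unname(ssi), c(0, 0, 0.4 / 5))
  expect_error(steadyStateNumeric(
    feedbackParams("nonlinear", epsilon = 0, mu_prime = 0, K = 0.01,
                   W = 0.01), 0.4), "no steady state")
})

test_that("linear responses superpose: pretreated and naive challenges match", {
  p <- linearParams("slow")
  horizon <- 1400
  combined <- makePretreatmentProtocol(0.2, delta_I = 0.6,
                                       t_challenge = 400, horizon = horizon)
  # components built on the same breakpoints so output grids coincide
  seg_pre <- data.frame(t_start = c(0, 400), kind = "constant",
                        level = c(0.2, 0.2), rate = 0)
  seg_chal <- data.frame(t_start = c(0, 400), kind = "constant",
                         level = c(0, 0.6), rate = 0)
  args <- list(rtol = 1e-11, atol = 1e-14)
  tr_all <- do.call(simulateModel,
                    c(list(p, combined), args))
  tr_pre <- do.call(simulateModel,
                    c(list(p, stressProtocol(seg_pre, horizon)), args))
  tr_chal <- do.call(simulateModel,
                     c(list(p, stressProtocol(seg_chal, horizon)), args))
  expect_equal(tr_all$time, tr_pre$time)
  scale <- max(abs(tr_all$H))
  expect_lt(max(abs(tr_all$H - (tr_pre$H + tr_chal$H))) / scale, 1e-8)
  expect_lt(max(abs(tr_all$A - (tr_pre$A + tr_chal$A))) /
              max(abs(tr_all$A)), 1e-8)
})

test_that("trajectories export and describe themselves", {
  p <- linearParams("slow")
  tr <- simulateModel(p, stepProtocol(0.4, horizon = 100))
  df <- as.data.frame(tr)
  expect_named(df, c("t_min", "I_mM", "H_mM", "A_mRNA", "A"))
  expect_true(all(diff(df$t_min) > 0))
  # input samples reproduce the protocol exactly at grid points
  expect_identical(df$I_mM, inputConcentration(tr$protocol, df$t_min))
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  writeTrajectory(tr, path)
  back <- read.csv(path)
  expect_equal(back$H_mM, df$H_mM, tolerance = 1e-12)
  expect_output(print(tr), "H_max")
})

test_that("nonlinear trajectories stay in the nonnegative orthant", {
  nl <- nonlinearParams()
  for (proto in list(stepProtocol(0.6, horizon = 1500),
                     rampProtocol(2.2e-3, amplitude = 2, horizon = 2000))) {
    tr <- simulateModel(nl, proto)
    expect_true(min(tr$H, tr$A_mRNA, tr$A) >= -1e4 * tr$atol)
  }
})
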