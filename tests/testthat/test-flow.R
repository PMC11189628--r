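# Flow module: gate calibration, positive fractions, population stats,
# gated two-channel comparisons.

test_that("gate calibration follows the strict nearest-rank rule", {
  ctl <- FlowSample(data.frame(spgfp = 1:1000), "ctl")
  gate <- calibrateGate(ctl, "spgfp", maxPositive = 0.01)
  expect_equal(gateThreshold(gate), 991)
  expect_equal(positiveFraction(ctl, gate), 0.009)

  # exhaustive-enumeration oracle on random samples
  set.seed(3)
  for (r in 1:6) {
    v <- rlnorm(2000, log(50), 0.5)
    g <- calibrateGate(FlowSample(data.frame(spgfp = v)), "spgfp")
    expect_equal(gateThreshold(g), bruteGate(v, 0.01))
    expect_lt(positiveFraction(FlowSample(data.frame(spgfp = v)), g), 0.01)
  }

  # all-constant control: threshold is that constant, zero positives
  cc <- FlowSample(data.frame(spgfp = rep(7, 100)))
  g <- calibrateGate(cc, "spgfp")
  expect_equal(gateThreshold(g), 7)
  expect_equal(positiveFraction(cc, g), 0)

  expect_error(calibrateGate(FlowSample(data.frame(spgfp = numeric())),
                             "spgfp"), "no events")
})

test_that("gate calibration is monotone in the positivity bound", {
  v <- generateFlowSample(5000, seed = 8)$sample
  thr <- vapply(c(0.05, 0.02, 0.01, 0.005, 0.001),
                function(mp) gateThreshold(calibrateGate(v, "spgfp", mp)),
                numeric(1))
  expect_true(all(diff(thr) >= 0))
})

test_that("gates are equivariant under strictly increasing transforms", {
  fs <- generateFlowSample(5000, positiveFraction = 0.1, seed = 4)
  s <- fs$sample
  g1 <- calibrateGate(s, "spgfp")
  f1 <- positiveFraction(s, g1)
  for (tr in list(exp = function(x) exp(x / 500), sqrt = sqrt,
                  affine = function(x) 3 * x + 11)) {
    st <- FlowSample(data.frame(spgfp = tr(s@events$spgfp)))
    g2 <- calibrateGate(st, "spgfp")
    expect_equal(gateThreshold(g2), tr(gateThreshold(g1)), tolerance = 1e-12)
    expect_equal(positiveFraction(st, g2), f1)
  }
})

test_that("positive fractions count events strictly above the gate", {
  gate <- new("GateModel", channel = "spgfp", threshold = 2,
              maxPositive = 0.01, calibrationSampleId = "x")
  expect_equal(positiveFraction(FlowSample(data.frame(spgfp = c(1, 2, 3))),
                                gate), 1 / 3)
  low <- new("GateModel", channel = "spgfp", threshold = 0,
             maxPositive = 0.01, calibrationSampleId = "x")
  expect_equal(positiveFraction(FlowSample(data.frame(spgfp = c(1, 2, 3))),
                                low), 1)
})

test_that("a shifted mixture's positive fraction is recovered", {
  ctl <- generateFlowSample(25000, seed = 31)
  mix <- generateFlowSample(25000, positiveFraction = 0.2, positiveShift = 3,
                            seed = 32)
  gate <- calibrateGate(ctl$sample, "spgfp")
  pf <- positiveFraction(mix$sample, gate)
  se <- sqrt(0.2 * 0.8 / 25000)
  # within 3 binomial SEs, allowing the <1% control leakage
  expect_lt(abs(pf - 0.2), 3 * se + 0.01)
})

test_that("population statistics match a loop oracle and flag low counts", {
  s <- FlowSample(data.frame(spgfp = c(1, 2, 3)))
  st <- populationStats(s, "spgfp", minEvents = 25000)
  expect_equal(st$mean, 2)
  expect_true(st$lowN)

  v <- rlnorm(10000, log(80), 0.3)
  big <- populationStats(FlowSample(data.frame(spgfp = v)), "spgfp",
                         minEvents = 10000)
  expect_equal(big$mean, loopMean(v))
  expect_false(big$lowN)
  expect_identical(big$n, 10000L)
  expect_error(populationStats(FlowSample(data.frame(spgfp = numeric())),
                               "spgfp"), "no events")
  expect_error(populationStats(s, "tmrm"), "not present")
})

test_that("gated splits recover a known second-channel difference", {
  fs <- generateFlowSample(
    25000, positiveFraction = 0.3, positiveShift = 3, seed = 44,
    secondChannel = list(name = "tmrm", negLogMean = log(200),
                         posLogMean = log(150), logSd = 0.2))
  gate <- calibrateGate(generateFlowSample(25000, seed = 45)$sample, "spgfp")
  sp <- splitByGate(fs$sample, gate, "tmrm")
  expect_false(sp$positive$empty)
  delta <- sp$negative$mean - sp$positive$mean
  trueDelta <- exp(log(200) + 0.02) - exp(log(150) + 0.02)
  se <- sqrt(sp$negative$sd^2 / sp$negative$n + sp$positive$sd^2 / sp$positive$n)
  expect_lt(abs(delta - trueDelta), 3 * se + 2)

  # independent channels give equal group means within sampling error
  ind <- generateFlowSample(
    25000, positiveFraction = 0.3, positiveShift = 3, seed = 46,
    secondChannel = list(name = "tmrm", negLogMean = log(200),
                         posLogMean = log(200), logSd = 0.2))
  spI <- splitByGate(ind$sample, gate, "tmrm")
  seI <- sqrt(spI$negative$sd^2 / spI$negative$n +
                spI$positive$sd^2 / spI$positive$n)
  expect_lt(abs(spI$negative$mean - spI$positive$mean), 4 * seI)

  # gate below every event: negative group empty and flagged
  lowGate <- new("GateModel", channel = "spgfp", threshold = 0,
                 maxPositive = 0.01, calibrationSampleId = "x")
  spE <- splitByGate(fs$sample, lowGate, "tmrm")
  expect_true(spE$negative$empty)
  expect_true(is.na(spE$negative$mean))
})

test_that("held-out controls stay near the strict-rule expectation", {
  pf <- vapply(1:200, function(s) {
    ctl <- generateFlowSample(25000, seed = 2 * s)$sample
    held <- generateFlowSample(25000, seed = 2 * s + 1)$sample
    positiveFraction(held, calibrateGate(ctl, "spgfp"))
  }, numeric(1))
  expect_gt(mean(pf), 0.005)
  expect_lt(mean(pf), 0.012)
})
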