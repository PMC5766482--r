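# Stochastic domain kinetics under force protocols.

test_that("Bell rate has the exponential force dependence", {
  expect_equal(bellRate(0.5, 0.3, 0), 0.5)
  expect_equal(bellRate(7.2e-4, 0.3, 100), 1.0658, tolerance = 1e-3)
  expect_equal(bellRate(2, 0, c(0, 50, 500)), rep(2, 3))
  expect_error(bellRate(-1, 0.3, 10), "non-negative")
  # default oxidized pair is calibrated to 1.06 1/s at 100 pN
  rs <- defaultRates()
  expect_equal(bellRate(rs@k0Unfold[["SS_BG"]], rs@dxUnfold[["SS_BG"]],
                        100), 1.06, tolerance = 1e-9)
})

test_that("unfolding dwell times at constant force are exponential", {
  rs <- defaultRates(kIso1 = 0, kIso2 = 0, kFoldBG = 0)
  sim <- simulateEnsemble(2000, "SS_BG", rs, constantForce(100, 30),
                          seed = 3)
  tu <- sim$events$time
  expect_equal(length(tu), 2000)  # everyone unfolds within 30 s
  ks <- stats::ks.test(tu, stats::pexp, 1.06)
  expect_gt(ks$p.value, 0.01)
})

test_that("isomerization branching matches the rate ratio", {
  sim <- simulateEnsemble(3000, "SS_BG", defaultRates(),
                          constantForce(100, 60), seed = 4)
  tab <- table(sim$events$transition)
  nBF <- tab[["iso_BG_BF"]]; nFG <- tab[["iso_BG_FG"]]
  pFG <- nFG / (nBF + nFG)
  se <- sqrt(0.5625 * (1 - 0.5625) / (nBF + nFG))
  expect_lt(abs(pFG - 0.027 / 0.048), 3.5 * se)
})

test_that("rates set to zero suppress their transitions entirely", {
  rs <- defaultRates(kIso1 = 0, kIso2 = 0)
  sim <- simulateEnsemble(500, "SS_BG", rs, constantForce(100, 30),
                          seed = 5)
  expect_false(any(startsWith(sim$events$transition, "iso_")))
})

test_that("buried-disulfide rule: chemistry only after unfolding", {
  rs <- defaultRates(tcepMM = 10)
  sim <- simulateEnsemble(400, "SS_BG", rs, constantForce(100, 40),
                          seed = 6)
  ev <- sim$events
  for (d in unique(ev$domain)) {
    de <- ev[ev$domain == d, ]
    chem <- startsWith(de$transition, "iso_") |
      startsWith(de$transition, "red_")
    if (any(chem)) {
      firstUnfold <- min(de$time[startsWith(de$transition, "unfold_")])
      expect_true(all(de$time[chem] > firstUnfold))
    }
  }
  # Tcep reduction happens and produces RED domains
  expect_true(any(startsWith(ev$transition, "red_")))
})

test_that("refolding is forbidden above the force gate", {
  rs <- defaultRates(kFoldBG = 5, refoldForceMax = 0)
  sim <- simulateEnsemble(200, "SS_BG", rs, constantForce(5, 20), seed = 7)
  expect_false(any(startsWith(sim$events$transition, "refold_")))
  # with a permissive gate the same rates do refold
  rs2 <- defaultRates(kFoldBG = 5, refoldForceMax = 10)
  sim2 <- simulateEnsemble(200, "SS_BG", rs2, constantForce(5, 20),
                           seed = 7)
  expect_true(any(startsWith(sim2$events$transition, "refold_")))
})

test_that("trajectory step sizes are path-additive at constant force", {
  # additive topology: complete trajectories from (FOLDED, SS_BG) to
  # (UNFOLDED, RED) must sum to the reduced unfolding step
  topo <- additiveTopology()
  rs <- defaultRates(kIso1 = 0.5, kIso2 = 0.5, tcepMM = 10, kRed2 = 0.05)
  sim <- simulateEnsemble(150, "SS_BG", rs, constantForce(100, 200),
                          seed = 8, topology = topo)
  target <- predictStepSize(c("FOLDED", "RED"), c("UNFOLDED", "RED"), 100,
                            topology = topo)
  done <- sim$finalStates$domain[sim$finalStates$redox == "RED" &
                                   sim$finalStates$fold == "UNFOLDED"]
  expect_gt(length(done), 50)
  for (d in done) {
    tot <- sum(sim$events$step_nm[sim$events$domain == d])
    expect_equal(tot, target, tolerance = 1e-6)
  }
})

test_that("identical seeds give identical event logs", {
  a <- simulateEnsemble(50, "SS_BG", defaultRates(),
                        triangleWave(0, 120, 0.5, 10), seed = 9)
  b <- simulateEnsemble(50, "SS_BG", defaultRates(),
                        triangleWave(0, 120, 0.5, 10), seed = 9)
  expect_identical(a, b)
  c <- simulateEnsemble(50, "SS_BG", defaultRates(),
                        triangleWave(0, 120, 0.5, 10), seed = 10)
  expect_false(identical(a$events, c$events))
})

test_that("ramp simulations agree with the exponential-integral oracle", {
  k0 <- defaultRates()@k0Unfold[["SS_BG"]]
  sim <- simulateEnsemble(1000, "SS_BG",
                          defaultRates(kIso1 = 0, kIso2 = 0),
                          forceRamp(40, 400), seed = 11)
  Fu <- sim$events$force_pN[startsWith(sim$events$transition, "unfold_")]
  oracle <- meanRampUnfoldingForce(k0, 0.3, 40)
  expect_lt(abs(mean(Fu) - oracle), 2 * stats::sd(Fu) / sqrt(length(Fu)))
  # monotonicity: faster loading -> higher mean unfolding force
  expect_gt(meanRampUnfoldingForce(k0, 0.3, 80),
            meanRampUnfoldingForce(k0, 0.3, 40))
  # most probable force of the reduced default near the printed 182 pN
  kT <- 4.11
  mode <- (kT / 0.3) * log(40 * 0.3 / (5e-6 * kT))
  expect_equal(mode, 181.9, tolerance = 0.05)
  expect_error(meanRampUnfoldingForce(0, 0.3, 40), "positive")
})

test_that("protocols are validated and queried correctly", {
  p <- threePulse(130, 5, 10, 130, 5)
  expect_equal(protocolDuration(p), 20)
  expect_equal(forceAt(p, c(1, 7, 16)), c(130, 0, 130))
  tri <- triangleWave(0, 30, 1, 3)
  expect_equal(forceAt(tri, c(0.5, 1.0, 1.25)), c(30, 0, 15))
  expect_error(constantForce(-5, 10), "non-negative")
  expect_error(forceRamp(-40, 100), "rate > 0")
})
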