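# Synthetic AFM trace generator and its ground-truth linkage.

test_that("noiseless synthesis reproduces the event log exactly", {
  quiet <- noiseModel(sigma = 0, drift = 0, stepResponseMs = 0)
  out <- synthesizeTrace(tetherSpec(8, "SS_BG"), defaultRates(),
                         constantForce(100, 15), quiet, seed = 1)
  st <- detectSteps(out$trace)
  ev <- out$events[out$events$step_nm > 2, ]
  expect_equal(nrow(st), nrow(ev))
  expect_equal(sort(st$size), sort(ev$step_nm), tolerance = 1e-9)
  expect_equal(st$force_pN, rep(100, nrow(st)))
})

test_that("synthesis is deterministic per seed", {
  a <- synthesizeTrace(tetherSpec(6, "SS_BG"), defaultRates(),
                       constantForce(100, 5), noiseModel(), seed = 2)
  b <- synthesizeTrace(tetherSpec(6, "SS_BG"), defaultRates(),
                       constantForce(100, 5), noiseModel(), seed = 2)
  expect_identical(a$trace@extension, b$trace@extension)
  expect_identical(a$events, b$events)
})

test_that("oxidized unfolding events cluster in the first seconds", {
  # at 100 pN the 6 nm unfolding steps appear with rate 1.06 1/s:
  # the fraction within 3 s approximates 1 - exp(-3 * 1.06) = 0.958
  tu <- c()
  for (s in 1:25) {
    out <- synthesizeTrace(tetherSpec(8, "SS_BG"), defaultRates(),
                           constantForce(100, 20), noiseModel(), seed = s)
    ev <- out$events
    tu <- c(tu, ev$time[startsWith(ev$transition, "unfold_")])
  }
  frac3 <- mean(tu < 3)
  se <- sqrt(0.958 * 0.042 / length(tu))
  expect_lt(abs(frac3 - 0.958), 4 * se)
})

test_that("reduced tethers produce a single step population", {
  sizes <- c()
  for (s in 1:15) {
    out <- synthesizeTrace(tetherSpec(8, "RED"), defaultRates(),
                           constantForce(170, 6), noiseModel(), seed = s)
    sizes <- c(sizes, detectSteps(out$trace)$size)
  }
  fit <- fitGaussianMixtureHist(sizes, 1)
  expect_equal(fit$mean, 26.4, tolerance = 1)
})

test_that("drift and smoothing shape the rendered trace", {
  drifty <- noiseModel(sigma = 0, drift = 3, stepResponseMs = 0)
  out <- synthesizeTrace(tetherSpec(1, "RED"),
                         defaultRates(k0UnfoldRed = 0),
                         constantForce(50, 2), drifty, seed = 3)
  # pure drift: extension follows 3 nm/s exactly
  expect_equal(out$trace@extension, 3 * out$trace@time, tolerance = 1e-9)
  expect_error(synthesizeTrace(tetherSpec(1, "RED"), defaultRates(),
                               constantForce(50, 2), noiseModel()),
               "seed")
})

test_that("three-pulse synthesis reproduces refolding kinetics", {
  prot <- threePulse(130, 5, 10, 130, 5)
  rs <- defaultRates(kIso1 = 0, kIso2 = 0)   # disulfide identity fixed
  cnt <- c(unfold = 0, probe = 0)
  for (s in 1:60) {
    out <- synthesizeThreePulse(tetherSpec(1, "SS_BG"), rs, prot,
                                noiseModel(), seed = s)
    cnt["unfold"] <- cnt["unfold"] + out$counts[["unfoldPulse"]]
    cnt["probe"] <- cnt["probe"] + out$counts[["probePulse"]]
  }
  p <- 1 - exp(-0.058 * 10)
  se <- sqrt(p * (1 - p) / cnt[["unfold"]])
  expect_lt(abs(cnt[["probe"]] / cnt[["unfold"]] - p), 3 * se)
})

test_that("no refolding rate means an empty probe pulse", {
  prot <- threePulse(130, 5, 10, 130, 5)
  rs <- defaultRates(kIso1 = 0, kIso2 = 0, kFoldBG = 0, kFoldBF = 0,
                     kFoldRed = 0)
  for (s in 1:10) {
    out <- synthesizeThreePulse(tetherSpec(4, "SS_BG"), rs, prot,
                                noiseModel(), seed = s)
    expect_identical(out$counts[["probePulse"]], 0L)
  }
})

test_that("a domain isomerized to SS_BF refolds and re-unfolds at 10 nm", {
  prot <- threePulse(130, 5, 10, 130, 5)
  # force the BF branch and fast refolding so the pathway is common
  rs <- defaultRates(kIso1 = 5, kIso2 = 0, kFoldBF = 2)
  found <- FALSE
  for (s in 1:30) {
    out <- synthesizeThreePulse(tetherSpec(1, "SS_BG"), rs, prot,
                                noiseModel(), seed = s)
    ev <- out$events
    probe <- ev[ev$time >= 15 & startsWith(ev$transition, "unfold_"), ]
    if (nrow(probe) && any(probe$transition == "unfold_SS_BF")) {
      found <- TRUE
      expect_equal(probe$step_nm[probe$transition == "unfold_SS_BF"][1],
                   predictStepSize(c("FOLDED", "SS_BF"),
                                   c("UNFOLDED", "SS_BF"), 130),
                   tolerance = 1e-9)
      break
    }
  }
  expect_true(found)
})

test_that("quench forces above the refold gate are refused", {
  prot <- threePulse(130, 5, 10, 130, 5, FQuench = 50)
  expect_error(synthesizeThreePulse(tetherSpec(1, "SS_BG"),
                                    defaultRates(), prot, noiseModel(),
                                    seed = 1), "quench force")
})

test_that("incompatible tether states are rejected", {
  rs <- defaultRates()
  rs@k0Unfold <- rs@k0Unfold[c("RED", "SS_BG", "SS_BF")]  # break it
  expect_error(
    suppressWarnings(synthesizeTrace(tetherSpec(2, "SS_FG"), rs,
                                     constantForce(100, 2), noiseModel(),
                                     seed = 1)),
    "incompatible")
})

test_that("batch synthesis writes paired trace and truth files", {
  dir <- tempfile(); dir.create(dir)
  synthesizeBatch(3, tetherSpec(4, "RED"), defaultRates(),
                  constantForce(170, 2), noiseModel(), seed = 4, dir = dir)
  expect_length(list.files(dir, pattern = "^trace_"), 3)
  expect_length(list.files(dir, pattern = "^truth_"), 3)
})
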