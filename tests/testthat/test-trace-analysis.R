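# Step detection, histogram fitting, refolding fractions, fingerprints.

test_that("noiseless staircases are recovered exactly", {
  t <- seq(0, 2, by = 1e-3)
  x <- rep(0, length(t))
  x[t >= 0.5] <- 26.4
  x[t >= 1.2] <- 26.4 + 6.0
  tr <- newTrace(t, x, rep(100, length(t)))
  st <- detectSteps(tr)
  expect_equal(nrow(st), 2)
  expect_equal(st$size, c(26.4, 6.0), tolerance = 1e-9)
  expect_equal(st$time, c(0.5, 1.2), tolerance = 2e-3)
  expect_equal(st$post - st$pre, st$size)
})

test_that("flat noisy traces yield zero step calls", {
  set.seed(5)
  t <- seq(0, 3, by = 1e-3)
  tr <- newTrace(t, rnorm(length(t)), rep(100, length(t)))
  expect_equal(nrow(detectSteps(tr)), 0)
})

test_that("detector rejects short and non-uniform traces", {
  expect_error(detectSteps(newTrace(1:50 / 1000, rnorm(50), rep(1, 50))),
               "100 samples")
  t <- c(seq(0, 0.099, by = 1e-3), 0.2, 0.4, 0.41)
  expect_error(newTrace(t, rnorm(length(t)), rep(1, length(t))),
               "uniform")
})

test_that("steps are recovered at instrument noise levels", {
  # oxidized octamer at 100 pN, sigma = 1 nm, 1 kHz
  tot <- 0; hit <- 0; spurTraces <- 0
  for (s in 1:30) {
    out <- synthesizeTrace(tetherSpec(8, "SS_BG"), defaultRates(),
                           constantForce(100, 20), noiseModel(), seed = s)
    st <- detectSteps(out$trace, minPlateau = 8)
    ev <- out$events[out$events$step_nm > 2, ]
    m <- matchEvents(st, ev)
    tot <- tot + m$truth; hit <- hit + m$matched
    if (m$spurious > 0) spurTraces <- spurTraces + 1
  }
  expect_gt(hit / tot, 0.9)
  expect_lt(spurTraces / 30, 0.2)
})

test_that("Gaussian histogram fit recovers a single population", {
  set.seed(42)
  sizes <- rnorm(496, 26.4, 0.7)
  fit <- fitGaussianMixtureHist(sizes, 1)
  expect_equal(nrow(fit), 1)
  expect_equal(fit$mean, 26.4, tolerance = 0.2)
  expect_gt(fit$sd, 0.4); expect_lt(fit$sd, 1.1)
  expect_equal(attr(fit, "binWidth"), 1)
})

test_that("Gaussian histogram fit separates two populations", {
  set.seed(43)
  sizes <- c(rnorm(300, 6.5, 0.5), rnorm(200, 26.4, 0.7))
  fit <- fitGaussianMixtureHist(sizes, 2)
  expect_equal(fit$mean, c(6.5, 26.4), tolerance = 0.3)
  expect_error(fitGaussianMixtureHist(numeric(0), 1), "at least")
  expect_error(fitGaussianMixtureHist(rnorm(25), 3), "at least")
})

test_that("refolding fraction matches the binomial oracle", {
  set.seed(9)
  N <- 131
  p <- 1 - exp(-0.058 * 10)
  probe <- rbinom(N, 1, p)
  rf <- refoldingFraction(rep(1, N), probe, seed = 2)
  semOracle <- sqrt(p * (1 - p) / N)
  expect_lt(abs(rf$fraction - p), 2 * semOracle)
  expect_equal(rf$sem, semOracle, tolerance = 0.35)
  # degenerate inputs
  z <- refoldingFraction(rep(1, 20), rep(0, 20), seed = 1)
  expect_identical(z$fraction, 0); expect_identical(z$sem, 0)
  one <- refoldingFraction(rep(2, 10), rep(2, 10), seed = 1)
  expect_identical(one$fraction, 1)
  expect_error(refoldingFraction(rep(0, 5), rep(0, 5)), "no unfolding")
})

test_that("repeat-step fingerprint keeps only repeated step sizes", {
  mk <- function(sizes) data.frame(time = seq_along(sizes), size = sizes)
  keep <- fingerprintFilter(list(mk(c(26.3, 26.5, 10.1)), mk(c(26, 10)),
                                 mk(21)), "repeat-step")
  expect_identical(keep, c(TRUE, FALSE, FALSE))
  expect_error(fingerprintFilter(list(), "no-such-mode"))
})

test_that("match-extension fingerprint compares pulse-end extensions", {
  prot <- threePulse(130, 5, 10, 130, 5)
  # a synthesized three-pulse trace reaches the same total extension at
  # the end of both high-force pulses (single tether, no isomerization)
  out <- synthesizeThreePulse(tetherSpec(4, "SS_BG"),
                              defaultRates(kIso1 = 0, kIso2 = 0,
                                           kFoldBG = 2),
                              prot, noiseModel(sigma = 0.3), seed = 3)
  expect_true(fingerprintFilter(list(out$trace), "match-extension")[1])
  # hand-built mismatch: an extra 17 nm level in the probe pulse (an
  # isomerization completing after the unfolding pulse)
  t <- seq(0, 20, by = 1e-3)
  ext <- ifelse(t < 5, 25, ifelse(t < 15, 0, 42))
  bad <- newTrace(t, ext, forceAt(prot, t),
                  metadata = list(protocol = prot))
  expect_false(fingerprintFilter(list(bad), "match-extension")[1])
  expect_error(fingerprintFilter(list(newTrace(t, ext, ext)),
                                 "match-extension"), "three-pulse")
})

test_that("trace CSV/TSV round trips preserve the data", {
  out <- synthesizeTrace(tetherSpec(2, "RED"), defaultRates(),
                         constantForce(170, 1), noiseModel(), seed = 5)
  for (ext in c(".csv", ".tsv")) {
    path <- tempfile(fileext = ext)
    writeTraceCsv(out$trace, path)
    back <- readTraceCsv(path)
    expect_equal(back@extension, out$trace@extension, tolerance = 1e-6)
    expect_equal(back@force, out$trace@force)
  }
  ep <- tempfile(fileext = ".csv")
  writeEventCsv(out$events, ep)
  expect_equal(readEventCsv(ep)$step_nm, out$events$step_nm,
               tolerance = 1e-6)
})
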