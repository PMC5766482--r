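# Polymer elasticity and contour-length arithmetic.

test_that("WLC inversion satisfies the interpolation formula round trip", {
  p <- polymerParams()
  F <- c(1, 5, 20, 100, 170, 500)
  z <- wlcFractionalExtension(F, p)
  expect_equal(wlcForce(z, p), F, tolerance = 1e-9)
  # frozen values computed by independent bisection of the formula
  expect_equal(wlcFractionalExtension(100, p), 0.834684103, tolerance = 1e-6)
  expect_equal(wlcFractionalExtension(170, p), 0.874687601, tolerance = 1e-6)
  expect_identical(wlcFractionalExtension(0, p), 0)
})

test_that("fractional extensions are monotone, bounded and error on F < 0", {
  p <- polymerParams()
  F <- seq(0, 400, by = 2)
  for (fn in list(wlcFractionalExtension, fjcFractionalExtension)) {
    z <- fn(F, p)
    expect_true(all(diff(z) > 0))
    expect_true(all(z >= 0 & z < 1))
    expect_error(fn(-1, p), "non-negative")
  }
  # Langevin function value at 30 pN, b = 1.1 nm (coth(8.03) - 1/8.03)
  expect_equal(fjcFractionalExtension(30, p), 0.8754548, tolerance = 1e-6)
  expect_identical(fjcFractionalExtension(0, p), 0)
  expect_gt(fjcFractionalExtension(5000, p), 0.999)
})

test_that("released residues follow the loop bookkeeping", {
  topo <- disulfideTopology()  # I69 defaults 51 / 11 / 57
  geom <- domainGeometry()
  u <- function(redox) releasedResidues(c("FOLDED", redox),
                                        c("UNFOLDED", redox), topo, geom)
  expect_equal(u("RED"), 88)
  expect_equal(u("SS_BG"), 31)   # 88 - 57
  expect_equal(u("SS_BF"), 37)
  expect_equal(u("SS_FG"), 77)
  expect_equal(releasedResidues(c("UNFOLDED", "SS_BG"),
                                c("UNFOLDED", "SS_FG"), topo, geom), 51)
  expect_equal(releasedResidues(c("UNFOLDED", "SS_BG"),
                                c("UNFOLDED", "SS_BF"), topo, geom), 11)
  expect_equal(releasedResidues(c("UNFOLDED", "SS_BG"),
                                c("UNFOLDED", "RED"), topo, geom), 57)
  # refolding re-sequesters what unfolding released
  expect_equal(releasedResidues(c("UNFOLDED", "RED"), c("FOLDED", "RED"),
                                topo, geom), -88)
  expect_error(releasedResidues(c("FOLDED", "SS_BG"),
                                c("UNFOLDED", "SS_BF")),
               "disallowed.*SS_BG.*SS_BF")
  expect_error(releasedResidues(c("FOLDED", "SS_BG"),
                                c("FOLDED", "SS_BF")), "disallowed")
})

test_that("predicted step sizes reproduce the printed populations", {
  # 51 residues at 100 pN -> 17 nm; 11 residues -> 3.7 nm (the "4 nm"
  # population); reduced unfolding at 170 pN -> 26.4 nm
  expect_equal(predictStepSize(c("UNFOLDED", "SS_BG"),
                               c("UNFOLDED", "SS_FG"), 100),
               17.0, tolerance = 0.05)
  expect_equal(predictStepSize(c("UNFOLDED", "SS_BG"),
                               c("UNFOLDED", "SS_BF"), 100),
               3.67, tolerance = 0.01)
  red170 <- predictStepSize(c("FOLDED", "RED"), c("UNFOLDED", "RED"), 170)
  expect_gt(red170, 25.4); expect_lt(red170, 27.4)
  expect_equal(red170, 26.39, tolerance = 0.01)
  # oxidized unfolding at 100 pN sits in the printed 6 nm population
  expect_equal(predictStepSize(c("FOLDED", "SS_BG"),
                               c("UNFOLDED", "SS_BG"), 100),
               5.95, tolerance = 0.05)
})

test_that("zero-release transitions and bad forces are refused", {
  topoDeg <- disulfideTopology(loopBF = 51, loopFG = 0, loopBG = 57)
  expect_error(predictStepSize(c("UNFOLDED", "SS_BG"),
                               c("UNFOLDED", "SS_BF"), 100,
                               topology = topoDeg), "zero residues")
  expect_error(predictStepSize(c("FOLDED", "RED"), c("UNFOLDED", "RED"),
                               -10), "positive")
})

test_that("step sizes are additive along paths for additive topologies", {
  topo <- additiveTopology()
  for (F in c(30, 100, 170)) {
    viaFG <- predictStepSize(c("FOLDED", "SS_BG"), c("UNFOLDED", "SS_BG"),
                             F, topology = topo) +
      predictStepSize(c("UNFOLDED", "SS_BG"), c("UNFOLDED", "SS_FG"), F,
                      topology = topo) +
      predictStepSize(c("UNFOLDED", "SS_FG"), c("UNFOLDED", "RED"), F,
                      topology = topo)
    viaBF <- predictStepSize(c("FOLDED", "SS_BG"), c("UNFOLDED", "SS_BG"),
                             F, topology = topo) +
      predictStepSize(c("UNFOLDED", "SS_BG"), c("UNFOLDED", "SS_BF"), F,
                      topology = topo) +
      predictStepSize(c("UNFOLDED", "SS_BF"), c("UNFOLDED", "RED"), F,
                      topology = topo)
    direct <- predictStepSize(c("FOLDED", "RED"), c("UNFOLDED", "RED"), F,
                              topology = topo)
    expect_equal(viaFG, direct, tolerance = 1e-9)
    expect_equal(viaBF, direct, tolerance = 1e-9)
  }
})

test_that("parameter containers validate their invariants", {
  expect_error(polymerParams(kT = -1), "positive")
  expect_error(domainGeometry(nExt = 0), "nExt")
  expect_error(disulfideTopology(loopBG = 10), "loopBG")
  expect_error(domainState("HALF", "RED"), "fold")
})
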