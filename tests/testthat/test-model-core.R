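test_that("premature-termination hazard follows the transit-time scaling", {
  expect_identical(ptHazard(SimParams(pPt = 0)), 0)
  p <- SimParams(pPt = 0.1, ptDistance = 2000L)
  expect_equal(ptHazard(p), 0.0025)
  expect_equal(ptHazard(p) * p@dt, 1e-5)       # per-step probability
  expect_equal(ptHazard(SimParams(pPt = 1, ptDistance = 6750L)),
               1 * 50 / 6750)
})

test_that("entrainment ramps linearly from the TSS and saturates", {
  p <- SimParams()
  expect_identical(entrainmentFactor(0, p), 0)
  expect_identical(entrainmentFactor(2000, p), 1)
  expect_identical(entrainmentFactor(5000, p), 1)
  expect_equal(entrainmentFactor(1000, p), 0.5)
  expect_error(entrainmentFactor(-1, p), "transcriptLength")
  # monotone non-decreasing
  lens <- seq(0, 4000, by = 37)
  expect_true(all(diff(entrainmentFactor(lens, p)) >= 0))
  # disabled LER means full entrainment everywhere
  expect_identical(entrainmentFactor(c(0, 10), SimParams(lerLength = 0L)),
                   c(1, 1))
})

test_that("step probabilities obey the velocity calibration contract", {
  p <- SimParams()
  u <- unitWithPols(3000)
  pr <- stepProbabilities(u, 1, NULL, p)
  expect_equal(sum(pr[c("p_forward", "p_backward", "p_stay")]), 1)
  expect_equal(pr[["p_forward"]] - pr[["p_backward"]], p@vBar * p@dt,
               tolerance = 1e-12)
})

test_that("steric exclusion and template edges zero the blocked direction", {
  p <- SimParams()
  # downstream neighbour exactly one footprint ahead blocks forward steps
  u <- unitWithPols(c(538, 500))
  expect_identical(stepProbabilities(u, 2, NULL, p)[["p_forward"]], 0)
  # position 1 cannot backtrack off the template
  u1 <- unitWithPols(1)
  expect_identical(stepProbabilities(u1, 1, NULL, p)[["p_backward"]], 0)
  # upstream neighbour within a footprint blocks backward steps
  expect_identical(stepProbabilities(u, 1, NULL, p)[["p_backward"]], 0)
})

test_that("structure bias suppresses backtracking and torsion pulls laggards", {
  p <- SimParams()
  u <- unitWithPols(3000)
  neutral <- stepProbabilities(u, 1, NULL, p)
  fold <- rep(1, p@geneLength)   # strong pairing everywhere
  biased <- stepProbabilities(u, 1, fold, p)
  expect_lt(biased[["p_backward"]], neutral[["p_backward"]])
  expect_equal(biased[["p_forward"]], neutral[["p_forward"]])
  # an upstream polymerase that has fallen behind (positive pair twist,
  # stored on the downstream member) is pulled forward by the convoy
  lag <- unitWithPols(c(3000, 2500), twists = c(2, 0))
  pulled <- stepProbabilities(lag, 2, NULL, p)
  expect_gt(pulled[["p_forward"]], neutral[["p_forward"]])
})

test_that("advanceUnit initiates, completes and counts in order", {
  p <- SimParams(initiationProb = 1)
  set.seed(1)
  u <- advanceUnit(UnitState(p@geneLength), p, nSteps = 1L)
  expect_equal(nrow(u@polymerases), 1L)
  expect_equal(u@polymerases$position, 1L)
  expect_equal(u@counters[["initiations"]], 1)
  # a polymerase one step from the end runs off on a forward move
  v <- unitWithPols(SimParams()@geneLength - 1L)
  set.seed(1)
  v2 <- advanceUnit(v, SimParams(initiationProb = 0), nSteps = 1L,
                    stochastic = FALSE)
  expect_equal(v2@counters[["productive"]], 1)
  expect_equal(nrow(v2@polymerases), 0L)
})

test_that("initiation is gated on a free promoter", {
  p <- SimParams(initiationProb = 1)
  u <- unitWithPols(10)   # occupies positions 1..footprint
  set.seed(1)
  u2 <- advanceUnit(u, p, nSteps = 1L, stochastic = FALSE)
  expect_equal(nrow(u2@polymerases), 1L)   # attempt blocked
})

test_that("polymerase bookkeeping is conserved exactly", {
  out <- simulateUnit(shortParams(pPt = 0.5, ptDistance = 7000L), burnIn = 0)
  cts <- counters(out)
  expect_identical(cts[["initiations"]],
                   cts[["productive"]] + cts[["nonProductive"]] +
                     out@engagedEnd)
  expect_gt(cts[["nonProductive"]], 0)
  # occupancy accounts for every engaged polymerase-step: the census is
  # taken after removals, so the two differ by exactly dt per departure
  departures <- cts[["productive"]] + cts[["nonProductive"]]
  expect_equal(sum(occupancyProfile(out, raw = TRUE)),
               out@meanPolCount * out@params@simTime +
                 out@params@dt * departures,
               tolerance = 1e-9)
  expect_true(all(occupancyProfile(out, raw = TRUE) >= 0))
  expect_equal(sum(occupancyProfile(out)), 1, tolerance = 1e-9)
})

test_that("empirical velocity matches the calibration within 5 percent", {
  # isolated polymerases (initiation spaced beyond one transit)
  p <- SimParams(simTime = 600, initiationInterval = 150,
                 initiationProb = 1, seed = 5L)
  out <- simulateUnit(p, burnIn = 0)
  expect_gte(counters(out)[["productive"]], 3)
  v <- p@geneLength / out@meanTransit
  expect_lt(abs(v - p@vBar) / p@vBar, 0.05)
})

test_that("the steric invariant holds throughout a debug run", {
  expect_no_error(simulateUnit(shortParams(pPt = 0.2, ptDistance = 7000L),
                               debug = TRUE))
})

test_that("identical parameters and seed give bit-identical output", {
  p <- shortParams(pPt = 0.3, ptDistance = 7000L)
  a <- simulateUnit(p)
  b <- simulateUnit(p)
  expect_identical(counters(a), counters(b))
  expect_identical(occupancyProfile(a, raw = TRUE),
                   occupancyProfile(b, raw = TRUE))
  expect_identical(a@meanPolCount, b@meanPolCount)
})

test_that("processivity is the productive fraction of departures", {
  expect_equal(processivity(90, 10), 0.9)
  expect_equal(processivity(7, 0), 1)
  expect_error(processivity(0, 0), "undefined")
  expect_error(processivity(c(productive = 0, nonProductive = 0)),
               "undefined")
  out <- simulateUnit(shortParams(simTime = 400))
  expect_identical(processivity(out), 1)   # pPt = 0: nothing terminates
})

test_that("productive output is non-increasing in the termination probability", {
  prods <- vapply(c(0, 0.5, 1), function(pp) {
    runs <- vapply(1:8, function(s)
      counters(simulateUnit(SimParams(pPt = pp, ptDistance = 7000L,
                                      simTime = 300, seed = 300L + s),
                            burnIn = 0))[["productive"]], numeric(1))
    mean(runs)
  }, numeric(1))
  expect_true(all(diff(prods) < 0))
})

test_that("non-integral simTime/dt is rounded down with a warning", {
  expect_warning(out <- simulateUnit(SimParams(simTime = 1.0021, seed = 1L)),
                 "rounding down")
  expect_s4_class(out, "SimOutput")
})

test_that("parameter validation rejects inconsistent configurations", {
  expect_error(SimParams(pPt = 1.5), "pPt")
  expect_error(SimParams(ptDistance = 8000L), "ptDistance")
  expect_error(SimParams(footprint = 7000L), "footprint")
  expect_error(SimParams(dt = 0), "dt")
})
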