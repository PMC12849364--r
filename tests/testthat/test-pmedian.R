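# All expected objectives below were first computed with the exhaustive
# enumeration oracle (bruteForcePMedian), which scores every feasible open
# set as sum_c min_h w_ch.

test_that("model structure matches the scenario cases", {
  x <- toy1()
  m <- buildPMedianModel(x$W, scenarioConfig(3, "liberal"))
  expect_equal(m@nX, 9L)
  expect_equal(m@nY, 3L)
  expect_equal(m@cardinality, 3L)
  expect_equal(m@bigM, 3)   # defaults to m, the demand count

  pinned <- buildPMedianModel(x$W, scenarioConfig(1, "prioritized", "H2"))
  expect_equal(pinned@pinnedOpen, "H2")
  expect_equal(length(pinned@candidates), 0L)
  expect_equal(pinned@pinnedClosed, c("H1", "H3"))

  below <- buildPMedianModel(x$W,
                             scenarioConfig(1, "prioritized", c("H1", "H3")))
  expect_setequal(below@candidates, c("H1", "H3"))
  expect_equal(below@pinnedClosed, "H2")

  above <- buildPMedianModel(x$W, scenarioConfig(2, "prioritized", "H1"))
  expect_equal(above@pinnedOpen, "H1")
  expect_setequal(above@candidates, c("H2", "H3"))

  expect_error(buildPMedianModel(x$W, scenarioConfig(1, "prioritized",
                                                     "H9")),
               "non-candidate")
  expect_error(scenarioConfig(1, "prioritized"), "non-empty")
})

test_that("solver reproduces the enumerated optima on the toy instance", {
  x <- toy1()
  expected <- c(50, 35, 25)
  for (p in 1:3) {
    sol <- solvePMedian(buildPMedianModel(x$W, scenarioConfig(p, "liberal")),
                        tmat = x$tmat)
    expect_equal(objectiveValue(sol), expected[p])
    expect_equal(solutionStatus(sol), "optimal")
    expect_equal(length(openSites(sol)), p)
  }
  sol1 <- solvePMedian(buildPMedianModel(x$W, scenarioConfig(1, "liberal")))
  expect_equal(openSites(sol1), "H2")
  pri <- solvePMedian(buildPMedianModel(x$W,
                                        scenarioConfig(2, "prioritized",
                                                       "H1")), tmat = x$tmat)
  expect_equal(objectiveValue(pri), 40)
  expect_setequal(openSites(pri), c("H1", "H2"))
})

test_that("the brute-force oracle enumerates, caps, and breaks ties lexicographically", {
  x <- toy1()
  expect_equal(objectiveValue(bruteForcePMedian(x$W,
                                                scenarioConfig(3, "liberal"))),
               25)
  expect_equal(objectiveValue(bruteForcePMedian(x$W,
                                                scenarioConfig(1, "liberal"))),
               50)
  expect_error(bruteForcePMedian(x$W, scenarioConfig(2, "liberal"),
                                 cap = 2), "cap")
  # fully tied instance: every pair scores the same; lexicographic rule
  flat <- x$W
  flat@values[] <- 1
  tied <- bruteForcePMedian(flat, scenarioConfig(2, "liberal"))
  expect_equal(openSites(tied), c("H1", "H2"))
})

test_that("infeasible scenarios come back flagged, not crashed", {
  x <- toy1()
  sol <- solvePMedian(buildPMedianModel(x$W, scenarioConfig(5, "liberal")))
  expect_equal(solutionStatus(sol), "infeasible")
  expect_equal(length(openSites(sol)), 0L)
})

test_that("scenario dispatch pins, restricts, or skips the solver as required", {
  inst <- randomInstance(7, m = 12, n = 5, n_service = 3)
  svc <- serviceIds(inst$hospitals)
  fixed <- solveScenario(inst$W, length(svc), "prioritized", svc,
                         tmat = inst$tmat)
  expect_setequal(openSites(fixed), svc)
  expect_equal(fixed@method, "fixed")
  below <- solveScenario(inst$W, 2, "prioritized", svc, tmat = inst$tmat)
  expect_true(all(openSites(below) %in% svc))
  above <- solveScenario(inst$W, 4, "prioritized", svc, tmat = inst$tmat)
  expect_true(all(svc %in% openSites(above)))
})

test_that("MILP equals exhaustive enumeration across scenario modes and linkings", {
  combos <- expand.grid(mode = c("liberal", "below", "above"),
                        linking = c("per_pair", "big_m"),
                        stringsAsFactors = FALSE)
  sizes <- data.frame(m = c(12, 18, 25, 16), n = c(5, 6, 8, 7))
  for (seed in 1:4) {
    inst <- randomInstance(seed + 100, m = sizes$m[seed],
                           n = sizes$n[seed], n_service = 3)
    svc <- serviceIds(inst$hospitals)
    for (i in seq_len(nrow(combos))) {
      mode <- combos$mode[i]
      p <- switch(mode, liberal = 1L + (seed + i) %% 4L, below = 2,
                  above = length(svc) + 1L)
      scen <- if (mode == "liberal")
        scenarioConfig(p, "liberal", linking = combos$linking[i])
      else scenarioConfig(p, "prioritized", svc,
                          linking = combos$linking[i])
      bf <- bruteForcePMedian(inst$W, scen)
      ml <- solvePMedian(buildPMedianModel(inst$W, scen))
      expect_equal(objectiveValue(ml), objectiveValue(bf),
                   tolerance = 1e-6)
    }
  }
})

test_that("objective is the nearest-open recomputation and monotone in p", {
  inst <- randomInstance(42, m = 25, n = 8, n_service = 3)
  zs <- vapply(1:5, function(p) {
    sol <- solvePMedian(buildPMedianModel(inst$W,
                                          scenarioConfig(p, "liberal")))
    manual <- sum(apply(weightedValues(inst$W)[, openSites(sol),
                                               drop = FALSE], 1, min))
    expect_equal(objectiveValue(sol), manual, tolerance = 1e-9)
    objectiveValue(sol)
  }, numeric(1))
  expect_true(all(diff(zs) <= 1e-9))
})

test_that("prioritized optima never beat liberal optima; incumbents never beat either", {
  for (seed in c(5, 17)) {
    inst <- randomInstance(seed, m = 20, n = 7, n_service = 4)
    svc <- serviceIds(inst$hospitals)
    for (p in c(2, 4, 5)) {
      lib <- solveScenario(inst$W, p, "liberal")
      pri <- solveScenario(inst$W, p, "prioritized", svc)
      expect_lte(objectiveValue(lib), objectiveValue(pri) + 1e-9)
      incumbent <- evaluateSiteSet(inst$W, hospitalIds(inst$hospitals)[1:p])
      expect_lte(objectiveValue(lib), objectiveValue(incumbent) + 1e-9)
    }
  }
})
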