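test_that("lower weighted quantile follows the cumulative-weight scan", {
  expect_equal(weightedQuantile(c(5, 5, 10), c(1, 1, 1), 0.5), 5)
  expect_equal(weightedQuantile(c(10, 5, 5), c(1, 2, 1), 0.5), 5)
  expect_equal(weightedQuantile(c(3, 9, 7), c(1, 1, 1), 1), 9)
  expect_equal(weightedQuantile(c(3, 9, 7), c(1, 1, 1), 0), 3)
  # cumulative scan: value 2 carries weight up to 0.6 of the mass
  expect_equal(weightedQuantile(c(1, 2, 3), c(3, 3, 4), 0.6), 2)
  expect_equal(weightedQuantile(c(1, 2, 3), c(3, 3, 4), 0.61), 3)
  expect_error(weightedQuantile(1:3, c(0, 0, 0), 0.5), "zero")
  expect_error(weightedQuantile(1:3, 1:2, 0.5), "equal length")
})

test_that("toy-instance metrics match direct arithmetic", {
  x <- toy1()
  minutes <- nearestAssignment(x$tmat, c("H1", "H2", "H3"))$minutes
  m <- accessSummary(minutes, x$demand, threshold = 8)
  expect_equal(m@weightedMean, 6.25)
  expect_equal(m@unweightedMean, 20 / 3)
  expect_equal(m@weightedMedian, 5)
  expect_equal(m@propAboveThreshold, 0.25)
  expect_equal(m@populationAboveThreshold, 1)
})

test_that("a constant travel time collapses the whole panel", {
  pops <- c(2, 3, 5)
  m <- accessSummary(rep(12, 3), pops, threshold = 40)
  expect_equal(m@weightedMean, 12)
  expect_equal(m@weightedMedian, 12)
  expect_equal(m@weightedIqrLow, 12)
  expect_equal(m@weightedIqrHigh, 12)
  expect_equal(m@propAboveThreshold, 0)
  over <- accessSummary(rep(45, 3), pops, threshold = 40)
  expect_equal(over@propAboveThreshold, 1)
  # threshold is strict: exactly 40 does not count as exceeding
  at <- accessSummary(rep(40, 3), pops, threshold = 40)
  expect_equal(at@propAboveThreshold, 0)
})

test_that("uniform densities make weighted and unweighted fields identical", {
  withr::with_seed(5, minutes <- runif(40, 5, 60))
  m <- accessSummary(minutes, rep(7, 40), threshold = 40)
  expect_equal(m@weightedMean, m@unweightedMean)
  expect_equal(m@weightedMedian, m@unweightedMedian)
  expect_equal(m@weightedIqrLow, m@unweightedIqrLow)
  expect_equal(m@weightedIqrHigh, m@unweightedIqrHigh)
})

test_that("metrics are scale-equivariant in time units", {
  withr::with_seed(6, {
    minutes <- runif(30, 1, 80)
    pops <- runif(30, 1, 100)
  })
  s <- 2.5
  a <- accessSummary(minutes, pops, threshold = 40)
  b <- accessSummary(s * minutes, pops, threshold = s * 40)
  expect_equal(b@weightedMean, s * a@weightedMean)
  expect_equal(b@weightedMedian, s * a@weightedMedian)
  expect_equal(b@weightedIqrLow, s * a@weightedIqrLow)
  expect_equal(b@unweightedIqrHigh, s * a@unweightedIqrHigh)
  expect_equal(b@propAboveThreshold, a@propAboveThreshold)
})

test_that("weighted mean stays within the observed range", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      minutes <- runif(20, 0, 90)
      pops <- runif(20, 0.1, 10)
    })
    m <- accessSummary(minutes, pops)
    expect_gte(m@weightedMean, min(minutes))
    expect_lte(m@weightedMean, max(minutes))
  }
})

test_that("stratification partitions the population above threshold", {
  ctry <- smallCountry()
  tm <- buildTravelMatrix(ctry$demand, ctry$hospitals)
  minutes <- nearestAssignment(tm, serviceIds(ctry$hospitals))$minutes
  strat <- stratifiedMetrics(minutes, ctry$demand, threshold = 15)
  classes <- setdiff(names(strat), "overall")
  expect_equal(sum(vapply(strat[classes],
                          function(s) s@populationAboveThreshold,
                          numeric(1))),
               strat$overall@populationAboveThreshold)
  expect_equal(sum(vapply(strat[classes],
                          function(s) s@populationTotal, numeric(1))),
               strat$overall@populationTotal)
})

test_that("single-class demand reduces stratified output to the overall panel", {
  x <- toy1()
  minutes <- c(10, 5, 5)
  strat <- stratifiedMetrics(minutes, x$demand, threshold = 8)
  expect_equal(as.data.frame(strat$urban)[-1], as.data.frame(strat$overall)[-1])
})

test_that("classes with disjoint time ranges give all-or-nothing proportions", {
  df <- data.frame(point_id = paste0("P", 1:6), x = 1:6, y = 0,
                   region_id = "R", urbanization = rep(c("urban", "rural"),
                                                       each = 3),
                   density = 10, cell_area = 1)
  d <- makeDemandSet(df)
  minutes <- c(5, 6, 7, 50, 60, 70)
  strat <- stratifiedMetrics(minutes, d, threshold = 40)
  expect_equal(strat$urban@propAboveThreshold, 0)
  expect_equal(strat$rural@propAboveThreshold, 1)
})

test_that("unknown stratum labels are rejected", {
  x <- toy1()
  bad <- x$demand
  bad@points$urbanization <- "suburban"
  expect_error(stratifiedMetrics(c(1, 2, 3), bad, 40), "suburban")
})

test_that("Mann-Whitney U matches the brute-force pair count under ties", {
  withr::with_seed(31, {
    for (r in 1:8) {
      na <- sample(5:60, 1)
      nb <- sample(5:60, 1)
      a <- sample(1:20, na, replace = TRUE)   # heavy ties on purpose
      b <- sample(5:25, nb, replace = TRUE)
      cmp <- compareDistributions(a, b)
      pairs <- outer(a, b, ">")
      ties <- outer(a, b, "==")
      expect_equal(cmp@statistic, sum(pairs) + sum(ties) / 2)
    }
  })
})

test_that("separated and identical samples give the expected U and p", {
  cmp0 <- compareDistributions(c(1, 2, 3), c(101, 102, 103))
  expect_equal(cmp0@statistic, 0)
  x <- c(4, 8, 15, 16, 23, 42)
  same <- compareDistributions(x, x)
  expect_gte(same@pValue, 0.99)
  expect_error(compareDistributions(c(1, 2), c(1, 2, 3)), "at least 3")
})

test_that("normality p values are reported and large samples are thinned", {
  withr::with_seed(8, {
    a <- rnorm(6000)
    b <- rexp(6000)
  })
  cmp <- compareDistributions(a, b)
  expect_gte(cmp@normalityPA, 0.0)
  expect_lte(cmp@normalityPB, 1e-6)   # exponential is decisively non-normal
})

test_that("change reports carry deltas, percents and percentage points", {
  base <- accessSummary(c(10, 20, 30, 50), c(1, 1, 1, 1), threshold = 40)
  none <- relativeChange(base, base)
  expect_true(all(none$delta == 0))
  expect_true(all(none$pct_change[!is.na(none$pct_change)] == 0))

  # a proportion moving 9.17% -> 5.86% is -3.31 points, -36.1% relative
  b <- base; a <- base
  b@propAboveThreshold <- 0.0917
  a@propAboveThreshold <- 0.0586
  rc <- relativeChange(b, a)
  row <- rc[rc$metric == "prop_above_threshold", ]
  expect_equal(row$pp_change, -3.31, tolerance = 1e-9)
  expect_equal(row$pct_change, -36.0961, tolerance = 1e-4)

  # a median moving 28.32 -> 24.08 is a 14.97% reduction
  b@unweightedMedian <- 28.32
  a@unweightedMedian <- 24.08
  rc2 <- relativeChange(b, a)
  expect_equal(rc2$pct_change[rc2$metric == "unweighted_median"],
               -14.9718, tolerance = 1e-4)
})

test_that("zero baselines yield undefined (NA) percent change, not infinity", {
  zero <- accessSummary(c(10, 20), c(1, 1), threshold = 40)
  zero@propAboveThreshold <- 0
  zero@populationAboveThreshold <- 0
  after <- accessSummary(c(10, 50), c(1, 1), threshold = 40)
  rc <- relativeChange(zero, after)
  expect_true(is.na(rc$pct_change[rc$metric == "prop_above_threshold"]))
})
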