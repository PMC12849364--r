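test_that("synthetic travel time follows the circuity formula", {
  expect_equal(syntheticTravelTime(c(3, 4), c(3, 4)), 0)
  expect_equal(syntheticTravelTime(c(0, 0), c(70, 0),
                                   syntheticTravelParams(70, 1.0)), 60)
  expect_equal(syntheticTravelTime(c(0, 0), c(30, 40)),
               60 * 1.3 * 50 / 70)
  expect_error(syntheticTravelParams(speed_kmh = 0), "positive")
  expect_error(syntheticTravelParams(detour_factor = 0.5), ">= 1")
})

test_that("wgs84 mode uses great-circle distance", {
  # one degree of longitude at the equator is ~111.19 km
  t <- syntheticTravelTime(c(0, 0), c(1, 0),
                           syntheticTravelParams(70, 1.0), mode = "wgs84")
  expect_equal(t, 60 * 111.19 / 70, tolerance = 1e-3)
})

test_that("travel matrix respects input order and colocated zero", {
  one <- makeDemandSet(data.frame(point_id = "A", x = 5, y = 5,
                                  region_id = "R", urbanization = "rural",
                                  density = 3, cell_area = 1))
  h <- makeHospitalSet(data.frame(hospital_id = "H", x = 5, y = 5,
                                  service = TRUE))
  tm <- buildTravelMatrix(one, h)
  expect_equal(unname(timeValues(tm)), matrix(0))

  inst <- randomInstance(1)
  tm1 <- buildTravelMatrix(inst$demand, inst$hospitals)
  perm <- inst$hospitals
  ord <- rev(seq_len(nrow(perm@sites)))
  perm@sites <- perm@sites[ord, ]
  tm2 <- buildTravelMatrix(inst$demand, perm)
  expect_equal(timeValues(tm2), timeValues(tm1)[, ord])
})

test_that("mixed coordinate modes and empty sets are rejected", {
  inst <- randomInstance(2)
  wg <- inst$hospitals
  wg@mode <- "wgs84"
  expect_error(buildTravelMatrix(inst$demand, wg), "coordinate modes")
})

test_that("weighting scales each row by its density", {
  x <- toy1()
  expect_equal(unname(weightedValues(x$W)),
               matrix(c(10, 20, 30, 40, 10, 50, 30, 20, 5), 3,
                      byrow = TRUE))
  ones <- x$demand
  ones@points$density <- 1
  ones@points$population <- ones@points$cell_area
  expect_equal(weightedValues(weightMatrix(x$tmat, ones)),
               timeValues(x$tmat))
  zero <- x$demand
  zero@points$density[2] <- 0
  zero@points$population[2] <- 0
  expect_true(all(weightedValues(weightMatrix(x$tmat, zero))[2, ] == 0))
  bad <- x$demand
  bad@points$point_id <- c("A", "B", "Z")
  expect_error(weightMatrix(x$tmat, bad), "do not match")
})

test_that("nearest assignment picks row minima with first-column ties", {
  x <- toy1()
  a <- nearestAssignment(x$tmat, c("H1", "H2", "H3"))
  expect_equal(a$hospital_id, c("H1", "H2", "H3"))
  expect_equal(a$minutes, c(10, 5, 5))
  single <- nearestAssignment(x$tmat, "H2")
  expect_true(all(single$hospital_id == "H2"))
  expect_equal(single$minutes, unname(timeValues(x$tmat)[, "H2"]))
  expect_error(nearestAssignment(x$tmat, character(0)), "non-empty")
  # ties go to the first listed column
  tie <- new("TravelMatrix",
             values = matrix(c(5, 5), 1,
                             dimnames = list("A", c("H1", "H2"))))
  expect_equal(nearestAssignment(tie, c("H2", "H1"))$hospital_id, "H2")
})

test_that("opening more sites never worsens any demand point", {
  for (seed in 1:5) {
    inst <- randomInstance(seed, m = 15, n = 6)
    ids <- hospitalIds(inst$hospitals)
    small <- nearestAssignment(inst$tmat, ids[1:2])
    large <- nearestAssignment(inst$tmat, ids[1:5])
    expect_true(all(large$minutes <= small$minutes + 1e-12))
  }
})

test_that("matrix CSV round trip preserves values and the w = p*t identity", {
  inst <- randomInstance(3)
  path <- withr::local_tempfile(fileext = ".csv")
  writeTravelMatrix(inst$tmat, path)
  back <- readTravelMatrix(path)
  expect_equal(timeValues(back), timeValues(inst$tmat), tolerance = 1e-12)
  Wback <- weightMatrix(back, inst$demand)
  dens <- demandPoints(inst$demand)$density
  for (i in seq_len(nrow(timeValues(back))))
    expect_equal(weightedValues(Wback)[i, ], dens[i] * timeValues(back)[i, ],
                 tolerance = 1e-12)
})

test_that("routing adapter replays its cache and guards synthetic mode", {
  inst <- randomInstance(4)
  expect_error(routingAdapter(inst$demand, inst$hospitals, "x.csv"),
               "synthetic")
  wdemand <- inst$demand
  wdemand@mode <- "wgs84"
  whosp <- inst$hospitals
  whosp@mode <- "wgs84"
  cache <- withr::local_tempfile(fileext = ".csv")
  fetch_calls <- 0L
  fetch <- function(d, h) {
    fetch_calls <<- fetch_calls + 1L
    timeValues(inst$tmat)
  }
  t1 <- routingAdapter(wdemand, whosp, cache, fetch)
  t2 <- routingAdapter(wdemand, whosp, cache,
                       fetch = function(d, h) stop("no network"))
  expect_equal(timeValues(t2), timeValues(t1), tolerance = 1e-12)
  expect_equal(fetch_calls, 1L)
  bad_fetch <- function(d, h) {
    v <- timeValues(inst$tmat)
    v[1, 1] <- Inf
    v
  }
  expect_error(routingAdapter(wdemand, whosp,
                              withr::local_tempfile(fileext = ".csv"),
                              bad_fetch), "unreachable")
})
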