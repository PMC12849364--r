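test_that("config validation rejects malformed inputs", {
  expect_error(syntheticCountryConfig(country_width_km = 0),
               "positive area")
  expect_error(syntheticCountryConfig(class_shares = c(0.5, 0.4, 0.2)),
               "sum to 1")
  expect_error(syntheticCountryConfig(n_service = 40, n_hospitals = 30),
               "n_service")
  expect_error(syntheticCountryConfig(
    density_ranges = list(urban = c(10, 5), intermediate = c(1, 2),
                          rural = c(1, 2))), "low < high")
})

test_that("a single-region country is one urban cell covering the rectangle", {
  cfg <- syntheticCountryConfig(n_regions = 1,
                                class_shares = c(1, 0, 0), seed = 3)
  rs <- generateRegions(cfg)
  tab <- regionTable(rs)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$urbanization, "urban")
  expect_equal(tab$area_km2, 280 * 380)
})

test_that("the generator is deterministic given its seed", {
  cfg <- syntheticCountryConfig(n_regions = 12, n_hospitals = 30,
                                n_service = 10, seed = 99)
  a <- generateSyntheticCountry(cfg)
  b <- generateSyntheticCountry(cfg)
  expect_identical(regionTable(a$regions), regionTable(b$regions))
  expect_identical(demandPoints(a$demand), demandPoints(b$demand))
  expect_identical(hospitalSites(a$hospitals), hospitalSites(b$hospitals))
})

test_that("urbanization class counts stay within exact binomial 99% bounds", {
  cfg <- syntheticCountryConfig(n_regions = 50,
                                class_shares = c(0.3, 0.4, 0.3), seed = 7)
  counts <- tabulate(factor(regionTable(generateRegions(cfg))$urbanization,
                            c("urban", "intermediate", "rural")), 3L)
  shares <- c(0.3, 0.4, 0.3)
  lo <- qbinom(0.005, 50, shares)
  hi <- qbinom(0.995, 50, shares)
  expect_true(all(counts >= lo & counts <= hi))
})

test_that("region polygons tile the country rectangle", {
  for (seed in c(1, 5, 23)) {
    cfg <- syntheticCountryConfig(n_regions = 25, seed = seed)
    rs <- generateRegions(cfg)
    expect_equal(sum(regionTable(rs)$area_km2), 280 * 380,
                 tolerance = 1e-6)
  }
})

test_that("hex spacing admitting exactly one centroid gives one full cell", {
  cfg <- syntheticCountryConfig(country_width_km = 10,
                                country_height_km = 10, n_regions = 1,
                                class_shares = c(1, 0, 0), seed = 1)
  rs <- generateRegions(cfg)
  d <- generateDemandGrid(rs, 12)
  pts <- demandPoints(d)
  expect_equal(nrow(pts), 1L)
  expect_equal(pts$cell_area, sqrt(3) / 2 * 12^2)
})

test_that("uniform density propagates to every centroid", {
  cfg <- syntheticCountryConfig(country_width_km = 60,
                                country_height_km = 60, n_regions = 1,
                                class_shares = c(0, 0, 1), seed = 2)
  rs <- generateRegions(cfg)
  d <- generateDemandGrid(rs, 8)
  expect_true(all(demandPoints(d)$density ==
                  regionTable(rs)$density[1L]))
})

test_that("centroid count equals direct lattice enumeration", {
  cfg <- syntheticCountryConfig(country_width_km = 100,
                                country_height_km = 100, n_regions = 4,
                                seed = 9)
  rs <- generateRegions(cfg)
  s <- 10
  d <- generateDemandGrid(rs, s)
  # independent enumeration of the anchored pointy-top lattice
  v <- s * sqrt(3) / 2
  count <- 0L
  row <- 0L
  repeat {
    y <- v / 2 + row * v
    if (y > 100) break
    x0 <- s / 2 + (row %% 2) * s / 2
    if (x0 <= 100) count <- count + floor((100 - x0) / s) + 1L
    row <- row + 1L
  }
  expect_equal(nrow(demandPoints(d)), count)
})

test_that("spacing beyond the country extent is rejected as an empty grid", {
  cfg <- syntheticCountryConfig(country_width_km = 10,
                                country_height_km = 10, n_regions = 1,
                                class_shares = c(1, 0, 0), seed = 1)
  rs <- generateRegions(cfg)
  expect_error(generateDemandGrid(rs, 25), "empty grid")
})

test_that("every demand point has exactly one region and hospitals sit on centroids", {
  ctry <- smallCountry()
  pts <- demandPoints(ctry$demand)
  expect_true(all(pts$region_id %in% regionTable(ctry$regions)$region_id))
  hs <- hospitalSites(ctry$hospitals)
  key <- paste(pts$x, pts$y)
  expect_true(all(paste(hs$x, hs$y) %in% key))
})

test_that("hospital sampling honours counts, bounds and the service flag", {
  ctry <- smallCountry()
  expect_error(generateHospitals(ctry$demand, n_hospitals = 1e6,
                                 n_service = 1), "exceeds")
  all_svc <- generateHospitals(ctry$demand, 10, 10, seed = 4)
  expect_true(all(hospitalSites(all_svc)$service))
})

test_that("density bias concentrates sites in dense cells per the sampling law", {
  # two blocks of cells: 200 at density 100, 200 at density 1000; with
  # bias 2 a single draw lands in the dense block with probability
  # 200*1000^2 / (200*1000^2 + 200*100^2)
  df <- data.frame(point_id = sprintf("P%03d", 1:400),
                   x = rep(1:20, 20), y = rep(1:20, each = 20),
                   region_id = rep(c("R1", "R2"), each = 200),
                   urbanization = rep(c("rural", "urban"), each = 200),
                   density = rep(c(100, 1000), each = 200),
                   cell_area = 1)
  demand <- makeDemandSet(df)
  p_dense <- 1000^2 / (1000^2 + 100^2)
  draws <- vapply(1:400, function(s) {
    h <- hospitalSites(generateHospitals(demand, 1, 0,
                                         site_density_bias = 2, seed = s))
    df$density[match(h$demand_point_id, df$point_id)] == 1000
  }, logical(1L))
  n_dense <- sum(draws)
  expect_gte(n_dense, qbinom(0.0005, 400, p_dense))
  expect_lte(n_dense, qbinom(0.9995, 400, p_dense))
})

test_that("bias zero reduces to uniform sampling over centroids", {
  ctry <- smallCountry()
  pts <- demandPoints(ctry$demand)
  flat <- pts
  flat$density <- 7        # any constant: uniform weights
  flat$population <- flat$density * flat$cell_area
  uniform <- makeDemandSet(flat)
  h_bias0 <- generateHospitals(ctry$demand, 8, 2, site_density_bias = 0,
                               seed = 21)
  h_unif <- generateHospitals(uniform, 8, 2, site_density_bias = 1,
                              seed = 21)
  expect_identical(hospitalSites(h_bias0)$demand_point_id,
                   hospitalSites(h_unif)$demand_point_id)
})
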