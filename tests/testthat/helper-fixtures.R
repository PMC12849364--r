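# Shared fixtures, built in code.

# TOY-1: three demand points (densities 1, 2, 1; unit cell areas), three
# hospitals, hand-set travel times. Small enough that every optimum is
# verifiable by full enumeration.
toy1 <- function() {
  t <- matrix(c(10, 20, 30,
                20,  5, 25,
                30, 20,  5),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("H1", "H2", "H3")))
  demand <- makeDemandSet(data.frame(
    point_id = c("A", "B", "C"), x = c(0, 1, 2), y = 0,
    region_id = "R1", urbanization = "urban",
    density = c(1, 2, 1), cell_area = 1))
  tmat <- new("TravelMatrix", values = t)
  list(demand = demand, tmat = tmat, W = weightMatrix(tmat, demand))
}

# Random planar instance: m demand points, n candidate sites placed on
# demand centroids, synthetic road travel, heterogeneous densities.
randomInstance <- function(seed, m = 20, n = 6, n_service = 3) {
  withr::with_seed(seed, {
    xy <- matrix(runif(2 * m, 0, 100), ncol = 2)
    dens <- runif(m, 1, 50)
    hidx <- sample.int(m, n)
    svc <- sample.int(n, n_service)
  })
  demand <- makeDemandSet(data.frame(
    point_id = sprintf("C%03d", seq_len(m)), x = xy[, 1], y = xy[, 2],
    region_id = "R1",
    urbanization = rep(c("urban", "intermediate", "rural"), length.out = m),
    density = dens, cell_area = 2))
  hospitals <- makeHospitalSet(data.frame(
    hospital_id = sprintf("H%02d", seq_len(n)),
    x = xy[hidx, 1], y = xy[hidx, 2],
    service = seq_len(n) %in% svc))
  tmat <- buildTravelMatrix(demand, hospitals)
  list(demand = demand, hospitals = hospitals, tmat = tmat,
       W = weightMatrix(tmat, demand))
}

# A small synthetic country shared by several suites.
smallCountry <- function(seed = 11) {
  generateSyntheticCountry(syntheticCountryConfig(
    country_width_km = 120, country_height_km = 100, n_regions = 8,
    hex_spacing_km = 9, n_hospitals = 20, n_service = 6, seed = seed))
}
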