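test_that("scenario SST reduces to its parameters in the noise-free case", {
  sc <- sst_scenario(seasonal_amplitude = 0, noise_sd = 0)
  f <- generate_sst_field(sc, lat = sc$ref_lat, lon = sc$ref_lon,
                          years = 1954, months = 1)
  expect_equal(f$sst, sc$base_temp)

  f2 <- generate_sst_field(sc, lat = sc$ref_lat + c(0, 1), lon = sc$ref_lon,
                           years = 1954, months = 1)
  expect_equal(diff(f2$sst), -sc$lat_gradient)

  f3 <- generate_sst_field(sc, lat = sc$ref_lat, lon = sc$ref_lon + c(0, 1),
                           years = 1954, months = 1)
  expect_equal(diff(f3$sst), -sc$lon_gradient)
})

test_that("scenario trend segments must be contiguous and cover the years", {
  expect_error(sst_scenario(trend_segments = data.frame(
    year_start = 1960, year_end = 2013, rate = 0)), "cover")
  expect_error(sst_scenario(trend_segments = data.frame(
    year_start = c(1954, 1990), year_end = c(1980, 2013),
    rate = c(0, 0))), "contiguous")
  expect_error(generate_sst_field(sst_scenario(), years = 1930),
               "outside scenario coverage")
})

test_that("analytic isotherm velocity matches a fine-grid scan of the field", {
  tau <- 0.05; g <- 0.4
  sc <- sst_scenario(lat_gradient = g, lon_gradient = 0,
                     trend_segments = data.frame(year_start = 1954,
                                                 year_end = 2013,
                                                 rate = tau),
                     seasonal_amplitude = 0, noise_sd = 0)
  lat_fine <- seq(45, 64, by = 0.001)
  crossing <- function(year) {
    f <- generate_sst_field(sc, lat = lat_fine, lon = sc$ref_lon,
                            years = year, months = 1)
    i <- which(diff(sign(f$sst - 12)) != 0)[1]
    mean(lat_fine[i + 0:1])
  }
  scanned_velocity <- (crossing(1990) - crossing(1960)) / 30
  expect_equal(scanned_velocity, tau / g, tolerance = 1e-3)
})

test_that("tow generation is deterministic and respects the domain", {
  plan <- sampling_plan(n_tows_per_year = 200, seed = 5)
  sc <- sst_scenario(seed = 5)
  taxa <- list(taxon_spec("a", "conservative", seed = 7),
               taxon_spec("b", "plastic", seed = 8))
  t1 <- generate_tows(plan, sc, taxa, years = 1960:1961)
  t2 <- generate_tows(plan, sc, taxa, years = 1960:1961)
  expect_identical(t1, t2)
  expect_true(all(t1$count >= 0))
  expect_true(all(t1$count == round(t1$count)))
  expect_true(all(t1$latitude >= plan$lat_min & t1$latitude <= plan$lat_max))
  expect_true(all(t1$longitude >= plan$lon_min &
                    t1$longitude <= plan$lon_max))
  expect_s3_class(t1$datetime_utc, "POSIXct")
  expect_error(generate_tows(plan, sc, list()), "no taxa")

  tr <- generate_tows(sampling_plan(n_tows_per_year = 200,
                                    route_style = "tracks", seed = 5),
                      sc, taxa[1], years = 1960)
  expect_true(all(tr$latitude >= plan$lat_min & tr$latitude <= plan$lat_max))
})

test_that("conservative response peaks at the thermal optimum", {
  tx <- taxon_spec("c", "conservative", thermal_optimum = 12,
                   thermal_sd = 1)
  sst <- seq(5, 19, by = 0.01)
  resp <- taxon_response(tx, lat = 55, sst = sst, month = tx$peak_month)
  expect_equal(sst[which.max(resp)], 12, tolerance = 0.011)
})

test_that("plastic expected range centre sits at home_latitude under any trend", {
  tx <- taxon_spec("p", "plastic", home_latitude = 54.5, home_sd = 2.5)
  sc <- sst_scenario(noise_sd = 0)
  lat <- seq(45, 64, by = 0.001)
  for (t in c(1956, 1986, 2006)) {
    # expected count scale: exp(log-response) - 1, absent where negative
    w <- pmax(0, exp(taxon_response(tx, lat,
                       sst_climatology(sc, lat, sc$ref_lon, t),
                       month = tx$peak_month)) - 1)
    expect_equal(sum(lat * w) / sum(w), 54.5, tolerance = 1e-6)
  }
})

test_that("conservative expected range centre drifts at the isotherm velocity", {
  tx <- taxon_spec("c", "conservative")  # optimum 12.25, interior range
  sc <- sst_scenario(noise_sd = 0)
  lat <- seq(45, 64, by = 0.001)
  centre <- function(t) {
    w <- pmax(0, exp(taxon_response(tx, lat,
                       sst_climatology(sc, lat, sc$ref_lon, t),
                       month = tx$peak_month)) - 1)
    sum(lat * w) / sum(w)
  }
  # warming segment: 0.0476 degC/yr over gradient 0.35
  drift <- centre(2004) - centre(1994)
  expect_equal(drift, 10 * 0.0476 / 0.35, tolerance = 0.01)
})

test_that("tow and SST CSV round-trips preserve the data", {
  plan <- sampling_plan(n_tows_per_year = 50, seed = 2)
  sc <- sst_scenario(seed = 2)
  tows <- generate_tows(plan, sc, taxon_spec("a", "plastic", seed = 3),
                        years = 1970)
  f <- tempfile(fileext = ".csv")
  write_tows(tows, f)
  back <- read_tows(f)
  expect_equal(back$count, tows$count)
  expect_equal(back$latitude, tows$latitude, tolerance = 1e-12)
  expect_equal(as.numeric(back$datetime_utc),
               as.numeric(trunc(tows$datetime_utc, "secs")))

  sst <- generate_sst_field(sc, years = 1970, months = 1:2)
  f2 <- tempfile(fileext = ".csv")
  write_sst_csv(sst, f2)
  expect_equal(read_sst_csv(f2)$sst, sst$sst, tolerance = 1e-12)
  unlink(c(f, f2))
})
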