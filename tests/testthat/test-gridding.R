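test_that("samples land in their 5-year period and month buckets", {
  dt <- as.POSIXct(c("1954-03-15 10:00:00", "2013-12-31 23:00:00",
                     "1953-06-01 00:00:00", "1984-01-01 00:00:00"),
                   tz = "UTC")
  s <- data.frame(taxon = "x", latitude = 50, longitude = 0,
                  datetime_utc = dt, count = 1)
  expect_message(out <- assign_periods(s), "excluded")
  expect_equal(nrow(out), 3)
  expect_equal(out$period_label, c("1954-1958", "2009-2013", "1984-1988"))
  expect_equal(out$month, c(3L, 12L, 1L))
})

test_that("night filter keeps 18:00-06:00 local solar time for diel taxa only", {
  dt <- as.POSIXct(c("2000-06-01 12:00:00",   # local noon at lon 0
                     "2000-06-01 17:45:00",   # local 18:15 at lon 7.5 E
                     "2000-06-01 23:00:00"),  # night everywhere nearby
                   tz = "UTC")
  s <- data.frame(taxon = rep(c("diel", "calm"), each = 3),
                  latitude = 55, longitude = rep(c(0, 7.5, 0), 2),
                  datetime_utc = rep(dt, 2), count = 1)
  out <- night_filter(s, diel_taxa = "diel")
  kept_diel <- out[out$taxon == "diel", ]
  expect_equal(nrow(kept_diel), 2)                  # noon tow removed
  expect_equal(kept_diel$longitude, c(7.5, 0))
  expect_equal(nrow(out[out$taxon == "calm", ]), 3) # untouched
  expect_identical(night_filter(s, character()), s)
})

test_that("log transform follows log(n+1) in the configured base", {
  expect_equal(log_transform(0), 0)
  expect_equal(log_transform(exp(1) - 1), 1)
  expect_equal(log_transform(99), log(100))
  expect_equal(log_transform(99, base = 10), 2)
  expect_error(log_transform(-1), "negative")
})

test_that("variogram fitting needs enough points and bins", {
  expect_error(fit_variogram(1:3, 1:3, 1:3), "insufficient data")
  set.seed(1)
  expect_error(fit_variogram(runif(20), runif(20), rep(1, 20)), "constant")
})

test_that("white noise fits an almost pure nugget model", {
  set.seed(101)
  x <- runif(500, 0, 1000); y <- runif(500, 0, 1000)
  v <- rnorm(500)
  m <- fit_variogram(x, y, v)
  expect_gt(m$nugget / m$sill, 0.8)
  expect_equal(m$sill, var(v), tolerance = 0.25)
})

test_that("a spherical Gaussian process is recovered within half its range", {
  set.seed(202)
  gp <- simulate_spherical_gp(500, nugget = 0.1, sill = 1.1, range = 300)
  m <- fit_variogram(gp$x, gp$y, gp$v)
  expect_gt(effective_range(m), 150)
  expect_lt(effective_range(m), 450)
})

test_that("ordinary kriging honours its defining properties", {
  set.seed(7)
  g <- analysis_grid()
  model <- structure(list(family = "spherical", nugget = 0, sill = 1,
                          range = 400, fit_score = 0),
                     class = "variogram_model")
  lat <- runif(25, 46, 63); lon <- runif(25, -19, 7)
  v <- sin(lat / 3) + cos(lon / 4)

  # single observation: constant surface
  one <- krige_field(lat[1], lon[1], v[1], model, g)
  expect_true(all(one$values == v[1]))

  f <- krige_field(lat, lon, v, model, g)
  # unbiasedness: weights sum to 1 at every cell
  expect_lt(attr(f, "max_weight_error"), 1e-9)
  # nugget 0: exact interpolation at the data points (nearest cell trick:
  # predict on a grid through the exact data location)
  g1 <- analysis_grid(lat_min = lat[1] - 0.25, lat_max = lat[1] + 0.25,
                      lon_min = lon[1] - 0.25, lon_max = lon[1] + 0.25)
  f1 <- krige_field(lat, lon, v, model, g1)
  expect_equal(f1$values[1, 1], v[1], tolerance = 1e-6)
  # translation of the value scale
  f2 <- krige_field(lat, lon, v + 5, model, g)
  expect_equal(f2$values, f$values + 5, tolerance = 1e-8)
})

test_that("kriging matches an independent dense solve on a 5-point fixture", {
  g <- analysis_grid()
  pts <- data.frame(lat = c(47.3, 51.8, 54.6, 58.1, 62.4),
                    lon = c(-15.2, -7.9, 0.4, -12.6, 3.7),
                    v = c(1.2, 0.7, 2.4, 1.9, 0.3))
  model <- structure(list(family = "spherical", nugget = 0.1, sill = 1.1,
                          range = 500, fit_score = 0),
                     class = "variogram_model")
  f <- krige_field(pts$lat, pts$lon, pts$v, model, g)

  # oracle: brute-force 6x6 ordinary kriging system per cell
  p <- project_km(pts$lat, pts$lon)
  D <- as.matrix(dist(p))
  A <- rbind(cbind(sph_gamma(D, 0.1, 1.1, 500), 1), c(rep(1, 5), 0))
  for (cell in list(c(5, 11), c(20, 40), c(38, 56), c(1, 1))) {
    cp <- project_km(g$lat[cell[1]], g$lon[cell[2]])
    d0 <- sqrt((p[, "x"] - cp[, "x"])^2 + (p[, "y"] - cp[, "y"])^2)
    w <- solve(A, c(sph_gamma(d0, 0.1, 1.1, 500), 1))
    expect_equal(f$values[cell[1], cell[2]], sum(w[1:5] * pts$v),
                 tolerance = 1e-8)
  }
})

test_that("duplicate coordinates are averaged instead of breaking the solve", {
  g <- analysis_grid()
  model <- structure(list(family = "exponential", nugget = 0.05, sill = 1,
                          range = 200, fit_score = 0),
                     class = "variogram_model")
  lat <- c(50, 50, 55, 60); lon <- c(-10, -10, 0, 5); v <- c(1, 3, 2, 4)
  expect_warning(f <- krige_field(lat, lon, v, model, g), "duplicate")
  expect_warning(fm <- krige_field(c(50, 55, 60), c(-10, 0, 5), c(2, 2, 4),
                                   model, g), NA)
  expect_equal(f$values, fm$values, tolerance = 1e-10)
})

test_that("monthly fields average into a 5-yearly field month by month", {
  g <- analysis_grid()
  per <- period_table()[1, ]
  mk <- function(x) period_grid(matrix(x, length(g$lat), length(g$lon)),
                                g, period = per, month = 1L)
  same <- period_mean_field(rep(list(mk(2)), 12))
  expect_true(all(same$values == 2))
  expect_equal(same$n_months, 12L)

  two <- period_mean_field(list(mk(0), mk(2)))
  expect_true(all(two$values == 1))

  # a missing month is excluded, equal to an explicit-mask recomputation
  set.seed(3)
  grids <- lapply(1:12, function(m)
    period_grid(matrix(rnorm(38 * 56), 38, 56), g, per, month = m))
  grids[[7]] <- NULL
  got <- period_mean_field(grids)
  oracle <- Reduce(`+`, lapply(grids, `[[`, "values")) / 11
  expect_equal(got$values, oracle)
  expect_equal(got$n_months, 11L)
  expect_error(period_mean_field(list()), "no monthly grids")
})
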