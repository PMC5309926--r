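# shared simulators and constructors for the test suite

# stationary AR(1) series
ar1_series <- function(n, phi, sd = 1) {
  x <- numeric(n)
  x[1] <- rnorm(1, sd = sd / sqrt(1 - phi^2))
  for (i in 2:n) x[i] <- phi * x[i - 1] + rnorm(1, sd = sd)
  x
}

# spherical semivariance (independent of the package's model_semivariance)
sph_gamma <- function(h, nugget, sill, range) {
  psill <- sill - nugget
  g <- ifelse(h >= range, psill,
              psill * (1.5 * h / range - 0.5 * (h / range)^3))
  out <- nugget + g
  out[h == 0] <- 0
  out
}

# Gaussian process with spherical variogram on random 2-D points
simulate_spherical_gp <- function(n, nugget, sill, range, extent = 1000) {
  x <- runif(n, 0, extent)
  y <- runif(n, 0, extent)
  D <- as.matrix(stats::dist(cbind(x, y)))
  C <- sill - sph_gamma(D, nugget, sill, range)
  diag(C) <- sill
  v <- drop(t(chol(C + diag(1e-8, n))) %*% rnorm(n))
  list(x = x, y = y, v = v)
}

# a period_grid with given values on the default analysis grid
make_field <- function(values, grid = analysis_grid(), period = NULL) {
  if (is.function(values)) {
    values <- outer(grid$lat, grid$lon, values)
  } else if (length(values) == 1) {
    values <- matrix(values, length(grid$lat), length(grid$lon))
  }
  period_grid(values, grid, period = period)
}

# an isotherm_track at constant (or per-column) latitude
make_track <- function(latitude, temp = 12, grid = analysis_grid(),
                       period = NULL) {
  lat <- rep_len(latitude, length(grid$lon))
  structure(list(temp = temp, period = period, longitude = grid$lon,
                 latitude = lat,
                 mean_latitude = mean(lat, na.rm = TRUE)),
            class = "isotherm_track")
}

# a plasticity_result with a chosen significance flag
make_plasticity <- function(significant, r = if (significant) -0.9 else 0.1) {
  structure(list(r = r, n = 12, n_eff = 10,
                 p_one_sided = if (significant) 0.01 else 0.5,
                 alpha = 0.05, significant_negative = significant),
            class = "plasticity_result")
}

# per-period named vectors over the twelve default periods
period_named <- function(values) {
  stats::setNames(rep_len(values, 12), period_table()$label)
}
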