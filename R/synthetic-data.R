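#' Synthetic sea-surface-temperature scenario
#'
#' Describes a deterministic SST climate plus noise used to drive the
#' synthetic sampling module.  The mean field is linear in latitude with a
#' seasonal cycle and a piecewise-linear multi-decadal trend:
#'
#' \deqn{T(lat, t) = base - g (lat - lat_{ref}) + trend(t) +
#'       A \cos(2\pi (month - peak)/12) + \epsilon}
#'
#' The default trend emulates the North-East Atlantic's multi-decadal
#' structure over 1954--2013: flat to 1959, consistent cooling 1959--1984,
#' consistent warming 1984--2008, then flat.  With a latitudinal gradient
#' `g` (degC per degree latitude) a trend of `tau` degC/yr moves every
#' isotherm poleward at `tau / g` degrees of latitude per year, so the
#' implied climate velocity is known exactly.
#'
#' @param base_temp mean SST (degC) at (`ref_lat`, `ref_lon`) at the start
#'   of coverage.
#' @param lat_gradient degC decrease per degree of northward latitude; must
#'   be positive (cooler polewards).
#' @param lon_gradient degC decrease per degree of eastward longitude
#'   (North-East Atlantic convention: the Atlantic inflow in the west is
#'   warmer than the North Sea).  The zonal tilt makes the isotherms cross
#'   the 0.5-degree grid at a different sub-cell phase in every longitude
#'   column, as real isotherms do; with perfectly zonal isotherms the
#'   grid-discretization error of every column would be in phase and
#'   mass-fraction statistics would inherit a deterministic aliasing
#'   signal.
#' @param trend_segments data.frame with columns `year_start`, `year_end`,
#'   `rate` (degC per year); segments must be contiguous and cover
#'   `years`.
#' @param seasonal_amplitude amplitude (degC) of the annual cycle.
#' @param seasonal_peak_month month of the SST maximum (late-summer default
#'   of August, North Atlantic convention).
#' @param noise_sd standard deviation (degC) of cell-level Gaussian noise.
#' @param ref_lat,ref_lon reference position (degrees N / degrees E).
#' @param years calendar years the scenario covers.
#' @param seed integer seed making the noise reproducible.
#' @return An object of class `sst_scenario`.
#' @export
sst_scenario <- function(base_temp = 12,
                         lat_gradient = 0.35,
                         lon_gradient = 0.05,
                         trend_segments = default_trend_segments(),
                         seasonal_amplitude = 2,
                         seasonal_peak_month = 8,
                         noise_sd = 0.2,
                         ref_lat = 54.5,
                         ref_lon = -6,
                         years = 1954:2013,
                         seed = 1L) {
  stopifnot(lat_gradient > 0, seasonal_amplitude >= 0, noise_sd >= 0,
            all(c("year_start", "year_end", "rate") %in%
                  names(trend_segments)))
  seg <- trend_segments[order(trend_segments$year_start), , drop = FALSE]
  if (seg$year_start[1] > min(years) || seg$year_end[nrow(seg)] < max(years))
    stop("trend segments must cover the scenario years ",
         min(years), "-", max(years))
  if (nrow(seg) > 1 &&
      any(seg$year_start[-1] != seg$year_end[-nrow(seg)]))
    stop("trend segments must be contiguous")
  structure(list(base_temp = base_temp, lat_gradient = lat_gradient,
                 lon_gradient = lon_gradient, trend_segments = seg,
                 seasonal_amplitude = seasonal_amplitude,
                 seasonal_peak_month = seasonal_peak_month,
                 noise_sd = noise_sd, ref_lat = ref_lat, ref_lon = ref_lon,
                 years = years, seed = as.integer(seed)),
            class = "sst_scenario")
}

#' @rdname sst_scenario
#' @details `default_trend_segments()` returns the default piecewise trend:
#'   0 degC/yr over 1954--1959, -0.0142 degC/yr over 1959--1984 (cooling),
#'   +0.0476 degC/yr over 1984--2008 (warming), 0 over 2008--2013.  With the
#'   default gradient of 0.35 degC per degree latitude these rates put the
#'   warming-era isotherm velocity at 0.0476/0.35 = 0.136 degrees of
#'   latitude per year, about 151 km per decade.
#' @export
default_trend_segments <- function() {
  data.frame(year_start = c(1954, 1959, 1984, 2008),
             year_end   = c(1959, 1984, 2008, 2013),
             rate       = c(0, -0.0142, 0.0476, 0))
}

# cumulative trend (degC) accrued from the first covered year to fractional
# year t, integrating the piecewise-constant rates
cumulative_trend <- function(scenario, t) {
  seg <- scenario$trend_segments
  out <- numeric(length(t))
  for (i in seq_len(nrow(seg))) {
    lo <- seg$year_start[i]; hi <- seg$year_end[i]
    out <- out + seg$rate[i] * (pmin(pmax(t, lo), hi) - lo)
  }
  out
}

# deterministic (noise-free) part of the scenario SST
sst_mean <- function(scenario, lat, lon, t, month) {
  sst_climatology(scenario, lat, lon, t) +
    scenario$seasonal_amplitude *
      cos(2 * pi * (month - scenario$seasonal_peak_month) / 12)
}

#' Climatological (seasonally detrended) scenario SST
#'
#' The annual-mean SST surface of a scenario at fractional year `t`:
#' the base temperature, meridional and zonal gradients and accumulated
#' trend, without the seasonal cycle or noise.
#'
#' @param scenario an [sst_scenario()].
#' @param lat,lon position in degrees.
#' @param t fractional year.
#' @return Climatological SST in degC.
#' @export
sst_climatology <- function(scenario, lat, lon, t) {
  scenario$base_temp -
    scenario$lat_gradient * (lat - scenario$ref_lat) -
    scenario$lon_gradient * (lon - scenario$ref_lon) +
    cumulative_trend(scenario, t)
}

#' Generate a gridded monthly SST series
#'
#' Evaluates an [sst_scenario()] on a regular lat/lon grid for a set of
#' (year, month) slices, emulating a HadISST-style 1 x 1 degree monthly
#' product.  A slice at (year, month) is timestamped at the month's
#' mid-point, `year + (month - 0.5)/12` in fractional years.
#'
#' @param scenario an [sst_scenario()].
#' @param lat,lon grid cell-centre vectors.  The default 1-degree grid
#'   extends one degree beyond the analysis domain on every side
#'   (44.5--64.5 N, -20.5--8.5 E), as a global SST product would: kriging
#'   the temperature onto the analysis grid then interpolates everywhere
#'   instead of extrapolating at the domain edges, where flattened
#'   estimates would otherwise bend the per-column polynomial fits and
#'   bias the recovered isotherm latitudes.
#' @param years,months calendar years and months to generate; all must fall
#'   within the scenario's coverage.
#' @return A long-format data.frame with columns `year`, `month`, `lat`,
#'   `lon`, `sst` (degC).  Deterministic given the scenario seed.
#' @export
generate_sst_field <- function(scenario,
                               lat = seq(44.5, 64.5, by = 1),
                               lon = seq(-20.5, 8.5, by = 1),
                               years = scenario$years,
                               months = 1:12) {
  if (any(!years %in% scenario$years))
    stop("requested years outside scenario coverage ",
         min(scenario$years), "-", max(scenario$years))
  stopifnot(all(months %in% 1:12))
  slices <- expand.grid(month = months, year = years)
  cells <- expand.grid(lat = lat, lon = lon)
  out <- vector("list", nrow(slices))
  with_seed(scenario$seed, {
    for (i in seq_len(nrow(slices))) {
      yr <- slices$year[i]; mo <- slices$month[i]
      t <- yr + (mo - 0.5) / 12
      sst <- sst_mean(scenario, cells$lat, cells$lon, t, mo)
      if (scenario$noise_sd > 0)
        sst <- sst + rnorm(nrow(cells), sd = scenario$noise_sd)
      out[[i]] <- data.frame(year = yr, month = mo,
                             lat = cells$lat, lon = cells$lon, sst = sst)
    }
  })
  do.call(rbind, out)
}

#' Synthetic taxon with a known thermal niche behaviour
#'
#' A taxon is either `"conservative"` (its abundance peaks where local SST
#' equals `thermal_optimum`, so its range tracks moving isotherms) or
#' `"plastic"` (its abundance peaks at a fixed `home_latitude` regardless of
#' SST, so its range stays put as isotherms move).  Expected log-abundance
#' of a tow is
#'
#' \deqn{\log A = \mu + a_s e^{-d_m^2 / (2 w^2)} + a_n e^{-z^2/2}}
#'
#' where `d_m` is the circular month distance from `peak_month`, `w` the
#' seasonal width, and `z` the standardized niche distance
#' (`(SST - optimum)/thermal_sd` or `(lat - home)/home_sd`).  Realized
#' counts are `max(0, round(exp(log A + eps) - 1))` with Gaussian noise
#' `eps` on the log scale.
#'
#' @param name taxon label.
#' @param niche_mode `"conservative"` or `"plastic"`.
#' @param thermal_optimum,thermal_sd thermal niche centre and width (degC),
#'   used in conservative mode.
#' @param home_latitude,home_sd geographic niche centre and width (degrees
#'   latitude), used in plastic mode.
#' @param peak_month,peak_width seasonal peak month (1--12) and Gaussian
#'   width in months.
#' @param mean_log_abundance baseline log-abundance away from the niche and
#'   seasonal peaks (natural-log units).  The default of -3 keeps the
#'   probability of a non-zero count negligible outside the niche even at
#'   the height of the season and in the upper tail of the log-noise: the
#'   taxon is absent beyond its range, as marine plankton taxa are, so the
#'   range bump -- not a domain-wide stochastic background -- carries the
#'   whole distribution signal.  A residual background would not track
#'   isotherms and would leak a spurious niche-plasticity signal into
#'   taxa meant to be conservative.
#' @param niche_amp,seasonal_amp amplitudes (log-units) of the niche and
#'   seasonal terms.
#' @param noise_log_sd standard deviation of the additive log-scale noise.
#' @param diel_migrator logical; if `TRUE` the taxon performs diel vertical
#'   migration and the pipeline's night filter applies to it.
#' @param seed integer seed for the taxon's abundance noise.
#' @return An object of class `taxon_spec`.
#' @export
taxon_spec <- function(name,
                       niche_mode = c("conservative", "plastic"),
                       thermal_optimum = 12.25, thermal_sd = 0.9,
                       home_latitude = 54.5, home_sd = 2.5,
                       peak_month = 5, peak_width = 1.5,
                       mean_log_abundance = -3,
                       niche_amp = 6, seasonal_amp = 1.5,
                       noise_log_sd = 0.5,
                       diel_migrator = FALSE,
                       seed = 1L) {
  niche_mode <- match.arg(niche_mode)
  stopifnot(thermal_sd > 0, home_sd > 0,
            peak_month >= 1, peak_month <= 12, peak_width > 0,
            niche_amp >= 0, seasonal_amp >= 0, noise_log_sd >= 0)
  structure(list(name = name, niche_mode = niche_mode,
                 thermal_optimum = thermal_optimum, thermal_sd = thermal_sd,
                 home_latitude = home_latitude, home_sd = home_sd,
                 peak_month = peak_month, peak_width = peak_width,
                 mean_log_abundance = mean_log_abundance,
                 niche_amp = niche_amp, seasonal_amp = seasonal_amp,
                 noise_log_sd = noise_log_sd,
                 diel_migrator = isTRUE(diel_migrator),
                 seed = as.integer(seed)),
            class = "taxon_spec")
}

# circular distance between months on the 12-month wheel
month_circular_distance <- function(m1, m2) {
  d <- abs(m1 - m2)
  pmin(d, 12 - d)
}

#' Expected log-abundance of a synthetic taxon
#'
#' The noise-free response surface underlying [generate_tows()]; exposed so
#' that downstream estimates (range medians, movements) can be checked
#' against direct integration of the expected field.
#'
#' @param taxon a [taxon_spec()].
#' @param lat latitude in degrees.
#' @param sst local sea surface temperature (degC).
#' @param month month 1--12.
#' @return Expected log-abundance (natural-log units), vectorized over the
#'   inputs.
#' @export
taxon_response <- function(taxon, lat, sst, month) {
  dm <- month_circular_distance(month, taxon$peak_month)
  seasonal <- taxon$seasonal_amp * exp(-0.5 * (dm / taxon$peak_width)^2)
  z <- if (taxon$niche_mode == "conservative") {
    (sst - taxon$thermal_optimum) / taxon$thermal_sd
  } else {
    (lat - taxon$home_latitude) / taxon$home_sd
  }
  taxon$mean_log_abundance + seasonal + taxon$niche_amp * exp(-0.5 * z^2)
}

#' Sampling plan for synthetic tow surveys
#'
#' @param n_tows_per_year number of tow positions drawn per calendar year.
#' @param route_style `"random"` (positions uniform over the domain) or
#'   `"tracks"` (positions along straight cross-domain transects, a crude
#'   stand-in for ship-of-opportunity routes).
#' @param lat_min,lat_max,lon_min,lon_max the survey bounding box.
#' @param coastal_exclusion_km samples closer than this to a coast are
#'   excluded in real surveys; the default open-ocean box contains no
#'   modelled coastline, so the setting is retained for interface fidelity
#'   but acts as a no-op.
#' @param seed integer seed for tow placement and timing.
#' @return An object of class `sampling_plan`.
#' @export
sampling_plan <- function(n_tows_per_year = 2000,
                          route_style = c("random", "tracks"),
                          lat_min = 45, lat_max = 64,
                          lon_min = -20, lon_max = 8,
                          coastal_exclusion_km = 10,
                          seed = 1L) {
  route_style <- match.arg(route_style)
  stopifnot(n_tows_per_year > 0,
            lat_min >= -90, lat_max <= 90, lat_min < lat_max,
            lon_min >= -180, lon_max <= 180, lon_min < lon_max)
  structure(list(n_tows_per_year = as.integer(n_tows_per_year),
                 route_style = route_style,
                 lat_min = lat_min, lat_max = lat_max,
                 lon_min = lon_min, lon_max = lon_max,
                 coastal_exclusion_km = coastal_exclusion_km,
                 seed = as.integer(seed)),
            class = "sampling_plan")
}

# one year's tow positions under the plan (no RNG management here)
draw_positions <- function(plan, n) {
  if (plan$route_style == "random") {
    data.frame(latitude = runif(n, plan$lat_min, plan$lat_max),
               longitude = runif(n, plan$lon_min, plan$lon_max))
  } else {
    # straight transects between random points on opposite domain edges,
    # sampled at uniform fractions along each track
    per_track <- 25L
    n_tracks <- ceiling(n / per_track)
    pos <- vector("list", n_tracks)
    for (k in seq_len(n_tracks)) {
      a <- c(runif(1, plan$lat_min, plan$lat_max), plan$lon_min)
      b <- c(runif(1, plan$lat_min, plan$lat_max), plan$lon_max)
      f <- runif(per_track)
      pos[[k]] <- data.frame(latitude = a[1] + f * (b[1] - a[1]),
                             longitude = a[2] + f * (b[2] - a[2]))
    }
    utils::head(do.call(rbind, pos), n)
  }
}

#' Generate synthetic tow samples
#'
#' Draws tow positions and times under a [sampling_plan()], evaluates the
#' scenario's mean SST at each tow, and realizes counts for each taxon from
#' its [taxon_response()] surface plus log-scale Gaussian noise.  Tow
#' datetimes are uniform over the 24-h day (so a night filter removes about
#' half the samples of diel taxa) and uniform over the year.
#'
#' @param plan a [sampling_plan()].
#' @param scenario an [sst_scenario()].
#' @param taxa a list of [taxon_spec()] objects.
#' @param years calendar years to simulate (default: the scenario's).
#' @param niche_sst which SST drives the thermal niche of conservative
#'   taxa: `"climatological"` (default) uses the seasonally detrended
#'   surface of [sst_climatology()] -- range limits set by the
#'   climatological mean temperature, with the seasonal cycle expressed
#'   through the taxon's phenology term -- while `"instantaneous"` uses the
#'   full seasonal SST, letting the range bump migrate with the seasons.
#' @return A data.frame with one row per (tow, taxon): columns `taxon`,
#'   `latitude`, `longitude`, `datetime_utc` (POSIXct, UTC) and integer
#'   `count`.  Deterministic given the plan and taxon seeds.
#' @export
generate_tows <- function(plan, scenario, taxa, years = scenario$years,
                          niche_sst = c("climatological",
                                        "instantaneous")) {
  niche_sst <- match.arg(niche_sst)
  if (length(taxa) == 0) stop("no taxa")
  if (inherits(taxa, "taxon_spec")) taxa <- list(taxa)
  tows <- with_seed(plan$seed, {
    out <- vector("list", length(years))
    for (i in seq_along(years)) {
      yr <- years[i]
      pos <- draw_positions(plan, plan$n_tows_per_year)
      day <- runif(nrow(pos), 0, 365)      # day-of-year, fractional
      hour <- runif(nrow(pos), 0, 24)
      t0 <- as.POSIXct(sprintf("%d-01-01 00:00:00", yr), tz = "UTC")
      dt <- t0 + floor(day) * 86400 + hour * 3600
      out[[i]] <- data.frame(
        year = yr,
        month = as.integer(format(dt, "%m", tz = "UTC")),
        latitude = pos$latitude, longitude = pos$longitude,
        datetime_utc = dt
      )
    }
    do.call(rbind, out)
  })
  t_frac <- tows$year + (tows$month - 0.5) / 12
  sst <- if (niche_sst == "climatological")
    sst_climatology(scenario, tows$latitude, tows$longitude, t_frac)
  else
    sst_mean(scenario, tows$latitude, tows$longitude, t_frac, tows$month)
  res <- vector("list", length(taxa))
  for (k in seq_along(taxa)) {
    tx <- taxa[[k]]
    mu <- taxon_response(tx, tows$latitude, sst, tows$month)
    counts <- with_seed(tx$seed, {
      eps <- if (tx$noise_log_sd > 0)
        rnorm(length(mu), sd = tx$noise_log_sd) else 0
      pmax(0, round(exp(mu + eps) - 1))
    })
    res[[k]] <- data.frame(taxon = tx$name,
                           latitude = tows$latitude,
                           longitude = tows$longitude,
                           datetime_utc = tows$datetime_utc,
                           count = as.integer(counts))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write or read the tow-sample CSV interchange format
#'
#' One row per observation with columns
#' `taxon,latitude,longitude,datetime_utc,count`; datetimes are ISO-8601
#' UTC.
#'
#' @param tows a tow-sample data.frame as from [generate_tows()].
#' @param path file path.
#' @return `read_tows()` returns the tow data.frame with `datetime_utc`
#'   parsed as POSIXct (UTC).
#' @export
write_tows <- function(tows, path) {
  out <- tows
  out$datetime_utc <- format(out$datetime_utc, "%Y-%m-%dT%H:%M:%SZ",
                             tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tows
#' @export
read_tows <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("taxon", "latitude", "longitude", "datetime_utc", "count")
  if (!all(need %in% names(x)))
    stop("tow CSV must have columns ", paste(need, collapse = ","))
  x$datetime_utc <- as.POSIXct(x$datetime_utc,
                               format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  x
}

#' @rdname write_tows
#' @param sst a long-format SST data.frame as from [generate_sst_field()].
#' @export
write_sst_csv <- function(sst, path) {
  utils::write.csv(sst, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tows
#' @export
read_sst_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "month", "lat", "lon", "sst")
  if (!all(need %in% names(x)))
    stop("SST CSV must have columns ", paste(need, collapse = ","))
  x
}
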