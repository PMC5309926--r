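#' Analysis grid and study-period definitions
#'
#' The analysis domain is the box 45--64 degrees N, 20 degrees W -- 8 degrees
#' E.  All kriged fields live on a fixed 0.5 x 0.5 degree grid whose cell
#' centres sit at the quarter-degree points (45.25, 45.75, ... 63.75 N and
#' -19.75, ... 7.75 E), i.e. 38 latitude rows by 56 longitude columns; the
#' domain edges are cell boundaries and cells are half-open `[lo, hi)`.
#'
#' @param lat_min,lat_max,lon_min,lon_max domain edges in decimal degrees
#'   (longitude west of Greenwich negative).
#' @param cell cell size in degrees.
#' @return An object of class `analysis_grid`: a list with cell-centre
#'   vectors `lat` (south to north) and `lon` (west to east), the cell size
#'   and the domain edges.
#' @export
analysis_grid <- function(lat_min = 45, lat_max = 64,
                          lon_min = -20, lon_max = 8, cell = 0.5) {
  stopifnot(lat_max > lat_min, lon_max > lon_min, cell > 0)
  g <- list(
    lat = seq(lat_min + cell / 2, lat_max - cell / 2, by = cell),
    lon = seq(lon_min + cell / 2, lon_max - cell / 2, by = cell),
    cell = cell,
    lat_min = lat_min, lat_max = lat_max,
    lon_min = lon_min, lon_max = lon_max
  )
  class(g) <- "analysis_grid"
  g
}

#' @export
print.analysis_grid <- function(x, ...) {
  cat(sprintf("<analysis_grid> %d x %d cells of %.2f deg, %g-%g N, %g-%g E\n",
              length(x$lat), length(x$lon), x$cell,
              x$lat_min, x$lat_max, x$lon_min, x$lon_max))
  invisible(x)
}

#' Five-year study periods
#'
#' The study spans 1954--2013 divided into twelve contiguous 5-year periods
#' (1954--1958, 1959--1963, ..., 2009--2013).
#'
#' @param start_year,end_year first and last calendar year covered.
#' @param span period length in years.
#' @return A data.frame with columns `label` (e.g. `"1954-1958"`),
#'   `start_year`, `end_year` and `mid_year` (arithmetic mid-point).
#' @export
period_table <- function(start_year = 1954, end_year = 2013, span = 5) {
  starts <- seq(start_year, end_year - span + 1, by = span)
  data.frame(
    label = sprintf("%d-%d", starts, starts + span - 1),
    start_year = starts,
    end_year = starts + span - 1,
    mid_year = starts + (span - 1) / 2,
    stringsAsFactors = FALSE
  )
}

#' Projected planar coordinates for kriging distances
#'
#' Distances are computed on a local equirectangular projection about the
#' domain's central latitude: 1 degree of latitude = `km_per_deg` km and 1
#' degree of longitude = `km_per_deg * cos(ref_lat)` km.  At the extent of
#' the analysis domain this is accurate to a few percent, which is ample for
#' variogram fitting and kriging weights.
#'
#' @param lat,lon coordinate vectors in degrees.
#' @param ref_lat reference latitude for the longitude scale factor.
#' @param km_per_deg kilometres per degree of latitude (default 111.0).
#' @return A two-column matrix of `x` (east) and `y` (north) in km.
#' @export
project_km <- function(lat, lon, ref_lat = 54.5, km_per_deg = 111.0) {
  cbind(x = lon * km_per_deg * cos(ref_lat * pi / 180),
        y = lat * km_per_deg)
}

#' Kriged field for one 5-year period
#'
#' Container for a gridded field (log-abundance or SST) over the analysis
#' grid, produced by [krige_field()] or [period_mean_field()].
#'
#' @param values numeric matrix, rows = latitude (south to north), columns =
#'   longitude (west to east).
#' @param grid an [analysis_grid()].
#' @param period one row of [period_table()] (or `NULL`).
#' @param month month 1--12, or `NA` for a period-mean field.
#' @param n_months number of monthly fields averaged into this one.
#' @return An object of class `period_grid`.
#' @export
period_grid <- function(values, grid, period = NULL, month = NA_integer_,
                        n_months = 1L) {
  stopifnot(is.matrix(values),
            nrow(values) == length(grid$lat),
            ncol(values) == length(grid$lon))
  structure(list(values = values, grid = grid, period = period,
                 month = month, n_months = n_months),
            class = "period_grid")
}

#' @export
print.period_grid <- function(x, ...) {
  lab <- if (is.null(x$period)) "?" else x$period$label
  mon <- if (is.na(x$month)) sprintf("mean of %d months", x$n_months)
         else sprintf("month %d", x$month)
  cat(sprintf("<period_grid> %s (%s): %d x %d cells, range [%.3g, %.3g]\n",
              lab, mon, nrow(x$values), ncol(x$values),
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

# run RNG-dependent code under a fixed seed without disturbing the caller's
# RNG stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}
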