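#' Percentage of a population north of an isotherm
#'
#' For each longitude column where the isotherm latitude is known, the mass
#' (kriged log-abundance) north of the isotherm is accumulated; the cell
#' containing the isotherm contributes the linear fraction of its value
#' lying north of the line.  Columns with a missing isotherm latitude are
#' excluded from both numerator and denominator.
#'
#' @param field a [period_grid()] of log-abundance.
#' @param track an [isotherm_latitude()] result for the same period.
#' @return Percentage in `[0, 100]`.
#' @export
percent_north <- function(field, track) {
  stopifnot(inherits(field, "period_grid"),
            inherits(track, "isotherm_track"))
  grid <- field$grid
  stopifnot(length(track$longitude) == length(grid$lon))
  half <- grid$cell / 2
  cols <- which(!is.na(track$latitude))
  if (length(cols) == 0) stop("no non-missing isotherm columns")
  north <- 0; total <- 0
  for (j in cols) {
    v <- field$values[, j]
    iso <- track$latitude[j]
    frac <- pmin(1, pmax(0, (grid$lat + half - iso) / grid$cell))
    north <- north + sum(v * frac, na.rm = TRUE)
    total <- total + sum(v, na.rm = TRUE)
  }
  if (total <= 0) stop("total field mass is not positive")
  100 * north / total
}

#' Z-score a series
#'
#' @param x numeric series of length >= 2.
#' @return `(x - mean(x)) / sd(x)` with the sample (n-1) standard
#'   deviation.
#' @export
zscore_series <- function(x) {
  if (length(x) < 2) stop("need >= 2 values to z-score")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("constant series: z-score degenerate")
  (x - mean(x)) / s
}

#' Median latitude of a kriged range
#'
#' The latitude at which the south-to-north cumulative sum of row totals
#' reaches half the total mass, interpolating linearly within the crossing
#' row's cell (mass assumed uniform within a cell).
#'
#' @param field a [period_grid()] of log-abundance.
#' @return Latitude in degrees N.
#' @export
median_range_latitude <- function(field) {
  stopifnot(inherits(field, "period_grid"))
  grid <- field$grid
  rows <- rowSums(field$values, na.rm = TRUE)
  total <- sum(rows)
  if (total <= 0) stop("total field mass is not positive")
  cs <- cumsum(rows)
  half <- total / 2
  i <- which(cs >= half)[1]
  below <- if (i == 1) 0 else cs[i - 1]
  bottom <- grid$lat[i] - grid$cell / 2
  bottom + grid$cell * (half - below) / rows[i]
}

#' Population index of a kriged field
#'
#' The mean of the kriged values over all (non-missing) grid cells; on the
#' log scale this is the per-period population index plotted against SST.
#'
#' @param field a [period_grid()].
#' @return Mean grid value.
#' @export
population_index <- function(field) {
  stopifnot(inherits(field, "period_grid"))
  v <- field$values[is.finite(field$values)]
  if (length(v) == 0) stop("field has no finite cells")
  mean(v)
}

#' Northward displacement between two latitudes
#'
#' @param lat_start,lat_end latitudes in degrees N.
#' @param km_per_deg kilometres per degree of latitude (111.0, consistent
#'   with 10 degrees ~ 1,110 km).
#' @return Displacement in km, positive northwards.
#' @export
displacement_km <- function(lat_start, lat_end, km_per_deg = 111.0) {
  (lat_end - lat_start) * km_per_deg
}

#' Per-decade velocity of a displacement between two 5-year periods
#'
#' The divisor is the inclusive calendar span from the start of the first
#' period to the end of the last, in decades: for 1984--1988 to 2004--2008
#' that is (2008 - 1984 + 1)/10 = 2.5 decades.
#'
#' @param displacement displacement in km.
#' @param start,end rows of [period_table()] (lists with `start_year`,
#'   `end_year`).
#' @return Velocity in km per decade.
#' @export
per_decade_velocity <- function(displacement, start, end) {
  span <- (end$end_year - start$start_year + 1) / 10
  if (span <= 0) stop("end period must follow start period")
  displacement / span
}
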