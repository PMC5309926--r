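#' Locate an isotherm's latitude at each longitude column
#'
#' For each 0.5-degree longitude column of a kriged SST field, a polynomial
#' (cubic by default) of SST on latitude is fitted and solved for the
#' latitudes at which it equals `temp`.  Among real roots inside the
#' column's latitude span, only crossings where the fitted SST decreases
#' northwards are physically meaningful (the poleward-cooling front); if
#' several such crossings exist their median is taken.  Columns without a
#' qualifying root are recorded as missing.
#'
#' @param sst_grid a [period_grid()] of SST (degC).
#' @param temp isotherm temperature in degC.
#' @param degree polynomial degree; columns with fewer than `degree + 3`
#'   valid cells fall back to the largest degree their support allows.
#' @return An object of class `isotherm_track`: list with `temp`, `period`,
#'   `longitude` (the 56 column centres), `latitude` (per-column isotherm
#'   latitude, `NA` where missing) and `mean_latitude`.
#' @export
isotherm_latitude <- function(sst_grid, temp, degree = 3) {
  stopifnot(inherits(sst_grid, "period_grid"), degree >= 1)
  grid <- sst_grid$grid
  lats <- grid$lat
  out <- rep(NA_real_, length(grid$lon))
  for (j in seq_along(grid$lon)) {
    sst <- sst_grid$values[, j]
    ok <- is.finite(sst)
    if (sum(ok) < 2) next
    deg <- min(degree, max(1, sum(ok) - 3))
    out[j] <- column_isotherm(lats[ok], sst[ok], temp, deg)
  }
  if (all(is.na(out)))
    stop(sprintf("isotherm %g degC not found at any longitude", temp))
  structure(list(temp = temp, period = sst_grid$period,
                 longitude = grid$lon, latitude = out,
                 mean_latitude = mean(out, na.rm = TRUE)),
            class = "isotherm_track")
}

# one column: fit poly of given degree, return the qualifying crossing
column_isotherm <- function(lat, sst, temp, degree) {
  # centre latitude for numerical conditioning of the monomial basis
  mu <- mean(lat)
  X <- outer(lat - mu, 0:degree, `^`)
  coef <- stats::lm.fit(X, sst)$coefficients
  coef[1] <- coef[1] - temp
  roots <- polyroot(coef)
  re <- Re(roots)[abs(Im(roots)) < 1e-8]
  re <- re[re >= min(lat) - mu & re <= max(lat) - mu]
  if (length(re) == 0) return(NA_real_)
  # derivative of the polynomial at each candidate root
  dcoef <- coef[-1] * seq_len(degree)
  slope <- vapply(re, function(z)
    sum(dcoef * z^(seq_len(degree) - 1)), 0)
  cand <- re[slope < 0]
  if (length(cand) == 0) return(NA_real_)
  stats::median(cand) + mu
}

#' @export
print.isotherm_track <- function(x, ...) {
  lab <- if (is.null(x$period)) "?" else x$period$label
  cat(sprintf(
    "<isotherm_track> %g degC, %s: mean latitude %.3f N (%d/%d columns)\n",
    x$temp, lab, x$mean_latitude, sum(!is.na(x$latitude)),
    length(x$latitude)))
  invisible(x)
}

#' Mean latitude of an isotherm track
#'
#' Arithmetic mean of the per-longitude isotherm latitudes over non-missing
#' columns.
#'
#' @param track an [isotherm_latitude()] result.
#' @return Mean latitude in degrees N.
#' @export
mean_isotherm_latitude <- function(track) {
  lat <- track$latitude[!is.na(track$latitude)]
  if (length(lat) == 0) stop("no non-missing isotherm latitudes")
  mean(lat)
}

#' Export isotherm tracks as a long data.frame
#'
#' @param tracks a list of [isotherm_latitude()] results.
#' @return data.frame with columns `temp`, `period`, `longitude`,
#'   `latitude`.
#' @export
isotherm_tracks_df <- function(tracks) {
  do.call(rbind, lapply(tracks, function(tr) {
    data.frame(temp = tr$temp,
               period = if (is.null(tr$period)) NA_character_
                        else tr$period$label,
               longitude = tr$longitude,
               latitude = tr$latitude)
  }))
}
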