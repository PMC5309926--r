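#' Assign tow samples to 5-year period and month buckets
#'
#' Each sample lands in exactly one (period, month) bucket; samples dated
#' before the first or after the last covered year are excluded (a message
#' reports how many).
#'
#' @param samples tow-sample data.frame with a POSIXct `datetime_utc`
#'   column.
#' @param periods a [period_table()].
#' @return The samples with added columns `year`, `month` and
#'   `period_label`, out-of-range rows dropped.
#' @export
assign_periods <- function(samples, periods = period_table()) {
  stopifnot(inherits(samples$datetime_utc, "POSIXct"))
  yr <- as.integer(format(samples$datetime_utc, "%Y", tz = "UTC"))
  mo <- as.integer(format(samples$datetime_utc, "%m", tz = "UTC"))
  idx <- findInterval(yr, periods$start_year)
  keep <- idx >= 1 & yr <= max(periods$end_year)
  if (any(!keep))
    message(sum(!keep), " sample(s) outside ",
            min(periods$start_year), "-", max(periods$end_year),
            " excluded")
  out <- samples[keep, , drop = FALSE]
  out$year <- yr[keep]
  out$month <- mo[keep]
  out$period_label <- periods$label[idx[keep]]
  rownames(out) <- NULL
  out
}

#' Night filter for diel vertically migrating taxa
#'
#' Diel migrators (e.g. the copepod genera *Metridia* and *Pleuromamma*)
#' are only reliably present near the surface at night, so for those taxa
#' only samples taken between 18:00 and 06:00 local solar time are
#' retained.  Local solar time is approximated as UTC + longitude / 15
#' hours.  Non-diel taxa pass through unchanged.
#'
#' @param samples tow-sample data.frame (`taxon`, `longitude`,
#'   `datetime_utc`).
#' @param diel_taxa character vector of taxon ids subject to the filter.
#' @return The filtered data.frame.
#' @export
night_filter <- function(samples, diel_taxa = character()) {
  if (length(diel_taxa) == 0 || !any(samples$taxon %in% diel_taxa))
    return(samples)
  utc_hour <- as.numeric(format(samples$datetime_utc, "%H", tz = "UTC")) +
    as.numeric(format(samples$datetime_utc, "%M", tz = "UTC")) / 60 +
    as.numeric(format(samples$datetime_utc, "%S", tz = "UTC")) / 3600
  local_hour <- (utc_hour + samples$longitude / 15) %% 24
  is_night <- local_hour >= 18 | local_hour < 6
  keep <- !(samples$taxon %in% diel_taxa) | is_night
  out <- samples[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Log-transform abundance counts
#'
#' Counts are transformed as `log(n + 1)` before any spatial analysis.
#'
#' @param count non-negative counts.
#' @param base logarithm base (`exp(1)`, the default, or e.g. `10`).  All
#'   downstream percent-north, median-latitude and correlation statistics
#'   are invariant to the base, which only rescales the transformed values.
#' @return `log(count + 1)` in the chosen base.
#' @export
log_transform <- function(count, base = exp(1)) {
  if (any(count < 0)) stop("negative count")
  log(count + 1, base = base)
}

# semivariance of a fitted model at distances h; gamma(0) = 0 exactly so
# that kriging honours observed values
model_semivariance <- function(model, h) {
  psill <- model$sill - model$nugget
  g <- switch(model$family,
    spherical = ifelse(h >= model$range, psill,
                       psill * (1.5 * h / model$range -
                                0.5 * (h / model$range)^3)),
    exponential = psill * (1 - exp(-h / model$range)),
    gaussian = psill * (1 - exp(-(h / model$range)^2)),
    stop("unknown variogram family ", model$family)
  )
  out <- model$nugget + g
  out[h == 0] <- 0
  out
}

#' Empirical semivariogram on distance bins
#'
#' @param x,y planar coordinates in km (see [project_km()]).
#' @param v values at the points.
#' @param n_bins number of equal-width distance bins.
#' @param cutoff maximum separation considered; default one third of the
#'   maximum pairwise distance, the usual geostatistical convention.
#' @return data.frame with bin mean distance `h`, semivariance `gamma` and
#'   pair count `n`, empty bins dropped.
#' @export
empirical_variogram <- function(x, y, v, n_bins = 15, cutoff = NULL) {
  n <- length(v)
  stopifnot(length(x) == n, length(y) == n)
  d <- as.vector(stats::dist(cbind(x, y)))
  sq <- as.vector(stats::dist(v))^2 / 2
  if (is.null(cutoff)) cutoff <- max(d) / 3
  keep <- d <= cutoff & d > 0
  d <- d[keep]; sq <- sq[keep]
  bins <- cut(d, breaks = seq(0, cutoff, length.out = n_bins + 1),
              include.lowest = TRUE)
  h <- tapply(d, bins, mean)
  g <- tapply(sq, bins, mean)
  nn <- tapply(sq, bins, length)
  ok <- !is.na(g)
  data.frame(h = as.numeric(h[ok]), gamma = as.numeric(g[ok]),
             n = as.integer(nn[ok]))
}

# weighted SSE of one family fit, optimized over (nugget, psill, range)
fit_one_family <- function(emp, family, var_v, max_h) {
  w <- emp$n / emp$h^2
  obj <- function(p) {
    m <- list(family = family, nugget = p[1], sill = p[1] + p[2],
              range = p[3])
    pred <- model_semivariance(m, emp$h)
    sum(w * (emp$gamma - pred)^2)
  }
  starts <- list(c(0.1 * var_v, 0.9 * var_v, max_h / 3),
                 c(0.5 * var_v, 0.5 * var_v, max_h / 10),
                 c(1e-6, var_v, max_h))
  best <- NULL
  for (s in starts) {
    fit <- try(stats::optim(s, obj, method = "L-BFGS-B",
                            lower = c(0, 1e-10, max_h / 200),
                            upper = c(2 * var_v + 1e-10, 5 * var_v + 1e-8,
                                      4 * max_h)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) return(NULL)
  list(family = family, nugget = best$par[1],
       sill = best$par[1] + best$par[2], range = best$par[3],
       fit_score = best$value)
}

#' Fit a variogram model with automatic family selection
#'
#' Computes the empirical semivariogram and fits each candidate family
#' (spherical, exponential, gaussian) by weighted least squares with
#' Cressie-style weights `N_j / h_j^2`; the family with the smallest
#' weighted SSE wins.  This mirrors the automatic model-selection workflow
#' common in applied geostatistics.
#'
#' @param x,y planar coordinates in km.
#' @param v values.
#' @param families candidate families.
#' @param n_bins,cutoff passed to [empirical_variogram()].
#' @return An object of class `variogram_model`: list with `family`,
#'   `nugget`, `sill`, `range` (km) and `fit_score`.
#' @export
fit_variogram <- function(x, y, v,
                          families = c("spherical", "exponential",
                                       "gaussian"),
                          n_bins = 15, cutoff = NULL) {
  if (length(v) < 10)
    stop("insufficient data for variogram: need >= 10 points")
  emp <- empirical_variogram(x, y, v, n_bins = n_bins, cutoff = cutoff)
  if (nrow(emp) < 5)
    stop("insufficient data for variogram: need >= 5 non-empty bins")
  var_v <- stats::var(v)
  if (var_v == 0) stop("constant values: variogram undefined")
  fits <- lapply(families, fit_one_family, emp = emp, var_v = var_v,
                 max_h = max(emp$h))
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) stop("all variogram fits failed")
  best <- fits[[which.min(vapply(fits, `[[`, 0, "fit_score"))]]
  structure(best, class = "variogram_model")
}

#' Effective (practical) range of a variogram model
#'
#' The separation distance at which the model reaches ~95% of its sill:
#' the range parameter itself for the spherical family, three times it for
#' the exponential and `sqrt(3)` times it for the gaussian.  Comparable
#' across families, unlike the raw range parameter.
#'
#' @param model a [fit_variogram()] result.
#' @return Effective range in km.
#' @export
effective_range <- function(model) {
  switch(model$family,
         spherical = model$range,
         exponential = 3 * model$range,
         gaussian = sqrt(3) * model$range,
         stop("unknown variogram family ", model$family))
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf(
    "<variogram_model> %s: nugget %.4g, sill %.4g, range %.4g km (wSSE %.4g)\n",
    x$family, x$nugget, x$sill, x$range, x$fit_score))
  invisible(x)
}

# average values at duplicated coordinates so the kriging system stays
# nonsingular
dedupe_points <- function(x, y, v) {
  key <- paste(signif(x, 10), signif(y, 10))
  if (!anyDuplicated(key)) return(list(x = x, y = y, v = v))
  warning("duplicate coordinates averaged before kriging")
  agg <- rowsum(cbind(v, 1), key)
  ux <- tapply(x, key, `[`, 1)
  uy <- tapply(y, key, `[`, 1)
  ord <- names(ux)
  list(x = as.numeric(ux[ord]), y = as.numeric(uy[ord]),
       v = as.numeric(agg[ord, 1] / agg[ord, 2]))
}

#' Ordinary kriging onto the analysis grid
#'
#' Solves the ordinary kriging system (semivariogram form, with a Lagrange
#' multiplier enforcing unit-sum weights) once for all grid cells.
#' Distances use the local equirectangular projection of [project_km()].
#'
#' @param lat,lon observation coordinates in degrees.
#' @param v observed values (log-abundance or degC).
#' @param model a [fit_variogram()] result.
#' @param grid an [analysis_grid()].
#' @param period,month metadata attached to the result.
#' @param km_per_deg kilometres per degree of latitude.
#' @return A [period_grid()] with the kriged estimates.  Attribute
#'   `max_weight_error` records the largest deviation of any cell's weight
#'   sum from 1.
#' @export
krige_field <- function(lat, lon, v, model, grid = analysis_grid(),
                        period = NULL, month = NA_integer_,
                        km_per_deg = 111.0) {
  stopifnot(length(lat) == length(v), length(lon) == length(v),
            length(v) >= 1, inherits(model, "variogram_model"))
  ref <- (grid$lat_min + grid$lat_max) / 2
  p <- project_km(lat, lon, ref_lat = ref, km_per_deg = km_per_deg)
  pts <- dedupe_points(p[, "x"], p[, "y"], v)
  n <- length(pts$v)
  cells <- expand.grid(lat = grid$lat, lon = grid$lon)
  cp <- project_km(cells$lat, cells$lon, ref_lat = ref,
                   km_per_deg = km_per_deg)
  if (n == 1) {
    vals <- matrix(pts$v, nrow = length(grid$lat), ncol = length(grid$lon))
    out <- period_grid(vals, grid, period = period, month = month)
    attr(out, "max_weight_error") <- 0
    return(out)
  }
  D <- as.matrix(stats::dist(cbind(pts$x, pts$y)))
  A <- rbind(cbind(model_semivariance(model, D), 1), c(rep(1, n), 0))
  d0 <- sqrt(outer(pts$x, cp[, "x"], `-`)^2 +
             outer(pts$y, cp[, "y"], `-`)^2)
  B <- rbind(model_semivariance(model, d0), 1)
  sol <- try(solve(A, B), silent = TRUE)
  if (inherits(sol, "try-error")) {
    # near-singular system (e.g. pure-nugget with coincident-ish points):
    # fall back to a ridge-stabilized solve
    sol <- solve(A + diag(c(rep(1e-8, n), 0)), B)
  }
  w <- sol[seq_len(n), , drop = FALSE]
  pred <- drop(crossprod(w, pts$v))
  vals <- matrix(pred, nrow = length(grid$lat), ncol = length(grid$lon))
  out <- period_grid(vals, grid, period = period, month = month)
  attr(out, "max_weight_error") <- max(abs(colSums(w) - 1))
  out
}

#' Average monthly grids into one 5-yearly field
#'
#' Cell-wise mean over the monthly fields available for a period; months
#' skipped upstream (e.g. for insufficient samples) are simply absent from
#' the mean.  The number of contributing months is recorded.
#'
#' @param monthly_grids list of [period_grid()]s sharing period and shape.
#' @return A [period_grid()] with `month = NA` and `n_months` set.
#' @export
period_mean_field <- function(monthly_grids) {
  monthly_grids <- Filter(Negate(is.null), monthly_grids)
  if (length(monthly_grids) == 0) stop("no monthly grids to average")
  dims <- vapply(monthly_grids, function(g) dim(g$values), integer(2))
  if (any(dims != dims[, 1])) stop("monthly grids differ in shape")
  labs <- vapply(monthly_grids,
                 function(g) if (is.null(g$period)) "" else g$period$label,
                 "")
  if (length(unique(labs)) > 1) stop("monthly grids differ in period")
  acc <- Reduce(`+`, lapply(monthly_grids, `[[`, "values"))
  period_grid(acc / length(monthly_grids),
              grid = monthly_grids[[1]]$grid,
              period = monthly_grids[[1]]$period,
              month = NA_integer_,
              n_months = length(monthly_grids))
}
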