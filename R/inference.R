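#' Effective degrees of freedom for correlated time series
#'
#' Correlations between serially autocorrelated series overstate their
#' nominal sample size.  The effective sample size is re-estimated from the
#' two series' sample autocorrelation functions via the cross-correlation
#' formula
#'
#' \deqn{1/n_{eff} = (1/n) \left(1 + 2 \sum_{j=1}^{J}
#'       \hat\rho_x(j)\,\hat\rho_y(j)\right)}
#'
#' with truncation `J = floor(n/5)` (the Pyper--Peterson realization of the
#' Chelton adjustment).  The estimate is clipped from below at just over 2
#' so a t test remains defined, but deliberately not clipped from above at
#' `n`: the lag-sum is an estimate whose sampling noise is symmetric, and
#' discarding only the noise excursions that would raise `n_eff` while
#' keeping those that lower it makes the resulting test conservative even
#' for serially independent series.  Left unclipped, the test holds its
#' nominal size under independence while still discounting genuinely
#' autocorrelated series.
#'
#' @param x,y numeric series of equal length `n >= 5`.
#' @return Effective sample size (possibly fractional; `Inf` in the
#'   degenerate case of an estimated non-positive total correlation time,
#'   where the t reference collapses to the normal).
#' @export
effective_dof <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 5)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant series: autocorrelation undefined")
  J <- floor(n / 5)
  rx <- stats::acf(x, lag.max = J, plot = FALSE)$acf[-1]
  ry <- stats::acf(y, lag.max = J, plot = FALSE)$acf[-1]
  inv <- (1 + 2 * sum(rx * ry)) / n
  n_eff <- if (inv <= 0) Inf else 1 / inv
  max(n_eff, 2 + 1e-6)
}

#' Test a percent-north series for niche plasticity
#'
#' Pearson correlation between the (z-scored) percentage of a population
#' north of an isotherm and the isotherm's mean latitude, with significance
#' from a t statistic on `n_eff - 2` degrees of freedom where `n_eff` is
#' the autocorrelation-adjusted sample size of [effective_dof()].  The test
#' is one-sided for negative correlation: a population whose range moves
#' less than the isotherm loses proportion north of it as the isotherm
#' moves poleward.
#'
#' @param percent_z percent-north series (z-scored or raw; the correlation
#'   is scale-invariant).
#' @param isotherm_lat mean isotherm latitude series.
#' @param alpha significance level (default 0.05).
#' @return An object of class `plasticity_result`: list with `r`, `n`,
#'   `n_eff`, `p_one_sided` and `significant_negative`.
#' @export
plasticity_test <- function(percent_z, isotherm_lat, alpha = 0.05) {
  n <- length(percent_z)
  stopifnot(length(isotherm_lat) == n, n >= 5)
  r <- stats::cor(percent_z, isotherm_lat)
  if (!is.finite(r)) stop("degenerate series: correlation undefined")
  n_eff <- effective_dof(percent_z, isotherm_lat)
  df <- n_eff - 2
  p <- if (abs(r) >= 1) {
    if (r < 0) 0 else 1
  } else {
    stats::pt(r * sqrt(df / (1 - r^2)), df = df)
  }
  structure(list(r = r, n = n, n_eff = n_eff, p_one_sided = p,
                 alpha = alpha,
                 significant_negative = (r < 0 && p < alpha)),
            class = "plasticity_result")
}

#' @export
print.plasticity_result <- function(x, ...) {
  cat(sprintf(
    "<plasticity_result> r = %.3f (n = %d, n_eff = %.2f), one-sided p = %.4f%s\n",
    x$r, x$n, x$n_eff, x$p_one_sided,
    if (x$significant_negative) " *" else ""))
  invisible(x)
}

#' Correlation between population index and mean SST
#'
#' Two-sided Pearson test with Chelton-adjusted degrees of freedom, applied
#' over one or more period windows (by default the warming window and the
#' full series).  Returns the sign of the correlation if it is significant
#' in any window, preferring the window with the smallest p-value; `"none"`
#' otherwise.
#'
#' @param pop population-index series over all periods.
#' @param sst mean-SST series over the same periods.
#' @param windows named list of integer index vectors (each of length >= 5)
#'   selecting the periods of each window.
#' @param alpha significance level.
#' @return list with `sign` (`"+"`, `"-"` or `"none"`) and a `detail`
#'   data.frame of per-window `r`, `n_eff` and two-sided `p`.
#' @export
abundance_sst_correlation <- function(pop, sst,
                                      windows = list(all =
                                        seq_along(pop)),
                                      alpha = 0.05) {
  stopifnot(length(pop) == length(sst))
  rows <- lapply(names(windows), function(w) {
    idx <- windows[[w]]
    stopifnot(length(idx) >= 5)
    x <- pop[idx]; y <- sst[idx]
    r <- stats::cor(x, y)
    if (!is.finite(r)) stop("degenerate series in window ", w)
    n_eff <- effective_dof(x, y)
    df <- n_eff - 2
    p <- if (abs(r) >= 1) 0 else
      2 * stats::pt(-abs(r) * sqrt(df / (1 - r^2)), df = df)
    data.frame(window = w, r = r, n = length(idx), n_eff = n_eff, p = p)
  })
  detail <- do.call(rbind, rows)
  sig <- detail[detail$p < alpha, , drop = FALSE]
  sign <- if (nrow(sig) == 0) "none" else
    if (sig$r[which.min(sig$p)] > 0) "+" else "-"
  list(sign = sign, detail = detail)
}

#' Classify a taxon as niche-plastic or niche-conservative
#'
#' A taxon is `plastic_all3` if its percent-north series shows a
#' significant negative correlation with isotherm latitude at all three
#' reference isotherms, `plastic_partial` if at one or two, and
#' `conservative` if at none.  Median-latitude movements are reported for
#' the cooling and warming windows.
#'
#' @param results list of three [plasticity_test()] results (one per
#'   isotherm, named by temperature).
#' @param median_latitude named numeric vector of per-period median
#'   latitudes (names = period labels).
#' @param population named numeric vector of per-period population indices.
#' @param cooling,warming character vectors of two period labels each:
#'   `c(start, end)` of the cooling and warming windows.
#' @param taxon taxon id.
#' @param km_per_deg km per degree of latitude.
#' @return An object of class `taxon_classification`: list with `taxon`,
#'   `verdict`, `n_significant`, `movement_cooling_km`,
#'   `movement_warming_km`, `abundance_mean`, `abundance_sd`.
#' @export
classify_taxon <- function(results, median_latitude, population,
                           cooling = c("1959-1963", "1984-1988"),
                           warming = c("1984-1988", "2004-2008"),
                           taxon = NA_character_, km_per_deg = 111.0) {
  stopifnot(length(results) == 3)
  need <- unique(c(cooling, warming))
  missing <- setdiff(need, names(median_latitude))
  if (length(missing) > 0)
    stop("median latitude missing for period(s): ",
         paste(missing, collapse = ", "))
  n_sig <- sum(vapply(results, `[[`, FALSE, "significant_negative"))
  verdict <- if (n_sig == 3) "plastic_all3" else
    if (n_sig > 0) "plastic_partial" else "conservative"
  mv <- function(w) displacement_km(median_latitude[[w[1]]],
                                    median_latitude[[w[2]]],
                                    km_per_deg = km_per_deg)
  structure(list(taxon = taxon, verdict = verdict, n_significant = n_sig,
                 movement_cooling_km = mv(cooling),
                 movement_warming_km = mv(warming),
                 abundance_mean = mean(population),
                 abundance_sd = stats::sd(population)),
            class = "taxon_classification")
}

#' Seasonal peak of a monthly abundance profile
#'
#' The abundance-weighted mean month, `S_p = sum(M * x_m) / sum(x_m)` for
#' months `M = 1..12`.  Taxa with two seasonal blooms (local maxima at
#' least 3 months apart, the minor at least 60% of the major) would have
#' their weighted mean fall between the blooms, so for bimodal profiles
#' the weighted mean is restricted to months within a circular distance of
#' 3 from the most populous peak.
#'
#' @param x_m twelve monthly mean abundances, all `>= 0`, not all zero.
#' @return Seasonal peak `S_p` in fractional months.  For unimodal (and
#'   full-profile) means this lies in `[1, 12]`; when a bimodal taxon's
#'   bloom window wraps the year boundary the value is circular, in
#'   `(0.5, 12.5]` (e.g. 12.5 is the turn of the year).
#' @export
seasonal_peak <- function(x_m) {
  stopifnot(length(x_m) == 12)
  if (any(x_m < 0)) stop("negative monthly abundance")
  if (all(x_m == 0)) stop("all-zero seasonal profile")
  months <- 1:12
  if (is_bimodal(x_m)) {
    major <- which.max(x_m)
    # unwrap months relative to the major peak so a window crossing the
    # year boundary averages correctly, then wrap back into [1, 12]
    delta <- ((months - major + 5) %% 12) - 5   # in -5..6
    sel <- abs(delta) <= 3
    m_unwrapped <- major + delta[sel]
    sp <- sum(m_unwrapped * x_m[sel]) / sum(x_m[sel])
    sp - 12 * ceiling((sp - 12.5) / 12)   # wrap into (0.5, 12.5]
  } else {
    sum(months * x_m) / sum(x_m)
  }
}

# two circular local maxima >= 3 months apart with minor >= 60% of major
is_bimodal <- function(x_m) {
  prev <- x_m[c(12, 1:11)]; nxt <- x_m[c(2:12, 1)]
  peaks <- which(x_m > prev & x_m >= nxt)
  if (length(peaks) < 2) return(FALSE)
  major <- peaks[which.max(x_m[peaks])]
  others <- setdiff(peaks, major)
  any(month_circular_distance(others, major) >= 3 &
        x_m[others] >= 0.6 * x_m[major])
}

#' Phenological shift between two seasonal profiles
#'
#' @param x_start,x_end twelve-month profiles for the start and end
#'   windows.
#' @return `seasonal_peak(x_end) - seasonal_peak(x_start)` in months;
#'   negative values mean the peak moved earlier in the year.
#' @export
phenological_shift <- function(x_start, x_end) {
  seasonal_peak(x_end) - seasonal_peak(x_start)
}

#' Correlation between range movement and phenological shift
#'
#' Cross-taxon Pearson correlation (ordinary degrees of freedom; the
#' observations are taxa, not time points) between northward range
#' movement and phenological shift within a taxonomic group, two-sided.
#'
#' @param movements_km northward movements, one per taxon.
#' @param shifts_months phenological shifts, one per taxon.
#' @return list with `r`, `n`, `p`.
#' @export
phenology_vs_range <- function(movements_km, shifts_months) {
  n <- length(movements_km)
  stopifnot(length(shifts_months) == n)
  if (n < 4) stop("need >= 4 taxa in group")
  if (stats::sd(movements_km) == 0 || stats::sd(shifts_months) == 0)
    stop("degenerate group: zero variance")
  ct <- stats::cor.test(movements_km, shifts_months, method = "pearson")
  list(r = unname(ct$estimate), n = n, p = ct$p.value)
}
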