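#' Build a pipeline run configuration
#'
#' Collects every tunable of the end-to-end analysis in one list.  Input
#' data are either supplied (`tows`, `sst` data.frames or CSV paths) or
#' generated by the synthetic module from `plan`, `scenario` and `taxa`.
#'
#' @param tows tow samples: data.frame, CSV path, or `NULL` to simulate.
#' @param sst monthly gridded SST: long-format data.frame (`year`, `month`,
#'   `lat`, `lon`, `sst`), CSV path, or `NULL` to simulate.
#' @param plan,scenario,taxa synthetic-data inputs used when `tows` /
#'   `sst` are `NULL`.
#' @param grid the [analysis_grid()].
#' @param periods the [period_table()].
#' @param isotherm_temps reference isotherm temperatures (degC),
#'   strictly increasing.
#' @param diel_taxa taxon ids subject to the night filter (when simulating,
#'   derived from the taxon specs by default).
#' @param cooling,warming period-label pairs bounding the cooling and
#'   warming movement windows.
#' @param alpha significance level for all tests.
#' @param log_base base of the abundance log transform.
#' @param km_per_deg kilometres per degree of latitude.
#' @param min_samples minimum samples per (period, month, taxon) bucket;
#'   smaller buckets are skipped (logged), never kriged.
#' @param abundance_floor detection floor in transformed (log(n+1))
#'   units: cells of a period-mean abundance field below it are set to 0
#'   (taxon absent).  Kriging in regions empty of a taxon leaves low-level
#'   noise of either sign which, accumulated over the ~2,000 cells of the
#'   grid, can rival a compact range's tail mass and bias mass-fraction
#'   statistics; the default 0.15 (under one organism per five samples)
#'   sits a few standard deviations above that noise while trimming only
#'   the extreme skirt of a real range.
#' @param max_krige_points cap on points entering one kriging system;
#'   larger buckets are randomly thinned (seeded).  Bounds the cost of the
#'   dense solve with negligible loss at these sampling densities.
#' @param seed master seed for bucket thinning.
#' @param out_dir if non-`NULL`, result CSVs are written there.
#' @return A list of class `run_config`.
#' @export
run_config <- function(tows = NULL, sst = NULL,
                       plan = NULL, scenario = NULL, taxa = NULL,
                       grid = analysis_grid(), periods = period_table(),
                       isotherm_temps = c(11, 12, 13),
                       diel_taxa = NULL,
                       cooling = c("1959-1963", "1984-1988"),
                       warming = c("1984-1988", "2004-2008"),
                       alpha = 0.05, log_base = exp(1),
                       km_per_deg = 111.0,
                       min_samples = 30, max_krige_points = 1000,
                       abundance_floor = 0.15,
                       seed = 1L, out_dir = NULL) {
  if (any(diff(isotherm_temps) <= 0))
    stop("isotherm temperatures must be strictly increasing")
  if (is.null(tows) && (is.null(plan) || is.null(scenario) ||
                        is.null(taxa) || length(taxa) == 0))
    stop("no taxa: supply tows or a synthetic plan/scenario/taxa block")
  if (is.null(diel_taxa))
    diel_taxa <- if (is.null(taxa)) character() else
      vapply(Filter(function(t) t$diel_migrator, taxa), `[[`, "", "name")
  structure(list(tows = tows, sst = sst, plan = plan, scenario = scenario,
                 taxa = taxa, grid = grid, periods = periods,
                 isotherm_temps = isotherm_temps, diel_taxa = diel_taxa,
                 cooling = cooling, warming = warming, alpha = alpha,
                 log_base = log_base, km_per_deg = km_per_deg,
                 min_samples = min_samples,
                 max_krige_points = max_krige_points,
                 abundance_floor = abundance_floor,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Demo configuration: two synthetic taxa with known niche behaviour
#'
#' One thermally conservative taxon (optimum 12.25 degC, so its range
#' tracks the moving isotherms) and one plastic taxon anchored at 54.5
#' degrees N, sampled at 2,000 tows per year over 1954--2013 under the
#' default cooling-then-warming scenario.  The conservative taxon's
#' geometry follows a containment rule: its measurable range (niche width
#' times the SST gradient, plus the zonal tilt of the isotherms and the
#' kriging smoothing scale) must stay inside the study box in every
#' period, because a range pressed against a domain edge is truncated
#' there, which attenuates apparent range shifts and leaks a spurious
#' plasticity signal; at the same time the three reference isotherms
#' should straddle the range so each crosses a well-populated part of the
#' distribution, where mass-fraction statistics are stable.  Running the
#' pipeline on this configuration should classify the taxa as
#' `conservative` and `plastic_all3` respectively.
#'
#' @param n_tows_per_year sampling density.
#' @param seed master seed, from which the scenario, plan and taxon seeds
#'   are derived.
#' @param ... further arguments passed to [run_config()].
#' @return A `run_config`.
#' @export
demo_config <- function(n_tows_per_year = 2000, seed = 1L, ...) {
  seed <- as.integer(seed)
  scenario <- sst_scenario(seed = seed)
  plan <- sampling_plan(n_tows_per_year = n_tows_per_year,
                        seed = seed + 1L)
  taxa <- list(
    taxon_spec("tracker", niche_mode = "conservative",
               thermal_optimum = 12.25, seed = seed + 2L),
    taxon_spec("stayer", niche_mode = "plastic",
               home_latitude = 54.5, seed = seed + 3L)
  )
  run_config(plan = plan, scenario = scenario, taxa = taxa,
             seed = seed, ...)
}

# resolve data.frame / path / synthetic inputs
resolve_inputs <- function(config) {
  tows <- config$tows
  if (is.character(tows)) tows <- read_tows(tows)
  if (is.null(tows))
    tows <- generate_tows(config$plan, config$scenario, config$taxa)
  sst <- config$sst
  if (is.character(sst)) sst <- read_sst_csv(sst)
  if (is.null(sst)) {
    if (is.null(config$scenario)) stop("no SST input and no scenario")
    sst <- generate_sst_field(config$scenario)
  }
  list(tows = tows, sst = sst)
}

# krige one (period, month) bucket of point values; returns NULL if the
# bucket is too small
krige_bucket <- function(lat, lon, v, config, period, month, log) {
  n <- length(v)
  if (n < config$min_samples) {
    log$push(sprintf("skip %s month %d: %d < %d samples",
                     period$label, month, n, config$min_samples))
    return(NULL)
  }
  if (n > config$max_krige_points) {
    keep <- sample.int(n, config$max_krige_points)
    lat <- lat[keep]; lon <- lon[keep]; v <- v[keep]
  }
  ref <- (config$grid$lat_min + config$grid$lat_max) / 2
  p <- project_km(lat, lon, ref_lat = ref, km_per_deg = config$km_per_deg)
  model <- tryCatch(
    fit_variogram(p[, "x"], p[, "y"], v),
    error = function(e) {
      log$push(sprintf("skip %s month %d: %s", period$label, month,
                       conditionMessage(e)))
      NULL
    })
  if (is.null(model)) return(NULL)
  suppressWarnings(
    krige_field(lat, lon, v, model, grid = config$grid, period = period,
                month = month, km_per_deg = config$km_per_deg))
}

# small append-only log used across pipeline stages
new_log <- function() {
  lines <- character()
  list(push = function(msg) lines <<- c(lines, msg),
       get = function() lines)
}

#' Run the full range-shift analysis pipeline
#'
#' Stages: (1) resolve or simulate inputs; (2) krige monthly SST per 5-year
#' period to the 0.5-degree grid and average into 5-yearly SST fields;
#' (3) per taxon, apply the night filter (diel taxa only), bucket samples
#' by (period, month), log-transform and krige each bucket, and average
#' months into 5-yearly abundance fields; (4) track the reference isotherms
#' and their mean latitudes; (5) compute percent-north, median latitude and
#' population index per taxon and period; (6) run the plasticity tests,
#' classification, abundance--SST correlations and phenology statistics.
#'
#' @param config a [run_config()].
#' @return An object of class `plankton_run`: list with `isotherms`
#'   (per-period mean latitudes), `trajectories` (per taxon/period/isotherm
#'   percent-north etc.), `plasticity` (per taxon/isotherm test results),
#'   `report` (one row per taxon in the reference-table layout),
#'   `phenology`, `sst_summary`, `fields` (the 5-yearly grids) and `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- new_log()
  inputs <- resolve_inputs(config)
  periods <- config$periods
  grid <- config$grid

  with_seed(config$seed, {

  ## --- SST fields: per period, krige each month's 5-year cell means ----
  sst <- inputs$sst
  sst_fields <- vector("list", nrow(periods))
  names(sst_fields) <- periods$label
  for (i in seq_len(nrow(periods))) {
    per <- periods[i, ]
    in_per <- sst[sst$year >= per$start_year & sst$year <= per$end_year, ]
    monthly <- vector("list", 12)
    for (m in 1:12) {
      mm <- in_per[in_per$month == m, ]
      if (nrow(mm) == 0) next
      cell <- stats::aggregate(sst ~ lat + lon, data = mm, FUN = mean)
      monthly[[m]] <- krige_bucket(cell$lat, cell$lon, cell$sst, config,
                                   per, m, log)
    }
    sst_fields[[i]] <- period_mean_field(monthly)
  }

  ## --- isotherm tracks ------------------------------------------------
  tracks <- list()
  iso_rows <- list()
  for (temp in config$isotherm_temps) {
    for (lab in periods$label) {
      tr <- isotherm_latitude(sst_fields[[lab]], temp)
      tracks[[paste(temp, lab)]] <- tr
      iso_rows[[paste(temp, lab)]] <-
        data.frame(temp = temp, period = lab,
                   mean_latitude = tr$mean_latitude)
    }
  }
  isotherms <- do.call(rbind, iso_rows)
  rownames(isotherms) <- NULL

  ## --- abundance fields per taxon -------------------------------------
  tows <- assign_periods(inputs$tows, periods)
  taxa_ids <- unique(tows$taxon)
  fields <- list()
  phen_rows <- list()
  for (tx in taxa_ids) {
    samp <- night_filter(tows[tows$taxon == tx, , drop = FALSE],
                         config$diel_taxa)
    fields[[tx]] <- vector("list", nrow(periods))
    names(fields[[tx]]) <- periods$label
    for (i in seq_len(nrow(periods))) {
      per <- periods[i, ]
      in_per <- samp[samp$period_label == per$label, ]
      monthly <- vector("list", 12)
      for (m in 1:12) {
        mm <- in_per[in_per$month == m, ]
        if (nrow(mm) == 0) next
        monthly[[m]] <- krige_bucket(
          mm$latitude, mm$longitude,
          log_transform(mm$count, base = config$log_base),
          config, per, m, log)
      }
      fields[[tx]][[i]] <- tryCatch({
        f <- period_mean_field(monthly)
        f$values[f$values < config$abundance_floor] <- 0
        f
      },
        error = function(e) {
          log$push(sprintf("taxon %s period %s: %s", tx, per$label,
                           conditionMessage(e)))
          NULL
        })
    }
    ## phenology: monthly mean log-abundance from the raw (filtered)
    ## samples in the warming-window endpoint periods
    for (lab in config$warming) {
      in_per <- samp[samp$period_label == lab, ]
      x_m <- vapply(1:12, function(m) {
        v <- in_per$count[in_per$month == m]
        if (length(v) == 0) 0 else
          mean(log_transform(v, base = config$log_base))
      }, 0)
      phen_rows[[paste(tx, lab)]] <-
        data.frame(taxon = tx, period = lab,
                   t(stats::setNames(x_m, sprintf("m%02d", 1:12))))
    }
  }

  ## --- range metrics ---------------------------------------------------
  traj_rows <- list()
  for (tx in taxa_ids) {
    for (lab in periods$label) {
      f <- fields[[tx]][[lab]]
      if (is.null(f)) next
      med <- median_range_latitude(f)
      pop <- population_index(f)
      for (temp in config$isotherm_temps) {
        tr <- tracks[[paste(temp, lab)]]
        traj_rows[[paste(tx, lab, temp)]] <- data.frame(
          taxon = tx, period = lab, isotherm_temp = temp,
          percent_north = percent_north(f, tr),
          median_latitude = med, population_index = pop)
      }
    }
  }
  trajectories <- do.call(rbind, traj_rows)
  rownames(trajectories) <- NULL
  ## z-score the percent-north series within taxon x isotherm
  trajectories$percent_north_z <- stats::ave(
    trajectories$percent_north,
    trajectories$taxon, trajectories$isotherm_temp,
    FUN = function(x) if (length(x) >= 2 && stats::sd(x) > 0)
      zscore_series(x) else NA_real_)

  ## --- inference -------------------------------------------------------
  sst_summary <- data.frame(
    period = periods$label,
    mean_sst = vapply(periods$label,
                      function(l) population_index(sst_fields[[l]]), 0))
  warm_idx <- which(periods$label >= config$warming[1] &
                    periods$label <= config$warming[2])
  plas_rows <- list()
  report_rows <- list()
  phenology <- do.call(rbind, phen_rows)
  rownames(phenology) <- NULL
  for (tx in taxa_ids) {
    res3 <- list()
    for (temp in config$isotherm_temps) {
      sub <- trajectories[trajectories$taxon == tx &
                          trajectories$isotherm_temp == temp, ]
      iso <- isotherms[isotherms$temp == temp, ]
      common <- intersect(sub$period, iso$period)
      if (length(common) < 5) {
        log$push(sprintf("taxon %s isotherm %g: only %d periods, test skipped",
                         tx, temp, length(common)))
        next
      }
      pt <- plasticity_test(
        sub$percent_north[match(common, sub$period)],
        iso$mean_latitude[match(common, iso$period)],
        alpha = config$alpha)
      res3[[as.character(temp)]] <- pt
      plas_rows[[paste(tx, temp)]] <- data.frame(
        taxon = tx, isotherm_temp = temp, r = pt$r, n = pt$n,
        n_eff = pt$n_eff, p_one_sided = pt$p_one_sided,
        significant_negative = pt$significant_negative)
    }
    sub <- trajectories[trajectories$taxon == tx &
                        trajectories$isotherm_temp ==
                          config$isotherm_temps[1], ]
    med <- stats::setNames(sub$median_latitude, sub$period)
    pop <- stats::setNames(sub$population_index, sub$period)
    if (length(res3) != 3 ||
        !all(unlist(config$cooling) %in% names(med)) ||
        !all(unlist(config$warming) %in% names(med))) {
      log$push(sprintf("taxon %s: incomplete series, not classified", tx))
      next
    }
    cls <- classify_taxon(res3, med, pop,
                          cooling = config$cooling,
                          warming = config$warming,
                          taxon = tx, km_per_deg = config$km_per_deg)
    common <- intersect(names(pop), sst_summary$period)
    corr <- abundance_sst_correlation(
      pop[common],
      sst_summary$mean_sst[match(common, sst_summary$period)],
      windows = list(warming = match(periods$label[warm_idx], common),
                     all = seq_along(common)),
      alpha = config$alpha)
    ## phenological shift over the warming window
    pr <- phenology[phenology$taxon == tx, ]
    shift <- tryCatch({
      xs <- as.numeric(pr[pr$period == config$warming[1], -(1:2)])
      xe <- as.numeric(pr[pr$period == config$warming[2], -(1:2)])
      phenological_shift(xs, xe)
    }, error = function(e) {
      log$push(sprintf("taxon %s: phenology degenerate (%s)", tx,
                       conditionMessage(e)))
      NA_real_
    })
    report_rows[[tx]] <- data.frame(
      taxon = tx, verdict = cls$verdict,
      n_isotherms_negative = cls$n_significant,
      movement_cooling_km = cls$movement_cooling_km,
      movement_warming_km = cls$movement_warming_km,
      sst_corr_sign = corr$sign,
      abundance_mean = cls$abundance_mean,
      abundance_sd = cls$abundance_sd,
      phenological_shift_months = shift)
  }
  report <- do.call(rbind, report_rows)
  rownames(report) <- NULL
  plasticity <- do.call(rbind, plas_rows)
  rownames(plasticity) <- NULL

  out <- structure(list(isotherms = isotherms,
                        trajectories = trajectories,
                        plasticity = plasticity,
                        report = report,
                        phenology = phenology,
                        sst_summary = sst_summary,
                        fields = fields,
                        sst_fields = sst_fields,
                        config = config,
                        log = log$get()),
                   class = "plankton_run")
  if (!is.null(config$out_dir)) write_run(out, config$out_dir)
  out

  })
}

#' @export
print.plankton_run <- function(x, ...) {
  cat(sprintf("<plankton_run> %d taxa, %d periods, isotherms %s degC\n",
              length(unique(x$trajectories$taxon)),
              length(unique(x$trajectories$period)),
              paste(x$config$isotherm_temps, collapse = "/")))
  if (!is.null(x$report)) {
    cat("\n")
    print(x$report[, c("taxon", "verdict", "movement_cooling_km",
                       "movement_warming_km", "sst_corr_sign")],
          row.names = FALSE)
  }
  if (length(x$log)) cat("\n", length(x$log), "log message(s)\n")
  invisible(x)
}

# write the standard result CSVs and the run log
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  w(run$report, "taxon_report.csv")
  w(run$isotherms, "isotherm_summary.csv")
  w(run$trajectories, "trajectories.csv")
  w(run$phenology, "phenology.csv")
  writeLines(run$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' Group-level summary of range movements
#'
#' @param report a data.frame with at least `taxon`, `verdict` (or
#'   `n_isotherms_negative`), `movement_warming_km` and optionally
#'   `movement_cooling_km`.
#' @param warming_decades length of the warming window in decades (2.5 for
#'   1984--1988 to 2004--2008).
#' @param threshold_km movement magnitude defining a "large" shift.
#' @return list with per-group mean warming movements (`all`,
#'   `conservative`, `plastic_all3`, in km and km/decade), counts of taxa
#'   moving more than `threshold_km` north and south in the warming
#'   window, the maximum pairwise movement difference, and per-taxon net
#'   movements over both windows.
#' @export
summarize_groups <- function(report, warming_decades = 2.5,
                             threshold_km = 100) {
  stopifnot(nrow(report) > 0)
  if (!"verdict" %in% names(report) &&
      "n_isotherms_negative" %in% names(report)) {
    n <- report$n_isotherms_negative
    report$verdict <- ifelse(n == 3, "plastic_all3",
                             ifelse(n > 0, "plastic_partial",
                                    "conservative"))
  }
  mw <- report$movement_warming_km
  grp_mean <- function(sel)
    if (!any(sel)) NULL else
      list(n = sum(sel), mean_km = mean(mw[sel]),
           mean_km_per_decade = mean(mw[sel]) / warming_decades)
  net <- if ("movement_cooling_km" %in% names(report))
    data.frame(taxon = report$taxon,
               net_movement_km = report$movement_cooling_km + mw)
  else NULL
  list(
    all = grp_mean(rep(TRUE, nrow(report))),
    conservative = grp_mean(report$verdict == "conservative"),
    plastic_all3 = grp_mean(report$verdict == "plastic_all3"),
    n_moved_north = sum(mw > threshold_km),
    n_moved_south = sum(mw < -threshold_km),
    max_difference_km = max(mw) - min(mw),
    net_movements = net
  )
}

#' Reference range-shift table for 35 North-East Atlantic plankton taxa
#'
#' Published median-latitude displacements (km, positive north) of 35
#' diatom, dinoflagellate and copepod taxa and of the 11, 12 and 13 degC
#' isotherms in the NE Atlantic and North Sea, over the 1959--1984 cooling
#' window (period 1959--1963 to 1984--1988) and the 1984--2008 warming
#' window (1984--1988 to 2004--2008), derived from six decades of
#' Continuous Plankton Recorder sampling.  `n_isotherms_negative` counts
#' the isotherms (0--3) at which the taxon's percent-north series showed a
#' significant negative correlation with isotherm latitude;
#' `sst_corr_sign` is the sign of any significant population--SST
#' correlation; `abundance_mean` / `abundance_sd` summarize the
#' log-abundance population index over the twelve 5-year periods.  Groups:
#' DIA diatoms, DIN dinoflagellates, CEU *Calanus*/*Euchaeta*/
#' *Undeuchaeta*, MP *Metridia*/*Pleuromamma*.
#'
#' @return `reference_movements()`: data.frame of the 35 taxa.
#'   `reference_isotherm_movements()`: data.frame of the three isotherms'
#'   displacements over the same windows.
#' @export
reference_movements <- function() {
  utils::read.csv(system.file("extdata", "cpr_range_shifts.csv",
                              package = "planktonshift"),
                  stringsAsFactors = FALSE)
}

#' @rdname reference_movements
#' @export
reference_isotherm_movements <- function() {
  utils::read.csv(system.file("extdata", "cpr_isotherm_shifts.csv",
                              package = "planktonshift"),
                  stringsAsFactors = FALSE)
}
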