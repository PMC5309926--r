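test_that("effective sample size shrinks for autocorrelated series", {
  expect_error(effective_dof(rep(1, 10), rnorm(10)), "constant")
  set.seed(21)
  # white noise: close to nominal on average
  ratio_wn <- mean(replicate(60, effective_dof(rnorm(100), rnorm(100)))) / 100
  expect_gt(ratio_wn, 0.85)
  expect_lt(ratio_wn, 1.15)
  # AR(1) with phi = 0.5: ratio near (1 - phi^2)/(1 + phi^2) = 0.6
  ratio_ar <- mean(replicate(60,
    effective_dof(ar1_series(200, 0.5), ar1_series(200, 0.5)))) / 200
  expect_gt(ratio_ar, 0.54)
  expect_lt(ratio_ar, 0.66)
})

test_that("plasticity test flags perfect anticorrelation and nothing else", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3, 5, 8)
  neg <- plasticity_test(-x, x)
  expect_equal(neg$r, -1)
  expect_equal(neg$p_one_sided, 0)
  expect_true(neg$significant_negative)
  pos <- plasticity_test(x, x)
  expect_equal(pos$r, 1)
  expect_false(pos$significant_negative)
  expect_gte(pos$p_one_sided, 1)
})

test_that("plasticity p-values are invariant to affine transforms", {
  set.seed(22)
  for (i in 1:10) {
    x <- rnorm(12); y <- rnorm(12)
    p0 <- plasticity_test(x, y)$p_one_sided
    expect_equal(plasticity_test(3 * x + 7, y)$p_one_sided, p0)
    expect_equal(plasticity_test(x, 0.2 * y - 40)$p_one_sided, p0)
  }
})

test_that("taxon classification follows the three-isotherm rule", {
  med <- period_named(c(53, 53.2, 53.1, 52.9, 52.7, 52.5, 52.6, 53.0,
                        53.5, 54.0, 54.4, 54.5))
  pop <- period_named(c(1.1, 1.0, 0.9, 1.2, 1.0, 1.1, 1.0, 0.9, 1.0, 1.1,
                        1.2, 1.0))
  all3 <- classify_taxon(replicate(3, make_plasticity(TRUE),
                                   simplify = FALSE), med, pop,
                         taxon = "t")
  expect_equal(all3$verdict, "plastic_all3")
  none <- classify_taxon(replicate(3, make_plasticity(FALSE),
                                   simplify = FALSE), med, pop)
  expect_equal(none$verdict, "conservative")
  one <- classify_taxon(list(make_plasticity(TRUE), make_plasticity(FALSE),
                             make_plasticity(FALSE)), med, pop)
  expect_equal(one$verdict, "plastic_partial")
  expect_equal(one$n_significant, 1)
  # movements are the displacement of the median latitude over each window
  expect_equal(all3$movement_cooling_km,
               111 * (med[["1984-1988"]] - med[["1959-1963"]]))
  expect_equal(all3$movement_warming_km,
               111 * (med[["2004-2008"]] - med[["1984-1988"]]))
  expect_equal(all3$abundance_mean, mean(pop))
  expect_error(classify_taxon(replicate(3, make_plasticity(TRUE),
                                        simplify = FALSE),
                              med[1:3], pop), "missing for period")
})

test_that("abundance-SST correlation reports a sign only when significant", {
  sst <- c(11.8, 11.9, 11.7, 11.6, 11.5, 11.4, 11.6, 11.9, 12.1, 12.3,
           12.5, 12.6)
  up <- abundance_sst_correlation(sst * 2 - 3, sst)
  expect_equal(up$sign, "+")
  dn <- abundance_sst_correlation(-sst, sst)
  expect_equal(dn$sign, "-")
  set.seed(23)
  flat <- abundance_sst_correlation(rnorm(12), sst,
                                    windows = list(all = 1:12))
  expect_true(flat$sign %in% c("+", "-", "none"))
  expect_equal(nrow(flat$detail), 1)
})

test_that("seasonal peak is the abundance-weighted mean month", {
  x <- rep(0, 12); x[6] <- 4
  expect_equal(seasonal_peak(x), 6)
  expect_equal(seasonal_peak(rep(1, 12)), 6.5)
  y <- rep(0, 12); y[4] <- 1; y[8] <- 3
  expect_equal(seasonal_peak(y), 7)   # minor peak below the 60% rule
  expect_equal(seasonal_peak(y * 13.7), 7)  # scale invariance
  expect_error(seasonal_peak(rep(0, 12)), "all-zero")
  expect_error(seasonal_peak(c(-1, rep(1, 11))), "negative")
})

test_that("bimodal profiles restrict the mean to the major bloom", {
  x <- rep(0, 12); x[3] <- 3; x[9] <- 2.5   # two blooms, minor at 83%
  expect_equal(seasonal_peak(x), 3)
  x2 <- c(2.4, rep(0, 5), 3, rep(0, 5))     # major July, minor January
  expect_equal(seasonal_peak(x2), 7)
  # window can wrap across the year boundary (circular value allowed)
  x3 <- rep(0, 12); x3[1] <- 3; x3[12] <- 3; x3[7] <- 2.5
  expect_equal(seasonal_peak(x3), 12.5)  # mid Dec-Jan bloom
  expect_gt(seasonal_peak(x3), 0.5)
  expect_lte(seasonal_peak(x3), 12.5)
})

test_that("phenological shift subtracts the two seasonal peaks", {
  x <- rep(0, 12); x[7] <- 2
  y <- rep(0, 12); y[6] <- 5
  expect_equal(phenological_shift(x, x), 0)
  expect_equal(phenological_shift(x, y), -1)
  set.seed(24)
  a <- runif(12); b <- runif(12)
  expect_equal(phenological_shift(a, b),
               seasonal_peak(b) - seasonal_peak(a))
})

test_that("phenology-range correlation uses ordinary cross-taxon dof", {
  shifts <- c(-0.5, 0.2, -1.1, 0.7, -0.3)
  out <- phenology_vs_range(2 * shifts, shifts)
  expect_equal(out$r, 1, tolerance = 1e-12)
  expect_lt(out$p, 1e-6)
  expect_error(phenology_vs_range(1:3, 1:3), "4 taxa")
  expect_error(phenology_vs_range(rep(1, 5), shifts), "degenerate")
  # independent pairs: p should not be systematically tiny
  set.seed(25)
  ps <- replicate(200, phenology_vs_range(rnorm(12), rnorm(12))$p)
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
})
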