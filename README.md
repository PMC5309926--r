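# planktonshift

Do marine plankton track the velocity of climate change, or do their
ranges lag behind it? `planktonshift` is an R package for answering that
question from ship-of-opportunity survey data (Continuous Plankton
Recorder style tow samples) and gridded sea surface temperature, in the
North-East Atlantic box 45–64° N, 20° W–8° E over 1954–2013. It is aimed
at plankton ecologists and biogeographers who want a tested, reusable
version of the isotherm-tracking analysis rather than a one-off script.

The core logic: the latitude of a reference isotherm (11, 12 or 13 °C) is
the moving edge of a taxon's thermal envelope. If a taxon's range tracks
the isotherm (*niche conservatism*), the proportion of its population
north of that isotherm stays constant; if the range lags (*niche
plasticity*), the proportion north falls as the isotherm moves north. The
package tests, per taxon and isotherm, for a negative Pearson correlation
between the percent-north series and the isotherm's mean-latitude series
across twelve 5-year periods, with the degrees of freedom re-estimated for
serial autocorrelation (Chelton adjustment, Pyper–Peterson form):

    1/n_eff = (1/n) * (1 + 2 * sum_{j=1..J} rho_x(j) * rho_y(j)),
    J = floor(n/5)

and a one-sided t test on `n_eff − 2` degrees of freedom. Around that sit
the supporting stages: 5-yearly monthly ordinary kriging of `log(n+1)`
abundance and SST to a 0.5° grid (automatic spherical / exponential /
gaussian variogram selection), night-filtering of diel vertical migrators
(18:00–06:00 local solar time), per-longitude cubic-polynomial isotherm
tracking, median range latitudes and per-decade velocities
(111 km/degree; inclusive calendar spans, so 1984–1988 → 2004–2008 is
2.5 decades), abundance–SST correlations, and seasonal-peak phenology
`S_p = Σ M·x_m / Σ x_m`.

Because the original survey archives are not redistributable, the package
ships a synthetic-data module that generates SST fields with a known
cooling (1959–1984) / warming (1984–2008) history and CPR-like tow samples
for taxa whose niche behaviour — conservative or plastic — is known by
construction, so the whole pipeline can be validated against ground truth.
A published reference table of range-shift statistics for 35 NE-Atlantic
taxa is bundled (`inst/extdata/`) for arithmetic cross-checks.

## Worked example

The bundled demo pairs a thermally conservative taxon ("tracker", optimum
12.25 °C) with a plastic one ("stayer", anchored at 54.5° N), 2,000 tows
per year for 60 years:

```r
library(planktonshift)
run <- run_pipeline(demo_config(seed = 1))   # ~2 min
print(run)
#> <plankton_run> 2 taxa, 12 periods, isotherms 11/12/13 degC
#>
#>    taxon      verdict movement_cooling_km movement_warming_km sst_corr_sign
#>  tracker conservative          -64.428450        301.65553937             -
#>   stayer plastic_all3            1.118147          0.03665756          none
```

Reading the numbers: the 12 °C isotherm's mean latitude falls from
54.50° N (1954–1958) to 54.39, 54.19 … during the cooling phase and climbs
to 56.54° N by 2004–2008 — a warming-phase displacement of about 301 km
north. The tracker's median range latitude moves 302 km north over the
same window (tracking ratio 1.002) and shows no significant negative
percent-north correlation at any isotherm: verdict `conservative`. The
stayer's range moves 0.04 km while the isotherms sweep past it, and its
percent-north series correlates negatively with isotherm latitude at all
three isotherms: verdict `plastic_all3`. Its phenology also shifted about
one month earlier — with a fixed range, seasonal timing is the remaining
margin of response.

Fleet-level arithmetic on the bundled reference table:

```r
s <- summarize_groups(reference_movements())
round(s$all$mean_km_per_decade)   # 54  km/decade mean poleward shift
s$n_moved_south; s$n_moved_north  # 3 taxa < -100 km; 18 taxa > +100 km
round(s$max_difference_km)        # 905 km spread between extremes

iso <- reference_isotherm_movements()
pt  <- period_table()
per_decade_velocity(iso$movement_warming_km,
                    pt[pt$label == "1984-1988", ],
                    pt[pt$label == "2004-2008", ])
#> 150.960 126.096 104.340   # km/decade at 11, 12, 13 degC
```

A thin command-line front-end is included at
`inst/cli/planktonshift-run.R` (`--config run.yaml --out results/
--seed 1`); the R functions above are the primary interface.

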