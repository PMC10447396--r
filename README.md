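# heatasthma

A time-stratified case-crossover analysis of warm summer temperature and
asthma hospitalisation, packaged end to end: synthetic data with known
ground truth, record cleaning, exposure linkage, referent-stratum
construction, Bayesian conditional Poisson inference, subgroup analyses
and a posterior-draw yearly-trend procedure.

## Who this is for

Environmental epidemiologists and biostatisticians who want a tested,
reproducible implementation of the heat--asthma case-crossover pipeline.
Individual hospital-episode data and residence locations are
confidential, so the package ships a first-class generator that emulates
every real input -- a fine (1 km) daily temperature grid, a coarse
(11 km) grid of meteorological confounders, a holiday calendar, a
patient population, and Poisson admission events with a known effect --
which makes every downstream claim testable without any data access.

## The model

Each admission defines a stratum: the event day plus every other
same-weekday day in the same calendar month and year (3 or 4 referents).
Within stratum *s*, day *j*, admissions are Poisson with

    log mu_sj = alpha_s + beta * x_sj + gamma' z_sj

where `x_sj` is the mean daily temperature, `(Tmin + Tmax)/2`, averaged
over lags 0--3 at the patient's 1 km grid cell (100 m location jitter),
and `z_sj` holds rainfall, relative humidity, wind speed and a national
holiday indicator. Conditioning on stratum totals cancels the `alpha_s`,
leaving the conditional-logistic likelihood; the package fits it with
weakly informative priors by a deterministic Laplace approximation
(optional Metropolis-Hastings cross-check backend). Effects are reported
as the percent change in hospitalisation risk per 1 °C,
`100 * (exp(beta) - 1)`, with 95% credible intervals. Sensitivity
analyses: a random-walk-2 smooth exposure-response curve (shrunk toward
linearity by a second-difference penalty) and an exposure-lag sweep over
windows 0..L for L = 0..5. The yearly trend is estimated by drawing 1000
values from each year's effect posterior and fitting 1000 ordinary
least-squares lines of effect on year.

See `vignettes/case-crossover-methods.Rmd` for the full methods account.

## Worked example

```r
library(heatasthma)

cfg <- sim_config(seed = 2024, years = 2002:2004, grid_shape = c(22, 22),
                  coarse_factor = 11, n_regions = 4, n_patients = 2000,
                  target_events = 5000)       # truth: 2% risk increase per 1 °C
temp <- make_temperature_surface(cfg)
cov  <- make_covariate_surfaces(cfg, temp)
hol  <- make_holiday_calendar(cfg)
pat  <- make_patients(cfg, temp)
rec  <- simulate_admissions(cfg, temp, cov, hol, pat)
rec  <- inject_cascade_noise(rec, c(duplicates = 5, out_of_extent = 2,
                                    non_summer = 10, under_5 = 3, missing = 1))

cleaned <- apply_exclusions(rec)
print(cleaned$report)
#> Exclusion cascade
#>   input records                4883
#>   - removed duplicate records        5
#>   - removed outside extent          2
#>   - removed non-summer months       10
#>   - removed aged under 5            3
#>   - removed missing sex or age        1
#>   retained for analysis        4862

linked <- link_records(cleaned$records, temp, cov, hol, seed = 2024)
strata <- build_strata(linked, temp, cov, hol)
fit <- fit_model(build_design_matrix(strata, adjusted_spec()))
print(fit)
#> <cco_fit> 4862 strata; laplace backend
#>   % change per 1C: 2.19% (95% CrI 0.91% to 3.49%)
#>       term  estimate      lower    upper       se
#> 1     temp  0.021659  0.0090275 0.034291 0.006445
#> 2 rainfall -0.010108 -0.0257328 0.005517 0.007972
#> 3 humidity  0.002985 -0.0004201 0.006390 0.001737
#> 4     wind -0.018077 -0.0398254 0.003671 0.011096
#> 5  holiday -0.222512 -0.4629579 0.017935 0.122679
```

The cascade removes exactly the 21 injected defects; the fitted percent
change per 1 °C (2.19%, CrI 0.91--3.49%) covers the generator's true 2%,
and the `temp` row holds the same estimate on the log-rate scale.
Subgroup re-fits follow the same pattern:

```r
sg <- subgroup_fit(linked, c("sex", "age_group"), adjusted_spec(),
                   temp, cov, hol)
as.data.frame(sg)
#>         subgroup n_events pct_change  lower upper
#> 1  female / 5-15      761       1.69 -1.512  5.00
#> 2    male / 5-15      649       3.13 -0.347  6.73
#> 3 female / 16-64     1229       1.01 -1.477  3.56
#> 4   male / 16-64     1364       1.84 -0.555  4.29
#> 5   female / 65+      460       2.29 -1.983  6.74
#> 6     male / 65+      399       6.03  1.405 10.87
```

Event counts sum to the cohort total, and each subgroup is an
independent full re-fit. `run_pipeline(run_config(...))` performs the
whole sequence -- including RW2 and lag-sweep sensitivity fits and the
yearly trend -- and writes tidy CSV/JSON artifacts plus a manifest of
seeds and hashes.

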