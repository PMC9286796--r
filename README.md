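# waitest

Waiting times to establishment from invasion monitoring trap catches.

`waitest` is for invasion ecologists and pest-management analysts who hold
multi-year pheromone-trap records over an invasion's transition zone and
want to know (1) how long each 5 × 5 km quadrat took to go from first
detection of the invader to local establishment, and (2) which
environmental and anthropogenic characteristics of a quadrat lengthen or
shorten that wait.

## The method

Trap records (`trap_id, x, y, year, count`) are gridded into quadrats and
reduced to yearly **median** catches, after discarding trap-years within
1.5 km of a treated area. Each quadrat's series `y_t` is modeled, on the
`z = log(1 + y)` scale, by a Bayesian local-level state-space model

    z_t = mu_t + eps_t,        eps_t ~ N(0, sigma2_eps)
    mu_{t+1} = mu_t + eta_t,   eta_t ~ N(0, sigma2_eta)

fitted per target year on an expanding window by a forward-filter
backward-sample (FFBS) Gibbs sampler with conjugate inverse-gamma variance
updates. One-step-ahead predictive draws give `p_t`, the posterior
probability that the year's median catch is zero. Then

* **detection** D = first year with median ≥ 1,
* **establishment** E = first year at/after D with `p_t < 0.01`,
* **waiting time** W = E − D.

Waiting times are regressed on quadrat-level drivers (seasonal climate,
elevation, host abundance, human footprint) plus two forced background
variables — year of first detection and the surrounding 3 × 3 neighborhood
mean waiting time — in linear mixed models with a level-IV eco-region
random intercept, with exhaustive all-subsets AIC selection, VIF
diagnostics, and marginal / conditional / driver-only R² (Nakagawa-style
variance decomposition). A synthetic invasion simulator with full ground
truth (traveling wave, covariate-dependent lags, negative-binomial
trapping, treatment discs) backs every stage with recovery tests.

## Worked example

```r
library(waitest)

cfg <- pipeline_config(
  sim = sim_config(n_rows = 10, n_cols = 10, seed = 42),
  drivers = c("winter_temp", "spring_tmax", "summer_precip", "anthro_frag"),
  seed = 42)
run <- run_pipeline(cfg)
run
#> waitest pipeline run (seed 42 )
#>   traps          9300
#>   treatments     31
#>   quadrats       100
#>   eligible       100
#>   included       100
#>   analysis_rows  100
#>   models         16

summarize_waiting_times(run$establishment,
                        run$sim$landscape[, c("row", "col", "level2")])
#> # A tibble: 4 × 6
#>   subregion                       n  mean median   q25   q75
#>   <chr>                       <int> <dbl>  <dbl> <dbl> <dbl>
#> 1 overall                       100  9.03      9     7    10
#> 2 northern_mixed_wood_shield     40  9.95      9     7    12
#> 3 central_plains                 30  7.77      8     7     9
#> 4 southeastern_forests_plains    30  9.07      9     8    10

run$regression
#> All-subsets AIC selection: 16 models fitted
#> Best model terms: winter_temp+spring_tmax
#> Mixed model: waiting_time ~ winter_temp + spring_tmax + detection_year +
#>   neighborhood_wait + (1 | level4 )
#>   n = 100, AIC = 405.6, logLik = -195.8 (ML)
#>   R2 marginal = 0.588, conditional = 0.609

tidy(run$regression$best)
#> # A tibble: 5 × 4
#>   term              estimate std.error statistic
#>   <chr>                <dbl>     <dbl>     <dbl>
#> 1 (Intercept)          9.02      0.204    44.3
#> 2 winter_temp         -2.27      0.534    -4.25
#> 3 spring_tmax          2.36      0.552     4.29
#> 4 detection_year      -1.25      0.275    -4.54
#> 5 neighborhood_wait    0.328     0.358     0.916
```

Reading the output: the simulated wave takes on average ~9 years from
detection to establishment per quadrat. The AIC search over the 2⁴ driver
subsets keeps exactly the two drivers given nonzero effects by the
simulator — colder winters lengthen the wait (negative standardized
coefficient on `winter_temp` means warmer → shorter), hotter springs
lengthen it — and drops the two null drivers. Coefficients are per
standard deviation of the driver, in years.

Per-result-type plots: `autoplot(run$establishment)` (probability-of-zero
trajectories), `plot_waiting_times()`, `plot_waiting_map()`, and
`autoplot()` on a fitted model (coefficient dot-whisker).

See `vignettes/waiting-times.Rmd` for the full model description, prior
choices, simulator design, and limitations.

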