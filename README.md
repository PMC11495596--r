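# qitraj

Small-area quality-indicator trajectories: empirical-Bayes shrinkage on
the logit scale followed by group-based trajectory modelling
(latent-class growth analysis), with BIC model selection and post-hoc
group profiling.

## The problem

Healthcare quality indicators are often event proportions measured on
small geographic areas over consecutive years — the motivating case is
the share of acute myocardial infarction (AMI) admissions receiving
primary percutaneous coronary intervention (pPCI) within one day,
tracked across Japan's 335 secondary medical areas (SMAs) nested in 47
prefectures. Two statistical obstacles stand between such data and a
statement like "these areas improved, those stayed behind":

1. **Instability.** An area with few cases has a wildly noisy proportion.
   qitraj stabilises each area-period cell with an empirical-Bayes
   shrinkage estimator: the area's continuity-corrected logit
   $\mathrm{SMA}_j = \log\frac{r_j+0.5}{n_j-r_j+0.5}$ is pulled toward
   its parent region's pooled logit $\mathrm{Pref}$ by
   $\mathrm{SMA}_j^* = w_j\,\mathrm{SMA}_j + (1-w_j)\,\mathrm{Pref}$,
   with precision weight $w_j = \frac{1/s_j^2}{1/s_j^2 + 1/t^2}$ built
   from the sampling variance
   $s_j^2 = \frac{(n_j+1)(n_j+2)}{n_j(r_j+1)(n_j-r_j+1)}$ and the
   inter-area variance $t^2$ of the member logits.
2. **Heterogeneous time courses.** One average trend hides subgroups.
   The stabilised trajectories are clustered with a finite mixture of
   regressions over a time basis (cubic B-spline by default), fitted by
   EM; the number of groups is selected by
   $\mathrm{BIC} = -2\ell + p\log N$, with posterior-weighted error
   metrics (WMAE, WRSS) reported alongside. Groups are ordered and named
   by their fitted level bands, e.g. "high to high" or "low to middle".

Because the motivating study's claims database is access-restricted, the
package ships a seeded synthetic-panel generator with known latent
structure (nested geography, binomial counts, group-shifted covariates);
the test suite validates the whole pipeline by recovery of that truth.

## Worked example

```r
library(qitraj)

sim    <- simulate_panel(sim_config(seed = 42))   # 335 areas x 7 periods
shrunk <- shrink_panel(sim$panel)                 # stage 1: stabilise
Y      <- panel_to_matrix(shrunk, shrunk_prop)    # 335 x 7 matrix
sel    <- select_trajectories(Y, 1:5, seed = 1)   # stage 2: fit K = 1..5
sel
#> Model selection over K = {1, 2, 3, 4, 5}; chosen K = 4 (min BIC)
#> # A tibble: 5 × 7
#>       k loglik n_params    bic   wmae  wrss converged
#>   <int>  <dbl>    <dbl>  <dbl>  <dbl> <dbl> <lgl>
#> 1     1  1278.        5 -2528. 0.115  46.1  TRUE
#> 2     2  2669.       10 -5280. 0.0571 12.4  TRUE
#> 3     3  3883.       15 -7678. 0.0306  3.88 TRUE
#> 4     4  4168.       20 -8220. 0.0277  2.97 TRUE
#> 5     5  4179.       25 -8213. 0.0275  2.90 TRUE

fit <- chosen_fit(sel)
attr(assign_groups(fit), "group_levels")
#> # A tibble: 4 × 5
#>   group group_name       first_mean final_mean     pi
#>   <int> <chr>                 <dbl>      <dbl>  <dbl>
#> 1     1 high to high          0.742      0.743 0.651
#> 2     2 middle to middle      0.573      0.580 0.182
#> 3     3 low to middle         0.241      0.575 0.0388
#> 4     4 low to low            0.388      0.386 0.128
```

BIC bottoms out at four groups, and the fitted groups read directly as
the design planted them: a large flat high group, a flat middle group, a
small "catching-up" group rising from a low start to the middle band,
and a flat low group. The mixing proportions `pi` recover the simulated
shares (0.62 / 0.20 / 0.05 / 0.13 up to sampling noise), and the modal
assignments match the generator's truth table exactly on this seed
(adjusted Rand index 1.0).

Post-hoc profiling and plots:

```r
profile_groups(assign_groups(fit), sim$covariates)  # medians + IQR per group
trend_table(assign_groups(fit), sim$covariates)     # 2014 vs 2018 staffing
autoplot(fit)                                       # class curves over spaghetti
autoplot(sel)                                       # BIC / WMAE vs K
```

`run_pipeline(pipeline_config(...), out_dir)` executes
simulate → shrink → select → profile in one call and writes every
artifact (CSVs, model JSON, a manifest with config hash and seeds) for
bit-reproducible reruns; `inst/cli/qi-traj` wraps the same stages as a
command-line tool (`qi-traj simulate | shrink | fit | select | profile |
run-all`).

## Documentation

The methods vignette (`vignettes/qitraj-methods.Rmd`) documents the
estimator and model assumptions, the numerical choices (initialisation,
convergence, variance floor, edge-case policies), what the synthetic
design does and does not validate, and known limitations of BIC-based
selection under model misspecification.
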