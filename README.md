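# megadecline

Post-PSMC analysis of megafauna population histories in R.

Single-genome demographic inference (PSMC) turns one diploid genome into a
step function of effective population size N<sub>e</sub> over coalescent
time. Applied across the surviving large terrestrial mammals, such
trajectories make the late-Quaternary megafauna decline quantifiable: when
did declines accelerate, does body mass predict their severity, are they
better explained by glacial-cycle climate or by the staggered worldwide
arrival of *Homo sapiens*, and what did the decline cost in individuals,
biomass and metabolic energy turnover? `megadecline` implements that
analysis chain end to end, for population geneticists and macroecologists
working with PSMC output:

* **Ingestion** — parse PSMC text output, select the best-supported `-p`
  run, rescale to calendar years: `N0 = theta0 / (4 mu s)`,
  `Ne_k = N0 lambda_k`, `boundary_k = 2 N0 t_k g`.
* **Breakpoint detection** — continuous two-segment least squares of
  log10 Ne on forward log-time (`x = -log10(years BP)`, so declines toward
  the present are negative slopes), breakpoint profiled by grid search with
  continuous refinement, bootstrap confidence intervals, realm-level and
  global pooled fits, percent change per segment.
* **Bayesian decline statistics** — hierarchical per-species slopes
  partially pooled around `alpha + beta * z(log10 mass)`; decline severity
  `1 - Ne_min/Ne_max` and its logit regression on mass and extremum
  timing; one-per-genus and phylogenetic (Pagel's lambda on a
  Brownian-motion correlation) robustness variants; HPDI and split-R-hat
  machinery built in.
* **The 32-model trajectory family** — 12 climate-only, 4 human-only
  (logistic / exponential / linear post-arrival suppression with a latent
  arrival time, plus a human-presence ramp), 16 combined; fitted per
  species over the last 742 kyr, compared by an in-package leave-one-out
  cross-validation (exact Student-t LOO for the conjugate linear specs;
  Pareto-smoothed importance sampling over the nonlinear human-trend
  parameters otherwise), plus hold-out prediction (fit 742–100 kya,
  predict 100–0 kya) with per-25-kyr observed-vs-predicted contrasts.
* **Consequences** — Holocene-Ne/IUCN-census ratios convert effective to
  census sizes; totals of census, biomass (Gt C at 15% body carbon) and
  energy turnover (pJ/day) per time window against a 100–742 kya baseline;
  census–mass extrapolation with smearing correction; historical-census
  calibration; Ne/Nc extinction-risk summaries.
* **Synthetic data** — a first-class generator emulating PSMC-style
  log-spaced trajectories under stable, piecewise-decline, climate-forced
  and human-suppression scenarios, writing PSMC-format fixture files whose
  parse-and-rescale round-trip is exact. Every estimator is validated
  against its generating truth in the test suite.

## Worked example

Simulate a 24-species cohort under the default study conditions (50-kyr
breakpoint, mass-dependent post-breakpoint slopes, observation noise 0.1
on log10 Ne), ingest its PSMC files and locate the global breakpoint:

```r
library(megadecline)

sim <- simulate_dataset("cohort", n_species = 24, seed = 42)
traits <- read_traits("cohort/species.tsv")

trajs <- lapply(seq_len(24), function(i) {
  runs <- parse_psmc_output(file.path("cohort/psmc",
                                      paste0(traits$species_id[i], ".psmc")))
  scale_to_real_units(select_run(runs), mu = traits$mu[i],
                      gen_time_yr = traits$gen_time_yr[i],
                      species_id = traits$species_id[i])
})
names(trajs) <- traits$species_id

pts <- do.call(rbind, lapply(trajs, function(tr) {
  w <- trajectory_windows(tr)
  data.frame(log10_t = log10(pmax(w$mid_yr, 1)), log10_ne = w$log10_ne)
}))
fit <- fit_piecewise(pts)
fit
#> <breakpoint_fit> break at 50,112 yr BP (slopes pre 0.001, post -0.561; rss 25.05; ok)
segment_change(fit, 1e6, fit$breakpoint_yr)   # % decline, 1 Myr -> breakpoint
#> [1] -0.1594057
segment_change(fit, fit$breakpoint_yr, 1e3)   # % decline since the breakpoint
#> [1] 88.892
```

The fitted breakpoint lands on the generating 50-kyr value, the
pre-breakpoint trend is essentially flat, and the post-breakpoint segment
wipes out ~89% of effective population size — the accelerating-decline
pattern the pipeline is built to detect. The hierarchical slope model then
recovers the generating mass effect (−0.1 per SD of log10 mass), and the
LOO ranking puts the logistic human-arrival model first on cohorts
generated under human suppression:

```r
co <- simulate_slope_cohort(n = 60, beta_mass = -0.1, seed = 42)
slopes <- fit_slope_model(co$trajectories, co$traits,
                          mcmc_config(chains = 2, warmup = 500, draws = 500,
                                      seed = 42))
slopes
#> <slope_posterior> 60 species, 1000 draws; mass effect beta mean -0.106, 95% HPDI [-0.118, -0.093]
```

The numbered scripts under `analysis/` run the whole workflow at study
shape — `01_simulate.R` through `07_consequences.R` — writing tables under
`results/` (breakpoints, per-species slope HPDIs, the 32-model LOO
ranking, hold-out contrasts, ecosystem totals and baseline contrasts).

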