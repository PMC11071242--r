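# microrecov

Disturbance and recovery dynamics of microbial communities across
environments.

## What it does, and for whom

Experimental microbiome studies track communities through a discrete
disturbance — antibiotics in a mouse gut, nutrient pulses in a seawater
mesocosm, heat or contamination in soil — by 16S rRNA amplicon
sequencing of replicated samples before and after the event. Comparing
such studies across environments requires common metrics, a common
observation depth, and models that respect the nesting of samples in
time series (one disturbance treatment) in studies. `microrecov` is for
microbial ecologists who want that comparison as a reproducible pipeline
over taxon-by-sample count tables plus a per-sample design table
(`study_id`, `time_series_id`, `environment`, `disturbance_type`,
`time_days` with negative values marking pre-disturbance controls,
`replicate_id`, `unit_id`).

The pipeline computes, per time series and per environment:

* **Richness** — Hill numbers q=0 (observed taxa) and q=2 (inverse
  Simpson) on counts rarefied without replacement to 1500 reads, with
  sample completeness from the Chao–Jost coverage estimator
  C&#770; = 1 − (f₁/n)·(n−1)f₁ / ((n−1)f₁ + 2f₂).
* **Dispersion** — Bray–Curtis dissimilarity
  BC(x,y) = Σ|xᵢ−yᵢ| / Σ(xᵢ+yᵢ) between replicates at the same time
  point (same-experimental-unit pairs excluded).
* **Turnover** — Bray–Curtis between pre-disturbance controls and every
  post-disturbance sample within 50 days; falling turnover means
  recovery toward baseline, rising turnover means drift away.
* **Z-scores** — each pair's dissimilarity standardised against a
  richness-preserving permutation null (abundances reassigned to random
  taxa from the time series' pool, richness and depth held fixed):
  z = (u − μ)/σ over (by default) 1000 permuted matrices. Negative z =
  replicates more similar than random taxon identity predicts.
* **Trends** — hierarchical Bayesian GLMs (negative binomial/log for
  richness, Beta/logit for dissimilarities, heteroskedastic Gaussian for
  Z-scores) with study intercepts and per-series intercepts and slopes;
  before-after contrasts (< 4 days) and 0–50-day time slopes are
  classified *down / neutral / up* by whether the 95% credible interval
  excludes zero, and raw-vs-Z comparisons attribute each trend to
  richness or relative-abundance change.

A seeded multi-study simulator with environment presets (mammal: 43% of
taxa survive, richness recovers ~2%/day through the return of the lost
taxa; aquatic: no loss but compositional drift; soil: weak effects;
null: nothing happens) generates data with known truths, so the whole
pipeline is testable without sequence archives.

## Worked example

```r
library(microrecov)

cfg <- sim_preset("mammal", n_studies = 3, series_per_study = 2, seed = 42)
out <- simulate_dataset(cfg)          # dataset + known truths
out$dataset
#> <mrc_dataset> 178 taxa x 108 samples
#>   studies: 3 | time series: 6 | environments: mammal
#>   time range (days): [-3, 35]

ds  <- filter_replicates(rarefy(out$dataset, depth = 1500, seed = 42))
div <- diversity_table(ds)

fit <- fit_before_after(div, "richness", backend = "laplace", seed = 42)
env_contrasts(fit)
#>   environment effect_mean ci_low ci_high classification ratio_mean ...
#> 1 mammal           -0.811 -0.899  -0.725 down                0.445
```

The immediate contrast says post-disturbance richness is 44.5% [40.7,
48.7] of the pre-disturbance mean — the preset's injected survival
fraction is 0.43 — and the interval excludes zero, so the immediate
richness change is classified *down*.

```r
trend <- fit_trend(div, "richness", backend = "laplace", seed = 42)
dplyr::filter(classify_trends(trend), scope == "environment")
#>   scope       id     environment slope_mean ci_low ci_high classification
#> 1 environment mammal mammal          0.0178 0.0152  0.0203 up
```

The temporal slope 0.0178/day on the log scale (≈ +1.8%/day, injected
truth log 1.02 ≈ 0.0198) is classified *up*: richness recovers.

```r
nz <- null_zscores(ds, dispersion_pairs(ds), n_resamples = 300, seed = 42)
mean(nz$z < 0)
#> [1] 1
```

Every replicate pair is less dissimilar than its richness-preserving
null expectation — the signature of a selective disturbance that removes
the same taxa in every replicate.

`run_pipeline()` chains all stages (ingest/simulate → rarefy → filter →
diversity → pair sets → null model → fits, raw and Z in parallel →
classification → attribution) and returns a report whose
`table1` counts down/neutral/up series per environment and comparison;
`report_json()` serialises it deterministically. `autoplot()` methods
draw trajectory, forest, and immediate-effect-versus-turnover figures.
`fit_*(backend = "mcmc")` swaps the fast Laplace approximation for full
posterior sampling with JAGS; see the vignette in `vignettes/` for the
model, priors, and design choices.

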