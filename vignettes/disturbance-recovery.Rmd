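---
title: "Methods: quantifying microbiome disturbance and recovery across environments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying microbiome disturbance and recovery across environments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microrecov)
```

## The problem

Disturbed microbial communities can lose taxa, become more (or less)
variable between replicates, and drift away from — or recover toward —
their pre-disturbance composition. Comparing these responses across
environments (aquatic, mammal-associated, soil) requires a common
temporal scale, a common observation depth, and a modeling approach that
respects the nested structure of multi-study data: samples within time
series (one disturbance treatment), time series within studies.

`microrecov` implements that comparison as a pipeline over taxon-by-sample
amplicon count tables and a per-sample design table. Time is coded in days
with the disturbance at day 0: `time_days < 0` marks the pre-disturbance
(control) community. Only the first 50 days post-disturbance enter the
temporal models, and every (time series, time point) group must carry at
least three experimental replicates.

## Diversity, dispersion, turnover

Per-sample diversity is summarised by Hill numbers: order $q = 0$
(observed richness, the count of taxa present) and $q = 2$ (inverse
Simpson, $1/\sum_i p_i^2$, the dominance-weighted effective taxon count).
Before any diversity or dissimilarity computation, samples are rarefied
without replacement (multivariate hypergeometric subsampling) to a common
depth of 1500 reads, so detection effort is comparable across studies;
samples below the target depth are dropped. A per-study mode (each study
standardised to its own deepest common depth, bounded below by 1500) is
available as a robustness check. Sample completeness — the estimated
fraction of the community's individuals belonging to detected taxa — is
reported from the Chao–Jost coverage estimator

$$\hat C = 1 - \frac{f_1}{n}\cdot\frac{(n-1)f_1}{(n-1)f_1 + 2f_2},$$

with $f_1, f_2$ the singleton and doubleton counts at depth $n$. When a
sample has no singletons $\hat C = 1$; no further special-casing is
needed, because the denominator is positive whenever $f_1 > 0$.

Compositional variation is measured by Bray–Curtis dissimilarity
$BC(x,y)=\sum_i |x_i-y_i| / \sum_i (x_i+y_i)$, computed on rarefied
counts (equal depths, so the count and relative-abundance formulations
coincide), in two pair sets:

* **dispersion** — all unordered pairs of replicates at the same time
  point within a time series, excluding pairs that share an experimental
  unit (repeated-measures designs would otherwise contaminate
  between-replicate variability with within-unit autocorrelation);
* **turnover** — every pre-disturbance control paired with every
  post-disturbance sample up to the 50-day horizon, the pair timestamped
  by the post-disturbance sample. A declining turnover trend means
  recovery toward baseline; an increasing trend means drift away.

When a series has several pre-disturbance time points they are pooled as
controls; dispersion, by contrast, is computed per sampling day. Same-unit
control-versus-post pairs are kept in turnover by default (the comparison
is *across* the disturbance, not between contemporaneous replicates); a
flag excludes them for sensitivity analysis.

## The richness-preserving null model

Both dispersion and turnover respond to richness changes alone. To
isolate compositional change, each sample's positive abundance values are
reassigned, without replacement, to a uniformly random subset of a
candidate taxon pool of size equal to the sample's richness; richness and
depth are preserved exactly. Recomputing every pair's Bray–Curtis on each
of $R$ permuted matrices (default $R = 1000$) yields a per-pair null mean
$\mu$ and SD $\sigma$, and the Z-score $z = (u^{obs}-\mu)/\sigma$.
Negative $z$ means the two communities are more similar than expected for
random taxon identities at the same richness ("under-dispersed").

Three choices deserve note:

* **Pool scope.** The candidate pool is the union of taxa observed
  anywhere in the same time series (taxa from unrelated studies are never
  plausible members of a community); study-level pooling is offered as a
  sensitivity option. Shuffling abundances only among a sample's already
  occupied taxa would leave presence/absence intact and degenerate the
  dispersion null for replicates with shared membership, so the full-pool
  reading is used.
* **Matrix-wise resampling.** One permuted matrix per iteration serves
  every pair, so dispersion and turnover nulls of the same iteration are
  coupled. Since all pairs are within-series, the implementation iterates
  series-outer / iteration-inner, which is computationally cheaper and
  distributionally identical.
* **Determinism.** A single seeded RNG stream with a fixed
  (series, iteration, sample) loop order makes the full output
  bit-identical across runs; no parallel execution is offered, so
  per-substream seeding is unnecessary. $\sigma$ uses the $n-1$
  denominator. Pairs with $\sigma = 0$ (no compositional freedom beyond
  richness) are flagged `NA` and excluded from Z-score models.

## Hierarchical models and trend classification

Five comparisons are fitted, each in a before-after and/or time-series
design: immediate richness, temporal richness, immediate dispersion,
temporal dispersion, and turnover; dissimilarity comparisons are fitted
to raw values and Z-scores in parallel. Families follow the response:

* richness — negative binomial, log link, per-study shape (aggregation);
* raw dissimilarities — Beta, logit link, per-study precision, with the
  standard compression $y' = (y(n-1)+0.5)/n$ pulling boundary values into
  the open interval;
* Z-scores — Gaussian, identity link, residual SD structured by
  environment and study (heteroskedasticity).

The before-after design contrasts controls against samples taken less
than 4 days post-disturbance; the time-series design models days 0–50
with time centered on the mean observed day of the modeled data (one
shared covariate, hence one shared center; per-series centering would
change the meaning of the common intercept). All models carry varying
intercepts for studies and varying intercepts and slopes (or
after-effects) for time series within studies, with an
environment-by-key-term interaction when several environments are
present. Including varying after-effects in the before-after models is a
deliberate extension of study-only intercept structure: it is what makes
*per-time-series* immediate-change classification possible, and it
reduces to shrinkage noise when series behave alike.

Two backends sit behind one interface. The `"mcmc"` backend samples the
full posterior with JAGS using weakly regularizing priors — normal(0, 1)
on slopes and contrasts, a wide normal on the intercept, half-normal(0, 1)
on group SDs, exponential priors on the NB shape and Beta precision — and
hierarchically centered group means (series means drawn around study
means around the global intercept, series slopes around the
environment-level slope), without which the intercept and slope chains
mix poorly due to additive confounding. Defaults are 4 chains with 1000
adaptation + 1000 retained iterations, and fits with $\hat R > 1.05$ are
flagged before classification. The `"laplace"` backend wraps glmmTMB
maximum-likelihood fits and draws from the multivariate-normal
approximation to the posterior (fixed effects from the estimated
covariance; series deviations from their conditional modes and SDs). It
is deterministic given a seed, roughly two orders of magnitude faster,
and is the backend used for replication-heavy simulation studies in the
test suite; single headline fits use full MCMC. glmmTMB does not allow
random effects in its dispersion formula, so "varies among studies"
becomes per-study fixed dispersion terms there; the JAGS backend models
study-level log-SD offsets as stated. When a Laplace fit fails to
converge cleanly — typically a variance component at its boundary — the
random structure is simplified stepwise (drop the dispersion structure,
then series slopes), and a boundary fit with finite covariance is
accepted with a note rather than discarded.

A trend is classified from the central 95% credible interval of the
relevant slope (2.5–97.5 posterior percentiles): *up* if the interval
lies above zero, *down* if below, *neutral* otherwise. Per-series slopes
combine the fixed time effect, the environment adjustment, and the
series-level deviation. Classifications computed on raw dissimilarities
and Z-scores are then compared: a trend present in the raw values is
attributed to richness change; one present only in the Z-scores to
relative-abundance change; neither, to no detectable change.

## The synthetic-data generator

Real multi-study archives are deliberately not required. The generator
reproduces the statistical structure the analysis assumes: a lognormal
regional taxon pool; studies with log-richness intercept offsets
(SD 0.15–0.2); series with per-day slope offsets (SD 0.003); communities
as abundance-weighted pool subsets; a disturbance at day 0 removing a
fraction of residents; recolonisation driving expected richness along
$R_{after}\cdot r^t$ (capped at baseline); logit-scale abundance drift of
the survivors; multinomial counts at Poisson-jittered depth (mean 3000,
so the 1500-read rarefaction has real work to do); and at least three
replicates per time point, with optional repeated-measures unit sharing.

Removal is *selective* by default: a per-series susceptibility ranking
kills the same taxa in every replicate, and the least susceptible lost
taxa return first. This is what produces strongly negative dispersion
Z-scores (replicates share membership) and recovery by the same taxa; an
iid-removal mode provides the non-selective contrast. Between-series
variation in the drift rate is multiplicative, not additive: dissimilarity
grows under drift in *any* direction, so additive jitter around zero
would turn a no-effect configuration into systematic positive turnover.

Environment presets encode the observed regimes with richness anchored to
typical pre-disturbance means: mammal (baseline 86 taxa, 43% surviving,
recovery 1.02/day, repeated measures), aquatic (baseline 184, no loss,
drift +0.03 logit/day), soil (baseline 327, weak effects, larger and less
even pool), plus a `"null"` preset with no effects for calibration. The
generator does **not** emulate sequencing error, chimeras, taxonomic
misassignment, phylogenetic structure, or mechanistic species
interactions — passing tests demonstrate that the pipeline recovers the
effects the generative model encodes, not that any particular real
dataset satisfies that model.

## Numerical choices and problem sizes

Validation rejects negative, non-integer, or duplicated entries, drops
all-zero samples with a warning, and treats counts without metadata as a
hard error. Replicate filtering groups by exact equality of `time_days`
(designs sample at discrete days) and is applied after rarefaction by
default, so low-depth sample loss can trigger the filter. Completeness is
computed on the rarefied table.

The test suite verifies the metric implementations against hand-evaluated
closed forms and brute-force loops (tolerance $10^{-12}$), pair-set sizes
against combinatorial formulas, and the permutation null against
exhaustive enumeration of all assignments on a four-taxon pool (within
three Monte-Carlo standard errors at 10,000 resamples). Calibration and
recovery studies run at deliberately modest sizes chosen once: null-true
Z-calibration on 170 two-replicate series over a 20-taxon pool
(>1000 independent pairs, 250 resamples); parameter recovery with truths
injected at the response level (ratio 0.43, slope $\log 1.02$, logit
slopes $\pm 0.03$/day) on 6 studies × 4 series × 3 replicates over 20
seeded replications; end-to-end regime recovery on 3 studies × 2 series
per preset over 20 replications, using the Laplace backend. The
acceptance script re-runs the headline analyses at 4 studies × 3 series
with the MCMC backend (2 chains × 1000 + 1500 iterations) and 300–1000
null resamples.

## Known limitations

* Real archives mix read depths, primers, and processing choices that
  rarefaction only partially harmonises; the generator does not model
  them.
* The Beta models treat pairwise dissimilarities as exchangeable within
  the grouping structure; shared samples among pairs induce residual
  dependence that the hierarchy absorbs only approximately. A
  time-point-mean mode is available for sensitivity.
* Laplace posterior draws treat series-level deviations as independent of
  the fixed effects; with few series per study this understates joint
  uncertainty relative to full MCMC (the backends agree closely on the
  designs tested).
* Coverage-based (rather than size-based) standardisation, richness
  extrapolation, and other dissimilarity indices (Jaccard, UniFrac) are
  out of scope.
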