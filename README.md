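# fearscape

Spatiotemporal predator–prey analysis for camera-trap surveys.

Large herbivores in resource-limited landscapes must balance feeding
against the risk of meeting a predator. Camera-trap surveys let ecologists
measure both sides of that trade-off from one data stream: where and when
herbivores are detected, and what happened at the same site in the hours
and days around each detection. `fearscape` implements the full analysis
chain used in such studies, for ecologists who have per-image detection
records, a camera deployment table, and site covariates — or who want to
validate the methods on simulated data first.

## What it computes

**Event preparation.** Cameras within ~150 m on a shared landscape
feature are grouped into clusters (the sampling unit); effort is counted
in camera-nights; detections are thinned by the 30-min independence rule
(keep only detections ≥ 30 min after the previously retained detection of
that species at that unit); detection rates are reported per 100
camera-nights per cluster.

**Diel activity overlap.** Detection times become angles θ = 2πt/24h.
Activity densities are von Mises kernel density estimates with a plug-in
bandwidth, and temporal partitioning between a herbivore and a predator
is the coefficient of overlapping

    Δ = ∫ min(f(θ), g(θ)) dθ  ∈ [0, 1],

estimated by grid integration (Δ̂₁, smaller samples) or by averaged
density-ratio minima at the observed points (Δ̂₄, larger samples), with
percentile-bootstrap CIs and the conventional low (< 0.5) / moderate
(0.5–0.75) / high (> 0.75) categories.

**Case-crossover conditional logistic regression.** Every hour with a
focal detection (case) is matched to up to five hours from the same
cluster, month, and hour-of-day without a detection (controls). Exposure
is time since the last predator detection — short-term [0, 6) h or
delayed [6, 24) h, with ≥ 24 h as reference — and the conditional
likelihood Π_s exp(x_case·β)/Σ_j exp(x_j·β) is maximised by
Newton–Raphson. Exponentiated coefficients are odds ratios for herbivore
detection after recent predator presence; output includes Wald CIs,
p-values, a likelihood-ratio test, concordance, and explicit flags for
quasi-complete separation.

**Hierarchical Bayesian detection model.** Daily presence/absence per
cluster is modelled as Bernoulli with logit link, fixed covariate and
predator effects, and random intercepts for cluster and survey, with
priors Normal(0, 2) on slopes, Normal(0, 5) on the intercept, and
Exponential(1) on group sds. An adaptive Metropolis-within-Gibbs sampler
(slice updates for fixed effects and hyperparameters) provides posterior
draws with split R-hat/ESS diagnostics, Bayesian R², three-tier
effect-strength classification, and post hoc pruning of near-zero
predictors.

**Synthetic data.** `simulate_cameratrap()` generates hourly Bernoulli
detection streams with von Mises diel profiles (diurnal herbivores,
nocturnal predators), cluster/survey random intercepts, covariate
effects, and injected short-term avoidance with a known odds ratio, so
every estimator above can be checked by parameter recovery.

## Worked example

```r
library(fearscape)

cfg <- sim_config(n_clusters = 10, n_surveys = 1, days_per_survey = 90,
                  seed = 42)
sim <- simulate_cameratrap(cfg)
clusters <- cluster_cameras(sim$deployments)
filtered <- filter_independent(sim$detections, clusters)

pair <- overlap_pair_times(filtered, "gemsbok", "lion")
estimate_overlap(pair$theta_a, pair$theta_b, n_boot = 1000, seed = 1,
                 names = c("gemsbok", "lion"))
#> Diel overlap gemsbok-lion (dhat4, n = 596 vs 296)
#>   Delta = 0.104  95% CI [0.076, 0.132]  (low overlap, 1000 bootstrap)
#>   mean activity time gemsbok: 12.70 h [12.51, 12.92]
#>   mean activity time lion: 2.09 h [1.72, 2.45]

hmat <- build_hourly_matrix(filtered, clusters, sim$deployments)
strata <- build_strata(hmat, "gemsbok", c("lion", "spotted_hyena"), seed = 1)
fit_clogit(strata)
#> Conditional logistic regression (case-crossover)
#>   n events = 596 strata; LR chisq = 19.72 on 4 df, p = 0.000568; concordance = 0.531
#>                              coef        se        OR    ci_low   ci_high ...
#> lion_short            -1.01453221 0.3724116 0.3625720 0.1747395 0.7523110
#> lion_delayed          -0.04509742 0.1021293 0.9559044 0.7824925 1.1677468
#> spotted_hyena_short   -0.74425092 0.2815689 0.4750900 0.2735897 0.8249966
#> spotted_hyena_delayed  0.05379312 0.1039426 1.0552663 0.8607645 1.2937184
```

Read: the herbivore shares only ~10% of the diel cycle with the predator
(midday vs. early-morning activity), and its detection odds in the six
hours after a predator passed the cluster are roughly a third of matched
baseline hours — the generator injected a true short-term odds ratio of
0.33 — while delayed effects are absent. `run_pipeline()` chains all
stages for every focal species and writes CSV reports plus a manifest;
`fit_hier_bernoulli()` / `posterior_summary()` give the spatial model
with effect tiers.

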