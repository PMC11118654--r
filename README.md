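# sigkit

Somatic mutational-signature analysis at catalog level, with the
environmental-exposure association layer that sits downstream of it.

Large tumor whole-genome cohorts — never-smoker lung cancer being the
motivating case — summarize each tumor's mutations as counts over context
categories, factorize those catalogs into mutational signatures, assign
signatures back to samples and to individual mutations, and then ask whether
exposures such as fine-particulate air pollution (PM2.5) or secondhand
tobacco smoke shift mutation burden, signature activities, telomere length or
driver-gene prevalence. sigkit implements that pipeline as a tested,
reusable R package for analysts who have variant calls (or catalogs) in hand
and need the signature and association machinery, not the upstream calling.

## What it does

- **Context classification** — SBS-96/288 (trinucleotide, optionally
  transcription-stranded), DBS-78, ID-83, and configurable copy-number
  (68-category default, with sub-100 kb resolution) and structural-variant
  (38-category default, with a sub-1 kb bin) schemas; catalog assembly with
  exact count conservation; fraction of genome with aberrant copy number.
- **De novo extraction** — replicated Kullback–Leibler NMF
  (`V ≈ WH`, `W ≥ 0` column-stochastic, `H ≥ 0`) on hypermutator-normalized
  catalogs (per-sample cap, default 10,000 mutations), Poisson-bootstrap
  replicates, replicate-matched consensus clustering, silhouette stability,
  and rank selection by the largest stable rank within an error slack.
- **Assignment** — forward-stagewise sparse nonnegative least squares with
  cosine add/remove penalties (defaults 0.05/0.01, relaxed 0.01 for
  sensitivity); decomposition of de novo signatures into a reference set;
  cohort rules (global exclusions, ID6→SBS3 and ID3→SBS92 rescues, an MSI
  rescue set); per-mutation Bayes posteriors
  `P(s|c,j) = W[c,s]A[s,j] / Σ W[c,·]A[·,j]` and driver-mutation
  attribution with a strict confidence threshold.
- **Power simulation** — inject a target signature at controlled levels
  (subtract-then-inject with exact pre-noise total conservation, 10%
  per-category Gaussian noise), re-assign under the relaxed penalty, and
  report detection fractions per level and replicate.
- **Exposure association** — individual PM2.5 estimates (diagnosis year
  back to 1998, 20 µg/m³ dichotomization), presence/median dichotomization
  of activities, covariate-adjusted logistic and log-scale linear models
  (odds ratios per 10 µg/m³; percent change per µg/m³ as `10^β − 1`),
  driver-gene enrichment above 2% prevalence, Fisher exact and rank-sum
  tests, Benjamini–Hochberg control per analysis family, and a flagged Firth
  fallback under separation.
- **Synthetic cohorts** — a seeded generator (log-normal activities,
  hypermutator tail, region-level PM2.5 with log-linear signature effects,
  burden-only passive-smoking effect, telomere and driver models) with a
  full truth manifest, so every stage is testable without controlled-access
  data.

## Worked example

```r
library(sigkit)

## a small cohort with a planted pollution effect
scenario <- scenarioPreset("pollution", nSamples = 120, seed = 42)
sim <- simulateCohort(scenario)
sim$catalog
#> MutationCatalog: 96 categories x 120 samples [ SBS96 ]
#>   events per sample: median 4588 range 1955 - 50349

## sparse signature activities for one sample against the reference panel
profile <- catalogCounts(sim$catalog)[, "S0001"]
activities <- assignActivities(profile, sim$panel)
round(activities)
#> Sig1 Sig2 Sig3 Sig4 Sig5
#> 2111  588  693  908    0
round(attr(activities, "cosine"), 4)
#> [1] 0.9913

## dose-response of the clock-like signature on individual PM2.5 estimates
d <- sim$subjects
d$clocklike <- sim$activities["Sig2", ]
fit <- fitLinearModel(d, "clocklike", "pm25",
                      covariates = c("age", "sex", "ancestry", "histology",
                                     "purity"), logBase = 10)
round(100 * c(pct_per_ugm3 = fit$transformed_estimate,
              ci_low = fit$transformed_ci_low,
              ci_high = fit$transformed_ci_high), 2)
#> pct_per_ugm3       ci_low      ci_high
#>         2.69         1.31         4.08
signif(fit$p_value, 3)
#> [1] 0.000113
```

The sample's mutations are apportioned across four of the five reference
signatures with an exact zero on the fifth (off-support zeros are exact by
construction), at reconstruction cosine 0.99. The covariate-adjusted
regression of log10 clock-like mutations on PM2.5 recovers the planted
dose-response — a 2.69% (CI 1.31–4.08%) increase in assigned mutations per
µg/m³ against a planted 2.3% — at p = 1.1e-4.

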