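# circMASLD

Circadian rest-activity amplitude and metabolic dysfunction-associated
steatotic liver disease (MASLD): a tested, reusable R implementation of
the full analysis chain that epidemiologists and proteomics analysts run
on accelerometry + plasma-proteome cohorts — from raw 24-hour activity
profiles to a parsimonious protein risk panel.

## The problem and the methods

Disrupted rest-activity rhythms are summarized by **relative amplitude**

```
RA = (M10 - L5) / (M10 + L5)
```

where M10 and L5 are the mean acceleration over the most active 10-hour
and least active 5-hour windows of the 24-hour profile (circular search
over all start hours). Participants more than two sample SDs below the
mean RA form the low-RA group. Hepatic steatosis is phenotyped with the
fatty liver index, `FLI = 100·σ(0.953 ln TG + 0.139 BMI + 0.718 ln GGT +
0.053 WC − 15.745)` with cutoff 60, and MASLD as steatosis plus at least
one cardiometabolic arm (type 2 diabetes; BMI ≥ 25; or ≥ 2 metabolic
abnormalities).

The analysis chain is:

1. **Association** — 2×2 Wald odds ratios and a nested logistic-model
   ladder (crude → fully adjusted) for low RA → MASLD.
2. **Differential abundance** — per-protein two-group contrasts with
   empirical-Bayes variance moderation (`s²̃ = (d₀s₀² + d·s²)/(d₀+d)`),
   BH adjustment, and the intersection of the low-RA and MASLD DEP sets.
3. **Mediation screen** — per-protein ACME/ADE/proportion-mediated by
   g-computation over a linear mediator model and a logistic outcome
   model, with nonparametric-bootstrap inference; proteins pass at
   ACME p < 0.05 and proportion mediated > 0.10.
4. **Panel selection** — L1-penalized logistic regression (λ at minimum
   10-fold CV deviance), ranking by |standardized coefficient|, an
   incremental-AUC curve on a stratified 70/30 split, and the parsimony
   rule: smallest panel within 0.01 of the best AUC.
5. **Evaluation** — logistic, random-forest, gradient-boosted-tree and
   SVM classifiers behind one fit/predict-probability contract, scored
   with midrank Mann-Whitney ROC/AUC; plus offline hypergeometric
   gene-set enrichment and degree-centrality hub detection.

Because the cohorts such analyses need are access-restricted, the
package includes a synthetic-cohort generator (`generateCohort()`) with
planted exposure → protein → outcome mediation paths and full ground
truth, so every stage is testable end to end.

## Worked example

```r
library(circMASLD)

cfg <- synthConfig(n_participants = 2000, seed = 42)
res <- runPipeline(list(synth = cfg, n_boot = 300))

res$cohort
#> SyntheticCohort with 2000 participants
#>   proteome: 300 proteins ( 6 planted mediators )
#>   MASLD prevalence: 0.364

head(res$ra, 3)
#>   participant_id      m10       l5 m10_start_hour l5_start_hour        ra
#> 1         p00001 43.84211 6.565032             10             1 0.7395197
#> 2         p00002 43.83739 9.539656             10             0 0.6425559
#> 3         p00003 42.31921 8.158279              9             0 0.6767557

res$ladder[, c("model", "or_", "ci_low", "ci_high")]
#>       model      or_   ci_low  ci_high
#> 1     crude 4.828022 3.063645 7.608518
#> 2 adjusted1 4.824877 3.042452 7.651538
#> 3 adjusted2 4.888277 3.080068 7.758028
#> 4 adjusted3 4.889466 3.078212 7.766482

res$manifest[c("n_deps_common", "n_mediation_pass", "k_star")]
#> $n_deps_common    [1] 6
#> $n_mediation_pass [1] 5
#> $k_star           [1] 5

res$models$logistic
#> PanelModel (logistic) with 5 proteins; held-out AUC = 0.745
```

The crude odds ratio here (4.83, CI 3.06–7.61) is the low-RA → MASLD
association in this simulated cohort; it barely moves across the
adjustment ladder because the generator plants no confounding. Of 300
proteins, the moderated-t screens intersect to 6 common DEPs (exactly
the planted mediators), 5 survive the mediation filters at this sample
size, and the parsimony rule keeps all 5, giving a held-out AUC of
0.745 against a generating-model optimum near 0.76.

Individual components work standalone, e.g. the Wald odds ratio from a
published 2×2 table:

```r
oddsRatio2x2(a = 1633, b = 1387, c = 24390, d = 54020)
#>        or_  ci_low  ci_high       p_value method
#> 1 2.607669 2.42373 2.805568 1.887067e-145   wald
```

and risk prediction for a new participant from a fitted panel:

```r
predictRisk(res$models$logistic,
            setNames(rep(1, res$panel$k_star), res$panel$panel))
#> [1] 0.8256362
```

## Package layout

- `R/` — S4 containers (`SyntheticCohort`, `PanelModel`) and the stage
  functions (`raMetrics`, `derivePhenotypes`, `modelLadder`,
  `moderatedTTest`, `mediationScreen`, `lassoLogisticCV`,
  `trainClassifiers`, `hypergeomEnrich`, `runPipeline`, ...).
- `vignettes/circadian-masld-pipeline.Rmd` — the methods vignette:
  models, assumptions, parameter defaults, numerical choices and
  limitations.
- `tests/testthat/` — unit, property and acceptance suites, including
  brute-force and independent-optimizer oracles.
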