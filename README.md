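# resilmet — serum metabolomics of cognitive resilience

`resilmet` is an R implementation of an analysis pipeline linking untargeted
LC-MS/MS serum metabolomics to *cognitive resilience* in a longitudinal aging
cohort. It is aimed at metabolomics and aging researchers who want the full
chain — from longitudinal cognitive scores to sparse multivariate feature
selection and tandem-MS structure queries — as reusable, tested functions,
together with a fully labeled synthetic cohort generator so that every stage
can be exercised and validated without access to cohort data.

## The model at the core

**Resilience score.** Composite cognitive z-scores are modeled with a linear
mixed-effects model over time `t` in decades after age 70:

    z_ij = β0 + β1·t_ij + β2·sex_i + β3·edu_i + b0_i + b1_i·t_ij + ε_ij,
    (b0_i, b1_i) ~ N(0, Σ),   ε_ij ~ N(0, σ²)

The participant's resilience score is the deviation of their person-specific
slope from the overall slope, i.e. the BLUP `b1_i` — higher means flatter
decline, more stable cognition. In the emulated cohort the population slope
is −0.7 SD per decade.

**Feature selection.** After conditioning the feature table (dead-volume
filter at 0.7 min, 5× blank filter, one visit per participant chosen to
minimize the SD of age, minimum-presence filter, robust centered log-ratio
transform, age residualization, near-zero-variance removal), a one-component
sparse PLS regression of resilience on the feature matrix is fitted: the
loading-weight vector is the soft-thresholded cross-covariance `X'y` keeping
the `keep` largest entries, with `keep` tuned by a ranked scree knee plus
10-fold cross-validated RMSE (one-standard-error rule). Stability scores
(fraction of CV folds selecting a feature), permutation testing, and
external validation on a held-out visit (Jaccard similarity, loading-weight
correlation) quantify robustness.

**Association follow-up.** A two-step hurdle model asks per feature whether
its *presence* (logistic step) and, among detected samples, its *abundance*
(linear step) track resilience, with Benjamini–Hochberg correction per step;
per-feature linear mixed models with participant random slopes test age
associations; fold changes compare low/high resilience groups (median
split). MS/MS operators find glucuronide conjugates via their 176.0321 /
194.0425 Da neutral losses and β-blocker drug metabolites via four shared
aryloxypropanolamine backbone fragments, followed by parent co-occurrence,
retention-time precedence and delta-mass annotation
(glucuronidation +176.0321, hydroxylation +15.9949, demethylation −14.0157,
and combinations — all derived from an exact monoisotopic element table).

## Worked example

```r
library(resilmet)
cfg <- sim_config(seed = 7)          # 237 participants, 3 visits, 500 features
res <- run_pipeline(cfg, keep = "auto", n_perm = 100, branch = "resilience")
print(res$trajectory)
#> <trajectory_fit> cognitive decline model (blup)
#>   fixed slope: -0.738 SD/decade; random slope SD: 0.236; resid SD: 0.520
#>   237 participants; converged: TRUE; singular: FALSE
print(res$spls)
#> <spls_fit> 1 component, keep = 112 of 426 features
#>   R2 = 0.509 (p = 3.93e-38), RMSE = 0.076
print(res$external)
#> <external_validation>
#>   r2_ext = 0.097 (p = 1.05e-06), cv r = 0.294
#>   Jaccard = 0.217, loading correlation = 0.282
#>   top-5% reselected = 50%, overall overlap = 36%
```

The fixed slope recovers the generator's −0.7 SD/decade decline. The sparse
model selects 112 of 426 surviving features and recovers 20 of the 30
planted resilience-associated features; the held-out visit reproduces the
selection direction (positive loading correlation, top-weighted features
reselected at twice the overall rate). Note the modest cross-validated R²:
with only three visits the estimated resilience scores carry substantial
estimation noise, which attenuates every downstream association — the
methods vignette quantifies this bound. The spectral stage finds all 8
planted glucuronide conjugates and retains exactly the 6 planted drug
metabolites (annotated glucuronidation, hydroxylation, demethylation and
combinations) while rejecting every distractor:

```r
res$drug_matches[res$drug_matches$passes_all,
                 c("parent", "delta", "annotation")]
#>       parent     delta                    annotation
#> 3 metoprolol 176.03058               glucuronidation
#> 4   atenolol  15.99686                 hydroxylation
#> 5 metoprolol -14.01748                 demethylation
#> 6   atenolol 192.02623 hydroxylation+glucuronidation
#> 7 metoprolol 162.02089 demethylation+glucuronidation
#> 8   atenolol 176.03366               glucuronidation
```

## Acceptance script

`scripts/acceptance.R` regenerates a synthetic cohort from a seed, runs the
complete pipeline (trajectory model, preprocessing, tuned sparse PLS with
cross-validation and permutation testing, external validation, hurdle and
fold-change stages, spectral queries) against the installed package, prints
stage summaries, and writes a JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
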