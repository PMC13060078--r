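---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its science: the models it
fits, the tunable parameters and their defaults, what the synthetic
generator does and does not emulate, and the choices made where the design
was genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The resilience score

Cognitive performance is summarized per participant and visit as a composite
z-score. We model it with a linear mixed-effects model in which time is
expressed in *decades after age 70*, so the slope reads directly as SD-units
per decade:

$$z_{ij} = \beta_0 + \beta_1 t_{ij} + \beta_2\,\mathrm{sex}_i +
\beta_3\,\mathrm{edu}_i + b_{0i} + b_{1i} t_{ij} + \varepsilon_{ij}$$

with correlated participant-level random intercepts and slopes and Gaussian
residuals. The resilience score is the difference between the
person-specific slope and the overall slope — exactly the random-slope BLUP
$b_{1i}$. Higher scores mean flatter decline.

Choices:

* **BLUP vs per-person refits.** Whether "person-specific slope" means the
  mixed-model conditional mean or an independent per-person OLS slope is
  underdetermined; we default to the BLUP (it is the standard estimator and
  shrinks noisy short series toward the population), and expose
  `fit_trajectory(..., method = "ols")` as the unshrunken alternative. On
  low-noise data the two agree in rank almost perfectly (tested).
* **Estimation.** The model is fit by REML via `lme4`. A hand-rolled
  optimizer for the 2×2 random-effects covariance would reimplement a
  solved problem; `lme4` is also what practitioners in this field use. If
  the correlated fit fails to converge we refit with the intercept–slope
  correlation fixed at zero and flag the fit. A fully noise-free cohort
  (zero residual variance) short-circuits to the exact closed-form answer
  instead of entering the optimizer.
* **p-values.** Fixed-effect p-values in the per-feature age models use the
  normal approximation to the t statistic (a Satterthwaite correction would
  require an additional dependency); with hundreds of observations the
  approximation error is negligible relative to the BH threshold.

### How much slope information do three visits carry?

This bound matters for interpreting every downstream result. With $v$
visits spaced $\Delta$ years and residual SD $\sigma_e$, the per-person
slope information is $\mathrm{SS}_t = \sum_j (t_j-\bar t)^2$ (in decades²),
and the correlation between true and estimated (BLUP) slopes is bounded by
$\sqrt{\sigma_s^2/(\sigma_s^2 + \sigma_e^2/\mathrm{SS}_t)}$. At the
generator's stated world — slope SD $\sigma_s = 0.3$ SD/decade, residual SD
$\sigma_e = 0.5$, three visits spanning eight years ($\mathrm{SS}_t =
0.32$) — this bound is $\approx 0.32$; the measured recovery correlation
(acceptance suite) is $\approx 0.38$, slightly above the single-person
bound because the mixed model pools information across participants with
varying baseline ages. Recovery reaches $\approx 0.77$ at six visits and
$\approx 0.88$ at eight visits (24–28 years of follow-up) on matched seeds
(tested). The source study computed resilience from up to 28 years of
cognitive testing, not from the three serum visits; a three-visit design
cannot reach recovery 0.7 at this noise level, and the corresponding
acceptance check is intentionally left failing rather than met by quietly
shrinking the stated residual noise. Consequences: associations estimated
against the *estimated* score are attenuated by roughly this factor, which
is why the end-to-end worked example shows a modest cross-validated R²
while feature recovery against the *true* planted slopes is strong.

## 2. Feature-table conditioning

The resilience branch runs, in order: dead-volume filter (RT < 0.7 min),
5× blank filter, age-harmonizing visit selection, minimum-presence filter
(0.4), robust centered log-ratio transform, age residualization, and
near-zero-variance removal. The aging branch runs dead-volume, blank,
minimum-presence (0.3), then per-feature pseudocount (half the minimum
non-zero value) and natural log. Each wrapper reports survivor counts per
step, and every filter is reproduced by an independent one-line recount
oracle in the tests.

* **Presence semantics.** The source descriptions of the sparsity cutoffs
  conflict in direction ("non-sparsity with cutoff <70%" vs "present in at
  least 40%"). We fix the semantics as a *minimum presence fraction* —
  operational, monotone, and both readings are reachable through the
  parameter (0.3 aging branch, 0.4 resilience branch by default).
* **Blank aggregation** is the mean over non-zero entries on both sides
  (configurable to max); a feature never seen in blanks is always kept.
* **RCLR** is applied per sample across features (the compositional axis
  for LC-MS tables): observed entries become log values centered on the
  mean log of that sample's *observed* entries; zeros become `NA`. This is
  numerically identical to `vegan::decostand(..., "rclr", impute = FALSE)`
  (cross-checked in the tests) and makes the table invariant to per-sample
  scale, which the tests assert directly.
* **Visit selection.** The stated objective is one visit per participant
  minimizing the SD of selected ages; no algorithm is stated. We exploit
  the decomposition $\min_S \mathrm{Var} = \min_m \min_S \sum (a_i - m)^2$:
  for fixed target age $m$ the optimal selection picks each participant's
  age nearest to $m$, and the selection can only change when $m$ crosses a
  midpoint between two of one participant's ages. Scanning one
  representative $m$ per midpoint interval therefore enumerates every
  candidate selection and attains the exact global optimum in
  $O(n^2 v^2)$ — verified against exhaustive search ($3^6$–$3^8$
  selections) in the acceptance suite. An earlier coordinate-descent
  heuristic (initialized from the best uniform visit) was measurably
  suboptimal on random cohorts and was replaced; a final descent sweep is
  kept as a fixed-point check. Ties break toward the earlier visit.
* **External visit**: among unselected visits, the one closest in age to
  the selected visit (ties toward earlier); single-visit participants are
  dropped with a warning.

## 3. Sparse PLS, tuning, validation

With one component and one response, the sparse PLS loading-weight vector
is the soft-thresholded cross-covariance $X^\top y$ keeping exactly `keep`
entries, renormalized; the latent score is $t = Xw$ and $y$ is regressed on
$t$ for $R^2$, RMSE and an F-test p-value. This identity makes exhaustive
top-$|\mathrm{cov}|$ selection an *independent oracle*, which the
acceptance suite checks on 100 random problems.

* **Scaling** (unit variance) is on by default and recorded in the fit;
  selection is then by $|\mathrm{cor}|$ rather than $|\mathrm{cov}|$ —
  both routes are tested against their respective oracles.
* **Missing RCLR entries** are mean-filled per feature before the matrix
  fit (recorded, reused for projection); sPLS needs a complete matrix and
  no imputation scheme is stated upstream.
* **Tuning**: features are ranked by covariance magnitude; the knee of the
  ranked curve is the unit-invariant farthest-from-chord point; candidates
  `knee × {¼, ½, 1, 2, 4}` are scored by 10-fold CV RMSE with a
  one-standard-error rule toward smaller `keep`. The knee criterion is a
  stand-in for an unspecified "ranked scree" procedure, not a
  reconstruction of it. A flat curve falls back to CV-only selection over
  a default grid, flagged.
* **Cross-validation** assembles out-of-fold predictions over all folds;
  observed r is `cor(y, oof)`; stability is the fraction of folds
  selecting a feature. Folds are seeded, participant-level, unstratified
  (the response is continuous).
* **External validation** reports projection $R^2$ with its F-test p, CV
  observed r on the external data, and a refit with identical parameters
  for Jaccard similarity and loading-weight correlation. The loading
  correlation is computed over the *union* of the two selected sets with
  unselected entries contributing 0 (the support convention is not stated
  upstream; the union is the conservative choice that penalizes
  non-overlap), plus the fraction of the original top 5% by |w| that is
  reselected.
* **Permutation test**: $p = (1 + \#\{R^2_{perm} \ge R^2_{obs}\})/(n_{perm}+1)$,
  floor $1/(n_{perm}+1)$.

## 4. Hurdle, age models, groups

* **Hurdle step 1** is logistic regression of presence on resilience via
  IRLS (`glm`); it is declared inestimable when either presence group has
  fewer than `min_group = 5` samples or when separation is detected
  (fitted-probability warning or |coefficient| > 15) — separated features
  are flagged rather than penalized, since an infinite MLE is not
  evidence against the feature. Step 2 is OLS of log raw abundance on
  resilience over detected samples only. BH correction runs within each
  step across estimable features.
* **Presence** means area > 0 *after* upstream blank filtering; zeros in
  the stored table are non-detects by construction (no NaNs on disk).
* **Groups** for fold changes are a median split (lower two quartiles =
  low); ties go low. Fold changes use raw peak areas over detected
  samples, matching how peak-area distributions are usually plotted, with
  a rank-sum test on log areas.
* **Aging selection.** The two textual descriptions of the aging-branch
  selection are opposite ("heterogeneous slope across individuals" vs
  "absence of detectable inter-individual heterogeneity"). Rather than
  guess intent, `lmm_age()` takes `selection_rule = require_singular` /
  `require_nonsingular` (singular = random-slope variance at the zero
  boundary, i.e. no detectable heterogeneity), applies it *after* BH, and
  always reports both counts.

## 5. Spectral queries

Monoisotopic masses are computed from an exact element table (C ≡ 12);
the glucuronide neutral loss is `monoisotopic_mass("C6H8O6")` = 176.0321
(4 decimals), and every modification delta is derived from its composition
change, never typed in as a constant. The published second glucuronide
loss, 194.0425 Da, is 0.0002 Da below the computed C6H8O6+H2O value; the
queries take the printed values as inputs and the 0.01 Da default
tolerance absorbs the difference. That tolerance is a deliberate choice:
below the 0.05 Da fragment tolerance used for library matching upstream,
wide enough for the generator's 0.002 Da instrument noise. `min_matched`
defaults to 3 of the 4 backbone fragments. Intensity is ignored in
matching (presence-based queries), with an optional relative-intensity
floor. Parent assignment for a candidate metabolite prefers the parent
whose precursor delta is explained by a known modification (ties flagged
ambiguous, falling back to the smaller raw delta); retention-time
precedence is strict (equality fails; missing RT is indeterminate, not
false).

## 6. The synthetic world

The generator's defaults are the stated conditions of the emulated cohort:
237 participants, 3 visits spaced 4 years, baseline age 70 ± 3 y, 64%
female, population slope −0.7 SD/decade, slope SD 0.3, residual SD 0.5
(the last two are generator choices — the source states no values), small
sex/education offsets (0.2 SD, 0.05 SD/yr) present only so the covariate
machinery is exercised. Feature tables are zero-inflated log-normal:
baseline log-areas N(11.5, 1.0) across features, within-feature log-SD
0.5 (a ~50% CV, typical for untargeted serum profiling), left-censored at
a detection limit of e^10 ≈ 2.2×10⁴ area units — censoring, not random
dropout, so presence/absence is informative, which is exactly the
structure the hurdle model targets. Resilience effects enter through the
*true* random slope (0.5 log-units per unit resilience by default), so
recovery tests measure genuine end-to-end estimation error; age effects
enter within-person (0.05 log-units/yr). Blanks sit at 10³ with ~2%
contaminant features whose blank signal exceeds their sample signal.
Spectra carry Gaussian fragment noise (SD 0.002 Da) and the planted
glucuronide/parent/metabolite/distractor structure described above, with
each distractor violating exactly one diagnostic property; filler
fragments deliberately avoid the diagnostic m/z windows so that a
distractor cannot accidentally satisfy the property it is built to
violate.

What the generator does **not** emulate: chromatographic drift and batch
effects, correlated feature blocks (adducts, isotopologues, in-source
fragments), heavy-tailed intensity noise, missing visits, and informative
dropout. A green test therefore establishes correctness of the statistical
machinery on a well-specified world, not robustness to instrument
artifacts.

## 7. Numerical conventions

Retention times are minutes internally (`RTINSECONDS` converted on read);
zeros in stored tables mean non-detected; ties in visit selection and
external-visit choice break toward earlier visits; BH adjustment is the
textbook step-up with explicit monotonicity (matched to the reference
implementation to 1e-12 in tests); the permutation p-value floor is
1/(n+1); sparse-PLS thresholding resolves covariance ties by rank order so
exactly `keep` features are always returned.

## 8. Known limitations

* Resilience-score recovery is information-bounded by the visit design
  (section 1); three-visit cohorts should treat the score as a noisy proxy.
* One component, one response only; multi-component sPLS is out of scope.
* The hurdle's separation handling discards rather than penalizes
  (no Firth correction).
* Spectral queries are presence-based; no cosine similarity, adduct
  disambiguation, or molecular networking.
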