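---
title: "Cross-cohort CAD phenotyping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-cohort CAD phenotyping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phecad)
```

# The two-stage classification model

`phecad` classifies coronary artery disease (CAD) from EMR features in two
stages, so that one algorithm can be carried across disease cohorts whose CAD
prevalence differs by a factor of five or more.

**Stage 1 — screen.** A patient is *possible CAD* when they carry at least
one ICD9 code in the ischemic-heart-disease families (prefixes 410–414,
dotted-string matching: `"414"` covers `414`, `414.0`, `414.01`) or at least
one NLP mention of a CAD-related concept (CAD, CAD procedures, CAD
biomarkers, positive stress test). The screen is deliberately one-sided: its
purpose is a negative predictive value of at least 99%, so the expensive
stages (chart review, modeling) only ever see screen positives, and screen
negatives are classified non-CAD outright. Monotonicity holds by
construction: adding codes or mentions can never un-flag a patient.

**Stage 2 — phenotype model.** On chart-reviewed screen positives we fit a
logistic model by adaptive LASSO:

1. pilot fit: ridge-penalized logistic regression (fixed penalty $10^{-3}$ on
   standardized features, intercept unpenalized). Ridge is used because it is
   defined even under complete separation, which small reviewed training sets
   can exhibit;
2. adaptive weights $w_j = 1/|\hat\beta_{\text{init},j}|^\gamma$ with
   $\gamma = 1$ (the standard default). Pilot magnitudes are floored at
   $10^{-4}$ before inversion so no weight is infinite, while null features
   still receive penalties up to $10^{4}$ times larger than strong ones;
3. an $\ell_1$-penalized path over 100 log-spaced penalties from
   $\lambda_{\max}$ (the smallest penalty that zeroes every penalized
   coefficient) down to $10^{-4}\lambda_{\max}$, solved by IRLS with
   coordinate descent on the weighted quadratic approximation (compiled; an R
   reference implementation is kept and tested for equivalence);
4. per-path-point $\mathrm{BIC} = -2\,\ell + \mathrm{df}\,\ln n$ with
   $\mathrm{df}$ = nonzero penalized coefficients + 1 for the intercept
   (the standard LASSO df estimate); the minimum-BIC model is selected, ties
   broken toward the sparser (larger) penalty.

All feature columns — binary indicators included — are standardized to mean
0, SD 1, so fitted coefficients are comparable across variable types.
Whether one should standardize binary indicators at all is genuinely open;
we standardize them because it makes every coefficient a
per-standard-deviation log-odds increment and matches how the reference
coefficient set is reported.

**Stage 3 — PPV-anchored cutoffs.** Each cohort receives its own probability
cutoff $C$: candidate cutoffs are the observed unique probabilities of the
reviewed records, classification is $p \ge C$, and $C$ is the *smallest*
candidate whose classified positives have empirical PPV at or above the
target (0.90 by default). Smallest-qualifying maximizes sensitivity subject
to the PPV constraint, which is the point of comparing feature sets at
matched PPV. Restricting $C$ to observed probabilities makes it well-defined
and reproducible; placing it at the smallest qualifying observed probability
makes the $\ge$ and $>$ conventions classify identical sets. When no cutoff
qualifies, the calibration is flagged `attainable = FALSE` and the largest
candidate is reported with its achieved metrics — downstream reports carry
the flag rather than silently degrading.

Calibration uses only reviewed (labeled) records, and the cutoff is then
applied to the whole cohort. Review-then-apply is the only version of the
procedure that is well-defined without further chart review of classified
positives, and it is what the package's validation flow mirrors.

# Feature dictionary

The model's candidate variables (15 when NLP is included, 11 structured-only):

| feature | provenance | definition |
|---|---|---|
| `icd9_cad` | structured | count of coronary-atherosclerosis codes (414.x) |
| `icd9_ihd` | structured | count of other ischemic-heart-disease codes (410.x–413.x) |
| `icd9_total` | structured | total coded facts in the EMR |
| `icd9_normalized` | structured | CAD-family count (410–414) divided by total facts; 0 when no facts |
| `cabg_pci` | structured | CABG or PCI procedure flag |
| `echocardiogram` | structured | echocardiogram performed |
| `followup_months` | structured | EMR follow-up time |
| `age` | structured | years |
| `mean_ldl`, `no_ldl` | structured | mean LDL (mg/dL); paired missingness indicator |
| `htn` | structured | hypertension |
| `nlp_cad`, `nlp_cad_procedure` | NLP | concept mentions |
| `nlp_never_smoker`, `nlp_current_smoker` | NLP | smoking-status mentions |

Two definitions here are package choices, because the underlying code and
concept dictionaries are not public: the split of 414.x ("CAD") from
410–413.x ("other ischemic heart disease"), and `icd9_normalized` as
CAD-family count over total utilization (a utilization normalization; its
sign pattern against `icd9_total` cannot be validated without the original
data). The two-code baseline rule (`baseline_icd9_rule`) counts the union
410–414 by default.

Records with no LDL values get the training-set mean filled in — which
standardizes to exactly 0, the neutral value — plus the `no_ldl` indicator.
Zero-variance columns are dropped at training time and recorded, so scoring
drops the same columns.

# The synthetic EMR generator

The generator exists so that every stage can be exercised against known
truth. Per cohort it draws:

* **covariates** independently from the cohort's marginals — age (Gaussian,
  clamped to 18–100), sex, race (white/black/other), hypertension,
  hyperlipidemia, ever-smoking, follow-up (Gaussian years, clamped to
  0.25–30). Defaults reproduce the published characteristics of the three
  cohorts (e.g. RA 79.1% female, DM 80.6% hypertension);
* **true CAD** from a logistic model on age, male sex, hypertension,
  hyperlipidemia and ever-smoking. Default coefficients correspond to odds
  ratios 1.05/yr, 2.27, 1.80, 2.48 and 1.92 — the adjusted estimates a large
  EMR study of CAD risk reports — so the synthetic data carry realistic
  confounding for the adjusted analysis to undo. The intercept is root-found
  (`uniroot`, tolerance $10^{-10}$) so the realized-covariate mean risk
  equals the target prevalence (defaults 0.05 RA, 0.042 IBD, 0.261 DM);
* **observable features** conditional on true status only: Poisson code
  counts per ICD9 code, Bernoulli procedure flags and NLP mentions
  (sensitivity-like under CAD, 1−specificity under non-CAD), smoking
  mentions conditional on the smoking covariate, Gaussian LDL with 15%
  missingness, and a background coded-fact rate of 6/year (+10 for CAD)
  driving `icd9_total`.

Default emission parameters are chosen so that (a) the screen's non-CAD
false-positive rate is ~12–13%, reproducing realistic screen-positive
fractions (~17–19% at 5% prevalence), (b) the screen's NPV exceeds 99% by a
wide margin, and (c) the NLP CAD mention (sensitivity 0.92, specificity
0.95) captures a substantial share of CAD patients whose structured evidence
is thin — the mechanism by which narrative data add sensitivity at matched
PPV in low-prevalence cohorts. These are study conditions, not tuning knobs:
tests characterize the pipeline under these defaults.

**Two generation modes.** `generate_cohort()` calibrates each cohort's
intercept to its own target prevalence — the right mode for screening,
modeling and calibration studies. `generate_pooled_cohorts()` instead
anchors the reference cohort (DM) to its prevalence and applies explicit
cohort log-odds offsets (defaults log 0.34 for IBD, log 0.37 for RA), making
the true adjusted cohort effect an exactly known parameter. The two anchors
— exact per-cohort prevalences *and* an exact conditional cohort effect —
cannot hold simultaneously when covariates are independent within cohort, so
the package provides both and the adjusted-OR recovery study uses the pooled
mode, where "truth" is well-defined.

**What the generator does not emulate:** inter-feature correlation beyond
what true CAD status induces (real coded data are correlated through
utilization, care site and documentation habits), longitudinal visit
structure, miscoding, imperfect chart review (review is modeled error-free,
as a gold standard), and differential ascertainment across cohorts. Passing
tests therefore demonstrate that the machinery is correct and behaves as
designed under its stated assumptions — not that the published operating
characteristics transfer to any particular EMR.

# Numerical choices

* Optimizer convergence: relative change in the penalized objective below
  $10^{-8}$, or 10,000 coordinate-descent sweeps; hitting the cap raises a
  warning and is recorded in the model (`converged = FALSE`). Near-separable
  training sets at the smallest penalties occasionally hit the cap; the
  returned model is still the path iterate, and BIC essentially never
  selects those path points.
* IRLS weights floored at $10^{-5}$; working-response update identical to
  the standard penalized-GLM formulation.
* At $\lambda = 0$ the path solver agrees with an independently implemented
  Newton–Raphson MLE to $10^{-6}$ (tested), and against `glmnet` at matched
  penalty factors to $2\times 10^{-4}$.
* The association model is fit with `stats::glm` (IRLS = Newton–Raphson for
  the canonical logit link; covariance = inverse observed information), with
  explicit rank-deficiency and separation diagnostics wrapped around it.
* Woolf intervals require all cells positive; a Haldane–Anscombe 0.5
  correction is available only behind an explicit flag, never silently.
* Rounding: percentages to 1 decimal, odds ratios and CIs to 2 decimals;
  raw values are always stored alongside.
* Reproducibility: every generating function takes an explicit seed and
  restores the caller's RNG state; the pipeline fans one top-level seed out
  to per-stage child seeds by a stable string hash, so adding a stage does
  not perturb earlier stages.

# Problem sizes used by the test suite

The shipped studies run at sizes chosen to give stable Monte-Carlo behavior
on a single CPU: quarter-size cohorts (RA 1,113 / IBD 2,744 / DM 16,275) for
the screening, direction and NPV studies; 50 seeds for the stochastic
direction and support-recovery properties; n = 2,000 with 15 features (4
truly nonzero, $|\beta| \ge 0.8$) for support recovery; and ~20,000–40,000
pooled patients for adjusted-OR recovery. Marginal-calibration checks use
3-binomial-SD tolerances at n = 5,000; coefficient-recovery checks use
3-standard-error tolerances.

# Known limitations

* The synthetic cohorts are a stylized model of EMR data; operating
  characteristics measured on them (sensitivities, specificities, classified
  counts) describe the synthetic conditions, not any real cohort.
* The adaptive-LASSO model reports no standard errors; post-selection
  inference is out of scope.
* Penalty selection is BIC-only (no cross-validation), matching the
  procedure the package implements.
* The screen's default code and concept lists contain only the families
  quoted in the published method description; site-specific dictionaries
  should be supplied via `screen_rule()` and the generator's `signal_params`.
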