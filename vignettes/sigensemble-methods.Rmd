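---
title: "sigensemble: methods, model and numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sigensemble: methods, model and numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigensemble)
```

This vignette documents the statistical model behind the synthetic
cohorts, every numerical convention the package commits to, and the
rationale for choices that a method description alone would leave open.
It is the authoritative reference for "why does the package do it this
way"; the README covers "how do I use it".

## 1. The framework in brief

A multi-gene prognostic signature is applied to the *same* cohort
pre-processed in many different ways, and the per-pipeline risk
classifications are aggregated by unanimity voting:

* a **pipeline variant** is one cell of a factorial design: normalization
  algorithm × probe annotation × dataset handling;
* each variant yields an expression matrix ("view") and casts one
  high/low risk vote per patient;
* the **ensemble score** of a patient is the number of high votes; only
  unanimous patients are classified, the rest stay `unclassified`.

Risk separation is quantified by Cox proportional-hazards regression
(hazard ratio of high vs low), and the ensemble's behaviour is mapped by
permutation sweeps over ensemble size and exhaustive subgroup
enumeration.

## 2. The factorial pipeline design

`pipeline_design()` enumerates 6 algorithms (`RMA`, `GCRMA`, `MAS5`,
`log2MAS5`, `MBEI`, `log2MBEI`) × 2 annotations (`default`,
`alternative`) × 2 handlings (`separate`, `merged`) = 24 variants.

The two `log2*` algorithms are **defined** as the exact elementwise log2
of their normal-space partners (`MAS5`, `MBEI`) — no additional noise is
injected for them. This is a structural commitment, not an
implementation convenience: the signature score (Section 4) consumes
only the rank of each patient relative to the per-gene median, and log2
is strictly monotone, so a log2 variant always produces the *identical*
classification to its partner. The 24 variants therefore collapse to
exactly 16 distinct classification vectors on any cohort with distinct
expression values. This invariant is an acceptance target of the test
suite.

Because normal-space views can contain non-positive values (the
generator adds Gaussian noise), a view is shifted by `1 - min(view)`
before a log2 partner is taken whenever any value is ≤ 0. The shift is
rank-preserving per gene and therefore classification-preserving.

## 3. The synthetic-cohort generator

Real multi-cohort microarray data cannot ship with the package, so
`simulate_cohort()` emulates the *essential causal structure* that the
framework exploits:

* each patient has a latent risk `z ~ N(0, 1)`;
* **signature genes** are `effect_size * z + N(0, noise_sd_gene)`
  — their expression is informative about risk;
* all other genes are pure `N(0, 1)` noise;
* survival time is exponential with hazard
  `baseline_hazard * exp(log_hazard_beta * z)`;
* censoring time is `Uniform(0, censor_horizon]`; the observed time is
  the minimum of the two and `event` indicates which came first;
* the ground-truth label is the median split of `z` (ties to low, as
  everywhere in the package).

`render_pipeline_views()` then adds independent
`N(0, noise_sd_pipeline)` perturbations per non-log variant, emulating
pre-processing disagreement, and constructs the log2 variants as exact
transforms (Section 2).

**What the generator deliberately does *not* emulate:** probe-level
effects, batch structure, platform-specific intensity distributions,
correlated gene-gene noise, non-proportional hazards, or informative
censoring. The package's claims are structural and statistical
(invariants, oracle equivalence, monotone trends), none of which depend
on those features; adding them would only slow the test suite without
sharpening any tested property.

### Default parameters and rationale

| parameter | default | rationale |
|---|---|---|
| `n_patients` | 250 | typical single-cohort size in survival microarray studies; large enough for stable median splits |
| `n_genes` | 500 | enough background genes for the per-gene screen and FDR to be meaningful at desk scale |
| `signature_size` | 25 | representative published hypoxia-signature size (tens of genes) |
| `effect_size` | 1 | signature genes carry signal comparable to their noise (`noise_sd_gene` = 1): informative but not trivially separable |
| `noise_sd_gene` | 1 | unit scale; only the signal-to-noise *ratio* matters |
| `noise_sd_pipeline` | 1 | pipeline disagreement on the same scale as biological noise, so votes genuinely differ across variants |
| `log_hazard_beta` | 1 | one latent-risk SD roughly e-folds the hazard: a strong but realistic prognostic factor |
| `baseline_hazard` | 0.1 | with `censor_horizon` = 30 gives a mixed censoring pattern (roughly half to two-thirds events) |
| `censor_horizon` | 30 | see above; uniform administrative censoring |
| `seed` | 1 | reproducibility; see Section 7 |

These defaults are the package's fixed "study conditions". Tests and the
acceptance script use them (or explicitly documented smaller/larger
variations for runtime or statistical-power reasons) and never tune them
against observed outcomes.

## 4. Signature scoring and classification

For a signature of N (up-regulated) genes, patient *j*'s score in one
view is

\[ \mathrm{score}_j = \sum_{i=1}^{N} s_{ij}, \qquad
   s_{ij} = \begin{cases} +1 & x_{ij} > \mathrm{median}_i \\
                          -1 & \text{otherwise} \end{cases} \]

with the median taken across patients within the view. Two tie rules are
fixed package-wide:

* **per-gene dichotomization**: *strictly above* the median counts +1;
  values equal to the median count −1 ("ties low"). With an even number
  of patients and distinct values this is immaterial; with ties it makes
  the split deterministic and conservative for an up-regulated
  signature.
* **score split**: patients *strictly above* the median score are
  high-risk; patients at or below it (including ties) are low-risk.
  A published description of "split at the median" leaves the tied
  patient's side open; ties-to-low was chosen to mirror the per-gene
  rule and is applied identically in every view, so the choice cannot
  favour any pipeline.

Genes of the signature absent from a view are dropped with a warning
(the score then sums over the genes present); a signature with *no*
genes in the view is an error. If a gene id matches several rows, the
highest-variance row is used — the conventional probe-collapsing rule.

## 5. Ensemble rules

* **Unanimity**: with M variants, `high` iff score = M, `low` iff
  score = 0, else `unclassified`. Adding variants can only shrink the
  classified set (tested as a superset invariant).
* **Matched-count individual classifiers**: to compare a single pipeline
  with the ensemble on equal footing, `matched_individual_classify()`
  labels exactly `k_high` patients high (largest scores) and `k_low` low
  (smallest), with ties broken deterministically by patient id
  (ascending id wins for high, loses for low).
* **Combining two signatures**: `intersect` classifies a patient only
  when both signatures agree on a risk group; `union` classifies when at
  least one signature takes a side *and* they do not conflict —
  conflicting high/low calls become `unclassified` in both modes. The
  "union" reading (conflicts excluded rather than resolved by either
  side) was chosen because an ensemble framework built on unanimity
  should never silently overrule a disagreement.

## 6. Survival statistics

* **Cox model**: binary covariate high(1) vs low(0), unclassified
  patients excluded, Efron tie handling, Wald test, normal-approximation
  95% CI on the log hazard ratio. The fitter is `survival::coxph.fit`
  (the numerical core of `coxph`), because resampling sweeps fit tens of
  thousands of models.
* **Non-estimable fits are first-class results**, not errors: an empty
  risk group, zero events, or a monotone partial likelihood (complete
  separation; detected by non-convergence or |log HR| > 15) yields an
  object with `estimable = FALSE`, `NA` estimates and a human-readable
  `reason`. Resampling keeps such replicates as `NA` rows and reports
  `n_inestimable` rather than dropping them silently.
* **BH-FDR** is `stats::p.adjust(method = "BH")`, applied *within* each
  pipeline variant across its estimable genes only.
* **Paired t-tests** compare pipeline aspects on hazard ratios, pairing
  variants identical in every other factor; a zero-variance difference
  vector is a `sigensemble_degenerate_error` rather than a p-value of
  `NaN`.
* **Spearman correlation** uses midranks; it is `NA` when either side is
  constant.

## 7. Randomness and reproducibility

Every stochastic function takes an explicit integer `seed` and uses an
isolated RNG scope (`withr::with_seed`), so library calls never disturb
the caller's RNG state. Internally, one master seed is expanded into
independent sub-streams by `derive_seed(seed, key)` — a deterministic
polynomial hash of a purpose string (e.g. `"view/MAS5.default.separate"`,
`"run/sweep"`) folded with the seed modulo 2^31 − 1, so derived seeds are
always valid and distinct purposes never share a stream. The same
(inputs, seed) pair reproduces every output byte for byte, including the
TSV/JSON files of `run_full_analysis()`.

## 8. The ensemble-size sweep

`sweep_ensemble_size()` draws, for each requested size n, `reps` random
n-subsets of the M variants (default `reps = 2000`). Each subset is
drawn *without replacement internally* (a subset never contains the same
variant twice), while subsets may recur across replicates. The
alternative reading — sampling variants with replacement inside one
subset — would make "an ensemble of n pipelines" contain duplicate
voters whose votes are perfectly dependent; the chosen reading keeps n
the number of *distinct* pipelines, which is the quantity the sweep is
about. Exhaustive subgroup enumeration (`exhaustive_subgroup_sweep()`)
has no such ambiguity: it enumerates every subset once via
`utils::combn`.

Summaries report the arithmetic mean hazard ratio per size and its log2
(the scale on which sweeps are usually plotted), the mean classified
percentage, the HR range, and the count of non-estimable replicates.

## 9. The significant-gene count model

`fit_count_model()` regresses the number of significant genes per
variant on the design factors by ordinary least squares. Baselines
follow the factorial convention: `alternative` annotation, `HG-U133A`
platform, `merged` handling, `GCRMA` algorithm (falling back to the
alphabetically first level when a baseline level is absent). Factors
constant in the data are dropped with a message; a rank-deficient design
is an error naming the aliased terms.

`stepwise_aic_backward()` removes one term at a time, always the removal
that lowers the AIC most, stopping when none does. Two conventions:

* **AIC scale**: Gaussian `n log(RSS/n) + 2(k + 1)`; only differences
  between nested models on the same data matter, and these match
  `stats::drop1(k = 2)` exactly.
* **Marginality**: a main effect is only removable once no retained
  interaction contains it (inherited from `drop1`'s candidate set). Ties
  in AIC improvement are broken alphabetically by term name for
  determinism.

Note that AIC *by design* retains a spurious d-degree-of-freedom term
with probability roughly P(χ²_d > 2d) (≈ 0.16 at 1 df); the package's
tests assert that behaviour rather than pretending backward selection
always finds the generating model.

## 10. Problem sizes used by the test suite

The acceptance tests fix their own cohort sizes as package choices,
selected for statistical power within the suite's runtime budget and
recorded here so they are not mistaken for tuned values:

* *parameter recovery*: 200 cohorts of n = 2000 with β = 1 and an
  effectively infinite censoring horizon — 3-SE coverage must be ≥ 99%;
* *ensemble benefit*: 50 seeds at n = 150 patients, 60 genes,
  20 signature genes, pipeline noise equal to gene noise — the ensemble
  HR must beat the median single-pipeline HR in ≥ 70% of seeds;
* *sweep shape*: the same cohorts, sizes {1, 2, 4, 8, 16, 24} at
  200 replicates — per-step paired mean differences must be monotone up
  to twice their Monte-Carlo standard error, and the end-to-end trend
  strictly monotone;
* *BH null control*: 1000 simulations of 100 uniform p-values — the
  any-rejection rate at q ≤ 0.05 must not exceed 0.05 plus twice its
  binomial standard error.

## 11. Worked example

```{r example}
cohort <- simulate_cohort(sim_config(n_patients = 120, n_genes = 100,
                                     signature_size = 15, seed = 7))
views <- render_pipeline_views(cohort)
votes <- classify_views(views, cohort$signature)
ens <- ensemble_classify(votes)
fit_cox_binary(cohort$patients, ens)
summarise_sweep(sweep_ensemble_size(votes, cohort$patients,
                                    n_values = c(1, 4, 12, 24),
                                    reps = 100, seed = 1))
```
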