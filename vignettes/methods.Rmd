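---
title: "Methods: a holistic metabolomic LDT pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a holistic metabolomic LDT pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(metaboldt)
```

`metaboldt` implements a holistic, untargeted laboratory-developed test (LDT)
for direct-infusion mass-spectrometry metabolomics. Instead of quantifying a
fixed analyte panel, it profiles *all* detected peaks of an individual against
a reference population, maps abnormal peaks to metabolites, and scores the
over-representation of the abnormal metabolites in curated metabolite sets
(diseases, pathways, known concentration abnormalities, biofluid/tissue
locations). A cohort-level diagnostic score and its ROC operating point follow
from the set scores.

This vignette describes the statistical model, every tunable parameter and its
default, the numerical choices, and — importantly — what the validation on
synthetic data does and does not demonstrate.

## 1. Data model and preprocessing

The central object is a `peak_table`: an \(n \times p\) intensity matrix
\(X\) (samples by peaks) with a strictly increasing m/z vector and optional
`control`/`case` labels. `preprocess_peak_table()` applies, in order:

1. **Cross-spectrum alignment** (`align_peaks`): peaks from all spectra are
   pooled, sorted by m/z, and grouped greedily — a new group starts when a
   peak's m/z exceeds the running intensity-weighted group mean by more than
   `mass_tol_ppm` (default **10 ppm**). Contributions of one spectrum to one
   group are summed.
2. **Mass-range filter** (`filter_mass_range`): keep the closed interval
   \([45, 900]\) m/z, the informative small-molecule range for this assay.
3. **Prevalence filter** (`filter_by_prevalence`): keep peaks with a nonzero
   intensity in at least `min_nonzero_samples` samples (default **10**, i.e.
   "more than nine" out of a 56-sample design); rarer peaks carry too little
   information for correlation-based annotation.
4. **Total-signal normalization** (`normalize_intensities`): each spectrum is
   scaled to a constant total (`target_sum`, default \(10^4\)), the standard
   correction for infusion-to-infusion signal drift.

## 2. Annotation by biochemical context

A measured m/z is compatible with compound \(c\) under adduct \(a\) when

\[ \left| m/z - \frac{M_c + \delta_a}{|z_a|} \right| \le
   \mathrm{tol} \cdot \frac{m/z}{10^6}, \]

with \(\delta_a\) the adduct mass shift (defaults: \([M+H]^+\) +1.007276 and
\([M+Na]^+\) +22.989218, singly charged) and tol = 10 ppm. In direct infusion
this lookup is ambiguous; `context_annotate()` disambiguates with two graphs:

- the **correlation graph**: peaks \(i, j\) are connected when
  \(|r_{ij}| \ge\) `corr_threshold` (default **0.7**, Pearson, across
  samples) — co-regulated metabolites correlate;
- the **pathway graph**: compounds co-occurring in a pathway are adjacent
  (clique expansion of the membership table).

The *support* of candidate \((i, c)\) is the number of distinct correlated
peaks \(j\) that have at least one candidate \(c'\) with pathway distance
\(d(c, c') \le\) `pathway_distance` (default **1**; \(d(c,c)=0\)). Per peak,
the candidates with maximal support are retained, provided the maximum reaches
`min_support` (default **1**); ties retain all tied candidates. This is a
conservative voting rule: it never invents a candidate, it only discards
context-free ones.

## 3. Individual profile and set over-representation

For sample \(s\), `loo_zscore()` computes a leave-one-out z-score per peak:

\[ z_{s,k} = \frac{x_{s,k} - \bar{x}^{(-s)}_k}{\sigma^{(-s)}_k}, \]

where mean and standard deviation (denominator \(n-1\)) come from the
reference population *excluding* \(s\). If \(\sigma^{(-s)}_k\) is degenerate,
\(z = 0\) when the value matches the constant reference and \(\pm\infty\) when
it deviates. Peaks with \(|z| \ge\) `z_threshold` (default **2**) are
abnormal; the retained compounds on abnormal peaks form the individual's
*selection*.

The selection of size \(k\) from the annotated universe of size \(N\) is
compared against each metabolite set \(S\): the observed overlap
\(o = |{\rm sel} \cap S|\) is referred to a Monte-Carlo null of overlaps of
uniform random size-\(k\) draws (`n_perm`, default **30,000**), giving

\[ p = \frac{1 + \#\{o^{\rm null} \ge o\}}{n_{\rm perm} + 1}, \qquad
   \mathrm{score} = \mathrm{clip}\big(100\,(1 - 2p),\ 0,\ 100\big). \]

The null is exactly hypergeometric; the Monte-Carlo construction is kept
because it generalizes to constrained nulls, and its calibration is verified
against `dhyper` in the test suite. Scores near 100 mean the set is strongly
over-represented among the individual's abnormal metabolites; \(p \ge 1/2\)
maps to 0.

## 4. Cohort evaluation and the diagnostic score

`evaluate_pipeline()` profiles every sample, producing one score matrix per
set category. Per set, `group_contrast()` reports the case-mean minus
control-mean score (the set's over-representation in cases), plus the set's
own ROC operating point. The `top_k` (default **20**) sets by pooled contrast
define the per-person diagnostic score (the sum of that person's scores over
those sets), whose ROC is summarized at the accuracy-optimal threshold
(midpoints between distinct scores, \(\pm\infty\) sentinels; ties broken by
sensitivity+specificity, then lower threshold; trapezoid AUC; the Youden
point is also reported).

### Reference population

`profile_individual()` defaults to `reference = "all"` (all other samples):
for a single submitted individual the labels of the reference bank are
irrelevant. `evaluate_pipeline()` defaults to `loo_reference = "controls"`:
in a case-control cohort where every case carries a group effect, a mixed
reference is contaminated by the effect itself — an affected peak's LOO z
against *all* others is \(\approx 1\) regardless of effect size, so the
effect becomes invisible at \(|z| \ge 2\). Standardizing against controls
matches the clinical reading of "abnormal relative to the normal population".
Both choices are plain config flags.

### In-sample optimism: a deliberate, documented limitation

The evaluation is *in-sample*: the top-\(k\) sets are selected by the contrast
on the same cohort on which the ROC is computed, and the operating point is
the accuracy-maximizing threshold. Both steps are optimistic. Empirically, on
effect-free synthetic 28+28 cohorts (~190 sets), the full pipeline still
reaches ≈ 70–80 % in-sample optimal accuracy — chance plus selection bias, not
signal. Consequences, both unit-tested:

- A full pipeline re-run on permuted labels is **not** a chance-level
  reference; it re-selects sets on the permuted contrast and inherits the same
  optimism.
- `label_permutation_null()` implements the classical fixed-score null
  (labels permuted in the ROC only). Its accuracies hover near chance
  (≈ 58 % with 28+28, reflecting only max-over-thresholds optimism), but its
  p-value is anti-conservative for the *selected* score: even an effect-free
  cohort's observed accuracy beats it, because the score definition already
  used the real labels.

An honest out-of-sample estimate requires external validation or a
cross-validation wrapper around the *entire* selection, which is out of scope
for this version. Claims of genuine signal recovery in the test suite
therefore rest on ground-truth checks (planted sets ranked top of their
category, planted abnormal compounds recovered through LOO), not on in-sample
accuracy alone.

## 5. Synthetic data: scope of validation

`generate_reference()` builds a reference world: by default **160** compounds
with uniform masses in \([45, 900]\) at ≥ 5 ppm mutual spacing, **25**
disjoint pathways of 4–8 compounds, and four set collections (**63** disease,
**81** pathway-associated, **35** abnormal-concentration, **11** location
sets — one tenth of the motivating study's catalog sizes) formed as unions of
pathway fragments. `generate_cohort()` draws, by default, 28 controls and 28
cases with log-normal intensities

\[ \log x = \mu + \sigma\big(\sqrt{\rho}\, F_{\rm pathway} +
   \sqrt{1-\rho}\,\varepsilon\big), \qquad
   \sigma = \sqrt{\log(1 + \mathrm{cv}^2)}, \]

with cv = 0.3 and within-pathway correlation \(\rho = 0.8\), so the
correlation graph used by context annotation has real structure. A group
effect multiplies the intensities of an effect set's compounds in cases by
`effect_size` (3 in the validation runs). `inject_ambiguity()` adds decoy
compounds within half the mass tolerance of real ones but in unrelated
pathways, to stress disambiguation; `plant_abnormalities()` sets chosen
compounds of one sample to a fixed number of reference standard deviations.

What the synthetic validation **shows**: the pipeline's algebra is correct
against brute-force oracles (annotation voting, ROC sweep, adduct lookup);
the permutation null is calibrated (uniform p-values, hypergeometric
overlaps); planted annotations, abnormalities, and group effects are
recovered under the stated generator conditions. What it **does not show**:
performance on real spectra (isotopes, in-source fragments, matrix effects
and batch structure are not modeled), robustness to misspecified pathway
knowledge, or out-of-sample diagnostic accuracy (see above).

## 6. Numerical choices

- Seeds: all stochastic steps take explicit integer seeds; derived per-sample
  and per-collection seeds stay below \(2^{31}\). `with_seed()` restores the
  ambient RNG state.
- Empirical p-values use the add-one estimator, which is never 0 and is
  exact-test valid.
- Mass tolerances are relative (ppm of the observed m/z); the alignment
  consensus is intensity-weighted to favor well-measured spectra.
- Zero-variance peaks get correlation 0 (excluded from context edges) rather
  than `NA`.
- ROC thresholds at midpoints between distinct scores make the operating
  point invariant to monotone jitter below the score resolution.

## 7. Worked example

```{r example, eval = FALSE}
ref <- generate_reference(seed = 1)
cohort <- generate_cohort(ref,
                          effect_sets = names(ref$collections$disease$sets)[1],
                          effect_size = 3, seed = 2)
cfg <- default_config(n_perm = 2000)
ann <- annotate_peak_table(cohort$table, ref$db, ref$pathways, cfg)
report <- evaluate_pipeline(cohort$table, ann, ref$collections, cfg)
print(report)
null <- label_permutation_null(report$diagnostic_scores,
                               unname(report$labels), n_perm = 200, seed = 3)
mean(null$accuracies)  # fixed-score chance level, ~58% for 28+28
```
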