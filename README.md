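# metaboldt

A holistic metabolomic laboratory-developed test (LDT) pipeline for
direct-infusion mass-spectrometry peak tables.

## The problem

Targeted clinical assays quantify a fixed panel of analytes. A *holistic* LDT
instead profiles every detected peak of one individual against a reference
population, asks which peaks are abnormal, which metabolites those peaks
plausibly are, and which curated metabolite sets — diseases, pathways, known
concentration abnormalities, biofluid/tissue locations — are over-represented
among the abnormal metabolites. The resulting set scores support both
individual interpretation ("this person's abnormal metabolites look like
disease X") and cohort-level diagnosis via a summed diagnostic score with ROC
performance estimation.

The hard parts, all implemented here, are:

- **Annotation ambiguity.** In direct infusion a measured m/z matches any
  compound whose adduct mass \(\;(M_c + \delta_a)/|z_a|\;\) lies within a ppm
  tolerance, so one peak typically has several candidate identities.
  `context_annotate()` disambiguates by biochemical context: candidate
  \((i, c)\) earns one vote of *support* from every correlated peak \(j\)
  (\(|r_{ij}| \ge 0.7\)) that has a candidate within pathway distance 1 of
  \(c\); per peak, the maximal-support candidates are retained.
- **Abnormality without a fixed panel.** `loo_zscore()` standardizes each
  peak of a sample against the reference population excluding that sample,
  \(z = (x - \bar{x}^{(-s)})/\sigma^{(-s)}\), flagging \(|z| \ge 2\).
- **Set over-representation with honest nulls.** The overlap of a person's
  abnormal-metabolite selection with each set is referred to a Monte-Carlo
  permutation null (30,000 draws by default; exactly hypergeometric), giving
  \(p = (1 + \#\{o^{\mathrm{null}} \ge o\})/(n_{\mathrm{perm}} + 1)\) and a
  score \(\mathrm{clip}(100(1-2p), 0, 100)\).
- **Cohort evaluation.** Case-minus-control mean score per set
  (`group_contrast`), top-20 sets pooled across categories, per-person
  diagnostic score = sum over those sets, and its ROC with an
  accuracy-optimal operating point (`roc_curve`, `evaluate_pipeline`).

A seeded synthetic-data generator (`generate_reference`, `generate_cohort`,
`inject_ambiguity`, `plant_abnormalities`) produces cohorts with known ground
truth — pathway-correlated log-normal intensities, planted group effects,
mass-collision decoys — so every stage is testable against planted truth and
brute-force oracles. See `vignettes/methods.Rmd` for the full model,
parameter defaults, and limitations (in particular the in-sample optimism of
the top-k selection plus optimal-threshold evaluation, and why a full
pipeline re-run on permuted labels is *not* a chance-level reference).

## Worked example

```r
library(metaboldt)

ref <- generate_reference(seed = 1)                    # compounds, pathways, sets
cohort <- generate_cohort(ref,
                          effect_sets = names(ref$collections$disease$sets)[1],
                          effect_size = 3, seed = 2)   # 28 controls + 28 cases
print(cohort$table)
#> <peak_table> 56 samples x 160 peaks, m/z 57.1886-894.7521
#>   labels: control=28 case=28 unknown=0

cfg <- default_config(n_perm = 2000)
ann <- annotate_peak_table(cohort$table, ref$db, ref$pathways, cfg)
report <- evaluate_pipeline(cohort$table, ann, ref$collections, cfg)
print(report)
#> <ldt_report> 28 controls / 28 cases; diagnostic score ROC: accuracy 94.6%,
#>   sensitivity 100.0%, specificity 89.3%, AUC 0.991
#>   top overrepresented sets:
#>    - disease:disease_set_001
#>    - disease:disease_set_048
#>    - abnormal_concentration:abnormal_concentration_set_029
#>    - abnormal_concentration:abnormal_concentration_set_012
#>    - abnormal_concentration:abnormal_concentration_set_024

# fixed-score label-permutation null of the diagnostic score
null <- label_permutation_null(report$diagnostic_scores,
                               unname(report$labels), n_perm = 200, seed = 3)
mean(null$accuracies)
#> [1] 57.33929
```

The planted set `disease_set_001` tops the pooled contrast, and the
fixed-score permutation accuracies sit near chance.

Individual-level use mirrors the clinical workflow: `profile_individual()`
returns one person's abnormal peaks, metabolite selection, and per-category
set scores; `render_cloud()` draws the scores as a name cloud (SVG or text);
`run_pipeline()` plus the `inst/cli/metldt.R` script drive everything from
files (`simulate`, `preprocess`, `annotate`, `profile`, `evaluate`, `run`).

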