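---
title: "Methods: from feature table to microbiota-dependent metabolites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from feature table to microbiota-dependent metabolites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`fetometab` analyses non-targeted LC-MS feature tables from a two-group
fetal-organ design: fetuses of germ-free (GF) and specific-pathogen-free
(SPF) mouse dams, three organs (brain, intestine, placenta), four analytical
modes (RP+/RP−/HILIC+/HILIC−), with pooled-QC injections interleaved through
the run. This vignette is the package's account of the methods: the models,
the tunable parameters, the numerical choices, and what the synthetic-data
tests do and do not establish.

## The data model

A `FeatureTable` couples a non-negative intensity matrix (features ×
injections; `NA` means not detected) with feature metadata (mode, m/z in Da
within the 50–1500 collection window, retention time in minutes) and
injection metadata (order, sample type, group, organ, dam, fetus sex).
Missingness is a first-class state: detection-rate metrics and the
exclusivity rule depend on distinguishing "absent" from "zero", so 0-filled
exports are converted to missing only under an explicit dialect flag.

## Drift correction

Instrument response drifts smoothly over a run. Per feature we fit a cubic
smoothing spline (smoothness by generalized cross-validation) to the
*detected QC* log intensities against injection order and divide all
intensities by `exp(ghat(order) - ghat(order_ref))`, anchoring at the first
QC. Numerical choices:

* QC log values are centred before fitting; the correction only uses
  differences of `ghat`, and centring makes it exactly scale-equivariant
  (multiplying a feature by a constant multiplies its corrected values by
  the same constant).
* Fewer than 4 detected QCs: least-squares line. Fewer than 2: no
  correction.
* The correction is applied only if it *strictly reduces* the feature's QC
  classic RSD (`gate = TRUE`); applied corrections therefore never worsen
  the QCs. The gate is configurable off.

Drift correction runs per mode *before* the quality filter. The alternative
order (filter first) lets uncorrected drift masquerade as technical
dispersion: at the generator's default drift amplitude (±10 %), filtering
uncorrected data flags a large fraction of otherwise clean features on
D-ratio\*, while filtering corrected data keeps ≥ 95 % of fully detected
null features — the behaviour a QC filter is supposed to have.

## Quality filtering

Per feature, computed on detected values only:

| metric | definition | keep threshold |
|---|---|---|
| QC detection rate | fraction of QC injections detected | > 0.70 |
| group detection rate | best per-group fraction over biological injections | ≥ 0.60 in ≥ 1 group |
| overall detection rate | fraction over all injections | ≥ 0.50 |
| RSD\* | 1.4826 · MAD(QC) / median(QC) | < 0.20 |
| D-ratio\* | MAD(QC) / MAD(biological) | < 0.10 |
| rescue clause | classic RSD, RSD\* and basic D-ratio | all < 0.10 |

Kept ⇔ all detection criteria pass AND (starred dispersion passes OR the
rescue clause does). MAD here is the raw median absolute deviation; the
1.4826 consistency constant appears in RSD\* (matching the non-parametric
RSD definition) and cancels in D-ratio\* as a ratio of two MADs. The
"low number of missing values" criterion is quantified as the overall ≥ 0.50
rate — a mild explicit default, configurable, since no canonical value
exists. Detection rates pool biological injections across organs (the filter
precedes any per-organ analysis); metrics needing ≥ 2 detected values are
reported missing with a reason code, and missing metrics always fail their
criterion. Flagged features are excluded from statistics but retained for
raw-signal presence lookups.

## Imputation

Modes are merged (row concatenation over a shared injection set, mode-
prefixing clashing ids) and QCs removed — pooled QCs are mixtures and would
bias any fill. Missing cells are then imputed by iterative random forests
(missForest-style) on the log scale: initialize missing cells at half the
feature's minimum detected intensity (detection-limit missingness makes a
low start the right prior; a mean start pre-judges MNAR cells toward the
detected group), visit features in order of increasing missingness, regress
each on all others (`ranger`, 100 trees, single-threaded with per-fit seeds
for determinism), and stop when the total squared change of the imputed
cells rises or after 10 iterations, keeping the last improving iterate.
Observed cells are never altered, and a feature missing in every biological
injection is a hard error (it cannot have survived the detection criteria).
The reported `oob_error` is the mean over imputed features of OOB MSE
normalized by the feature's observed variance; it is a run diagnostic, not a
target.

## Differential abundance and exclusivity

Per organ (12 GF vs 12 SPF samples), each feature gets a pooled-variance
Student t test on log intensities — "simple linear model" and two-group
pooled t test are the same model; Welch is available behind a flag.
Benjamini–Hochberg runs within each organ (each organ is its own family,
matching per-organ volcano-plot practice; global adjustment is a flag).
Effect size is classic Cohen's d with the pooled SD and the **GF − SPF sign
convention**: SPF-higher features have d < 0. The double threshold for
significance is q < 0.05 and |d| > 0.8. Zero-pooled-variance features get a
missing p and are excluded from the BH family size, so undefined tests do
not dilute the adjustment. The log scale makes the planted log-fold effects
of the generator the estimand of d, and is standard for lognormal LC-MS
intensities.

Exclusivity ("present only in SPF") is a raw-signal rule: SNR — the mean of
*detected pre-imputation* intensities in that group and organ divided by a
per-mode noise floor — must exceed 5 in SPF and stay below 5 in GF, together
with q < 0.05 and d < −0.8. The noise floor is an explicit constant
(user-supplied, or estimated as the 1st percentile of detected intensities)
because aligned feature exports do not carry the vendor's per-feature S/N;
whichever definition is used is recorded with the run. One caption-level
ambiguity is resolved deliberately: both significance directions are stated
in the literature with opposite sign conventions for the same comparison, so
the package fixes GF − SPF everywhere and documents it rather than
reconciling silently. Features whose SNR pattern is one-sided but whose
statistics miss the thresholds are reported as `both` (detected, not
exclusivity-called); only the four-condition rule produces `spf_only` /
`gf_only`.

The organ-wise Venn partition records, per feature, the *exact* organ subset
in which it is SPF-higher and in which it is GF-higher (a feature can
appear in both diagrams), with the seven cell counts summing to each "at
least one organ" margin by construction.

## Unsupervised structure

* **t-SNE** on per-feature z-scored log intensities, exact (theta = 0) at
  these sample sizes, initialized from the first two PCA scores scaled to
  SD 1e-4. PCA initialization makes coordinates reproducible and keeps
  identical samples coincident (identical inputs share gradients from an
  identical start). Perplexity defaults to 10 for whole-dataset scopes; the
  pipeline uses 7 so the 24-sample per-organ scopes satisfy the
  `n > 3 · perplexity` feasibility constraint, which is checked with a
  helpful error.
* **k-means** (k = 10) on z-scored feature profiles per organ, 100 restarts
  under a fixed seed; with k = 10 the restart count is what buys basin
  coverage, and 100 restarts are cheap at heatmap scale. Rows order by
  cluster and then by decreasing correlation with the cluster mean profile.
* **Hierarchical ordering** of annotated features: average linkage on
  1 − Pearson r of profiles; zero-variance features have no defined
  correlation and are placed last with a warning.

## Annotation

Identification confidence follows the community's four levels. Evidence per
candidate (library entry × adduct): m/z match within 10 ppm of the adduct
mass ([M+H]+/[M+Na]+ positive, [M−H]−/[M+Cl]− negative by default — primary
ions only), RT within 0.1 min when the entry has an RT, and MS2
modified-cosine ≥ 0.7. Level 1 requires an in-house standard with all three;
level 2 is m/z + MS2 against any source, or — when the feature has no MS2 —
RT + formula-derived mass against an in-house standard; level 3 requires a
user-supplied class-rule table (none ships, so no level-3 calls by default);
level 4 is everything else. The MS2 similarity is a greedy one-to-one peak
match within 0.02 Da scored as the cosine of square-root intensity vectors,
with symmetric tie-breaks so the score is order-invariant. Because one
metabolite yields several features (modes, adducts, fragments), all matches
are reported and the best-evidence feature per compound is flagged as its
representative.

## Pathway analysis

A deliberately simplified mummichog: normalization (per-sample median,
cube-root, per-feature autoscale — the order forbids non-positive inputs),
putative m/z → compound matching at 10 ppm under the adduct rules (isobars
all retained), the compound universe defaulting to everything reachable from
the observed m/z list, then per pathway a one-sided Fisher exact test
(hypergeometric upper tail) on significant-vs-universe compound counts and a
permutation null: draw as many random m/z as were significant, recompute
hits, `perm_p` is the add-one-smoothed fraction of permutations with at
least the observed hits. No currency-metabolite network or activity
weighting is attempted; the pathway sets are user-supplied GMT (toy
synthetic sets ship for demonstration — no KEGG/BioCyc content is bundled).

## The synthetic generator: what it emulates, and what it does not

The generator reproduces the study design: 6 dams × 2 fetuses per group
(7 male / 5 female), 3 organs, 4 modes sharing one injection layout, 9
pooled QCs interleaved evenly (QC counts are not reported for the original
runs; one per ~9 injections is conventional and configurable). Biological
log intensities are feature baselines N(log 5000, 0.8) plus per-feature
per-organ offsets (SD 0.5), per-feature dam intercepts (SD 0.1; the two
fetuses of a dam share them, modelling the litter nesting without forcing
mixed models downstream), planted class effects, and lognormal noise at 50 %
CV. QCs are the per-feature mean of the biological log intensities plus 5 %
CV technical noise — by construction less dispersed than biology, which is
what makes the D-ratio meaningful. Smooth multiplicative drift (default
±10 %, polynomial in order; linear and sinusoidal available) multiplies all
injections. Detection is logistic in log intensity with midpoint at the log
noise floor — a signal at the floor has even odds of detection — anchoring
the missingness model and the SNR denominator to the same per-mode
constant. Exclusive-class features sit at 20× the floor where present and
at the floor where absent, so the SNR rule holds by construction (the
generator errors on configs that cannot clear the threshold), absent-group
cells are mostly-but-not-entirely missing, and the few detected low values
give the imputer genuine evidence — the detection-limit behaviour real
exclusive features show.

Defaults are 1500 features/mode (≈ 6000 total), a desk-scale stand-in for a
cleaned real table about twice that size; the bundled analysis scripts use
300/mode and the acceptance script 300–1500/mode so the full suite runs in
minutes on one CPU.

What passing tests on this generator *show*: the decision rules, formulas
and thresholds do what they claim, planted effects of known size are
recovered at the expected rates, and the pipeline is deterministic and
self-consistent. What they *do not* show: robustness to correlated
feature blocks from shared peaks/adducts, heavy-tailed or batch-structured
technical noise, retention-time-dependent drift shapes, or real MS2 spectra
— none of which the generator attempts.

## Known limitations

* The t tests ignore the dam nesting (as the design's standard analysis
  does); the generator's dam variance is small, and at larger litter effects
  the per-organ false-call fraction would rise.
* Exclusivity calls inherit imputation behaviour: a feature with *no*
  detected absent-group values anywhere forces the forest to extrapolate,
  and the d < −0.8 gate can then fail. The generator's noise-floor anchoring
  makes this rare; on real data a left-censored imputer could be substituted.
* Level-3 (compound-class) annotation requires an external class-rule table;
  in-silico fragmentation is out of scope.
* The pathway module reports over-representation only; no GSEA-style ranked
  variant is provided.
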