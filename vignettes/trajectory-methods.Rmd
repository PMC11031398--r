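---
title: "Methods: clinical disease trajectories, cross-disorder statistics and temporal subtypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clinical disease trajectories, cross-disorder statistics and temporal subtypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind `neurotraj`, the
numerical choices made in its implementation, and the limitations of the
synthetic data generator that stands in for restricted brain-bank records.

## 1. Data model

A donor record consists of a free-text clinical history, a set of clinical
diagnoses (CDs) assigned during life, and one neuropathological diagnosis
(ND, possibly a combined code such as `AD;DLB`) from post-mortem examination.
The ND is treated as ground truth throughout.

The unit of analysis is the **observation**: a (donor, calendar year,
attribute) triple asserting that one of 90 ontology-defined signs or symptoms
was described for that donor in that year. A donor's **trajectory** is the
resulting binary year × attribute matrix. Clinical text asserts presence
only; absence of an observation is *missingness*, not evidence of absence —
this asymmetry drives several choices below (persistence imputation,
mask-equals-input sequences for the recurrent classifier, presence-only
count matrices).

## 2. Corpus parsing

Histories are segmented with a conservative rule-based splitter (terminators
`.!?` followed by whitespace, with abbreviation and decimal protection) and
each sentence is assigned the calendar years it describes:

- literal 4-digit years and ranges (`2005–2007`, `2005 to 2007`), ranges
  expanded to every covered year;
- relative expressions: `last N years` spans the N+1 years up to the anchor
  (the enclosing section year if present, else the death year); sub-year
  expressions (`last N months`) map to the anchor year alone; `at birth` maps
  to `death_year - age_at_death`;
- back-references (`worse than in 2003`, `in comparison to 2001`) are
  stripped *before* year extraction so they cannot anchor a sentence;
- years after death are dropped with a warning; a sentence with no usable
  anchor is categorised *year unknown* and excluded from all temporal
  analyses (it is retained in a side table).

## 3. Sentence classification

Attribute extraction is multilabel one-vs-rest classification over sentence
text. Two baseline families are provided: ridge-penalised logistic regression
on bag-of-words counts (`glmnet`; the per-attribute penalty path ends at
`1 / (C * n)` so `C` behaves as an inverse regularisation strength) and a
linear SVM (`e1071`). Attributes whose minority class has fewer than two
training sentences fall back to a constant majority-class predictor rather
than failing.

Splits use **iterative multilabel stratification**: labels are assigned to
the 20% test set and the 5 cross-validation folds rarest-attribute-first so
that rare attributes are represented proportionally everywhere.
Hyperparameters are tuned by random search; the final model is chosen in two
stages — shortlist the top five trials by mean cross-validated micro-F1, then
pick the highest mean micro-precision, breaking ties toward the lower trial
index. Attributes are **retained** for downstream analysis when test
precision ≥ 0.8 *or* F1 ≥ 0.8; precision is deliberately sufficient on its
own because false positives corrupt trajectories more than false negatives
impoverish them. Undefined precision/recall ratios (zero denominators) are
reported as 0. Annotation quality is quantified with Cohen's kappa per
attribute and pooled over all sentence × attribute cells.

## 4. Trajectories, imputation and cohort filters

Sentence-level predictions collapse to deduplicated observations per (donor,
year, attribute). **Persistence imputation** then fills, for attributes
flagged as neurodegeneration-associated in the ontology *and* donors whose ND
is progressive neurodegenerative, every year between the first observation
and death. The rule is idempotent and gated on both flags: psychiatric
symptoms in a depression donor, or any symptom in a psychiatric-only donor,
are never imputed.

Cohort filters are applied in a fixed order with per-donor exclusion reasons:
history length > 500 characters, autopsy year ≥ 1997 (earlier summaries are
systematically shorter), a purpose-specific diagnosis allow-list (modeling:
twelve common single NDs plus the AD-DLB combination; clustering:
additionally psychiatric and mixed/rare dementia codes), and ≥ 5
non-imputed observations for non-control donors. Counting imputed rows
toward the minimum is available as an explicit switch but is off by default —
the conservative reading, since imputed rows are model output, not evidence.

## 5. Cross-disorder statistics

**Enrichment.** For each attribute × diagnosis group the statistic is the
group mean of per-donor observation-year counts (matching the dot-plot colour
statistic; group proportion is available as an alternative). Significance is
a one-sided permutation test over diagnosis-label reassignments: with all
`n!/(prod n_g!)` distinct arrangements within a budget (default 5,000) the
exact tail proportion is reported; otherwise sampled permutations with the
add-one correction `p = (1 + #{perm >= obs}) / (1 + n_perm)`, which cannot
return 0 and is never anti-conservative. Ties are counted as exceedances
(with an epsilon guard against floating-point noise). Discoveries are
controlled at BH-FDR `q < 0.1`.

**Diagnostic importance.** The 2×2 cross-tabulation of significant
enrichments against a-priori diagnostic-importance flags is tested with a
Pearson chi-square *without* continuity correction (the classical test for
this design; e.g. `[[20,10],[10,20]]` gives 6.667).

**Group comparisons.** Observation-count and observation-age distributions
are compared with two-sided Mann–Whitney U tests. For small samples the test
enumerates all assignments and computes `P(|U - n1*n2/2| >= |obs|)` exactly —
unlike the classical exact distribution this remains valid under ties, which
are ubiquitous in count data. Large samples use the tie-corrected normal
approximation with continuity correction. Sex-balanced subsampling equalises
sexes within each diagnosis group before profiling, dropping single-sex
groups with a warning.

**Survival.** Time from first observation of an attribute to death is
summarised with the Kaplan–Meier product-limit estimator
(`survival::survfit`); group differences default to pairwise Mann–Whitney
tests on durations (log-rank is available, but with brain-bank data every
donor has died, so censoring-oriented machinery adds little).

## 6. Diagnosis evaluation

The **accuracy dictionary** is derived from a clinical-diagnosis class
hierarchy: for each ND, the accurate set is its disease class plus all
descendants; proper ancestors (umbrella classes such as generic *dementia*)
form the ambiguous set. PD and PDD intentionally share one accurate set, as
do the components of AD-DLB.

Verdicts for a donor's CD list: *accurate* if every ND component is matched
by a specific CD and no conflicting specific CD for another disorder is
present; *ambiguous* for partial matches to combined NDs, matches
co-occurring with a conflicting specific CD (an AD donor with CDs {AD, FTD}),
or umbrella-only matches; *inaccurate* otherwise. A strictness switch
downgrades exact-plus-umbrella to ambiguous. Model predictions use the same
component logic (predicting AD for an AD-DLB donor is ambiguous). Per
disorder, concordance between the ND donor set and the CD donor set is
reported as a Jaccard score with both directional percentages.

The prediction harness trains within diagnosis-stratified folds (classes
with fewer than five donors are pooled into a rare stratum for fold
assignment) and predicts each donor exactly once, from a model that never saw
it. The baseline is multinomial logistic regression (`nnet::multinom`, mild
weight decay) on aggregated features: per-attribute observation counts,
first-observation ages, sex and age at death. A decay-based recurrent
classifier is provided as an alternative: a gated recurrent unit over yearly
observation steps whose hidden state decays exponentially with the gap since
the previous observation and whose unobserved inputs decay from their last
observed value toward the empirical mean — both decay rates learned. It is
implemented in base R with analytic backpropagation through time (verified
against central finite differences in the test suite) and Adam updates.

## 7. Temporal subtype clustering

Two count matrices describe each donor: **flattened** (lifetime
observation-year counts per attribute) and **temporal** (counts within
overlapping 30-year age bins stepped by 5 years; bins are half-open
`[start, start + width)` so no observation is double-counted at bin edges).
Each matrix is depth-normalised per donor (`x / total * 1e4`), `log1p`
transformed, z-scaled per feature (zero-variance features dropped) and
reduced by PCA with component signs fixed deterministically.

The modalities are fused per donor with weighted-nearest-neighbor
integration: each donor's embedding in each modality is predicted from its
within-modality and cross-modality neighbors; affinities use an exponential
kernel with a per-donor bandwidth (`max(d_k - d_1, eps)`), and the
within/cross affinity ratios pass through a softmax to give per-donor
modality weights. The joint graph sums weight-scaled kernels over the union
of neighbor sets (top-k edges per donor) and is clustered with Leiden
modularity at resolution 0.8. UMAP (single-threaded for reproducibility)
provides the display embedding. Clusters are profiled with one-sided Fisher
overrepresentation of diagnosis labels (two-sided for genotype contrasts such
as APOE4/4), BH-corrected rank-sum marker attributes on both matrices, and
recursive subclustering (the neighbor count shrinks automatically on small
subsets).

The temporal modality is what distinguishes *when* from *how much*: the
acceptance suite plants two symptom programs with identical attribute sets
and observation-window lengths differing only in onset age (~50 vs ~75) and
verifies they are separated only when the temporal matrix participates.

## 8. Synthetic cohort generator

`default_cohort_config()` defines the standard study conditions: 15 diagnosis
profiles with prevalences proportional to common brain-bank diagnosis counts,
clinically plausible onset ages and per-year observation probabilities, a 15%
misdiagnosis rate along typical confusion directions (MSA → PD, DLB → AD,
…), a 20% umbrella-CD rate (half of those donors keep their specific CD,
half have only the umbrella diagnosis on record), APOE4/4 excess in
Alzheimer-type dementias, and 1% background observation noise. Onset ages
are drawn by inverse-CDF truncated-normal sampling from a single uniform
draw, and per-year observations consume a fixed number of uniforms per
attribute, so cohorts are exactly reproducible and respond monotonically to
probability parameters under a common seed.

Sentences are rendered from a template bank (three surface forms per
attribute, three year phrasings), with occasional two-attribute conjunction
sentences (two-hot gold labels) and label-free distractors, half of them
without any year anchor.

**Limitations.** The generator's sentences are template-bound: classifier
scores near 1.0 on synthetic corpora say the pipeline is correct, not that
the models would reach that performance on real clinical Dutch/English
summaries (reported inter-annotator kappa and real-text F1 are materially
lower). Disease profiles are low-dimensional caricatures — attribute onsets
are independent given the diagnosis, whereas real symptom cascades are
correlated. Synthetic cohort sizes (hundreds of donors) are chosen for test
runtime, not to mirror the thousands of donors in a full brain bank.

## 9. Reproducibility

All stochastic steps take explicit integer seeds and restore the caller's
RNG state. `scripts/acceptance.R --seed S --out F` re-runs the full pipeline
and writes its principal quantities to JSON; the testthat suite checks every
statistical kernel against hand-computed oracles (exhaustive permutation
tails, BH on a worked example, chi-square 20/3, exact Mann–Whitney 0.1,
Kaplan–Meier 2/3, Fisher 1/252) and every pipeline stage against planted
ground truth.
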