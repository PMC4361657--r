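---
title: "Methods: tolerance-signature discovery with tolsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tolerance-signature discovery with tolsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tolsig)
```

# The problem and the design

Operationally tolerant (TOL) transplant recipients are, by definition, off
all immunosuppression (IS), while non-tolerant (non-TOL) patients remain on
it. A two-group expression comparison therefore confounds tolerance biology
with drug exposure. The design analysed here addresses that with a third,
healthy-control group and a set-algebra filter: genes moved in the *same
direction* in both patient groups relative to controls are attributed to
transplantation or IS generally and discarded; the final TOL signature is
restricted to genes that separate TOL from *both* non-TOL and controls.
`tolsig` implements that whole chain — preprocessing, SAM, filtering,
enrichment, classification — with a synthetic cohort generator so each
stage's operating characteristics can be measured against planted truth.

# The synthetic cohort generator

`generate_dataset()` draws a log2-scale probe-set matrix under an additive
Gaussian model:

* **Design.** 15 TOL / 17 non-TOL / 10 control samples and 2000 probe sets
  by default — the cohort sizes of the cross-sectional design the package
  targets, with the probe count scaled to desk size (the statistics are
  per-probe, so calibration does not depend on array size; tests verify
  this scale runs in seconds).
* **Baseline and noise.** Per-probe baselines are Uniform(4, 12) log2
  units, mimicking microarray dynamic range; noise is independent Gaussian
  with per-probe sd drawn Uniform(0.2, 0.6). Both are stand-in choices —
  the motivating study published no variance or intensity estimates — and
  they match the variance-stabilized output RMA produces.
* **Planted structure.** TOL-unique and non-TOL-unique probes per
  direction (defaults 50+50 and 30+30) shifted by `effect_log2` (default
  1.0, i.e. 2-fold — comfortably above the 1.5-fold detectability floor
  the analysis uses); 100 confounded probes shifted with the *same sign*
  in both patient groups versus control; optional agent-linked probes
  shifted only in exposed non-TOL samples; six lineage-tagged sets
  (CD4/CD8/CD14/CD19/CD56/CD66, 50 probes each) placed on otherwise-null
  probes, with an optional coherent shift for enrichment positive controls.
* **Agent exposure.** Each agent is assigned to exactly half of the
  non-TOL samples (no exposure frequencies are published); TOL and control
  samples carry no agents by definition.
* **What it does not emulate.** Batch and scanner artifacts, probe-sequence
  affinity structure, and correlation beyond the planted modules.
  Recovery results on these cohorts therefore bound what the methods do
  under their own assumptions, not what they achieve on real arrays, where
  unmodelled correlation typically inflates false-call variability.

`generate_probe_level()` expands the same cohort to probe level
(`intensity = 2^(signal + affinity + noise)`, affinities fixed per probe
across arrays) as a fixture for preprocessing.

# Preprocessing

The three RMA-style steps operate per probe set:

* **Background.** The full normal+exponential convolution model is not
  implemented; `prep_config(background = "shift")` subtracts a per-array
  quantile (default q = 0.05) and floors at ε = 0.5. The acceptance
  surface of this package is the downstream statistics, so background is a
  configuration point (`"none"` by default) rather than a modelling focus.
* **Quantile normalization.** Columns are mapped onto the row-mean of the
  column-sorted matrix. Tied values receive the mean of the target values
  their ranks span, which keeps the operation well defined on discrete
  data; on tie-free data the transform is idempotent and makes all column
  distributions identical.
* **Median polish.** `stats::medpolish` fits
  `log2(I) = μ + probe + array` with row-then-column median sweeps
  (stopping at `polish_tol = 1e-8` or 20 sweeps); the summary is
  `μ + array effect`. Fixed probe affinities are absorbed into probe
  effects, which is why zero-noise fixtures are recovered exactly.
  Probe sets need ≥ 2 member probes; single-probe sets are rejected.

# SAM

For probe *i*, `d_i = (x̄_A − x̄_B) / (s_i + s0)` with the pooled standard
error using `a = (1/n_A + 1/n_B)/(n_A + n_B − 2)`.

* **s0.** Candidates are the 0, 5, …, 100 percentiles of `s`; the chosen
  value minimizes the coefficient of variation of the MAD of `d` across
  100 `s`-quantile windows (fewer on small fixtures). Ties take the
  smallest candidate, so homoscedastic data gets `s0 = 0` (with a
  warning). A fixed `s0` bypasses the search.
* **Permutation null.** Group labels are permuted; all distinct
  assignments are enumerated when there are at most `n_perm` of them
  (e.g. 3 vs 3 gives 20), otherwise `n_perm` (default 200) are sampled
  under the seed. Sorted permuted `d` vectors are averaged to the expected
  order statistics `d̄_(i)`.
* **Delta calibration.** Over a 200-point grid from 0 to
  `max|d_(i) − d̄_(i)|`, the classic cut rule applies: moving outward from
  the origin of the expected quantiles, the first probes exceeding the
  band define upper/lower cuts and everything beyond them is called. The
  FDR estimate is the median (or 90th percentile, by option) count of
  permuted values beyond the cuts divided by the number called, with the
  true-null proportion fixed conservatively at 1. The returned delta is
  the smallest grid value meeting the target (default 0.10); if none
  does, the call set is empty and the best estimate is reported.
* **Fold filter.** Fold change is `2^|x̄_A − x̄_B|` — the ratio of group
  geometric means, the natural reading of a fold difference of means on
  log2 data — and called probes must reach `min_fold` (default 1.5).
* **Power.** `estimate_power()` simulates repeated two-group cohorts and
  reports the mean fraction of planted probes called and the realized
  FDR. The published 99%-power figure for a 10 vs 10 pilot with 233 true
  genes at 1.5-fold was computed from another cohort's (unpublished)
  variance, so it is not a reproduction target; the acceptance script
  reports the power our generator's sd = 0.4 implies instead.

# The confound filter

`derive_unique_lists()` treats a probe as *shared* only when it appears in
both vs-control lists with the same direction; opposite-direction probes
stay informative in both unique lists. `derive_final_lists()` matches the
two-group list against the unique lists **by probe id**: membership, not
direction agreement, defines the finals, because a probe can legitimately
rank TOL-high against non-TOL yet TOL-low against controls. When the
two-group and vs-control directions disagree the probe is kept, the
vs-control direction is reported, and the id is flagged in
`direction_conflicts`. The per-agent check runs SAM exposed-vs-unexposed
within non-TOL (agents with fewer than 2 samples on either side are
skipped with a warning) and reports overlaps with the phenotype list.

The matched-pair secondary analysis replaces the probe-level MAS 5.0
change algorithm with a probe-set-level paired rule — Wilcoxon signed-rank
p < 0.05 on per-pair log2 ratios plus a 1.5 geometric-mean fold floor —
since probe-level data ends at preprocessing and the secondary analysis
only serves as a concordance check (α is configurable, with an optional BH
correction; the original thresholds are unpublished).

# Enrichment

Ranking uses signal-to-noise `(μ_A − μ_B)/(σ_A + σ_B)` with each σ floored
at `max(0.2·|μ|, 0.2)` (the classic GSEA floor), ties broken by probe id
for determinism. The weighted-KS enrichment score (hit weight exponent
p = 1) increments by normalized |score| at members and decrements
`1/(N − N_H)` elsewhere; ES is the signed maximal deviation. NES divides
ES by the mean of same-signed permuted ES; p-values are one-sided
same-sign exceedance fractions with add-one smoothing; FDR uses the
standard NES-ratio estimator clipped to [0, 1]. Phenotype permutation is
the default but requires ≥ 7 samples, below which the test switches to
gene-set permutation with a warning. Over-representation is the exact
upper-tail hypergeometric with BH q-values across sets; proprietary
process-network databases are not shipped — the packaged GMT
(`inst/extdata/synthetic_lineage_sets.gmt`) contains the generator's six
synthetic lineage sets, and any user GMT loads through `read_gmt()`.

# Classification

* **Folds.** "Leave-10%-out repeated with unique samples" is realized as a
  stratified 10-fold partition — every patient held out exactly once,
  class counts per fold within one of proportionality — which is the only
  reading consistent with pooling a full 15 + 17 confusion matrix.
* **Selection.** Per fold, the top-k (default 20, studied range 20–80)
  features by |moderated d| with `s0` chosen on that training fold; only
  training samples are seen, the leakage-safe reading of per-validation
  feature selection. Ties break lexicographically.
* **Model.** The published classifier is an artificial neural network with
  unstated architecture; the default here is a 3-unit single-hidden-layer
  logistic network (`nnet`, weight decay 0.05, ≤ 500 epochs,
  fixed-seed initialization, one perturbed-seed retry before failing).
  The model is a swappable `fit`/`score` contract, so any classifier can
  be plugged in.
* **Reporting.** *Weighted accuracy* is pooled correct over total
  classified — consistent with a published 87.5–90.6% range equalling
  28–29 of 32 — with macro-averaged per-class accuracy alongside to cover
  the alternative reading. AUC comes from the tie-corrected rank
  statistic (equal to the trapezoid over the empirical ROC); its CI is a
  stratified percentile bootstrap (2000 replicates by default), chosen
  because the published interval's construction is unstated.

# Numerical and testing choices

Determinism is end-to-end: every stochastic stage takes a seed, and the
pipeline manifest contains no timestamps, so identical configurations
produce byte-identical output. Degenerate inputs fail loudly: groups of
fewer than 2 samples, zero-variance probes at `s0 = 0`, gene sets equal to
or disjoint from the universe, single-class ROC truth, probe sets with one
member.

Validation experiments run at the study's sample design (15/17/10) with
2000 probes: SAM recovery uses 100 planted probes at log2 effect 1.0 and
sd 0.4 over 10 seeds; null calibration uses 20 pure-null cohorts; the
confound filter plants 100 TOL-unique, 50 non-TOL-unique and 100
confounded probes; the classifier positive control uses a log2 effect of
2.0 over 10 seeds and its leakage guard pools three permuted-label null
runs. These sizes keep the full suite near a minute on one core while
leaving Monte-Carlo margins far from the asserted thresholds.

# Limitations

The generator's independence and Gaussianity assumptions are favourable
to every method tested; planted-recovery rates are upper bounds, not
field performance. The background-adjustment step is a placeholder for
the RMA convolution model. GSEA FDR with few sets and the NES-ratio
estimator is coarse (permutation counts bound attainable p-values). The
classifier makes no claim of transportability across cohorts or
platforms — the published attempt at external replication of the original
signature was itself unsuccessful.
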