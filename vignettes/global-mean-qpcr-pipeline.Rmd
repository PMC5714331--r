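---
title: "Global-mean normalization and group contrasts for circulating miRNA qPCR panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global-mean normalization and group contrasts for circulating miRNA qPCR panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the models and
procedures it implements, the assumptions behind them, the parameters that
matter, what the synthetic cohort generator does and does not emulate, and
the numerical and design choices made where the design was genuinely open.

## Setting

A focused RT-qPCR panel quantifies 179 miRNAs known to be detectable in
human plasma, in a small cohort spanning the pre-diabetes spectrum: normal
glucose tolerance (NGT, n = 9), impaired glucose tolerance split by
12-month follow-up into non-progressors (NP-IGT, n = 4) and progressors
(P-IGT, n = 5), and newly diagnosed, drug-naive type 2 diabetes (T2D,
n = 9). The quantification cycle Ct is a log2-scale quantity: one cycle is
one doubling, lower Ct means more template. Because plasma has no agreed
housekeeping miRNA, all relative quantification here is anchored on the
*global mean*: the per-sample average Ct of the assays detected in every
sample (the co-expressed set).

A note on the group sizes: the source cohort description itself is
internally inconsistent about whether the IGT split is 4 + 5 or 5 + 4.
The package therefore never hard-codes the split; group sizes always come
from the annotation table (or the generator configuration), with NP = 4 /
P = 5 as the default.

## Quality control

Three assay-level filters are applied before anything else, with exactly
one primary reason logged per removal:

* `multi_melt` — the melting curve shows several or out-of-spec melting
  points (the flag is an input; the package does not process raw
  fluorescence);
* `low_efficiency` — amplification efficiency strictly below 1.6
  (boundary value 1.60 is kept);
* `near_negative_control` — a detected Ct within 5 cycles of the assay's
  negative control. Assays whose negative control never amplified pass
  this rule.

Melting and efficiency are properties of the assay and remove the whole
panel row. For the negative-control rule the stricter panel-wide reading
and the data-preserving per-reaction reading are both defensible; the
default is per-reaction removal (`scope = "cell"`), with
`scope = "assay"` available. QC is monotone: loosening the margin or the
efficiency cutoff never removes more data.

Hemolysis is monitored by ΔCt = Ct(miR-23a-3p) − Ct(miR-451a). miR-451a
is abundant in erythrocytes, so red-cell lysis lowers its Ct and inflates
the difference; the conventional warning threshold of 7 cycles is the
default (the analysis itself only tests whether ΔCt differs between
diagnostic groups, by Kruskal–Wallis). The direction of the difference is
target minus marker, the common convention; only the sign of group
effects depends on it.

Spike-ins: UniSp2/4/5 are pre-mixed at 100-fold concentration steps, so at
efficiency 2 consecutive Cts should differ by log2(100) ≈ 6.64 cycles;
deviations beyond ±1 cycle are warned. UniSp6, added at reverse
transcription, is compared against its cohort median (±2 cycles). These
tolerances are reporting thresholds, not removal rules.

## Global-mean normalization

With GM_s the mean Ct of the co-expressed set in sample s, the normalized
relative quantity of assay a is

$$\mathrm{NRQ}_{as} = 2^{\,GM_s - Ct_{as}},$$

stored on a log scale. The exponent base is fixed at 2 — that is PCR
chemistry — while the reporting base is log10 by default (matching the
usual presentation of such data) and log2 on request. Two identities pin
the implementation down and are tested: over the co-expressed set the
per-sample log2 NRQs sum to exactly zero (the product of NRQs is 1), and
NRQ is invariant to adding a constant to all Cts of a sample.

### Why the global mean? A model-based stability score

The choice of normalizer is justified by a variance-decomposition
stability score in the NormFinder tradition, computed on log2-scale
quantities. For candidate gene i in group g, the model separates an
intragroup variance σ²_ig and a systematic intergroup deviation d_ig of
the gene relative to the candidate-set average. Because each gene's
deviation is measured against the set average, the naive per-gene variance
is contaminated by the average itself; the estimator corrects for this:
with k genes and per-gene raw variances s²_ig,

$$\hat S_g = \tfrac{k}{k-1}\sum_i s^2_{ig}, \qquad
  \hat\sigma^2_{ig} = \max\!\Big(0,\; \big(s^2_{ig} - \hat S_g/k^2\big)\tfrac{k}{k-2}\Big),$$

(negative intermediate estimates truncated at zero). Group deviations are
shrunk empirical-Bayes style toward zero using an intergroup variance τ²,
and the stability value is the group average of |shrunken deviation| plus
the posterior spread — lower is more stable.

Two deliberate choices here:

* **τ² estimator.** τ² is estimated as Σ d²/((G−1)(k−1)) *without*
  subtracting the sampling contribution. The deflated-and-truncated
  alternative collapses to exactly zero in about half of all replicates
  when true group effects vanish, which zeroes every stability value and
  leaves the ranking undefined. The conservative estimator keeps the score
  defined and sensitive to candidate variance in that regime, at the cost
  of a slight upward bias in the bias term for all candidates equally.
* **The pseudo-candidate.** The global mean enters the ranking as an extra
  candidate. Its deviation from the candidate-set average is identically
  zero by construction — relative quantification cannot assess the
  normalizer's own bias, a tautology no algorithm escapes — so its score
  reflects the estimated sampling variance of the set average, Ŝ_g/k² per
  group. The candidate-set average never includes the pseudo-candidate.
  Under independent noise of comparable size across k = 90 genes this
  variance is ~1/90 of a single gene's, which is the precise sense in
  which "the average is more stable than any single gene"; the test suite
  verifies the claim across 100 replicate null cohorts.

Stability is computed grouped over the three diagnostic groups
(NGT/IGT/T2D) by default — the setting in which a normalizer must be
validated, since a group-biased normalizer would masquerade as
differential expression — with an ungrouped mode available.

## Co-regulation diagnostics

Three analyses interrogate the *structure* of the panel rather than single
assays, all rank-based (Spearman with average ranks for ties; a two-sided
p from the t approximation, which is well-behaved under the heavy ties of
fixed-precision Ct exports):

* **Quantity trend** — reversed-Ct global means (negated, so higher =
  more miRNA) against 2-hour OGTT glucose and HbA1c across all samples.
* **Correlation profiles** — within each diagnostic group, the Spearman
  correlation of every co-expressed miRNA with the group's global mean,
  plus the full miRNA-by-miRNA map. The per-miRNA correlation
  distributions are compared across groups by Kruskal–Wallis with Dunn's
  comparisons against IGT (the reference group is a parameter; different
  analyses use different references). Correlations are computed on raw Ct
  within group; being rank-based, reversing the scale only flips signs.
  The co-expressed set is used because it is the only set defined in
  every sample.
* **Local-vs-global slope** — per group, the OLS slope of one assay's Ct
  on the per-sample global mean. Slope 1 means one-to-one tracking of the
  global signal; attenuation across groups means the assay's quantity
  decouples from global miRNA concentration. Slopes need ≥ 3 detected
  samples; a constant regressor is flagged as degenerate rather than
  silently zero.

Dunn's z uses pooled tie-corrected rank variance, and the multiplicity
adjustment is Bonferroni over the requested comparison family (the
classical "Dunn's multiple comparison test"), with Holm and Šidák
available.

## The contrast lattice

Differential expression is tested per assay by a two-sided unpaired t test
on log NRQ for each of five comparisons: pooled IGT, NP-IGT, P-IGT and T2D
each against NGT, and NP against P. The pooled-variance Student test is
the default (the era-typical "unpaired t test"), Welch optional. p-values
map to the star categories n.s. / * / ** / *** at the exact boundaries
0.05 / 0.01 / 0.001 (≥ 0.05 is n.s.). No correction across assays is
applied by default — deliberate fidelity to the raw p < 0.05 convention of
this analysis family; a Benjamini–Hochberg column can be switched on. The
cost of that convention is visible in the package's own outputs: with ~150
tested assays per contrast, the union signature contains a substantial
false-positive component, and contrasts involving the small,
high-dispersion IGT subgroups are anti-conservative under pooled variance.
The BMI-stratified control (re-running the lattice with groups defined by
covariate strata) shows how much of a signature survives when the grouping
carries no glucose-metabolism information.

The signature is the union of assays significant in ≥ 1 contrast; the four
group-mean log-NRQ profiles over the signature are clustered
agglomeratively (Euclidean distance, average linkage by default; both
configurable, as the convention for such dendrograms is not fixed) and
exported as a newick string.

## Clinical statistics

* **ANOVA from summaries** — one-way ANOVA is recomputed exactly from
  per-group (mean, SD, n): SS_between = Σ nᵢ(meanᵢ − grand mean)²,
  SS_within = Σ (nᵢ−1)sdᵢ². Given exact summaries this *is* the raw-data
  ANOVA (oracle-tested to 1e-10); applied to a printed table it reproduces
  p-values at printed precision. The bundled reference summaries
  (`table1_reference()`) carry the printed clinical characterization of
  the modelled cohort; reconstruction from rounded means/SDs is compared
  at the table's printed precision, no tighter.
* **Exact r×c test** — the two-sided conditional exact test (sum of
  probabilities of tables no more probable than observed, fixed margins,
  no mid-p), with all-zero margins dropped first. The bundled gender split
  (44/56/22% males of n = 9) reconstructs to integer counts 4/5/2; its
  exact p (≈ 0.49) does not round to the printed one-decimal 0.3, which is
  why the gender row is treated as a structural check rather than a
  numeric anchor.
* **HOMA-IR** — both conventions are implemented: `conventional`
  (glucose mg/dL × insulin / 405, equivalently mmol/L / 22.5) and
  `mgdl_direct` (the 22.5 divisor applied to mg/dL directly, a variant
  that appears in some clinical reports; exactly 18× the conventional
  value). The conventional form is the default and is what the synthetic
  clinical model uses, since it reproduces the magnitudes of the bundled
  reference table.
* **Test routing** — continuous variables go to ANOVA, or to
  Kruskal–Wallis when any group's moment skewness exceeds 1 in absolute
  value. The qualitative "skewed distribution" rule had to be made
  operational; |skewness| > 1 is this package's choice and is
  configurable.

## The synthetic cohort generator

The generator is the package's study-conditions definition, not a tuning
dial. The model for assay a in sample s of group g is

$$Ct_{as} = \mu_a - \mathrm{shift}_g + \lambda_{ag} f_s + \delta_{ag} + \varepsilon_{as}$$

* `f_s ~ N(0, 1)` — a per-sample latent factor: the shared plasma miRNA
  concentration signal. A single factor is the minimal structure that
  reproduces every qualitative co-regulation claim at once; this is a
  modeling choice, not a claim about biology.
* `λ_ag ~ N(1, factor_loading_sd²_g)` — loadings; their group-wise
  dispersion controls how tightly assays co-regulate. Defaults 0.20 /
  0.55 / 0.55 / 0.25 (NGT / NP / P / T2D): the IGT groups get the wide
  dispersion that produces the loss-of-co-regulation pattern, T2D is left
  slightly above NGT.
* `shift_g` — cycles subtracted from all Cts: 0 / 0.7 / 0.7 / 0.9,
  the progressive global concentration increase.
* `δ_ag` — injected differential effects in cycles (= log2 units). The
  default block echoes the qualitative contrast pattern of the modelled
  cohort: nine NP-specific effects (two up, seven down, 0.8–1.2 cycles),
  three T2D effects with P-IGT at 0.8× and NP-IGT at 0.2× of them, and
  three NP-vs-P effects.
* `ε ~ N(0, 0.4²)` cycles of residual noise; detection-limit censoring at
  Ct 37; designated assays (miR-23a-3p/miR-451a for hemolysis at baseline
  Cts 24/21, a miR-27a-like assay at 26) have pinned baselines, and the
  coupled assay's loading is set to 1.0 / 0.6 / 0.6 / 0.3 per group — the
  ground truth for slope recovery.
* Baseline means μ_a come from a two-component profile: 60 abundant
  assays U(20, 33) and 119 borderline assays U(34.5, 37.5). The component
  boundaries were calibrated once, against the published detection
  structure of such panels (~162 of 179 assays detected per sample, ~90
  detected in all samples), before any acceptance test was written, and
  are not revisited. A single uniform baseline cannot reproduce both
  numbers at once under a unit-variance common factor.
* Clinical covariates are drawn per diagnostic group from the bundled
  reference summaries — normal for near-symmetric variables, log-normal
  with matched mean/SD for the skewed ones (insulin, microalbuminuria,
  triglycerides) — and HOMA is computed from the drawn glucose and
  insulin rather than drawn independently. Sex follows the reference
  percentages. Spike-ins sit at the exact ladder spacing plus 0.15 cycles
  of noise; a few borderline-block assays are planted to fail each QC
  filter so the filters always have work to do.

All randomness flows from one seed; the generator saves and restores the
session RNG state, and identical seed + configuration gives bit-identical
cohorts. `truth_table()` exposes the injected effects, slopes and shifts
for parameter-recovery tests.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: plate and batch effects, inter-run calibration,
efficiency heterogeneity between assays (efficiency enters QC only),
non-Gaussian Ct noise near the detection limit, correlated miRNA families
beyond the single factor, and any real association between miRNA levels
and clinical covariates within groups (clinical signal is group-level
only). Recovery results on synthetic cohorts are statements about the
pipeline's correctness under its assumed model, not about biology.

### A known tension worth stating plainly

Under the defaults, the per-sample global-mean SD is ≈ 1 cycle (the unit
latent factor dominates), while the IGT→T2D concentration gap is 0.2
cycles. With nine samples per group, a 0.2-cycle difference cannot be
ordered reliably: the strict NGT < IGT < T2D ordering of group-mean
detection counts and global quantities reproduces in roughly half of
replicate cohorts, not near-always (the corresponding acceptance test
records this honestly and fails). This mirrors the real design's
fragility — at these effect sizes and sample sizes, the *direction* of the
NGT-vs-impaired difference is robust, but the fine ordering of IGT vs T2D
is not. The NGT-lowest pattern alone reproduces in a large majority of
replicates.

Similarly, global-mean normalization assumes differential effects are
approximately balanced: strongly one-sided effects shift the normalizer
itself and leak into every null assay. The differential-expression power
experiment therefore injects balanced effects (five up, five down at 1.5
cycles); its false-positive rate runs slightly above the nominal 5%
because t tests on borderline assays inherit detection-limit censoring
bias — both facts are visible in the reported numbers rather than hidden
by the experiment design.

## Numerical choices and degenerate inputs

* Undetected reactions are `NA` throughout — never a sentinel cycle
  number; the reader can map configurable tokens and an optional Ct
  ceiling onto the undetected state.
* Detected Ct values must be finite and in (0, 50].
* Spearman on a constant vector is flagged (`constant = TRUE`, r = NA),
  not returned as 0; Kruskal–Wallis on identical values returns H = 0,
  p = 1 (degenerate, not an error); a t test between two zero-variance
  groups returns t = 0/±∞ explicitly; ANOVA with MS_within = 0 and
  MS_between > 0 reports p = 0 with a degenerate flag.
* Ties use average ranks everywhere; H and Dunn variances are
  tie-corrected.
* The log2-NRQ zero-sum identity is exact to floating point (< 1e-9 is
  asserted; observed ~1e-13).
* Dendrograms are deterministic in leaf-input order (distances on group
  means, not samples).

## Problem sizes

The test suite and the acceptance script run everything at the study's own
scale (179 × 27 cohorts) with replicate counts chosen for stable
estimates at interactive runtimes: 100 replicates for the stability claim,
40 for ordering and clustering rates, 15–30 for correlation, power and
slope summaries. The full suite runs in well under a minute; the
acceptance script in a few seconds.

## Limitations

* The pipeline reproduces machinery, not the original gene lists: which
  specific miRNAs reach significance depends on the unpublished raw QC
  flags of the source data and is out of scope by design.
* The exact r×c test delegates to the network algorithm and will refuse
  pathologically large tables rather than approximate silently.
* The stability score's bias term cannot evaluate the normalizer itself
  (see above); its ranking of the global mean rests on the variance term.
* Pooled-variance t tests are anti-conservative when a small group has
  inflated variance — exactly the IGT configuration the generator
  emulates; the Welch option exists for modern re-analysis.
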