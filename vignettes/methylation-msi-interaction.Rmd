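---
title: "Methods: paired methylation analysis with an MSI interaction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired methylation analysis with an MSI interaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msimeth)
```

## The design and the models

`msimeth` analyses a paired tumor/normal methylation study: every person
contributes one tumor and one matched normal sample, and a person-level
subgroup label (microsatellite instability, MSI vs MSS) may modify the
tumor effect. The response at each CpG locus is the beta value, the
methylated fraction of probe intensity, in [0, 1].

Three per-locus ANOVA models are fitted:

* **Paired model** `y ~ tumor + person`. Person is a random effect; the
  model is the classical randomized block, so the tumor F statistic with
  df (1, n−1) equals the squared paired-t statistic — this identity is
  enforced by an oracle test. The person variance component is estimated
  by the method of moments from the expected mean squares:
  `sigma2_person = (MS_person − MS_error) / 2`, truncated at zero (the
  untruncated value is kept for diagnostics). The F denominator for every
  term is the residual mean square; with two observations per person this
  is the standard paired analysis. (Whether a synthesized error term
  should be used instead for mixed models is ambiguous in general; for
  this balanced two-observation design MS_error is the conventional
  choice.)
* **Interaction model** `y ~ tumor * msi`. Deliberately fitted *without*
  a person term, matching the model equations the analysis is defined by;
  a person term can be added by fitting the location/paired machinery on
  residuals, but the default surface keeps the stated model. A
  consequence discussed below is that the interaction test is
  conservative when person heterogeneity is present.
* **Location model** `y ~ tumor + msi + location + tumor:msi +
  tumor:location`, which reports the Tumor×MSI interaction adjusted for
  tumor site. If a factor has fewer than two observed levels its terms
  are dropped with a flag and the model degrades gracefully to the
  smaller one.

Fixed-effect tests use Type III sums of squares with sum-to-zero
contrasts. The study design is only mildly unbalanced (equal tumor/normal
split, unequal MSI/MSS), and Type III keeps main-effect tests meaningful
in the presence of the interaction; on balanced designs it coincides with
Type I. The implementation is QR projector algebra: the design is
identical across loci, so the full-model and each term-deleted basis are
computed once and a genome-wide scan reduces to a handful of matrix
products (2000 loci × 250 samples scan in well under a second). Tests
verify the fits against `car::Anova(type = 3)` and explicit
model-comparison F statistics.

Missing betas use pairwise deletion per locus: a pair is dropped when
either half is missing, and loci that lose too much design (fewer than
two pairs, an empty interaction cell) are flagged in the output rather
than dropped or thrown.

## DML calling and interaction categories

Stratified DML calls (within MSI, within MSS) require Benjamini–Hochberg
q ≤ 0.001 *and* |Δβ| ≥ 0.2 (a 20% methylation difference; the magnitude
filter removes statistically firm but biologically trivial effects).
Interaction membership requires q ≤ 0.05 on the Tumor×MSI term and is
*not* magnitude-filtered — the source analysis reports interaction loci
without one, and the categories below reintroduce magnitude through the
stratified calls. All thresholds live in `dml_thresholds()` and are
configurable.

Each locus then receives exactly one category from its membership triple
(MSI-DML, MSS-DML, interaction): A = both strata, no interaction;
B = MSI only, with interaction; C = both strata, with interaction;
D = MSS only, with interaction; otherwise none. The mapping is a pure
function of the triple and is tested over all eight membership patterns.

The promoter-island filter restricts the universe to loci in a CpG island
and promoter-associated, then applies a Bonferroni threshold
`alpha / n_filtered` to the interaction p-value — the family-wise
correction is computed on the filtered universe, not the whole chip.

BH ties are handled by the step-up procedure itself (shared rank of the
sorted position); missing p-values propagate as missing and do not count
toward the number of tests.

## Enrichment, cohort and expression statistics

Gene-category enrichment is a 2×2 Pearson chi-square (no continuity
correction) of the category's share of significant genes against its
share of the chip; the score is −log10 p, base 10 chosen for
readability. The chip background includes the significant genes by
default (an exclusive background is a toggle). A gene is "significant"
when at least one of its loci is in the significant list — the least
restrictive mapping, appropriate because loci, not genes, are tested.

Cohort characteristics use uncorrected Pearson chi-square by default;
Yates-corrected and exact Fisher variants are exposed because published
per-row p-values of such tables are frequently a mix of the three and no
single method reproduces them all. Display percentages round half-up at
integer precision, with full precision retained.

Expression analysis assumes log2-scale input and performs no
normalization. Fold changes are back-transformed mean paired log2
differences with a t-based confidence interval (the CI method is a
package choice; bootstrap or model-based intervals would also be
defensible). The signed-fold convention maps a ratio r to r when r ≥ 1
and to −1/r otherwise — monotone, so CI bounds map through it. The
gene-set average fold pools probe-by-pair log2 differences with equal
weights; pooling (rather than averaging per-probe estimates) matches the
narrow set-level intervals typical of array reports and reduces to the
per-probe estimate for a singleton set.

## What the simulator emulates — and what it does not

`simulate_cohort()` reproduces the study conditions the analysis assumes:
125 persons, 30 MSI, right-sided tumors in 13/30 of MSI and 11/95 of MSS
persons, 72/125 males, ages near 46 (SD 14), stages I/II/III in
proportions 25/33/67. Betas are generated on the logit scale —
`plogis(qlogis(baseline) + tumor·delta_logit + person + residual)` —
which keeps every value strictly inside (0, 1) and shares the person
intercept between a person's two samples exactly as the paired model
assumes. The logit shift is chosen as
`qlogis(baseline + delta) − qlogis(baseline)` so that at zero noise the
tumor-minus-normal difference on the beta scale equals the planted delta
to machine precision; deltas are specified on the beta scale because the
calling threshold is a beta-scale quantity. With noise the realized mean
delta is mildly attenuated by the nonlinearity — tests therefore check
planted deltas at zero noise exactly and recovery at realistic noise
statistically.

Noise defaults are calibration choices, not published values: the source
observation to anchor is that person-to-person variation explains more
than 62% of the variation — a share of ANOVA sums of squares. On the
generating scale, a *variance* ratio of 0.62 would produce an SS share
near 0.81 at 125 pairs, so the generator parameterises the person effect
by its expected SS share instead: `calibrate_person_sd(share,
sigma_error, n_pairs)` inverts
`E[share] = A(2·sp² + se²) / (se² + A(2·sp² + 2·se²))`, A = n_pairs − 1.
The defaults `sigma_person = 0.2`, `sigma_error = 0.35` (logit scale)
give an expected share of 0.621 at 125 pairs, and the Monte-Carlo
recovery test confirms the fitted mean share lands within ±0.05 of 0.62.

The type-I-error calibration of the interaction test is run under the
model's own null: person SD set to zero. With person heterogeneity
present, the interaction model (which has no person term) is
*conservative*, not anti-conservative — the interaction contrast is a
within-person difference of differences and cancels person intercepts,
while the residual mean square in the denominator absorbs them — so its
rejection rate under person noise falls below the nominal level. The
matched-null check is the meaningful statement about the test itself.

Not emulated: raw two-channel intensities and IDAT files, probe-type
chemistry biases, chip batch structure, control-probe normalization, and
any dependence of methylation on sex, age or stage. Passing the recovery
tests therefore shows the pipeline is correct and well calibrated for
data satisfying its model assumptions; it does not certify robustness to
array artefacts that real 450K data can carry.

A single global seed expands deterministically into per-stage streams
(cohort, betas, annotation, expression), so pipelines are reproducible
end to end while stages stay independently re-runnable.

## Numerical choices and degenerate inputs

* Sums of squares are computed as differences of squared projections;
  values below `1e-11 · max(total SS, 1)` are rounding noise and set to
  exact zeros. On an exactly interpolated locus (zero residual) a zero
  term SS reports F = 0, p = 1 and a positive one F = Inf, p = 0, with a
  `zero_residual` flag.
* A paired t-test with zero spread reports p = 0 (flagged degenerate)
  for a nonzero mean and p = 1 for a zero mean.
* Variance decomposition of a constant locus flags degeneracy and
  reports all shares as 0.
* Beta I/O rejects values outside [0, 1] naming the offending cell,
  ragged rows, and duplicate identifiers; round-trips preserve 12+
  significant digits. "Deep Sea"/"Open Sea" spellings are accepted as
  aliases of the OpenSea region category on input.
* The beta denominator carries no intensity offset by default (the
  formula is the plain fraction); the Illumina +100 convention is
  available via the `offset` argument.

## Problem sizes used in the validation suite

The suite exercises the full study geometry where it matters and small
designs elsewhere: calibration and recovery checks use 2000 loci × 250
samples (125 pairs, 30 MSI), classification recovery uses 500 loci (100
per effect class, |Δβ| = 0.3), expression power uses 200 replicates of a
single planted probe, and CI coverage uses 1000 replicates at 30 pairs.
Oracle equivalences run on hundreds of small randomized designs. The
whole suite completes in about half a minute on one core.

## Known limitations

* Variance components use the method of moments, not REML; no shrinkage
  or empirical-Bayes moderation across loci (a limma-style analysis is a
  different design point).
* No covariates beyond tumor, MSI and location; no batch or
  surrogate-variable correction.
* The interaction model omits the person term by construction (fidelity
  to the stated equations); under strong person heterogeneity its
  interaction test loses power relative to a within-person contrast.
* Enrichment operates on user-supplied category maps only; no live
  ontology queries.
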