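# msimeth

Genome-wide interaction analysis of microsatellite instability (MSI) and
tumor DNA methylation in paired tumor/normal designs.

## The scientific problem

In colorectal cancer, roughly 15% of tumors show microsatellite
instability. Tumor DNA methylation is a second, independent axis of
molecular change, and the two interact: far more loci become
differentially methylated in tumors from MSI patients than in
microsatellite-stable (MSS) patients. `msimeth` implements the full
per-CpG analysis for detecting and classifying that interaction in a
paired design where every person contributes one tumor and one matched
normal sample (the motivating study: 125 persons, 30 with MSI, Illumina
450K beta values), together with a synthetic-data generator that emulates
the design so the whole pipeline can be exercised and validated without
access to patient data.

## The models

Per CpG locus, with the beta value
`beta = X / (X + Y)` (methylated over total probe intensity) as the
response `Y`:

1. **Paired model** `Y_ijk = mu + Tumor_i + Person_j + e_ijk` — a
   randomized-block ANOVA with Person as a random effect. The tumor F test
   equals the squared paired-t statistic; the person variance component is
   estimated by the method of moments,
   `sigma2_person = max(0, (MS_person - MS_error) / 2)`.
2. **Interaction model** `Y_ijk = mu + Tumor_i + MSI_j + Tumor*MSI_ij +
   e_ijk` — the Tumor×MSI term tests whether the tumor-minus-normal delta
   beta differs between MSI and MSS patients (Type III sums of squares,
   sum-to-zero contrasts).
3. **Location model** adds `Location` and `Tumor*Location`, testing the
   interaction adjusted for tumor site (proximal/distal).

Downstream, loci are called **differentially methylated (DML)** per
stratum when the Benjamini–Hochberg q-value of the paired test is ≤ 0.001
and |Δβ| ≥ 0.2, interaction loci at FDR 0.05 on the Tumor×MSI term, and
every locus is classified by its membership in the three sets:
**A** (shared effect, no interaction), **B** (MSI-only effect),
**C** (both, different magnitude), **D** (MSS-only effect). Region
tabulation (CpG island / shore / shelf / open sea), chi-square gene-set
enrichment (score = −log10 p), cohort characteristic tests, and paired
expression fold changes with t-based 95% CIs under the signed-fold
convention complete the pipeline.

## Worked example

```r
library(msimeth)
sheet <- simulate_cohort(cohort_config(seed = 1))   # 125 persons, 30 MSI
eff <- rbind(
  locus_effects(200, "null",     baseline = 0.35),
  locus_effects(20,  "msi_only", 0.3, 0,   0.3, locus_id = sprintf("mi%03d", 1:20)),
  locus_effects(10,  "shared",   0.3, 0.3, 0.3, locus_id = sprintf("sh%03d", 1:10))
)
sim <- simulate_beta_matrix(sheet, eff, noise_spec(), seed = 1)
res <- dml_scan_results(sim$beta, sheet)
build_dml_catalog(res)
#> DML catalog: 230 loci
#> MSI DML: 30 | MSS DML: 10 | interaction: 22
#> category
#>    A    B    C none
#>    9   20    1  200
```

The 20 planted MSI-only loci are all called in the MSI stratum and 20 land
in category B; the 10 shared loci are DML in both strata (9 in category A;
one drifts into C through a borderline interaction q-value); the 200 null
loci stay uncalled. A single locus can be inspected directly:

```r
fit_interaction_model(sim$beta["mi001", ], sheet)
#> Per-locus ANOVA (interaction model), n = 250
#>       term  df       ss         ms       f           p
#>      tumor   1 1.205980 1.20598000 177.361 7.79989e-31
#>        msi   1 1.333740 1.33374000 196.151 3.63276e-33
#>  tumor:msi   1 0.943007 0.94300700 138.686 1.10012e-25
#>      error 246 1.672700 0.00679958      NA          NA
#> delta beta: all 0.08785 | MSI 0.3064 | MSS 0.01882
```

This locus gains ~0.31 methylation in tumors of MSI patients but only
~0.02 in MSS patients, and the Tumor×MSI term is decisive — the planted
MSI-only effect.

A file-based end-to-end run (simulate → scan → classify → enrich →
cohort → expression) is available as `pipeline_demo("outdir", seed = 1)`
or from the shell via the wrapper in `inst/scripts/msimeth`.

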