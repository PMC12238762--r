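---
title: "Methods: cross-version methylation array comparison in methCompare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-version methylation array comparison in methCompare}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methCompare)
```

# Scope and data model

`methCompare` analyzes matched-donor DNA methylation β-value data
measured on the two MethylationEPIC array versions. The central
container is the `MethylationSet`, a `SummarizedExperiment` whose
`beta` assay holds methylation fractions in [0, 1] (missing cells
permitted), with optional `detectionP` and `beadcount` QC assays of the
same shape, the probe manifest in `rowData` and the per-array sample
sheet in `colData`. All pairwise statistics use complete-pairs deletion
per probe; probe and sample identifiers are case-sensitive exact
strings.

The package starts from β values, not raw fluorescence: IDAT parsing,
background correction and normalization are upstream concerns (any
normalization whose output is a β matrix can feed the pipeline).

# Harmonization

EPICv2 measures a few thousand base CpGs with 2–10 replicate probes.
`collapseReplicateProbes()` reduces these to one row per base CpG by
one of three strategies. The default, `"detp"`, selects the replicate
row with the lowest mean detection *P*-value across samples as the
representative probe — the mean over samples makes the choice a
property of the probe rather than of individual probe–sample cells, so
one physical probe represents the CpG everywhere. Ties (exactly equal
mean detection *P*) resolve to the lowest replicate index; this
tie-break is a convention, but ties essentially never occur with
continuous detection *P*-values. The `"mean"` and `"median"` strategies
aggregate element-wise and are provided for sensitivity analysis; with
identical replicate rows all three strategies coincide.

`harmonizeSharedProbes()` aligns the two versions on the sorted
intersection of base CpGs and reports version-unique probes rather than
silently dropping them. `flagLowQualityProbes()` implements the
detection-*P*/beadcount rule (failure in strictly more than 1% of
samples on either criterion); flagged probes are *reported and
retained*, since removing them would change the probe universe on which
cross-version comparisons are made. Flagging is monotone in the
detection-*P* threshold by construction.

# Concordance metrics

Array-level concordance is the sample-to-sample correlation matrix
(Pearson for linear agreement, Spearman for systematic possibly
nonlinear shifts), clustered by the two-step approach: complete-linkage
agglomeration on Euclidean distances *between rows of the correlation
matrix*, so samples cluster by the similarity of their correlation
profiles rather than by raw β distance. `hclust` is deterministic for a
given input order, with merge ties resolved toward the earliest index.

Probe-level concordance is the Spearman correlation (mid-ranks for
ties) between a probe's v1 and v2 values across matched donors,
technical replicates excluded. A rank correlation is uninformative when
a probe barely varies between donors, so each probe also gets a pooled
SD — the two-group Bessel-weighted combination of its per-version
sample SDs. We use the two-group estimator rather than the SD of the
concatenated values because "pooled" conventionally denotes exactly
that, and the matched design makes the two groups equal-sized so the
distinction is numerically small but principled.

`classifyProbes()` partitions probes: pooled SD at or below the
variability threshold → `low_variability`; otherwise ρ ≤ 0.70 →
`poorly_concordant`; otherwise `concordant`. The default variability
threshold is the lower quartile of the cohort's pooled-SD distribution
(empirically near 0.01 on the β scale in real cohorts); fixed
alternatives (e.g. SD 0.05 with ρ 0.50) can be supplied to build
threshold grids. Probes with undefined ρ (zero variance or too few
complete pairs) are excluded and counted.

Technical-replicate reliability uses RMSE and the intraclass
correlation ICC(2,1): two-way random effects, absolute agreement,
single measure, computed from the two-way ANOVA mean squares with
probes as targets and replicate arrays as raters. Absolute agreement is
the right variant because replicate arrays should reproduce the *value*
of β, not merely its ranking; the consistency variant would forgive a
constant shift between replicates, which is precisely a signal we want
to detect.

# Variance attribution

`runPCA()` centers probes across samples and decomposes β values
directly. β values are kept on their natural scale (not M-values) and
are not variance-scaled by default — probes share a common, bounded
scale, so unit-variance scaling would up-weight near-constant probes;
a `scale.` flag exposes the alternative. `associatePCs()` fits, per
(component, variable) pair, the simple regression of scores on the
variable (categorical variables via one-way ANOVA encoding) and
records the overall-F *P*-value and R². The Bonferroni family is the
set of tests actually performed — with 5 components and 18 variables
that is 90 tests; single-level variables (e.g. sex in a single-sex
cohort) are skipped with a warning and do not inflate the family.

# Cell-type deconvolution

Reference-based deconvolution follows the constrained-projection
approach: given a reference matrix R of mean β profiles of purified
cell types over discriminating probes, each sample's proportions solve
min ‖β − Rw‖² subject to w ≥ 0, by Lawson–Hanson non-negative least
squares. Only non-negativity is enforced — no sum-to-one constraint —
matching the behaviour of the standard blood-deconvolution
implementation; the proportion sum is reported as a diagnostic and a
`normalize` flag rescales to the simplex when desired. A rank check on
the shared-probe reference fails fast with the most collinear pair of
cell types named.

Discriminating probes come either from a fixed pre-selected panel
(restricted to the probes available on the target platform;
restriction fails when over half the panel would be lost) or from the
automatic method: per probe a one-way ANOVA F statistic across cell
types, and per cell type the top 100 probes with F-test *P* < 1e−8
ranked by one-vs-rest mean difference, split 50 hypermethylated / 50
hypomethylated. The even split is a convention of the reference
implementation; since the defining publication does not pin it down,
`split = "magnitude"` provides the pure top-|difference| alternative.

# Linear scores, clocks and EAA

A `CoefficientSet` is a named linear predictor: intercept plus CpG →
weight map, an output transform (`identity`; the piecewise
`horvath_antilog` with its knot at `adultAge`, mapping x ≤ 0 to
(1+A)eˣ−1 and x > 0 to (1+A)x+A; or `equal_weight_mean`, the
mitotic-clock convention of a plain mean β over the set), and optional
training reference means. Missing CpGs are imputed before scoring:
training (reference) means when the set ships them, otherwise the
CpG's cohort mean across samples; CpGs absent from the matrix entirely
have no cohort mean and fall back to reference means. More than half
the CpGs missing is an error, as the score is then no longer the
published predictor in any meaningful sense. The imputation used is the
common convention of published clock calculators; each run records the
number of imputed CpGs per sample.

Epigenetic age acceleration is the residual of epigenetic age regressed
on chronological age. Three strategies address two-version designs:
fitting each version separately makes residuals version-free by
construction; pooling both versions lets a systematic version offset
surface in the residuals; pooling with a version indicator covariate
absorbs the offset. In a balanced matched design the arithmetic is
exact: a constant +Δ offset on v2 yields per-version mean EAA of ∓Δ/2
under pooling and exactly zero under the other two strategies — the
qualitative pattern the acceptance tests assert. Rate-style estimates
(pace-of-aging, telomere length, mitotic tick counts) have no age
regression; they are version-adjusted by regressing out the version
indicator and re-centering at the grand mean.

# Batch correction and paired comparison

`combatAdjust()` is a parametric empirical-Bayes location/scale
adjustment, per probe: least-squares fit of batch means plus optional
protected covariates; standardization by the pooled residual variance;
per-batch location (γ) and scale (δ²) estimates shrunk toward
batch-level hyperpriors (normal for γ, inverse-gamma for δ², moment
estimates, fixed-point iteration with relative tolerance 1e−4); batch
terms removed and the grand mean and covariate effects restored.
`shrink = FALSE` gives plain per-batch location/scale equalization,
useful as a closed-form oracle. Because the adjustment can leave the
unit interval, values are clipped to [1e−6, 1−1e−6] and the clip count
is reported. Two numerical facts worth knowing: (i) the standard
estimator uses n−1 within batches but N for the pooled variance, so
re-running correction contracts residuals by exactly sqrt((N−B)/N) per
pass (~0.4% at our sizes) — correction is idempotent up to this known
factor, not exactly; (ii) covariates *not* passed to the model are
protected only insofar as they are balanced across batches, which a
matched design guarantees; in unbalanced designs pass them explicitly,
and confounded covariates are rejected via a rank check.
`combatSequential()` applies the correction over version, then chip,
then row, skipping single-level variables.

`pairedCompare()` performs paired *t* tests on per-donor differences
d = v2 − v1, Bonferroni-adjusted over the endpoints passed in the call
(mirroring per-figure families). The effect size is Cohen's d for
paired data, d_z = mean(d)/sd(d), positive when v2 estimates are
higher; d_z is the natural paired-design quantity and matches the
reported sign convention, while `dMethod = "av"` (mean difference over
the average group SD) is available for comparison with unpaired-style
effect sizes. Classes follow the conventional benchmarks: |d| < 0.2
negligible, 0.2–0.49 small, 0.5–0.79 medium, ≥ 0.8 large. With zero
difference SD and a nonzero mean the comparison is flagged degenerate
rather than given a fabricated finite t.

# The synthetic cohort generator

The simulator exists so that every pipeline stage can be validated
against known truth without external data. Its signal model lives in
logit space: donor truth is logit of the cell-mean mixture under
Dirichlet mixing weights, plus a sex shift at ~1% of probes and a
per-probe donor random effect; observations add the per-probe version
offset (v2 only), chip and row effects, and technical noise, then map
back through the inverse logit, so every β lies strictly in (0, 1).
Additive effects on the logit scale are the natural choice for
fraction-valued data; on the β scale the same effects would need
boundary-aware truncation.

Deliberate exceptions and conventions:

* **Clock CpGs are β-linear in age.** A fixed linear score of β values
  cannot equal age exactly through the logistic link, so the planted
  age signal at clock CpGs is linear on the β scale, with slopes
  (±0.002–0.005 per year) and baselines chosen to stay inside
  (0.1, 0.9) over the age range. `simulateCoefficients()` inverts that
  map (w_c = 1/(K s_c)), making the noiseless score *exactly*
  chronological age — a sharp calibration oracle. Clock CpGs carry no
  extra donor random effect; age is their biological signal.
* **Version effects at clock CpGs are explicit.** Random per-probe
  version offsets are drawn on non-clock probes; the clock's version
  effect is injected through `clockVersionShiftYears`, expressed
  directly in years of clock-output shift. A random offset at clock
  CpGs would make the injected shift an uncontrolled sum of
  random-signed terms that can cancel to zero, defeating the purpose
  of an injected scenario.
* **Discordant probes** receive independent per-(donor, version) noise
  (SD 1.5 logit by default) on top of the shared signal, driving their
  cross-version correlation toward zero while keeping their pooled SD
  high — the signature of a poorly concordant probe. They are drawn
  from shared background probes so planted markers and clock CpGs keep
  their designed behaviour.
* **Biological variability is bimodal**: a `fracLowVariability`
  fraction of probes gets donor SDs of 0.01–0.1 logit (the
  near-constant probes that populate the low-variability class), the
  rest 0.4–1.2. Background probe means are drawn from a bimodal logit
  mixture, as on real arrays.
* **Cell mixing** uses a neutrophil-dominant Dirichlet (concentration
  60 around whole-blood-like proportions across the 12 immune cell
  types) — realistic for venous whole blood; fully configurable.
* **Technical replicates** re-measure the source array's observed logit
  signal plus fresh technical noise, inheriting chip and row labels.
  Between-version replicate pairs are the matched v1/v2 arrays of
  replicated donors, so between-version reliability includes the
  version offsets while within-version reliability does not — which is
  why the between-version RMSE exceeds, and ICC falls below, the
  within-version values whenever a version offset is present.
* **Detection *P*-values** are Beta(0.1, 10) for well-behaved cells
  with a configurable uniform fraction emulating failed measurements;
  beadcounts are Poisson(13) clamped at 1, so a realistic sliver of
  cells fails each QC criterion.

Everything is reproducible: the configuration seed fully determines all
outputs through fixed sub-stream offsets (layout, cohort, replicates,
reference), and identical configurations give bit-identical cohorts.

What the generator does **not** emulate: raw fluorescence and
bisulfite-conversion chemistry, probe design-type (I/II) differences,
color-channel and dye-bias structure, genomic positions and
neighbourhood correlation between CpGs, cross-hybridization, underlying
genetic variants, and population structure. Passing tests therefore
demonstrate that the statistical machinery recovers planted effects of
realistic magnitude under a plausible noise model — not that any
specific real cohort will show effects of that size.

# Default parameters

| Parameter | Default | Units / rationale |
|---|---|---|
| `nDonors` | 50 | typical matched-cohort scale |
| `nCpgs` | 20,000 | desk-scale probe universe; statistics are per-probe, so results transfer to full arrays |
| `fracShared` | 0.9 | most base CpGs shared, the rest version-unique |
| `fracV2Replicated` | 0.005 | ~0.5% of CpGs carry 2–10 replicate probes |
| `ageRange` | 25–85 y | adult cohorts |
| `versionOffsetSd` | 0.4 logit | small systematic per-probe offsets on `fracVersionShifted` = 20% of probes |
| `fracDiscordant` | 0.05 | planted poorly concordant probes |
| `discordantNoiseSd` | 1.5 logit | drives ρ ≈ 0 at high variability |
| `techNoiseSd` | 0.07 logit | ≈ 0.017 β-scale SD at β = 0.5, matching replicate-level noise |
| `chipEffectSd`, `rowEffectSd` | 0.05, 0.02 logit | chip > row, both ≪ biology |
| `nTechReplicates` | 2 per version | small, as in real designs |

Validation problem sizes (the package's own choices, stated for
reproducibility): discordant-probe recovery at 50 donors × 20,000 CpGs
with 10% planted discordant probes over 5 seeds; deconvolution recovery
on 100 Dirichlet-mixed samples of the 12-type reference with β noise SD
0.01; the EAA/remediation scenario at 60 donors × 5,000 fully shared
CpGs with a +3 y clock shift plus broad version offsets (SD 0.8 logit
on half the probes) so the version signature is visible on PC1 before
correction; version clustering at 20 donors × 3,000 CpGs with offsets
on all probes (SD 1.5); reliability ordering at 20 donors × 4,000 CpGs
with 3 technical replicates per version; paired-test calibration on
2,000 null endpoints.

# Known limitations

* The probe-classification thresholds (ρ 0.70, lower-quartile pooled
  SD) are conventions, not estimated quantities; the package exposes
  threshold grids precisely because the variability–correlation
  relationship is a continuum.
* Batch correction assumes version is not confounded with biology; in
  unbalanced or longitudinal designs regressing out version can remove
  or fabricate signal. The matched design the simulator emulates is the
  favourable case.
* The empirical-Bayes correction is parametric only (normal /
  inverse-gamma priors); a non-parametric mode is out of scope.
* Scores are generic linear predictors; published clocks whose weights
  are not public, and PC-based clocks with very large loading sets,
  cannot be represented and are out of scope.
* The ICC is the array-level ICC(2,1) of replicate arrays; per-probe
  reliability across cohorts is not implemented.
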