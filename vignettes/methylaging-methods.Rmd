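---
title: "Methods: epigenetic aging analysis for methylation-array cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: epigenetic aging analysis for methylation-array cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylaging)
```

## The problem this package addresses

DNA methylation at age-associated CpG sites is a robust molecular readout of
aging: linear "epigenetic clocks" aggregate weighted beta values over a CpG
panel into an epigenetic age (EA), and the excess of EA over chronological
age — epigenetic age acceleration (EAA) — associates with disease. In acute
myeloid leukemia (AML) the methylation landscape is reshaped by driver
mutations in methylation-pathway genes (DNMT3A, IDH2), and a recurring
observation is that the affected CpGs concentrate at Polycomb Repressive
Complex 2 (PRC2) binding sites, whose mean methylation (PRC2m) shifts down
in DNMT3A-mutant and up in IDH2-mutant disease. This package implements the
complete analysis chain needed to study those effects on any 450K-style
beta-value matrix: cohort QC, clock application and EAA, PRC2 target
construction and scoring, mutation-stratified differential methylation with
TF-binding enrichment, age-adjusted correlation analyses, survival
stratification, and the aging stratification of PRC2-bound low-methylated
regions — together with a seeded synthetic-cohort generator that plants all
of that structure with known truth.

## Epigenetic clocks and calibration

A clock is data, not code: a `clock_definition()` holds an intercept, a
named weight per CpG, a calibration mode and a normalization requirement.
`apply_clock()` computes the linear predictor
$s_i = b_0 + \sum_g w_g \beta_{gi}$ per sample. Two calibrations are
supported:

* **identity** — the predictor is already in years. Causality-enriched
  clocks (AdaptAge/DamAge/CausAge-style) are of this kind and consume *raw*
  betas.
* **log_linear_adult** — pan-tissue-style clocks are trained on
  $F(a)=\log(a+1)-\log(A+1)$ for ages up to the adult knot $A$ (default 20
  years) and $(a-A)/(A+1)$ above it; `calibrate_age()` inverts this
  piecewise transform exactly (`calibrate_age(age_transform(a)) == a` to
  1e-10). These clocks expect BMIQ-normalized betas; the pairing is stored
  on the clock so pipelines can enforce it.

EAA is computed as the plain difference `EA - chronological age`
(`compute_eaa()`). The residual-from-regression alternative is deliberately
not offered for leukemic cohorts: the EA/age relation there is not linear,
so residuals from a global linear fit are not a trustworthy acceleration
measure.

Missing clock CpGs are either an error (default) or cohort-mean imputed
with the imputed count reported; both policies exist because public
matrices often lack a handful of clock probes and the right choice is the
analyst's.

## Cohort QC: the iterative PC1 outlier filter

`pca_outlier_filter()` screens samples along the first principal component
of the probe-centred beta matrix (no scaling — betas already share the
[0, 1] scale). Per iteration, each sample's squared distance $d_i^2$ from
the cohort mean along PC1 is standardized to $z_i$, converted to one-sided
upper-tail normal p-values (only *large* distances indicate outliers — the
squared distance is one-sided by construction), BH-adjusted, and samples
with adjusted p below 0.2 are removed. Iteration stops when all current
z-scores lie in [-20, 20], when nothing is removed, or at the iteration
cap. The stopping band could alternatively be read as a band on the PC1
coordinates themselves; the z-score reading is implemented and recorded in
the report (`stopping_rule`) so either convention can be audited.

Two properties shape expectations on clean data. The z-score of a *squared*
distance is heavy-tailed when PC1 scores are Gaussian, so a cohort whose
leading variation is pure noise will always surrender its extreme tail; the
filter is designed for cohorts whose PC1 reflects a bounded biological
driver (an age span). And any genuinely long-tailed latent structure (e.g.
strong latent-age jitter) produces samples the filter *correctly* flags —
"zero removals" is a property of tight, bounded-driver cohorts, which is
exactly what the synthetic tight-cluster configuration provides for
testing.

## Normalization

**BMIQ-style normalization** (`bmiq_normalize()`) fits a three-state beta
mixture (unmethylated / hemimethylated / methylated) to the sample and to
the reference by EM — states initialized by the 0.2/0.8 beta thresholds,
responsibility-weighted method-of-moments M-steps, convergence at 1e-4
relative log-likelihood, at most 100 iterations, with a hard error carrying
the likelihood trace on non-convergence. The sample is then mapped through
the two fitted mixture CDFs, $x \mapsto F_{\text{ref}}^{-1}(F_{\text{sample}}(x))$.
Mapping through the full mixture CDF (rather than state-by-state with the
unmethylated state untouched) is a deliberate choice: the full-CDF map is
strictly monotone, so within-sample rank order is preserved by
construction, and it reduces to the identity when sample and reference
coincide; a state-wise map can invert ranks at state boundaries. Ties can
appear only where the CDF saturates in floating point (betas
indistinguishable from 0 or 1). The default reference is the probe-wise
median sample of the cohort — deterministic and cohort-internal. BMIQ is
used on the pan-tissue clock path only.

**M-values** (`mvalue_transform()`): $M = \log_2(\beta'/(1-\beta'))$ with
$\beta'$ clipped to [epsilon, 1 - epsilon], epsilon = 0.001. Clipping keeps
boundary betas finite; the transform is strictly increasing on the
interior and exactly invertible on clipped values.

## Differential methylation with variance moderation

`moderated_t_test()` implements the standard empirical-Bayes moderated t
for a two-group contrast on M-values. Per-probe sample variances are
modeled as scaled-F draws around a prior variance $s_0^2$ with prior
degrees of freedom $d_0$; `fit_moderation()` estimates both by method of
moments on $e_g = \log s_g^2 - \psi(d/2) + \log(d/2)$, solving
$\psi'(d_0/2) = \max(\mathrm{var}(e) - \psi'(d/2), 10^{-8})$ with a Newton
trigamma inversion ($d_0 = \infty$, prior variance = mean variance, when
there is no excess spread). The posterior variance
$\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0+d)$ feeds
$\tilde t = \Delta/(\tilde s \sqrt{1/n_1 + 1/n_2})$ with $d_0 + d$ degrees
of freedom, capped at 1e6 rather than switching to a normal reference.
DMCs are probes with BH-FDR < 0.05 (configurable). The scheme is
implemented here rather than wrapped; the limma implementation of the same
published method serves as an independent cross-check in the test suite
(agreement to 1e-8 on simulated data), and the $d_0 \to 0$ limit
reproduces the ordinary pooled-variance t exactly. Probes with missing
values use complete-case group means with per-probe df adjustment — the
simplest defensible policy, reported per probe. Covariate adjustment
(age, sex) is deliberately out of scope for the two-group contrast;
the design matrix hook is the natural extension point.

## TF-binding enrichment of DMCs

`tf_enrichment()` tests, per transcription factor, whether DMCs
over-populate the TF's binding-region CpGs: upper-tail
$P(X \ge k)$, $X \sim \mathrm{Hypergeom}(N, K, n)$ over the measured-probe
universe. TFs with fewer than five *universe* CpGs in their regions are
excluded before BH adjustment — the small-$K$ reading of the
"fewer than five overlapping CpGs" guard, chosen because tiny annotation
sets are the standard spurious-enrichment hazard; the small-$k$ reading is
available via `exclude_on = "dmc_overlap"`. Excluded TFs never enter the
BH family, so they cannot perturb other TFs' FDR. The universe is the set
of probes present in the analyzed matrix after QC.

`ea_tf_methylation_correlation()` complements the enrichment with
age-adjusted association: per TF, the partial Pearson correlation between
mean binding-site methylation and EA controlling chronological age, ranked
by |r|. Mean methylation per TF set (not per-CpG aggregation) is the
implemented aggregation.

## PRC2 targets, PRC2m, and LMC stratification

PRC2 binding regions are the base-wise intersection of EZH2 and SUZ12 peak
sets (`build_prc2_regions()`); regions containing at least one TSS within
[start, end) are TSS regions; promoter windows are 3000 bp upstream /
200 bp downstream, strand-aware, clipped at zero. Probes (1-based manifest
positions, treated as [pos-1, pos) intervals) map to every containing
region. PRC2m is the unweighted mean beta over all PRC2-region CpGs per
sample (`region_methylation_score()`), with sample-wise exclusion of
missing values and the used-CpG count recorded.

`lmc_stratification()` reproduces the aging view of PRC2-bound
low-methylated regions (LMCs): regions whose cohort-reference mean beta
(probe-wise cohort median) falls below 0.3 are retained, ranked ascending
by that reference value, and split into equal-count bins; samples are
ranked by the grouping variable and split into seven equal-count groups
(remainder to the oldest groups, deterministically); each cell is the mean
beta over a group x bin block. Three conventions were genuinely open and
are fixed here: the LMC threshold (0.3 on cohort-median methylation,
exposed in the interface), the region ranking key (reference mean
methylation ascending; a peak-score ranking would be a drop-in
alternative), and equal-count rather than equal-width region bins. Seven
equal-count groups honor the "equal sample size" construction; group sizes
differ by at most one.

## Cohort statistics and survival

Group comparisons of EA/EAA use the two-sided Mann-Whitney U test
(distributions are not normal in such cohorts): exact via the null U
distribution when $n_1 + n_2 \le 12$ without ties, otherwise the normal
approximation with midrank-tie and continuity corrections. The mutation
screen tests every mutation flag with at least 3 carriers
("carrier number > 2") and BH-adjusts across the tested genes only.
Association outliers are flagged at |residual| > 2 SD from a simple least
squares fit (numerically perfect fits flag nothing). Median stratification
sends values above the median to High, ties at the median deterministically
to Low. One-way ANOVA is the classical F.

Kaplan-Meier estimation and the two-group log-rank test are implemented
from the product-limit and hypergeometric-table definitions, with
`survival`'s implementations as independent cross-checks in the tests.
Early-window survival contrasts (e.g. the first 18 months of treatment)
are implemented as administrative censoring at the horizon before the
log-rank test.

## The synthetic cohort generator

`generate_cohort()` emits beta matrices, clinical tables, probe manifests,
TF peak sets, TSS lists and truth with the full planted structure:

* **Ages** are stratified-uniform over the configured range (one sample per
  1/n quantile stratum, random order): the marginal distribution is
  uniform, but coverage of the range is balanced, emulating a cohort
  recruited across an age span. Latent biological age adds Normal(0, 5 y)
  jitter by default; setting `bioage_jitter_sd = 0` (with `noise_sd = 0`)
  gives a fully deterministic cohort in which every planted difference is
  exact.
* **Age CpGs** drift with biological age at 0.002 beta units/year —
  a typical strongly age-associated 450K CpG slope. **Adaptive CpGs**
  drift with the planted *adaptive score*: biological age plus the
  mutation-group PRC2 shift expressed in bioage-equivalent years
  (shift / gain). They are deliberately disjoint from the PRC2 regions,
  matching the empirical observation that causality-enriched clock CpGs
  barely overlap PRC2 targets; the truth clocks built from them
  (`truth_clock()`) recover the planted drivers with r > 0.99 at the
  default noise.
* **PRC2 regions** (default 200 regions x 5 probes) start near beta 0.12
  (plus a per-region spread up to 0.10, so the LMC ranking is non-trivial),
  gain 0.002 beta units per year of biological age, and are shifted by
  -0.05 (DNMT3A-like) / +0.05 (IDH2-like) in carriers. The shifts are free
  parameters: the source analyses report significance, not effect sizes,
  so these are chosen as clearly detectable at n about 200 without being
  caricatures. Carrier counts default to 47/194 and 18/194.
* **Background probes** have bimodal baselines (two-component beta
  mixture, low/high modes) so BMIQ and M-value stages see realistic
  marginals. Gaussian noise (default sd 0.02) is added everywhere and
  betas are clipped to [0, 1].
* **Outliers**: a configurable number of samples receive a +0.15 global
  mean shift.
* **Survival**: exponential event times with the Low planted-adaptive
  group at median 12 months and the High group at 1/2.5 of that hazard,
  plus independent exponential censoring tuned to about 30% censoring —
  the simplest mechanism preserving the KM assumptions.
* **Decoys**: 10 decoy TF peak sets over background probes and 6 decoy
  mutation flags (12% carriers, independent of everything) give the
  enrichment and screen stages something to rank against.

The genomic layout is one synthetic chromosome with probes every 1000 bp;
EZH2-like and SUZ12-like peaks each extend a PRC2 region on one flank
only, so their intersection recovers exactly the planted regions.

What the generator does **not** emulate: Infinium type I/II probe
chemistry, SNP-affected probes, cell-composition effects, batch structure,
and the genome-scale probe count (the default 12,000 probes are a
down-sampled 450K layout). Tests that pass on these cohorts therefore
certify the statistical machinery — planted-effect recovery, calibration,
determinism — not robustness to array artifacts.

## Problem sizes and numerical choices

The test suite and the acceptance script run the generator at 2,500-12,000
probes and 60-300 samples, the DMC calibration study at 5,000 probes with
20 samples per group, the outlier study across 20 seeds, and the log-rank
power study across 200 replicates at 150 per arm — sizes chosen so every
study completes in seconds to a couple of minutes on one core while
keeping Monte-Carlo error well below the decision margins.

Numerical conventions, in one place: beta clipping at 1e-6 for the mixture
EM and 0.001 for M-values; mixture-CDF inversion by bisection to 1e-12;
EM convergence at 1e-4 relative log-likelihood; trigamma inversion by
Newton to 1e-10 relative steps; moderated-t df capped at 1e6; PC1 via the
samples x samples cross-product eigendecomposition; median-tie samples to
Low; LMC remainder samples to the oldest groups; BED coordinates 0-based
half-open, manifest positions 1-based, strand ignored throughout (CpG
methylation is strand-symmetric).

## Limitations

Coefficients of real published clocks are third-party data and are not
shipped; the package reads them from CSV and ships synthetic stand-ins
only. The DMC model is a two-group contrast without covariates. Enrichment
is probe-level; no region-level (DMR) calling. Survival analysis is
nonparametric (KM/log-rank); no proportional-hazards modeling. The
BMIQ-style normalization operates per sample against a cohort-internal
reference and does not model type I/II probe design.
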