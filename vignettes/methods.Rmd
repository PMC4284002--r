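---
title: "Models and methods behind grasspred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind grasspred}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`grasspred` implements the statistical workflow used to analyse outbred,
clonally replicated grass diversity panels genotyped by
reduced-representation sequencing: SNV quality control, population
structure, trait repeatability, mixed-model association, perturbation-based
power assessment, and ridge-regression genome-wide prediction. This
vignette records the models, the defaults and why they were chosen, the
numerical decisions, and what the synthetic-data tests do and do not
establish.

## The SNV filters

RAD-Seq-style genotype calls in heterozygous species fail in characteristic
ways: undercovered calls (heterozygotes read as homozygotes), collapsed
paralogs (excess heterozygosity), and restriction-site dropout
(missingness). The filter engine therefore works in two passes. Per-call
criteria run first — calls below `min_depth` reads, and heterozygous calls
whose minor-read fraction falls below `min_het_read_fraction`, are set
missing. Per-locus statistics (missingness, allele frequencies, observed
and expected heterozygosity) are then recomputed before the locus-level
thresholds apply. Recomputing after masking is a deliberate ordering
choice: a locus whose heterozygotes were mostly unreliable should be
judged — and possibly removed — on its post-masking missingness.

The Hardy–Weinberg departure statistic is `F_IS = 1 − H_o/H_e` with
`H_e = 2p(1−p)` uncorrected for sample size; `F_IS = 1` flags loci that
never show heterozygotes despite intermediate allele frequency (collapsed
repeats, null alleles), `F_IS` near −1 flags universal heterozygosity
(paralog collapse). The two built-in profiles mirror common practice:
`"stringent"` (site quality ≥ 15, call depth ≥ 14, missingness ≤ 10%,
|F_IS| ≤ 0.25, het minor-read fraction ≥ 0.05, strictly biallelic; no MAF
restriction, so rare variants survive for structure analysis) and
`"liberal"` (call depth ≥ 3, mean depth ≥ 6, missingness ≤ 20%, ≥ 3 copies
of the minor allele, strictly biallelic), which trades call stringency for
marker count in association and prediction. The MAF criterion is a
*copy count*, not a frequency — at n in the low hundreds, "at least 3
copies" is the natural unit. The heterozygote read-balance rule is applied
per call (mask) by default because that is what the statistic measures;
`het_read_action = "drop_locus"` is available for users who prefer
locus-level removal.

LD is measured as the squared Pearson correlation of dosage vectors
(genotypic `r²`), the only definition available without phase. Pruning is
greedy within sliding windows (defaults 50 loci, step 5, threshold 0.2):
while any retained pair in the window exceeds the threshold, the member of
the worst pair with lower MAF is dropped (ties: the later locus). The drop
rule is a documented convention — external tools do not specify theirs —
and the tested guarantee is the constraint itself: no retained pair within
any window exceeds the threshold.

## Kinship, PCA and Tracy–Widom significance

Two relatedness summaries are provided. The identity-by-state matrix
`K_ij = mean((2 − |g_i − g_j|)/2)` over jointly observed loci is bounded in
[0, 1] with unit diagonal and feeds the mixed model. The VanRaden genomic
relationship matrix `ZZ'/(2Σp(1−p))` (dosages centered at `2p`) estimates
relatedness on the pedigree scale and averages ~1 on its diagonal under
Hardy–Weinberg; both orderings agree closely (tested: Spearman > 0.9), so
the choice mostly affects scale, not inference.

PCA uses the binomial normalization: mean-imputed dosages centered at `2p`
and scaled by `sqrt(p(1−p))`, eigendecomposition of the individual
covariance `MM'/m`. Under this scaling the null distribution of the
leading eigenvalue follows Tracy–Widom (GOE) theory, with an effective
marker count estimated from the eigenvalue spectrum by moment matching
(this partially absorbs LD between markers); each subsequent axis is
tested on the spectrum that remains after removing the preceding ones.
Because no installed package ships the TW distribution, the package
computes it once per session from the Painlevé II representation: the
Hastings–McLeod solution of `q'' = sq + 2q³` is integrated from `s = 8`
(initialized with the asymptotic Airy expansion) and the GOE CDF assembled
from its integrals. The computed quantiles match published values to ~1e-6
(0.9793 → p 0.0500, 2.0234 → p 0.0100); the test suite asserts this.
Sequential axis testing is conservative beyond the first axis — the null
calibration test therefore pools axes and accepts type-I rates in
[0.02, 0.09] at nominal 0.05.

Outlier removal mirrors the usual smartpca procedure: individuals more
than 6 SDs from the mean along any of the top 10 axes are removed and the
PCA recomputed, up to 5 rounds. Whether the SD rule should consider all
top axes or only Tracy–Widom-significant ones is genuinely ambiguous in
the field's practice; both are supported (`axes_rule = "top_n"` default,
`"significant"` optional). Subpopulation assignment clusters the
significant-axis scores by Ward hierarchical clustering rather than
k-means: determinism and permutation equivariance matter more here than
marginal cluster quality, and both are tested.

## Trait BLUPs and heritability

Replicated field observations follow
`y_ij = μ + block_j + g_i + e_ij` with fixed blocks and random genotypes.
The variance ratio `δ = σ²_E/σ²_G` is estimated by restricted maximum
likelihood profiled on the spectral scale: with the fixed effects
projected out via the eigendecomposition of `S(K+I)S` (where `K = ZZ'` is
the genotype incidence cross-product), the restricted likelihood is a
cheap 1-D function of `δ`, optimized by a coarse grid plus golden-section
refinement to 1e-10 on `log δ`. Working with `S(K+I)S` rather than `SKS`
matters: the zero eigenspace of `SKS` mixes the fixed-effect span with
genuine contrasts and cannot be disentangled numerically, while adding
`I` separates them by a unit gap. The implementation agrees with `lme4`
and with a dense-matrix REML oracle to six or more digits (tested).

Broad-sense heritability is reported on the clone-mean basis,
`H² = σ²_G/(σ²_G + σ²_E/ñ)`, with `ñ` the harmonic-mean replicate count —
the repeatability of genotype means, which is the quantity that caps
predictive ability in clonally replicated trials. Genetic correlations
come in the two classical flavours: from genetic covariances (method of
moments on block-adjusted genotype means, for traits measured in the same
trial) and from `r_G = r_p/√(H²_x H²_y)` (for traits from different
trials). Estimates outside [−1, 1] are clipped and flagged, never
silently.

## Mixed-model association

The association model is `y = Xβ + g·b + u + e`, `u ~ N(0, σ²_g K)`. The
EMMAX approximation fits `(σ²_g, σ²_e)` once under the null (`b = 0`) and
retests every marker by generalized least squares with the covariance held
fixed — the whitening transform is cached from one eigendecomposition of
`K`, so a scan is a single matrix multiplication plus vectorized
regressions. Significance uses an F-test on `n − q − 1` residual degrees
of freedom by default: at `n = 138` the χ² Wald test is visibly
anti-conservative in the tail, and the F-test is the defensible default
(χ² remains available via `test = "chisq"`). The scan-level genomic
inflation factor `λ_GC = median(χ²)/0.455` is always reported; the package
reproduces the classic confounding contrast on synthetic structured data —
naive OLS scans of a PC-correlated trait inflate (`λ_GC > 1.3`) while the
mixed model with kinship and two PCs stays calibrated (tested).

Exactness is tested, not assumed: scan p-values match a dense per-marker
GLS oracle (full `n × n` solve) to |Δlog₁₀p| < 1e-6, and the REML optimum
matches a 1e-3 grid search.

Multi-locus selection (MLMM) alternates forward steps — add the most
significant marker as a fixed cofactor, refit variance components —
with backward elimination of the least significant cofactor, up to nine
steps. The reported model is the largest on the path whose cofactors all
pass the genome-wide Bonferroni threshold (the multiple-Bonferroni
criterion). Markers in complete LD cannot both enter: once one is a
cofactor the other has no residual variance and is flagged untestable
(tested).

Missing dosages are mean-imputed for testing; with per-locus missingness
capped by the filters this attenuates, never inflates, single-marker
signals.

## Perturbation-based power

Rather than simulating phenotypes from scratch, the power module perturbs
the real (or synthetic) trait BLUPs: a random SNV with MAF ≥ 0.05 receives
constant additive effects `(−a, 0, a)` by genotype class, where
`a = k·SD(BLUPs)` and `k` solves the expected proportion of variance
explained `PVE(p, k) = v/(1+v)`, `v = 2p(1−p)k²` — the Hardy–Weinberg
additive variance of the injected effect over the total variance after
injection. The SD is that of the unperturbed BLUPs, computed once.
Missing calls at the chosen SNV receive no effect (the observed genotype
classes define the perturbation). Each replicate refits the variance
components (cheap: the projected spectrum is cached) and tests the
perturbed SNV exactly as the real scan would; power is the fraction
reaching `α = 1e-5`, and for those hits the naive PVE is the `R²` of the
simple regression of perturbed BLUPs on dosage. Because only significant
hits contribute, the conditional naive PVE exhibits the winner's curse: at
low power only upward noise excursions cross the threshold, so naive
estimates exceed the true PVE severalfold (tested: ≥ 2× at expected PVE
0.02 with 1000 replicates on a 138-individual panel, where empirical
power is a fraction of a percent).

## Genome-wide prediction

Ridge-regression BLUP treats all markers as random effects with a common
variance: `y = μ + Zα + e`, `α ~ N(0, σ²_m I)`. The shrinkage
`λ = σ²_e/σ²_m` is REML-estimated through the equivalent individual-level
model with covariance `ZZ'`, and effects solve
`α = Z'(ZZ' + λI)⁻¹(y − μ)`. Cross-validation predicts through the GBLUP
identity with the marker cross-product precomputed once, which is
algebraically the same model (the duality is asserted to 1e-8 in the
tests).

Design decisions that guard against leakage: `λ` is re-estimated inside
every training fold; markers are centered by training-fold means, and test
genotypes are centered (and their missing calls imputed) with those same
training means; informed marker selection — lowest mixed-model GWAS
p-values or largest |ridge effect| — is likewise computed within the
training fold only. Random fold assignment is stratified by subpopulation
when labels exist (toggleable), so a "random" CV does not accidentally
become a structure split.

Per repeat, held-out predictions are pooled across folds and summarized
as predictive ability `r`, accuracy `Accu = r/√H²`, and the calibration
intercept/slope of observed-on-predicted. One numerical subtlety: because
`λ` is refit per fold, fold-level prediction intercepts jitter, and for
heavily shrunken (highly polygenic) traits that jitter is comparable to
the within-fold prediction spread and can cancel a pooled correlation
entirely. `r` is therefore computed after centering observations and
predictions within fold — it reduces to the plain pooled correlation
whenever folds are homogeneous — while `b0`/`b1` stay on the raw scale,
since they exist precisely to expose such calibration artifacts.

The across-subpopulation design trains on one labelled group and predicts
another, against 100 random partitions of identical sizes; the drop of the
across-group `r` below the random band measures how much apparent
predictive ability rides on structure and relatedness rather than linked
QTL.

## The synthetic-data generator

The generator emulates the statistical regime of a weakly structured
outbred panel: `n = 138` individuals in two subpopulations, subpopulation
allele frequencies drawn from the Balding–Nichols beta distribution
(variance `F_ST·p(1−p)` around ancestral frequencies uniform on
[0.05, 0.5]), genotypes as two independent gametes (hence exact
within-subpopulation Hardy–Weinberg), and positive local LD from a shared
per-gamete block uniform: with `ld_strength = 0.8`, equal-frequency loci
in a 10-locus block correlate at `r² ≈ 0.4`, matching the substantial
fine-scale LD of reduced-representation data. Read support is Poisson
depth (mean 14) with binomial allele sampling (balance 0.5 at
heterozygotes, `error_rate` leakage at homozygotes) and a likelihood-based
Phred-like genotype quality. Phenotypes follow the randomized complete
block design with four blocks; genotypic values (QTL sum plus optional
subpopulation shift) are rescaled so the realized clone-mean heritability
equals the target exactly, which makes parameter-recovery tests sharp.
Demonstration data use the 17 published reference heritabilities
(0.48–0.89) as targets, with every fourth trait confounded with structure.

What the generator does *not* emulate — and what passing tests therefore
do not establish for real data: pedigree/family relatedness within
subpopulations (prediction in the synthetic panel is QTL-tagging- and
structure-driven, with no close relatives to exploit), genotyping error
correlated with genomic features, multi-allelic and indel variation,
spatial field trends, genotype-by-environment interaction, and LD beyond
the block scale. Two downstream consequences are worth noting. First,
absolute predictive abilities on synthetic traits are lower than published
values for comparably heritable real traits, where close relatives and
long-range LD help; the qualitative contrasts (training-size monotonicity,
marker-count plateau, across-subpopulation penalty, informed-selection
advantage) are what the tests assert. Second, the marker-count plateau
only appears once markers tag every independent segment redundantly; the
plateau test therefore uses a strong-LD panel (blocks of 15 at
`ld_strength = 0.95`, ~440 independent loci among 3000) chosen to put the
sweep's upper half past that saturation point, as in the source regime
where tens of thousands of markers cover a similar number of independent
loci.

## Numerical choices and degenerate inputs

- REML: ratio profiled on `log δ ∈ [−10, 10]`, 81-point grid plus local
  refinement (tolerance 1e-10); eigenvalues clamped at zero; a kinship
  proportional to the identity triggers a "ratio not identifiable"
  warning rather than an error, and the GLS limit then reproduces OLS.
- Markers with (near-)zero variance after imputation are flagged
  untestable (`NA` p) rather than dropped silently; `λ_GC` uses tested
  markers only.
- `F_IS` is undefined (`NA`) at monomorphic loci and such loci pass the
  `|F_IS|` filter (they carry no heterozygosity evidence either way).
- LD `r²` returns `NA` (an undefined flag, not an error) when either
  locus is constant over the jointly observed individuals.
- Tracy–Widom p-values are clamped at the table ends (`p = 1` below
  `s = −10`, `~3e-11` above `s = 8`): axis decisions happen many orders
  of magnitude away from the clamp.
- Genetic correlations outside [−1, 1] are clipped with a `clipped`
  attribute; non-positive moment estimates of genetic variance yield `NA`
  with a reason, never a fabricated value.
- Seeds: every stochastic operation takes an explicit seed and restores
  the caller's RNG state afterwards; the pipeline fans a master seed into
  per-stage seeds by a fixed counter scheme, so any stage can be rerun
  alone and full reruns are byte-identical (tested on the manifest
  checksums).

## Problem sizes used by the test suite

Simulated instances are sized to exercise the statistics, not to stress
hardware: panels of 50–300 individuals and 200–20 000 loci, 2–10-fold
cross-validation with 2–50 repeats, 150–1000 perturbation replicates, and
50-replicate null calibrations. Parameter-recovery checks (heritability
within ±0.08, Hudson-estimator F_ST within ±0.015, REML versus grid
search, scan p-values versus dense GLS) all run at these scales with
fixed seeds.

## Known limitations

Single-trait models only (no multi-trait REML or spatial field-trend
correction); genotype dosages are treated as known (no genotype-likelihood
propagation); the EMMAX approximation holds variance components fixed
across markers, which is standard but slightly conservative for the very
largest effects; Bayesian whole-genome regressions are out of scope (the
source regime found them comparable or worse than ridge); and the
Tracy–Widom moment correction absorbs LD only approximately, which is why
axis significance should be read jointly with the scree and the biology.
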