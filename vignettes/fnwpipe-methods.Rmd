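---
title: "Femoral neck width genetics: models and methods"
author: "fnwpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Femoral neck width genetics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific question

Areal femoral neck bone mineral density (FN-BMD, g/cm^2^) from DXA is the
standard basis for hip-fracture risk assessment, but it confounds true
volumetric density with bone depth. Femoral neck width (FNW, mm), measurable
from the same scan, carries the missing size information. `fnwpipe`
implements the full analysis chain for asking whether FNW relates to hip
fracture risk *independently* of FN-BMD by genetic means: width extraction
from landmark annotations, a genome-wide association scan with
conditional/joint signal selection, LD score regression genetic
correlation, two-sample and multivariable Mendelian randomization (MR),
and weighted genetic risk score (GRS) survival models — together with a
synthetic-data module that generates every input with known ground truth.

# Geometry: minimum neck width from 85 landmarks

An annotation is 85 ordered image points; points 6–12 trace the inferior
neck contour and points 32–38 the superior contour. After scaling pixel
coordinates to millimetres (x by the column spacing, y by the row spacing;
the two may differ on DICOM-derived data), `computeFNW()` returns the
minimum distance between the two polylines.

We interpret the "line-segment" minimum as the bidirectional
vertex-to-segment minimum: the smallest distance from any vertex of one
polyline to any segment of the other, in both directions. For non-crossing
contours this equals the true set distance between the polylines — an
interior segment–segment minimum cannot fall below all vertex-to-segment
minima — so no densification is needed and the result is exact. Crossing
contours (invalid anatomy) return 0 with a warning. The operation is
symmetric, invariant under rigid motions with isotropic spacing, and shifts
by exactly *d* when one contour of a parallel fixture is displaced by *d*
along the separation normal.

The synthetic annotation generator places the two neck contours as
circular arcs of radius 16 mm bowing away from each other, seven vertices
at 2 mm arc spacing, with the apex separation equal to the requested
width. The narrowest point is therefore unique and well separated from its
neighbours (+0.25 mm at the first neighbour pair), so at zero jitter the
round trip is exact, and under jitter the recovered minimum is nearly
unbiased rather than being dragged down by a minimum over many equidistant
candidates. Annotation noise is Gaussian per coordinate, truncated at 1.5
standard deviations: landmark placement error from a trained shape model is
bounded in practice, and the truncation guarantees the recovered width can
never exceed the target by more than 3 jitter SDs. The remaining 71 points
are an elliptical outline; only their count matters to the width
computation.

# The synthetic cohort

Genotypes come from latent-Gaussian-threshold haplotypes: within an LD
block the latent normals follow an AR(1) process with correlation
$\rho^{|i-j|}$, and an allele is present when the latent value falls below
$\Phi^{-1}(\mathrm{EAF})$. Dosage is the sum of two independent
haplotypes, so dosage correlation equals haplotype allele correlation.
This gives controllable LD without coalescent machinery — the analyses
only consume LD structure, not ancestry realism. Phasing, imputation,
relatedness and population structure are deliberately not simulated; the
mixed-model machinery those features motivate is replaced by per-variant
least squares (a declared simplification, not an emulation).

The causal architecture mirrors the study's headline numbers: 71 FNW and
49 FN-BMD causal variants by default, sharing a mostly sign-opposed subset
(12 inverse, 1 "LRP5-like" same-sign variant), with effects on the
standardized-genotype scale scaled so the FNW causal set explains 7.6% of
trait variance. Causal variants sit at most one per LD block, so the
theoretical variance explained ($\sum\beta^2$ on the standardized scale,
equivalently $\sum 2pq\beta^2$ on the allelic scale) matches the realized
joint-fit $R^2$.

Standardized FNW is the genetic value plus a body-size factor (loading
0.3, shared with height and weight so size-adjustment analyses have a
qualitative analogue), a small age effect (0.1 SD per SD of age), and
Gaussian noise filling the variance to 1. Sex enters through per-sex
millimetre means and SDs (males 34.6/2.4, females 29.0/2.0), not a
regression coefficient. FN-BMD is analogous with its own causal set
(variance explained 0.10, a desk-scale choice of the same order as its
FNW counterpart).

Fracture times are exponential proportional-hazards draws per site with
log-hazard `log_hr_fnw * FNW_sd + log_hr_bmd * BMD_sd`. Default per-SD
hazard ratios follow the directional pattern of the study: FNW raises
femoral-neck (and hence any-hip) fracture hazard (1.5–1.6) and has no
effect on trochanteric or forearm sites; FN-BMD lowers hazard at every
site. Times are drawn over a window opening 5 years before baseline:
events before baseline are prevalent (used by the binary outcome scans,
excluded from survival fits), events within 15.5 years after baseline are
incident, later ones are administratively censored — there is no competing
mortality. `hip_any` is the union of femoral-neck and trochanteric events,
so the site hierarchy holds by construction; its marginal effect is the
event-weighted blend of the two sub-sites rather than an independent
parameter. Baseline hazards default to roughly UK-cohort incidence (about
2–3% any-hip over the full window).

# Phenotype and association scans

`preparePhenotype()` residualizes FNW (mm) within each sex on age,
genotyping chip and 20 ancestry PCs, standardizes the residuals per sex
and recombines them, so the analysis trait has mean 0 / SD 1 in each sex
and the scan is sex-balanced. `runQuantGwas()` is simple per-variant least
squares with MAF ≥ 1% and INFO > 0.3 filters (INFO is 1.0 for simulated
variants; the filter is exercised with hand-edited fixtures).
`runBinaryGwas()` is per-variant logistic regression of case status
(incident, optionally plus prevalent) on dosage, age and sex; complete
separation is flagged rather than propagated.

# Conditional and joint selection

`cojoSelect()` performs stepwise selection on summary statistics plus a
reference panel. Effects are standardized ($b^* = \hat\beta \cdot
\mathrm{SD(dosage)}$ with a unit-variance phenotype); for a set $S$ the
joint effects are $b_J = R_S^{-1} b^*$ with $\mathrm{Var}(b_J) = \sigma^2
R_S^{-1}/n$ and $\sigma^2 = 1 - b^{*\top} b_J$. Selection starts at the
smallest-p genome-wide significant variant and adds the candidate with the
smallest conditional p (two-sided normal test) while it stays below
5×10^-8^; candidates with $r^2 > 0.9$ to the selected set are ineligible,
ties break by p then position, and the correlation-scale algebra
presupposes a single cohort with homogeneous per-variant sample size
(where it coincides with the allele-count parameterization). Variance
explained is reported as $\sum 2pq\beta^2$; for the printed 71-variant
table this reproduces the published 7.6% within the rounding of
2-decimal betas (whether the original figure came from this formula or a
joint-model $R^2$ is not stated; for unlinked signals the two coincide,
which is how the generator is configured).

# LD score regression

`computeLDScores()` sums bias-adjusted squared correlations
$\tilde r^2 = r^2 - (1-r^2)/(n_\mathrm{ref}-2)$ within a 1000 kb window
(self term included), over variants with MAF > 5% — the usual
regression-SNP restriction standing in for a HapMap3 list. `ldscH2()`
regresses $\chi^2_j$ on $n\,l_j/M$ with weights $1/l_j$, single step: the
full iterative weighting scheme needs genome-scale panels, and the
recovery tests validate calibration at desk scale. The intercept is always
estimated, never constrained, so simulated sample overlap is visible.
Standard errors are leave-one-block-out jackknives over 200 contiguous
blocks (reduced automatically when variants are scarce).
`ldscRg()` regresses $z_1 z_2$ on $\sqrt{n_1 n_2}\,l_j/M$; the intercept
absorbs overlap, $r_g = \mathrm{gencov}/\sqrt{h^2_1 h^2_2}$, and the
jackknife recomputes all three regressions per block. Binary traits are
treated on the observed scale (no liability conversion). A caveat the
tests make explicit: the intercept is only well pinned when LD scores
span a wide range, so test panels mix unlinked variants with strong-LD
blocks, as real genomes do.

# Mendelian randomization

Instruments are genome-wide significant, MAF > 1%, and greedily pruned to
pairwise $r^2 < 0.01$ in p-value order. When two exposures' instrument
lists contain a linked cross-pair, the primary rule keeps the variant more
strongly associated with the second exposure (FN-BMD) and a sensitivity
mode keeps the other. Harmonization aligns outcome (and second-exposure)
rows to the exposure's effect allele, resolving strand complements;
palindromic A/T and C/G variants are aligned by allele frequency when both
MAFs are below 0.42 and removed as non-clear strand otherwise (the
ambiguity threshold is a convention; the study reports only that two such
variants were dropped). Steiger filtering removes instruments whose
outcome variance explained significantly exceeds the exposure's, with
binary-outcome $r^2$ approximated on the observed scale as
$z^2/(z^2+n)$ — liability-scale conversion is a known limitation.
Instrument strength is the mean squared $\gamma/\mathrm{se}$.

Estimators: IVW combines Wald ratios $\Gamma_j/\gamma_j$ with weights
$\gamma_j^2/\mathrm{se}(\Gamma_j)^2$; the Wald-ratio SE uses the
first-order delta method (ignoring $\mathrm{se}(\gamma)$, standard
two-sample practice). Cochran's Q against $\chi^2_{J-1}$ decides the
effects model: at Q p < 0.05 the SE is inflated multiplicatively by
$\sqrt{Q/(J-1)}$, never below the fixed-effects SE. MR-Egger adds an
intercept after orienting $\gamma_j \ge 0$; the intercept tests
directional pleiotropy. The weighted median interpolates the ratio at
cumulative normalized weight 0.5 with a 5000-draw parametric bootstrap SE
(seeded; draw count is a documented choice). MR-LASSO penalizes
per-instrument intercepts (L1, `glmnet`, slope unpenalized) and picks the
largest penalty whose zero-intercept set passes the Q test at p ≥ 0.05 —
the heterogeneity stopping rule; the estimate is IVW on the retained set,
and at the $\lambda\to\infty$ limit it is plain IVW. MVMR is zero-intercept
weighted regression of $\Gamma$ on both exposure effect vectors; an
all-zero column drops out (its estimate is NA) so the other exposure
degrades exactly to univariable IVW.

# Risk scores and survival

`computeGrs()` builds the weighted dosage sum after aligning each variant
to its effect allele and standardizes it to mean 0 / SD 1 over the
analysis sample — the post-exclusion sample, a documented choice where
the source text is silent. `coxFit()` fits Cox partial likelihood with
Efron tie handling (synthetic follow-up times tie heavily at coarse
scales), always excluding prevalent cases and, by default, the discovery
subsample, so score weights and survival data come from disjoint samples.
Interactions are Wald tests on product terms with stratified fits
alongside (age split 71.7 years by default, recomputable from the data).
`binarizeGroups()` cuts the FNW score at the top 50/25/10% and the BMD
score at the bottom 50/25/10%, forming the four no/no … yes/yes groups;
`groupHazardRatios()` contrasts groups 2–4 against the no/no reference
with sex and age as covariates.

# Problem sizes and what the tests show

The package is validated at deliberately modest problem sizes chosen once:
association and cohort recoveries at 8,000–60,000 individuals and tens to
hundreds of variants; LD score regression at M = 5,000 variants and
n = 20,000 GWAS samples (simulated at the summary level from the panel's
block LD, the standard device for validating LDSC-type estimators without
genome-scale genotype matrices); MR coverage at 40 + 40 instruments and
100 replicates; survival recoveries at 50,000 individuals with a few
thousand events. The default end-to-end pipeline (`runPipeline()`) uses a
compressed architecture — 10 FNW / 8 FN-BMD causal variants carrying the
same total variance — so genome-wide significant discovery is possible at
n = 12,000; its per-variant effects are correspondingly larger than the
study's. Passing tests therefore demonstrate correctness of the
estimators and the internal consistency of the chain under the stated
generative model; they do not demonstrate robustness to population
structure, relatedness, imputation error, competing risks, or liability
scale subtleties, none of which are simulated.

# Numerical and degenerate-input choices

Monomorphic variants are excluded from scans rather than erroring; a
singular conditioning matrix in stepwise selection drops the offending
candidate with a warning; selection ties break deterministically (p, then
chromosome and position); nearest-gene ties report the upstream feature;
MAF class boundaries (1%, 5%) carry an epsilon guard so printed two-digit
frequencies classify as intended; zero-variance scores and phenotypes are
errors naming the cause; group-hazard fits refuse empty groups by name.
Summary statistics are written at full precision so write–read round
trips are exact.
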