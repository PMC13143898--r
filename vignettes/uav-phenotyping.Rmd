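---
title: "Digital phenotyping of forage-grass trials from UAV RGB imagery: methods"
author: "uavPheno"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital phenotyping of forage-grass trials from UAV RGB imagery: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uavPheno)
```

# Scope and model of the data

`uavPheno` implements a complete analysis chain for single-plant forage
breeding trials phenotyped from UAV RGB imagery: per-plot plant
segmentation, extraction of 171 digital traits, collinearity reduction,
association with conventionally measured traits, machine-learning
prediction under repeated cross-validation, REML mixed-model genetic
evaluation with heritabilities, and coincidence-index comparison of
genotype selections. Because raw field imagery at trial scale is not
shippable inside a package, the package also contains a first-class
synthetic generator that produces complete experiments — design, trait
tables and rendered plot images — with the statistical structure the
downstream analysis assumes, so every stage is testable end to end.

The experimental unit is one spaced plant (a plot) of a tropical forage
grass such as *Megathyrsus maximus* in an augmented block design: every
block carries the same few replicated check genotypes (typically the two
parents and a commercial cultivar) while each test progeny appears in a
single block; replication of progenies comes from repeated harvests, not
from within-environment replication. `makeDesign()` constructs such
layouts (five blocks of 3 checks + 42 progenies gives the canonical 225
plots and 213 distinct entries).

## Trait model

Conventional traits (canopy height CH in cm; green matter yield GMY in
kg/plant; leaf, stem and dead dry components LDMY, SDMY, DMP in g/plant;
their total TDMY in kg/plant) are modelled per environment as

$$y_{ijkmn} = \mu + C_{n/m} + H_j + CH_{nj} + G_{i/m} + GH_{ij} + B_{jk}
+ \varepsilon_{ijk},$$

with fixed check effects $C$, harvest effects $H$ and their interaction;
random progeny effects $G \sim N(0, \sigma^2_G)$, progeny-by-harvest
$GH \sim N(0, \sigma^2_{GH})$, block-within-harvest
$B \sim N(0, \sigma^2_B)$ and residual
$\varepsilon \sim N(0, \sigma^2_\varepsilon)$. Digital traits replace
the harvest structure by a fixed ground-sampling-distance (GSD) effect
and a plain random block. `simulateTraits()` draws exactly from this
model; `fitLmmReml()` estimates it back.

Two generator choices go beyond the bare model and deserve emphasis:

* **Cross-trait genetic correlation.** Yield traits of a forage grass
  are strongly genetically correlated; selection-coincidence analyses
  between a digital biomass proxy and LDMY only make sense if the
  simulated traits share genetic signal. Genetic effects of all traits
  therefore load on one latent merit score with pairwise correlation
  `geneticCor` (default 0.8, a typical genetic correlation between fresh
  and component dry yields). Set it to 0 to simulate independent traits.
* **Truncation at zero.** Yields are physical quantities; draws below 0
  are truncated. Truncation slightly biases variance-component recovery
  upward-shifted means and is visible only when $\mu$ is within about two
  standard deviations of zero; the defaults keep $\mu$ well away from
  the boundary.

TDMY is stored in kg/plant as (LDMY + SDMY + DMP)/1000, keeping the
component identity exact while preserving the conventional units.

## Image rendering

`renderPlotImage()` maps two latent scores to pixels on a default
256 x 256 canvas at 0.27 cm/pixel (tests and the worked examples use 48
or 64 px to stay fast):

* **Biomass → projected area.** The plant footprint is the top-$n$
  region of a field of six overlapping elliptical "tussock lobes", with
  $n$ proportional to biomass (`areaGain`, canvas fraction per unit
  biomass) up to a 85 % cap. Using a potential field and an exact pixel
  budget makes mask area strictly monotone in biomass, which the tests
  exploit.
* **Biomass → texture.** Canopy texture is a mixture
  $(1-\lambda)\,\mathrm{smooth} + \lambda\,\mathrm{white}$ of a blurred
  and an i.i.d. Gaussian field with
  $\lambda = g b/(1 + g b)$ (`textureGain` $g$, biomass $b$), and an
  amplitude that also rises with $\lambda$. More biomass therefore means
  both higher within-canopy variance and higher spatial frequency — the
  GLCM-entropy signal that real dense canopies show.
* **Vigor → greenness.** The plant base colour has green channel
  $60 + \mathrm{hueGain}\cdot v/(1+v)$, so green chromaticity rises in
  vigor. Texture multiplies all three channels equally and highlight
  clipping rescales channels jointly, so chromaticity carries the vigor
  signal only — vegetation-index means and structural features stay
  separable, as observed in real data where VIs track illumination and
  physiology while pixel count and entropy track structure.
* **Soil.** Brown base colour (120, 90, 70) modulated by a multiplicative
  shading field shared across channels (sd 0.08) plus small additive
  noise (sd 2.5). Shared shading is the realistic choice — surface
  roughness scales all channels — and it keeps soil MExG strictly
  negative, as for real brown soil. With independent per-channel noise
  of realistic size, soil pixels would straddle the vegetation threshold
  and small plants would be unsegmentable by any global threshold.

What the generator does **not** emulate: perspective and mosaicing
artifacts, specular highlights on leaves, shadows cast by neighbours,
senescent or flowering tissue, and between-date phenology. Passing tests
therefore demonstrate the correctness of the analysis chain and its
qualitative behaviour (structure beats colour for yield), not
photogrammetric robustness on real orthomosaics.

# Segmentation

MExG $= 1.262G - 0.884R - 0.311B$ on raw 8-bit values is thresholded by
Otsu's criterion (256-bin histogram). Two practical points:

* Otsu **always** proposes a split, including on a bare plot where it
  only carves soil noise. `binarizeMexg()` accepts the split only when
  the two classes separate by more than `minSeparation` (default 3)
  pooled within-class standard deviations; a unimodal Gaussian scores
  about 2.7. Rejected plots get an empty mask — the correct answer for a
  plot whose yield was zero.
* No morphological cleanup is applied by default; small-object removal
  (4-connected components) is available via `minObjectSize`.

A fixed threshold (`method = "fixed"`) is available for exact
reproducibility across sensors.

# Digital traits

Per plot: 14 vegetation indices x 7 statistics (mean, q25, q50, q75,
population sd, moment skewness, excess kurtosis; quantiles by linear
interpolation), 12 GLCMs (distances 1, 5, 10 px; angles 0, 45, 90,
135 degrees) x 6 Haralick descriptors, and the plant pixel count —
171 features. The VI registry uses the canonical literature forms (see
`viRegistry()`); it is an argument, so alternative formulations can be
swapped in without touching the extraction code. GRVI/NGRDI and
GLI/VDVI are kept as distinct registry entries even though some
formulations make them monotone transforms of each other.

GLCMs are computed on luminance (0.299R + 0.587G + 0.114B) quantized to
32 levels over the plant-pixel range; 32 levels balance histogram
resolution against sparsity at a few hundred plant pixels. Matrices are
symmetric, normalized to sum 1, and pairs involving any background pixel
are excluded. Entropy is reported in bits. Angle 0 is +x (rightward) in
row-major, top-left-origin coordinates.

Collinearity pruning scans each group (the 7 statistics of one VI at
threshold 0.75; the 12 configurations of one descriptor at threshold
0.95) in registry order and drops any later feature whose |r| with a
retained one exceeds the group threshold — earlier feature wins, which
makes the procedure deterministic and idempotent. |r| is used because a
negatively collinear feature is equally redundant.
`presetReduction()` is a data-independent preset of the canonical
reduced configuration (drop q50/q75 everywhere; keep one GLCM
configuration at distance 1, angle 0, without ASM, entropy's
complement), yielding
14 x 5 + 5 + 1 = 76 features regardless of the data.

# Association and prediction

Pearson r with the t test $t = r\sqrt{n-2}/\sqrt{1-r^2}$ (two-sided,
$n-2$ df) is computed per feature x trait pair; "strong" means r > 0.75
strictly, and no multiplicity correction is applied (none is applied in
the analyses this reproduces; the grid reports raw p-values). Flights
within 1 day of a measurement match to it; flights 3-7 days after a
harvest match forward to the next measurement date.

Four regressors run under repeated 4-fold cross-validation (default 100
repetitions = 400 splits): a 100-tree random forest (variance split
criterion, node size 1, unlimited depth, bootstrapping), an RBF-kernel
support-vector regression, a single-hidden-layer 100-unit ReLU
perceptron trained by Adam on standardized data, and AdaBoost.R2 over
depth-3 regression trees with the linear loss and weighted-median
prediction. Hyperparameters are frozen in `predictionConfig()` rather
than inherited from library defaults. Targets are min-max normalized
before CV so the 0.1 RMSE-gap comparison rule is scale-meaningful;
metrics are computed per validation fold and averaged over splits
(pooled out-of-fold metrics are available via `pooled = TRUE`).

Scott-Knott clustering of model means uses the likelihood-ratio
statistic $\lambda = \frac{\pi}{2(\pi-2)} B_0/\hat\sigma_0^2$ against
$\chi^2_{k/(\pi-2)}$ at $\alpha = 0.05$, recursing on accepted splits; a
Tukey-HSD letter grouping is provided as the alternative.
`rfFeatureImportance()` normalizes impurity importances to sum 1 and
selects features above 0.1 — meaningful when the feature set is large
(at 76 features the uniform baseline is 0.013); with a handful of
features every importance exceeds 0.1 trivially.

# Genetic evaluation

`fitLmmReml()` maximizes the restricted log-likelihood directly over
log-variances. Each evaluation uses the mixed-model-equations identity
$\log|V| + \log|X'V^{-1}X| = \log|R| + \log|G| + \log|C|$, so one sparse
Cholesky of the coefficient matrix replaces an $n \times n$
factorization. The optimizer is Nelder-Mead followed by a bounded
quasi-Newton polish — derivative-free first because finite-difference
gradients of sparse determinants are noisy enough to abort line
searches. Components are constrained positive by the log
parameterization; estimates collapsing to the lower bound are reported
as 0 with a boundary flag. Convergence is declared by optimizer
stationarity (relative tolerance 1e-13); balanced-design estimates match
ANOVA closed forms to better than 1e-6.

The check/progeny split of the augmented design is realized literally:
the progeny random term's design matrix has all-zero rows for check
plots (`progenyF` is `NA` there), while checks enter the fixed part.
This is also why the model is fitted by in-package REML — the zero-row
random design cannot be expressed cleanly in the common mixed-model
interfaces, which are used instead as independent oracles in the tests.

BLUEs, BLUPs and the full PEV covariance of the progeny BLUPs come from
the inverse MME coefficient matrix at the estimates. Standard errors of
components are from the central-difference Hessian of the deviance.
Wald F tests are incremental (sequential terms, drop in the generalized
residual quadratic form divided by the term df) with the residual-df
approximation $n - p$ for the denominator — simpler than reference
implementations' adjusted df, exactness is not claimed for unbalanced
designs. Variance-component LRTs use the boundary mixture
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$.

Heritabilities: $H^2 = \sigma^2_G/\sigma^2_P$ with an explicit basis —
default entry-mean basis
$\sigma^2_P = \sigma^2_G + \sigma^2_{GH}/n_h + \sigma^2_\varepsilon/(n_h n_r)$,
plot basis (simple sum) as an option; the basis is attached to the
result because the bare ratio leaves the basis ambiguous. Cullis
heritability is $H^2_C = 1 - \bar v_\Delta / (2\hat\sigma^2_G)$ with
$\bar v_\Delta$ the mean variance of pairwise BLUP differences computed
from the PEV covariance — the "average variance of individual plant
comparisons" reading of the printed formula.

# Selection analysis

Genotypes are ranked by BLUP (descending; ties broken by label), and the
coincidence index between two traits at intensity $\alpha$ is
$100\,|A \cap B|/\lceil \alpha n\rceil$ over the two top sets. Ceiling
is used for the top-set size. On bivariate-normal BVs with correlation
0.8 the expected CI at 50 % intensity is
$2\left(\tfrac14 + \arcsin(0.8)/2\pi\right) \approx 0.795$, which sets
the 60-90 % scale that strongly correlated trait proxies should reach.
The BV
correlation network thresholds |r|, and BV PCA standardizes columns by
default (traits are on different scales) with component signs fixed by
the largest-magnitude loading.

# Problem sizes and numerical choices

The shipped tests and examples use deliberately modest sizes chosen as
representative desk-scale analogues: 48-64 px canvases, 225-plot single
environments, 100-replicate recovery loops, 2-5 CV repetitions in unit
tests. The REML oracle suite covers 50 random balanced designs; GLCM
oracles cover all 12 configurations on random 16 x 16 images at 1e-10.
Degenerate inputs follow explicit rules stated on each function:
zero-spread distributions return skewness/kurtosis 0 with a warning,
constant features normalize to zero with a warning, division by zero in
a VI invalidates the pixel, bare plots yield empty masks, and constant
responses or singular fixed designs are errors that name the offender.

# Known limitations

* The renderer is a statistical stand-in, not a photorealistic or
  radiometrically calibrated simulator; conclusions about real
  orthomosaics require real imagery.
* Wald denominator df are approximate; for strongly unbalanced designs
  prefer the LRT.
* The Cullis estimator assumes $\hat\sigma^2_G > 0$; boundary fits raise
  an error rather than returning a fabricated value.
* No spatial correlation, pedigree or genomic relationship structures;
  single-trait models only.

# A minimal run

```{r, eval = FALSE}
cfg <- pipelineConfig(
  seed = 42,
  design = list(nBlocks = 2L, checks = c("A", "B"),
                progeniesPerBlock = 8L),
  traits = list(nHarvests = 2L, geneticCor = 0.8),
  render = list(canvas = 48L, areaGain = 0.02, textureGain = 0.3,
                imagingHarvest = 1L),
  predict = list(models = "rf", k = 4L, repetitions = 3L,
                 importanceThreshold = 0.1, rmseGap = 0.1))
report <- runPipeline(cfg, outDir = tempfile("uavpheno"))
report$stages$select
```
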