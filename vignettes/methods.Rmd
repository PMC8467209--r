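---
title: "Methods: equal-area auditing of street panoramas and exposure-response modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: equal-area auditing of street panoramas and exposure-response modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panoscape)
```

## The problem

Street-view and panoramic imagery are widely used to audit what people see
in urban environments, and increasingly to relate visual exposures to
physiological and subjective emotional responses. Consumer panoramic
cameras deliver equirectangular images (2:1 aspect, longitude and latitude
linear in pixel coordinates). On that grid a pixel's solid angle shrinks
with the cosine of its latitude, so naive pixel counting over-weights
whatever sits near the zenith and nadir — typically sky and road. Any
"percentage of view" statistic computed on the raw panorama is therefore
biased.

`panoscape` implements an auditing pipeline that removes this bias and then
quantifies the *global visual pattern* of each scene — not just how much of
each element is visible, but how fragmented and how diverse the scene is —
and links those scene-level exposures to per-participant emotion
indicators.

## Equal-area reprojection

The pipeline reprojects panoramas to the Hammer projection, an equal-area
cartographic projection onto a 2:1 ellipse. With $\lambda$ longitude,
$\varphi$ latitude and $D = \sqrt{1 + \cos\varphi\,\cos(\lambda/2)}$:

$$x = \frac{2\sqrt{2}\,\cos\varphi\,\sin(\lambda/2)}{D}, \qquad
  y = \frac{\sqrt{2}\,\sin\varphi}{D}.$$

Equal-area means equal pixel counts correspond to equal solid angles, so
all downstream metrics are simple masked pixel counts. Resampling inverts
each output pixel center back to the sphere (`hammer_inverse()`); the
inverse exists in closed form and round-trips below $10^{-10}$ radians
away from the poles. Numerical choices:

* **Pixel centers.** Column $k$ of width $W$ maps to
  $\lambda = -\pi + (k - 0.5)\,2\pi/W$; row 1 is the sky side. This matches
  consumer panoramic output orientation.
* **Nearest neighbor for labels.** Categorical rasters are resampled
  nearest-neighbor only — interpolation must never invent labels. RGB may
  use bilinear with longitude wrap. Because classification is pixel-wise,
  classifying then reprojecting (nearest) equals reprojecting then
  classifying; the package classifies on the equirectangular raster so
  that no interpolated color is ever classified.
* **Poles.** The inverse clamps $|\varphi|$ to $\pi/2 - 10^{-12}$ to keep
  the longitude determinate; the affected area is a single pixel row at
  most.
* **Output width.** Defaults to the source width (preserving nominal
  resolution); the audit default is 1024, where band-share errors from
  discretization are well under 1%.

Two independent oracles guard the geometry: cosine-weighted counting on
the equirectangular grid (`solid_angle_proportions()`, exact up to
row discretization) and a chi-square test that uniformly drawn sphere
points land uniformly in the ellipse (`ellipse_uniformity_chisq()`).

## Color classification

Pixels are converted to HSV (hexcone: $v = \max/255$,
$s = (\max-\min)/\max$) and assigned one of six classes — red, green,
blue, gray, white, black — by an ordered, first-match list of interval
rules over $(h, s, v)$. The shipped default is:

| rule | condition | class |
|---|---|---|
| 1 | $v < 0.15$ | black |
| 2 | $s < 0.15$ and $v \ge 0.80$ | white |
| 3 | $s < 0.15$ | gray |
| 4 | $h \in [300°, 360°) \cup [0°, 60°)$ | red |
| 5 | $h \in [60°, 180°)$ | green |
| 6 | $h \in [180°, 300°)$ | blue |

The darkness gate comes first (a dark saturated pixel reads as black), the
achromatic gates next, and three 120° hue sectors partition the rest.
Half-open intervals make the partition unambiguous at boundaries, and the
constructor rejects any rule set that leaves part of HSV space unmatched
(probed on a dense grid). These cut points are a reasonable default that
separates sky, roads, buildings and vegetation in practice; they are
deliberately a configuration (`color_rules()`, YAML serializable), and
users with a calibrated threshold table should encode it there.

## Landscape-pattern metrics

Scene structure is measured with three metrics borrowed from landscape
ecology, treating scene elements as patches, element categories as patch
classes, and the scene as the landscape:

* **PLAND** (class level): $100 \sum_j a_{ij} / A$ — percent of the
  masked scene area occupied by category $i$.
* **DIVISION** (landscape level):
  $1 - \sum_i \sum_j (a_{ij}/A)^2$ — the probability that two randomly
  chosen pixels fall in different patches; 0 for a single patch,
  approaching 1 under heavy fragmentation.
* **SHDI** (landscape level): $-\sum_i P_i \ln P_i$ — Shannon diversity
  of category proportions, 0 for one category, at most $\ln m$ for $m$
  categories.

Because the metrics are area *ratios*, physical units cancel: on the
equal-area grid masked pixel counts are valid areas. Patches are maximal
connected same-category pixel sets; connectivity defaults to 8 (queen),
the convention of the common spatial-pattern analysis programs for
categorical maps, with 4 (rook) available — the 2×2 checkerboard example
(DIVISION 0.75 rook vs 0.5 queen) documents the difference. Patch
labeling is a compiled union-find pass cross-checked in the test suite
against a pure-R flood fill. Pixels grouped to an `other` category remain
part of the landscape-level metrics (they occupy visual field) but are
not emitted as model covariates. SHDI uses proportions in $(0,1]$ with
the $p \ln p \to 0$ limit for absent classes, while PLAND reports
percent.

Both layers of each scene are audited: the *constituent elements*
(semantic categories such as plant, sky, road, building — supplied as a
precomputed segmentation raster and grouped by a `class_scheme`) and the
*colors* (the six HSV classes). Street scale (small/medium/large by lane
count) is an input annotation, not computed from imagery.

## Exposure-response models

Let the five visual-pattern covariates of one layer be PLAND of the three
headline categories plus scene-level DIVISION and SHDI. Controls are two
street-scale dummies (medium is the reference, as the most common scale)
and gender (male = 1). The package fits, per layer:

* **Linear models** for the nine continuous physiological indicators
  (six EEG performance metrics, SCR count and summed amplitude, mean
  heart rate). Outcome and continuous covariates are z-scored so slopes
  are standardized betas; dummies enter raw, since a standardized dummy
  has no interpretation. Per-coefficient p-values are two-sided t-tests,
  the model p is the overall F-test. Exact collinearity aborts with the
  offending columns named.
* **Multinomial (baseline-category) logistic models** for the three
  ordinal ratings (interestingness, comfort, vitality; scores 1–3,
  level 1 the reference): $\log(P_n/P_1) = X\beta_n$ for $n = 2, 3$.
  The fit is Newton-Raphson with analytic gradient and Hessian,
  deterministic zero start, step-halving, and convergence when the
  log-likelihood moves by less than $10^{-8}$ (cap 200 iterations).
  Wald per-coefficient p-values; likelihood-ratio model p against the
  intercept-only model (whose MLE is the observed level frequencies).
  Coefficients are reported unstandardized by default — effects per
  percentage point or per index unit — with a `standardize_x` toggle.
  A diverging effect scale ($|\beta_j|\,\mathrm{sd}(x_j) > 15$) raises a
  separation warning.
* **Correlation matrix** across all twelve indicators: Pearson between
  continuous pairs, Spearman whenever an ordinal rating is involved,
  pairwise-complete observations (cells under 3 complete pairs are
  missing), with the three-level star convention (* p < 0.1, ** p < 0.05,
  *** p < 0.01) and no multiplicity correction — the conventional
  reporting style for this design.

Records missing an outcome are dropped per model, not globally, so each
indicator family keeps its own valid N. Repeated measures per participant
are *not* modeled (fits are pooled); this mirrors the common practice in
this literature but understates standard errors when within-person
correlation is material — a known limitation, flagged here deliberately.

## The synthetic study

Because auditing pipelines of this kind are usually validated against
field data that cannot be redistributed, the package ships generators
whose ground truth is known by construction.

**Scenes** (`scene_spec()`, `generate_scene()`). A sky band above
$\varphi_h$, a road band below $\varphi_r$, building facades between,
split into longitude blocks with gray/white/red prototype colors, and
plant disks (spherical caps) painted on top. Band areas have the closed
form $(\sin\varphi_2 - \sin\varphi_1)/2$; with caps painted over, truth
proportions are evaluated by cosine weighting of the label raster — a
code path independent of the Hammer resampling it validates. Prototype
colors classify to the intended class with margin for the ±6 RGB jitter.
`synthetic_scene_specs()` draws study-like conditions: road share
$\mathcal{N}(0.40, 0.036)$, sky $\mathcal{N}(0.1875, 0.0716)$, plant
target $\mathcal{N}(0.1662, 0.1005)$ (clamped to feasible ranges), street
scales in a 17:13:9 small:medium:large ratio. The plant-disk count is set
from the expected union area of independently placed caps,
$k = \log(1-t)/\log(1-a)$, so self-overlap does not bias coverage
downward; realized plant share still runs slightly below target where
the normal draw is clamped.

**Cohorts** (`effect_config()`, `generate_cohort()`). 26 participants ×
12 scenes by default (participants assigned cyclically to four scene
groups drawn from the 39-scene pool), gender Bernoulli(0.5). Covariates
are centered at their scene means before the linear predictor is formed,
so intercepts set marginal levels and slopes are unchanged. Generative
laws are declared conventions chosen to respect each indicator's range,
not inferences about any real data-generating process:

* EEG metrics: logistic squashing of a Gaussian linear predictor —
  strictly inside $(0,1)$ and smooth, unlike truncation;
* SCR.n: Poisson, log link, null mean 8.12; SCR.Amp: gamma sum of SCR.n
  exponential amplitudes (mean 0.23 each, so ~1.87 total);
* HR.Avg: Gaussian, identity link, null mean 76.58, SD 10.88;
* ratings: multinomial with baseline-category logits.

Block missingness emulates device dropout (EEG 1/3, SCR 0.32, HR and
ratings 0.006), reproducing the familiar pattern where each outcome
family has its own valid N (about 208/213/310 out of 312).

Passing tests on these cohorts show that the pipeline recovers what it
planted under its own generative laws; they do not show that real EEG or
electrodermal indicators follow those laws. In particular the linear
model is the *correct* model only for the identity-link indicator — for
squashed or count indicators it is the same approximation it is in
practice — so parameter-recovery checks use HR and the ratings, where
fit and generator share a law. `null_cohort()` zeroes every effect for
calibration: across replicated null cohorts the overall-F p-value is
uniform and the 5% rejection rate is honored.

## Problem sizes and runtime choices

Unit tests audit at widths 128–512 and validate the generator/auditor
closure at width 512 source / 1024 audit, where half-pixel band
discretization keeps PLAND within 1% of truth; the projection uniformity
test uses 20k points (100k in the acceptance script). Calibration uses
1000 null cohorts of 312 records (KS on the first 500); recovery uses
one cohort of ~2000 records (167 participants), where every fitted
coefficient of the HR and comfort models must land within 3 estimated
standard errors of its planted value. The acceptance script re-runs the
full study footprint — 39 scenes at width 1024, 26 participants — from
scratch.

## Known limitations

* Color thresholds are a default partition, not a calibrated instrument;
  results on real imagery depend on encoding the user's own cut points.
* The grouping of fine-grained segmentation ids into scene categories is
  an editable configuration; no canonical 150-class mapping is imposed.
* Metrics are computed over the full spherical field of view; studies
  cropping to a display field of view should mask accordingly.
* Pooled fits ignore participant clustering (see above).
* The synthetic scenes are geometric stand-ins: they share the band/block
  composition statistics of urban streets but none of the texture,
  lighting or occlusion structure of photographs.
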