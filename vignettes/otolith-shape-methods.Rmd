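---
title: "Otolith shape analysis with wavelet descriptors: models and methods"
author: "otoshape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Otolith shape analysis with wavelet descriptors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otoshape)
```

## The problem

Fish stocks that mix at sea but reproduce separately need markers that
identify where an individual grew up. The sagittal otolith — the largest of
the calcium-carbonate ear stones — accretes material throughout life, and
its final outline integrates the environment and growth history of the
fish. Populations of herring occupying different fjords, lakes and oceanic
habitats develop recognizably different otolith outlines, so outline shape
can serve as a population tag where genetic differentiation is weak.

`otoshape` implements the full chain from a grayscale otolith image to
population-level inference:

1. **Outline extraction** — threshold, keep the largest connected
   component, fill holes, trace the boundary.
2. **Radial profile** — sample the distance from the outline's area
   centroid to the boundary at `n_angles` equally spaced angles.
3. **Wavelet descriptors** — an orthonormal periodized discrete wavelet
   transform (DWT) of the radial profile; the coefficients are the shape
   variables.
4. **Variance partition** — an intraclass-correlation (ICC) profile along
   the outline showing *where* populations differ.
5. **Statistics** — ANCOVA screening of allometric coefficients,
   canonical analysis of principal coordinates (CAP) with age as a
   covariate, ANOVA-like permutation tests, within-population variance by
   age group, and a dispersion-on-age regression.
6. **Geography** — along-coast distances, Mantel tests of isolation by
   distance, and an outlier report for population pairs off the trend.

A synthetic generator produces datasets with known structure so that each
stage, and the pipeline end to end, is testable.

## The radial representation

An outline is reduced to the single-valued function \(r(\theta)\): the
distance from the area centroid to the boundary at angle \(\theta\),
sampled on a grid of \(2^J\) angles (default \(2^9 = 512\)). Where the
outline is locally non-convex (the excisura notches), the *farthest*
ray–boundary intersection is taken, so a notch appears as a local minimum
of \(r\) rather than an undefined value. The area centroid (polygon first
moments), not the vertex mean, anchors the polar frame: boundary tracing
returns unevenly spaced vertices, and the vertex mean would drift with
vertex density.

Two practical choices surface as options rather than fixed behavior,
because they are lab protocol rather than mathematics: whether one otolith
side is mirrored into a common orientation (`mirror` in `runConfig()`),
and outline smoothing (off by default — the wavelet transform itself
separates fine detail into its own bands, so pre-smoothing mostly
discards information).

## The wavelet descriptors

The radius function is periodic, so the DWT uses circular convolution.
The analysis operator at each level is the matrix of even circular shifts
of a quadrature-mirror filter pair; it is exactly orthogonal, so the sum
of squared coefficients equals the sum of squared radii and the inverse
transform is the transpose. Decomposition stops before a level's signal
becomes shorter than the filter, keeping every level exactly orthogonal:
with the default 20-tap filter and 512 radii this gives 5 levels (16
scaling coefficients + 496 detail coefficients = 512, a complete
transform before any filtering).

The default filter is the Daubechies least-asymmetric wavelet with 10
vanishing moments (`sym10`); `db4` and `haar` are also built in, and the
family is configurable because nothing in the method depends on a
particular filter beyond orthonormality and reasonable localization.

**Coefficient-to-angle mapping.** Plotting per-coefficient statistics
against outline position requires assigning each coefficient a centre
angle. Within a band of \(m\) coefficients, successive positions step
\(360/m\) degrees; the band's *offset* is computed as the circular energy
centroid of its position-0 basis function (the inverse transform of a
unit coefficient). The naive alternative — the support midpoint
\(360(k+0.5)/m\) — ignores the filter's phase delay, which for a 20-tap
asymmetric filter at coarse levels mislocates coefficients by up to half
the circle; the energy-centroid mapping keeps a localized deformation's
coefficients attributed to the correct angular region at every level. The
naive mapping remains available via `coefMap(n, levels, family = NULL)`.

## Variance partition along the outline

For each coefficient, a one-way random-effects ANOVA partitions variance
between and within populations. With mean squares MSB and MSW and the
unbalanced-design coefficient \(n_0 = (N - \sum_i n_i^2/N)/(k-1)\),

\[\hat\sigma^2_b = \frac{\mathrm{MSB} - \mathrm{MSW}}{n_0},\qquad
\mathrm{ICC} = \frac{\hat\sigma^2_b}{\hat\sigma^2_b + \mathrm{MSW}},\]

with a negative \(\hat\sigma^2_b\) truncated to zero so the reported ICC
lies in \([0,1]\). "Proportion of variation among groups" names exactly
this estimator; the profile of ICC against coefficient centre angle shows
which outline regions are population-informative.

## Allometry screen and ordination

**ANCOVA filter.** Otolith size tracks fish length. For each coefficient
the model `coefficient ~ length * population` is compared against
`coefficient ~ length + population` with the nested-model F-test; a
significant interaction (default \(\alpha = 0.05\)) means the
length–shape relationship differs among populations, so that coefficient
confounds shape with growth and is excluded. P-values are deliberately
uncorrected across coefficients — the screen is meant to be conservative
about what enters the ordination, and under a global null it removes
about \(\alpha\) of the coefficients by chance.

**CAP.** The among-specimen Euclidean distance matrix on the retained
coefficients is decomposed into principal coordinates (every axis with
eigenvalue above \(10^{-10}\) of the largest is kept — no discriminant
axis selection). If age is supplied as a covariate, the coordinate scores
are residualized on it and the covariate's share of the inertia is
reported as *conditional*. The residualized coordinates are then
constrained on population indicators (redundancy analysis), giving the
canonical axes CAP1, CAP2, … Because the distances are Euclidean on
orthonormal-transform coefficients, this CAP is algebraically a (partial)
redundancy analysis of the coefficients themselves; the test suite
verifies the pseudo-F and eigenvalue spectrum against an independent RDA
implementation.

**Permutation test.** Significance of the constraints uses
\[F = \frac{\mathrm{inertia_{constrained}}/\mathrm{df}_1}
          {\mathrm{inertia_{residual}}/\mathrm{df}_2}\]
against row permutations of the (residualized) coordinates —
reduced-model permutation when a covariate is present. The sampled
p-value uses the add-one convention \(p = (1+b)/(1+m)\), never exactly
zero, and ties count as extreme. When enumerating all \(n!\) row orders
costs no more than the requested number of permutations, the test
switches to exact exhaustive mode (p = fraction of all orderings,
identity included, with \(F \ge F_{obs}\)). A-priori contrasts (e.g. one
population against several pooled ones) are expressed as named pools of
population ids; unlisted populations drop out of that test.

**Dispersion.** Within each population × age-group cell, dispersion is
\(\sum_{i<j} d_{ij}^2 / (n(n-1))\) over pairwise Euclidean distances,
which equals the trace of the within-cell covariance. The
dispersion-on-age regression fits cell variance (default) or per-specimen
distance-to-centroid against age by OLS with the usual t-test; both modes
exist because "variation decreasing with age" can be summarised at either
granularity, and the cell mode is the default since cell variances are
the quantity tabulated per age group.

## Isolation by distance

Population-level shape distances are Euclidean distances between
population centroids on (CAP1, CAP2) only — the two leading canonical
axes, matching how population orderings are read off an ordination plot.
Geographic distances run *along the coast*: an ordered waypoint path is
supplied by the user, each population anchors to its nearest waypoint,
and distance is the difference of cumulative great-circle arc lengths
(haversine, mean Earth radius 6371.0 km; an ellipsoidal model would move
hand-traced coastal distances by far less than the tracing error). The
Mantel statistic is the Pearson correlation over upper-triangle pairs,
tested one-sided against positive association by simultaneous row/column
permutation — one-sided because isolation by distance predicts a positive
sign; a two-sided option exists. The pair report regresses shape distance
on coast distance and flags pairs with \(|residual| > 2\,\mathrm{SD}\);
an exactly linear configuration flags nothing (the 2-SD screen is
suppressed when residual scatter is at rounding-noise level).

## The synthetic generator

`generateDataset()` draws specimens with radius functions

\[r(\theta) = r_0\Big[1 + \sum_s a_{p,s}\,
   e^{-(\theta - c_s)^2/2w_s^2} + \epsilon(\theta)\Big],\qquad
  a_{p,s} = \mathrm{slope} \times \mathrm{coast\ km}_p/1000 \times
  \mathrm{sign}_s,\]

i.e. localized Gaussian deformations whose amplitude grows linearly with
along-coast position, plus smooth circular noise (a mixture of the first
8 Fourier harmonics — smooth so outlines stay simple polygons) whose SD
shrinks linearly with age, floored at 20% of its base value. Ages are
uniform on 3–12, lengths follow a linear length–age model, and
populations sit on a synthetic meridional coastline so the geographic
stage runs end to end.

Default calibration (chosen once, as a realistic desk-scale analogue of a
coastal herring survey):

| parameter | default | why |
|---|---|---|
| populations × specimens | 12 × 30 | a dozen sampling areas at realistic per-area sample size |
| coast span | 2200 km | southern-fjord-to-northern-fjord scale |
| deformation sites | notch at 10° (−), bump at 175° (+) | the excisura-major and rostrum/excisura-minor regions where between-population variation concentrates |
| `gradient_slope` | 0.025 / 1000 km | max ~5.5% radial deformation — visible but far from caricature |
| `noise_sd` | 0.02 | individual variation comparable to the between-population range, so discrimination is detectable, not trivial |
| `age_variance_slope` | −0.08 / yr | older fish converge on the population norm |
| length model | 24 + 0.9·age ± 1.5 cm | herring-like lengths, 26–35 cm over ages 3–12 |

What the generator deliberately does *not* emulate: otolith size scaling
with fish length (the radius formula keeps \(r_0\) fixed, so length
enters only through its correlation with age), non-Gaussian individual
variation, measurement artefacts of real imaging (glare, debris,
broken rostra), and any mechanistic accretion biology. Passing the
end-to-end tests therefore shows the *machinery* recovers structure of
this kind at these magnitudes — it does not validate the biological
interpretation of any real dataset.

`rasterizeOutline()` renders outlines as white-on-black images with a
soft one-pixel edge using a radial fill, which is exact for outlines
star-shaped about their centroid (all generated outlines are, since
radii are positive by construction); it is not a general polygon
rasterizer.

## Numerical choices and degenerate inputs

- All randomness in a pipeline run flows from one seed (`rng_seed`); the
  generator and the permutation tests restore the caller's RNG state.
- Permutation p-values: add-one in sampled mode, plain fraction in
  exhaustive mode; tie comparisons use a relative tolerance of
  \(10^{-8}\) so floating-point jitter cannot flip a tie.
- PCoA axis retention: eigenvalues \(> 10^{-10} \times\) the largest.
- ICC with zero total variance reports 0; negative between-group
  components truncate to 0.
- Blank or constant images, empty masks, zero-area polygons, centroids
  outside very concave outlines, single-specimen populations,
  single-population tests and constant-age regressions all fail fast
  with messages naming the problem; a component touching the image
  border or an outline under 64 points warns rather than errors.
- Coefficient tables are written with 17 significant digits so the CSV
  round trip is exact at double precision.

## Problem sizes in the test suite

The checks run at desk scale: 100 random vectors for transform
round-trips, 1000 small datasets for the ICC oracle and the permutation
type-I study (199 permutations each), exhaustive enumeration at \(n = 6\)
specimens and 5 populations, 50 outlines at 1024² pixels for the image
round trip, and one full 12 × 30 pipeline with 2000/10000 permutations.
These sizes make the whole suite complete in a couple of minutes while
leaving each check statistically meaningful.

## Known limitations

- The radial representation needs the centroid inside the outline and
  loses information for strongly non-star-shaped outlines (the farthest
  intersection rule keeps it single-valued but merges deep overhangs).
- The ANCOVA screen tests only a linear length interaction.
- No leave-one-out allocation variant of CAP, no partial Mantel tests,
  no mixed-effects alternatives — outside the package's scope.
- The bundled coastline in the generator is a straight meridian;
  real analyses should supply a traced coastal path.
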