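---
title: "Geometric morphometrics of ceratomyxid myxospores: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric morphometrics of ceratomyxid myxospores: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceratomorph)
```

## The problem

Myxospores of *Ceratomyxa* (Cnidaria: Myxozoa) are crescent-shaped spores
whose size and shape are primary taxonomic characters. Seen in sutural view,
a spore consists of two shell valves joined along a straight suture line:
the suture is the axis of bilateral (object) symmetry, and the two valves
are connected mirror images. Classical descriptions summarize such a spore
by three measurements - length (the axial diameter), thickness (the
tip-to-tip distance), and the posterior angle between the two valves - but
these discard most of the outline geometry. Landmark-based geometric
morphometrics replaces them with a configuration of eight 2-D landmarks
that covers the outline, analysed with the standard Procrustes toolkit.

`ceratomorph` implements that entire workflow: the eight-landmark
construction, generalized Procrustes analysis (GPA), the object-symmetry
decomposition, digitization quality control, morphospace PCA with
thin-plate-spline deformation grids, and Procrustes ANOVA/ANCOVA with
residual-randomization permutation (RRPP) inference. Because the
morphometric raw data of the motivating study were not deposited, the
package also provides a parametric spore simulator whose frozen default
population reproduces that study's printed summary statistics, so every
stage of the pipeline is testable end to end.

## The landmark scheme

For an outline with annotated suture points:

* **L1** - anterior suture point (apex of the convex margin),
* **L5** - posterior suture point (apex of the concave margin),
* **L3, L7** - left and right valve tips, the points of maximal smoothed
  discrete boundary curvature on either side of the suture axis,
* **L2, L8** (anterior) and **L4, L6** (posterior) - constructed landmarks:
  with `M` the midpoint of the chord L1-L5, for each tip `T` a line
  perpendicular to `M-T` at its midpoint is intersected with the outline;
  the convex-side intersection is the outer landmark, the concave-side one
  the inner landmark.

The bilateral pairing is (L2, L8), (L3, L7), (L4, L6), with L1 and L5 on
the midline. Traditional measures follow directly: length `|L1 - L5|`,
thickness `|L3 - L7|`, and the posterior angle at L5 between the rays to
the two tips. Two conventions are deliberate: "the middle of the suture
line" is the chord midpoint (no other definition is computable from the
landmarks alone), and thickness is the straight tip-to-tip chord rather
than the curved extent - consistent with crescent spores whose "thickness"
exceeds their "length". Curvature for tip detection uses the three-point
circumradius estimator smoothed over a seven-vertex window; both are
configurable, and the window is small enough not to displace the tips at
the >= 200-vertex resolutions the package requires.

## Procrustes machinery

Configurations are treated as complex 8-vectors: centering removes the
mean, unit centroid size is unit norm, and the optimal reflection-free
rotation aligning `z` to `c` is multiplication by the phase of
`sum(Conj(z) * c)`. GPA centres and scales every configuration to unit
centroid size and iterates rotation-to-consensus / consensus re-estimation
until the consensus root-mean-square change falls below 1e-10 (at most 100
iterations; non-convergence is flagged, never silent). Reflections are
excluded throughout because left/right valve identity is biologically
meaningful; the symmetry decomposition handles reflection explicitly.
Configurations stay at unit centroid size (full-Procrustes scaling, no
post-hoc rescaling by the cosine of the Procrustes distance), and the
converged consensus is rotated to its principal axes for a deterministic
frame. Tangent-space coordinates are the orthogonal (complex) projection of
the aligned configurations onto the orthogonal complement of the consensus
- this removes both the scale and the in-plane rotation directions.
`tangent_space_check()` quantifies the adequacy of the linearization by
regressing tangent Euclidean distances on Procrustes geodesic distances
over all specimen pairs; on the default cohort the uncentred correlation
exceeds 0.99.

## Object symmetry

The reflect-relabel operation negates x and swaps paired labels; it is an
orthogonal involution `P` of the 16-dimensional coordinate space. The
decomposition runs a joint GPA of the originals and their
reflected-relabelled copies, symmetrizes the consensus, and projects each
specimen's tangent deviation onto the +1 and -1 eigenspaces of `P`. Because
these are orthogonal complements, `SS_symmetric + SS_asymmetric` equals the
total tangent sum of squares to machine precision - an invariant the test
suite asserts. With two digitization replicates, replicates are averaged
per specimen before this partition; the replicate-retaining variant is what
the quality-control module uses for percent measurement error. The package
reports the symmetric percentage (among-spore variation) and the
asymmetric percentage (between-valve variation within spores).

## Quality control

Repeatability and measurement error both superimpose all specimen x
replicate configurations in one joint GPA so replicate placements are
compared in a common frame. Repeatability is the intraclass correlation of
each tangent coordinate from a one-way random-effects ANOVA with specimen
as the grouping factor (`s2_among = (MS_among - MS_within) / r`, truncated
at zero, so an ICC is never negative), averaged over the 16 coordinates.
Percent measurement error pools the sums of squares over coordinates and
reports the within-specimen variance component as a percentage of the
total. For unbalanced replication `r` is the harmonic-mean replicate count.
Outlier screening orders specimens by Procrustes distance from the
consensus; the default rule is the Tukey fence (`d > Q3 + 1.5 IQR`). A
literal "above the upper quartile" rule is kept behind a flag for
comparison, but it tags a quarter of any sample by construction and cannot
be a usable screen, which is why the fence is the default.

## Morphospace

PCA is an eigen-decomposition of the covariance matrix of the
(replicate-averaged) tangent coordinates - not of the symmetric component,
matching a workflow in which the PCA precedes the symmetry extraction; a
caller can pass the symmetric component instead. PC signs follow a fixed
convention (largest-magnitude loading positive). The number of meaningful
PCs uses the eigenvalue-ratio rule: a leading run of PCs each at least 1.32
times its successor. Landmark contributions to a PC are the normalized
squared loadings summed per landmark, with 12.5% (= 100/8) the
more-than-average threshold. Extreme shapes displace the consensus by the
extreme observed scores along a PC; deformation grids use the exact
interpolating thin-plate spline with kernel `U(r) = r^2 log r^2`
(`U(0) = 0`), reporting the bending energy of the non-affine part. Convex
hulls per host visualize morphospace occupancy.

## RRPP inference

Sequential (type I) sums of squares are traces of residual cross-products
in tangent space - sums of squared Procrustes residual distances. For each
term, the SS is the drop in residual SS when the term joins its
predecessors; pseudo-F uses the full-model residual mean square. RRPP
permutes the residuals of the reduced model (the terms preceding the one
under test), adds them back to the reduced-model fitted values, and
recomputes the statistic; the observed arrangement counts as one of the
`n_perm` iterations, so the smallest attainable p is `1/n_perm`. The effect
size is `Z = (log F_obs - mean log F*) / sd log F*`; the log transform
stabilizes the skew of the F distribution (the convention is stated because
published tables rarely define Z). The ANCOVA of interest models the
symmetric shape component on centroid size, host identity and their
interaction, in that order; the covariate is raw centroid size by default
(log size is an option). The companion univariate ANOVA tests centroid size
against host identity with the same machinery. Dispersion homogeneity - the
assumption permutation ANOVA is sensitive to - is checked by a
permutational test on distances to group centroids in tangent space
(`dispersion_test()`, cross-checked in the tests against
`vegan::betadisper`).

## The synthetic population

The simulator's shape family is a circular-arc centerline of radius `R`
spanning `+/- phi` about the suture axis, offset by a half-width profile
`w(s) = W (1 - s^2)^p`. Its three defining numbers map one-to-one onto the
traditional measurements - length `2W`, thickness `2 R sin(phi)`, posterior
angle from `(R, phi, W)` in closed form - so the population mean shape is
solved exactly from the published means (8.6 um, 20.5 um, 104.3 deg; the
default taper `p = 0.75` gives rounded tips whose curvature maximum is
exactly the zero-width endpoint). Two symmetric modes deform it: mode 1
shifts the arc half-angle (the posterior-angle mode, matching the dominant
PC) and mode 2 the log half-width (the length mode, matching PC2).

Population structure, with the five-host 20/16/19/17/35 design:

* a lognormal size factor with host-shifted log-mean; each outline is
  normalized so that its centroid size is exactly the size factor times
  the mean-configuration size, keeping shape and size uncoupled;
* allometry: both mode scores receive a component proportional to centroid
  size, with a common slope across hosts. The mode-1 share is essential:
  the published ANCOVA attributes more shape variance to size than the
  whole PC2 budget contains, so allometry must load on the angle mode.
  Because the slopes are host-invariant and linear in raw centroid size,
  the size:host interaction is genuinely null - without the centroid-size
  normalization above, the shape-to-size coupling would make the apparent
  slope scale like 1/size per host and the interaction test would reject
  far above its nominal rate;
* host shape effects as fixed standardized contrasts on the mode-2 score,
  assigned so host size and host shape effects are nearly uncorrelated;
* bilateral asymmetry as left-valve-only perturbations of the arc angle,
  log half-width and log taper, blended to zero at the suture by a smooth
  ramp (suture points stay on the axis); `asymmetry_sd` is expressed as the
  RMS displacement of the perturbed-valve landmarks in um;
* per-replicate Gaussian digitization noise on the landmark coordinates.

Two deliberate conditioning choices make the frozen calibration meaningful
at the study's n = 107. First, cohorts are conditioned on their sample
moments, in the spirit of `MASS::mvrnorm(empirical = TRUE)`: latent streams
are residualized against the design and against each other and rescaled to
their exact target SDs. Cohort-level statistics are then essentially
seed-invariant, rather than fluctuating with the +/- 10-30% sampling error a
107-specimen cohort would otherwise show. Second, latent scores are
truncated at +/- 2.5 SD: the published trait ranges span about that much,
and more extreme draws would push the nonlinear outline map far enough that
a single specimen distorts the cohort covariance spectrum. Small
`cohort_adjust` offsets (an arc-angle and a log-width shift, plus the
`mean_size` factor) absorb the residual nonlinear-averaging bias so that
cohort means reproduce the printed means while `mean_params` itself remains
the exact closed-form mean shape.

The remaining variance-component constants were obtained by a moment-match
through the full pipeline (see `tools/calibrate.R`): score SDs solve for
the published PC1 (64.1%), PC1+PC2 (82.8%) and asymmetric (21.9%) shares
and the posterior-angle SD (22.8 deg), with an n = 107 bias-correction
pass; size components target the centroid-size CV (15.2%) and the host
share of size variation (25%); digitization noise targets a measurement
error around 0.3% (comfortably below the published < 1% with repeatability
above 0.99).

What the generator does *not* emulate: real micrograph artefacts (focus,
perspective, mounting), pixel quantization, non-Gaussian digitization
blunders such as landmark swaps, polar capsules and other internal
structures (excluded from the landmark scheme on purpose), and
heavy-tailed biological outliers - the published study saw no outliers,
whereas the calibrated generator's right-skewed Procrustes distances let
the Tukey fence tag a few spores in some cohorts. Passing round-trip tests
therefore validates the computational pipeline and the study-level
statistical structure, not the behaviour of the method on arbitrary real
images. One printed value is deliberately not matched: the published
absolute centroid-size range (16.1-32.5) is geometrically incompatible
with the published mean length/thickness/angle under this landmark
construction (which forces a mean centroid size near 26.6 um); the package
reproduces the size CV and the 2x max/min ratio instead and treats the
printed means as primary.

## Numerical choices and degenerate inputs

* GPA convergence 1e-10 (consensus RMS change), 100 iterations maximum;
  far below any measurement noise.
* Tip detection refuses outlines with uniform curvature (circles) and
  outlines that do not straddle the suture axis.
* Landmark construction fails loudly when the perpendicular misses the
  outline or crosses it more than twice on the tip's side.
* Degenerate generator draws (self-overlapping outlines) are redrawn, at
  most 100 times per specimen, with a warning and a count on the result.
* `meaningful_pcs` never counts the final eigenvalue (it has no
  successor); zero successors count as meaningful only if the eigenvalue
  itself is positive.
* Permutation p-values include the observed arrangement; p is never 0.
* ICC variance components are truncated at zero, never negative.
* Problem sizes in the shipped tests: large-cohort means use n = 5992
  (56x the study design), all n = 107 statistics use the study design
  itself, null-calibration suites use 1000 simulated datasets with 999
  permutations, and the recovery suite 100 cohorts with 4999 permutations
  - sizes chosen so the whole suite completes in a few minutes on one
  core.

## Limitations

The package is strictly 2-D and eight-landmark-scheme specific in its
landmark constructor (the Procrustes/RRPP machinery is general in the
landmark count). There are no sliding semilandmarks, no between-group PCA
or CVA, no mixed-effect shape models, and no directional-versus-fluctuating
asymmetry significance testing - the symmetry module reports the variance
split only. The TPS reader supports the tpsDig-style dialect (LM=,
coordinate lines, IMAGE=, ID=, SCALE=) and not CURVES/OUTLINES blocks.
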