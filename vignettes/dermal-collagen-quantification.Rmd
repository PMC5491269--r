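---
title: "Quantifying dermal collagen architecture: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dermal collagen architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dermalign)
```

# The measurement problem

Healthy dermis shows a basket-weave: collagen bundles interleave along two
distinct axes, so the distribution of bundle orientations relative to the
epidermis is bimodal and roughly balanced. Fibrotic dermis loses this
organization — bundles align along one axis and the distribution becomes
skewed or unimodal. `dermalign` turns a stained section into three numbers
per sample:

* **dermis thickness** = dermis area / epidermal contour length (px). For a
  rectangular band this is exactly the band height; for curved sections it is
  the mean depth of dermis below the epidermis.
* **total collagen** = stain-positive fraction of the dermis mask, in [0, 1].
* **alignment score** = fraction of bundles in the greater of the two angular
  peaks, in [0.5, 1].

The package then relates these metrics to transcriptomes (per-metric gene
signatures) and to fibroblast motility (trajectory statistics).

# Angles are axial

A fiber at θ and at θ + 180° is the same physical axis, so all orientations
live on the half-circle [0°, 180°) and are compared with the axial distance
min(|Δ|, 180 − |Δ|). Circular machinery is applied after doubling
(θ → 2θ), the standard device that maps axes onto the full circle.
Epidermis-relative angles are additionally folded to [0°, 90°] where only
the deviation from the epidermis matters; raw orientations stay in
[0°, 180°).

Coordinates are pixel centers with origin at the top-left, x rightward, y
downward; orientations are degrees counterclockwise from +x as displayed.
These conventions are shared by the generator, the segmenter and the
epidermis tangent, and are exercised by the equivariance tests.

# The two-peak mixture and the alignment score

Given a sample of axial angles, the package fits a two-component von Mises
mixture to the doubled angles by expectation–maximization:

* initialization at the two largest modes of a 5°-bin histogram (equal
  weights, moderate concentration), plus seeded random restarts (default 5
  starts total); the best log-likelihood wins. Ties are impossible in
  practice; restarts are ordered by the seed so the procedure is
  reproducible.
* convergence at an absolute log-likelihood change below `tol` (default
  1e-6), at most `max_iter` (500) iterations; non-convergence is returned as
  a flag, never hidden.
* concentrations are estimated by inverting the mean-resultant-length
  equation A(κ) = I₁(κ)/I₀(κ) (piecewise approximation polished by Newton
  steps) and capped at κ = 500 so spike inputs stay finite.

The **alignment score** is the larger component weight. Two degenerate paths
are defined explicitly:

* if the two fitted peak locations are closer than `min_separation` (default
  20° axial), the sample is effectively unimodal: all fibers belong to one
  peak and the score is 1.0. This maps fully aligned dermis to the top of
  the scale, which is the behavior the score needs for skewed or unimodal
  fibrotic distributions.
* inputs with (near-)zero angular spread short-circuit to the same result
  without EM.

On exact two-spike inputs the EM responsibilities are hard 0/1 assignments,
so the weights equal the exact spike proportions — the brute-force counting
oracle in the tests. A nonparametric alternative (`alignment_score_modes()`:
hard assignment of each angle to the nearer of the two KDE modes) is
provided for sensitivity analysis, because mixture responsibilities and hard
nearest-peak assignment can differ slightly and no single assignment rule is
canonical.

# Histology processing

Segmentation thresholds the stain channel (Otsu by default, a fixed
threshold as the alternative), applies a morphological opening (disk radius
1, removing sub-bundle speckle), labels connected components, and drops
components below `min_area` (default 40 px²). Each bundle's orientation is
the principal axis of its second-order central moments — closed-form,
deterministic, and exact for elongated primitives. Already-binary images
skip thresholding.

The epidermis is recovered from the dermis mask as the ordered per-column
boundary polyline on the declared side. The contour length sums chords over
every 4th vertex rather than consecutive pixels: naive pixel-chain length
overestimates smooth digitized curves by ~3% (staircase effect), while chord
summation is exact on straight edges and accurate to a few tenths of a
percent on circular arcs. One pixel of end extent is added so a straight
edge spanning W columns measures exactly W px (and a 200×50 rectangle has
thickness exactly 50). A disconnected dermis mask is an error by default,
with an explicit `largest_component = TRUE` fallback.

Whether bundle angles should be measured against the global mean epidermis
tangent or the local tangent nearest each bundle is genuinely open; both are
implemented (`reference = "global"` is the default — it is stabler on
near-straight epidermis, while the local option matters for strongly curved
sections).

# Gene signatures

The paper-facing content of this stage is the **criteria and the
intersection workflow**, so the differential-expression engine is a
deliberately simple, fully deterministic desk-scale test:

* median-of-ratios normalization (size factor = median over genes of the
  ratio to the per-gene geometric mean, computed on genes positive in every
  sample; an explicit pseudo-reference option exists for sparse matrices).
* per-gene Welch t-test on log2(normalized + 1) per treatment-vs-control
  contrast, BH adjustment across all tested genes. Fold changes use group
  means of normalized counts with a pseudocount of 1 (no division by zero at
  low counts). Zero-variance genes get p = 1 when the group means are equal
  and p = 0 otherwise.
* a gene passes iff mean normalized count strictly exceeds the species
  threshold (mouse 3, human 4), |FC| > 1.5, and adjusted p < 0.05; pooled
  DEGs pass in **any** contrast against control.
* signatures: genes with r² above the metric cutoff (thickness 0.7, collagen
  0.4, alignment 0.4), intersected with the pooled DEGs. Unique sets are the
  genes in exactly one metric's signature (pairwise disjoint by
  construction). Correlation is Pearson on log2(normalized + 1) by default;
  whether the original analysis used Pearson or Spearman, raw or log scale,
  is unstated, so both scales and Spearman are options.
* the "expressed gene" prefilter (mean normalized count above the count
  threshold across all samples) mirrors the count clause of the DEG
  criteria.

The BH step-up adjustment is implemented in the package (it is a stated,
oracle-tested primitive of this workflow) and is cross-checked against
`stats::p.adjust` and a brute-force double-loop in the tests.

# Migration statistics

Per cell: net displacement (start→end distance), accumulated distance (sum
of step lengths) and directionality (their ratio; accumulated ≥ net by the
triangle inequality, asserted on all data). Tracks spanning less than half
the movie are excluded and counted in a QC report — the original tracking
software's filter is unknown, so the cutoff is exposed
(`min_span_frac = 0.5`). Group means are normalized to a control condition
(control ↦ 1 exactly). Condition comparisons default to a Welch t-test on
per-cell net displacement (Mann–Whitney by option); the test behind the
published p-value is unnamed, so the choice is recorded here and both are
available. No drift correction is applied by default.

# What the synthetic generators emulate — and what they do not

**Slides.** Bundles are anti-aliased capsules (length ≫ width) placed
without overlap below a gently curved near-horizontal epidermis; bundle
geometry beyond its orientation is unspecified in real sections, and
elongated primitives give unambiguous principal axes. Orientations are
i.i.d. draws from a two-component axial von Mises mixture whose dominant
weight is the ground-truth alignment score. The axial von Mises form is a
modeling convention — no distributional form for real bundle-angle spread is
established. Not emulated: polarized-light birefringence, stain color
deconvolution, bundle crossings/merging, scanner optics. Segmentation
results on these slides therefore bound the easy case: real sections have
touching bundles that any connected-component method will merge.

**Counts.** Negative binomial with log-normal size-factor variation (so the
normalization stage is actually exercised). Planted genes have log2 expected
counts linear in their metric; `slope_for_target_r2()` converts a target
population r² into a slope, counting both the biological log-noise and an
analytic approximation of the NB sampling noise
(var(log2 X) ≈ (1/μ + φ)/ln(2)², accurate at the default μ = 200, φ = 0.05).
One practical caveat the tests encode: planted co-regulated genes must be a
minority of the matrix, otherwise median-of-ratios normalization absorbs
their shared signal as apparent sequencing depth.

**Trajectories.** Persistent random walk: constant step length (8-minute
frames, 4.5 h movies → 34 positions, `floor(duration/dt) + 1`), headings
updated with von Mises turning noise whose mean resultant length is the
`persistence` parameter. An aligned substrate adds (i) axial attraction of
the heading toward the fiber axis and (ii) contact-guidance damping of the
turning noise while moving along the axis
(`turn × (1 − axis_damp·cos 2(axis − heading))`, default damp 0.5).
Attraction alone proved insufficient: axial flips across the perpendicular
cancel most of the persistence gain, while the damping term produces the
robust increase in displacement and directionality that aligned substrates
show. A knockdown multiplies step length, which scales expected net
displacement by exactly that factor — making the knockdown factor directly
recoverable as the control-normalized mean displacement. Not emulated: cell
division and death, cell–cell collisions, finite-well boundaries, tracking
errors.

Because the generators define the easy regime (clean stain, non-overlapping
bundles, honest tracks), passing tests demonstrate the correctness of the
estimators and the workflow logic, not robustness to real-section artifacts.

# Numerical choices and degenerate inputs

* all randomness flows through required integer seeds; generator calls with
  the same (spec, seed) are bit-identical, and seeding never disturbs the
  caller's RNG stream.
* EM: κ capped at 500; weights floored at 1e-12 to avoid empty components;
  components sorted by weight descending so w₁ is always the score.
* blank images segment to zero bundles (not an error); empty dermis masks,
  constant metrics, contrasts with < 2 samples per group, and p-values
  outside [0, 1] are errors.
* angle histograms use half-open bins [lo, hi) and require the bin width to
  divide 180.

# Study sizes used in the tests

The test and acceptance runs use sizes that keep the full suite in the
single-digit minutes on one CPU while leaving Monte-Carlo noise well inside
the asserted tolerances: 2000 angles per mixture fit, 200-bundle slides on
800×1100 canvases, 1000-gene × 24-sample matrices with 30 planted genes,
500 cells per migration condition, and 1000 null repetitions (40 cells per
group) for the type-I calibration of the displacement test.

# Known limitations

* k = 2 mixtures only; no spatial (position-dependent) orientation fields.
* The Welch-on-log2 DE test is a stand-in interface for count-model engines;
  it is calibrated at the matrix sizes used here but is not a negative
  binomial GLM.
* Segmentation has no bundle-splitting step, so merged bundles in dense real
  sections are undercounted.
* The epidermal polyline is single-valued per column (one boundary pixel per
  x), which assumes a roughly horizontal epidermis; strongly folded sections
  would need a full boundary trace.
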