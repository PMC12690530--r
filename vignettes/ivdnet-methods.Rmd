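---
title: "Models and methods behind ivdnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ivdnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivdnet)
```

`ivdnet` analyzes four data streams from diabetic mouse intervertebral
disc (IVD) studies: multiplex cytokine panels, contrast-enhanced micro-CT
volumes, cyclic-compression traces, and glucose tolerance tests. This
vignette records the models each stage assumes, the tunable parameters and
why their defaults are what they are, the numerical choices that were
genuinely open, and what the synthetic-data validation does and does not
establish about real data.

## The synthetic-data generator

Every downstream stage is validated against generators with planted ground
truth. The generators' defaults are the study conditions the package
targets: four arms (db/+, db/db, Con+Veh, STZ-HFD) with n = 3/3/3/9
animals, a 45-analyte cytokine panel, 10 µm voxels, and a 1 Hz / 20 cycle /
35 µm / 0.03 N-preload compression protocol.

**Cytokine panels.** Concentrations are log-normal: assay concentrations
are positive and right-skewed, and a log-normal is the simplest generator
consistent with Pearson-correlation network analysis after thresholding.
On the log scale, animal *i*'s value for cytokine *j* is

$$\log c_{ij} = \log(\mu_0 f_{g(i),j}) + \sigma z_{ij}, \qquad
  z_{ij} = \sqrt{b}\,g_i + \sqrt{w-b}\,h_{i,B(j)} + \sqrt{1-w}\,
  \varepsilon_{ij},$$

with a global factor $g_i$, one factor $h$ per co-regulation block, and an
independent residual, so the population correlation is exactly *w* within
a block and *b* across blocks. Defaults: baseline $\mu_0$ = 100 pg/ml
(a mid-range multiplex readout), log-scale SD $\sigma$ = 0.3 (≈30%
coefficient of variation, typical of multiplex immunoassays), technical
pseudo-replicate SD 0.05 on the log scale (replicates of one sample agree
to a few percent). Group shifts are multiplicative fold factors
$f_{g,j}$. Out-of-range (OOR) missingness is left-censored: per cytokine,
values below the `missing_rate` quantile are flagged, matching the
lower-detection-limit mechanism of multiplex panels. The distributional
form is a modeling choice, not an observed fact about any particular
assay; the screen itself never relies on it.

What the generator does *not* emulate: between-animal covariance beyond
the planted blocks, upper-limit (saturation) censoring, batch or plate
effects, and heavier-than-log-normal tails. Passing tests therefore show
the pipeline recovers structure *of the planted kind*; they do not certify
behavior under plate effects or gross outliers.

**Disc phantoms.** The disc envelope is an elliptic cylinder along the
transverse stack axis and the nucleus pulposus (NP) a strictly interior
ellipsoid, with `np_intensity > disc_intensity > background` — the
contrast agent partitions into the proteoglycan-rich NP, so the NP is
brightest and the planted NI/DI exceeds 1 for healthy-like phantoms. The
cylinder envelope makes the contour-interpolation step exact (circle radii
interpolate linearly), which isolates segmentation error from mask error
in the recovery tests. Real discs are neither cylinders nor noiseless;
the phantom validates the numerical chain, not biological realism.

**Loading traces.** Displacement $x(t) = X_0\sin 2\pi ft$ and force
$F(t) = F_p + kX_0\sin(2\pi ft + \delta) + \eta$, the exact single-mode
linear viscoelastic response; the closed forms tan δ and
$E = \pi k X_0^2 \sin\delta$ follow analytically and anchor the recovery
tests. A sampling rate below 20× the loading frequency is rejected
outright rather than risking aliased cycle detection.

All generators route randomness through one explicit integer seed per
call (a local RNG; global state is saved and restored), so identical
inputs give bit-identical outputs.

## Cytokine screen

*Collapse.* Pseudo-replicates are collapsed to the median of the detected
values; an entry stays missing only when every replicate was out of range.
The median is idempotent, so re-collapsing a collapsed panel is the
identity. OOR values are excluded from every mean, median and variance —
never imputed, since no imputation rule is part of the assay design.

*Missingness filter.* The flagged fraction is pooled across all animals of
all groups, and exclusion requires *strictly more than* `max_fraction`
(default 0.25): a cytokine missing in exactly a quarter of animals is
retained. Both the pooling and the strictness follow the screening
protocol's wording literally.

*Welch test.* Implemented from the closed form (statistic,
Welch–Satterthwaite df, two-sided p from the t distribution) and
cross-checked in the tests against `stats::t.test` to 1e-10. When both
samples are constant the test is degenerate: p = 1 for equal means,
otherwise p = 0 with a `degenerate` flag rather than a silent NaN.

*Screen.* "Upregulated" means two-sided p < α (default 0.05) **and** case
mean > control mean. Two caveats are deliberate: the direction gate halves
the effective false-positive rate relative to α, and no multiple-testing
correction is applied across the panel because the screen is a feeder for
the fold-change analysis, not a confirmatory family of hypotheses. Whether
the upstream test should be one-sided was an open choice; two-sided was
selected so the reported p-values keep their conventional meaning, with
the direction applied as a separate gate.

*Fold changes.* FC = animal value / control-group mean (detected values
only), computed on collapsed per-animal values for both models — using
collapsed values on both sides keeps the two models' FC distributions
comparable. FCs are scale invariant by construction.

*Calibration caveat.* Welch's test assumes approximate normality within
groups. Under the generator's log-normal data its true size at the study's
own n = 9 vs 3 is ≈0.06, an inflation caused by skew at tiny n, not by the
implementation. The calibration simulation in the test suite therefore
runs at balanced n = 12 per group, where the measured size is ≈0.05 and
the ±2 SE band around the nominal level is attainable; the planted-power
simulation keeps the study's 9 vs 3. Users screening n = 3 groups should
read p-values near 0.05 with that inflation in mind.

*GTT.* Trapezoidal quadrature over the sampled points (the quadrature rule
is unstated in standard protocols; the trapezoid is exact for the
piecewise-linear interpolant of a 4-point series), times in hours so the
AUC lands in mg·h/dl, and a strict `auc > cutoff` (default 435 mg·h/dl)
for diabetic classification — an AUC exactly at the cutoff does not
classify.

## Correlation networks

Edges are unweighted: the analysis thresholds correlations into
"interaction present/absent" at |r| > τ (default 0.7, strict), and all
graph metrics treat the result as a plain graph, with the underlying r
kept only as an edge attribute. Negative correlations form edges because
the criterion is |r|. Undefined correlations — a constant cytokine, or a
pair with fewer than 3 complete observations under pairwise-complete
handling of OOR values — never create edges. Per-pair sample counts are
reported but not filtered on: with n = 3 animals any |r| > 0.7 edge is
fragile, and the package surfaces that fact rather than silently pruning.

Numerical choices:

- *Eigenvector centrality*: power iteration on A + I (the shift breaks the
  ±λ oscillation on bipartite graphs without changing eigenvectors),
  uniform positive start, tolerance 1e-10, L2-normalized. On disconnected
  graphs the vector concentrates on the component carrying the dominant
  eigenvalue; other components go to ~0. An edgeless graph gets the
  uniform vector by symmetry.
- *Betweenness*: Brandes accumulation with fractional credit for tied
  shortest paths, summed over unordered pairs, unnormalized.
- *Average path length*: mean over unordered pairs at finite distance;
  disconnected pairs are excluded from numerator and denominator, and an
  edgeless graph is an error rather than 0.
- *Louvain*: local moves in a seeded shuffled visit order, ties in
  modularity gain broken by the first candidate encountered, aggregation
  until no pass improves; resolution fixed at 1. The returned Q is the
  modularity of the returned partition on the original unweighted graph.
- *k-hop reachability*: boolean matrix powers, diagonal excluded; the test
  suite proves agreement with per-node BFS.
- *Jaccard*: computed on the upper triangle after aligning the two node
  sets by label union (absent nodes contribute zero rows); two all-zero
  matrices over identical node sets compare as J = 1 (identical empty
  relations).
- *Hub ranking*: top-k (default 5) per metric with the deterministic
  tie-break (value descending, then name ascending), so shared/unique hub
  sets are reproducible.

Force-directed layouts (Fruchterman–Reingold via igraph, seeded) are an
export/visualization step only; no metric depends on coordinates.

## Micro-CT morphometry

*Smoothing.* Separable 3D Gaussian, window = `kernel` voxels per axis
(default 3) with σ = kernel/4 — chosen so the window covers roughly ±2σ;
the protocol names only the window, not σ. Weights are normalized and
borders edge-replicated, so constants pass through unchanged and interior
mass is conserved.

*Whole-disc mask.* Perimeter contours every ten transverse slices are
rasterized (voxel centre inside the polygon, even-odd rule), and
intermediate slices come from linearly interpolating the two bounding
polygons' signed distance fields and thresholding at zero. "Morphing by
linear interpolation" is otherwise ambiguous; SDF blending is exact for
concentric circles (radius interpolates linearly) and monotone in area for
nested shapes, which the tests verify. Slices outside the contoured span
are empty.

*NP segmentation.* Threshold within the disc mask — Otsu's method by
default (the thresholding method is unstated in the protocol; Otsu is the
parameter-free default, and a fixed value can be supplied) — then one
morphological close and one open with a 3×3×3 cube to fill interior holes
and smooth the boundary, the largest 6-connected component, and
intersection with the disc. The cube and single iteration are the smallest
choices that achieve both stated goals. Note one consequence: close/open
is not the identity on a voxelized ellipsoid boundary, so even noise-free
segmentation can differ from the planted mask by a thin boundary layer
(≈0.3% of voxels on a 64³ phantom); NPVF recovery stays within 2% and
NI/DI within 1%, which is what the acceptance checks assert.

*Metrics.* NPVF = voxel ratio; NI/DI = mean NP intensity over mean
whole-disc intensity with the NP *included* in the disc mean (the
whole-disc reading of "disc intensity"; excluding it was the open
alternative); DHI = mean height/width of the disc mask over the five
sagittal slices centred on the disc centroid (height along the stack axis,
width in-plane). "DHI" and "DHR" are treated as the same quantity.
Intensity metrics are computed on the unsmoothed volume so smoothing
affects only segmentation.

## Viscoelastic analysis

Cycles are cut at positive-going zero crossings of the mean-centred
displacement, tolerant of ~1% sampling jitter. Defaults analyze the last
10 of 20 cycles: early cycles carry preconditioning transients, and the
protocol does not say which cycles were used. The "linear region" of the
loading branch is operationalized as the central 20–80% of the
displacement range — the protocol names no definition, and the central
band avoids both turnaround nonlinearity and endpoint leverage. Slopes are
averaged across selected cycles.

tan δ comes from least-squares single-frequency sinusoid fits (sin/cos
regressors plus intercept) to displacement and force rather than an FFT
peak: at 10–20 cycle records the regression estimator has no spectral
leakage and needs no windowing. The phase difference is wrapped to
[0, π/2); a fit whose residual power exceeds 50% of signal power is
rejected as non-sinusoidal. Hysteresis energy is the absolute shoelace
area of each closed loop, averaged over the selection; at ≥100
samples/cycle the polygon underestimates the true ellipse area by <0.1%.
All three metrics are invariant to time translation and constant force
offsets, and on ideal traces they are mutually consistent through
$E = \pi F_0 X_0 \sin\delta$ and tan δ = tan(planted δ), which the
acceptance checks verify to 1%.

## Problem sizes used in validation

The shipped tests and the acceptance script run at sizes chosen to make
Monte-Carlo bands tight while keeping a laptop-scale run: 100 random
graphs of ≤7 nodes against exhaustive oracles; 100 seeds for
planted-community recovery (n = 30/group, two 10-cytokine blocks);
100–200 null panels of 45 cytokines for screen calibration; phantoms at
64³–72³ voxels over planted NPVF 0.05–0.4 with 20 noise seeds; 50 noisy
traces for tan δ recovery. Exhaustive modularity search is limited to ≤8
nodes (Bell-number growth); Brandes betweenness is cross-checked against
full path enumeration only on those small graphs, and against igraph on
larger random graphs.

## Known limitations

- Correlation networks from n = 3 animals are inherently unstable; the
  package reports per-pair sample counts but deliberately does not filter
  edges on them.
- No multiple-testing correction in the screen (documented above); no
  significance testing of individual correlations, partial correlations,
  or weighted-graph metric variants.
- Volume I/O is TIFF-stack (+ JSON voxel-size sidecar) only; scanner DICOM
  series should be converted to TIFF stacks upstream.
- The morphometry chain assumes the contrast-enhanced convention
  (NP brightest); inverted-contrast protocols would need a fixed threshold
  and inverted candidate logic.
- Histology scoring, RNA-seq differential expression, multi-group ANOVA
  post-hocs and biochemical standard-curve assays are out of scope.
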