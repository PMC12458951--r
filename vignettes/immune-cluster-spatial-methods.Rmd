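---
title: "Methods: immune-cluster detection, ICAT, and centered L-function summaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: immune-cluster detection, ICAT, and centered L-function summaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunospat)
```

This vignette explains the models and procedures implemented by
`immunospat`, the assumptions behind them, the parameters that matter, and
the choices made where the design was genuinely open. The package operates
on per-cell feature tables (id, centroid in μm, marker intensities and/or
binary calls) together with polygonal tumor annotations; it does not touch
images, segmentation, or threshold selection.

## Data model and gating

Cells are points in a planar micrometre frame (image convention: origin
top-left, y increasing downward). Marker positivity is a strict threshold
(`intensity > t`): cells exactly at the threshold are negative. This
boundary convention is arbitrary but deterministic, and it makes gating
idempotent. Thresholds are *inputs* — in practice they come from
per-specimen visual review, and no automated selection is attempted.
Markers that are only reliable inside dense immune aggregates (Ki67, TCF1,
PD-1 are typical) can be gated with a polygon restriction: the call is
forced negative outside the regions of interest.

Phenotypes are assigned by an ordered rule list over the binary calls;
the first matching rule wins and unmatched cells are `"unclassified"`, so
the assignment is a partition. Lineage doublets (e.g. CD20⁺CD3d⁺, usually
a segmentation artifact in packed aggregates) are resolved purely by rule
order; the default hierarchy puts the more specific CD8 T-cell states
first (Tpex = TCF1⁺PD-1⁺CD8⁺, CTL = GZB⁺CD8⁺, Tex = PD-1⁺CD8⁺), then T
lineages, then B states — so T beats B on doublets. The order is
configurable where a panel warrants otherwise.

## BIC and TIC detection

B-cell immune clusters (BICs) are detected in two stages with three
interpretable parameters: neighbourhood sizes `k = 25` (nucleation) and
`k = 100` (expansion), and B-cell fractions 50% and 20%.

1. *Nucleation*: keep B cells whose 25 nearest neighbours (self excluded)
   are at least 50% B cells. This is a local-majority filter that is
   insensitive to absolute density.
2. *Grouping*: nucleation cells are grouped into nuclei by connected
   components of the symmetric 25-NN graph. The grouping rule is not
   dictated by the detection parameters themselves; the symmetric KNN
   graph was chosen because it is deterministic, scale-free (no distance
   threshold to tune), and consistent with the nucleation neighbourhood.
3. *Expansion*: any immune cell — phenotype in the immune set, or positive
   for one of the 20 canonical immune markers (CD11b, CD68, CD163, CD4,
   CD3d, CD8a, TCF1, FOXP3, PD-1, CD57, CD11c, GZB, CD15, HLA-DR, CD103,
   CD31, pTBK1, CD24, CD44, CD206) — joins if at least 20% of its 100
   nearest neighbours are B cells *and* it lies in the symmetric 100-NN
   neighbourhood of a current member, iterated to a fixpoint. The
   adjacency condition stops absorption chains: eligibility requires a
   cell's own neighbourhood to reach back into B-rich territory, so the
   expansion halo extends at most about one 100-NN radius beyond the
   core (≈ 600 μm in sparse stroma at ~80 cells/mm²).
4. Clusters under 300 cells are discarded.

Neighbour lists are computed once over all cells with an exact k-d tree;
coordinate ties are broken by input order (measure-zero for continuous
coordinates). The detector is deterministic and invariant to rigid motion
and cell-id relabeling.

T-cell immune clusters (TICs) use DBSCAN over the T cells (CD3d/CD4/CD8
lineages) with expansion radius `eps = 50` μm and a 100-cell minimum
applied as a post-filter. DBSCAN's core-point threshold is not part of the
published parameterization; the default here is 10 neighbours within
`eps` (a T-cell density of ~1 270 cells/mm²), exposed in `tic_params()`.
Border points join the first core point that reaches them, which is
deterministic in input order.

## ICAT

ICAT summarizes cluster organization from member coordinates alone:

$$\mathrm{ICAT} = c\,\frac{\sigma_1 + \sigma_2}{\sqrt{n}},$$

with σᵢ the standard deviations (μm) of the centered coordinates projected
on two unit-norm, maximally independent directions, and `c = 1` by
default. The √n normalization makes ICAT a *per-cell* dispersion: at fixed
shape it falls as clusters densify, and at fixed n it scales linearly with
dilation, so dense symmetric follicles score low and sparse irregular
aggregates high. For a uniform disk of radius R, σ = R/2 in every
direction, so a 1000-cell, 200 μm disk sits near 2·100/√1000 ≈ 6.3; among
equal-area ellipses the disk minimizes σ₁+σ₂ (AM–GM), so elongation always
raises ICAT. The constant `c` absorbs any alternative normalization
convention and is exposed in `icat_config()`.

**Degeneracy and the PCA fallback.** The independent directions are
estimated by FastICA on the raw coordinates. For elliptically symmetric
clusters this estimate is fundamentally non-identifiable: whitening maps
the cluster to a rotation-invariant disk, the ICA contrast is flat, and
the returned directions depend on initialization — and with them the
projection σ's. The implementation therefore runs FastICA from two fixed
rotations of the initial demixing matrix and accepts the ICA directions
only when both runs agree within 5° (folded, up to sign and order);
otherwise, or on non-convergence, the orthogonal PCA eigenvectors are used
and the result is flagged `pca_fallback`. For genuinely non-Gaussian
anisotropy (e.g. a rotated box of independent uniforms) both runs agree on
the true axes; for circles the projection σ is direction-independent, so
the fallback changes nothing discontinuously. `min_cells = 50` guards the
covariance estimate; collinear input is an error.

Classification uses strict quartile cutoffs `organized < 13.7 <
intermediate < 32.4 < disorganized`; values exactly at a cutoff are
intermediate. The cutoffs are reference values from the prostate cohort
the statistic was calibrated on and are parameters, not constants.

## Centered and multitype L-functions

Ripley's estimator on a rectangular window W,

$$\hat K(r) = \frac{|W|}{n(n-1)}\sum_{i \ne j} e_{ij}\,\mathbf 1(d_{ij} \le r),
\qquad \mathrm{CLF}(r) = \sqrt{\hat K(r)/\pi} - r,$$

is zero-mean under complete spatial randomness (CSR); the multitype
version normalizes by n_A·n_B over ordered cross-pairs and is zero under
independence of the two type fields. Edge corrections: Ripley isotropic
(default), translation, or none; the published analysis names no
correction, and the choice only matters near the window scale. The radius
grid starts at the first increment (default 30 μm, up to 1.5 mm; an
exemplar mode of 10 μm steps suits close-ups) because L − r is 0/0 at
r = 0.

**Tiling.** Whole-slide curves average per-tile CLFs over 3 × 3 mm tiles
laid at the four systematic half-tile offsets (0,0), (½,0), (0,½), (½,½) —
a deterministic reading of "fourfold bootstrap" that mitigates bracketing
bias without randomness. Tiles need ≥ 10 points of each subject type, and
boundary-clipped tiles participate when at least half their area is in
frame. The tile estimator assumes local homogeneity within 9 mm²;
tissue-scale intensity gradients leak into the curve as apparent
clustering, which is the motivation for tiling in the first place.

**Summaries.** CI is the trapezoidal integral of the positive part of the
curve (μm²); R50 is the smallest grid radius at which the cumulative
positive integral reaches half of CI; ECR = 2·R50. The doubling is a
deliberately conservative stand-in for the radius at which the curve
re-enters the CSR band: the direct envelope crossing is unstable under the
L-function's right skew, so the envelope (`csr_envelope()`, pointwise
min/max of 39 conditional CSR simulations ⇒ 2/40 pointwise exceedance) is
kept diagnostic. An everywhere-nonpositive curve summarizes to (0, 0, 0).

## Geometry

- *Compartments*: boundary-inclusive point-in-polygon against the
  pathologist domains; overlapping domains resolve to the smallest
  containing one (with a warning).
- *Infiltration*: phenotype count inside a domain divided by the area of
  the union of 20 μm disks around **all** cells in that domain, overlaps
  counted once; disks are 256-gons, keeping the single-disk area error
  below 0.01% (contract: 0.5%). Domains with no cells report missing, not
  zero. Whether the denominator should be restricted to particular cell
  classes is unspecified upstream; all non-excluded cells are used.
- *Cluster localization*: a cluster is intratumoral iff its centroid (the
  arithmetic mean of member coordinates — "center" is otherwise
  undefined) lies inside a domain; otherwise the distance is the minimum
  to any domain boundary. Tumor-free specimens are excluded (an error),
  matching the upstream handling.
- *Contact*: centroid distance ≤ 2·cell_radius + gap, default 5 μm radius
  and 2 μm gap, i.e. 12 μm. The ≤ 2 μm interaction distance is defined on
  segmentation-mask boundaries upstream; masks are out of scope here, so
  the effective-radius convention stands in, with both knobs exposed.

## The synthetic generator

`generate_specimen()` assembles per-phenotype CSR stromal backgrounds,
planted clusters, and Fourier-perturbed-circle tumor polygons, with a
ground-truth table. One root seed spawns per-component child seeds through
a fixed arithmetic splitting scheme (R's default Mersenne-Twister
underneath), so adding a cluster does not perturb the background draw and
recorded coordinates are reproducible across platforms. Out-of-frame
points are truncated, not reflected.

Cluster presets bracket the ICAT organization scale and were fixed
analytically from the moments above: *organized* = uniform disk, n = 1000,
R = 200 μm (ICAT ≈ 6.3, well under 13.7); *disorganized* = Gaussian blob,
n = 400, σ = 500 μm, axis ratio 2 (ICAT ≈ (500+250)/20 ≈ 37.5, above
32.4). The `validation_spec()` reference condition plants three organized
B clusters (560 cells, 150 μm disks) and three T clusters (200 cells) with
centres ≥ 1.5 mm apart in sparse stroma on a 6 × 6 mm frame; its
planted-BIC composition keeps the expected T content per B cluster near 50
cells, safely below the 100-cell TIC cutoff, so the ground truth contains
exactly three clusters of each lineage and recovery can be scored
unambiguously.

What the generator does *not* emulate: marker-intensity distributions
beyond a two-component mixture, segmentation artifacts and signal
spillover (the usual source of lineage doublets), holes and folds,
tissue-scale density gradients, or 3D structure. Perfect recovery on
planted fixtures therefore validates the algorithms and their
implementation, not robustness to the full messiness of real slides.

For Thomas-process recovery checks the reference condition is 40
parents/mm² with 15 offspring (σ displacement), a 3 × 3 mm window and a
10 μm radius grid to 750 μm, with medians over 7 draws. Two numerical
effects drove these choices: on the 30 μm cohort grid ECR is quantized to
60 μm steps, which produces spurious ties between nearby σ values; and
sparse parent fields add a 1/κ tail to the CLF that swamps the σ signal
(for Thomas, K(r) = πr² + (1−e^{−r²/4σ²})/κ, so the centered tail decays
only like 1/(2πκr)).

## Statistics

Jonckheere–Terpstra is implemented directly (sum of between-group
Mann–Whitney counts over ordered pairs, ties at ½), with the tie-corrected
normal approximation or a Monte-Carlo permutation p; its size was checked
against a simulated null. Jensen–Shannon divergence uses base 2 (values in
[0, 1] bits) with 0·log 0 = 0. The remaining two-sample tests delegate to
the standard routines behind one record-shaped interface; Levene is the
classic mean-centered form; the two-proportion z is computed directly with
pooled variance to preserve the sign. Sidedness is always an explicit
argument. Raw p-values are reported — no multiplicity correction is
applied by default, matching upstream practice — with a Benjamini–Hochberg
utility available.

An optional normality-prescreen dispatcher (t vs Mann–Whitney by
Kolmogorov–Smirnov) was considered and deliberately left out of the
default path: analyses call the named test directly, which keeps results
reproducible from the config alone.

## Problem sizes and determinism

The bundled validation runs use 6 × 6 mm specimens of roughly 8 000 cells,
9 mm² CSR calibration windows at 200 cells/mm² (200 replicates; 39-sim
envelopes), Thomas fields of ~5 400 points, and ICAT presets at n ≤ 1000
over ≤ 100 seeds — sizes at which every documented property is measurable
in minutes on one core. All stochastic paths take explicit seeds;
`run_pipeline()` writes byte-identical CSVs when config and seed are
fixed, and records the seed and a config hash in its manifest.

## Known limitations

- BIC expansion eligibility depends on local composition only; a dense
  non-B immune aggregate overlapping a B-rich core joins the BIC wholesale.
- ICAT compares clusters of similar n best; the √n normalization is a
  convention (area- or n-normalizations are plausible alternatives) and
  only the relative ordering, not the absolute scale, should be
  over-interpreted when `c` is left at 1.
- The tile average weights all eligible tiles equally rather than by
  point count; heavily unbalanced slides could justify count-weighting.
- `union_disk_area()` is exact up to the 256-gon disk approximation;
  degenerate all-coincident inputs return a single disk's area.
- DBSCAN border-point assignment is order-dependent in the standard
  algorithm; with the 100-cell post-filter this has never changed a
  cluster decision in testing, but tie cases are theoretically possible.
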