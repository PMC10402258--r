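---
title: "Multi-scale neuronal morphometry: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale neuronal morphometry: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphoscale)
```

## Scope

`morphoscale` quantifies neuronal anatomy at five nested scales —
regional neurite co-occurrence across brains, dendritic
microenvironments, whole-neuron morphology, sub-neuronal arbors,
tracts and hubs, and axonal varicosities (boutons) — and ties the
scales together through a cross-scale feature vector and
diversity-and-stereotypy (DS) matrices. Because the imaging data this
style of analysis targets are terabyte-to-petabyte whole-brain volumes, every
stage here is exercised on seeded synthetic stand-ins generated by the
package itself: a toy labelled atlas, stochastic skeleton growth with
planted class structure, rendered image blocks, profile ledgers, and
density matrices with planted modules. The generators are first-class,
tested code; their ground-truth ledgers are what the test-suite and
the acceptance script score against.

## Skeletons and morphometric features

Skeletons use the 7-column SWC convention (id, structure code, x, y,
z, radius, parent; micrometres). A tree must have exactly one root
(the soma), no dangling parents, and full reachability from the root.
Branches run between consecutive critical points (root, branch point,
tip); branch order starts at 1 for stems and a k-furcation behaves as
k − 1 stacked bifurcations, which keeps orders deterministic without
assuming binary trees.

`lmeasure_features()` provides the 22 classical whole-neuron
measurements. Conventions that the literature leaves open are fixed as
follows and verified against naive per-definition oracle
implementations in the tests:

* soma surface is `4*pi*r^2` of the root node; average diameter is the
  mean of `2*r` over nodes;
* membrane surface and volume treat each compartment as a cylinder
  with the child node's radius;
* fragmentation is the number of compartments per branch;
* bifurcation angles (local between immediate children, remote between
  child-branch endpoints) are reported in degrees, and tilt is the
  smaller of the two parent–child angles;
* partition asymmetry is `|l - r| / (l + r - 2)` over subtree tip
  counts, defined as 0 for a (1,1) split;
* the Hausdorff dimension uses 3-D box counting over four dyadic
  scales starting at the bounding box, on points densely resampled
  along edges (half the median edge length), with a least-squares
  slope. Four levels keep the estimate stable on trees with tens to
  thousands of nodes.

The 24-dimensional local-dendrite vector drops Nodes, SomaSurface,
AverageDiameter and Surface (they scale with reconstruction density
rather than shape) and appends PCA shape descriptors: the explained
variance ratios of the first three principal components and the
sum-normalised absolute loadings of the first component. Collinear
degenerate clouds yield variance ratios (1, 0, 0) by convention. The
47-dimensional whole-morphology vector combines seven global features
(with OverallVolume read as the bounding-box volume) with min, max,
mean and sd of the ten per-branch/per-bifurcation features.

## Synthetic study conditions

The generator grows rooted binary trees by stochastic segment
extension: Gamma-distributed branch lengths, a per-micrometre
bifurcation rate (branch-end probability `1 - exp(-rate * length)`),
and von Mises direction jitter with persistence. Axons grow as a
persistent primary tract with locally dense subtrees ("arbors")
planted at waypoints; several stems per waypoint make the planted
arbors genuinely dense relative to the connecting wire, as real
axonal arborisations are. Default study conditions:

* soma fields: 30 spheres of radius 5 voxels in a 128^3 block at
  SNR 8, occupying under 1% of the volume as in sparsely labelled
  brains (the 99th-percentile binarisation step presumes sparse
  foreground);
* image noise: additive Gaussian with sd = amplitude/SNR, low-pass
  filtered (two 5^3 box passes) to emulate the spatial correlation
  that optics and downsampling averaging impose on microscopy
  background — unfiltered per-voxel white noise is not what the
  detectors ever see on real downsampled data;
* density matrices: 50 regions x 50 brains, 8 planted modules of 3–6
  regions sharing a log-normal per-brain loading at SNR 10, all other
  regions varying independently, columns normalised to sum to 1;
* bouton profiles: 20 planted bumps per axon (intensity 200 on a
  90-baseline 8-bit profile, radius doubled, 15 um minimum gap);
* three "super-classes" (cortex-like, thalamus-like, striatum-like
  regimes differing in branch length, branching rate, stem count,
  tract length and straightness) define the DS experiments, 20
  neurons per class.

What the generators do *not* emulate: real tissue artefacts
(vasculature, label aggregates), registration distortion, tracer
topology errors beyond those the curation fixtures construct, and
anatomically realistic regional geometry. Passing tests therefore
demonstrate algorithmic correctness and recoverability of planted
structure at desk scale, not performance on real brains.

## Image-domain detectors

The neurite segmenter follows a six-step scheme: a global empirical
threshold `0.9 * min(max(mu + 1.5*sigma, 400), 1000)` on 16-bit
statistics; block pre-filtering (maximum below 300 skips the block);
local-mean-subtraction denoising (5^3 window, clamped at zero); an
anisotropy score per 16^3 cuboid from the intensity-weighted PCA
eigenvalues of foreground voxels,
`(S1-S2)/(S1+S2) * (S1-S3)/(S1+S3)`; multiplication of the denoised
image by the upsampled score map; and thresholding at `0.1 * thresh`.
Cuboid foreground is taken at half the cuboid's maximum denoised
intensity — a scale-free choice that still sees a tube as a line when
a cuboid clips only its corner. Region-wise summing of mask voxels,
divided by the total count, yields the per-brain density vector.

Soma detection binarises the Z-scored 8-bit block at its 99th
percentile and scores foreground voxels with a gray-scale distance
transform: geodesic chamfer propagation from the background where a
step into a voxel costs `step / w` with `w` the normalised intensity,
reducing exactly to the Euclidean distance transform on uniform
foreground. Voxels scoring 5–30 are candidates (in voxel-distance
units; the alternative intensity-weighted reading is a parameter),
non-maximal suppression keeps the strongest candidate within 8 voxels,
and mean-shift refinement (15-voxel window after zero-clipping below
mu + sigma) polishes the centres. Candidates that converge onto the
same attractor (within 3 voxels) collapse to the brighter one; the
15-voxel dim-midpoint duplicate rule then handles split annotations of
elongated blobs. Overlapping spheres produce a flat distance ridge on
which suppression alone cannot decide — that is precisely the case the
mean-shift duplicate stage resolves, and the tests exercise it.

## Curation of local reconstructions

Five independent filters run on the raw tree and their surviving node
sets are intersected; the largest root-connected component is kept and
results under 20 nodes are discarded. Conventions: the parent–child
branch angle uses vectors (parent end to start) and (child start to
end) so that 180 degrees means straight continuation; the radius rule
compares mean branch radii; crossovers are multifurcations or
consecutive bifurcations within 5 voxels, resolved by the 80/100/150
degree bands; foreign somas are large-radius node clusters (area
above 500 px^2) outside a 50-px protection zone, cut where the
length-weighted deviation-angle integral flips allegiance, ties kept
on the side with more nodes; winding tests the root-to-branch-end
path against its chord (ratio strictly above 3 prunes; the per-branch
variant is available as an option).

## Population, typing, sub-neuronal and bouton analyses

Regional co-occurrence uses Spearman correlations across brains
(constant rows get 0 with a warning). Initial modules come from an
average-linkage dendrogram on `1 - rho`: merge heights split into a
tight and a loose mode by 1-D 2-means, and a module is a maximal tight
cluster of 3–15 regions; leftovers attach to the most correlated
module with room, undersized modules merge, oversized ones split along
the leaf order. The height cut matters: without it, mutually
uncorrelated modules glue pairwise below the 15-region cap purely by
merge order. Tight modules drop regions hit fewer than twice in the
target-correlated sets (Spearman at or above 0.8) and keep modules
with at least two survivors; the consistency score annotated is
observed, not thresholded.

Full-morphology typing multiplies the cosine similarity of z-scored
47-feature vectors by `exp(-d / d_norm)` of the soma distance
(`d_norm` defaults to the maximal pairwise distance). The spectral
embedding clamps negative affinities to zero (affinity matrices must
be non-negative), uses the symmetric normalised Laplacian, and
k-means with a fixed seed; the cluster count is a parameter with an
eigengap diagnostic.

Arbor decomposition clusters axonal nodes (resampled to 20 um) with a
locally scaled Gaussian affinity and repairs connectivity so each
arbor is a connected subtree; the automatic arbor count applies the
eigengap on high-density nodes only (at least 30% of the maximal
local density within 50 um), with a fixed 100 um bandwidth sitting
between arbor diameter and arbor separation — sparse connecting wires
otherwise masquerade as clusters. Hubs resample axons at 80 um, count
neighbours within 500 um, threshold at 70, dilate by a 10^3 voxel
kernel at 25 um and label connected components. The primary tract
starts from the longest root-to-tip axonal path and trims terminal
branches shorter than the tree's second-longest branch; tract groups
are resampled to 200 arc-uniform points, their per-percentile radius
is the 75th percentile of distances to the centre in the first two
principal components, and the terminal-to-soma radius ratio classifies
convergent (< 0.8), divergent (> 1.25) or parallel patterns.

Bouton detection partitions axonal branches into 20 um fragments and
requires the intensity and radius profiles to peak within 2 um of
each other, a local radius at least 1.5 times the median of the
surrounding (±10 um, excluding a ±2 um core) shaft, an 8-bit
intensity above 120, and deduplication below 5 voxels. Terminaux
boutons are within 5 um of a terminal tip (an explicit convention;
`tau = 0` restricts to exact tips). The six radar features are the
per-neuron bouton count, TEB ratio, mean and sd of the inter-bouton
distance, and mean and maximum distance to the soma, min-max scaled
to 0–100 across groups.

## Cross-scale vectors and DS matrices

The 84-dimensional vector concatenates: 18 morphometric features of
the fused microenvironment, the same 18 for the whole neuron, 4
arbors (apical, basal, two axonal, absent apical = zeros) x
(n_branch, volume, max_density, dist2soma), the 6 bouton summaries,
and a motif block of tract descriptors zero-padded to 26 so the total
is 84; the block composition is configurable and recorded via the
configuration hash in every pipeline manifest. Each dimension is
z-scored over the population. A DS entry is the mean Pearson
correlation over all neuron pairs of two types, dimensions acting as
observations; intra-type averages exclude self-pairs, zero-variance
vectors are excluded with a count, singleton types have an undefined
diagonal. Scale distances are `1 - cor` of the vectorised upper
triangles (diagonal included, since stereotypy lives there). Moment
summaries report mean, sd, skewness and excess kurtosis, with higher
moments flagged on fewer than four samples.

## Problem sizes and determinism

The shipped experiments use: 30-sphere soma fields at 128^3; 20
neurons x 20 planted boutons; 50 x 50 density matrices over 20 seeds;
60 neurons (4 classes) over 10 seeds for typing; 20 neurons for arbor
recovery; 60 neurons (3 super-classes) over 10 seeds for DS. These
sizes make planted-structure recovery statistically unambiguous while
keeping a full run of the test-suite and the acceptance script
comfortable on a single CPU. Every generator is a pure function of
its seed, and `run_pipeline()` writes byte-identical CSV outputs for
a fixed configuration; the resolved configuration and its hash
accompany every run directory.

## Known limitations

* The toy atlas has convex regions and no laminar structure; analyses
  that depend on real anatomical geometry (hemispheric symmetry,
  layer gradients) are only mechanically exercised.
* The curation filters assume radii are meaningful; tracers that emit
  unit radii disable the radius-based rules silently.
* The GSDT is a chamfer (26-neighbour) approximation; distances carry
  the usual few-percent chamfer metric error, which the candidate
  band tolerates.
* The DS analysis reports whatever block composition it is configured
  with; comparisons across configurations are only meaningful at an
  identical composition hash.
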