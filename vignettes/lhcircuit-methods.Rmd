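---
title: "Methods: models, parameters, and design choices in lhcircuit"
author: "lhcircuit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and design choices in lhcircuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lhcircuit)
```

lhcircuit packages the computational chain used to characterize
mushroom-body output projections into the lateral horn: an image-based
screen for candidate synaptic partners, skeleton polarity analysis,
morphology-based cell typing, connector-table connectivity statistics, and
the calcium-imaging and T-maze index computations used to interpret
silencing and activation experiments. This vignette explains each model,
its parameters and defaults, the numerical conventions, and what the
synthetic-data generator does and does not emulate.

## The overlap screen

A driver line's registered expression volume is compared against two
aligned boolean masks: the *target* mask (the MBON's presynaptic terminals
in the dorsal LH) and a *peduncle* mask (the Kenyon-cell axon bundle, a
proxy for MB expression that would confound behavioral epistasis). The
per-line score is

    score = #{voxels in target with signal > t} − #{voxels in peduncle with signal > t}

**Threshold `t`.** Defaults to the volume's global Otsu threshold (computed
on the flattened grid so a 3D stack yields one threshold); a fixed
threshold can be supplied. The screen's original pixel threshold is not
something we can recover, so it is configurable; Otsu is a standard
parameter-free choice that lands between a bright neurite class and
background.

**Why subtraction, not a ratio.** The combination of target and peduncle
counts is only loosely constrained by how such screens are reported, but
observed score distributions include values in the thousands below zero —
impossible for a ratio of non-negative counts. Subtraction reproduces that
behavior naturally; a `ratio` mode (`target / (peduncle + 1)`) is available
behind a flag.

**Selection.** Lines are sorted by descending score (ties broken
lexicographically by line id, so ranking is deterministic) and selected
when their score reaches the empirical `quantile` (default 0.97, the "top
~100 of ~3,500" regime; with all scores equal every line equals its own
quantile and all are selected). Replicate volumes sharing a `line_id` are
scored per brain and averaged before ranking. Counting suprathreshold
voxels is the default; an intensity-sum mode exists because either reading
of "pixel overlap" is defensible.

**Mask building** (`buildMask`) overlays replicate volumes by voxelwise
maximum, contrast-stretches to [0, 1], blurs with an anisotropic Gaussian
(σ given in µm, default 1.0, converted to per-axis voxel sigmas), and
applies Otsu. The blur is implemented as separable per-axis convolution
with kernels truncated at 3σ and renormalized at the borders, so no signal
leaks off the volume edge. `maskPercentOverlap(a, b)` is
`100·|a∩b|/|a|` — deliberately asymmetric, with the *query* mask (e.g. the
PD2 axon mask) as denominator — and flags candidates strictly above 15%.

**Coordinate convention.** Skeleton coordinates are µm in template space;
voxel grids are 0-based conceptually with voxel centers at
`(i + 0.5)·voxel_size`, so in R's 1-based indexing a point x falls in voxel
`floor(x / voxel_size) + 1`. An edge counts toward a mask restriction iff
its *child* node falls inside — a simple, order-independent rule.

## Polarity: synapse flow centrality and the segregation index

For a rooted skeleton with per-node presynapse weights `pre` and
postsynapse counts `post`, the centrifugal synapse flow centrality of node
v with distal subtree T(v) is

    SFC(v) = (post_total − post_in(T(v))) × pre_in(T(v)),

the number of (postsynapse, presynapse) pairs whose tree path crosses v
with the postsynapse on the root side. It is computed in O(n) by subtree
accumulation; the test suite checks it against explicit path-pair
enumeration. At the root the distal subtree is the whole cell, so
`SFC(root) = 0`.

The split sits at the SFC maximum. Ties are resolved to the most
root-proximal candidate (then lowest node id): this yields the largest
well-defined axonal subtree and makes the split deterministic — an
unsynapsed linker between the arbors has constant SFC along its length, and
the proximal end of that plateau is chosen. The side of the split holding
more than half the presynapses becomes the axon. Nodes on the root path are
refined into `soma` (the root), `primary_neurite` (the unsynapsed stretch
before the first synapse-bearing branch) and `primary_dendrite` (an
unsynapsed stretch between the arbors, when the split falls distal to it).

Presynapse counting follows the `connector_once` convention by default —
a polyadic presynapse counts once regardless of how many postsynaptic
links it makes — with a `per_link` mode weighting each presynapse by its
fan-out for output-centric summaries.

The segregation index uses natural-log entropies (SI is a ratio of
entropies, so the base cancels): for compartment i with `N_i` synapses of
which fraction `p_i` are presynaptic,
`S_i = −(p_i ln p_i + (1−p_i) ln(1−p_i))` (0·ln 0 := 0),
`S = Σ_i (N_i/N)·S_i`, `Ŝ` is the entropy at the whole-cell presynaptic
fraction, and `SI = 1 − S/Ŝ`, clamped to [0, 1]; if `Ŝ = 0` (all synapses
one role) SI is defined as 0. Synapses landing on soma/primary nodes are
assigned to the nearer arbor by path distance (unweighted hops); with the
default generator this case does not arise because the refinement labels
any synapse-bearing stretch of the root path as dendrite.

```{r}
pop <- makeNeuronPopulation(simulationConfig(seed = 0))
flowCentrality(pop$skeletons[[1]], pop$connectors)
```

## Morphometry: dotprops, NBLAST scoring, Ward clustering

`toDotprops` resamples the skeleton's unbranched chains at a uniform step
(default 1 µm) and attaches to each point the first principal direction of
its k nearest points (default k = 5). When restricting to axon and/or
dendrite, primary neurite and primary dendrite nodes are stripped first:
those fasciculated tracts are nearly identical across neurons of a tract
and would mask arbor-level differences. Resampling preserves chain
endpoints, and points duplicated at branch nodes are deduplicated.

`nblastRaw` scores a query against a target by nearest-neighbour lookup
(kd-tree): each query point contributes `f(d, |u·v|)` with d the distance
to its nearest target point and u, v the unit tangents. The default is the
parametric exponential `exp(−d/σ)·|u·v|` with σ = 3 µm — chosen because no
specific trained scoring-matrix version can be assumed — and a binned
log-odds table (CSV of distance/dot-product bin edges and values) can be
supplied for fidelity to trained scoring. A self-comparison scores exactly
the point count, so normalized self-scores are exactly 1; the `mean` matrix
averages the two directed normalized scores and is symmetric by
construction. Raw scores are invariant to rigid motions applied to both
neurons.

`clusterTypes` runs `hclust(method = "ward.D2")` on Euclidean distances
between rows of the (by default mean) score matrix — Ward's criterion on
Euclidean distances between score vectors, not on `1 − score` — and cuts at
k groups or a height. Whether normalized or mean scores feed the clustering
is not externally fixed; mean is the default with a flag for normalized.

## Connectivity analytics

Input fractions are link counts over the target's total links of that
direction in the neuropil (a polyadic connector contributes one link per
postsynaptic partner), so fractions over an exhaustive partition sum to 1;
unknown partners form an explicit `other/undefined` category. Fan-out
statistics, in contrast, treat each presynaptic connector once (mean ±
sample SD of per-connector post-link counts). Excitatory-share bounds
bracket a focal input's contribution to direct excitation:
`upper = 100·focal/excitatory`, `lower = 100·focal/(excitatory +
undefined)`, with uniglomerular PNs and MBONs as the known-excitatory
categories. On the printed input fractions 26.5 (PN), 4.6 (MBON) and 15.6
(undefined) this gives 9.85–14.79%. Heatmap matrices count incoming links
per partner group, normalize by each target's per-neuropil postsynapse
total, drop groups with no connectivity, and order rows and columns by
descending totals.

## Physiology

ΔF/F₀ uses F₀ = mean fluorescence over the window (default 2 s)
immediately before stimulus onset; "onset" is operationalized as the first
frame acquired at or after the valve switch — deterministic at the 128–640
ms sampling used, where a physiological onset detector would add jitter of
a sample or two (a threshold-crossing detector is available behind a
flag). The response integral is the plain sum of ΔF/F₀ over 10 consecutive
samples starting at the onset sample — dimensionless by construction; no
trapezoid correction is applied since the quantity is defined as a sum
over time points, not an area. Permissive/restrictive trial sets are
trial-averaged and both divided by the maximum of the permissive
(low-temperature) average; thermogenetic activation magnitude is the mean
ΔF/F₀ over a 20 s window starting 5 s after the setpoint change, matching
the measured ~8–11 s temperature rise time.

## Behavior

The group score `(N_CS+ − N_CS−)/(N_CS+ + N_CS−)` is applied literally, so
aversive memory yields negative scores toward the shocked odor; a
presentation flag flips the sign for plotting positive performance
indices, rather than silently altering the printed formula. A performance
index is the mean of exactly two reciprocal group scores (opposite CS+
odors, enforced), which cancels any additive innate preference for one
odor; avoidance uses the same formula and attraction is its negative. SEM
is computed over independent index values (pairs), not flies.

## The synthetic-data generator

All generators are pure functions of a `simulationConfig` (identical
configs give identical output; each line/neuron/trace/group draws from its
own counter-derived substream, so output does not depend on generation
order). Defaults describe the study conditions the pipeline targets:

* **Expression library** (default 200 lines, 5 positives, 20 confounds,
  64×64×32 voxels at 0.56×0.56×1.0 µm): positives carry a bright
  Gaussian-blurred polyline ("tubular neurite") inside the target region;
  confounds carry the same inside the peduncle region (optionally also
  weak target signal via `confoundTargetSignal`; off by default so the
  planted positives are exactly the suprathreshold-target lines);
  negatives express a polyline elsewhere over sparse dim background — as
  real GAL4 lines express *somewhere*, which keeps each volume's Otsu
  threshold anchored to a bright class.
* **Neuron population** (default 3 families × 5 neurons): soma → primary
  neurite → dendritic arbor → primary dendrite → axonal arbor. Branch
  directions are a family-level property (cell types are stereotyped; a
  `shapeSeed` lets two families share a blueprint), jitter displaces each
  branch smoothly with small node noise, and `registrationUm` sets
  whole-cell placement scatter (~1 µm for light-level registration, 0 for
  skeletons traced in a single EM volume). The calyx construction — two
  families sharing a blueprint and differing only in a long calycal
  dendritic trunk-plus-tuft — uses the EM setting, since that is the
  scenario in which dendrite-restricted similarity separates two cell
  types whose axons are indistinguishable. Postsynapses are placed on the
  dendritic arbor and presynapses on the axonal arbor with mixing fraction
  m (m = 0 perfectly segregated, m = 0.5 fully mixed); polyadic connector
  fan-outs default to 1 + Poisson(6.8) (mean 7.8), and post links are
  sampled across the population's postsynaptic placements.
* **Calcium traces**: baseline + amplitude × (exponential-decay kernel
  peaking at the first frame at/after onset, τ default 1 s) + Gaussian
  noise, at 128 ms sampling, 2 s stimuli, with the planted amplitude kept
  as ground truth.
* **Behavior counts**: reciprocal pairs of groups of 50;
  `N_CS+ ~ Binomial(50, p ± bias)` where `bias` is an additive arm
  preference for the first odor (+ when it is the CS+, − when it is not),
  which reciprocal averaging cancels exactly in expectation.

**What passing tests show — and what they do not.** The generator emulates
geometry, counting structure and noise, not optics, EM imagery, or odor
chemistry: volumes have idealized backgrounds and perfectly disjoint
masks; skeletons are smooth star-like arbors without tortuosity, spines or
tracing errors; synapse placement is uniform within an arbor; calcium
kernels are single exponentials without bleaching or motion; behavior is
binomial without group-level overdispersion. Recovery on these data
demonstrates that the *computations* are correct (the screen arithmetic,
the SFC/SI formulas, NBLAST scoring, the index algebra), not that the
pipeline is robust to the artefacts of real imagery or tracing.

## Problem sizes and numerical notes

The shipped tests and the acceptance script use a 200-line screen on
64×64×32 grids, populations of 8–15 neurons with 40 presynapses and 60
postsynapses each, 20 random trees of up to ~200 nodes for the SFC oracle,
50-point dotprops pairs for the NBLAST oracle, 1,000–2,000 behavioral
groups, and a few hundred Monte-Carlo replicates for the averaging-scaling
checks — sizes chosen so every property is measured with comfortable
statistical margin while the whole suite runs in about a minute.
Degenerate inputs are rejected rather than coerced: neurons without both
synapse roles are "unsplittable", empty compartments and empty masks
error, a single behavioral index reports SEM as `NA`. Quantities that
require the real traced EM dataset (per-neuron presynapse counts such as
183/190, the 0.27 ± 0.09 and 0.72 segregation indices, the 732-postsynapse
input breakdown) are context for interpretation only; the synthetic ground
truth is the acceptance surface.
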