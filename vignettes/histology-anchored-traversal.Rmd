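---
title: "Histology-anchored traversal of spatial transcriptomics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Histology-anchored traversal of spatial transcriptomics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sttraverse)
```

## The problem

Visium-style spatial transcriptomics overlays a hexagonal grid of
barcoded capture spots on an H&E-stained tissue section. Many tissues —
the gut wall, the cortex — are organized as stacked histological layers,
and the natural way to compare expression across samples is along a
one-dimensional depth axis through those layers. Methods that define
layers from expression and then model expression along the layers are
circular; this package instead anchors the axis in the histology image
alone. The user supplies only two anchor spots (one on each outer layer);
everything else is learned from the image.

The procedure, implemented by `sttraverse()`:

1. **Tiles.** One square image tile per spot, side equal to the spot
   diameter in pixels, centered on the spot.
2. **Embedding.** A self-supervised encoder `f` is trained with triplet
   loss: for a triplet (anchor tile $a$, positive $p$ drawn from the
   anchor's six lattice neighbors, negative $n$ drawn from all other
   tiles), $L = \max(0,\, m(f(a),f(p)) - m(f(a),f(n)) + \alpha)$ with
   mean-squared-error distance $m$ and margin $\alpha$. Adjacent tiles —
   which look alike and transition gradually — are pulled together,
   distant tiles pushed apart, so the embedding encodes layer identity
   and the gradual transitions between layers.
3. **Traversal.** The lattice graph (vertices = spots, edges = the hex
   adjacency offsets $(0,\pm2), (\pm1,\pm1)$) is weighted by the
   Euclidean distance between endpoint embeddings. Dijkstra's algorithm
   finds the cheapest path $P^\*$ between the anchors: the path crosses
   visually homogeneous territory cheaply and layer transitions only
   where it must, so it runs "down" through the layer stack.
4. **Alignment.** Every spot $s$ is assigned to the path tile minimizing
   the Euclidean embedding distance, $C(s) = \arg\min_{p \in P^\*}
   \lVert f(s)-f(p)\rVert$; the assignment sets $S_p$ partition the
   slide and project it onto the path.
5. **Trajectories.** Counts are normalized per slide as
   $\tilde X_{s,g} = \ln(1 + t\,X_{s,g}/(\Sigma X/|S|))$ with target
   $t = 10^4$, and averaged within each $S_p$:
   $\hat X_{p,g} = |S_p|^{-1}\sum_{s \in S_p}\tilde X_{s,g}$ — one value
   per path tile per gene.
6. **Length normalization.** Path index $i$ (of $k$) maps to relative
   position $(i-1)/(k-1)$ and each gene is linearly interpolated at every
   0.01 step, giving a $101 \times |G|$ matrix comparable across samples
   with different path lengths.

Downstream, `build_pair_pool()`/`sample_pairs()` generate "reasonable"
anchor pairs to test invariance of trajectories to the anchor choice,
`average_trajectories()` summarizes them with a normal-approximation 95%
confidence band ($\pm 1.96\,\mathrm{sd}/\sqrt{n}$), `spearman_concordance()`
quantifies agreement between trajectories, and `segment_from_path()` +
`adjusted_rand_index()` quantize an alignment into discrete layers at
annotated boundary crossings and score it against manual labels.

## The encoder

The package has no deep-learning framework behind it; the encoder is
implemented natively and has two parts:

* a **fixed, seeded random convolutional feature bank** — three blocks of
  3×3 convolution (zero padding), ReLU and 2×2 mean pooling, global mean
  pooling per channel, concatenated with the tile's raw per-channel mean
  and standard deviation. Random convolutional features preserve color
  and oriented-texture statistics without training;
* a **trainable MLP projection head** optimized by SGD (momentum 0.9,
  weight decay $10^{-4}$) on the triplet loss, with analytically derived
  gradients. The head output is the representation used downstream — the
  loss is defined directly on it, so it, and not an intermediate feature,
  is `f`.

`train_config("small")` (the default) uses channel widths (8, 16, 32),
one hidden layer of 64 units, output dimension 32, 40 epochs of 1024
triplets in batches of 128, learning rate 0.05 and margin $10^{-3}$. It
trains in a few seconds on one CPU for a ~400-spot slide and reliably
separates layers on synthetic slides. `train_config("paper")` keeps the
optimizer settings used at full scale on real slide datasets — margin
$10^{-3}$, 1000 epochs, batch 768, learning rate 0.05, momentum 0.9,
weight decay $10^{-4}$, a three-layer 2048-wide head — on a wider feature
bank; it is a setting for real data, not something the examples or tests
run. Distances are mean squared error during training and Euclidean for
graph weights and alignment, matching the two roles the distances play.

Triplet sampling excludes the anchor *and its neighbors* from the
negative pool, so a sampled negative can never be a legal positive (a
safeguard the loosest reading of "all other tiles" would not give).
Anchors and positives are always drawn within a slide; with a list of
grids, negatives are drawn across the pooled dataset, and tile
standardization statistics can likewise be pooled (`tile_stats()` on a
list) or computed per slide — the `stats` argument of
`normalize_tiles()` makes the scope explicit and lets inference reuse
the training statistics exactly (persisted via `write_tile_stats()`).

## Numerical and convention choices

* **Indexing.** Path indices, assignment levels and segment labels are
  1-based throughout, following R convention.
* **Logarithm.** Count normalization uses the natural log, the standard
  in the single-cell normalization this transform mirrors.
* **Average count per spot.** The normalization denominator is the
  average *total* count per spot (all genes summed), the standard
  library-size reading; it makes the transform invariant to global
  rescaling of the raw counts.
* **Tile geometry.** Tile side is `round(diameter)`; the tile's top-left
  corner sits `floor(side/2)` pixels up-left of the (0-based) spot
  center, so extraction is bit-exact for odd and even sides alike.
* **Dijkstra tie-breaks.** Ties on total cost are broken by fewest
  spots, then by the lexicographically smallest barcode sequence —
  shortest paths are therefore reproducible across runs and platforms.
  Zero-weight edges (identical embeddings) are legal; no epsilon floor
  is added.
* **Assignment tie-break.** The earliest path index wins, which is
  stable and orientation-respecting; a path spot is always assigned to
  itself because its self-distance is exactly zero (enforced against
  floating-point drift in the distance expansion).
* **Depth quantization.** External per-spot scalar depths are rounded
  half-away-from-zero and re-indexed to consecutive levels; linear
  spacing is assumed at length normalization (`spacing = "cost"` offers
  weight-proportional spacing for traversals where that matters).
* **Boundary crossings.** Segmentation uses a half-open convention: the
  first path index lying on boundary $l$ *starts* layer $l+1$. Only
  first crossings count; re-entering an earlier boundary after a later
  one has been crossed is ignored, while meeting a later boundary before
  an earlier one is an annotation error. A consequence (deliberate, and
  shared with any one-spot-thick boundary convention) is that an
  assignment set spanning a boundary follows its path tile's run.
* **Confidence band.** The 95% band uses the normal approximation
  $\pm 1.96\,\mathrm{sd}/\sqrt{n}$; at $n = 1$ the sd is undefined and
  the band is omitted rather than drawn at zero width.
* **Unequal edge lists.** When the start and end edges of a pair pool
  have different lengths, the end-window is centered at the
  proportionally scaled index — the natural generalization of the
  "opposite spot" pairing, which assumes equal lengths.
* **Spearman ties.** Average ranks (the standard convention); constant
  inputs raise an explicit undefined-correlation error instead of
  returning `NA`.

## The synthetic study conditions

Real layered tissue sections from the platform this package targets are
not redistributable, so the package carries a simulator
(`make_layered_slide()`, with `simulate_study_slide()` as the reference
configuration) that generates the situation the method assumes:

* **Geometry.** Contiguous, approximately equal-width straight bands of
  spots perpendicular to the layer axis — the stacked-layer architecture
  of the evaluation tissue. Curved or fragmented morphologies are not
  simulated.
* **Image.** Each layer renders with its own base color, an oriented
  striped texture (because cell *orientation*, not just color,
  distinguishes otherwise-similar layers such as inner and outer smooth
  muscle), and Gaussian pixel noise. Stripes are drawn in absolute slide
  coordinates so texture is continuous across adjacent tiles, as in a
  real stained section.
* **Counts.** Poisson at layer-specific per-gene means — the minimal
  count law, sufficient to exercise normalization and averaging. Real
  data are sparser and overdispersed; nothing downstream assumes the
  count law, but passing tests on Poisson data demonstrates the
  machinery, not robustness to real-data noise.
* **Reference configuration.** 20×20 grid (400 spots), spot diameter 12
  px, 3 layers, 20 genes; gene 1 marks layer 1 (expected counts 100, 10,
  1 across layers), gene 20 marks layer 3 (1, 10, 100), the rest have
  moderate layer-shuffled means drawn once from U(5, 30). These sizes
  keep a full train-traverse-align-segment cycle in seconds while
  leaving ~130 spots per layer, enough for stable layer statistics.

All randomness flows from one integer seed; identical inputs give
bit-identical slides. `make_boundary_annotations()` derives the
one-spot-thick boundary sets from the truth labels, standing in for a
pathologist's boundary annotation.

What synthetic success does **not** show: robustness to stain variation,
faded eosin, tissue folds, or visually similar adjacent layers — the
known failure modes of appearance-based alignment on real slides.
Augmentation (flips/rotations) is deliberately not offered: orientation
is informative here, and augmenting it away degrades alignment.

## What the checks compute

The test suite verifies each stage against independent oracles: Dijkstra
against exhaustive simple-path enumeration (and an independent graph
library) on all lattices up to 4×4; the count transform, triplet loss,
Spearman $\rho$ and ARI against closed-form hand computations; exact
conservation laws (assignment sets partition the spots; the
size-weighted trajectory rows reconstruct every gene's global mean to
$10^{-10}$; length-normalized endpoints equal the path endpoints
exactly); and, on the reference synthetic slide with the small encoder,
recovery of the planted structure — within-layer embedding distances
below between-layer distances, segmentation ARI against truth of at
least 0.7, a declining layer-1 marker trajectory
($\rho \le -0.8$ against position), and median pairwise trajectory
concordance above 0.5 across 12 sampled anchor pairs.
`scripts/acceptance.R` recomputes these quantities from scratch for any
seed.

## Limitations

* The embedding is appearance-based: layers that look alike (or differ
  only in features the small feature bank misses) can be aligned
  together; patches of misaligned tissue are possible and visible as
  noisy segment boundaries.
* Anchors remain user input. The pair-pool machinery quantifies
  sensitivity to that choice but does not remove it, and building the
  pool requires knowing the tissue orientation.
* Dijkstra returns one optimal path; branched or multi-anchor traversals
  are out of scope, as is any smoothing of the returned path.
* The trajectory is an average over assignment sets of varying size;
  `set_sizes` is exposed so users can judge how much support each
  position has.
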