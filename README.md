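# sttraverse

Histology-anchored traversal and alignment of spatial transcriptomics.

## What it is for

Visium-style spatial transcriptomics pairs a spot × gene count matrix
with an H&E image of the section. In layered tissues (gut wall, cortex),
the scientifically useful axis is *depth through the layers*, but
defining that axis from expression — and then modeling expression along
it — is circular, and manual pathologist annotation is expensive. This
package builds the axis from the histology image alone. The user picks
two anchor spots on the outer layers; the package learns a spatially
aware tile embedding, traverses the spot lattice between the anchors,
and projects the whole slide onto that one-dimensional path, yielding
gene expression trajectories that can be averaged and compared across
samples. It is aimed at anyone analyzing layered Visium sections who
wants expression-vs-depth curves without per-slide manual segmentation.

## The method

With spots $S$ on a hexagonal lattice (neighbors at array offsets
$(0,\pm2), (\pm1,\pm1)$), tile embedding function $f$, anchors
$a, b \in S$:

1. Train $f$ with triplet loss on spot-centered tiles:
   $L = \max(0,\, m(f(a),f(p)) - m(f(a),f(n)) + \alpha)$, positive $p$
   a lattice neighbor of the anchor, negative $n$ any other tile,
   $m$ = mean squared error, margin $\alpha = 10^{-3}$. Counts are
   normalized per slide as
   $\tilde X_{s,g} = \ln(1 + t X_{s,g} / (\Sigma X/|S|))$, $t = 10^4$;
   tiles are standardized per channel over the dataset.
2. Weight each lattice edge by $\lVert f(s_i) - f(s_j)\rVert$ and find
   the shortest path $P^* = \arg\min_{P \in \mathcal P_{a\to b}}
   \sum_i W_{i,i+1}$ (Dijkstra; ties broken by fewest spots, then
   lexicographically).
3. Assign every spot to its nearest path tile,
   $C(s) = \arg\min_{p\in P^*} \lVert f(s) - f(p)\rVert$, and average
   $\tilde X$ within each assignment set $S_p$ to get the trajectory
   $\hat X_{p,g}$ ($k \times |G|$).
4. Length-normalize: position $(i-1)/(k-1)$, linear interpolation at
   every 0.01, giving $\bar X$ ($101 \times |G|$), comparable across
   samples.

Consistency tooling: sampling of "reasonable" anchor pairs and
trajectory averaging with 95% confidence bands, Spearman rank
concordance between trajectories, quantization of an alignment into
discrete layers at annotated boundary crossings, and the adjusted Rand
index against manual labels. A synthetic layered-slide simulator with
known ground truth makes the whole pipeline testable end to end.

## Worked example

```r
library(sttraverse)

slide <- simulate_study_slide(seed = 1)       # 3 layers, 400 spots, 20 genes
g <- slide$grid
lefts  <- g$barcode[g$array_col <= 1]                      # left tissue edge
rights <- g$barcode[g$array_col >= max(g$array_col) - 1]   # right tissue edge

fit <- sttraverse(slide$image, g, slide$counts,
                  start = lefts[10], end = rights[10],
                  config = train_config("small", epochs = 30, seed = 1))
summary(fit)
#> Histology-anchored traversal fit
#>   400 spots, 20 genes; path of 21 tiles, cost 34.6338
#>   training loss: 0.1316 -> 0.007712 over 30 epochs
#>   assignment set sizes:
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max. 
#>    4.00    7.00   14.00   19.05   26.00   67.00 
```

The path runs 21 spots from the left anchor to the right one; every one
of the 400 spots is assigned to one of those 21 path tiles (set sizes
above), and the trajectory matrix holds the mean normalized expression
per path tile. Scoring the alignment against the simulator's ground
truth:

```r
seg <- segment_from_path(fit$assignment, make_boundary_annotations(slide))
adjusted_rand_index(seg$labels, slide$truth_labels)
#> [1] 0.8351119
spearman_concordance(fit$normalized$values[, "gene001"], fit$normalized$positions)
#> [1] -0.8961677
```

The boundary-quantized segmentation recovers the three planted layers
(ARI 0.84 against truth), and the layer-1 marker gene declines almost
monotonically along the traversal (rank correlation −0.90 with path
position). `plot(fit)` draws the length-normalized trajectories.

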