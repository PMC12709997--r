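---
title: "Algorithmic root traits: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Algorithmic root traits: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootart)
```

## The problem and the model

Conventional root-image pipelines summarise a segmented root system with
global morphometrics (total length, mean diameter, depth, volume). Those
numbers say little about *where* a plant concentrates its root mass. Under
water deficit, plants that position dense root clusters in wetter soil
strata tend to fare better, so the location and size of the largest dense
cluster is itself a phenotype worth measuring.

`rootart` treats a binary segmented root image as a point cloud of root
pixels and asks nine different clustering procedures the same question:
*where is the largest dense cluster, and how big is it?* Each algorithm
answers through its own mathematical lens — density connectivity, mixture
posteriors, mode seeking, superpixel tiling, kernel-density-guided
partitioning — and each answer becomes three traits:

* `<Algorithm>_density_points` — pixel count of the largest cluster,
* `<Algorithm>_centre_x`, `<Algorithm>_centre_y` — its centroid in image
  pixels (x = column, y = row, origin top-left, 0-based).

Nine algorithms times three traits gives the fixed 27-column trait block.
The column naming is a contract: downstream grouping (algorithm-level
permutation importance, ablation) parses it.

The algorithms and their defaults:

| Algorithm  | Family                | Key settings                          |
|------------|-----------------------|---------------------------------------|
| DBSCAN     | density-based         | `eps = 5`, `min_samples = 10`         |
| GMM        | soft partitioning     | `n_components = 2`, full covariance   |
| K-means    | hard partitioning     | `n_clusters = 5`, 10 k-means++ starts |
| HDBSCAN    | hierarchical density  | `min_cluster_size = 10`               |
| Mean-shift | mode seeking          | bandwidth quantile `0.1`              |
| OPTICS     | density ordering      | `min_samples = 10`, `xi = 0.05`       |
| SLIC       | superpixels           | `n_segments = 50`, compactness 10     |
| FCM        | fuzzy partitioning    | 5 clusters, fuzzifier 2, 10 starts    |
| Custom     | KDE-guided K-means    | 200-pixel cap, up to 5 clusters       |

The custom procedure runs in six steps: identify all root pixels; if more
than 200 exist, keep the 200 most locally dense (a pixel's local density is
the count of root pixels in its 3x3 neighbourhood, itself included; ties at
the cut break in row-major order so the step is deterministic); fit a
Gaussian kernel density estimate on the kept pixels (Scott's rule
bandwidth) and evaluate it at each pixel to obtain weights; run weighted
K-means with `min(5, number of distinct pixels)` clusters, weights entering
as sample weights; take the largest cluster by member count; report its
size and centroid. If all selected pixels coincide they form one cluster at
that coordinate.

Failures never raise: an extractor that cannot run reports
`insufficient_pixels` (too few points for its minimum) or `no_cluster`
(all points noise, or a degenerate fit), and its three traits carry `NA`.
`NA` — never zero — is the missing sentinel, because zero is a legal
coordinate.

## Implementation notes on the clustering ensemble

DBSCAN, HDBSCAN, OPTICS, mean-shift and SLIC are implemented inside the
package (grid-binned fixed-radius search, chunked k-nearest-neighbour
distances, and a linear-memory Prim spanning tree keep them comfortable at
the default subsampling cap). GMM fits come from `mclust`, fuzzy C-means
from `e1071`, and the graph components inside DBSCAN from `igraph`.
Numerical choices that required a decision:

* **HDBSCAN** condenses the single-linkage hierarchy of mutual-reachability
  distances at `min_cluster_size` and selects clusters by excess of mass;
  the root is never selected, so a dataset that never splits is all noise.
* **OPTICS** extracts steep-area (`xi`) clusters from the reachability
  profile. A terminal sentinel closes a cluster running to the end of the
  ordering, the full-span root segment is discarded (the analogue of
  HDBSCAN's root rule), and nested clusters resolve to their innermost
  (leaf) segment, the conventional labelling. On perfectly uniform pixel
  discs larger than a few hundred pixels, leaf labelling can subdivide the
  disc at quantisation-scale steepness; real root clusters have density
  gradients and are much less prone to this.
* **Mean-shift** uses the flat kernel, the quantile bandwidth estimate
  (mean distance to the `floor(n * quantile)`-th neighbour), bin seeding
  beyond 2000 points, and assigns every point to its nearest surviving
  mode — it has no noise class.
* **SLIC** runs on the binary image with intensities mapped to 0/100, so
  superpixel boundaries adhere to the root/background edge; the superpixel
  containing the most root pixels wins and only its root pixels enter the
  centroid.
* **K-means and FCM** are restarted 10 times (k-means++ seeding for
  K-means, random distinct centres for FCM) and the best objective is
  kept; single-start fuzzy C-means otherwise lands in local optima often
  enough to split an obvious dominant cluster.
* **Ties** anywhere resolve deterministically: the largest-cluster rule
  breaks ties towards the smallest label, density selection breaks score
  ties row-major.

Masks larger than `subsample_cap` root pixels (default 20 000) are
represented by a seeded uniform subsample of exactly that many pixels; the
cap is constant per run and recorded in the provenance, keeping
`density_points` comparable across images of one run.

## What the synthetic generator emulates

`simulate_root_mask()` plants discs, ellipses or ragged (randomly eroded)
blobs of exactly known pixel count and centre, optionally over 1-pixel
random-walk strands (fine roots that must not dominate dense-cluster
detection) and sparse speckle. The reported truth is always recomputed
from the emitted grid, never assumed from the request. It does **not**
emulate soil occlusion, intensity noise, segmentation artefacts or root
thickness variation — passing the planted-truth suite shows the extractors
recover unambiguous dense clusters, not that segmentation errors are
survivable.

The planted-truth recovery property is checked in the regime where the
dominant cluster is unambiguous under *all nine* lenses at once: five
well-separated blobs (centres ~100 px apart on a 200 x 200 canvas), minor
blobs of 10-15 px (at or above the density minimum cluster size so none is
absorbed as stray mass), and a dominant blob of 70-110 px. Outside that
regime individual algorithms legitimately disagree: a k = 5 partitioner
will split a single very large uniform mass (so will fuzzy C-means, which
additionally prefers balanced clusters), and a two-component mixture will
pool minor blobs once they jointly outweigh the dominant one. Those are
properties of the algorithms, not defects; the trait table records each
lens faithfully.

Test and acceptance runs use deliberately small problem sizes — 50 masks of
200 x 200 px for recovery, 500 null simulations of 20 x 10 matrices for
PERMANOVA calibration, 10 replicates of 120-row tables for the classifier
null — sizes chosen so the whole suite runs in minutes on one core while
keeping Monte-Carlo error well inside the asserted bands.

## Comparing trait sets

`internal_variability()` and `permanova_features()` treat *features as the
units*: each feature column is z-scored across samples, and Euclidean
distances between feature columns are analysed. This is the reading under
which a 27-trait set and a 23-trait set each yield a population of
feature-pair distances, and under which a PERMANOVA grouping by trait-set
label (labels attach to features, not samples) is coherent. Z-scoring
first is an interpretation we make explicit: without it, features with
large raw units would dominate every distance. A consequence worth
remembering: a pure mean shift between two groups of columns vanishes
under column z-scoring; what the test detects is differing correlation
structure.

The PERMANOVA pseudo-F comes from the standard distance decomposition
(total minus within-group sums of squared distances over group sizes); the
p-value uses the add-one permutation estimator, or exact enumeration of
all relabellings (`method = "exhaustive"`) for small two-group instances.
Rows with missing trait values are dropped before distance computations
(the policy is logged); imputation is deliberately not silently applied.

PCA and MDS ordinations are thin wrappers over `prcomp` and `cmdscale`.
No t-SNE backend is installed with the package's dependency set, and
re-implementing t-SNE is out of scope, so `ordinate(method = "tsne")`
raises an informative error instead of silently substituting MDS.

## Ranking genotypes for drought response

For genotype *i* and physiological trait *j* (stomatal conductance at two
dates, relative water content, tiller number), all computed on 10 %
trimmed means `M` (per tail, `floor(0.1 n)` observations dropped):

* Robust Difference: `RD_ij = |M_ij,control − M_ij,drought|`
* Robust Stress Susceptibility Index: `SSI_ij = 1 − M_ij,drought / M_ij,control`

Within each trait, genotypes are ranked ascending (smaller response = more
tolerant = rank 1, average ranks on ties), then combined as weighted rank
sums with weights 2 for the conductance traits and 1 for RWC and tiller
number: `RANK1 = Σ_j rank(RD) w_j`, `RANK2 = Σ_j rank(SSI) w_j`,
`RANK3 = RANK1 + RANK2`. Lower scores mean higher tolerance. Negative SSI
(improvement under drought) is retained, not clipped; a zero control mean
makes SSI undefined (`NA`, warned). No published numeric example exists
for the rank scores, so their tests are property-based: the RANK3
identity, permutation-of-ranks structure, weight-scaling linearity and
order invariance.

Group comparisons gate on per-group Shapiro-Wilk at 0.05: all groups
normal leads to one-way ANOVA with Tukey's HSD, anything else to
Kruskal-Wallis with Dunn's post-hoc (rank-sum z statistics with tie
correction, Holm adjustment — implemented in-package as no installed
package provides it). Groups under 3 observations skip the normality test
and force the nonparametric branch; the report records which branch fired.
Effect sizes use Cliff's delta by full pair enumeration — the enumeration
*is* the definition, so the test oracle is an independent double loop.

Genotype clustering runs K-means, Ward agglomeration, a Gaussian mixture,
spectral clustering and a compact BIRCH (threshold-based cluster-feature
absorption in input order, then Ward merging of CF centroids; threshold
0.5 on the z-scored scale) to two groups each, with internal validation
(silhouette, Dunn, Calinski-Harabasz, Davies-Bouldin) and, against
reference labels, ARI / NMI / Fowlkes-Mallows. Individual algorithm
failures are recorded per algorithm and do not stop the rest.

## The classification framework

Development data are doubled by bootstrap-plus-noise augmentation: `n`
bootstrap rows join the `n` originals, each perturbed by Gaussian noise
with σ = 0.02 *on the z-scored feature scale* (about 2 % of a feature's
spread, mapped back to raw units — the scale interpretation is ours and is
configurable). Originals are never altered and synthetic rows carry a
provenance flag. The stratified split takes `ceiling(0.2 n)` test rows,
allocated by largest remainder, which reproduces the 1388/348 arithmetic
at n = 1736.

The pipeline has three stages — z-scoring, feature selection (keep
features whose impurity importance under an auxiliary random forest is at
least the mean importance), and the main random forest — with stages 1-2
recomputed inside every training fold, so no held-out statistic reaches
the model. Hyperparameters come from an exhaustive grid (default: trees
100/300/500, depth unlimited/10/20, minimum node size 1/5) under
stratified 10-fold cross-validation optimising precision; per-metric fold
dispersion is reported as CV% (100·sd/mean) with a 95 % t-interval.
Confusion-matrix metrics use the fixed 0.5 threshold; ROC AUC, cumulative
gain and lift come from the predicted probabilities. Independent
validation can be guarded by a row-hash audit that refuses evaluation rows
whose feature vectors occur in the audited development table.

Importance is permutation-based: per feature, or per algorithm (an
algorithm's three trait columns shuffled together, preserving the
within-row coupling of everything else). Ablation refits the pipeline
without each algorithm's columns in turn, or restricted to a candidate
core subset. The `information_density()` summary is plain accuracy per
feature. The `baseline_total_pixels()` control collapses each mask to its
root-pixel count and runs the identical pipeline — classes that differ
only in cluster *position* defeat it while the full trait model separates
them, which is the cleanest demonstration that the traits carry spatial
information beyond size.

## Known limitations

* The extractors assume a reasonably clean binary segmentation; they do
  not correct segmentation errors and treat every foreground pixel alike.
* OPTICS leaf labelling can fragment very large perfectly uniform masses
  (see above); HDBSCAN and DBSCAN are the more stable density lenses
  there.
* The compact BIRCH is order-dependent by construction (as CF absorption
  always is); with few observations the other four genotype-clustering
  algorithms are usually preferable.
* PERMANOVA on feature columns detects correlation-structure differences,
  not mean shifts (removed by z-scoring) — this matches its use for
  comparing trait *sets*, not samples.

## A minimal end-to-end example

```{r example, eval = FALSE}
sim <- simulate_root_mask(
  200, 200,
  blobs = data.frame(
    centre_x = c(50, 150, 50, 150, 100),
    centre_y = c(50, 50, 150, 150, 100),
    n_pixels = c(90, 15, 12, 11, 10)
  ),
  seed = 1
)
traits <- extract_all(sim$mask, seed = 1)
traits[, c("DBSCAN_density_points", "DBSCAN_centre_x", "DBSCAN_centre_y")]
attr(traits, "statuses")
```
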