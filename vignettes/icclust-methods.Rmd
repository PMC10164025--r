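---
title: "Clustering IC topographies with icclust: model, algorithm and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering IC topographies with icclust}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icclust)
```

## The problem

Independent component analysis (ICA) decomposes multi-channel EEG into
maximally independent source signals. Each component is characterized
spatially by one column of the inverse mixing matrix — its *scalp map* or
topography. Comparing components across subjects is done by clustering
these maps, but two properties rule out ordinary Euclidean clustering:

* **Scale is arbitrary** — ICA fixes each component only up to an
  amplitude factor, so only the *pattern* of channel loadings matters.
* **Polarity is arbitrary** — each component may come out sign-flipped
  (the sign ambiguity), so a map and its negation are the same source.

The natural similarity between two maps is therefore the **absolute
Pearson correlation** \(|r_{ij}|\) of their channel loadings
(`compute_correlation_matrix()`, `to_similarity()`). Everything in this
package — pre-clustering, the fitness that drives the genetic refinement,
centroids and validity indices — is built on this similarity instead of a
distance.

## Pipeline overview

`cluster_ics()` composes four stages:

1. **Similarity graph.** \(J = |R|\), the elementwise absolute correlation
   matrix, read as a weighted graph over components. The unit diagonal
   (self-loops) is kept: it is part of the definition of \(J\) and only
   shifts all degrees equally.
2. **Spectral pre-clustering** (`precluster()`). The symmetric normalized
   Laplacian \(L = I - D^{-1/2} J D^{-1/2}\) is formed, its `k`
   eigenvectors with smallest eigenvalues are stacked as columns of
   \(U \in \mathbb R^{n\times k}\), rows of \(U\) are normalized to unit
   length, and k-means groups the rows. Every component receives a
   cluster at this stage — the outlier pool starts empty.
3. **Clustering genetic algorithm** (`run_cga()`). An elitist,
   mutation-only search over partitions that maximizes the local-density
   quality index \(\widehat{QI}\) and adapts the number of clusters and
   the outlier ("others") pool.
4. **Validity report** (`cvi_report()`): \(QI\), \(\widehat{QI}\),
   silhouette, inverted Davies–Bouldin, optionally the eye-set
   concordance \(RI_m\), plus cluster/outlier counts.

## Polarity and centroids

Averaging a cluster into a centroid first requires aligning polarities.
A sign vector \(s \in \{-1,+1\}^m\) is scored by the total absolute
correlation carried by pairs whose imposed relation \(s_i s_j\)
contradicts the observed sign of \(r_{ij}\):

\[\mathrm{cost}(s) = \sum_{i,j} \tfrac12 |s_i s_j - \mathrm{sgn}(r_{ij})|\,|r_{ij}|
 = \tfrac12\Big(\textstyle\sum_{ij}|r_{ij}| - s^\top R\, s\Big).\]

The second form (an algebraic identity, property-tested in the suite)
shows the problem is a \(\pm1\) quadratic maximization, akin to max-cut.
Template-based polarity assignment — take one map as reference and flip
everything negatively correlated with it — can fail badly when the
reference correlates weakly with part of the cluster;
`toy_correlation_matrix()` is a 4-component instance where the template
choice costs 2.4 while the global optimum costs 0.2.

Two solvers are provided:

* `solve_polarity_brute()` enumerates the \(2^{m-1}\) canonical sign
  vectors (first entry fixed +1). It is the oracle and the default for
  clusters of up to 15 members.
* `solve_polarity_ga()` for larger clusters: population 20, uniform
  crossover at rate 0.8, per-gene flip mutation at rate \(1/m\), at most
  200 generations with a 50-generation stagnation stop. The population is
  seeded with the all-ones vector, random vectors, and a greedy seed that
  propagates signs breadth-first over the maximum-\(|r|\) spanning tree
  (an edge's sign tells whether its endpoints agree). The incumbent is
  polished each generation by a greedy single-flip descent, which the
  quadratic identity makes \(O(m)\) per flip test. The memetic step is
  what makes the solver reliably match the exhaustive optimum on weakly
  correlated (hardest) instances; on 50 random 12-component instances it
  attains the exact minimum in 96% of cases and never reports a value
  below it.

Centroids (`compute_centroid()`) are means of RMS-normalized,
sign-corrected member columns, so each member contributes equal energy
and polarity flips do not cancel the average. Whether member maps should
be RMS-normalized before averaging is an interpretation we adopt for all
centroids; it only changes member weighting, not polarity handling.

## Validity indices on the correlation scale

All indices treat \(|r|\) as similarity; several classical definitions
are adapted accordingly.

* \(QI_c\) (per cluster): 100 × (mean within-cluster similarity − mean
  similarity to *all* other components, outliers included). \(QI\) is the
  size-weighted average with weights \(|C_m|/n\). Because outliers carry
  no weight, the weights of a partition with a populated others pool sum
  to less than one — over-use of the outlier pool is penalized by
  construction.
* \(\widehat{QI}\): as \(QI\) but each cluster's between term averages
  only its \(|C_m| \cdot F_c\) **largest** outside similarities (capped at
  the number available; default \(F_c = 10\)). A cluster is thus judged
  against its nearest neighbours — a local-density criterion. This is the
  GA fitness. When \(F_c\) covers all between pairs,
  \(\widehat{QI} = QI\) exactly (a test pins this limit).
* **Silhouette**: \(s_i = (a_i-b_i)/\max(a_i,b_i)\) with \(a_i\) the
  average similarity to the rest of the own cluster and \(b_i\) the best
  average similarity to another cluster. The \(a_i\) average divides by
  the full cluster size \(|C_m|\) — kept exactly as defined for this
  method even though the conventional divisor is \(|C_m|-1\); the
  `denominator = "standard"` switch restores the convention. Outliers are
  excluded from the average `sh_index()`.
* **Inverted Davies–Bouldin**: compactness \(d_m\) is the mean member-to-
  centroid \(|r|\); separation is the centroid-to-centroid \(|r_{MN}|\);
  \(DB_m = \max_{n\ne m} |r_{MN}|/(d_m+d_n)\) and \(DB\) is their mean.
  The ratio is inverted relative to the classical index because large
  values mean "close" here; smaller \(DB\) is better and orthogonal
  centroids give 0. Centroid polarity uses the exact solver up to the
  brute cap, so the index is deterministic.
* \(RI_m\) (`rim_index()`): with a reference eye set \(C_{eye}\) from an
  external classifier, \(RI_m = |C_{eye}|\sum_{C_i \cap C_{eye} \neq
  \emptyset} 1/|C_i|\) over the partition's clusters. It is 1 when one
  cluster equals the eye set and 0.5 when the set is absorbed into a
  cluster twice its size. The sum is deliberately not clamped: when the
  eye set fragments across many small clusters the index exceeds 1. This
  follows the index's definition as given; the package documents rather
  than "fixes" it.

**Singleton clusters** have no within pairs, so \(QI_c\) is undefined for
them. The pipeline folds size-1 clusters into the others pool before any
scoring; called directly on a singleton, `qic()` returns 0 with a
warning.

## The clustering GA

The search state is a single partition (integer encoding, label 0 =
others). Each iteration draws `n_children` components uniformly (with
replacement) and applies one mutation each to a copy of the seed:

* outlier drawn — **merge** (probability `alpha`): pair with the most
  similar fellow outlier into a new 2-cluster; otherwise
  **agglomerative**: join the cluster with the closest centroid. Merge
  falls back to agglomerative when no other outlier exists.
* clustered component drawn — **split** (probability `beta`): demote to
  the others pool; otherwise **move**: reassign to the cluster with the
  closest centroid.

Children are scored by \(\widehat{QI}\) and the best of seed and children
is the next seed, so the fitness history is non-decreasing by
construction (asserted in the tests). The run stops at `max_iter`
iterations or after `delta_iter` iterations without strict improvement.

Design choices that were genuinely open:

* **Closeness is always absolute correlation**, never Euclidean distance
  — consistent with the similarity measure everywhere else.
* **Leave-one-out own-centroid scoring in *move*.** A member's own
  centroid contains the member, which biases "closest centroid" toward
  the status quo; with self-inclusion the move operator degenerates to a
  near-no-op and partitions seeded with too many clusters cannot
  consolidate. The own-cluster similarity is therefore computed against
  the centroid with the member algebraically removed (cheap, since the
  cached centroid is a mean). A component whose own cluster is genuinely
  closest is still left in place.
* **Incremental fitness.** A child differs from its seed in one
  component's assignment, which changes the \(\widehat{QI}_c\) terms only
  of the clusters it left or joined (the outside set of any other cluster
  is unchanged as a set). Per-cluster terms are reused accordingly; a
  test asserts the incremental score equals a from-scratch recomputation.
* **Centroid memoization** keyed by the member set; exact polarity up to
  15 members (`brute_polarity_cap`), genetic solver above.
* **Determinism**: one root seed drives a single RNG stream consumed in a
  fixed child order, so identical seeds give byte-identical outputs; the
  k-means attempts and the polarity GA use seeds derived from the root.
* **Tie-breaking**: equal centroid or outlier similarities resolve to the
  lowest label/index.
* k-means itself is `stats::kmeans` (Hartigan–Wong) with 10 restarts
  under a derived seed — a standard, well-tested implementation is
  preferred over a bespoke seeding scheme; degenerate runs (empty
  cluster) are retried with fresh derived seeds.

## The synthetic generator

`generate_ic_set()` emulates a pooled multi-subject inverse-weight
matrix: `k` prototype maps (random Gaussian channel vectors,
QR-orthogonalized and re-noised so pairwise \(|r| \le 0.3\), unit channel
variance), cluster members = prototype × random polarity flip + i.i.d.
Gaussian channel noise, and pure-noise outlier columns. Defaults mirror
the reference conditions: 31 channels, 155 components, six planted
clusters, 8 outliers (~5%), `noise_sigma = 0.33` so the expected
within-cluster similarity is \(1/(1+\sigma^2) \approx 0.9\), and flip
probability 0.5 (maximal sign ambiguity).

What the generator does **not** emulate: biophysically realistic scalp
maps (no dipole or leadfield model), spatial channel correlation
structure, heterogeneous cluster tightness, or near-duplicate components
within one subject. Tests passing on this generator therefore establish
algorithmic correctness and recovery under idealized separation, not
performance on real recordings.

## Observed behavior at the study scale

Two properties of the method show up consistently on the default
synthetic conditions and are worth knowing about; both follow from the
fitness definition, and the test suite reports them honestly rather than
papering over them:

* **Chance outlier pairs can become clusters.** Among 8 independent
  noise columns in 31 channels the most similar pair reaches
  \(|r| \approx 0.45\) by chance, which can exceed the mean of the pair's
  top-\(|C_m| F_c\) between similarities; forming that 2-cluster then
  *increases* \(\widehat{QI}\) (outliers carry no weight). Recovered
  cluster counts on the defaults therefore tend to planted + 1 or + 2.
* **Tight merged clusters resist splitting from below.** If the
  pre-clustering merges two well-separated planted clusters (k chosen too
  small), the first single-component split step adds many high
  correlations to the cluster's top-between term and is strictly
  fitness-decreasing; an elitist single-mutation hill climb cannot cross
  this barrier, so runs seeded two or more clusters short stall below the
  planted structure. Seeding k at or above the expected count is the
  reliable regime — consolidation from above works well (the
  leave-one-out move repair above is what enables it).

## Numerical choices

* Correlation matrices are symmetrized as \((M+M^\top)/2\) and clipped to
  \([-1,1]\); symmetry/diagonal assertions use tolerance \(10^{-9}\).
* \(\mathrm{sgn}(0)\) is defined as +1 in the polarity cost; a zero
  correlation contributes zero weight either way.
* Laplacian eigenvalues are computed with the dense symmetric solver
  (problem sizes are a few hundred at most); near-zero detection uses
  threshold \(10^{-8}\).
* Stagnation counts iterations without *strict* improvement (no
  epsilon).
* Files are written with 15 significant digits, so round trips are exact
  to \(\sim10^{-15}\) and repeated runs diff cleanly.

The test suite exercises the full pipeline at a reduced scale chosen to
keep the default run fast: synthetic recovery uses 155 components with
`max_iter = 1000` (the search converges in a few hundred iterations
under these conditions), and oracle comparisons use instances of up to 30
components where exhaustive enumeration is exact.

## Limitations

* The GA is a hill climb in partition space: it refines and consolidates
  but cannot cross fitness barriers (see above); the quality of the
  spectral seed matters.
* \(RI_m\) requires externally supplied labels and is reported only when
  an eye set is given.
* No EEG time-series or EEGLAB file handling: the package starts from a
  numeric inverse-weight matrix and metadata table.
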