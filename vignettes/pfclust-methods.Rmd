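---
title: "Parameter-free clustering of similarity matrices: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parameter-free clustering of similarity matrices: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfclust)
```

## The model

`pfclust` partitions n elements described only by a symmetric pairwise
similarity matrix S (higher values = more similar; any finite real scale).
The central object is a cluster's similarity distribution: for a member set
C with |C| = m ≥ 2, the expectation value

$$E(C) = \binom{m}{2}^{-1} \sum_{i<j \in C} s(i,j)$$

is the mean over all unordered member pairs. Diagonal entries of S are
never used: self-similarity is degenerate and only pairs of distinct
elements carry information. A partition is *admissible at threshold T*
when every cluster with two or more members satisfies E(C) ≥ T. The
algorithm's promise of being parameter-free rests on deriving candidate
values of T from S itself and letting a validity index choose among the
resulting clusterings.

## Threshold estimation

One round of estimation randomly splits the n elements into clusters and
records E(C) for every random cluster with at least two members; the
default is 1000 rounds. Candidate thresholds are then drawn from the top
5% of the recorded distribution.

Two details of the randomisation matter and were fixed after explicit
experimentation (both are `pfclust`'s own design decisions; the procedure
is stated in the literature only as "randomly split, record the
expectation values"):

* **Granularity of the random splits.** The cluster count is drawn
  uniformly from {2, …, ⌊√n⌋} and the cluster *sizes* are a uniform random
  composition of n (k − 1 distinct cut points), rather than assigning each
  element independently. Independent assignment makes all random clusters
  about the same size n/k; the mean of thousands of pair similarities then
  concentrates tightly around the global mean similarity, the recorded
  distribution has almost no upper tail, and no candidate threshold can
  ever demand more cohesion than an arbitrary merge — the algorithm
  degenerates to one giant cluster. Random compositions routinely produce
  very small clusters (pairs, triples) alongside large ones at every n;
  small random clusters that happen to fall inside a true cluster record
  E values near the within-cluster similarity, which is precisely the
  upper tail the thresholds must reach. (The test suite checks the
  resulting tail contract directly: every selected threshold sits at or
  above the 95th percentile of the recorded distribution.)

* **Selection from the tail.** The recorded values are sorted once,
  descending; the tail is the top ⌈0.05 · N⌉ values (ties at the boundary
  kept). The 20 thresholds are the observed tail values nearest to 20
  evenly spaced points across the tail's *value range*, minimum and
  maximum always included. Rank-based spacing was tried first and rejected:
  the tail's mass usually sits near its lower boundary, so rank spacing
  can skip a thin but decisive high-similarity band entirely — on a
  many-cluster benchmark the band of thresholds that separates adjacent
  clusters holds only a small fraction of the tail's values, rank spacing
  places at most one threshold there, and adjacent clusters merge. Value
  spacing covers every such band by construction; it is deterministic
  given the random seed, and every threshold is an observed recorded
  mean, at or above the 95th percentile of the recorded distribution.

With default parameters (rounds R = 1000, top fraction 0.05, M = 20
thresholds) the tail always holds at least M values; `estimate_thresholds()`
enforces R ≥ M / top_fraction.

## The clustering engine

`cluster_at_threshold()` is deterministic — all randomness in the pipeline
lives in the estimation step. Three phases:

1. **Seed and grow.** The most similar unassigned pair seeds a cluster if
   its similarity reaches T (otherwise the lowest-index remaining element
   becomes a singleton). Growth repeatedly admits the unassigned element
   with the highest mean similarity to the current members while the grown
   cluster's E stays ≥ T. Because the admission quantity is monotone in
   the candidate's similarity sum, the best candidate failing implies all
   fail, so growth stops at the right moment without scanning further.
2. **Merge.** Cluster pairs are greedily joined, best union first, while
   the union's E stays ≥ T. This repairs the fragmentation that greedy
   seeding can leave behind.
3. **Reassign.** Each element, in index order, moves to the cluster with
   which it has the highest mean similarity — provided the enlarged target
   still satisfies E ≥ T and the diminished source either keeps E ≥ T or
   has fewer than two members left. The incumbent cluster wins exact ties.
   Sweeps repeat to a fixed point, capped at 100 passes (the cap is a
   termination guarantee; reaching it raises a warning and has not been
   observed on real inputs). If the best non-incumbent target is
   inadmissible the element simply stays: no second-best target is tried,
   keeping each sweep O(nk).

Phase 1 admits elements into a large cluster too easily — one far-away
element barely moves the mean of thousands of pairs — and phase 3 is what
repatriates such strays: their mean similarity to their true cluster
exceeds their mean similarity to the absorbing one, and both clusters
remain admissible after the move. The combination, not phase 1 alone,
produces exact recovery on separated data.

Tie-breaking is everywhere "lowest element index, then lowest cluster id",
so results are bit-identical across platforms and schedules. Cluster ids
are renumbered 1..k in order of first appearance after every phase.

**Numerical tolerance.** All admission comparisons use T − 10⁻¹² ·
max(1, |T|) instead of T. Thresholds are themselves recorded means;
summing a value like 0.4 (not representable in binary) across differing
pair counts shifts results by one representation step, and without slack a
threshold can land one ulp above the very similarity it was read from,
flipping a constant matrix from one cluster to all singletons. The slack
is far below any meaningful similarity difference. The silhouette applies
the same guard to its zero-denominator convention.

**Cost.** With k clusters the engine performs O(k n²) similarity lookups
(seeding dominates; growth, merging and reassignment bookkeeping are
incremental). The engine counts its lookups and reports them as an
attribute, which the test suite uses to check the quadratic scaling
empirically. Per-cluster mean/variance summaries are available through
`cluster_stats()`; the variance is reported but never gates admission — no
variance rule is specified in the literature, and inventing one would add
a hidden parameter.

## Model selection

Among the ≤ 20 candidate partitions per round, the winner is the one with
the largest mean silhouette width; ties break to fewer clusters, then to
the lower threshold. The silhouette is computed on the dissimilarity
induced by the similarity matrix, d(i, j) = s_max − s(i, j) with s_max the
largest off-diagonal similarity, giving per element

$$s(i) = \frac{a(i) - b(i)}{s_{max} - \min(a(i), b(i))}$$

with a(i) the mean similarity to own-cluster co-members and b(i) the best
mean similarity to another cluster. Singletons score 0; a single-cluster
partition has no b(i), scores `NA`, and is excluded from selection.

The choice of the induced-dissimilarity form over the naive similarity
ratio (a − b)/max(a, b) is deliberate and was forced by analysis: for a
Gaussian kernel, similarities are multiplicative in squared distance, and
on a symmetric blob layout the ratio form gives the true partition and the
partition that merges two adjacent blobs *identical expected scores* (the
identity w·y = x² for within/adjacent/far similarities w, x, y makes the
comparison a knife-edge that sampling noise systematically tips toward
merging). The induced-dissimilarity form is invariant to the additive
offset of the similarity scale, keeps the full contrast between the true
partition and the merge, and reduces to the classical silhouette when the
input is itself a distance-derived similarity.

## The outer loop

`run_pfclust()` repeats estimation + clustering + selection in rounds. At
least 4 rounds always run; from round 4 on, the loop stops when the Rand
index between consecutive round winners reaches 0.99, and in any case at
10 rounds. The 0.99 criterion and the cap quantify "repeat until the
answer stops changing" reproducibly and guarantee termination; the final
answer is the best candidate across *all* rounds (not the last round's
winner), so a lucky early round is never thrown away. If no round produces
a multi-cluster candidate — e.g. a constant matrix, where every threshold
equals the constant and every clustering is the single all-element cluster
— the single-cluster partition is returned with a warning.

The 20 clusterings within a round are independent and may run in forked
workers (`workers` argument, `parallel::mclapply`); results are collected
in threshold order, so worker count never changes the result, which the
test suite verifies. Duplicate thresholds are clustered once and shared.

All randomness flows from R's global RNG; `run_pfclust(seed =)` seeds it
locally and restores the caller's state. Two runs with the same seed and
configuration are bit-identical.

## Synthetic benchmarks

`generate_blobs()` and `generate_shapes()` produce labelled 2D datasets
with known ground truth; `benchmark_names()` lists a frozen suite of seven
specifications spanning 2–10 clusters and 100–5000 points: Gaussian blobs
(equal and circular layouts), a density-contrast pair (4× spread ratio), a
ring with a central core, and two elongated clusters (axis ratio 10). The
suite emulates the *style* of the 2D-vector benchmarks the algorithm was
originally demonstrated on — their exact composition is not published, so
the suite is a synthetic stand-in, not a reproduction, and agreement
numbers against the original implementation cannot be checked from it.

The default pipeline converts points to similarities with a Gaussian
kernel whose bandwidth σ is the median pairwise distance (the median
heuristic): a scale-free default that keeps the pipeline free of hand-set
parameters. What the generated data do *not* emulate: noise points and
outliers between clusters, similarity matrices that are not derived from
any embedding (e.g. alignment scores), non-metric or noisy similarities,
and cluster overlap beyond what the spread parameters induce. Passing the
benchmark therefore demonstrates correct mechanics and exact recovery on
separated geometric data, not performance on adversarial real data.

Problem sizes in the test suite were chosen to exercise every contract at
the smallest scale that is informative: metric oracles at n ≤ 40 (where
brute force is exact and fast), estimation contracts at n = 200, recovery
at n = 400 over ten seeds, and one full n = 1000 run as a performance
sanity check.

## Known limitations

* **Rings and other non-convex shapes with proximity kernels.** A ring's
  E(C) is low — opposite points are far apart — so no threshold can hold a
  full ring together while splitting off a central core; the ring-plus-core
  suite member is included precisely because the method fails on it with a
  Gaussian kernel (it returns arc fragments instead). This is a property
  of thresholding the *mean* pairwise similarity, not of the
  implementation; recovering such shapes requires a similarity that
  reflects connectivity rather than proximity.
* **Bandwidth sensitivity.** The median-distance σ is a robust default,
  but with many clusters the median pairwise distance is dominated by
  between-cluster distances; recovery then depends on the silhouette's
  offset invariance (see above). A σ chosen badly (orders of magnitude off)
  flattens the similarity distribution and with it the threshold tail.
* **Dense O(n²) storage and O(k n²) time.** A 5000-element matrix holds
  2.5 × 10⁷ doubles (~200 MB); the n = 5000 suite member runs in minutes,
  but the design targets the ≤ 10⁴ range, not millions of elements.
* **Mean-only admission.** Clusters are gated on E(C) alone; the variance
  of the similarity distribution is reported but unused, so a cluster
  mixing a tight core with a loose shell passes as long as the mean holds.
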