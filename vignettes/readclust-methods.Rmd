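---
title: "Two-stage clustering of short metagenomic reads: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage clustering of short metagenomic reads: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Metagenome assembly scales badly because reads from thousands of genomes are
assembled together. A *cluster-then-assemble* strategy first partitions reads
by genome of origin so each cluster can be assembled independently. Overlap
clustering of short reads is precise (clusters are almost always pure) but
deeply under-clustered: one genome shatters into hundreds or thousands of
small clusters, because short reads only certify *local* contiguity.

`readclust` implements a two-stage remedy:

1. **Local stage** — reads sharing sequence seeds are linked into an overlap
   graph and partitioned by label propagation (LPA). This yields many small
   clusters, each covering a contiguous slice of one genome.
2. **Global stage** — for every cluster, the sequencing coverage in each
   sample of a multi-sample dataset is estimated from the cluster's k-mer
   frequency spectrum. Clusters from the same genome have proportional
   coverage profiles across samples (they ride the same abundance
   trajectory), so clusters whose profiles have cosine similarity at or above
   a threshold are linked and merged by weighted LPA.

The package also contains a truth-labeled multi-sample community simulator
and purity/completeness scoring, so the whole method is testable end to end
without any external data.

## Seeds: canonical k-mers and minimizers

All seeds are *canonical*: a window `w` is represented by
`min(w, revcomp(w))` in byte order `A<C<G<T`, so opposite-strand reads share
seeds. In minimizer mode, every k-length window (default `k = 41`) is
represented by the lexicographically smallest canonical m-mer (default
`m = 22`) among its `k - m + 1` constituents; each m-mer is canonicalized
*before* the window minimum is taken, which is what makes minimizer sets
strand-invariant. Windows containing `N` are skipped entirely — the simplest
deterministic rule. Minimizer windowing reuses `k` as the window length, the
interpretation consistent with quoting a single (k, m) pair for the method.

Minimizers compress runs of adjacent shared k-mers into one seed, cutting
the seed table and the edge count several-fold with no practical loss of
sensitivity for reads a few times longer than `k`: two reads sharing an
exact substring of length `2k - m` are guaranteed to share a minimizer.

## Local clustering

Reads are grouped by seed; every seed shared by 2..`max_seed_occurrence`
reads contributes one co-occurrence to each read pair under it. The edge
weight is the number of *distinct* shared seeds, and edges with weight below
`min_shared_kmers` (default 2) are dropped. Two caps control repeat-driven
blowup:

* `max_seed_occurrence` (default 1000) discards seeds present in very many
  reads — repeat masking, and a hard guard against quadratic pair
  generation.
* `max_degree` (default 25) is a per-read edge budget: each read keeps at
  most 25 edges and an edge survives if *either* endpoint keeps it. Kept
  edges are ranked by partner token, which for arbitrary read ids is a
  positionally unbiased subsample of the read's neighbourhood. Ranking by
  weight was evaluated and rejected: the strongest edges are near-duplicate
  reads, and keeping only those localizes the graph so much that label
  propagation fragments deeply covered loci into clusters of a single read
  length. A hard *seed*-level cut at 25 was also evaluated and rejected:
  with pooled (all-sample) counting, every genome above roughly 35x pooled
  depth loses essentially all its seeds and cannot form a graph at all —
  exactly the high-coverage genomes the method should serve best.

### Label propagation

LPA here is synchronous, deterministic and damped:

* every node starts with its own label (labels are node tokens);
* each sweep, all nodes simultaneously adopt the label with the largest
  total among their neighbours' previous labels — edge-weight totals in
  weighted mode, neighbour counts otherwise — with ties broken toward the
  smallest label token;
* the node's current label receives a *self-stake* equal to its strongest
  incident edge weight (1 when unweighted). This breaks the two-cycle
  oscillations synchronous updates are otherwise prone to on bipartite-like
  subgraphs (a star collapses to one label in one sweep instead of swapping
  forever);
* a node switches only when the candidate strictly beats its current
  label's score, or ties it with a smaller token — so tie-driven flips are
  monotone and terminate.

The synchronous schedule was chosen over asynchronous sweeps after direct
measurement: asynchronous LPA (any tie rule, weighted or not) converges on
read overlap graphs to micro-communities of just the mutually overlapping
reads at one locus (~20–30 reads at 100x pooled depth), which the
`min_reads_per_cluster` filter then annihilates; the synchronous min-label
dynamic coarsens to multi-locus clusters. It also removes all randomness:
the `rng_seed` arguments are kept for interface stability, and identical
inputs give identical clusterings on any machine. All token orderings use C
byte order (radix sort) so results do not depend on the session locale.

The local stage runs LPA *unweighted*: overlap weights over-favour
near-identical reads and refragment clusters (measured directly on
simulated communities). The global stage uses weighted LPA, the standard
sum-of-weights rule.

Clusters below `min_reads_per_cluster` (default 50) are discarded: small
clusters do not yield reliable k-mer spectra. The threshold is inclusive
(a 50-read cluster survives); users wanting a strict "more than 50" can set
51.

## Coverage estimation

For each surviving cluster the pooled (all samples combined) k-mer spectrum
is computed from the cluster's own reads. Its peak sits at the cluster's
pooled depth in k-mer units — approximately base coverage scaled by
`(L - k + 1) / L` for read length `L`. Pooling maximizes spectrum depth;
per-sample depth is then read off separately (below).

Numerical choices:

* counts below `error_count_floor` (default 2) are ignored — k-mers
  containing sequencing errors dominate count 1;
* the peak is the count maximizing k-mer *mass* (`count * n_kmers`)
  smoothed over a +/-2-count window, ties broken by raw mass then by the
  larger count. Maximizing the raw number of distinct k-mers was evaluated
  and rejected: in sparse per-cluster spectra, *coincident* error k-mers
  (two reads erring at the same position and base share ~k error k-mers)
  pile up at counts 2–3 and out-vote the spread-out true mode, sending the
  peak to the error shoulder. On a clean single-peak spectrum both criteria
  agree;
* clusters whose spectrum is empty after the floor are excluded from the
  global stage (reported, and carried through unmerged).

Up to `rp` (default 100) *representative k-mers* are drawn with pooled
count within `peak_window` (default 2) of the peak, selected
deterministically by (distance from peak, lexicographic order). The
cluster's coverage in sample `s` is the **median** count of its
representative k-mers in that sample, with absent counts as 0; the median
damps repeat-inflated and error-deflated counts and is unchanged by
corrupting fewer than half of the counts symmetrically. Coverages are
reported in k-mer count units — only the profile shape across samples
matters downstream — and no per-sample depth normalization is applied
(depth differences between samples are themselves informative covariation,
and normalizing would not change cosine similarities by more than a
per-sample rescaling that affects all clusters identically).

## Global merging

Coverage vectors (columns of the samples x clusters matrix) are compared by
cosine similarity — scale-free, as required, because cluster size shifts
the spectrum height but not the profile. All pairs are computed exactly
(no approximate search; determinism and oracle-testability outweigh speed
at this scale); pairs at or above `cs` (default 0.925, "exceeding" read
inclusively) become weighted edges; zero-coverage clusters are excluded
from the graph and map to themselves. Weighted LPA partitions the cluster
graph and member clusters merge; the multiset of clustered reads is
conserved exactly.

Raising `cs` only removes edges, so the number of graph components — and
with it the granularity of merging — is monotone in the threshold: low
thresholds over-cluster, high thresholds leave under-clustering in place.

## Evaluation

With truth labels, each cluster is scored by **purity** (fraction of reads
from its predominant genome; ties toward the smaller token; species-level
purity computed the same way over species labels) and **completeness**
(fraction of *all* reads of that genome in the dataset — clustered or not —
captured by the cluster; the whole-dataset denominator keeps local/global
comparisons fair). A genome is *recovered* when one cluster simultaneously
has purity > 0.95 and completeness > 0.80, both strict. Summary medians are
over clusters (not read-weighted); per-cluster scores are available for any
other aggregation.

## The community simulator

The simulator generates what the method assumes and nothing more:

* i.i.d. uniform ACGT genomes (default 50 kb) — random genomes this size
  share essentially no 41-mers, giving controlled separability; optional
  strain pairs differ by Bernoulli substitutions to exercise species-level
  purity;
* per-(genome, sample) relative abundances are lognormal (default
  `meanlog = 0`, `sdlog = 1`), column-normalized. `sdlog = 1` was chosen by
  simulating the abundance model alone before the pipeline was built:
  profiles are distinct enough that cross-genome cosine essentially never
  reaches the 0.925 merge threshold in 10 samples, while pooled per-genome
  depth stays in a stable band; heavier tails (`sdlog = 2`, as some
  community simulators use) make pooled depth too volatile for
  few-genome communities;
* reads start uniformly on a circularized genome (no edge-coverage
  artifacts), strands fair, substitution errors i.i.d. (default 0.005);
  no indels — substitutions suffice to exercise the error-floor machinery;
  no quality realism, since nothing consumes qualities;
* `mean_base_coverage` is per genome per sample, scalar or per-sample
  vector (the vector form expresses single-genome depth profiles that a
  column-normalized abundance matrix cannot);
* read counts are `round(coverage_s * n_genomes * abundance * G / L)`; read
  names carry `genome=`/`species=` truth tokens and a sidecar truth TSV is
  written.

Everything is deterministic given `rng_seed` (fixed per-operation offsets).

What the simulator does **not** emulate — hence what passing tests do not
show about real data: shared sequence between genomes (conserved regions,
mobile elements) and repeat families within genomes, GC- or
position-dependent coverage bias, indels and quality-correlated errors,
paired-end structure (mates are treated as independent reads throughout),
and uneven per-sample sequencing depth beyond what the abundance model
induces. On real communities, inter-genome repeats create graph bridges the
purity results here cannot predict.

## Standard operating point and problem sizes

Defaults follow the method's published operating point: minimizer seeds
`k = 41`, `m = 22`, `min_shared_kmers = 2`, `max_degree = 25`,
`min_reads_per_cluster = 50`, `rp = 100`, `cs = 0.925`.

The validation suite runs desk-scale analogs: communities of 3 random 50 kb
genomes across 10 samples at ~10x mean per-sample depth (~100x pooled per
genome — the depth regime in which profile-based merging is designed to
work, mirroring the observation that recovery needs on the order of 100x),
about 100,000 reads per run, five seeds; plus single-genome simulations
(8–30 kb) for coverage-recovery checks. A full pipeline run at this scale
takes on the order of a minute.

```{r}
library(readclust)

spec <- community_spec(n_genomes = 3, n_samples = 10,
                       mean_base_coverage = 10, rng_seed = 7)
sim <- simulate_community(spec, "community")
cfg <- pipeline_config(sim$manifest_path, "community/run",
                       truth_path = sim$truth_path, rng_seed = 7)
res <- run_all(cfg)
res$evaluation$summary$recovered_genomes
```

## Known limitations

* Strain resolution: near-identical strains co-cluster; genome-level purity
  drops while species-level purity stays high, as expected from shared
  k-mers and shared abundance profiles.
* Few samples: with one or two samples, coverage profiles are nearly
  one-dimensional and cosine similarity loses discrimination; merging then
  helps little (this is the point of the multi-sample design).
* Low depth: genomes far below ~50x pooled depth fragment below the
  50-read cluster filter and cannot be recovered; this mirrors the
  coverage-dependence of the underlying method.
* The cosine threshold is the main accuracy knob and is data-dependent; on
  unlabeled data it must be chosen by judgment or external validation.
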