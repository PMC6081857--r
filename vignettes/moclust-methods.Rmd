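---
title: "Knowledge-guided multi-objective gene clustering: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-guided multi-objective gene clustering: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Genes with similar expression profiles are often assumed to share function,
but a partition optimised for expression compactness alone can group genes
whose co-expression is noise rather than biology. `moclust` treats gene
clustering as a two-objective optimisation problem: the *same* cluster
validity index is evaluated twice, once under an expression-based distance
and once under a distance derived from Gene Ontology (GO) annotations, and
the two scores are optimised simultaneously. The result is not one
clustering but a Pareto front of medoid clusterings trading co-expression
against biological coherence, from which a single solution is selected by
silhouette.

## Distances

**Expression-based distance.** Profiles are row-standardised (mean 0,
variance 1 per gene) and compared by Pearson correlation:
$D_{EB}(x, y) = 1 - \rho(x, y) \in [0, 2]$. Zero means perfectly correlated
profiles, two perfectly anti-correlated ones. Constant rows have undefined
correlation and are removed during normalisation rather than failing the
run. The range is deliberately left as $[0, 2]$; all indices consume
distances as-is.

**Biology-based distance.** Each gene carries a set of GO terms (restricted
to one namespace, `biological_process` by default — enrichment analyses in
this field conventionally use it, and a flag changes it). Term-to-term
similarity is Wang's semantic measure: within the ancestor closure of a term
$A$, S-values propagate as $S_A(A) = 1$ and
$S_A(t) = \max_{c \in \mathrm{children}(t)} w_e \, S_A(c)$ with edge weights
$w_e = 0.8$ for `is_a` and $0.6$ for `part_of` (the measure's original
semantic contribution factors; other OBO relationship types are ignored).
Then

$$WS(A,B) = \frac{\sum_{t \in T_A \cap T_B} \big(S_A(t) + S_B(t)\big)}
                 {SV(A) + SV(B)}, \qquad SV(A) = \sum_{t \in T_A} S_A(t).$$

Gene-level similarity aggregates the term-pair matrix by best-match average
(BMA) — each term's best match in the other set, averaged over both sets —
with `max` and `avg` available behind a flag. BMA is the conventional
combine rule of the GO semantic-similarity libraries this distance is meant
to reproduce. Finally $D_{BB} = 1 - WS \in [0, 1]$. The working gene set is
the intersection of expressed and annotated genes: $D_{BB}$ is undefined
outside it, and partial annotation is the norm, not an error. Evidence codes
are not filtered by default.

## Objectives and encoding

A solution is a chromosome of $K$ distinct medoid indices; genes are
assigned to their nearest medoid (ties to the lowest gene index; the
assignment depends only on the medoid *set*). Three indices are available,
each evaluated under both matrices:

* **Xie-Beni (XB, minimised, default)** — crisp medoid form:
  $\mathrm{XB} = \sum_k \sum_{x_i \in C_k} D^2(z_k, x_i) \,/\,
  \big(n \min_{k \neq l} D^2(z_k, z_l)\big)$. A literal all-pairs reading
  (every gene against every medoid) exists in the literature; it is
  implemented behind `xb_variant = "allpairs"`, with the crisp sum over
  assigned members the default for consistency with the deviation index and
  the medoid encoding.
* **Overall deviation (Dev, minimised)** —
  $\sum_k \sum_{x_i \in C_k} D(z_k, x_i)$.
* **Separation (Sep, maximised)** —
  $\frac{2}{K(K-1)} \sum_{i} \sum_{j \neq i} D^2(z_i, z_j)$ over ordered
  medoid pairs.

Each coordinate derives its own partition under its own matrix — the
expression coordinate under $D_{EB}$, the biology coordinate under $D_{BB}$
— because a single shared assignment would privilege one distance. Reported
partitions (and the silhouette used for final selection) use $D_{EB}$, which
is how published comparisons score their solutions. Internally, maximised
coordinates are negated so all dominance logic is minimisation.

Two degenerate situations are handled explicitly: medoids at distance zero
make XB infinite inside the engine (such solutions are dominated by
everything finite and drop out), while the exported `xie_beni()` treats them
as a caller error; and clusters of size one are legal, contributing $s_i = 0$
to the silhouette.

## The evolutionary engine

The engine is NSGA-II with medoid chromosomes:

* **Initial population** — half uniform random, half taken from the final
  population of a single-objective GA maximising the PBM index
  $\big(\tfrac{1}{K}\tfrac{E_1}{E_K}D_K\big)^2$ under $D_{EB}$. The PBM
  seeding hyper-parameters (population 50, 50 generations, the same
  operators, tournament size 2) are not externally prescribed; they simply
  give the SGA the same budget as one half of the main run and are logged
  with every run.
* **Selection** — binary tournament on (rank, crowding), random on full
  ties.
* **Crossover** — $(k{-}1)$-point: with $K-1$ cut points drawn from the
  $K-1$ internal boundaries of a length-$K$ chromosome, every boundary is
  cut, so alternating single positions are swapped. Duplicate medoids
  created by a swap are repaired by uniform draws from the non-members —
  the minimally disruptive repair that restores validity.
* **Mutation** — probability 0.01 *per individual* (the alternative,
  per-gene, is not used): one position is replaced by a uniform non-member.
* **Environmental selection** — parents and offspring are merged, only the
  first non-dominated front is kept, local search is applied to it
  (path-relinking first, then Pareto local search, in that order), and the
  next population is that front padded with random chromosomes or truncated
  by descending crowding distance to size $N$. Truncation by crowding is
  standard NSGA-II practice; only the padding case is externally prescribed.
* **Stopping** — a generation budget (default 100) or a stall rule: the
  multiset of front objective vectors, rounded at $10^{-9}$, unchanged for
  10 consecutive generations. Everything runs off one seeded generator, so
  a seed reproduces a front bit-for-bit.

Defaults (population 50, generations 100, crossover 0.80, mutation 0.01,
stall 10, $K \in \{4,5,6\}$, XB, both local searches) follow the
experimental configuration the method was designed with.

## Local search

**Multi-objective path-relinking (intensification).** Front members are
ordered by crowding distance; the top two form the first (start, guiding)
pair, and each subsequent pair reuses the previous guiding solution as the
new start with the next not-yet-considered member (tracked by medoid-set
identity) as guide, until every member has been selected. A relinking walk
repeatedly enumerates all single swaps that remove a medoid absent from the
guide and insert one unique to it, non-dominated- and crowding-sorts the
candidates, and moves to the top one; ties after rank and crowding fall back
to the lowest first objective and then lexicographic chromosome order, so
replays are deterministic. Walks run in both directions per pair; all
intermediates merge with the front and the new first front is returned.

**Pareto local search (diversification).** Starting from the front as an
archive of unexplored solutions: draw an unexplored solution at random,
pick one of its medoids at random, and evaluate the full neighbourhood that
replaces this medoid with every non-member gene. Neighbours not dominated by
the current solution enter the archive unexplored; the archive is pruned of
anything a new neighbour dominates; the current solution is marked explored.
The loop ends when nothing is unexplored. Termination is guaranteed (finite
space, monotone marks) but can be slow on large instances, so a cap on
explored solutions per call (default 500) is exposed; neighbourhoods are
always enumerated in full.

Both operators are no-worse: the returned front never contains a solution
dominated by any input solution.

## Evaluation stack

* **Hypervolume** — fronts are min-max normalised into the unit square
  (maximised coordinates negated first; infinite values sit on the worst
  boundary) and the area of the union of rectangles towards the reference
  point $(1,1)$ is computed by a sweep. When fronts are compared, the union
  of all of them defines the normalisation so the reference point is shared.
* **Single-solution selection** — the front member with the largest mean
  silhouette under $D_{EB}$; ties by lowest first objective, then
  lexicographic chromosome order.
* **Friedman test** — within-dataset ranks of algorithm scores (rank 1 =
  best), mid-ranks for ties, and the tie-corrected chi-square statistic on
  $k-1$ degrees of freedom. Some published tables print tied entries with
  the minimum rank of the group; that convention is exposed as
  `tie_method = "min"` for the reported ranks, while the statistic always
  uses mid-ranks.
* **Enrichment** — upper-tail hypergeometric probability of $k$ or more
  term-carrying genes in a cluster of size $n$ given $f$ carriers among $g$
  genes, computed through the exact log-space tail. Raw p-values only; no
  multiple-testing correction across terms is applied, matching how such
  cluster enrichments are conventionally reported at the 1% level.

## The synthetic fixture generator

Real microarray compendia with matched GO releases are not shippable, so
every stage is exercised on generated data. The generator plants `k`
clusters: each has a sinusoid template profile with cluster-specific phase
(time-course-like correlation structure), each gene is its template plus
Gaussian noise (default $\sigma = 0.3$ on 8 samples, 120 genes, 4 clusters),
and rows are standardised. A toy ontology gives each cluster its own subtree
(an `is_a` spine of depth 3 plus randomly attached leaves, 6 terms per
cluster); genes draw 1-3 terms from their own subtree with probability
`concordance` (default 0.9), otherwise from a subtree chosen uniformly over
*all* clusters. The uniform-over-all choice is deliberate: it makes the term
pools exchangeable at `concordance = 0`, so zero concordance means *no*
annotation signal rather than an anti-concordant one (drawing only from
other clusters' subtrees would plant a negative signal — with two clusters
it deterministically flips the labels). One seed feeds expression, ontology
and annotation randomness.

What passing on this fixture shows: the engine recovers planted structure
when expression and annotation agree, and local search improves front
quality on correlation-structured data. What it does not show: robustness to
dye bias, batch effects, heavy-tailed noise, unbalanced cluster sizes, or
the shallow, multiply-inheriting topology of the real GO graph.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the full default configuration
(population 50, up to 100 generations with stall 10, both local searches) on
the 120-gene planted fixture for $K \in \{4,5,6\}$, a five-seed ablation of
the four local-search modes at $K = 4$, oracle comparisons on 200 random
instances of up to 12 genes, and a $10^6$-sample Monte-Carlo check of the
hypervolume sweep. These sizes were chosen as the smallest at which the
planted-recovery and ablation claims are meaningful.

## Known limitations

* Exactly two objectives; the dominance and crowding code is general but the
  hypervolume sweep and normalisation are 2-D only.
* Pearson-only expression distance (no rank correlation or mutual
  information).
* The biology distance requires annotated genes; unannotated genes are
  excluded rather than imputed.
* No probe-to-gene mapping, quantile normalisation, or dataset downloading:
  the package starts from a numeric expression table, an OBO file, and an
  annotation table.
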