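---
title: "Methods: community comparison of sediment metagenomes"
author: "sednet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community comparison of sediment metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`sednet` re-implements, as a tested pipeline over synthetic data, the
analysis chain used to compare benthic microbial communities across a
crossed land-use (industrial vs residential) by rain-event (RE1/RE2) by
timing (before/after) design with six replicate sediment samples per cell —
48 metagenomes in all.  The chain is: read-level taxonomic binning →
count-matrix profiles → diversity indices → Bray-Curtis distances →
neighbor-net split networks → a bootstrap network-reproducibility statistic
→ permutational multivariate tests.  Everything operates on simulated
inputs with known ground truth; no external sequence databases are needed.

# The synthetic-data generator

The generator defines the study conditions the tests exercise.

* **Design**: `generate_metadata(n_reps)` builds the full
  2 × 2 × 2 × n factorial; `n_reps = 6` gives the 48-sample campaign.
* **Communities**: each sample's composition starts from a geometric-decay
  baseline over `n_taxa` species (default 60 in the package, 40 in the
  analysis scripts), shifted on the log scale by half the land-use effect
  (sign by land use) and half the rain effect (sign by timing), then
  renormalized.  Additive log effects are standard, invertible, and let
  the tests dial group separation directly.
* **Replicate noise** is Dirichlet with an exposed concentration
  parameter (default 100; larger = tighter replicates).  The study states
  no compositional noise model, so a Dirichlet-multinomial — the standard
  overdispersed count model for microbiome profiles — was chosen.
* **Library sizes** default to 30,000 reads per sample: the study's
  per-sample mean (3.0 × 10^7 mapped reads) scaled down three orders of
  magnitude so a full run fits on a desk.  The study's standard deviation
  is printed ambiguously ("91,74,804"), so depth is held constant rather
  than modelled.
* **Hit lists** emulate protein-database search output: every mapped read
  carries its true species with a bit score in [50, 100]; `decoy_rate`
  reads gain a wrong-taxon hit (half inside the top-score band, where it
  legitimately coarsens the LCA; half below it, where the band must
  discard it); `nohit_rate` reads carry only a sub-threshold hit (default
  0.5, matching the ~48% of shotgun reads that map in this habitat);
  `lowcomplexity_rate` reads get homopolymer sequence so the complexity
  filter diverts them.  Background read sequence is i.i.d. uniform, which
  has essentially maximal mononucleotide entropy, so the complexity filter
  fires only on the deliberately planted reads.
* **V6 ribotags**: reads optionally embed a concrete instantiation of the
  degenerate universal V6 primer `CGACRRCCATGCANCACCT` followed by a
  33-nt catalogue tag, a configurable fraction on the reverse strand.
* **Environment/rain**: rain intensities have a gamma marginal; each
  environmental variable couples to rain through a Gaussian copula with
  correlation `sin(pi * tau / 2)`, so its Kendall tau-b converges to the
  requested target.  Defaults reproduce the reported sign pattern
  (dissolved oxygen, temperature positive; sodium, potassium negative).
* **Seeds**: one global seed expands into per-operation substreams via
  `substream_seed(seed, stream)` (`(31 s + 7919 k + 1) mod (2^31 - 1)`),
  so stages are reproducible independently.

What the generator does **not** emulate: base-call errors and quality
scores, insert-size structure, chimeras, database incompleteness, real
taxonomic correlation structure, or the catchment's chemistry.  Passing
tests therefore demonstrate correctness of the *computations* under a
plausible statistical model of the data, not field realism.

# Taxonomic binning

Reads are binned MEGAN-style with the study's thresholds: minimum bit
score 35, top-percent band 10 (hits scoring at least 90% of the read's
best surviving hit are retained, ties at the boundary kept for
order-independence), minimum support 25, minimum sequence complexity
0.44.  The read is assigned to the lowest common ancestor of the retained
taxa; reads with no surviving hit go to a dedicated no-hits node.

Two points are deliberately explicit choices:

* **Complexity measure.**  The exact internal definition used by the
  original annotation tool is not documented, so normalized
  mononucleotide Shannon entropy (entropy of base composition / log 4) is
  used — transparent, bounded in [0, 1], and only the thresholding
  behaviour is load-bearing.  The threshold is configurable.
* **Minimum support** moves reads from an under-supported node to its
  nearest ancestor (repeating until the accumulated count clears the
  threshold or reaches the root), conserving totals and taxon-path
  information rather than discarding reads to an unassigned bin.

Rank projection counts each read toward its ancestor at the requested
rank; reads assigned above the rank, no-hits reads and complexity-filtered
reads are reported in separate audit rows so column totals always equal
read counts.

Note on threshold monotonicity: retaining *more* hits (a wider top-percent
band, or a lower score floor) can only move an assignment toward the root;
retaining fewer can move it deeper.  The tests assert this direction.
Paired-end voting is out of scope; each read is assigned independently.

# Ribotag extraction

Each read is scanned for an exact IUPAC match of the degenerate V6 primer
— forward strand first, then the reverse strand (configurable), first
match wins, consistent with one V6 region per fragment.  The 33
nucleotides immediately downstream are the OTU signature; reads with
fewer than 33 nt downstream are discarded.  No mismatch tolerance is
applied: the published tool permits variants but specifies none, and exact
matching is deterministic and testable.

# Profiles, distances, diversity

Depth adjustment multiplies each sample by `min(total)/total`
("normalized to the smallest data set size"), preserving within-sample
proportions exactly; a seeded subsampling alternative exists for parity
experiments.  Abundance analyses square-root transform before Bray-Curtis;
composition analyses use presence/absence with Jaccard.  A pair of
all-zero samples is assigned distance 0 with a warning rather than NaN so
network construction always receives a valid matrix.  Shannon diversity is
reported in nats ("entropy"), with Buzas-Gibson evenness `E = e^H / S`.
Rarefaction draws reads without replacement and is checked against the
closed-form hypergeometric expectation.  Hierarchical clustering of
prevalence-filtered (≥ 50% of samples) profiles uses average linkage on
Bray-Curtis row distances — the ecology convention; the study does not
name its linkage or row distance, and both are configurable.

# Neighbor-net and the splits graph

`nnet_ordering()` implements the published agglomeration: cluster pairs
chosen by the neighbor-joining adjusted distance on cluster-average
distances; the concrete node pair inside the selected clusters minimizes
the same criterion with remaining clusters averaged; 3 → 2 reductions use
the canonical convex weights (2/3, 1/3) with the averaged replacement
distance.  Correctness is enforced by oracles — on additive tree metrics
the output ordering must admit the tree's splits as intervals — rather
than by matching any particular external build.

`nnls_split_weights()` solves `min ||d − A w||`, `w ≥ 0`, over the
`n(n−1)/2` interval splits of the ordering.  For a circular ordering the
incidence matrix `A` is square and nonsingular, so the unconstrained
solution is tried first; only when it has negative entries is the problem
re-solved as a quadratic program with a dual active-set solver.  Weights
below `1e-9` are dropped as numerical dust (they change fitted distances
by less than `1e-6` even summed across all splits at these scales).

`build_splits_graph()` realizes the split system as the planar dual of a
chord arrangement: each split is a chord of a disk carrying the taxa on
its boundary; graph nodes are the regions, and each crossing of a chord
contributes one edge carrying that split's weight.  A straight segment
between two regions crosses exactly the separating chords once each, so
weighted shortest paths equal the split metric *by construction* — this is
the module's master invariant, tested to `1e-9` on every constructed
graph.  Whether two chords cross is decided combinatorially from the
cyclic endpoint order (endpoints within a boundary gap are nested by
circular distance to their partner gap); floating point is used only to
order crossings along a chord, with a small deterministic angular stagger
keeping chords in general position.  Node counts are reported per network;
at the analysis scripts' scale (48 samples, genus level, 10,000-read
bootstrap depth) they fall in the several-hundred range, the same order as
the published networks.

# Bootstrap network reproducibility

Per iteration: every sample is resampled with replacement to a common
depth from its genus-annotation proportions (a multinomial draw — the
study's depth adjustment, six million reads there, 10,000 by default
here, with the original value available); Bray-Curtis distances are
recomputed; the neighbor-net splits graph is rebuilt; the shortest-path
matrix over all graph nodes is restricted to the sample-node submatrix;
and that submatrix is decomposed into Gower-Krzanowski summary distances

\[ T = \tfrac1n \sum_{i<j} d_{ij}^2,\qquad
   W = \sum_g \tfrac1{n_g} \sum_{i<j \in g} d_{ij}^2,\qquad
   B = T - W . \]

`T = W + B` is an algebraic identity (verified to `1e-9` on random
inputs), and for Euclidean distances `B` equals the classical
between-group sum of squares.  Because the inset summary the study plots
does not state squaring, mean raw within- and between-group pairwise
distances are reported alongside.  "Six million reads … from each of the
48 data sets" is read as a per-sample depth (its stated purpose is
adjusting for depth differences among samples); a total-pool reading
would make columns unequal and defeat that purpose.  Shortest paths treat
edge weights as lengths (hop counts available by flag).  Per-iteration
seeds are `seed + iteration` substreams, so iterations are reproducible
in isolation.

# Permutational statistics

**PERMANOVA.**  The Gower-centered matrix `G = -½ J D² J` is partitioned
over all main effects and interactions of the crossed, balanced design
using sum-to-zero contrasts (orthogonal under balance; the partition is
exact to `1e-9`).  Pseudo-F denominators follow the mixed-model expected
mean squares with rain event random: a fixed term not containing the
random factor is tested against its interaction with the random factor;
the random main effect and all interactions are tested against the
residual.  P-values come from permutation of reduced-model residuals:
for term *t* the reduced model contains every other term, and the
permuted pseudo-F is computed from the permuted residuals alone.  The
reduced-model *fit* is deliberately not added back before recomputing:
with an interaction denominator that re-injects the observed denominator
variation on top of the permuted one and inflates the test's size
(empirically to ~0.6 at nominal 0.05); computed on residuals alone the
test is valid and, with the `+1` finite-sampling correction, mildly
conservative (measured ~0.04 at nominal 0.05 over repeated null
simulations of the 48-sample design).  Saturated designs (one replicate
per cell) leave residual-denominator terms untestable and they are
reported as `NA` rather than silently repartitioned.  Pooling follows the
referenced practice: interactions are examined highest order first, any
with `p > 0.25` are pooled into the residual, statistics are recomputed,
and the next order is examined once; pooled terms stay in the table,
flagged, with their original SS.

**PERMDISP** delegates to the standard principal-coordinates embedding
with negative-eigenvalue correction (`vegan::betadisper`) and permutes
group labels; centroids are the default (spatial medians optional).

**SIMPER** decomposes the average between-group Bray-Curtis dissimilarity
into per-feature contributions `|x_ij − x_ik| / Σ(x_i'j + x_i'k)` averaged
over between-group pairs; contributions sum exactly to the mean
between-group dissimilarity and are computed on the same square-root
transformed matrix as the distances.

**RELATE** is a Mantel-type test: Spearman correlation of the
off-diagonal upper triangles, one-sided significance by permuting the
sample identities of one matrix, `+1` correction.

**Univariate battery**: Welch t statistics per feature with label
permutation (999 by default) and Bonferroni flagging (`p ≤ α/m`); the
Welch form is the robust default where the study says only "t test", with
pooled variance available.  Mann-Whitney U uses midranks, exact
enumeration up to 12 observations and a tie-corrected,
continuity-corrected normal approximation beyond; two-sided means distance
of U from `n₁n₂/2`.  Kendall correlations are tau-b via `cor.test`.

# Numerical and procedural choices

* Permutation p-values always use the `+1` correction — never zero.
* LCA band ties (`≥` at the boundary) are retained: deterministic and
  order-independent.
* All-zero distance pairs → 0 with a warning, not NaN.
* NNLS weight floor `1e-9`; active-set QP only on demand.
* Deterministic tie-breaks throughout (first minimum in agglomeration;
  row order in clustering; lexicographic OTU rows).
* Exhaustive permutation (all `n!`) is available for `n ≤ 8` and is used
  by the oracle tests.

# Problem sizes

The shipped analysis scripts run the 48-sample design with 40 species,
10,000 reads per sample, 100 bootstrap networks at 10,000-read depth and
9,999-permutation tests; the test suite uses smaller replicas of the same
conditions (8-24 samples, hundreds to thousands of reads) chosen so the
whole suite exercises every code path with tight statistical oracles.
These sizes are the package's validation conditions; the machinery
accepts the study-scale values (six million reads, deeper libraries)
unchanged.

# Known limitations

* Single-read LCA only; the paired-end voting protocol of the original
  annotation tool is not reproduced.
* The published biological values (taxon tables, diversity figures,
  Table-level statistics) derive from the deposited sequencing data and
  are not recomputable from synthetic inputs; the pipeline validates the
  machinery, not those numbers.
* One random factor is supported in the mixed-model PERMANOVA (the
  design's case); arbitrary mixed designs are not.
* Neighbor-net orderings are deterministic but, like all agglomerative
  methods, can differ between implementations on near-tied inputs; the
  oracles therefore check realized distances and split sets, not a
  particular ordering.
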