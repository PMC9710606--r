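---
title: "Spaced-word placement: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spaced-word placement: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swplace)
```

## The placement model

`swplace` attaches short nucleotide reads to the edges of a rooted,
edge-weighted reference tree whose leaves carry reference sequences. The
signal is the set of *spaced-word matches* (SpaMs) between a read and
each reference: windows of pattern length ℓ that agree exactly at the
pattern's *w* match positions. Because identity is only forced at the
match positions, SpaMs survive point substitutions at the remaining
ℓ − w don't-care positions, and those don't-care columns in turn provide
an unbiased sample of per-site divergence — provided background matches
are removed.

Background removal is the crux of the method. A SpaM between unrelated
windows still occurs with probability 4^(-w) per window pair; with long
references most raw SpaMs are background. Each SpaM is therefore scored
over its don't-care columns with the HOXD70 substitution matrix
(diagonal 91/100/100/91, transitions −31, transversions −114 to −125)
and kept only if its score exceeds a threshold *t*. The default *t* = 0
sits between the strongly positive scores of homologous windows and the
strongly negative expectation of random pairs; the two populations are
well separated for moderately diverged sequences. One read occurrence
may match many reference occurrences and vice versa — every cross pair
within an equal-key block is scored independently.

From the filtered SpaMs of a pair (Q, S) the package pools the
don't-care columns into a mismatch proportion *p* and applies the
Jukes–Cantor correction d = −(3/4)·ln(1 − (4/3)·p). Jukes–Cantor is the
natural choice here because the don't-care columns are single-site
observations without rate context; it assumes equal base frequencies and
a single substitution rate, which matches the simulator below and is a
deliberate simplification for real data.

### Attachment heuristics

Five heuristics convert per-reference statistics into an edge choice;
all are O(#references) per read. The two leaf heuristics
(`minimum-distance`, `spam-count`) always return the pendant edge of the
best single reference. The two LCA heuristics (`lca-distance`,
`lca-count`) take the two best references and return the edge above
their lowest common ancestor — systematically an internal edge. The
default `spam-x` rule interpolates: with counts s₁ ≥ s₂ of the two best
references it places at the leaf when |s₁ − s₂| > (s₁ + s₂)/X and at
the LCA edge otherwise, with X = 4 by default. At X = 1 the inequality
can never hold, so `spam-x` degenerates to `lca-count` exactly; as X
grows it approaches `spam-count` whenever the counts differ at all.
Larger X therefore favours confident leaf placements; X = 4 keeps leaf
placements for reads that match one reference about 1.7× better than
the runner-up.

Degenerate cases are fixed rules, not errors: a read with no filtered
SpaM to any reference is recorded on the first child edge of the root
with pendant length 0 and `fallback_root = TRUE`; an LCA heuristic with
only one usable reference degrades to the corresponding leaf heuristic
(`degraded = TRUE`); when the two best references straddle the root —
whose parent edge does not exist — the placement goes to the root's
child edge toward the best reference, staying on the path to it.

### Branch lengths of a placement

The chosen edge is split at its midpoint (distal and proximal pieces
each half the original length, conserving the total exactly), and the
pendant length is max(0, d(Q,S₁) − path), where S₁ is the best-ranked
reference and `path` is the branch-length distance from the attachment
point to S₁'s leaf. This rule is this package's own convention: it
satisfies the only hard constraints of the model — length conservation
on the split edge and a non-negative pendant — and reduces to pendant 0
for reads that are exact substrings of their source. Downstream
node-distance evaluation depends only on the chosen edge, not on these
lengths.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| pattern weight w | 12 | match positions per pattern; 4^12 key space keeps random key collisions at ~6·10⁻⁸ per window pair |
| don't-care count | 32 | columns sampled per SpaM for the distance estimate (ℓ = 44) |
| number of patterns | 1 | accuracy is insensitive to the pattern set; counts and mismatch columns are pooled across patterns before *p* is formed |
| threshold t | 0 | score above which a SpaM is considered homologous (HOXD70 units) |
| X | 4 | leaf-vs-LCA routing ratio of `spam-x` |
| batch size | 512 | queries per matching batch; memory only, never results |
| seed | 42 | tie-breaking; each query derives its own stream from (seed, query id) |

The default pattern is a fixed, documented literal
(`render_pattern(default_pattern())`); only its weight, length and
canonical form (match positions first and last) matter for correctness.
Generated pattern sets sample interior match positions uniformly under a
seed. Patterns whose first position is a don't-care are rejected as
non-canonical: they are equivalent to a shifted shorter pattern and
would duplicate semantics.

## Strand handling

References are indexed on the forward strand; queries are enumerated on
both strands. Statistics are accumulated per (query, reference, strand)
and the strand with the larger filtered-SpaM count wins (ties go to
forward). Pooling both strands instead would contaminate *p* with
background matches from the wrong orientation, biasing distances upward.
Reverse-complementing a query therefore changes nothing but the reported
strand label.

## Determinism

The matcher is exact and serial: results are independent of batch size,
query order and the `threads` argument (accepted for interface
compatibility; it does not alter the computation). Ties inside equal-key
blocks are ordered by (sequence id, position); tie-breaking among
equally ranked references uses a per-query seeded stream, so the same
(seed, query id) always resolves the same way regardless of which other
queries are in the run — this is what makes jplace output byte-identical
across batchings and shufflings, while different seeds can pick
different winners among exact ties, honouring the "choose one at random"
contract.

## The synthetic-data generator

`simulate_sequences()` evolves a uniform random root sequence along the
tree under Jukes–Cantor: on a branch of length b each site substitutes
independently with probability p(b) = (3/4)(1 − e^(−4b/3)) to a
uniformly chosen different base. This is exactly the model the distance
estimator inverts, so estimated distances converge to branch-length sums
as sequences grow — which is the point: the generator isolates the
estimator and the placement logic from confounders. It deliberately does
**not** emulate several features of real data: indels (SpaMs are
gap-free, so moderate indel rates would only thin the match set),
rate heterogeneity across sites, unequal base composition,
low-complexity repeats (which inflate SpaM counts and are best masked
beforehand), or sequencing errors. Passing tests on this generator
therefore demonstrate correctness of the machinery and calibration of
the estimator under its own model, not field accuracy on real reads.

`fragment_reads()` cuts a sequence into consecutive non-overlapping
segments of a given length, keeping a final remainder only if at least
one pattern window fits (shorter fragments cannot produce an
occurrence; they are counted and dropped). `sample_read_bag()` draws
⌈coverage·|S|/read_len⌉ reads at uniform positions from both strands —
the "bag of reads" representation of an unassembled reference taxon.

## Evaluation: pruning-based accuracy

`pac_run()` removes one leaf at a time, suppresses the resulting
degree-2 node (merging its two incident edges, with either pre-merge
edge counting as the true attachment), fragments the removed leaf's
sequence into reads, places them on the pruned tree and records, per
read, the **node distance** between chosen and true edge: 0 for the same
edge, 1 for edges sharing a node, and generally one more than the number
of edges strictly between them. Prunings here are single leaves — at the
scale of the study trees, pruning larger subtrees would leave too little
reference signal to be informative. If the pruned leaf hung off the
root, the surviving child becomes the new root and any of its child
edges counts as distance 0. `control_baselines()` reports the node
distance of the two trivial strategies (everything at the root; every-
thing at the tree's midpoint edge, ties resolved to the lower edge
number), which put the method's numbers in context.

### Study conditions

All simulation-based checks use one fixed setting, chosen once: a
balanced 8-leaf tree with every branch length 0.05 substitutions/site
(total depth 0.15 — comfortably diverged but far from saturation),
10 kb leaf sequences (about 67 reads of 150 nt per pruned leaf, enough
for stable per-pruning means while keeping a full 8-pruning run in
seconds), 150-nt reads (the common short-read length), and the default
matcher/heuristic configuration. Distance-recovery checks use 100 kb
sequence pairs at true distances 0.05, 0.1 and 0.3, where the estimator
is expected to land within ±0.01 of the closed-form expectation. The
bag-of-reads comparison contrasts coverages 4 and 0.25 with three
seeded replicates: at coverage 4 nearly every query read overlaps
reference reads of its nearest taxa, while at 0.25 most reads find few
or no overlaps and drift toward LCA or root placements, so the mean
node distance should not improve as coverage drops — the direction, not
a magnitude, is the claim.

## Numerical choices and degenerate inputs

* Occurrence keys are base-4 integers held in doubles (exact up to
  w = 26); sorting doubles is equivalent to lexicographic key order
  because A < C < G < T matches the numeric base order.
* p ≥ 0.75 is outside the Jukes–Cantor domain; such pairs get the
  sentinel distance 5.0 with a warning. They still participate in
  minimisation but cannot beat any unsaturated pair.
* A pattern with no don't-care positions yields score 0 and mismatch
  proportion 0 by convention (no evidence of divergence); with the
  default t = 0 all its SpaMs are discarded, which is the correct
  behaviour for a filter that has nothing to filter on.
* Windows containing non-ACGT characters produce no occurrence (exact
  key comparison is preserved; skipped windows are counted and
  reported) rather than being wildcard-expanded.
* Edge numbers are assigned 0-based in preorder with children in input
  order; numbering is deterministic for a given Newick text, and jplace
  only requires consistency between the braced tree string and the
  placement records. After an insertion the proximal piece of the split
  edge inherits the old number and untouched edges keep theirs.
* Missing branch lengths parse as 0 with a warning; unrooted
  trifurcating input is treated as rooted at the trifurcation.

## Known limitations

* No sequencing-error or indel model in the generator; accuracy numbers
  are upper bounds relative to noisy real reads.
* Distances slightly underestimate at very low divergence because the
  score filter discards a small tail of genuinely homologous but
  low-scoring SpaMs, and overestimate near saturation; both effects are
  visible but well inside the tolerances used here.
* Low-complexity sequence inflates SpaM counts (many identical keys);
  inputs should be masked upstream, and the matcher guards only against
  pathological block blow-ups.
* A single placement per read: no likelihood weights or multi-edge
  output, by design.
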