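---
title: "Qualitative sign-consistency analysis of regulatory networks"
author: "qualnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Qualitative sign-consistency analysis of regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qualnet)
```

## The model

A curated regulatory network is represented as a **signed interaction
graph**: a directed graph whose edges carry an influence sign — `+`
(activation), `-` (inhibition) or `?` (dual, direction unknown) — and a
regulation level (`transcriptional` or `post_translational`). The data are
**observations**: variation signs of some nodes between two experimental
conditions, here the steady states before and after silencing of a driver
oncogene in Ewing's sarcoma cells.

The single qualitative rule connecting the two is: *the variation sign of
a node cannot be opposite to the signs of all the influences it gathers
from its predecessors*. An influence arriving at `v` along an edge
`u -> v` with sign $\sigma$ equals $s(u)\cdot\sigma$; a `?` edge supplies
both signs, as does any edge from a node whose sign is unknown. A node
with no predecessors is a free input. The rule is provably valid when the
two snapshots are steady states of the underlying dynamics; that
assumption is *not* checked by the package — it is part of the
experimental design.

A total assignment of signs to all nodes that extends the observations and
satisfies the rule everywhere is a *consistent completion*. Three
questions are asked of the constraint system:

* **Consistency** — does at least one completion exist?
* **Prediction** — which unobserved nodes carry the *same* sign in every
  completion (invariants)? Those are reported as predictions, labelled
  **forward** when the sign is forced locally by the node's precursors
  alone, and **backward** when it is forced globally through its
  successors (the only possible explanation of downstream observations).
* **Localization** — when no completion exists, which nodes (or which
  minimal observation subset) carry the conflict?

## The solver

The engine compiles the graph to integer adjacency lists and represents
each node's possible signs as a two-bit domain. **Arc-consistency
propagation** repeatedly intersects each node's domain with the set of
influences achievable from its predecessors' domains; this is sound (it
never removes a sign that occurs in some completion within the current
domains) and reaches a fixpoint because domains only shrink.
Satisfiability is decided by propagation plus branching on undetermined
nodes; branching is restricted to nodes with successors, because once
those are decided a converged fixpoint leaves only sink nodes whose
remaining domains are achievable by construction.

Invariants are established **by refutation**: after propagating the
observations, a node whose domain is already a singleton is predicted
directly; a node still allowing both signs is predicted `s` exactly when
fixing it to the opposite sign is unsatisfiable. This propagation/search
path carries no enumeration bound and is the production route. An
independent **brute-force enumeration oracle** (`enumerate_consistent`,
guarded at 25 unobserved nodes) realizes the same semantics explicitly;
the test suite checks exact agreement between the two on hundreds of
random instances per run, which is the package's strongest correctness
guarantee.

Localization first reports every *locally* unsatisfiable node found while
propagating forced signs (observed sign not achievable from the forced
predecessor signs, with the predecessor signs as witness context). If the
system is globally unsatisfiable without any such node — possible when
the conflict needs case analysis over a hidden regulator — a minimal
conflicting observation subset is found by deletion-based shrinking and
reported as one group. Reports are node-level; a subgraph-level view can
be recovered from the witness columns.

Numerical/ordering choices: node order is lexicographic (radix) sorting
everywhere, so predictions, reports and serialized outputs are
byte-stable; ties in branching are broken by that same order; self-loops
are allowed and a node's own value may serve as its witness (none occur in
the case study).

## Separating mRNA and protein nodes

Transcriptome data observe mRNAs, but curated networks typically carry
one node per gene product. `split_gene_products` rewrites the graph: each
product that is the target of at least one transcriptional regulation
*or* whose gene has transcript-level data gains an `mRNA_<gene>` node
that receives all transcriptional in-edges and activates the protein
node; post-translational in-edges and all out-edges stay on the protein
(the protein is the biochemical actor). Products meeting neither
criterion stay single nodes. Complexes receive activating
post-translational edges from their constituent proteins, protein–protein
edges with unspecified level default to post-translational, and an
optional splicing map lets several protein nodes share one mRNA. The
transform is idempotent, preserves every input edge, and guarantees the
invariant that transcriptional edges target mRNA nodes only.

Design choices made where the design was genuinely open: only
`GENE_PRODUCT`/`PROTEIN` kinds split (phenotypes never; families keep
their aggregate node unless `expand_family` is invoked explicitly, since
the curated network deliberately pools family members); transcription
factor activity originates from the protein node, matching the intended
causal reading. Transcriptional edges that target complexes or phenotypes
are rejected as modelling errors rather than silently re-targeted.

## Typing predictions against transcript data

Protein-level predictions (proteins, phosphoproteins, families) are
compared to the observed sign of their corresponding transcript
(`IGF1 -> mRNA_IGF1`; families via an alias table, `(RAC.) -> mRNA_RAC_`;
phosphoproteins map to the unmodified gene). **Type I** — opposite signs:
a post-translational regulation strong enough to reverse transcriptional
production is likely active. **Type II** — transcript absent from the
observation set: weaker evidence in the same direction, since absence may
just be assay insensitivity; the package deliberately does not
distinguish "measured but sub-threshold" from "not measured", because the
observation set by construction contains only significant calls.
**Type III** — same sign: transcription dominates. Complex, phenotype and
mRNA predictions are excluded from typing and reported separately.

## The trend caller

Observations are produced from probe-level expression series
(RMA-normalized log2 intensities are assumed; normalization is upstream
and out of scope). All probe-set lines of a gene are pooled — no
averaging — so transcript-variant spread enters the inference. A single
outlier-removal pass drops points whose residual from the pooled OLS line
exceeds 2 residual standard deviations ("SD of the gene dataset" is read
as the SD of residuals; the SD-of-intensities reading is the documented
alternative), then the line is refitted. A gene is called significant
when the slope t-test *and* a two-sample Student t-test between the
pooled first-time and last-time intensities both reject at 5%; the call
is the sign of the slope. For simple linear regression the slope t-test
coincides with the model F-test, which resolves the ambiguity of "the
regression line fitted with a statistical significance level". A Welch
variant is available by configuration. No multiplicity correction is
applied, by design: the gene list is already restricted to the network.

## What the generators emulate — and what they do not

`generate_network` emulates the curated network's scale (130 nodes,
expected in-degree 2.3 giving ~300 edges) with configurable sign/level
mixture, optionally acyclic. `simulate_timeseries` emulates the
statistical structure the trend caller assumes: per-gene linear response
plus Gaussian noise with sporadic large-displacement outliers, multiple
probe sets per gene. Defaults — 5 probe-set lines per gene, 7 time
points, noise SD 0.3 on the log2 scale — were fixed by a power
calculation: at the reference effect size of a 3-SD intensity change over
the series span, the end-point t-test has power 0.985 and the regression
test power ~1, so a simulated screen recovers essentially all injected
trends while the two-test conjunction keeps the null false-call rate
below its nominal 5%.

What the generators do *not* emulate: probe-level chemistry and
normalization artefacts, correlated noise across genes, non-linear
(e.g. transient) response shapes, and the biological curation process
that selects network edges. Passing tests therefore certify the logic and
the statistics under the stated model, not the fidelity of any particular
curated network.

`sample_consistent_observations` draws a hidden consistent total
assignment (forward-sampling along a topological order on DAGs;
randomized complete backtracking search on cyclic graphs) and reveals a
random subset — so sampled instances are consistent by construction,
which the engine must confirm. The search errors only on graphs that
admit *no* consistent assignment at all, such as a purely negative odd
cycle with no other inputs; this is a property of the constraint
semantics, not a sampler limitation.

## Known limitations

* The sign domain is `{+, -}`: "no change" is represented as absence of
  an observation, not a third value, matching the case study's tables.
  Systems where a genuine zero steady-state shift carries information
  need a three-valued extension.
* Refutation-based prediction performs up to two satisfiability searches
  per undetermined node; worst-case exponential, though propagation makes
  the case-study scale (hundreds of nodes) unproblematic in practice.
* Localization reports are heuristically minimal (deletion order fixed by
  the observation ordering); other minimal cores may exist.
* The full published 130-gene network is not redistributed; the packaged
  `synthetic_core` fixture is a desk-scale synthetic stand-in wiring the
  published motifs together, and full-scale reproduction requires the
  user to supply the original network and observation CSVs to
  `read_network`/`read_observations`/`run_case_study`.

## Problem sizes used in the test suite

Desk-scale motifs (7–17 nodes) for the published examples; 200 random
12-node instances for oracle-equivalence; 200-gene simulated panels for
trend-caller operating characteristics. These sizes keep the full suite
under ten seconds while the random-instance counts give the property
tests real discriminating power.
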