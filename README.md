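# qualnet

Qualitative sign-consistency analysis of signed gene-regulatory networks.

## The problem

Large-scale transcriptomics measures mRNAs, but much of what a perturbed
regulatory network does happens at the protein level, where mRNA and
protein variations need not agree. `qualnet` is for systems biologists who
have (a) a curated, signed, directed interaction network whose edges are
annotated as transcriptional or post-translational, and (b) the variation
signs of some nodes between two steady states — for example gene
expression shifts after silencing a driver oncogene. The package decides
whether the network can explain the data, predicts the variation signs of
unmeasured nodes, pinpoints the parts of the network that cannot explain
the data, and flags proteins whose predicted behaviour contradicts their
own transcript — candidate sites of active post-translational regulation.

## The rule at the core

Each edge `u → v` carries a sign σ(u→v) ∈ {+, −, ?}. For a total
assignment of variation signs s(·) to nodes, the consistency rule is:

> for every node v with at least one predecessor,
> s(v) ∈ { s(u)·σ(u→v) : u a predecessor of v },
> where a `?` edge (and any edge from a node of unknown sign) contributes
> both signs; nodes without predecessors are free inputs.

The rule is provably valid when the two measured snapshots are steady
states. Given observations on a subset of nodes, the package:

* decides **consistency** (does a total assignment extending the
  observations and satisfying the rule exist?);
* computes **predictions** — unobserved nodes whose sign is invariant over
  *all* consistent completions — labelled **Forward** (forced locally by
  the node's precursors) or **Backward** (forced globally via its
  successors);
* **localizes inconsistencies** when no completion exists;
* classifies protein-level predictions against transcript observations:
  **Type I** (opposite sign: post-translational regulation likely
  active), **Type II** (transcript not significant/absent), **Type III**
  (same sign: transcription dominates).

It also ships the supporting workflow: mRNA/protein node splitting
(`split_gene_products`), a microarray time-series trend caller
(`extract_observations`), synthetic-data generators, desk-scale fixtures
from the published Ewing's sarcoma case study, and an end-to-end driver
(`run_case_study`).

## Worked example

The IGF/AKT motif: seven nodes, three transcript observations
(`mRNA_AKT1 = +`, `mRNA_IGF1 = −`, `mRNA_IGFBP3 = +`).

```r
library(qualnet)
g   <- load_fixture("fig1_igf_motif")
obs <- load_fixture("fig1_observations")
cp  <- compute_predictions(g, obs)
cp$predictions
#>       node sign deduction
#> 1   (.RAS)    +  BACKWARD
#> 2 (PIK3C.)    +   FORWARD
#> 3     IGF1    +  BACKWARD
#> 4   IGFBP3    -  BACKWARD
```

Reading: the up-regulated `mRNA_AKT1` is regulated by IGF1 only, so IGF1
protein must be up (backward deduction); since IGF1's own transcript is
down, only loss of its inhibitor IGFBP3 can explain that, forcing IGFBP3
down and its repressor family (.RAS) up; finally every influence on
(PIK3C.) is now positive, so it is up by a forward deduction. Typing the
predictions against the full published observation table:

```r
typed <- type_predictions(cp$predictions, load_fixture("table1_observations"))
typed[, c("node", "sign", "deduction", "ptype")]
#>       node sign deduction ptype
#> 1   (.RAS)    +  BACKWARD   III
#> 2 (PIK3C.)    +   FORWARD   III
#> 3     IGF1    +  BACKWARD     I
#> 4   IGFBP3    -  BACKWARD     I
```

IGF1 and IGFBP3 are Type I: their predicted protein behaviour opposes
their measured transcripts — the signature of active post-translational
control in the IGF axis.

The full two-pass workflow (check the unseparated network, split, re-check,
predict, classify, confront with new data) on the packaged desk-scale
core network:

```r
core <- load_fixture("synthetic_core")
rep  <- run_case_study(core$graph, core$observations,
                       extra_observations = core$extras)
rep
#> == case study report ==
#> original network: inconsistent (2 node(s): (PIK3R.), Cell_Migration)
#> split: 4 gene(s) separated into mRNA + protein nodes
#> modified network: consistent
#> predictions:8 (I=4, II=2, III=2, NA=0)
#> refinement check: inconsistent (mRNA_AKT1)
```

The unseparated network fails exactly where transcript observations sit on
protein-behaving nodes; separating mRNA and protein nodes resolves both
conflicts; and adding the follow-up observation `IGFBP3 = +` makes the
model inconsistent again on the IGF1 pathway — the signal that regulations
are missing there.

To analyze your own network at full scale, read it with
`read_network()` (CSV: `source,target,sign,level`), your observations with
`read_observations()` (CSV: `node,sign`), and call `run_case_study()`;
`write_case_study_report()` serializes the results as TSV + JSON.

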