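---
title: "Evidence networks: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence networks: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evinet)
```

## The model

`evinet` treats a STITCH/STRING-style knowledge-base as an undirected
heterogeneous graph: protein nodes (`9606.ENSP...`), chemical nodes
(`CIDm...`), and edges carrying per-channel evidence sub-scores plus a
combined confidence $S \in [0,1]$. The working assumption is that an edge's
confidence is a usable proxy for how well prior research supports the
interaction, and therefore that the *explanation* a researcher wants for a
drug–mediator statistical association is the set of lightest paths under

$$ w_{edge} = 1 - S_{edge}. $$

An evidence network for drug $d$ and mediator $m$ is built by enumerating
loopless $d\!-\!m$ paths in nondecreasing total weight (a modified Yen's
$K$-shortest-paths algorithm over Dijkstra searches) and merging them until
either the supply is exhausted or the network holds at least $N$ distinct
nodes. Two properties follow by construction and are enforced by tests:
the accepted path list is a prefix of the full weight-ranked enumeration,
and removing the last accepted path always leaves fewer than $N$ distinct
nodes (unless the supply ran out first). $N$ caps interpretive clutter,
not information: the final path may overshoot the threshold by more than
one node.

```{r toy}
net <- buildEvidenceNetwork(toy1(), "D", "M", N = 4)
net
```

## Parameters that matter

* **`N`** (default 10, dimensionless node count) — the distinct-node
  stopping threshold. Chosen as a display budget: networks beyond roughly
  ten nodes stop being readable in an interactive viewer. It is not a
  statistical parameter; results for any prefix of paths are unchanged by
  it.
* **`maxIntermediates`** (default 3) — the cap on genes strictly between
  drug and mediator per path. Pairs connected only through longer chains
  are treated as unrelated; the classifier reports them `unreachable`.
  The cap is applied *inside* the enumeration (spur searches are
  hop-bounded), so `k` in `kShortestPaths` counts accepted paths, and the
  hop-bounded subroutine remains exact (it is a uniform-cost search over
  loopless paths rather than plain Dijkstra, because a hop budget breaks
  subpath optimality).
* **Channel multipliers** (`channelWeights`, each in $[0,1]$) — scale
  channel sub-scores before recombination. The presets `NONE` = 0,
  `LOW` = 0.5 and `DEFAULT` = 1 mirror interactive-portal settings; the
  numeric values of `LOW`/`NONE` are this package's convention, since only
  the labels are conventional in the field.

### The effective-score discontinuity

With every multiplier at 1, `effectiveScore` returns the file's
`combined_score` unchanged. The public databases compute that score with a
prior correction that cannot be reproduced from the published sub-scores,
so the pass-through preserves database semantics exactly. As soon as any
multiplier differs from 1 the package switches to the naive noisy-OR
recombination $S = 1 - \prod_c (1 - m_c s_c)$ over channels present on the
edge. The two regimes do not meet continuously as $m_c \to 1$; this is a
deliberate trade-off (exact database scores by default, self-consistent
re-weighting on demand) and both branches are tested, including the
property that silencing a channel ($m_c = 0$) is path-for-path identical
to deleting that channel from every edge.

## Determinism and numerical choices

* **Tie-breaking.** Among equal-weight paths the lexicographically
  smallest node-id sequence wins, everywhere: Dijkstra reconstructs the
  lexicographically least optimum by walking the tight-edge subgraph in
  ascending id order (with backtracking, so zero-weight cycles cannot trap
  it), and Yen's candidate pool is ordered by (weight, sequence). Node ids
  are compared in C-locale byte order, independent of the session locale.
* **Tolerances.** Weight comparisons use an absolute $10^{-9}$ band. File
  scores live on the $1/1000$ grid, so genuinely different path sums differ
  by at least $\sim 10^{-3}$ minus accumulated floating-point error
  ($\sim 10^{-15}$); the band is six orders of magnitude away from both.
* **Zero-weight edges** ($S = 1$) are legal and traversed; looplessness is
  enforced per path, and ties the zero-cost edges create resolve by the
  lexicographic rule.
* **Degenerate inputs.** `src == dst` yields the single-node path of
  weight 0; a disconnected pair yields an empty-path network (with the
  endpoints kept as isolated nodes), not an error; `not_in_db` and
  not-found chemical matches are values, not exceptions. Self-loop rows in
  input files are dropped with a logged warning. Duplicate symmetric rows
  collapse; duplicate rows with *conflicting* scores abort the parse for
  protein files, while chemical files merge by per-channel maximum because
  the CIDs$\to$CIDm stereo-merge makes collisions legitimate there.

## Design choices where the design was open

* **Direct-edge priority in classification.** A pair with a database edge
  classifies `direct` even when a multi-hop path is lighter (in `toy1()`
  the direct edge scores 0.2 while the best path weighs 0.3). The
  alternative — classifying by the weight-shortest path and calling the
  pair "1" — would under-count known drug–target relations.
* **Weight-based, not hop-based, shortest path for the intermediate
  count.** Either reading is defensible; weight-based is used because the
  whole method ranks evidence by weight. Consequence worth knowing: a pair
  two hops apart can classify "2" via a lighter three-edge path (`E`–`A`
  in `toy1()` does exactly this).
* **Shared DDN neighbors** enter both condition-specific networks by
  default (`specificOnly = FALSE`); portal figures that show only
  condition-specific edges correspond to `specificOnly = TRUE`. Including
  shared neighbors is the conservative superset.
* **Per-neighbor subnetworks** in the pathway-weighted construction reuse
  the same `N` and `maxIntermediates` as the main pair; nothing suggests
  the neighbors deserve different budgets.
* **Salt stripping** keeps the fragment with the most heavy atoms (ties:
  lexicographically smallest canonical fragment) — the standard desalting
  convention, made deterministic. Stereo reduction is implemented both by
  stripping stereo marks before hashing and by matching on the InChIKey's
  14-character connectivity block; block matching is authoritative.
* **Substitute compounds.** When a drug is absent from the database, the
  single-source extension ranks the chemicals closest to the mediator;
  choosing a homologous compound as a substitute is left to the user as an
  explicit node id, since homolog selection is a chemistry judgment this
  package should not automate.
* **Viewer export.** Edge opacity equals the effective score clipped to
  $[0.1, 1]$; the floor keeps weak edges visible. Outbound links are
  template URLs keyed by the edge's node ids.
* **Priority queue.** Dijkstra here uses a scan-based extraction rather
  than a Fibonacci heap; the contract is Dijkstra's semantics, and at the
  graph sizes the package targets the heap is an optimization, not a
  correctness concern.

## What the synthetic generator does and does not emulate

`generateFixtureFiles` emits files in the exact STRING/STITCH dialects:
integer scores on the 0–1000 grid, per-section channel vocabularies,
chemical–protein edges only between the two node kinds, and byte-identical
output for identical (spec, seed) — the RNG kind is pinned. Channel scores
are Beta-distributed with a configurable absence probability (defaults
0.6, Beta(2,2)), and the combined score is the noisy-OR of the channels.
It does **not** emulate the heavy-tailed degree distributions, the prior
correction inside real combined scores, homology transfer, or the sheer
scale of the public databases. Passing tests therefore demonstrate
algorithmic correctness on the specified file dialects, not calibration
against any particular database release — real-data results additionally
depend on which STITCH/STRING version is used, which this package leaves
to the user.

Test and acceptance sweeps run on graphs of 5–12 nodes with edge densities
around 0.25–0.6 and 200 random replicates for the oracle-equivalence
check — sizes at which exhaustive simple-path enumeration is a feasible
independent oracle, which is the point of the sweep design.

## Known limitations

* The exact solver targets desk-scale graphs (fixtures, single queries
  against a pre-filtered neighborhood); building the full human
  STITCH+STRING graph in memory and running thousands of queries would
  want an indexed store and a faster $K$-shortest-paths scheme (e.g.
  Eppstein's algorithm).
* Default-weight scores inherit whatever biases the database's combined
  score carries, text-mining prominently included; channel re-weighting is
  the provided mitigation, not a correction.
* The evidence-description annotation table is a flat three-column file;
  no attempt is made to reproduce the relational evidence-description
  databases the public distributions ship.
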