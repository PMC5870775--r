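---
title: "Causal network analysis: methods and design notes"
author: "upstream package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal network analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(upstream)
```

## The problem

Enrichment-style interpretation of a differential expression experiment
classifies what changed; it says little about *why*. Causal reasoning turns
the question around: given a signed, directed interaction network (a
*causal graph*: activation and inhibition edges between genes, proteins or
compounds) and the observed direction of change of each measured gene, it
asks which upstream entity, perturbed in which direction, would best
explain the observed pattern. In a drug-discovery setting such points of
convergence are candidate targets; in basic biology they are candidate
master regulators.

`upstream` implements this analysis end to end: network and signature
input, signed-graph reasoning, hypothesis ranking with significance,
consensus filtering across path lengths, and reconstruction of the
explained regulatory subnetwork in files Cytoscape can load.

## The computational causal graph

The engine's substrate is a *computational causal graph* (CCG). Every
entity $e$ of the input network is split into two node copies, $e^+$ and
$e^-$, and each signed edge $(a, s, b)$ with $s \in \{+1, -1\}$ becomes
two arcs

$$a^+ \to b^{\,s}, \qquad a^- \to b^{\,-s}.$$

A directed path in the CCG starting at $a^+$ ends at $b^+$ exactly when
the product of the traversed edge signs is $+1$, and at $b^-$ when it is
$-1$. Sign propagation therefore reduces to plain reachability, computed
here by breadth-first search (`igraph::distances`) on the doubled graph.
The construction is symmetric under a global sign flip, which the test
suite checks by arc enumeration, and which lets the ranking step do one
BFS per entity instead of two.

## Predictions, ambiguity, and the path-length horizon

A *hypothesis* is a signed entity, e.g. "X is up-regulated". Its
prediction at horizon $\delta$ (`predict_regulation`) is obtained by BFS
from the matching node copy to depth $\delta$ *edges*, inclusive; the
start copy counts at distance 0, so the regulator's own transcript is part
of its prediction. For each entity:

* only the $+$ copy reached: predicted up (+1);
* only the $-$ copy reached: predicted down (-1);
* both copies reached within $\delta$: *ambiguous* (0) — the regulator can
  push the entity either way inside the horizon, so no signed call is made;
* neither copy reached: no prediction.

Ambiguity is defined by reachability of both copies within $\delta$, not
by tied shortest distances. The distance-tie rule looks similar but is not
monotone in $\delta$; the reachability rule guarantees that growing the
horizon can only add predicted entities or degrade a signed call to
ambiguous, never flip it. This monotonicity is asserted as a property test
and is what makes the consensus filter (below) meaningful.

Cycles are handled with no special casing: a negative feedback loop
genuinely does make its members ambiguous once $\delta$ admits both an
even- and an odd-inhibition walk, and a coherent positive loop does not.

## Scoring and significance

Signatures are ternary: $+1$ up, $0$ unchanged, $-1$ down, one value per
gene; magnitudes are deliberately ignored (discretization is the caller's
concern). After mapping the signature onto the network (unmapped genes are
counted and warned about, since public causal knowledge is sparse), each
hypothesis is scored over the genes it makes predictions about:

$$\mathrm{score} = \#\{\text{correct}\} - \#\{\text{incorrect}\},$$

where a gene is correct if the predicted and observed signs agree and
incorrect if they disagree. Ambiguous predictions and zero-observed genes
contribute nothing to the score — but they are *not* discarded: they
occupy cells of the null model's contingency table, so a hypothesis that
explains 3 of 3 measured genes is distinguishable from one that explains
3 of 300.

Significance (`score_significance`) holds the predictions fixed and
assigns the multiset of observed values uniformly at random across the
mapped genes; the p-value is $P(\mathrm{score} \ge
\mathrm{score}_{obs})$ under that null. Because the score depends only on
the $3 \times 3$ table of prediction class against observation class, the
exact tail is a sum of multivariate-hypergeometric table probabilities
over the four free cells, computed in log space. When the candidate-table
count exceeds a budget (`max_tables`, default $10^7$) the estimator
switches to seeded Monte Carlo shuffles with the add-one correction
$(k+1)/(n_{perm}+1)$. The exact path is verified against exhaustive
permutation enumeration on every instance up to 8 genes; the Monte Carlo
path against the exact one at $3\sigma$ binomial tolerance.

A sign-blind hypergeometric enrichment p-value
(`enrichment_significance`, via `stats::phyper`) accompanies each row: the
probability of at least the observed overlap between predicted and changed
genes given the margins.

`rank_hypotheses` emits all $2N$ signed hypotheses sorted by score, then
p-value, then enrichment p-value, then node name, then sign. The fixed
tie-break chain makes output diff-able; per-hypothesis Monte Carlo seeds
are derived from the user seed and the hypothesis' row index, so a
parallel scheduler would produce the identical table.

## Consensus across path lengths

A hypothesis that looks excellent at one horizon only is often a false
positive of the local wiring. `scan_hypotheses` re-runs the ranking over a
strictly increasing sequence of horizons (default `1, 2, 3`) and keeps the
signed hypotheses present in the top of *every* ranking. Two recorded
interpretations matter here:

* the cut at `top_n` (default 100) is by *score*, not row count: ties at
  the boundary are all kept, so the consensus cannot depend on
  lexicographic tie order;
* the unit is the signed hypothesis — `X+` and `X-` are distinct
  candidates.

Under these rules the consensus is provably anti-monotone in the delta
sequence and monotone in `top_n`, both enforced as property tests.
p-values are skipped during the scan since membership depends on scores
alone.

## Reconstruction of explained networks

For a chosen hypothesis, the *explained nodes* are the measured genes
whose signed prediction equals their observed sign. `reconstruct_network`
retains, for each explained node, **every shortest sign-consistent path**
from the hypothesis copy to the node's matching copy, and projects the
traversed arcs back to input edges. All-shortest (rather than one
arbitrary path, or all paths up to $\delta$) is a deliberate middle
ground: deterministic and size-bounded, yet it preserves redundant
parallel branches, which are biologically the interesting part.
Path nodes that are neither the hypothesis nor explained are the grey
*intermediate* nodes — unmeasured or unchanged members of the cascade —
annotated 0 in the output. Since any CCG path to a node's matching copy
has the matching sign product by construction, every retained path is
sign-consistent; the tests re-verify this from the raw edge list.

`write_explained_sif` writes the subnetwork as a SIF file (identical
dialect to the input parser, round-trip tested) plus a two-column node
attribute table (`NodeName`, `Regulation`) that Cytoscape can load to
colour nodes up/down/grey; `write_scan_networks` does this for every scan
consensus hypothesis with filesystem-safe, collision-suffixed names. Edges
and nodes are sorted, and no timestamps are embedded, so repeated runs are
byte-identical.

## The simulator and what it does (not) show

`simulate_network` draws a uniform random digraph over distinct ordered
pairs (no self-loops; self-loop semantics are tested on hand-built
graphs), with each edge an activation with probability 0.7 — roughly the
activation-heavy balance typical of curated signalling resources — and
`simulate_signature` plants a known regulator: it propagates the
hypothesis at a generation horizon (default 2), keeps a `coverage`
fraction of predicted entities, and corrupts each value with probability
`noise`, half of corruptions flipping the sign and half zeroing it, so
both the mismatch and the dropout path of the scorer are exercised. Under
this model the expected planted score at full coverage is
$n_{signed}(1 - \tfrac{3}{2}\,\mathrm{noise})$, which the tests assert
directly.

Noise-free, full-coverage fixtures give the planted hypothesis the
maximum attainable score, hence rank 1 up to prediction-identical ties —
the basis of the recovery suite (50 fixtures of 20–50 nodes, twice as
many edges as nodes; at noise 0.3 the planted regulator is required in the
tie-expanded top 5 in at least 80% of seeds). The walk-enumeration oracle
`oracle_predict` re-derives predictions by brute force on instances up to
14 nodes and horizon 5, and agrees with the BFS engine on 200 random
graphs per run.

The simulator emulates the input *formats* and the planted-regulator
logic, not real interactomes: degree distributions, motif structure, hub
dominance and study-specific noise are all unmodelled. Passing the
recovery suite shows the machinery is sound, not that any particular
biological network will yield its true regulator at rank 1.

## Numerical and degenerate-input choices

* `delta` counts edges and is inclusive; `delta >= 1` is required.
* Empty signature, or one entirely unmapped: every score is 0, every
  p-value 1 by convention; ranking falls back to name order.
* No genes predicted: permutation p-value 1 (the score is identically 0);
  degenerate enrichment margins likewise give 1.
* Contradictory curated edges (both signs on one ordered pair) are
  retained, making the target ambiguous downstream of that source rather
  than raising an error.
* Exact p-value summation is in `lgamma` log space; agreement with
  exhaustive enumeration is required to $10^{-12}$.
* Identifiers are taken verbatim and case-sensitively; no symbol
  harmonization is attempted.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` use 200 random graphs of up to
12 nodes for oracle equivalence, 100 instances of up to 8 genes for
exact-null verification, and 50 planted fixtures of 20–50 nodes for
recovery — sizes at which the brute-force oracles are exact and the whole
validation completes in well under a minute on one core.

## Limitations

* No magnitude weighting, edge confidence, or multiple-testing correction
  across hypotheses (p-values are per-hypothesis; correct downstream).
* No empirical FDR for consensus membership; the false-positive reduction
  of the multi-horizon filter is exercised only via planted fixtures.
* Only `Activates`/`Inhibits` SIF vocabularies; unsigned relations such as
  `Binds` carry no causal direction and are skipped or rejected.
* No Cytoscape session/style generation, layout or rendering — only files
  Cytoscape imports.
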