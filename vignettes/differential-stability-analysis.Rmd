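---
title: "Differential stability analysis of Boolean gene regulatory networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential stability analysis of Boolean gene regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reprodet)
```

## The model

A cellular phenotype is, at the transcriptional level, a stable expression
pattern.  reprodet models the gene regulatory network (GRN) behind such
patterns as a signed digraph: nodes are genes (or miRNAs), an edge
`u -> v` with sign $+1$ means *u activates v*, sign $-1$ means *u
inhibits v*.  Expression is binarized — a gene is ON (1) or OFF (0) — and
the network state evolves under a synchronous scheme: every gene
recomputes its state simultaneously from the previous global state.

The update rule is inhibitor-dominant: gene $v$ becomes active iff none
of its inhibitors is active and its activator requirement holds,

$$x_v' \;=\; \Big(\bigwedge_{u \dashv v} \lnot x_u\Big) \;\wedge\;
  \Big(\bigvee_{u \to v} x_u\Big).$$

**Default-ON convention.**  Read literally, the rule switches a gene OFF
whenever it has no active activator — which makes every gene whose
regulators are *all* inhibitors permanently OFF and destroys exactly the
bistability that inhibition-dominated networks (the double-negative
toggle, the EMT SNAI1/miR-34 circuitry, in which 15 of 17 interactions
are inhibitions yet two phenotype attractors exist) are famous for.  We
therefore treat the activator clause as vacuously true for genes with
zero activators: such a gene is ON unless repressed.  This is a modelling
inference, not a published statement, so `strict_activator_rule = TRUE`
restores the literal reading everywhere.  Under the strict rule a gene
with no incoming edges at all is an error: it should have been removed by
`prune_unregulated()`, which iteratively deletes in-degree-zero nodes
(they carry no regulatory constraint and, under default-ON, would act as
constant-ON inputs).

Fixed points of the synchronous map are the *attractors*; they are
identified with stable phenotypes.  Cyclic attractors exist in the
dynamics (any negative feedback ring oscillates) but transitions involving
them are outside the scope of the method; the simulator reports a `cycle`
terminal and all downstream machinery works with fixed points only.

## Attractor enumeration

`attractors()` is complete for fixed points by construction, via two
interchangeable strategies:

* **exhaustive** — iterate all $2^n$ states in vectorised blocks;
  refused above $n = 22$ because memory and time grow geometrically.
* **backtracking** — choose a feedback vertex set (FVS: every self-loop
  node plus greedily picked cycle breakers), enumerate its $2^{|FVS|}$
  assignments in blocks, derive every other node in topological order
  (their values are functionally determined once all cycles are cut), and
  keep assignments that close consistently on the FVS.  Sparse 20–40 gene
  networks typically have an FVS of a handful of nodes, so this is the
  default above 16 nodes.  A cap of 24 FVS nodes guards against densely
  cyclic inputs.

The two modes are tested for equality against each other and against a
brute-force $2^n$ oracle on random networks.  Attractor ids are assigned
in lexicographic order of the state vector (genes sorted by name), so ids
are stable across runs and machines.

## Circuits and their signs

Multistability requires positive feedback: an elementary circuit (no node
repeated; self-loops count, as length-1 circuits) is **positive** iff it
contains an *even number of inhibitions*.  This is the classical
definition — it is the parity of inhibitions, not of the circuit length,
that matters, and it is the only reading under which the double-negative
toggle comes out positive.  `circuits()` implements Johnson's algorithm,
extended to emit self-loops (which the classic formulation skips), with a
configurable cap on the number of circuits as a blow-up guard.
Enumeration order is deterministic and each circuit is reported once, in
canonical rotation starting at its smallest node.

## Differentially expressed positive circuits

Given an ordered attractor pair $(A_i, A_f)$, a positive circuit is a
**DEPC** when

1. *every* gene on the circuit changes state between $A_i$ and $A_f$, and
2. the circuit's restricted states in both attractors are fixed points of
   the circuit *considered in isolation* — i.e. consistent around the
   ring (`state[v] = state[u]` across activation, negated across
   inhibition).

Criterion 2 is evaluated on the ring alone, not on the full-network
update, which keeps it independent of external regulators.  A positive
ring has exactly two isolated fixed points and they are complementary, so
under criterion 1 it suffices to check the initial restriction
(`ring_fixed_points()` exposes the primitive; a negative ring has none,
which is the algebraic reason negative circuits cannot hold a stable
differential pattern).  Circuits that share all nodes but differ in edges
are distinct DEPCs: the method counts circuits, not gene sets.

DEPCs are the stability elements that hold the two phenotypes apart;
reprogramming means defeating all of them at once, directly or
indirectly.

## Reprogramming determinants

`find_reprogramming_determinants()` searches for all minimal gene sets
whose clamping to final-attractor values drives the network from $A_i$ to
$A_f$:

1. **Minimum DEPC subsets** (`minimal_depc_sets()`): subsets of DEPCs are
   tried in increasing size; a subset is feasible when clamping *all* of
   its genes passes the simulation check.  The search is exhaustive with
   early exit at the first feasible size, which is exact; with a dozen or
   fewer DEPCs — the regime of the published case studies — this costs at
   most a few thousand simulations.  (A mixed-integer formulation could
   stand behind the same interface; with these problem sizes it would buy
   nothing.)
2. **Greedy gene cover with tie branching**
   (`minimal_gene_combinations()`): within a minimal DEPC subset, pick
   the gene occurring in the most uncovered DEPCs; on ties, branch into
   every tied choice, so all alternative covers are produced.  Covers
   clamp fewer genes than the full subset, so each is re-validated; if no
   cover of any minimal subset validates, the full (verified) gene sets
   are used instead.
3. **Redundancy pruning** (`prune_redundant_targets()`): genes are
   dropped, in ascending lexicographic order, whenever the transition
   still succeeds without them — this is how DEPCs regulated by other
   DEPCs lose their direct perturbation.  Order can matter, so every
   survivor is finally reduced to its minimal passing subsets by
   exhaustive search over proper subsets, and every emitted combination
   is re-validated post hoc.

**Perturbation semantics.**  The simulation check
(`verify_transition()`) is two-phase: hold the clamps until the clamped
system reaches a fixed point, then *release* them and require the free
system to settle exactly on $A_f$.  Transient clamps mirror how
reprogramming cocktails are applied and make "the final phenotype is
self-sustaining" a real assertion rather than an artefact of the clamp.
Because the original clamp duration is not specified anywhere,
`permanent_clamp = TRUE` provides the alternative reading (phase 1 only).
A cycle or an exhausted step cap (default 1000 steps, always reported,
never silently treated as convergence) counts as failure.

Clamp values are always the gene's final-attractor value, so each
combination reads as "activate X" / "repress Y".  Only DEPC member genes
are eligible targets, per the definition of a reprogramming determinant.

## Network contextualization

Literature-assembled networks mix regulations from many biological
contexts, so their attractors rarely match the profiles under study.
`contextualize()` prunes interactions with an estimation-of-distribution
algorithm (EDA):

* a candidate is an edge-removal mask, scored by
  `contextualization_score()` — enumerate attractors of the pruned
  network (after re-pruning any node left unregulated), match the best
  ordered attractor pair against the binarized initial/final profiles,
  and return the mean fraction of measured gene states explained;
* masks are sampled from per-edge removal probabilities $p_e$ coupled
  with per-positive-circuit retention probabilities $r_c$; the coupling
  is protective, $P(\text{remove } e) = p_e \prod_{c \ni e} (1 - r_c)$,
  so stability elements are broken only when the elite evidence supports
  it.  (The superficially natural alternative — multiplying retention
  into the *keep* probability — is self-defeating: any retention below 1
  raises circuit-edge removal above baseline, elites then rarely contain
  intact circuits, and the distribution runs away until every stability
  element is destroyed.  We observed exactly this collapse on a four-edge
  toy and adopted the damping form.)
* both distributions are pulled toward the elite fraction of each
  generation with a learning rate, clipped to $[p_{\min}, 1-p_{\min}]$ to
  keep exploration alive; the empty mask is always evaluated, so an
  already-consistent network is returned unchanged; the best candidate
  ever seen is kept (elitism), making the reported score monotone.

Defaults — population 50, elite fraction 0.2, learning rate 0.3,
$p_{\min}$ 0.02, 100 generations — are sized for the ≤ 40-gene regime and
all config-exposed.  On instances with at most 8 edges the EDA is tested
to attain the optimum found by exhaustive enumeration of all removal
masks.  The score is also the reliability indicator of the downstream
predictions: `run_pipeline()` warns (and continues) when it falls below a
threshold.  Only removal is available — the algorithm never invents
edges — and interactions on no circuit cannot be assessed by a stability
criterion at all.

## Synthetic networks and the in silico study

Real genome-scale regulatory maps cannot ship with the package, so the
generators produce structurally honest stand-ins:

* `sample_source_network()` grows a preferential-attachment digraph
  (~400 genes): hub regulators with a heavy out-degree tail, largely
  feed-forward wiring with occasional back edges (3%), 40% repression,
  autoregulation on 20% of genes with 80% of the self-loops activating.
  The self-loop sign mix is the load-bearing choice: positive
  autoregulation is the minimal Boolean latch, whereas a free-standing
  negative self-loop merely oscillates, so this knob sets how often
  extracted cores are multistable at all — the regime the study is
  about.
* `extract_subnetwork()` cuts study-sized cores out of a source by greedy
  neighbour selection (repeatedly add the outside node with most edges to
  the current set, ties uniform at random, self-regulations retained).
* `random_signed_network()` builds small fixtures with exact edge/sign
  counts, rejection-sampled until at least one positive circuit and two
  attractors exist, so every pipeline stage is exercisable in tests.

`run_insilico_study()` applies the full pipeline to every ordered
attractor pair of each generated network and reports: the fraction of
pairs separated by at least one DEPC, the fraction with a validated
minimal perturbation, per-pair minimal RD set sizes, and the per-network
fraction of genes that are reprogramming determinants.  Defaults analyse
50 networks of 20–40 genes — a desk-scale ensemble that runs in seconds
while leaving the per-pair analysis exact — with each network extracted
from its own source draw (greedy extraction repeatedly climbs the same
hubs of a shared source, which would pseudo-replicate the ensemble).
Stage failures (monostable cores, attractor or circuit blow-ups, capped
searches) are itemized in a `status` column and never fatal.  What
passing this study shows is internal consistency of the method on
networks with the modelled topology; it does not validate the biology of
any real network, and the RD gene fraction depends on the latch density
of the generator, so it is reported, not asserted, when compared with
values obtained on real bacterial network extractions.

## Numerical and degenerate-input choices

* All randomised routines take an explicit `seed` and restore the
  caller's RNG state; identical seeds give identical results, and
  attractor/circuit/combination orderings are deterministic even without
  a seed.
* `step_cap` (default 1000) bounds every simulation phase; reaching it is
  reported as its own terminal condition.
* Circuit (`max_circuits`), FVS (24) and network-size (`max_nodes`) caps
  turn combinatorial blow-ups into early, actionable errors.
* Duplicate edges with conflicting signs are an input error, never
  silently resolved; exact duplicates collapse.
* Ties: greedy covers branch on them; elite selection prefers fewer
  removed edges; attractor-pair matching breaks ties lexicographically.
* Empty networks, empty circuits and identical attractor pairs raise
  informative errors at the stage that detects them.

## Limitations

* Transitions through cyclic attractors are not modelled.
* All interactions are equally strong: one gene per circuit is assumed
  sufficient to destabilize it, so weak-interaction robustness (several
  perturbation points per circuit) is out of scope.
* Profiles must arrive binarized; thresholding expression data is the
  caller's responsibility.
* Of the six published reprogramming case studies, only the EMT network
  could be reconstructed from printed interaction tables (its summary
  statistics and attractors match the published description exactly);
  the other five live in a supplementary data file and their checks are
  reported as not reproducible rather than approximated.
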