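---
title: "Analysing a metabolic pathway in the context of its connected pathways"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing a metabolic pathway in the context of its connected pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathcontext)
```

## The question

A biosynthetic pathway never operates alone: its intermediates are shared
with neighbouring pathways, and its behaviour — both topological and
metabolic — changes when it is considered as part of that larger network.
`pathcontext` implements a two-track analysis of a focal pathway, modelled
on the aromatic amino acid (tryptophan–tyrosine–phenylalanine, "TTP")
biosynthesis pathway of prokaryotes:

1. **Network track.** Build a *directed reaction network* (nodes are
   reactions; an edge runs from a producer of a metabolite to its
   consumer) for the focal pathway alone, for the focal pathway combined
   with each *connected pathway* (one sharing at least one metabolite),
   and for the *combined connected network* (CCN) of all of them at once.
   Compare degree, clustering coefficient, closeness and betweenness
   centrality of the focal reactions across those contexts, and detect
   *hubs* — nodes in the top 20% of a measure.
2. **Flux track.** On a stoichiometric model, run flux balance analysis
   (FBA), measure the flux each *section* of the focal pathway carries,
   and scan gene/reaction deletions and fractional-efficiency constraints
   for adverse effects on those section fluxes.

The tracks meet in an overlap report: what percentage of network hubs are
also FBA-essential for the focal pathway?

## The reaction-network model

For reactions $A$ and $B$, the edge rule is

$$A \to B \iff \exists\, m \notin X:\; m \in P(A) \wedge m \in S(B),$$

where $P(A)$ is $A$'s product set — extended by its substrate set when $A$
is reversible, since a reversible reaction can run either way — $S(B)$ is
$B$'s substrate set, symmetrically extended, and $X$ is the excluded
(currency) metabolite set. Two consequences are worth noting:

* mutually reversible neighbours produce *antiparallel edge pairs* (the
  double edges of pathway diagrams);
* self-loops are never created, even for degenerate reactions that
  regenerate their own substrate.

**Currency metabolites.** Cofactors such as ATP, NAD(P)H, water and
protons take part in most reactions; leaving them in makes the reaction
graph near-complete and hides the chemical backbone, which is known to be
sparse and largely linear for biosynthetic pathways. The default excluded
set (`currency_metabolites()`) covers ATP/ADP/AMP, NAD(+/H), NADP(+/H),
H2O, H+, Pi, PPi and CO2 by KEGG compound id, and can be disabled or
replaced per call.

**Combination.** `combine_networks()` unions the underlying reactions and
*re-derives* edges, so cross-pathway edges between previously separate
pathways appear (the default, `rederive_cross_edges = TRUE`). Plain
node/edge union is kept behind the flag because published combined-network
analyses do not always state which variant they used; re-derivation is the
chemically meaningful choice since an edge is a statement about shared
chemistry, not about bookkeeping of pathway files.

## Conventions for the network parameters

Published centrality tables rarely state their conventions; ours are fixed
and tested:

* **degree** — total (in + out) on the directed graph, so a graph's
  average degree is exactly $2E/n$;
* **clustering** — on the undirected projection (directed clustering has
  many competing definitions; the undirected one is the common toolbox
  default);
* **closeness** of $v$ — $1/\sum_u d(v,u)$ with unreachable distances
  replaced by the vertex count $n$. Under this convention a node reaching
  nothing scores exactly $1/(n(n-1))$; at the scale of a combined
  connected network of ~321 nodes this is $\approx 10^{-5}$, the order of
  magnitude reported for such networks — the harmonic-mean alternative
  would not reproduce it;
* **betweenness** — directed shortest-path betweenness normalised by
  $(n-1)(n-2)$, hence in $[0,1]$; defined 0 for $n<3$ and for nodes with
  at most one neighbour;
* **average path length** — mean over ordered pairs at finite distance; a
  graph with no reachable pairs reports 0 with a warning rather than NaN.

**Hubs** are the nodes in the top 20% (configurable) of degree,
betweenness or closeness. The cutoff is the value at descending rank
$\lceil 0.2 n \rceil$ and *ties at the cutoff are included*, so hub sets
may exceed the nominal size; an all-equal metric degenerates to "every
node is a hub", which is reported rather than hidden. Common hubs across
organisms are computed per metric and as a union-of-metrics variant
("hub of any measure in every organism"), since summaries of hub overlap
do not always say which was meant; both are emitted.

**Variation across contexts** (organisms, or focal-plus-one-pathway
combinations) is summarised per core reaction as the standard deviation
and the maximum |z| of each metric, flagged at the conventional thresholds
(sd > 2 for degree/clustering calls; |z| > 3 for betweenness calls). Both
thresholds are parameters.

## The FBA core

`fba_optimize()` maximises the biomass objective under $S v = 0$ and the
bound constraints, then fixes the optimal biomass and minimises total
absolute flux (a parsimonious second stage). Plain FBA returns an
arbitrary vertex of the optimal face, so reported per-reaction fluxes
would depend on solver internals; the parsimonious stage makes section
fluxes reproducible. Solutions satisfy mass balance to $10^{-9}$ (tested).

The linear programs are solved by a dense two-phase simplex written for
this package, using Bland's anti-cycling rule — FBA systems are extremely
degenerate (every internal metabolite contributes a zero right-hand
side), and Bland's rule guarantees termination there. The intended scale
is pathway-sized and toy models (tens of reactions); genome-scale models
load and are structurally supported, but a dense tableau at thousands of
reactions is slow and a dedicated LP backend would be the right tool.

**Sections and reporters.** The focal pathway is divided into sections
(for the aromatic pathway: Input, Shikimate, Tryptophan, Phe/Tyr); each
section's flux is read off one designated *reporter* reaction. Within a
section's linear segment the flux is undivided, so any member reaction is
representative — the reporter just makes the choice explicit, and
`read_section_map()` validates the assignment.

**Perturbations.** `delete_genes()` evaluates each reaction's
gene-protein-reaction (GPR) boolean rule against the surviving gene set —
`and` encodes complexes, `or` isozymes — and closes reactions whose rule
fails. `delete_reactions()` knocks out reactions directly; both scans are
available in `essentiality_scan()` because published deletion studies mix
the two senses. A candidate is *essential for the focal pathway* when any
section flux falls below $(1-\varepsilon)$ of its wild-type value minus a
$10^{-6}$ tolerance; $\varepsilon = 0$ by default ("any reduction is
adverse"), configurable because the adversity cutoff is a modelling
choice, not a law. `constrain_efficiency()` scales the bound on the signed
side of the wild-type flux: a reaction running at $v^* < 0$ has its
*lower* bound moved to $f v^*$, so magnitude scales and direction is kept.

## Statistics

Cross-group comparisons use the Wilcoxon tests, two-sided: signed-rank for
paired designs (focal vs combined, per organism), rank-sum for unpaired
(Bacteria vs Archaea). For paired samples of at most 15 the two-sided p is
computed by full enumeration of sign assignments of the tied-rank
statistic, which remains exact under ties; larger or unpaired cases fall
back on `stats::wilcox.test`. No multiple-testing correction is applied by
default, matching common practice in descriptive cross-pathway scans;
`p.adjust` can be applied downstream by users who need it.

Hub/essential overlap requires the hub ids (KEGG-style R-numbers) and the
model ids (BiGG-style mnemonics) to live in one namespace; the mapping is
an explicit two-column table (`read_id_map()`), never name matching.
Unmapped hubs are excluded from the denominator with a message (or raise
an error under `strict = TRUE`).

## What the synthetic generator emulates — and what it does not

`generate_ensemble()` builds what the cross-organism study design needs:
an ensemble of pseudo-organisms sharing a mostly linear focal backbone
(default 20 reactions, the mid-range of real focal pathways) with 17 side
pathways of linear/branched/dense topology attached through shared
metabolites, 29 organisms by default, and per-organism reaction dropout.
Two deliberate design choices:

* **Planted bridge.** Side-pathway attachments concentrate (probability
  0.6) on one backbone metabolite, and pathways attached there consume
  it, so the backbone reaction producing that metabolite mediates all
  traffic into them. That reaction — identified by the neutral rule
  "backbone reaction adjacent to the most attachment points" — is the
  recorded ground truth a betweenness-hub analysis should recover.
* **Conserved interior.** Backbone dropout only affects the variable
  input/terminal segments, as in real organisms whose focal pathways
  differ mainly at the input region. Interior dropout would sever the
  linear spine and destroy the planted signal for reasons that have
  nothing to do with the analysis under test.

What the generator does *not* emulate: mass-balanced stoichiometry in the
ensemble (pathway files carry qualitative substrate/product sets, as KGML
does), currency metabolites, compartments, and the heavy-tailed pathway
sizes of real genome-scale networks. Passing the recovery test therefore
shows that the hub machinery finds a genuinely central planted node under
noise — not that real pathway extracts are this clean.

`generate_toy_model()` builds the minimal stoichiometric model with a
known optimum: a linear chain carrying uptake $U$ into a branch point
whose products feed biomass with coefficients $(a, b)$. The closed form —
growth $g = U/(a+b)$, branch fluxes $ag$ and $bg$ — ships with the model
and every solver result is checked against it (tolerance $10^{-8}$).
Isozyme duplicates (same conversion, own gene) reproduce the robustness
phenomenon where deleting either member of an alternate-route pair leaves
flux unchanged.

## Numerical choices and degenerate inputs

* LP tolerances: pivot tolerance $10^{-9}$, phase-1 feasibility $10^{-7}$,
  reported fluxes zeroed below $10^{-9}$; infinite bounds are capped at
  $10^{6}$.
* A wild-type reaction carrying zero flux cannot be meaningfully
  efficiency-constrained; the call warns and returns the model unchanged.
* Networks of one node define closeness 0; betweenness is 0 whenever
  $n < 3$.
* Reactions appearing in several pathways merge into one node keyed by id
  (provenance keeps all sources); differing chemistry under one id merges
  by union with a warning.
* Ties at the hub cutoff are all included (see above); ties in paired
  Wilcoxon ranks are handled by the enumeration test.
* A metabolite on both sides of a reaction is rejected unless explicitly
  allowed (`allow_two_sided = TRUE`).

## Problem sizes used in the shipped checks

The test-suite and acceptance-script runs use 200 random digraphs of up to
10 nodes for the exhaustive centrality oracle, 80–100 random pathways of
up to 12 reactions for the edge-rule oracle, 200 five-organism replicates
for planted-bridge recovery, a 29-organism default ensemble for the
study-scale summary, and 400 replicates for the rank-test power check —
sizes at which the brute-force oracles are exact and the whole run
completes in well under a minute each.

## Known limitations

* The dense simplex is not a genome-scale production solver (see above).
* KGML parsing reads `<reaction>` elements only; `<entry type="map">`
  cross-references are deliberately ignored, so maps that encode links but
  no reactions yield empty pathways.
* SBML support covers L3+`fbc` and L2+COBRA-notes, the two encodings of
  constraint-based models in circulation; kinetic SBML is out of scope.
* Section fluxes are read from one reporter per section; branched sections
  whose flux is *not* undivided need a deliberate reporter choice.
* The ensemble generator's pathways are qualitative (no stoichiometric
  coefficients), so they exercise the network track, not the FBA track;
  the toy models do the reverse.
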