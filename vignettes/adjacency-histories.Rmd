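---
title: "Reconstructing ancestral gene adjacencies along a dated species tree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing ancestral gene adjacencies along a dated species tree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ancadj)
```

## The problem

Comparative genomics reconstructs ancestral genomes at two scales. Gene
*content* comes from reconciled gene trees: each gene family's tree is
annotated with the events (speciation, duplication, loss, lateral transfer)
that explain it inside a species tree, and the ancestral genes are simply
the internal nodes of those trees. Gene *order* is the other half: which
ancestral genes were neighbours on a chromosome? `ancadj` reconstructs
neighbourhood relations — *adjacencies*, unordered pairs of genes that are
immediately consecutive on a chromosome — at every internal node of a dated
species phylogeny, taking lateral gene transfer into account. Transfer
matters in two ways for prokaryotic genome evolution: ignoring it badly
distorts reconciliations, and transfers of whole blocks of co-functioning
genes are themselves a biological signal that adjacency reconstruction can
detect.

## The model

**Dated species tree.** A rooted binary species tree whose $s-1$ internal
nodes are totally ordered in time by integer ranks (root = rank 0). The
interval opened by the node of rank $k$ is *time slice* $k$; extant leaves
occupy one additional slice $s-1$. Only the order matters, not branch
lengths. Every gene-tree event is located by a (species branch, slice)
pair.

**Reconciled gene trees.** Each node carries a species assignment, an event
label among `Extant`, `Spec` (speciation), `SpecOut` (speciation out of the
species tree — the gene lineage leaves the sampled phylogeny), `Trans` (a
transfer back in from the unsampled lineage), `Dup`, `Loss`, and a time
slice. Transfers are modelled as a `SpecOut`/`Trans` pair because donors
almost always lie in unsampled or extinct sister lineages; the arrival may
be in a later slice than the departure. Gene lineages are assumed not to
diversify outside the species tree; input nodes that do (speciations with
species `OUT`) are removed by `prune_outside_diversification()`, cutting
the tree into independently rooted pieces, each a fresh origination.

**Adjacency histories.** An adjacency propagates from a pair of ancestral
genes to pairs of their descendants according to deterministic propagation
rules, one per combination of events at its two extremities: both
extremities follow a speciation into each child species; a duplication
passes the adjacency to exactly one of the two copies (the second copy's
adjacency, as after a tandem duplication, is a new gain); a loss silently
ends the adjacency (gene losses are not rearrangements); a co-transfer
carries it into the recipient genome. A *history* is a set of extant and
ancestral adjacencies; every adjacency without a rule parent is a *gain*,
every present adjacency whose rule descendant is absent is a *breakage*,
and the cost of the history is the weighted count
$n_\mathrm{gain} C_G + n_\mathrm{break} C_B$. The package minimises this
cost exactly, subject to the extant adjacencies being exactly the observed
ones. Defaults $C_G = C_B = 1$ minimise the plain number of rearrangement
events; the algorithm supports any non-negative weights.

## The algorithm

**Slicing.** `subdivide()` inserts unary `NoEvent` nodes wherever a gene
branch crosses a slice boundary between events, so that every parent–child
step spans at most one boundary. This aligns independent lineages in time:
two lineages in one species meet the same boundaries, and transfers can
only pair up if they depart and arrive in the same slices.

**Classes.** Two extant adjacencies are *possibly homologous* if a pair of
distinct ancestral genes with disjoint subtrees, in one species and slice,
covers their extremities. `build_classes()` computes, for each extant
adjacency, its admissible ancestor pairs by reverse moves that mirror the
recurrences (ascend through a duplication; through the inside child of a
`SpecOut`; through aligned `NoEvent` crossings; through paired speciations
at one species node; and through a `Trans`/`Trans` pair into its paired
`SpecOut` context). Adjacencies sharing a pair form one class; the class
root is the earliest shared pair. A Transfer node paired with anything but
a same-slice Transfer cannot be ascended through, so transferred
adjacencies root additional classes — exactly the behaviour the transfer
model demands. When one component has no single covering pair (possible
for same-family adjacencies), it is split greedily into maximal coverable
subclasses, earliest root first.

**Dynamic program.** For each class, over pairs $(a, b)$ of gene-tree
nodes in one species, two values are computed: $c_1(a,b)$ and $c_0(a,b)$,
the minimum history cost for the two subtrees assuming an adjacency
between $a$ and $b$ does / does not exist. Nine recurrence cases dispatch
on the event pair, each translating the corresponding propagation rule and
adding every rearrangement possibility: extant pairs are pinned to the
input; a loss zeroes both values; aligned `NoEvent` crossings and paired
transfers allow one gain or breakage per boundary; duplications resolve
first within a slice, with both orderings and the simultaneous
16-configuration term (`d12_configurations()`) when both sides duplicate
in one slice; speciations split into species-matched child pairs with
independent gain/breakage options; a lone `SpecOut` forwards the adjacency
to its inside child; paired `SpecOut`s with co-arriving transfers
additionally propagate to the transferred pair, with a breakage (resp.
gain) option covering the untracked outside segment. When the two sides'
slices differ, the earlier side acts alone (chronological dispatch) — this
is what allows a lagging lineage to catch up and pair its `SpecOut` with
the partner's. The optimum per class is
$\min\{c_1(\mathrm{root}) + C_G,\ c_0(\mathrm{root})\}$, and backtracking
re-derives each case's alternatives top-down to emit one optimal history
with located gains, breakages, co-transfer and co-duplication links.

**Tie-breaking.** Among cost-equal alternatives the backtracking prefers
the one inferring fewer ancestral adjacencies, then the first in the
printed order of the recurrence terms. This is conservative (absence is
preferred when presence is not needed to explain anything) and makes
output deterministic; co-optimal histories with more ancestral content can
exist, so reported events and totals — not the identity of the optimal
history — are the stable quantities.

## Summaries

`degree_distribution()` reports, per genome, the proportion of genes by
number of incident adjacencies (binned 0–6 and 7+). Extant bacterial
chromosomes are circular, so a perfectly reconstructed genome has every
gene at degree 2; the shortfall of degree-2 genes measures lost signal.
`adjacency_gene_ratio()` (adjacencies per gene, ideally 1) summarises the
same thing per genome. `find_event_clusters()` extracts *co-transferred*
clusters — genes linked by adjacencies that were present on the donor side
and carried through a single transfer step (same donor and recipient
species and slices) — and *co-duplicated* clusters, linked by adjacencies
maintained through a simultaneous duplication of both extremities. Both
use connected components with a minimum size of 2, and both deliberately
require a shared event: two transfers in different slices never join one
cluster, which is the strictest reading of "co-transferred".

## The simulator

`simulate_adjacency_evolution()` generates the study conditions for every
test: a uniform ranked species-tree topology (only ranks matter to the
method), a circular root genome of `n_genes` single-gene families, and
forward evolution slice by slice. Per gene and slice: duplication
(`dup_rate`, tandem with probability `tandem_prob` — a tandem duplication
splits the old neighbours between the copies and gains the copy–copy
adjacency), loss (`loss_rate`, adjacencies vanish at no rearrangement
cost), and transfer (`transfer_rate`) through a `SpecOut`/`Trans` pair into
a uniformly chosen later-or-equal slice on another living branch, taking a
contiguous block of 2–4 genes with probability `block_prob`, the block's
internal adjacencies riding along free. Per adjacency and slice, breakage
(`break_rate`); per branch and slice, one random gain (`gain_rate`).
Non-tandem copies and arriving blocks are spliced into the host chromosome
(one breakage, two gains) with probability `integration_prob`, keeping
genomes near-circular, or float otherwise. Defaults (10 genes,
duplication/loss/transfer 0.02, gain 0.05, breakage 0.01 per slice, block
transfers 0.3) keep per-lineage event counts small over a handful of
slices, the regime in which ancestral reconstruction is informative;
rates an order of magnitude higher mostly erase signal and mostly test
robustness, which the suite samples separately.

Two accounting details align the generator with the model's semantics.
Distinct transfer events leaving one donor branch in one slice take
distinct (arrival slice, recipient) coordinates: transfers sharing all
four coordinates are, to the model, a single co-transfer context, and in
continuous time independent coincidences have measure zero. And because a
transferred block is a linear run, a donor adjacency between two
co-transferred genes that is not on the run (the closing junction of a
fully transferred circular chromosome) cannot arrive with it and is
charged as a breakage in the ground truth. The exact-recovery property
(below) is stated for root genomes larger than the maximal block, where
such forced breakages cannot arise and the optimum is unique.

What the simulator emulates: the event model above, block co-transfer, and
ground truth (true ancestral genomes, per-event log, true history cost).
What it does not emulate: sequence evolution and gene-tree estimation
error, origination of novel families away from the root, intra-slice event
ordering ambiguity, and replacement transfers. Passing tests therefore
validate the combinatorial machinery under the model's own assumptions,
not robustness to misreconciled inputs.

## Numerical and design choices

* Costs are finite non-negative doubles; `Inf` is the absorbing sentinel
  for pinned extant states and never appears in outputs.
* Gene pairs are canonicalised in C-locale (radix) order so results do not
  depend on the session locale.
* Event locations: an event charged on a child pair is reported at that
  pair's species and the later of its two node slices; a class-root gain
  is reported at the root pair.
* The exhaustive oracle (`brute_force_min_cost()`) enumerates presence
  assignments over the pairs reachable from a class root and scores them
  globally from the propagation rules, sharing no code with the dynamic
  program; it refuses instances with more than 16 free pairs. It exists
  for validation, not analysis.
* Degenerate inputs: an empty adjacency table gives an empty zero-cost
  history; a genome with no genes has no defined adjacency/gene ratio
  (error); duplicate input adjacencies collapse (the model has no
  adjacency copy number).
* Where several "highest" root pairs exist, the earliest slice then a
  lexicographic node order decides; determinism everywhere was preferred
  over enumerating co-optima, which are out of scope.

## Problem sizes

The test suite validates optimality exactly against the oracle on hundreds
of small instances (2–4 species, 3-gene root genomes) under three cost
settings, checks the no-event limit against an independent small-parsimony
implementation on 50 instances, and verifies the parsimony bound (DP cost
≤ true simulated cost) on 50 moderate-rate replicates plus exact truth
recovery on rearrangement-free replicates. The demonstration run uses 36
genomes with a 25-gene root genome in the suite and a larger root genome
in `scripts/acceptance.R`; these sizes were chosen so a complete check
runs on one ordinary CPU in minutes while exercising every recurrence
case, and they scale linearly in the family count.

## Known limitations

* A single optimal history is returned; co-optimal histories are neither
  enumerated nor sampled, so presence of a specific ancestral adjacency
  in the output should be read as "consistent with optimality", not
  "required by it" (events and totals are the robust summaries).
* Transfers that replace a homolog are not modelled: every transfer
  arrival is a new copy, so replacement transfers inflate gains slightly.
* Originations and losses necessarily pay adjacency gains/breakages for
  their neighbours; no special-casing reduces that cost.
* Adjacencies are unordered and unoriented gene pairs: no strand, no
  physical distance, no chromosome assignment. Ancestral genes may have
  degree > 2; the reconstruction does not force chromosomal linearity or
  circularity, which is precisely what makes the degree-2 proportion an
  informative diagnostic.

## A worked example

The package ships a four-species instance (`inst/extdata/toy4`) with two
families related by a block co-transfer, one tandem duplication family, a
loss and a post-departure breakage:

```{r}
d <- system.file("extdata", "toy4", package = "ancadj")
st <- read_species_tree(file.path(d, "species_tree.nwk"),
                        file.path(d, "species_ranks.tsv"))
gt <- read_gene_trees(file.path(d, "gene_trees.nhx"), st)
adj <- read_adjacencies(file.path(d, "adjacencies.tsv"), gt)
h <- reconstruct_adjacencies(st, gt, adj)
glance(h)
tidy(h, "events")
find_event_clusters(h, "Transfer")
```

The four extant adjacencies are explained by two gains and one breakage
(total cost 3): one ancestral adjacency gained at the root and carried
through the co-transfer into C, broken in B after the transfer departed,
and one tandem-duplication adjacency gained in A.
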