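# ancadj

Ancestral gene adjacency reconstruction from gene trees reconciled with
duplication, loss and lateral transfer.

## What it does, and for whom

Given (1) a rooted binary **dated species tree** whose internal nodes are
totally ordered in time, (2) one **reconciled gene tree** per family whose
nodes carry species, event and time-slice annotations (events among
`Extant`, `Spec`, `SpecOut`, `Trans`, `Dup`, `Loss`), and (3) the
**extant adjacencies** (pairs of immediately consecutive genes), `ancadj`
reconstructs adjacencies in every ancestral genome by minimising the
weighted number of adjacency **gains** and **breakages** needed to explain
the observed ones:

```
cost(history) = n_gains * C(Gain) + n_breaks * C(Break)
```

Adjacencies descend through the gene trees by deterministic propagation
rules (one per combination of events at their two extremities); lateral
transfer is modelled as a speciation out of the sampled phylogeny
(`SpecOut`) followed by a transfer back in (`Trans`), possibly in a later
time slice, so adjacencies between co-transferred genes ride along at no
cost. Extant adjacencies are partitioned into possible-homology classes;
each class is solved exactly by a dynamic program over pairs of gene
subtrees, computing for each comparable node pair the minimum costs
`c1`/`c0` with/without an adjacency between them, in polynomial time.
Backtracking returns one minimum-cost history with located events, plus
clusters of **co-transferred** and **co-duplicated** genes and per-genome
circularity diagnostics (gene degree distributions, adjacency/gene
ratios). The intended users are people studying prokaryotic (or any
transfer-rich) genome evolution who already have reconciled gene trees
from a dated-phylogeny workflow.

A forward simulator with full ground truth and an exhaustive small-instance
oracle are part of the package, so the whole pipeline is testable without
external data.

## Worked example

The package ships a four-species instance (`inst/extdata/toy4`):
species tree `((A,B)e,(C,D)f)r` dated `r < e < f`, two gene families
related by an ancestral adjacency that is co-transferred from the B branch
into the C branch, broken in B after the departure, and lost with its
extremity in D — plus a third family that tandem-duplicates in A.

```r
library(ancadj)
d  <- system.file("extdata", "toy4", package = "ancadj")
st  <- read_species_tree(file.path(d, "species_tree.nwk"),
                         file.path(d, "species_ranks.tsv"))
gt  <- read_gene_trees(file.path(d, "gene_trees.nhx"), st)
adj <- read_adjacencies(file.path(d, "adjacencies.tsv"), gt)
h   <- reconstruct_adjacencies(st, gt, adj)   # unit costs

glance(h)
#> # A tibble: 1 x 9
#>   n_classes n_adjacencies n_extant n_ancestral n_gains n_breaks gain_cost
#> 1         2            13        4           9       2        1         1
#> # break_cost 1, total_cost 3

tidy(h, "events")
#> # A tibble: 3 x 5
#>   event species slice gene1   gene2
#> 1 Gain  r           0 fam1.n1 fam2.n1
#> 2 Gain  A           3 Z_A1    Z_A2
#> 3 Break B           3 X_B     Y_B

find_event_clusters(h, "Transfer")
#> # A tibble: 1 x 6
#>   cluster kind     species slice n_genes genes
#> 1       1 Transfer C           2       2 fam1.n6,fam2.n6
```

Reading: the four extant adjacencies cost 3 rearrangements — one ancestral
adjacency gained at the root (`fam1.n1`–`fam2.n1`), carried through the
co-transfer into C (the one co-transfer cluster) and broken in B, plus the
tandem-duplication adjacency gained in A. `tidy(h)` lists every inferred
ancestral adjacency with its species and time slice;
`degree_distribution(h, "f")` and `ancestral_genome_stats(h)` summarise
how circular each reconstructed genome is; `autoplot(h)` plots the degree
distributions.

Simulated data with ground truth:

```r
sim <- simulate_adjacency_evolution(n_species = 8, n_genes = 10, seed = 1)
h   <- reconstruct_adjacencies(sim$bundle$species_tree,
                               sim$bundle$gene_trees,
                               sim$bundle$adjacencies)
h$cost <= sim$truth$cost   # parsimony bound, always TRUE
```

Command line (thin wrappers over the same functions):

```sh
exec/ancadj-simulate --species 8 --genes 10 --seed 1 --out-dir sim/
exec/ancadj-reconstruct --species-tree sim/species_tree.nwk \
    --ranks sim/species_ranks.tsv --gene-trees sim/gene_trees.nhx \
    --adjacencies sim/adjacencies.tsv --out-dir out/
```

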