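test_that("an empty adjacency set yields an empty zero-cost history", {
  toy <- load_toy4()
  h <- reconstruct_adjacencies(toy$species_tree, toy$gene_trees,
                               toy$adjacencies[0, ])
  expect_equal(h$cost, 0)
  expect_equal(nrow(h$adjacencies), 0)
  expect_equal(nrow(h$gains) + nrow(h$breaks), 0)
})

test_that("a perfectly conserved adjacency costs one gain at the root", {
  # pure speciation, 4 species, adjacency present in every extant genome
  sim <- simulate_adjacency_evolution(n_species = 4, n_genes = 2,
                                      dup_rate = 0, loss_rate = 0,
                                      transfer_rate = 0, gain_rate = 0,
                                      break_rate = 0, seed = 5)
  b <- sim$bundle
  h <- reconstruct_adjacencies(b$species_tree, b$gene_trees, b$adjacencies)
  # two genes on a circular root genome form one adjacency, conserved
  expect_equal(nrow(dplyr::distinct(b$adjacencies[, 1:2])), 4) # one per leaf
  expect_equal(h$cost, 1 * h$costs$gain)
  expect_equal(nrow(h$gains), 1)
  # the ancestral adjacency is present in every ancestral genome
  st <- b$species_tree
  for (sp in st$nodes$name[!st$nodes$is_leaf]) {
    expect_equal(nrow(ancadj:::genome_adjacencies(h, sp)), 1)
  }
})

test_that("histories are self-consistent and bounded by independent gains", {
  for (seed in c(3, 8, 21)) {
    sim <- sim_small(seed, n_species = 5, n_genes = 4)
    b <- sim$bundle
    h <- reconstruct_adjacencies(b$species_tree, b$gene_trees,
                                 b$adjacencies)
    # cost recomputed from the event lists equals the DP optimum
    expect_equal(nrow(h$gains) * h$costs$gain +
                   nrow(h$breaks) * h$costs$breakage, h$cost)
    expect_equal(sum(h$classes$cost), h$cost)
    # the all-independent-gains history is always feasible
    n_ext <- nrow(dplyr::distinct(
      canonical_adjacency(b$adjacencies$gene1, b$adjacencies$gene2)))
    expect_lte(h$cost, h$costs$gain * n_ext)
    # extant adjacencies of the output equal the input set exactly
    out <- h$adjacencies[h$adjacencies$extant, ]
    inp <- dplyr::distinct(
      canonical_adjacency(b$adjacencies$gene1, b$adjacencies$gene2))
    expect_setequal(paste(out$gene1, out$gene2),
                    paste(inp$gene1, inp$gene2))
  }
})

test_that("ties prefer the history with fewer ancestral adjacencies", {
  # one adjacency seen in a single extant genome of a 4-species tree: a
  # gain at the extant pair and a gain at the root are co-optimal; the
  # conservative choice infers no ancestral adjacency
  st <- stree4()
  gt <- read_gene_trees(c(
    "((gA1[&&NHX:S=A:Ev=Extant],gB1[&&NHX:S=B:Ev=Extant])[&&NHX:S=e:Ev=Spec],(gC1[&&NHX:S=C:Ev=Extant],gD1[&&NHX:S=D:Ev=Extant])[&&NHX:S=f:Ev=Spec])[&&NHX:S=r:Ev=Spec];",
    "((gA2[&&NHX:S=A:Ev=Extant],gB2[&&NHX:S=B:Ev=Extant])[&&NHX:S=e:Ev=Spec],(gC2[&&NHX:S=C:Ev=Extant],gD2[&&NHX:S=D:Ev=Extant])[&&NHX:S=f:Ev=Spec])[&&NHX:S=r:Ev=Spec];"
  ), st)
  adj <- canonical_adjacency("gA1", "gA2")
  h <- reconstruct_adjacencies(st, gt, adj)
  expect_equal(h$cost, 1)
  expect_equal(nrow(h$adjacencies), 1)     # only the extant pair itself
  expect_true(all(h$adjacencies$extant))
})
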