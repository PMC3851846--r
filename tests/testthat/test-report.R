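test_that("degree distributions and ratios behave on circular genomes", {
  # no events: every genome stays a 6-gene circle, all degrees 2, ratio 1
  sim <- simulate_adjacency_evolution(n_species = 4, n_genes = 6,
                                      dup_rate = 0, loss_rate = 0,
                                      transfer_rate = 0, gain_rate = 0,
                                      break_rate = 0, seed = 3)
  b <- sim$bundle
  h <- reconstruct_adjacencies(b$species_tree, b$gene_trees, b$adjacencies)
  st <- b$species_tree
  for (sp in st$nodes$name) {
    dd <- degree_distribution(h, sp)
    expect_equal(sum(dd$proportion), 1)
    expect_equal(dd$proportion[dd$degree == "2"], 1)
    expect_equal(adjacency_gene_ratio(h, sp), 1)
  }
  expect_error(degree_distribution(h, "nope"), "unknown species")
})

test_that("genes without adjacencies have degree zero and ratio zero", {
  # a single-gene root genome has no adjacencies anywhere
  sim <- simulate_adjacency_evolution(n_species = 3, n_genes = 1,
                                      dup_rate = 0, loss_rate = 0,
                                      transfer_rate = 0, gain_rate = 0,
                                      break_rate = 0, seed = 4)
  b <- sim$bundle
  h <- reconstruct_adjacencies(b$species_tree, b$gene_trees, b$adjacencies)
  sp <- b$species_tree$nodes$name[!b$species_tree$nodes$is_leaf][1]
  dd <- degree_distribution(h, sp)
  expect_equal(dd$proportion[dd$degree == "0"], 1)
  expect_equal(adjacency_gene_ratio(h, sp), 0)
})

test_that("degraded histories have fewer degree-2 genes than intact ones", {
  sim <- simulate_adjacency_evolution(n_species = 4, n_genes = 8,
                                      dup_rate = 0.01, loss_rate = 0.01,
                                      transfer_rate = 0.01,
                                      gain_rate = 0.02, break_rate = 0.01,
                                      seed = 8)
  b <- sim$bundle
  h <- reconstruct_adjacencies(b$species_tree, b$gene_trees, b$adjacencies)
  st <- b$species_tree
  root <- st$root
  full <- degree_distribution(h, root)
  p2_full <- full$proportion[full$degree == "2"]
  # degrade: delete half of the root genome's adjacencies
  h2 <- h
  at_root <- h2$adjacencies$species == root &
    h2$adjacencies$slice == st$nodes$node_slice[match(root, st$nodes$name)]
  drop <- which(at_root)[c(TRUE, FALSE)]
  h2$adjacencies <- h2$adjacencies[-drop, ]
  degraded <- degree_distribution(h2, root)
  expect_lte(degraded$proportion[degraded$degree == "2"], p2_full)
})

test_that("co-transferred blocks are recovered as one cluster", {
  # hand-built: three families co-transferred as a block from B to C, with
  # both internal adjacencies surviving in donor and recipient
  st <- stree4()
  fam <- function(g) paste0(
    "((", g, "_A[&&NHX:S=A:Ev=Extant],(", g, "_B[&&NHX:S=B:Ev=Extant],(",
    g, "_Ct[&&NHX:S=C:Ev=Extant])[&&NHX:S=C:Ev=Trans:ts=2])",
    "[&&NHX:S=B:Ev=SpecOut:ts=1])[&&NHX:S=e:Ev=Spec],(", g,
    "_C[&&NHX:S=C:Ev=Extant],", g, "_D[&&NHX:S=D:Ev=Extant])",
    "[&&NHX:S=f:Ev=Spec])[&&NHX:S=r:Ev=Spec];")
  gt <- read_gene_trees(vapply(c("w", "x", "y"), fam, character(1)), st)
  adj <- dplyr::bind_rows(
    canonical_adjacency(c("w_A", "x_A"), c("x_A", "y_A")),
    canonical_adjacency(c("w_B", "x_B"), c("x_B", "y_B")),
    canonical_adjacency(c("w_Ct", "x_Ct"), c("x_Ct", "y_Ct")))
  h <- reconstruct_adjacencies(st, gt, adj)
  cl <- find_event_clusters(h, "Transfer")
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_genes, 3)
  expect_equal(cl$species, "C")
  # no duplication clusters in this instance
  expect_equal(nrow(find_event_clusters(h, "Duplication")), 0)
})

test_that("independent single transfers form no cluster", {
  st <- stree4()
  fam <- function(g, so_slice, tr_slice) paste0(
    "((", g, "_A[&&NHX:S=A:Ev=Extant],(", g, "_B[&&NHX:S=B:Ev=Extant],(",
    g, "_Ct[&&NHX:S=C:Ev=Extant])[&&NHX:S=C:Ev=Trans:ts=", tr_slice,
    "])[&&NHX:S=B:Ev=SpecOut:ts=", so_slice,
    "])[&&NHX:S=e:Ev=Spec],(", g, "_C[&&NHX:S=C:Ev=Extant],", g,
    "_D[&&NHX:S=D:Ev=Extant])[&&NHX:S=f:Ev=Spec])[&&NHX:S=r:Ev=Spec];")
  # two transfers in different slices: not one event
  gt <- read_gene_trees(c(fam("w", 1, 2), fam("x", 2, 2)), st)
  adj <- canonical_adjacency(c("w_A", "w_B"), c("x_A", "x_B"))
  h <- reconstruct_adjacencies(st, gt, adj)
  expect_equal(nrow(find_event_clusters(h, "Transfer")), 0)
})

test_that("adjacencies kept through simultaneous duplication form a co-duplication cluster", {
  st <- stree4()
  fam <- function(g) paste0(
    "((", g, "_A1[&&NHX:S=A:Ev=Extant],", g,
    "_A2[&&NHX:S=A:Ev=Extant])[&&NHX:S=A:Ev=Dup:ts=1],", g,
    "_B[&&NHX:S=B:Ev=Extant])[&&NHX:S=e:Ev=Spec];")
  gt <- read_gene_trees(c(fam("u"), fam("v")), st)
  adj <- canonical_adjacency(c("u_A1", "u_A2", "u_B"),
                             c("v_A1", "v_A2", "v_B"))
  h <- reconstruct_adjacencies(st, gt, adj)
  # one ancestral gain, both duplicated copies keep the adjacency for free
  expect_equal(h$cost, 1)
  cl <- find_event_clusters(h, "Duplication")
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_genes, 2)
  expect_equal(cl$species, "A")
  expect_equal(cl$slice, 1L)
})

test_that("no transfers means no transfer clusters", {
  sim <- simulate_adjacency_evolution(n_species = 4, n_genes = 4,
                                      dup_rate = 0.05, loss_rate = 0.05,
                                      transfer_rate = 0, gain_rate = 0.1,
                                      break_rate = 0.05, seed = 77)
  b <- sim$bundle
  h <- reconstruct_adjacencies(b$species_tree, b$gene_trees, b$adjacencies)
  expect_equal(nrow(find_event_clusters(h, "Transfer")), 0)
})

test_that("the handshake bound holds on simulated reconstructions", {
  sim <- sim_small(123, n_species = 5, n_genes = 5)
  b <- sim$bundle
  h <- reconstruct_adjacencies(b$species_tree, b$gene_trees, b$adjacencies)
  stats <- ancestral_genome_stats(h)
  stats <- stats[stats$n_genes > 0, ]
  for (i in seq_len(nrow(stats))) {
    dd <- degree_distribution(h, stats$species[i])
    degs <- c(0:6, 7)
    maxdeg <- max(degs[dd$n_genes > 0])
    expect_lte(stats$ratio[i], maxdeg / 2 + 1e-12)
  }
})
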