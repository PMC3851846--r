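test_that("extant and loss cells take their closed-form values", {
  st <- stree4()
  gt <- read_gene_trees(c(
    "(gA1[&&NHX:S=A:Ev=Extant],gB1[&&NHX:S=B:Ev=Extant])[&&NHX:S=e:Ev=Spec];",
    "(gA2[&&NHX:S=A:Ev=Extant],gB2[&&NHX:S=B:Ev=Extant])[&&NHX:S=e:Ev=Spec];"
  ), st)
  sliced <- lapply(gt, subdivide, stree = st)
  adj <- canonical_adjacency("gA1", "gA2")
  ctx <- dp_context(sliced, cost_params(), adj)
  leaf <- function(tr, lab) which(sliced[[tr]]$label == lab)
  # an input extant adjacency: (c1, c0) = (0, Inf)
  expect_equal(cell_value(ctx, c(1L, leaf(1, "gA1"), 2L, leaf(2, "gA2"))),
               c(0, Inf))
  # a non-adjacent extant pair: (Inf, 0)
  expect_equal(cell_value(ctx, c(1L, leaf(1, "gB1"), 2L, leaf(2, "gB2"))),
               c(Inf, 0))
  # a lost gene against anything: (0, 0)
  gtl <- read_gene_trees(c(
    "(gA3[&&NHX:S=A:Ev=Extant],[&&NHX:S=B:Ev=Loss:ts=1])[&&NHX:S=e:Ev=Spec];",
    "(gA4[&&NHX:S=A:Ev=Extant],gB4[&&NHX:S=B:Ev=Extant])[&&NHX:S=e:Ev=Spec];"
  ), st)
  sl <- lapply(gtl, subdivide, stree = st)
  ctx2 <- dp_context(sl, cost_params(), canonical_adjacency("gA3", "gA4"))
  lossn <- which(sl[[1]]$event == "Loss")
  bleaf <- which(sl[[2]]$label == "gB4")
  expect_equal(cell_value(ctx2, c(1L, lossn, 2L, bleaf)), c(0, 0))
})

test_that("matrices are symmetric in the two trees and bounded in size", {
  toy <- load_toy4()
  sliced <- lapply(toy$gene_trees, subdivide, stree = toy$species_tree)
  adj <- toy$adjacencies
  cls <- build_classes(adj, sliced)
  big <- cls[[which.max(vapply(cls, function(x) nrow(x$members),
                               integer(1)))]]
  ctx_a <- dp_context(sliced, cost_params(), adj)
  v_a <- cell_value(ctx_a, big$root)
  ctx_b <- dp_context(sliced, cost_params(), adj)
  v_b <- cell_value(ctx_b, big$root[c(3, 4, 1, 2)])
  expect_equal(v_a, v_b)
  # cell count never exceeds the product of the two trees' node counts
  n_cells <- nrow(dp_cells(ctx_a))
  expect_lte(n_cells,
             nrow(sliced[[big$root[1]]]$nodes) *
               nrow(sliced[[big$root[3]]]$nodes))
})

test_that("cells are non-negative and at most one state is infeasible", {
  sim <- sim_small(202, n_species = 4, n_genes = 4)
  b <- sim$bundle
  sliced <- lapply(b$gene_trees, subdivide, stree = b$species_tree)
  adj <- dplyr::distinct(
    canonical_adjacency(b$adjacencies$gene1, b$adjacencies$gene2))
  ctx <- dp_context(sliced, cost_params(), adj)
  for (cls in build_classes(adj, sliced)) fill_matrix(cls, ctx)
  cells <- dp_cells(ctx)
  expect_true(all(cells$c1 >= 0 & cells$c0 >= 0))
  expect_false(any(is.infinite(cells$c1) & is.infinite(cells$c0)))
})

test_that("cell values are monotone in the event costs", {
  for (seed in c(11, 12, 13)) {
    sim <- sim_small(seed, n_species = 4, n_genes = 3)
    b <- sim$bundle
    sliced <- lapply(b$gene_trees, subdivide, stree = b$species_tree)
    adj <- dplyr::distinct(
      canonical_adjacency(b$adjacencies$gene1, b$adjacencies$gene2))
    cls <- build_classes(adj, sliced)
    ctx1 <- dp_context(sliced, cost_params(1, 1), adj)
    ctx2 <- dp_context(sliced, cost_params(2, 1), adj)
    ctx3 <- dp_context(sliced, cost_params(1, 3), adj)
    for (cl in cls) {
      v1 <- cell_value(ctx1, cl$root)
      v2 <- cell_value(ctx2, cl$root)
      v3 <- cell_value(ctx3, cl$root)
      expect_true(all(v2 >= v1 - 1e-12))
      expect_true(all(v3 >= v1 - 1e-12))
    }
  }
})

test_that("the oracle agrees with the DP on random small instances", {
  # a quick spot check; the full sweep lives in the acceptance suite
  res <- do.call(rbind, lapply(1:10, function(s)
    dp_vs_oracle(sim_small(s + 40)$bundle)))
  res <- res[!is.na(res$oracle), ]
  expect_gt(nrow(res), 10)
  expect_equal(res$dp, res$oracle)
})

test_that("the oracle is invariant under gene and species relabeling", {
  sim <- sim_small(77, n_species = 3, n_genes = 2)
  b <- sim$bundle
  sliced <- lapply(b$gene_trees, subdivide, stree = b$species_tree)
  adj <- dplyr::distinct(
    canonical_adjacency(b$adjacencies$gene1, b$adjacencies$gene2))
  cls <- build_classes(adj, sliced)
  base <- vapply(cls, function(cl)
    brute_force_min_cost(cl, sliced, cost_params(), adj), numeric(1))
  # relabel genes (prefix) and species everywhere
  relab <- function(tr) {
    tr$nodes$label <- paste0("Q", tr$nodes$label)
    tr$nodes$species <- paste0("Z", tr$nodes$species)
    out <- recon_gene_tree(tr$nodes, tr$family, validate = FALSE)
    out
  }
  sliced2 <- lapply(sliced, relab)
  adj2 <- canonical_adjacency(paste0("Q", adj$gene1),
                              paste0("Q", adj$gene2))
  cls2 <- build_classes(adj2, sliced2)
  again <- vapply(cls2, function(cl)
    brute_force_min_cost(cl, sliced2, cost_params(), adj2), numeric(1))
  expect_equal(sort(base), sort(again))
})

test_that("the oracle refuses oversized instances", {
  toy <- load_toy4()
  sliced <- lapply(toy$gene_trees, subdivide, stree = toy$species_tree)
  cls <- build_classes(toy$adjacencies, sliced)
  big <- cls[[which.max(vapply(cls, function(x) nrow(x$members),
                               integer(1)))]]
  expect_error(
    brute_force_min_cost(big, sliced, cost_params(), toy$adjacencies,
                         max_pairs = 2L),
    "refuses")
})
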