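test_that("the no-event limit gives intact circular genomes", {
  sim <- simulate_adjacency_evolution(n_species = 5, n_genes = 6,
                                      dup_rate = 0, loss_rate = 0,
                                      transfer_rate = 0, gain_rate = 0,
                                      break_rate = 0, seed = 42)
  b <- sim$bundle
  st <- b$species_tree
  leaves <- st$nodes$name[st$nodes$is_leaf]
  for (sp in leaves) {
    genes <- b$adjacencies[b$adjacencies$species == sp, ]
    expect_equal(nrow(genes), 6) # 6 genes -> 6 adjacencies (circular)
    deg <- table(c(genes$gene1, genes$gene2))
    expect_true(all(deg == 2))
  }
  # the true history cost is the 6 root originations
  expect_equal(sim$truth$cost, 6)
  expect_equal(sim$truth$n_gains, 6)
  expect_equal(sim$truth$n_breaks, 0)
})

test_that("the same seed reproduces the simulation byte for byte", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- sim_small(9, n_species = 5, n_genes = 4)
  s2 <- sim_small(9, n_species = 5, n_genes = 4)
  write_input_bundle(s1$bundle, d1)
  write_input_bundle(s2$bundle, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # and different seeds differ
  s3 <- sim_small(10, n_species = 5, n_genes = 4)
  expect_false(identical(s1$bundle$adjacencies, s3$bundle$adjacencies))
})

test_that("every simulated gene tree passes input validation", {
  for (seed in 1:10) {
    sim <- sim_small(seed + 900, n_species = 6, n_genes = 4)
    st <- sim$bundle$species_tree
    for (tr in sim$bundle$gene_trees) {
      expect_silent(ancadj:::validate_gene_tree(tr, st))
    }
    # serialised form re-parses to the same trees
    d <- withr::local_tempdir()
    write_input_bundle(sim$bundle, d)
    st2 <- read_species_tree(file.path(d, "species_tree.nwk"),
                             file.path(d, "species_ranks.tsv"))
    gt <- read_gene_trees(file.path(d, "gene_trees.nhx"), st2)
    expect_length(gt, length(sim$bundle$gene_trees))
  }
})

test_that("breakage counts follow their binomial expectation", {
  # per-adjacency per-slice breakage with everything else off: with one
  # 2-species tree (a single ancestral slice) each of the n root
  # adjacencies is tested exactly twice (once per terminal branch)
  p <- 0.2; n <- 8; reps <- 200
  breaks <- vapply(seq_len(reps), function(s) {
    sim <- simulate_adjacency_evolution(n_species = 2, n_genes = n,
                                        dup_rate = 0, loss_rate = 0,
                                        transfer_rate = 0, gain_rate = 0,
                                        break_rate = p, seed = 5000 + s)
    sim$truth$n_breaks
  }, numeric(1))
  trials <- 2 * n
  expected <- trials * p
  se <- sqrt(trials * p * (1 - p) / reps)
  expect_lt(abs(mean(breaks) - expected), 3 * se)
})

test_that("the true history is feasible: DP cost never exceeds it", {
  for (seed in 1:8) {
    sim <- sim_small(seed + 60, n_species = 5, n_genes = 4)
    b <- sim$bundle
    h <- reconstruct_adjacencies(b$species_tree, b$gene_trees,
                                 b$adjacencies)
    expect_lte(h$cost, sim$truth$cost)
  }
})
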