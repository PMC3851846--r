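test_that("canonical adjacencies are symmetric, idempotent and C-ordered", {
  expect_equal(canonical_adjacency("b", "a"),
               tibble::tibble(gene1 = "a", gene2 = "b"))
  expect_equal(canonical_adjacency("a", "b"),
               tibble::tibble(gene1 = "a", gene2 = "b"))
  # lexicographic, not numeric: "x10" sorts before "x9"
  expect_equal(canonical_adjacency("x9", "x10"),
               tibble::tibble(gene1 = "x10", gene2 = "x9"))
  expect_error(canonical_adjacency("g", "g"), "self-adjacency")
  # vectorised symmetry
  a <- c("q", "a", "z3"); b <- c("b", "q", "z11")
  expect_equal(canonical_adjacency(a, b), canonical_adjacency(b, a))
})

test_that("cost parameters are validated", {
  cp <- cost_params()
  expect_equal(cp$gain, 1)
  expect_equal(cp$breakage, 1)
  expect_error(cost_params(-1, 1), "non-negative")
  expect_error(cost_params(1, Inf), "finite")
})

test_that("dated species tree invariants are enforced", {
  st <- stree4()
  expect_equal(st$n_species, 4)
  expect_equal(sum(!st$nodes$is_leaf), 3) # s - 1 internal nodes
  # ranks must respect ancestry
  expect_error(
    dated_species_tree(data.frame(
      name = c("r", "e", "f", "A", "B", "C", "D"),
      parent = c(NA, "r", "r", "e", "e", "f", "f"),
      rank = c(2, 1, 0, NA, NA, NA, NA))),
    "rank")
  # duplicate labels rejected
  expect_error(
    dated_species_tree(data.frame(
      name = c("r", "A", "A"), parent = c(NA, "r", "r"),
      rank = c(0, NA, NA))),
    "duplicate")
})

test_that("gene tree arity rules reject malformed events", {
  st <- stree4()
  # duplication with a single child
  expect_error(
    read_gene_trees("((g_A[&&NHX:S=A:Ev=Extant])[&&NHX:S=A:Ev=Dup:ts=1],g_B[&&NHX:S=B:Ev=Extant])[&&NHX:S=e:Ev=Spec];",
                    st),
    "Dup")
  # transfer must sit below a SpeciationOut
  expect_error(
    read_gene_trees("((g_A[&&NHX:S=A:Ev=Extant])[&&NHX:S=A:Ev=Trans:ts=1],g_B[&&NHX:S=B:Ev=Extant])[&&NHX:S=e:Ev=Spec];",
                    st),
    "SpeciationOut|SpecOut|own donor")
})
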