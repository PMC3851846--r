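test_that("branch slice intervals match the dated topology", {
  st <- stree4() # ((A,B)e,(C,D)f)r with r=0 < e=1 < f=2
  sl <- assign_slices(st)
  n_slices <- function(sp) sl$n_slices[sl$species == sp]
  # branches to A, B and to the ancestor of C and D overlap two slices,
  # the others one
  expect_equal(n_slices("A"), 2)
  expect_equal(n_slices("B"), 2)
  expect_equal(n_slices("f"), 2)
  expect_equal(n_slices("e"), 1)
  expect_equal(n_slices("C"), 1)
  expect_equal(n_slices("D"), 1)
  # two-leaf tree: both terminal branches overlap exactly one slice
  st2 <- read_species_tree("(A,B)r;", data.frame(node = "r", rank = 0))
  sl2 <- assign_slices(st2)
  expect_true(all(sl2$n_slices[sl2$species %in% c("A", "B")] == 1))
  # caterpillar on 4 leaves: the deepest terminal branch spans 3 slices
  st3 <- read_species_tree("(((A,B)x,C)y,D)z;",
                           data.frame(node = c("z", "y", "x"), rank = 0:2))
  sl3 <- assign_slices(st3)
  expect_equal(sl3$n_slices[sl3$species == "D"], 3)
})

test_that("subdivision inserts NoEvent nodes exactly at crossed boundaries", {
  st <- stree4()
  # a lineage living through the two-slice branch to A with no event gets
  # exactly one NoEvent node
  tr <- read_gene_trees(
    "(g_A[&&NHX:S=A:Ev=Extant],g_B[&&NHX:S=B:Ev=Extant])[&&NHX:S=e:Ev=Spec];",
    st)[[1]]
  sub <- subdivide(tr, st)
  ne <- which(sub$event == "NoEvent")
  expect_equal(length(ne), 2) # one per terminal branch (A and B)
  expect_true(all(sub$slice[ne] == 2))
  # a branch within a single slice is unchanged
  st2 <- read_species_tree("(A,B)r;", data.frame(node = "r", rank = 0))
  tr2 <- read_gene_trees(
    "(h_A[&&NHX:S=A:Ev=Extant],h_B[&&NHX:S=B:Ev=Extant])[&&NHX:S=r:Ev=Spec];",
    st2)[[1]]
  expect_identical(subdivide(tr2, st2)$nodes, tr2$nodes)
})

test_that("subdivision bounds steps to one slice and is invertible", {
  for (seed in 1:20) {
    sim <- sim_small(seed + 500, n_species = 5, n_genes = 3)
    st <- sim$bundle$species_tree
    for (tr in sim$bundle$gene_trees) {
      sub <- subdivide(tr, st)
      # every parent-child step spans at most one slice boundary (outside
      # segments between SpecOut and Trans excepted)
      for (i in seq_len(nrow(sub$nodes))) {
        p <- sub$parent[i]
        if (is.na(p)) next
        if (sub$event[p] == "SpecOut" &&
            sub$species[i] != sub$species[p]) next
        expect_lte(sub$slice[i] - sub$slice[p], 1)
      }
      # leaf set, event multiset and species annotations are preserved
      expect_setequal(sub$label[sub$event == "Extant"],
                      tr$label[tr$event == "Extant"])
      expect_equal(sort(table(sub$event[sub$event != "NoEvent"])),
                   sort(table(tr$event)))
      # splicing the NoEvent nodes recovers the input exactly
      rec <- splice_noevent(sub)
      expect_equal(rec$nodes[order(rec$label), c("label", "species",
                                                 "event", "slice")],
                   tr$nodes[order(tr$label), c("label", "species",
                                               "event", "slice")],
                   ignore_attr = TRUE)
    }
  }
})

test_that("non-chronological reconciliations are rejected", {
  st <- stree4()
  # a duplication placed in a slice before its parent speciation
  expect_error(
    read_gene_trees(paste0(
      "((g_A[&&NHX:S=A:Ev=Extant],g_A2[&&NHX:S=A:Ev=Extant])",
      "[&&NHX:S=A:Ev=Dup:ts=0],g_B[&&NHX:S=B:Ev=Extant])",
      "[&&NHX:S=e:Ev=Spec];"), st),
    "slice|chronological")
})
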