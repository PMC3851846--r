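# shared helpers: the bundled four-species worked example, small builders,
# and an independent small-parsimony (Sankoff) implementation used as a
# cross-check in the no-event limit

toy4_dir <- function() {
  d <- system.file("extdata", "toy4", package = "ancadj")
  if (d == "") d <- file.path("..", "..", "inst", "extdata", "toy4")
  normalizePath(d)
}

load_toy4 <- function() {
  d <- toy4_dir()
  st <- read_species_tree(file.path(d, "species_tree.nwk"),
                          file.path(d, "species_ranks.tsv"))
  gt <- read_gene_trees(file.path(d, "gene_trees.nhx"), st)
  adj <- read_adjacencies(file.path(d, "adjacencies.tsv"), gt)
  list(species_tree = st, gene_trees = gt, adjacencies = adj)
}

# the four-species dated tree used throughout: ((A,B)e,(C,D)f)r,
# ranks r=0 < e=1 < f=2
stree4 <- function() {
  read_species_tree("((A,B)e,(C,D)f)r;",
                    data.frame(node = c("r", "e", "f"), rank = 0:2))
}

# small simulated instance with all pipeline stages exercised
sim_small <- function(seed, n_species = 4, n_genes = 3, ...) {
  simulate_adjacency_evolution(
    n_species = n_species, n_genes = n_genes,
    dup_rate = 0.08, loss_rate = 0.08, transfer_rate = 0.1,
    gain_rate = 0.15, break_rate = 0.08, block_prob = 0.4, seed = seed, ...)
}

# DP optimum of every class of an instance, plus the oracle value where the
# instance is small enough; returns a data frame of (dp, oracle) per class
dp_vs_oracle <- function(bundle, gain = 1, breakage = 1) {
  costs <- cost_params(gain, breakage)
  sliced <- lapply(bundle$gene_trees, subdivide,
                   stree = bundle$species_tree)
  adj <- bundle$adjacencies
  adj <- if (nrow(adj)) {
    dplyr::distinct(canonical_adjacency(adj$gene1, adj$gene2))
  } else {
    adj[, c("gene1", "gene2")]
  }
  classes <- build_classes(adj, sliced)
  ctx <- dp_context(sliced, costs, adj)
  out <- lapply(classes, function(cls) {
    v <- cell_value(ctx, cls$root)
    dp <- min(v[1] + costs$gain, v[2])
    oc <- tryCatch(
      brute_force_min_cost(cls, sliced, costs, adj),
      error = function(e) {
        if (grepl("refuses", conditionMessage(e))) NA_real_ else stop(e)
      })
    data.frame(dp = dp, oracle = oc)
  })
  do.call(rbind, out)
}

# Independent small parsimony on the species tree: leaf states are the
# presence/absence of the adjacency per extant species, substitution costs
# are asymmetric (0->1 costs `gain`, 1->0 costs `breakage`), and a present
# root state pays one extra gain. Plain Sankoff recursion, sharing nothing
# with the package's dynamic program.
sankoff_presence_cost <- function(stree, present_species, gain, breakage) {
  score <- function(name) {
    kids <- stree$nodes$name[!is.na(stree$nodes$parent) &
                               stree$nodes$parent == name]
    if (!length(kids)) {
      st <- if (name %in% present_species) c(Inf, 0) else c(0, Inf)
      return(st) # (cost assuming absent, cost assuming present)
    }
    tot <- c(0, 0)
    for (k in kids) {
      sk <- score(k)
      tot <- tot + c(min(sk[1], sk[2] + gain),
                     min(sk[2], sk[1] + breakage))
    }
    tot
  }
  s <- score(stree$root)
  min(s[1], s[2] + gain)
}
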