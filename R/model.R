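#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Event vocabulary used throughout. `NoEvent` nodes are synthesised by
# subdivide(), never required in input files.
EVENTS <- c("Extant", "Spec", "SpecOut", "Trans", "Dup", "Loss", "NoEvent")

# Species label marking gene lineages outside the sampled species tree.
OUT_SPECIES <- "OUT"

#' Put an adjacency in canonical (lexicographic) order
#'
#' Adjacencies are unordered, unoriented pairs of gene identifiers; a single
#' canonical representation makes deduplication and set comparisons trivial.
#' Vectorised over both arguments.
#'
#' @param gene1,gene2 Character vectors of gene identifiers.
#' @return A tibble with columns `gene1`, `gene2` where `gene1 < gene2`
#'   in C-locale string order, one row per input pair.
#' @examples
#' canonical_adjacency("b", "a")
#' @export
canonical_adjacency <- function(gene1, gene2) {
  gene1 <- as.character(gene1)
  gene2 <- as.character(gene2)
  if (length(gene1) != length(gene2)) {
    abort("gene1 and gene2 must have the same length")
  }
  if (any(gene1 == gene2)) {
    abort(paste0(
      "self-adjacency is undefined (gene paired with itself): ",
      paste(unique(gene1[gene1 == gene2]), collapse = ", ")
    ))
  }
  swap <- string_gt(gene1, gene2)
  g1 <- ifelse(swap, gene2, gene1)
  g2 <- ifelse(swap, gene1, gene2)
  tibble(gene1 = g1, gene2 = g2)
}

# Locale-independent string comparison (radix/C collation), so canonical
# order is stable across platforms. Vectorised: one radix sort of the
# combined vector; equal strings receive adjacent ranks, and elements are
# only ever compared within a pair of distinct strings.
string_gt <- function(a, b) {
  n <- length(a)
  if (!n) return(logical(0))
  v <- c(a, b)
  o <- order(v, method = "radix")
  rk <- integer(2L * n)
  rk[o] <- seq_len(2L * n)
  rk[seq_len(n)] > rk[n + seq_len(n)]
}

#' Gain and breakage costs
#'
#' Adjacency gains and breakages may be weighted differently; equal unit
#' costs (the default) minimise the plain number of rearrangements.
#'
#' @param gain Non-negative finite cost of an adjacency gain.
#' @param breakage Non-negative finite cost of an adjacency breakage.
#' @return A list of class `cost_params`.
#' @export
cost_params <- function(gain = 1, breakage = 1) {
  if (!is.numeric(gain) || length(gain) != 1 || !is.finite(gain) || gain < 0) {
    abort("`gain` must be a single finite non-negative number")
  }
  if (!is.numeric(breakage) || length(breakage) != 1 ||
      !is.finite(breakage) || breakage < 0) {
    abort("`breakage` must be a single finite non-negative number")
  }
  structure(list(gain = gain, breakage = breakage), class = "cost_params")
}

#' Construct a dated species tree
#'
#' A rooted binary species tree whose internal nodes are totally ordered in
#' time by integer ranks (root has the smallest rank). The s - 1 internal
#' nodes of a tree on s extant genomes define s - 1 ancestral time slices
#' (slice k starts at the internal node of rank k); extant leaves live in
#' one additional slice with index s - 1.
#'
#' @param nodes A data frame with columns `name` (unique node labels),
#'   `parent` (parent name, `NA` for the root) and `rank` (integer rank for
#'   internal nodes, `NA` for leaves).
#' @return An object of class `dated_species_tree`.
#' @export
dated_species_tree <- function(nodes) {
  nodes <- as_tibble(nodes)
  stopifnot(all(c("name", "parent", "rank") %in% names(nodes)))
  nodes$name <- as.character(nodes$name)
  nodes$parent <- as.character(nodes$parent)
  nodes$rank <- as.integer(nodes$rank)

  if (anyDuplicated(nodes$name)) {
    abort(paste0("duplicate species label: ",
                 nodes$name[duplicated(nodes$name)][1]))
  }
  if (sum(is.na(nodes$parent)) != 1) {
    abort("species tree must have exactly one root")
  }
  kids <- table(nodes$parent[!is.na(nodes$parent)])
  if (any(kids != 2)) {
    abort(paste0("non-binary species tree node: ",
                 names(kids)[kids != 2][1]))
  }
  is_leaf <- !(nodes$name %in% nodes$parent)
  n_leaf <- sum(is_leaf)
  n_int <- sum(!is_leaf)
  if (n_int != n_leaf - 1) {
    abort("species tree must be binary: expected s - 1 internal nodes")
  }
  if (any(is.na(nodes$rank[!is_leaf]))) {
    abort(paste0("missing rank for internal node: ",
                 nodes$name[!is_leaf & is.na(nodes$rank)][1]))
  }
  ranks <- nodes$rank[!is_leaf]
  if (anyDuplicated(ranks)) {
    abort("internal node ranks must be pairwise distinct")
  }
  if (!setequal(ranks, seq_len(n_int) - 1L)) {
    abort("internal node ranks must be the integers 0 .. s-2")
  }
  root <- nodes$name[is.na(nodes$parent)]
  if (nodes$rank[nodes$name == root] != 0L) {
    abort("the root must carry the smallest rank (0)")
  }
  # ranks must respect ancestry: parent rank < child rank
  rank_of <- stats::setNames(nodes$rank, nodes$name)
  for (i in seq_len(nrow(nodes))) {
    if (is_leaf[i] || is.na(nodes$parent[i])) next
    if (rank_of[[nodes$parent[i]]] >= nodes$rank[i]) {
      abort(paste0("rank of node ", nodes$name[i],
                   " does not exceed its parent's rank"))
    }
  }
  nodes$is_leaf <- is_leaf
  n_species <- n_leaf
  # slices overlapped by the branch above each node
  parent_rank <- ifelse(is.na(nodes$parent), NA_integer_,
                        rank_of[nodes$parent])
  first_slice <- ifelse(is.na(nodes$parent), 0L, as.integer(parent_rank))
  last_slice <- ifelse(is_leaf, n_species - 2L, nodes$rank - 1L)
  # root branch: the root genome itself sits at slice 0
  last_slice[is.na(nodes$parent)] <- 0L
  # degenerate 2-species tree: terminal branches overlap slice 0 only
  last_slice <- pmax(last_slice, first_slice)
  nodes$first_slice <- as.integer(first_slice)
  nodes$last_slice <- as.integer(last_slice)
  # slice at which the node itself sits
  nodes$node_slice <- ifelse(is_leaf, n_species - 1L, nodes$rank)
  nodes$node_slice <- as.integer(nodes$node_slice)

  structure(
    list(nodes = nodes, n_species = n_species, root = root),
    class = "dated_species_tree"
  )
}

#' @export
print.dated_species_tree <- function(x, ...) {
  cat("Dated species tree:", x$n_species, "extant genomes,",
      x$n_species - 1L, "ancestral genomes /", x$n_species - 1L,
      "ancestral time slices\n")
  invisible(x)
}

species_children <- function(stree, name) {
  stree$nodes$name[!is.na(stree$nodes$parent) & stree$nodes$parent == name]
}

species_field <- function(stree, name, field) {
  stree$nodes[[field]][match(name, stree$nodes$name)]
}

#' Construct a reconciled gene tree
#'
#' Wraps a node table into a validated reconciled gene tree. Every node
#' carries a species assignment (a species-tree node naming the branch the
#' gene lies on, or `"OUT"` for lineages in unsampled species), an event
#' label and a time slice.
#'
#' @param nodes Data frame with columns `id` (integer, 1..n), `parent`
#'   (integer, `NA` for the root), `label` (gene identifier; required for
#'   leaves), `species`, `event`, `slice`.
#' @param family Family identifier (character scalar).
#' @param validate Check arities and annotations immediately?
#' @return An object of class `recon_gene_tree`.
#' @export
recon_gene_tree <- function(nodes, family, validate = TRUE) {
  nodes <- as_tibble(nodes)
  stopifnot(all(c("id", "parent", "label", "species", "event", "slice")
                %in% names(nodes)))
  nodes$id <- as.integer(nodes$id)
  nodes$parent <- as.integer(nodes$parent)
  nodes$slice <- as.integer(nodes$slice)
  nodes$label <- as.character(nodes$label)
  nodes$species <- as.character(nodes$species)
  nodes$event <- as.character(nodes$event)
  nodes <- nodes[order(nodes$id), ]
  tree <- structure(list(nodes = nodes, family = as.character(family)),
                    class = "recon_gene_tree")
  tree <- index_gene_tree(tree)
  if (validate) validate_gene_tree_arities(tree)
  tree
}

# Build fast per-id lookups (children list, parent vector, ...). Node ids
# must be 1..n after this.
index_gene_tree <- function(tree) {
  nodes <- tree$nodes
  n <- nrow(nodes)
  if (!identical(nodes$id, seq_len(n))) {
    # reindex to 1..n preserving topology
    remap <- stats::setNames(seq_len(n), nodes$id)
    nodes$id <- seq_len(n)
    nodes$parent <- ifelse(is.na(nodes$parent), NA_integer_,
                           as.integer(remap[as.character(nodes$parent)]))
    tree$nodes <- nodes
  }
  children <- vector("list", n)
  for (i in seq_len(n)) children[[i]] <- integer(0)
  ip <- which(!is.na(nodes$parent))
  for (i in ip) {
    p <- nodes$parent[i]
    children[[p]] <- c(children[[p]], nodes$id[i])
  }
  tree$children <- children
  tree$parent <- nodes$parent
  tree$species <- nodes$species
  tree$event <- nodes$event
  tree$slice <- nodes$slice
  tree$label <- nodes$label
  tree$root <- nodes$id[is.na(nodes$parent)]
  tree
}

# Arity rules: Extant/Loss are leaves, NoEvent/Trans are unary,
# Spec/SpecOut/Dup are binary.
validate_gene_tree_arities <- function(tree) {
  n_children <- lengths(tree$children)
  want <- c(Extant = 0L, Loss = 0L, NoEvent = 1L, Trans = 1L,
            Spec = 2L, SpecOut = 2L, Dup = 2L)
  bad_ev <- !(tree$event %in% EVENTS)
  if (any(bad_ev)) {
    abort(paste0("family ", tree$family, ": unknown event label '",
                 tree$event[bad_ev][1], "' at node ",
                 node_name(tree, which(bad_ev)[1])))
  }
  mismatch <- n_children != want[tree$event]
  if (any(mismatch)) {
    i <- which(mismatch)[1]
    abort(paste0("family ", tree$family, ": event ", tree$event[i],
                 " at node ", node_name(tree, i), " has ", n_children[i],
                 " children (expected ", want[[tree$event[i]]], ")"))
  }
  leaves <- which(tree$event == "Extant")
  if (any(is.na(tree$label[leaves]) | tree$label[leaves] == "")) {
    abort(paste0("family ", tree$family,
                 ": extant leaf without a gene identifier"))
  }
  invisible(tree)
}

node_name <- function(tree, id) {
  lab <- tree$label[id]
  ifelse(is.na(lab) | lab == "", paste0("#", id), lab)
}

# Gene identifiers for every node: leaves keep their labels, internal nodes
# get a deterministic family-scoped identifier.
fill_node_labels <- function(tree) {
  lab <- tree$nodes$label
  missing <- is.na(lab) | lab == ""
  lab[missing] <- paste0(tree$family, ".n", tree$nodes$id[missing])
  tree$nodes$label <- lab
  tree$label <- lab
  tree
}

#' @export
print.recon_gene_tree <- function(x, ...) {
  cat("Reconciled gene tree, family", x$family, "-", nrow(x$nodes),
      "nodes,", sum(x$event == "Extant"), "extant genes\n")
  invisible(x)
}

# Validate a gene tree against the species tree: species labels known,
# slices within branch ranges, speciation children on the right branches,
# transfers below a SpeciationOut, transfer species differing from the
# donor lineage.
validate_gene_tree <- function(tree, stree) {
  validate_gene_tree_arities(tree)
  nm <- stree$nodes$name
  unknown <- !(tree$species %in% c(nm, OUT_SPECIES))
  if (any(unknown)) {
    i <- which(unknown)[1]
    abort(paste0("family ", tree$family, ": unknown species label '",
                 tree$species[i], "' at node ", node_name(tree, i)))
  }
  s_last <- stree$n_species - 1L
  for (i in seq_len(nrow(tree$nodes))) {
    ev <- tree$event[i]
    sp <- tree$species[i]
    ts <- tree$slice[i]
    if (sp == OUT_SPECIES) {
      if (!(ev %in% c("Spec", "NoEvent", "Loss"))) {
        abort(paste0("family ", tree$family, ": event ", ev, " at node ",
                     node_name(tree, i),
                     " cannot be outside the species tree"))
      }
      next
    }
    leaf_sp <- species_field(stree, sp, "is_leaf")
    node_sl <- species_field(stree, sp, "node_slice")
    fs <- species_field(stree, sp, "first_slice")
    ls <- species_field(stree, sp, "last_slice")
    if (ev == "Extant") {
      if (!leaf_sp) {
        abort(paste0("family ", tree$family, ": extant gene ",
                     node_name(tree, i), " mapped to ancestral species ",
                     sp))
      }
      if (!is.na(ts) && ts != s_last) {
        abort(paste0("family ", tree$family, ": extant gene ",
                     node_name(tree, i), " must be in slice ", s_last))
      }
    } else if (ev == "Spec") {
      if (leaf_sp) {
        abort(paste0("family ", tree$family, ": speciation ",
                     node_name(tree, i), " mapped to extant species ", sp))
      }
      if (!is.na(ts) && ts != node_sl) {
        abort(paste0("family ", tree$family, ": speciation ",
                     node_name(tree, i), " at species ", sp,
                     " must be in slice ", node_sl))
      }
      kid_sp <- tree$species[tree$children[[i]]]
      if (!setequal(kid_sp, species_children(stree, sp))) {
        abort(paste0("family ", tree$family, ": children of speciation ",
                     node_name(tree, i),
                     " do not lie on the two child branches of ", sp))
      }
    } else {
      if (!is.na(ts) && (ts < fs || ts > ls)) {
        abort(paste0("family ", tree$family, ": event ", ev, " at node ",
                     node_name(tree, i), " has slice ", ts,
                     " outside the branch above ", sp, " (slices ", fs,
                     "..", ls, ")"))
      }
    }
    if (ev == "Trans") {
      # parent chain must pass a SpeciationOut, and the recipient branch
      # must differ from the donor lineage's branch
      p <- tree$parent[i]
      seen_so <- FALSE
      donor <- NA_character_
      while (!is.na(p)) {
        if (tree$event[p] == "SpecOut") {
          seen_so <- TRUE
          donor <- tree$species[p]
          break
        }
        if (!(tree$species[p] %in% OUT_SPECIES)) break
        p <- tree$parent[p]
      }
      if (!seen_so) {
        abort(paste0("family ", tree$family, ": transfer ",
                     node_name(tree, i),
                     " has no SpeciationOut ancestor"))
      }
      if (identical(donor, sp)) {
        abort(paste0("family ", tree$family, ": transfer ",
                     node_name(tree, i),
                     " arrives on its own donor branch ", sp))
      }
    }
    if (ev == "SpecOut") {
      kid_sp <- tree$species[tree$children[[i]]]
      if (sum(kid_sp == sp) != 1) {
        abort(paste0("family ", tree$family, ": SpeciationOut ",
                     node_name(tree, i),
                     " must keep exactly one child on its branch ", sp))
      }
    }
    # chronology: child slice never earlier than parent slice
    p <- tree$parent[i]
    if (!is.na(p) && !is.na(ts) && !is.na(tree$slice[p]) &&
        tree$species[p] != OUT_SPECIES && sp != OUT_SPECIES &&
        ts < tree$slice[p]) {
      abort(paste0("family ", tree$family, ": node ", node_name(tree, i),
                   " is in an earlier slice than its parent",
                   " (non-chronological reconciliation)"))
    }
  }
  invisible(tree)
}

# History container --------------------------------------------------------

new_history <- function(adjacencies, gains, breaks, costs, classes,
                        species_tree, gene_trees, input_adjacencies,
                        cotransfers = NULL, coduplications = NULL) {
  cost <- nrow(gains) * costs$gain + nrow(breaks) * costs$breakage
  structure(
    list(
      adjacencies = adjacencies,
      gains = gains,
      breaks = breaks,
      cost = cost,
      costs = costs,
      classes = classes,
      species_tree = species_tree,
      gene_trees = gene_trees,
      input_adjacencies = input_adjacencies,
      cotransfers = cotransfers %||%
        tibble(gene1 = character(), gene2 = character(),
               donor = character(), recipient = character(),
               departure_slice = integer(), arrival_slice = integer()),
      coduplications = coduplications %||%
        tibble(gene1 = character(), gene2 = character(),
               species = character(), slice = integer())
    ),
    class = "adjacency_history"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.adjacency_history <- function(x, ...) {
  cat("Adjacency history\n")
  cat("  classes:       ", nrow(x$classes), "\n")
  cat("  adjacencies:   ", nrow(x$adjacencies),
      sprintf("(%d extant)", sum(x$adjacencies$extant)), "\n")
  cat("  gains:         ", nrow(x$gains), "\n")
  cat("  breakages:     ", nrow(x$breaks), "\n")
  cat("  total cost:    ", x$cost,
      sprintf("(gain cost %g, breakage cost %g)",
              x$costs$gain, x$costs$breakage), "\n")
  invisible(x)
}
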