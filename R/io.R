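# Reading and writing: species trees (Newick + rank table), reconciled gene
# trees (Newick with NHX-style tags), adjacency tables, history outputs.

#' Read a dated species tree
#'
#' The species tree is plain rooted binary Newick with labels on all nodes;
#' the dating is a separate two-column table (node label, integer rank)
#' covering all internal nodes, the root having rank 0. Only the total
#' order of internal nodes matters, not branch lengths.
#'
#' @param newick Newick text, or path to a file containing it.
#' @param ranks A data frame with columns `node` and `rank`, or path to a
#'   two-column tab-separated file (comments start with `#`).
#' @return A [dated_species_tree()].
#' @export
read_species_tree <- function(newick, ranks) {
  txt <- read_text_arg(newick)
  phy <- ape::read.tree(text = txt)
  if (is.null(phy)) abort("could not parse species tree Newick")
  labs <- c(phy$tip.label, phy$node.label)
  if (is.null(phy$node.label) || any(phy$node.label == "")) {
    abort("species tree must label all internal nodes")
  }
  if (anyDuplicated(labs)) {
    abort(paste0("duplicate label in species tree: ",
                 labs[duplicated(labs)][1]))
  }
  n_tip <- length(phy$tip.label)
  parent_of <- rep(NA_character_, length(labs))
  for (k in seq_len(nrow(phy$edge))) {
    parent_of[phy$edge[k, 2]] <- labs[phy$edge[k, 1]]
  }
  if (is.data.frame(ranks)) {
    rk <- as_tibble(ranks)
    names(rk)[1:2] <- c("node", "rank")
  } else {
    rk <- utils::read.table(text = read_text_arg(ranks), sep = "\t",
                            comment.char = "#", header = FALSE,
                            col.names = c("node", "rank"),
                            colClasses = c("character", "integer"))
    rk <- as_tibble(rk)
  }
  if (anyDuplicated(rk$node)) {
    abort(paste0("contradictory rank for node ",
                 rk$node[duplicated(rk$node)][1]))
  }
  internal <- labs[(n_tip + 1):length(labs)]
  missing <- setdiff(internal, rk$node)
  if (length(missing)) {
    abort(paste0("missing rank for internal node: ", missing[1]))
  }
  nodes <- tibble(
    name = labs,
    parent = parent_of,
    rank = as.integer(rk$rank[match(labs, rk$node)])
  )
  dated_species_tree(nodes)
}

read_text_arg <- function(x) {
  if (length(x) == 1 && !grepl("[(\n\t]", x) && file.exists(x)) {
    paste(readLines(x, warn = FALSE), collapse = "\n")
  } else {
    paste(x, collapse = "\n")
  }
}

# -- Newick/NHX parser ------------------------------------------------------

# Recursive-descent parser for one Newick string with NHX-style annotation
# blocks [&&NHX:S=...:Ev=...:ts=...]. Returns a node tibble. Tag order
# inside a block is free; branch lengths are accepted and ignored.
parse_newick_nhx <- function(text) {
  s <- gsub("[[:space:]]", "", text)
  pos <- 1L
  n <- nchar(s)
  ids <- integer(0); parents <- integer(0); labels <- character(0)
  tags <- list()
  next_id <- 0L

  peek <- function() substr(s, pos, pos)
  new_node <- function(parent) {
    next_id <<- next_id + 1L
    ids <<- c(ids, next_id)
    parents <<- c(parents, parent)
    labels <<- c(labels, NA_character_)
    tags[[next_id]] <<- list()
    next_id
  }
  read_label <- function() {
    m <- regexpr("^[^(),:;\\[]+", substr(s, pos, n))
    if (m == -1L) return("")
    lab <- regmatches(substr(s, pos, n), m)
    pos <<- pos + attr(m, "match.length")
    lab
  }
  read_suffix <- function(id) {
    # optional label, optional :length, optional [&&NHX:...] (any order of
    # length/comment)
    lab <- read_label()
    if (nzchar(lab)) labels[id] <<- lab
    repeat {
      ch <- peek()
      if (ch == ":") {
        pos <<- pos + 1L
        m <- regexpr("^[-+0-9.eE]+", substr(s, pos, n))
        if (m != -1L) pos <<- pos + attr(m, "match.length")
      } else if (ch == "[") {
        close <- regexpr("]", substr(s, pos, n), fixed = TRUE)
        if (close == -1L) abort("unterminated annotation block")
        block <- substr(s, pos, pos + close - 1L)
        pos <<- pos + close
        body <- sub("^\\[&&NHX:?", "", sub("]$", "", block))
        if (nzchar(body)) {
          for (kv in strsplit(body, ":", fixed = TRUE)[[1]]) {
            eq <- regexpr("=", kv, fixed = TRUE)
            if (eq > 0) {
              key <- substr(kv, 1, eq - 1)
              val <- substr(kv, eq + 1, nchar(kv))
              tags[[id]][[key]] <<- val
            }
          }
        }
      } else {
        break
      }
    }
  }
  parse_clade <- function(parent) {
    id <- new_node(parent)
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        parse_clade(id)
        if (peek() == ",") {
          pos <<- pos + 1L
        } else if (peek() == ")") {
          pos <<- pos + 1L
          break
        } else {
          abort(paste0("Newick parse error near position ", pos))
        }
      }
    }
    read_suffix(id)
    id
  }
  parse_clade(NA_integer_)
  if (peek() != ";" && pos <= n) {
    if (peek() != ";") abort("Newick parse error: expected ';'")
  }
  tag_get <- function(i, key) {
    v <- tags[[i]][[key]]
    if (is.null(v)) NA_character_ else v
  }
  tibble(
    id = ids,
    parent = parents,
    label = labels,
    S = vapply(ids, tag_get, character(1), key = "S"),
    Ev = vapply(ids, tag_get, character(1), key = "Ev"),
    ts = vapply(ids, tag_get, character(1), key = "ts")
  )
}

#' Read reconciled gene trees
#'
#' Each gene tree is Newick whose nodes carry NHX-style annotation blocks
#' `[&&NHX:S=<species>:Ev=<event>:ts=<slice>]` with events among
#' `Extant`, `Spec`, `SpecOut`, `Trans`, `Dup`, `Loss`; `S=OUT` marks
#' lineages in unsampled species. `ts` may be omitted for `Extant` and
#' `Spec` nodes (it is implied). Unary `S=OUT` chain nodes between a
#' `SpecOut` and its `Trans` child are accepted and spliced out.
#'
#' @param texts Character vector of Newick strings, or paths to files
#'   containing one Newick per line; one gene family per tree.
#' @param species_tree A [dated_species_tree()].
#' @param family_ids Optional family identifiers (defaults to `fam1`, ...).
#' @return A list of validated `recon_gene_tree` objects.
#' @export
read_gene_trees <- function(texts, species_tree, family_ids = NULL) {
  texts <- unlist(lapply(texts, function(x) {
    if (!grepl("[()]", x) && file.exists(x)) {
      lines <- readLines(x, warn = FALSE)
      lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
    } else {
      x
    }
  }), use.names = FALSE)
  if (is.null(family_ids)) family_ids <- paste0("fam", seq_along(texts))
  if (length(family_ids) != length(texts)) {
    abort("family_ids must match the number of gene trees")
  }
  trees <- vector("list", length(texts))
  for (k in seq_along(texts)) {
    trees[[k]] <- build_gene_tree(texts[[k]], species_tree, family_ids[[k]])
  }
  trees
}

build_gene_tree <- function(text, stree, family) {
  raw <- parse_newick_nhx(text)
  ev_map <- c(Extant = "Extant", Spec = "Spec", SpecOut = "SpecOut",
              Trans = "Trans", Dup = "Dup", Loss = "Loss",
              NoEvent = "NoEvent")
  ev <- ev_map[raw$Ev]
  missing_ev <- is.na(ev)
  if (any(missing_ev)) {
    i <- which(missing_ev)[1]
    abort(paste0("family ", family, ": node ",
                 ifelse(is.na(raw$label[i]), paste0("#", i), raw$label[i]),
                 " has missing or unknown Ev tag '", raw$Ev[i], "'"))
  }
  if (any(is.na(raw$S))) {
    i <- which(is.na(raw$S))[1]
    abort(paste0("family ", family, ": node #", i, " has no S tag"))
  }
  slice <- suppressWarnings(as.integer(raw$ts))
  # implied slices (a ts tag, if given, is kept and validated instead)
  s_last <- stree$n_species - 1L
  slice[ev == "Extant" & is.na(slice)] <- s_last
  isp <- match(raw$S, stree$nodes$name)
  implied <- ev == "Spec" & !is.na(isp) & is.na(slice)
  slice[implied] <- stree$nodes$node_slice[isp[implied]]
  nodes <- tibble(id = raw$id, parent = raw$parent, label = raw$label,
                  species = raw$S, event = unname(ev), slice = slice)
  nodes <- splice_out_chain_nodes(nodes, family)
  tree <- recon_gene_tree(nodes, family)
  tree <- fill_node_labels(tree)
  validate_gene_tree(tree, stree)
  tree
}

# Remove unary S=OUT bookkeeping nodes (between a SpeciationOut and its
# Trans child) so SpecOut nodes end with exactly one inside child and one
# Trans child.
splice_out_chain_nodes <- function(nodes, family) {
  repeat {
    kidn <- table(factor(nodes$parent, levels = nodes$id))
    unary_out <- nodes$species == OUT_SPECIES & kidn[as.character(nodes$id)] == 1 &
      nodes$event %in% c("NoEvent", "Spec")
    unary_out[is.na(unary_out)] <- FALSE
    if (!any(unary_out)) break
    drop <- nodes$id[which(unary_out)[1]]
    child <- nodes$id[!is.na(nodes$parent) & nodes$parent == drop]
    nodes$parent[nodes$id == child] <- nodes$parent[nodes$id == drop]
    nodes <- nodes[nodes$id != drop, ]
  }
  nodes
}

#' Read extant adjacencies
#'
#' Two tab-separated gene identifiers per line; `#` starts a comment.
#' Pairs are canonicalised and deduplicated; both genes must resolve to
#' extant leaves of the same species.
#'
#' @param tsv Text of the table or a file path.
#' @param gene_trees List of `recon_gene_tree` objects.
#' @return A tibble with columns `gene1`, `gene2` (canonical order) and
#'   `species`.
#' @export
read_adjacencies <- function(tsv, gene_trees) {
  txt <- read_text_arg(tsv)
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    gm <- gene_species_map(gene_trees)
    return(tibble(gene1 = character(), gene2 = character(),
                  species = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 2
  if (any(bad)) {
    abort(paste0("adjacency line ", lineno[bad][1],
                 ": expected two tab-separated gene identifiers"))
  }
  g1 <- vapply(parts, `[[`, character(1), 1)
  g2 <- vapply(parts, `[[`, character(1), 2)
  gm <- gene_species_map(gene_trees)
  for (i in seq_along(g1)) {
    for (g in c(g1[i], g2[i])) {
      if (!(g %in% names(gm))) {
        abort(paste0("adjacency line ", lineno[i], ": unknown gene '", g,
                     "'"))
      }
    }
    if (gm[[g1[i]]] != gm[[g2[i]]]) {
      abort(paste0("adjacency line ", lineno[i], ": genes ", g1[i], " and ",
                   g2[i], " belong to different species (", gm[[g1[i]]],
                   " vs ", gm[[g2[i]]], ")"))
    }
  }
  adj <- canonical_adjacency(g1, g2)
  adj$species <- unname(gm[adj$gene1])
  dplyr::distinct(adj)
}

gene_species_map <- function(gene_trees) {
  labs <- unlist(lapply(gene_trees, function(tr) {
    i <- tr$event == "Extant"
    stats::setNames(tr$species[i], tr$label[i])
  }))
  if (anyDuplicated(names(labs))) {
    abort(paste0("gene identifier used by more than one extant leaf: ",
                 names(labs)[duplicated(names(labs))][1]))
  }
  labs
}

#' Remove out-of-species-tree diversification nodes
#'
#' Speciation nodes of lineages outside the species tree (species `OUT`,
#' two children) describe diversification in unsampled species, which the
#' reconstruction does not model. They are removed, cutting the tree into
#' independent pieces; the root of each piece becomes a new origination.
#' Transfer nodes left at the root of a piece (their SpeciationOut context
#' was cut away) are spliced so the piece roots inside the species tree.
#'
#' @param tree A `recon_gene_tree` (not yet subdivided).
#' @param species_tree The [dated_species_tree()] used for re-validation.
#' @return A list of `recon_gene_tree` pieces (possibly empty).
#' @export
prune_outside_diversification <- function(tree, species_tree) {
  nodes <- tree$nodes
  div <- nodes$species == OUT_SPECIES & nodes$event == "Spec"
  if (!any(div)) return(list(tree))
  drop_ids <- nodes$id[div]
  nodes$parent[nodes$parent %in% drop_ids] <- NA_integer_
  nodes <- nodes[!div, ]
  repeat {
    changed <- FALSE
    # splice SpecOut nodes that lost their outside child
    kidn <- table(factor(nodes$parent, levels = nodes$id))
    so <- nodes$event == "SpecOut" & kidn[as.character(nodes$id)] == 1
    so[is.na(so)] <- FALSE
    if (any(so)) {
      drop <- nodes$id[which(so)[1]]
      child <- nodes$id[!is.na(nodes$parent) & nodes$parent == drop]
      nodes$parent[nodes$id %in% child] <- nodes$parent[nodes$id == drop]
      nodes <- nodes[nodes$id != drop, ]
      changed <- TRUE
    }
    # splice rootless OUT chains / transfers at piece roots
    roots <- nodes$id[is.na(nodes$parent)]
    bad_root <- roots[nodes$species[match(roots, nodes$id)] == OUT_SPECIES |
                        nodes$event[match(roots, nodes$id)] == "Trans"]
    if (length(bad_root)) {
      r <- bad_root[1]
      kids <- nodes$id[!is.na(nodes$parent) & nodes$parent == r]
      nodes$parent[nodes$id %in% kids] <- NA_integer_
      nodes <- nodes[nodes$id != r, ]
      changed <- TRUE
    }
    if (!changed) break
  }
  roots <- nodes$id[is.na(nodes$parent)]
  pieces <- list()
  for (k in seq_along(roots)) {
    ids <- collect_subtree_ids(nodes, roots[k])
    sub <- nodes[nodes$id %in% ids, ]
    fam <- if (length(roots) > 1) paste0(tree$family, ".p", k) else tree$family
    piece <- recon_gene_tree(sub, fam, validate = FALSE)
    piece <- fill_node_labels(piece)
    # a piece may be a bare loss or empty remainder; keep only pieces with
    # at least one extant gene or informative structure
    if (any(piece$event == "Extant")) {
      validate_gene_tree(piece, species_tree)
      pieces[[length(pieces) + 1]] <- piece
    }
  }
  pieces
}

collect_subtree_ids <- function(nodes, root) {
  out <- integer(0)
  stack <- root
  while (length(stack)) {
    cur <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, cur)
    stack <- c(stack, nodes$id[!is.na(nodes$parent) & nodes$parent == cur])
  }
  out
}

# -- Writers ---------------------------------------------------------------

#' Write a reconstructed history to disk
#'
#' Writes three tab-separated files under `dir`: `adjacencies.tsv`
#' (species, slice, gene1, gene2, extant flag), `events.tsv` (event,
#' species, slice, gene1, gene2) and `summary.tsv` (key/value run summary).
#' Rows are sorted so output is byte-reproducible.
#'
#' @param history An `adjacency_history`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_history <- function(history, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  adj <- history$adjacencies |>
    dplyr::select("species", "slice", "gene1", "gene2", "extant") |>
    dplyr::arrange(.data$species, .data$slice, .data$gene1, .data$gene2)
  ev <- dplyr::bind_rows(
    dplyr::mutate(history$gains, event = "Gain"),
    dplyr::mutate(history$breaks, event = "Break")
  )
  if (!nrow(ev)) {
    ev <- tibble(event = character(), species = character(),
                 slice = integer(), gene1 = character(),
                 gene2 = character())
  }
  ev <- ev |>
    dplyr::select("event", "species", "slice", "gene1", "gene2") |>
    dplyr::arrange(.data$event, .data$species, .data$slice, .data$gene1,
                   .data$gene2)
  smry <- tibble(
    key = c("n_classes", "n_adjacencies", "n_extant_adjacencies", "n_gains",
            "n_breaks", "gain_cost", "break_cost", "total_cost"),
    value = c(nrow(history$classes), nrow(history$adjacencies),
              sum(history$adjacencies$extant), nrow(history$gains),
              nrow(history$breaks), history$costs$gain,
              history$costs$breakage, history$cost)
  )
  paths <- file.path(dir, c("adjacencies.tsv", "events.tsv", "summary.tsv"))
  utils::write.table(adj, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ev, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(smry, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Serialise a dated species tree to Newick plus rank table
#' @param stree A [dated_species_tree()].
#' @return A list with `newick` and `ranks` (tibble) components.
#' @export
species_tree_text <- function(stree) {
  nodes <- stree$nodes
  build <- function(name) {
    kids <- species_children(stree, name)
    if (!length(kids)) return(name)
    paste0("(", paste(vapply(sort(kids), build, character(1)),
                      collapse = ","), ")", name)
  }
  list(
    newick = paste0(build(stree$root), ";"),
    ranks = nodes |>
      dplyr::filter(!.data$is_leaf) |>
      dplyr::arrange(.data$rank) |>
      dplyr::transmute(node = .data$name, rank = .data$rank)
  )
}

#' Serialise a reconciled gene tree to annotated Newick
#' @param tree A `recon_gene_tree`.
#' @return A single Newick/NHX string.
#' @export
gene_tree_text <- function(tree) {
  build <- function(id) {
    kids <- tree$children[[id]]
    core <- if (length(kids)) {
      paste0("(", paste(vapply(kids, build, character(1)), collapse = ","),
             ")", tree$label[id])
    } else {
      tree$label[id]
    }
    paste0(core, "[&&NHX:S=", tree$species[id], ":Ev=", tree$event[id],
           ":ts=", tree$slice[id], "]")
  }
  paste0(build(tree$root), ";")
}

#' Write a simulated input bundle in the package's file formats
#' @param bundle A list with `species_tree`, `gene_trees`, `adjacencies`
#'   (as returned in `simulate_adjacency_evolution()$bundle`).
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_input_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  st <- species_tree_text(bundle$species_tree)
  writeLines(st$newick, file.path(dir, "species_tree.nwk"))
  utils::write.table(st$ranks, file.path(dir, "species_ranks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  writeLines(vapply(bundle$gene_trees, gene_tree_text, character(1)),
             file.path(dir, "gene_trees.nhx"))
  adj <- bundle$adjacencies[order(bundle$adjacencies$gene1,
                                  bundle$adjacencies$gene2), ]
  utils::write.table(adj[, c("gene1", "gene2")],
                     file.path(dir, "adjacencies.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(file.path(dir, c("species_tree.nwk", "species_ranks.tsv",
                             "gene_trees.nhx", "adjacencies.tsv")))
}
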