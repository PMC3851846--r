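# Time slices: one ancestral slice per internal species node (slice k
# starts at the node of rank k) plus one extant slice. Gene-tree branches
# are subdivided with unary NoEvent nodes so that every parent-child step
# spans at most one slice boundary, which is what lets the dynamic program
# walk two gene trees in lockstep.

#' Slices overlapped by each species branch
#'
#' Maps every species-tree branch (named by its bottom node) to the
#' contiguous interval of ancestral time slices it overlaps, plus the slice
#' at which the bottom node itself sits (its rank for internal nodes, the
#' extant slice for leaves).
#'
#' @param stree A [dated_species_tree()].
#' @return A tibble with columns `species`, `first_slice`, `last_slice`,
#'   `node_slice`, `n_slices`.
#' @export
assign_slices <- function(stree) {
  stree$nodes |>
    dplyr::transmute(
      species = .data$name,
      first_slice = .data$first_slice,
      last_slice = .data$last_slice,
      node_slice = .data$node_slice,
      n_slices = .data$last_slice - .data$first_slice + 1L
    )
}

#' Subdivide a gene tree at slice boundaries
#'
#' Inserts unary `NoEvent` nodes wherever a gene branch crosses a time
#' slice boundary without an event: between a parent in slice `t_p` and a
#' child in slice `t_c` (same species branch, or entering a child branch
#' after a speciation), one `NoEvent` node is inserted per slice
#' `t_p + 1 .. t_c - 1`. No nodes are synthesised on the untracked segment
#' between a `SpecOut` departure and its `Trans` arrival.
#'
#' @param tree A validated `recon_gene_tree`.
#' @param stree The [dated_species_tree()] (used for error messages only;
#'   slices are taken from the node annotations).
#' @return A `recon_gene_tree` with `NoEvent` nodes inserted.
#' @export
subdivide <- function(tree, stree) {
  nodes <- tree$nodes
  n0 <- nrow(nodes)
  next_id <- n0
  extra <- list()
  new_parent <- nodes$parent
  n_new <- 0L

  for (i in seq_len(n0)) {
    p <- nodes$parent[i]
    if (is.na(p)) next
    sp_p <- nodes$species[p]
    sp_c <- nodes$species[i]
    if (sp_p == OUT_SPECIES || sp_c == OUT_SPECIES) next
    # untracked outside segment: SpecOut -> Trans
    if (nodes$event[p] == "SpecOut" && sp_c != sp_p) next
    tp <- nodes$slice[p]
    tc <- nodes$slice[i]
    if (is.na(tp) || is.na(tc)) {
      abort(paste0("family ", tree$family, ": missing time slice at node ",
                   node_name(tree, if (is.na(tp)) p else i)))
    }
    if (tc < tp) {
      abort(paste0("family ", tree$family, ": node ", node_name(tree, i),
                   " is in an earlier slice than its parent",
                   " (non-chronological reconciliation)"))
    }
    if (tc - tp <= 1L) next
    # branch the inserted nodes live on: the child's branch (covers both the
    # same-branch case and descent into a child branch after a speciation)
    branch <- sp_c
    prev <- p
    for (t in seq(tp + 1L, tc - 1L)) {
      next_id <- next_id + 1L
      n_new <- n_new + 1L
      extra[[n_new]] <- list(id = next_id, parent = prev,
                             label = paste0(tree$family, ".x", next_id),
                             species = branch, event = "NoEvent",
                             slice = t)
      prev <- next_id
    }
    new_parent[i] <- prev
  }
  if (!n_new) return(tree)
  nodes$parent <- new_parent
  extra_tb <- dplyr::bind_rows(lapply(extra, as_tibble))
  out <- dplyr::bind_rows(nodes, extra_tb)
  out_tree <- recon_gene_tree(out, tree$family, validate = TRUE)
  out_tree
}

#' Remove NoEvent nodes (inverse of subdivision)
#'
#' Splices every unary `NoEvent` node out of the tree, recovering the
#' event-only structure.
#'
#' @param tree A `recon_gene_tree`.
#' @return A `recon_gene_tree` without `NoEvent` nodes.
#' @export
splice_noevent <- function(tree) {
  nodes <- tree$nodes
  ne <- nodes$event == "NoEvent"
  if (!any(ne)) return(tree)
  parent <- stats::setNames(nodes$parent, nodes$id)
  resolve <- function(p) {
    while (!is.na(p) && nodes$event[match(p, nodes$id)] == "NoEvent") {
      p <- parent[[as.character(p)]]
    }
    p
  }
  nodes$parent <- vapply(nodes$parent, function(p) {
    if (is.na(p)) NA_integer_ else as.integer(resolve(p))
  }, integer(1))
  nodes <- nodes[!ne, ]
  recon_gene_tree(nodes, tree$family, validate = TRUE)
}
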