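#' Reconstruct ancestral gene adjacencies
#'
#' Runs the full pipeline: removal of out-of-species-tree diversification
#' nodes, slice subdivision, possible-homology class construction, the
#' dynamic program, and backtracking to one minimum-cost history of
#' adjacency gains and breakages.
#'
#' @param species_tree A [dated_species_tree()].
#' @param gene_trees List of `recon_gene_tree` objects (one per family, as
#'   read by [read_gene_trees()]; not yet subdivided).
#' @param adjacencies Data frame of extant adjacencies with columns
#'   `gene1`, `gene2` (any order; canonicalised and deduplicated).
#' @param gain_cost,break_cost Costs of one adjacency gain / breakage.
#' @return An `adjacency_history`; see [tidy.adjacency_history()],
#'   [glance.adjacency_history()], [autoplot.adjacency_history()],
#'   [degree_distribution()], [find_event_clusters()].
#' @examples
#' sim <- simulate_adjacency_evolution(n_species = 4, n_genes = 4, seed = 7)
#' h <- reconstruct_adjacencies(sim$bundle$species_tree,
#'                              sim$bundle$gene_trees,
#'                              sim$bundle$adjacencies)
#' glance(h)
#' @export
reconstruct_adjacencies <- function(species_tree, gene_trees, adjacencies,
                                    gain_cost = 1, break_cost = 1) {
  costs <- cost_params(gain_cost, break_cost)
  adjacencies <- as_tibble(adjacencies)
  if (nrow(adjacencies)) {
    adjacencies <- dplyr::distinct(
      canonical_adjacency(adjacencies$gene1, adjacencies$gene2))
  } else {
    adjacencies <- tibble(gene1 = character(), gene2 = character())
  }
  pieces <- list()
  for (tr in gene_trees) {
    pieces <- c(pieces, prune_outside_diversification(tr, species_tree))
  }
  sliced <- lapply(pieces, subdivide, stree = species_tree)
  classes <- build_classes(adjacencies, sliced)
  ctx <- dp_context(sliced, costs, adjacencies)
  for (cls in classes) fill_matrix(cls, ctx)
  history <- optimal_history(classes, ctx, species_tree)
  history$input_adjacencies <- adjacencies
  history
}

# -- broom-style methods ----------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an adjacency history
#'
#' @param x An `adjacency_history`.
#' @param what One of `"adjacencies"` (default; all extant and ancestral
#'   adjacencies with their species and slice), `"events"` (gain and
#'   breakage events), `"classes"` (per-class summary).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.adjacency_history <- function(x, what = c("adjacencies", "events",
                                               "classes"), ...) {
  what <- match.arg(what)
  switch(what,
    adjacencies = x$adjacencies |>
      dplyr::arrange(.data$slice, .data$species, .data$gene1, .data$gene2),
    events = dplyr::bind_rows(
      dplyr::mutate(x$gains, event = "Gain"),
      dplyr::mutate(x$breaks, event = "Break")
    ) |>
      dplyr::select(dplyr::any_of(c("event", "species", "slice", "gene1",
                                    "gene2"))) |>
      dplyr::arrange(.data$slice, .data$species, .data$gene1),
    classes = x$classes
  )
}

#' One-row summary of an adjacency history
#'
#' @param x An `adjacency_history`.
#' @param ... Unused.
#' @return A one-row tibble: class count, adjacency counts, event counts,
#'   costs and the total cost.
#' @export
glance.adjacency_history <- function(x, ...) {
  tibble(
    n_classes = nrow(x$classes),
    n_adjacencies = nrow(x$adjacencies),
    n_extant = sum(x$adjacencies$extant),
    n_ancestral = sum(!x$adjacencies$extant),
    n_gains = nrow(x$gains),
    n_breaks = nrow(x$breaks),
    gain_cost = x$costs$gain,
    break_cost = x$costs$breakage,
    total_cost = x$cost
  )
}

#' Plot the gene degree distribution of reconstructed genomes
#'
#' One panel of the proportion of genes by adjacency degree (0-6 and 7+)
#' per ancestral genome, the usual visual check of how circular the
#' reconstruction is (a perfectly reconstructed circular genome has all
#' genes at degree 2).
#'
#' @param object An `adjacency_history`.
#' @param species Species to include (default: all ancestral genomes).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.adjacency_history <- function(object, species = NULL, ...) {
  st <- object$species_tree
  if (is.null(species)) {
    species <- st$nodes$name[!st$nodes$is_leaf]
  }
  dd <- degree_distribution(object, species)
  ggplot2::ggplot(dd, ggplot2::aes(x = .data$degree, y = .data$proportion)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~species) +
    ggplot2::labs(x = "gene degree (number of adjacencies)",
                  y = "proportion of genes")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
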