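# Summaries of reconstructed genomes: gene degree distributions and
# adjacency-to-gene ratios per (ancestral or extant) genome, and clusters
# of co-transferred / co-duplicated genes.

# gene set of one genome: speciation nodes at an internal species node,
# extant leaves at a leaf species
genome_genes <- function(history, species) {
  st <- history$species_tree
  i <- match(species, st$nodes$name)
  if (is.na(i)) abort(paste0("unknown species: ", species))
  ev <- if (st$nodes$is_leaf[i]) "Extant" else "Spec"
  out <- character(0)
  for (tr in history$gene_trees) {
    sel <- tr$species == species & tr$event == ev
    out <- c(out, tr$label[sel])
  }
  out
}

# adjacencies of one genome: both extremities must be genes of that genome
# (speciation nodes at an internal species node, extant leaves at a leaf);
# pairs straddling a slice boundary mid-branch do not belong to it
genome_adjacencies <- function(history, species) {
  st <- history$species_tree
  i <- match(species, st$nodes$name)
  sl <- st$nodes$node_slice[i]
  genes <- genome_genes(history, species)
  history$adjacencies |>
    dplyr::filter(.data$species == !!species, .data$slice == !!sl,
                  .data$gene1 %in% genes, .data$gene2 %in% genes)
}

#' Gene degree distribution of one genome
#'
#' The degree of a gene is the number of adjacencies it belongs to; in a
#' perfectly reconstructed circular genome every gene has degree 2.
#' Degrees are binned 0-6 with a `7+` overflow bin.
#'
#' @param history An `adjacency_history`.
#' @param species One or more species (internal node names for ancestral
#'   genomes, leaf names for extant ones).
#' @return A tibble with columns `species`, `degree` (factor 0-6, `7+`),
#'   `n_genes`, `proportion`; proportions sum to 1 per species.
#' @export
degree_distribution <- function(history, species) {
  lv <- c(as.character(0:6), "7+")
  rows <- lapply(species, function(sp) {
    genes <- genome_genes(history, sp)
    adj <- genome_adjacencies(history, sp)
    deg <- stats::setNames(rep(0L, length(genes)), genes)
    if (nrow(adj)) {
      tab <- table(c(adj$gene1, adj$gene2))
      deg[names(tab)] <- as.integer(tab)
    }
    bin <- ifelse(deg >= 7, "7+", as.character(deg))
    cnt <- table(factor(bin, levels = lv))
    tibble(species = sp, degree = factor(lv, levels = lv),
           n_genes = as.integer(cnt),
           proportion = if (length(genes)) as.integer(cnt) / length(genes)
                        else rep(NA_real_, length(lv)))
  })
  dplyr::bind_rows(rows)
}

#' Adjacency-to-gene ratio of one genome
#'
#' The ratio between the number of adjacencies and the number of genes in a
#' genome; 1 for a circular chromosome, lower when reconstruction signal is
#' missing.
#'
#' @param history An `adjacency_history`.
#' @param species A single species name.
#' @return A single number.
#' @export
adjacency_gene_ratio <- function(history, species) {
  genes <- genome_genes(history, species)
  if (!length(genes)) {
    abort(paste0("species ", species,
                 " has no genes; the ratio is undefined"))
  }
  nrow(genome_adjacencies(history, species)) / length(genes)
}

#' Per-genome summary statistics
#'
#' @param history An `adjacency_history`.
#' @param species Species to summarise (default: all ancestral genomes).
#' @return A tibble with per-genome gene and adjacency counts, the
#'   adjacency/gene ratio and the proportion of degree-2 genes.
#' @export
ancestral_genome_stats <- function(history, species = NULL) {
  st <- history$species_tree
  if (is.null(species)) species <- st$nodes$name[!st$nodes$is_leaf]
  rows <- lapply(species, function(sp) {
    genes <- genome_genes(history, sp)
    adj <- genome_adjacencies(history, sp)
    deg2 <- if (length(genes)) {
      dd <- degree_distribution(history, sp)
      dd$proportion[dd$degree == "2"]
    } else NA_real_
    tibble(species = sp,
           slice = st$nodes$node_slice[match(sp, st$nodes$name)],
           n_genes = length(genes), n_adjacencies = nrow(adj),
           ratio = if (length(genes)) nrow(adj) / length(genes) else
             NA_real_,
           prop_degree2 = deg2)
  })
  dplyr::bind_rows(rows)
}

#' Clusters of co-transferred or co-duplicated genes
#'
#' Co-transferred genes are genes linked by adjacencies maintained across
#' one transfer step (present on the donor side and carried through the
#' `SpecOut`/`Trans` pair into the recipient); two such adjacencies join
#' one cluster only when they share a gene and the same transfer step (same
#' donor and recipient species and slices). Co-duplicated genes are linked
#' by adjacencies maintained through a simultaneous duplication of both
#' extremities. Clusters have at least 2 genes.
#'
#' @param history An `adjacency_history`.
#' @param kind `"Transfer"` or `"Duplication"`.
#' @return A tibble with one row per cluster: `cluster`, `kind`, event
#'   coordinates, `n_genes` and the comma-separated member `genes`.
#' @export
find_event_clusters <- function(history, kind = c("Transfer",
                                                  "Duplication")) {
  kind <- match.arg(kind)
  links <- if (kind == "Transfer") history$cotransfers else
    history$coduplications
  empty <- tibble(cluster = integer(), kind = character(),
                  species = character(), slice = integer(),
                  n_genes = integer(), genes = character())
  if (is.null(links) || !nrow(links)) return(empty)
  links <- dplyr::distinct(links)
  if (kind == "Transfer") {
    links$event_key <- paste(links$donor, links$recipient,
                             links$departure_slice, links$arrival_slice,
                             sep = "/")
    links$species <- links$recipient
    links$slice <- links$arrival_slice
  } else {
    links$event_key <- paste(links$species, links$slice, sep = "/")
  }
  out <- list()
  for (k in sort(unique(links$event_key))) {
    sub <- links[links$event_key == k, ]
    comps <- connected_components(sub$gene1, sub$gene2)
    for (genes in comps) {
      if (length(genes) < 2) next
      out[[length(out) + 1L]] <- tibble(
        kind = kind, species = sub$species[1], slice = sub$slice[1],
        n_genes = length(genes),
        genes = paste(sort(genes), collapse = ",")
      )
    }
  }
  if (!length(out)) return(empty)
  res <- dplyr::bind_rows(out) |>
    dplyr::arrange(.data$species, .data$slice, .data$genes)
  dplyr::bind_cols(tibble(cluster = seq_len(nrow(res))), res)
}

# connected components of an undirected edge list, base implementation
connected_components <- function(a, b) {
  verts <- unique(c(a, b))
  idx <- stats::setNames(seq_along(verts), verts)
  parent <- seq_along(verts)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in seq_along(a)) {
    ri <- find(idx[[a[e]]]); rj <- find(idx[[b[e]]])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  comp <- vapply(seq_along(verts), find, integer(1))
  unname(split(verts, comp))
}
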