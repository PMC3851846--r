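# Backtracking: recover one minimum-cost history from the filled matrices.
# The root state of each class is argmin{c1(root) + C(Gain), c0(root)};
# choices are propagated top-down by re-deriving each case's alternatives
# and picking, among the cost-minimal ones, the one inferring the fewest
# ancestral adjacencies, then the first in the printed order of the
# recurrence terms (ties are broken conservatively and deterministically).

#' Recover one minimum-cost adjacency history
#'
#' @param classes List of classes from [build_classes()].
#' @param ctx A [dp_context()]; matrices are filled on demand.
#' @param species_tree The [dated_species_tree()].
#' @return An `adjacency_history` object: tibbles of located adjacencies,
#'   gain and breakage events, co-transfer and co-duplication links, plus
#'   the total cost.
#' @export
optimal_history <- function(classes, ctx, species_tree) {
  acc <- new.env(parent = emptyenv())
  acc$adj <- list(); acc$gain <- list(); acc$brk <- list()
  acc$cot <- list(); acc$cod <- list()
  G <- ctx$costs$gain
  class_rows <- list()

  for (cls in classes) {
    v <- cell_value(ctx, cls$root)
    cost1 <- v[1] + G
    cost0 <- v[2]
    state <- if (cost1 < cost0) 1L else 0L
    cls_cost <- min(cost1, cost0)
    if (state == 1L) record_gain(acc, ctx, cls$root)
    backtrack_pair(ctx, cls$root, state, acc)
    class_rows[[length(class_rows) + 1L]] <- tibble(
      class_id = cls$id,
      n_members = nrow(cls$members),
      root_species = ctx$trees[[cls$root[1]]]$species[cls$root[2]],
      root_slice = pair_slice(ctx, cls$root),
      cost = cls_cost
    )
  }

  empty_ev <- tibble(species = character(), slice = integer(),
                     gene1 = character(), gene2 = character())
  adj <- if (length(acc$adj)) {
    dplyr::distinct(rows_to_tibble(acc$adj, extant = TRUE))
  } else {
    tibble(species = character(), slice = integer(), gene1 = character(),
           gene2 = character(), extant = logical())
  }
  gains <- if (length(acc$gain)) dplyr::distinct(rows_to_tibble(acc$gain))
    else empty_ev
  brks <- if (length(acc$brk)) dplyr::distinct(rows_to_tibble(acc$brk))
    else empty_ev
  cot <- if (length(acc$cot)) dplyr::distinct(dplyr::bind_rows(acc$cot))
    else NULL
  cod <- if (length(acc$cod)) dplyr::distinct(dplyr::bind_rows(acc$cod))
    else NULL
  classes_tb <- if (length(class_rows)) dplyr::bind_rows(class_rows) else
    tibble(class_id = integer(), n_members = integer(),
           root_species = character(), root_slice = integer(),
           cost = numeric())

  new_history(
    adjacencies = adj, gains = gains, breaks = brks, costs = ctx$costs,
    classes = classes_tb, species_tree = species_tree,
    gene_trees = ctx$trees,
    input_adjacencies = NULL, cotransfers = cot, coduplications = cod
  )
}

pair_species <- function(ctx, p) ctx$trees[[p[1]]]$species[p[2]]
pair_slice <- function(ctx, p) {
  max(ctx$trees[[p[1]]]$slice[p[2]], ctx$trees[[p[3]]]$slice[p[4]])
}
pair_genes <- function(ctx, p) {
  labs <- c(ctx$trees[[p[1]]]$label[p[2]], ctx$trees[[p[3]]]$label[p[4]])
  if (string_gt(labs[1], labs[2])) labs[2:1] else labs
}

# plain-list row accumulators (one tibble is built, and gene pairs are
# canonicalised in one vectorised pass, at the very end; per-row tibbles
# and per-row string comparisons would dominate the runtime)
record_adj <- function(acc, ctx, p) {
  ex <- ctx$trees[[p[1]]]$event[p[2]] == "Extant" &&
    ctx$trees[[p[3]]]$event[p[4]] == "Extant"
  acc$adj[[length(acc$adj) + 1L]] <- list(
    pair_species(ctx, p), pair_slice(ctx, p),
    ctx$trees[[p[1]]]$label[p[2]], ctx$trees[[p[3]]]$label[p[4]], ex)
}
record_gain <- function(acc, ctx, p) {
  acc$gain[[length(acc$gain) + 1L]] <- list(
    pair_species(ctx, p), pair_slice(ctx, p),
    ctx$trees[[p[1]]]$label[p[2]], ctx$trees[[p[3]]]$label[p[4]])
}
record_break <- function(acc, ctx, p) {
  acc$brk[[length(acc$brk) + 1L]] <- list(
    pair_species(ctx, p), pair_slice(ctx, p),
    ctx$trees[[p[1]]]$label[p[2]], ctx$trees[[p[3]]]$label[p[4]])
}

rows_to_tibble <- function(rows, extant = FALSE) {
  g1 <- vapply(rows, `[[`, character(1), 3)
  g2 <- vapply(rows, `[[`, character(1), 4)
  sw <- string_gt(g1, g2)
  out <- tibble(
    species = vapply(rows, `[[`, character(1), 1),
    slice = vapply(rows, `[[`, integer(1), 2),
    gene1 = ifelse(sw, g2, g1),
    gene2 = ifelse(sw, g1, g2)
  )
  if (extant) out$extant <- vapply(rows, `[[`, logical(1), 5)
  out
}

backtrack_pair <- function(ctx, p, state, acc) {
  repeat {
    if (state == 1L) record_adj(acc, ctx, p)
    d <- dispatch_cell(ctx, p)
    alts <- if (state == 1L) d$alts1 else d$alts0
    if (!length(alts) || all(!vapply(alts, function(a) length(a$ch) > 0,
                                     logical(1)))) {
      return(invisible())  # leaf case (extant pair or loss)
    }
    target <- cell_value(ctx, p)[if (state == 1L) 1L else 2L]
    a <- choose_alt(ctx, alts, target)
    # record events and tags
    if (!is.na(a$tag) && state == 1L) {
      if (a$tag == "cotransfer") {
        m <- a$meta
        acc$cot[[length(acc$cot) + 1L]] <- tibble(
          gene1 = m$genes[1], gene2 = m$genes[2], donor = m$donor,
          recipient = m$recipient, departure_slice = m$departure_slice,
          arrival_slice = m$arrival_slice
        )
      } else if (a$tag == "codup" &&
                 any(vapply(a$ch, function(x) x$s == 1L, logical(1)))) {
        m <- a$meta
        acc$cod[[length(acc$cod) + 1L]] <- tibble(
          gene1 = m$genes[1], gene2 = m$genes[2], species = m$species,
          slice = m$slice
        )
      }
    }
    for (ch in a$ch) {
      if (!is.na(ch$ev)) {
        if (ch$ev == "Gain") record_gain(acc, ctx, ch$p)
        else record_break(acc, ctx, ch$p)
      }
    }
    if (length(a$ch) == 1L) {
      # tail-recurse down unary chains to keep the stack shallow
      p <- a$ch[[1]]$p
      state <- a$ch[[1]]$s
    } else {
      for (ch in a$ch) backtrack_pair(ctx, ch$p, ch$s, acc)
      return(invisible())
    }
  }
}

choose_alt <- function(ctx, alts, target) {
  best <- NULL
  best_n1 <- Inf
  for (a in alts) {
    val <- eval_alt(ctx, a)
    if (is.finite(target)) {
      if (abs(val - target) > 1e-9) next
    } else if (is.finite(val)) next
    n1 <- sum(vapply(a$ch, function(x) x$s, numeric(1)))
    if (n1 < best_n1) {
      best <- a
      best_n1 <- n1
    }
  }
  if (is.null(best)) abort("internal: no alternative achieves the optimum")
  best
}
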