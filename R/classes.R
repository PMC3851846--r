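# Possible-homology classes. Two extant adjacencies may descend from a
# common ancestral adjacency only if a pair of distinct ancestral genes in
# the same species and slice covers their extremities. We compute, for each
# extant adjacency, the set of admissible ancestor pairs by walking reverse
# recurrence moves up the gene trees; adjacencies sharing a pair fall in
# one class, and the class root is the highest (earliest) shared pair.
# Ascent never crosses a Transfer node unless both sides transfer together
# (same recipient species and slice below SpeciationOut nodes in the same
# donor species and slice), which realises the observation that a Transfer
# paired with a non-Transfer roots an additional class.

pair_key <- function(t1, u, t2, v) {
  if (t1 > t2 || (t1 == t2 && u > v)) {
    paste(t2, v, t1, u, sep = ":")
  } else {
    paste(t1, u, t2, v, sep = ":")
  }
}

pair_from_key <- function(key) as.integer(strsplit(key, ":", fixed = TRUE)[[1]])

# is `anc` an ancestor of (or equal to) `desc` within one tree?
is_ancestor <- function(tree, anc, desc) {
  while (!is.na(desc)) {
    if (desc == anc) return(TRUE)
    desc <- tree$parent[desc]
  }
  FALSE
}

pair_ok <- function(trees, t1, u, t2, v) {
  if (t1 == t2) {
    if (u == v) return(FALSE)
    tr <- trees[[t1]]
    if (is_ancestor(tr, u, v) || is_ancestor(tr, v, u)) return(FALSE)
  }
  TRUE
}

# admissible ancestor pairs of one extant adjacency, as a character vector
# of pair keys (includes the extant pair itself)
admissible_pairs <- function(trees, t1, u, t2, v) {
  seen <- new.env(parent = emptyenv())
  queue <- list(c(t1, u, t2, v))
  assign(pair_key(t1, u, t2, v), TRUE, envir = seen)
  out <- character(0)
  while (length(queue)) {
    p <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    out <- c(out, pair_key(p[1], p[2], p[3], p[4]))
    for (q in parent_moves(trees, p)) {
      if (!pair_ok(trees, q[1], q[2], q[3], q[4])) next
      k <- pair_key(q[1], q[2], q[3], q[4])
      if (!exists(k, envir = seen)) {
        assign(k, TRUE, envir = seen)
        queue[[length(queue) + 1L]] <- q
      }
    }
  }
  out
}

# reverse recurrence moves from pair p = c(t1, u, t2, v)
parent_moves <- function(trees, p) {
  res <- list()
  tu <- trees[[p[1]]]; tv <- trees[[p[3]]]
  u <- p[2]; v <- p[4]
  sp <- tu$species[u]
  su <- tu$slice[u]; sv <- tv$slice[v]
  pu <- tu$parent[u]; pv <- tv$parent[v]
  eu_p <- if (!is.na(pu)) tu$event[pu] else NA_character_
  ev_p <- if (!is.na(pv)) tv$event[pv] else NA_character_
  eu <- tu$event[u]; ev <- tv$event[v]

  one_side <- function(par_tree, par, side) {
    # ascend one side through Dup / SpecOut-inside / NoEvent; partner fixed
    if (side == 1) list(c(p[1], par, p[3], v)) else list(c(p[1], u, p[3], par))
  }
  # Dup ascent (the partner must not be a Transfer node)
  if (!is.na(pu) && eu_p == "Dup" && tu$species[pu] == sp && ev != "Trans") {
    res <- c(res, one_side(tu, pu, 1))
  }
  if (!is.na(pv) && ev_p == "Dup" && tv$species[pv] == sp && eu != "Trans") {
    res <- c(res, one_side(tv, pv, 2))
  }
  # SpecOut inside-child ascent
  if (!is.na(pu) && eu_p == "SpecOut" && tu$species[pu] == sp &&
      ev != "Trans") {
    res <- c(res, one_side(tu, pu, 1))
  }
  if (!is.na(pv) && ev_p == "SpecOut" && tv$species[pv] == sp &&
      eu != "Trans") {
    res <- c(res, one_side(tv, pv, 2))
  }
  # NoEvent crossings: paired when aligned, single-sided to realign
  if (!is.na(pu) && !is.na(pv) && eu_p == "NoEvent" && ev_p == "NoEvent" &&
      tu$slice[pu] == tv$slice[pv]) {
    res <- c(res, list(c(p[1], pu, p[3], pv)))
  }
  if (!is.na(pu) && eu_p == "NoEvent" && ev != "Trans" &&
      tu$slice[pu] >= sv) {
    res <- c(res, one_side(tu, pu, 1))
  }
  if (!is.na(pv) && ev_p == "NoEvent" && eu != "Trans" &&
      tv$slice[pv] >= su) {
    res <- c(res, one_side(tv, pv, 2))
  }
  # paired speciation at the same species node
  if (!is.na(pu) && !is.na(pv) && eu_p == "Spec" && ev_p == "Spec" &&
      tu$species[pu] == tv$species[pv]) {
    res <- c(res, list(c(p[1], pu, p[3], pv)))
  }
  # co-transfer ascent: both sides Transfer in the same species and slice
  if (eu == "Trans" && ev == "Trans") {
    # above the transfer pair: paired SpeciationOut in one donor context
    if (!is.na(pu) && !is.na(pv) && eu_p == "SpecOut" && ev_p == "SpecOut" &&
        tu$species[pu] == tv$species[pv] &&
        tu$slice[pu] == tv$slice[pv]) {
      res <- c(res, list(c(p[1], pu, p[3], pv)))
    }
  } else {
    # ascend into a Transfer/Transfer pair
    if (!is.na(pu) && !is.na(pv) && eu_p == "Trans" && ev_p == "Trans" &&
        tu$species[pu] == tv$species[pv] &&
        tu$slice[pu] == tv$slice[pv]) {
      res <- c(res, list(c(p[1], pu, p[3], pv)))
    }
  }
  res
}

#' Are two extant adjacencies possibly homologous?
#'
#' True when a pair of distinct ancestral genes with disjoint subtrees, in
#' one species and slice, covers the extremities of both adjacencies under
#' some pairing. The relation is reflexive, symmetric and (by shared
#' covering pairs) generates the class partition.
#'
#' @param adj1,adj2 Length-2 character vectors (or 1-row data frames with
#'   `gene1`, `gene2`) naming extant genes.
#' @param trees List of subdivided `recon_gene_tree` objects.
#' @return Logical scalar.
#' @export
possibly_homologous <- function(adj1, adj2, trees) {
  lk <- leaf_lookup(trees)
  g1 <- as_pair(adj1); g2 <- as_pair(adj2)
  c1 <- adjacency_closure(trees, lk, g1)
  c2 <- adjacency_closure(trees, lk, g2)
  length(intersect(c1, c2)) > 0
}

as_pair <- function(x) {
  if (is.data.frame(x)) c(x$gene1[1], x$gene2[1]) else as.character(x[1:2])
}

leaf_lookup <- function(trees) {
  out <- list()
  for (k in seq_along(trees)) {
    tr <- trees[[k]]
    for (i in which(tr$event == "Extant")) out[[tr$label[i]]] <- c(k, i)
  }
  out
}

adjacency_closure <- function(trees, lk, genes) {
  a <- lk[[genes[1]]]; b <- lk[[genes[2]]]
  if (is.null(a) || is.null(b)) {
    abort(paste0("unknown extant gene in adjacency: ",
                 genes[if (is.null(a)) 1 else 2]))
  }
  admissible_pairs(trees, a[1], a[2], b[1], b[2])
}

#' Partition extant adjacencies into possible-homology classes
#'
#' Connected components of the possible-homology relation, each carrying
#' its root pair: the highest (earliest-slice) admissible ancestor pair
#' shared by all members. When no single pair covers a whole component
#' (possible for same-family adjacencies), the component is split greedily
#' into maximal coverable subclasses.
#'
#' @param adjacencies Tibble with columns `gene1`, `gene2` (canonical).
#' @param trees List of subdivided `recon_gene_tree` objects.
#' @return A list of classes; each is a list with `id`, `members` (tibble),
#'   `root` (integer vector `c(tree1, node1, tree2, node2)`).
#' @export
build_classes <- function(adjacencies, trees) {
  m <- nrow(adjacencies)
  if (!m) return(list())
  lk <- leaf_lookup(trees)
  closures <- vector("list", m)
  for (i in seq_len(m)) {
    closures[[i]] <- adjacency_closure(
      trees, lk, c(adjacencies$gene1[i], adjacencies$gene2[i]))
  }
  # union-find over adjacencies sharing any admissible pair
  parent <- seq_len(m)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  key_owner <- new.env(parent = emptyenv())
  for (i in seq_len(m)) {
    for (k in closures[[i]]) {
      if (exists(k, envir = key_owner)) {
        unite(i, get(k, envir = key_owner))
      } else {
        assign(k, i, envir = key_owner)
      }
    }
  }
  comp <- vapply(seq_len(m), find, integer(1))
  classes <- list()
  for (cid in sort(unique(comp))) {
    members <- which(comp == cid)
    # greedy split into subclasses covered by one shared pair
    remaining <- members
    while (length(remaining)) {
      grp <- remaining[1]
      common <- closures[[remaining[1]]]
      if (length(remaining) > 1) {
        for (j in remaining[-1]) {
          nx <- intersect(common, closures[[j]])
          if (length(nx)) {
            grp <- c(grp, j)
            common <- nx
          }
        }
      }
      root <- highest_pair(trees, common)
      classes[[length(classes) + 1L]] <- list(
        id = length(classes) + 1L,
        members = adjacencies[grp, , drop = FALSE],
        root = root
      )
      remaining <- setdiff(remaining, grp)
    }
  }
  classes
}

# choose the highest pair: earliest pair slice, then deterministic order
highest_pair <- function(trees, keys) {
  mat <- do.call(rbind, lapply(keys, pair_from_key))
  sl <- vapply(seq_len(nrow(mat)), function(i) {
    max(trees[[mat[i, 1]]]$slice[mat[i, 2]],
        trees[[mat[i, 3]]]$slice[mat[i, 4]])
  }, integer(1))
  o <- order(sl, mat[, 1], mat[, 2], mat[, 3], mat[, 4])
  mat[o[1], ]
}
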