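# The dynamic program. For two gene-tree nodes a, b in the same species,
# c1(a, b) is the minimum cost of an adjacency history for the two subtrees
# assuming an adjacency between a and b, and c0(a, b) the minimum assuming
# none. The recurrence dispatches on the pair of events at a and b; each
# case translates the propagation rule for that event combination and adds
# the possible rearrangements (gains at C(Gain), breakages at C(Break)).
#
# Cells are represented uniformly as lists of alternatives; an alternative
# fixes the presence state of each child pair, carries the rearrangement
# cost of that choice, and notes which child carries a gain or breakage
# event. The same alternatives drive both the minimisation and the
# backtracking, so the recovered history is exactly self-consistent.

alt_ <- function(k, ch = list(), tag = NA_character_, meta = NULL) {
  list(k = k, ch = ch, tag = tag, meta = meta)
}
ce_ <- function(p, s, ev = NA_character_) list(p = p, s = s, ev = ev)

#' Create a dynamic-programming context
#'
#' Holds the subdivided gene trees, the costs, the extant adjacency set and
#' the cell memo shared by all classes of one run.
#'
#' @param trees List of subdivided `recon_gene_tree` objects.
#' @param costs A [cost_params()].
#' @param extant_adjacencies Tibble with canonical `gene1`, `gene2`.
#' @return A dp context (list with a memo environment).
#' @export
dp_context <- function(trees, costs, extant_adjacencies) {
  ex <- new.env(parent = emptyenv())
  if (nrow(extant_adjacencies)) {
    for (i in seq_len(nrow(extant_adjacencies))) {
      # both orientations, so membership tests need no re-canonicalisation
      assign(paste(extant_adjacencies$gene1[i], extant_adjacencies$gene2[i],
                   sep = "|"), TRUE, envir = ex)
      assign(paste(extant_adjacencies$gene2[i], extant_adjacencies$gene1[i],
                   sep = "|"), TRUE, envir = ex)
    }
  }
  list(trees = trees, costs = costs, extant = ex,
       memo = new.env(parent = emptyenv()))
}

is_extant_adjacency <- function(ctx, lab1, lab2) {
  exists(paste(lab1, lab2, sep = "|"), envir = ctx$extant)
}

#' Compute one DP cell
#'
#' Returns the pair `(c1, c0)` for two gene subtree roots in the same
#' species, computing (and memoising) all needed child cells.
#'
#' @param ctx A [dp_context()].
#' @param p Integer vector `c(tree1, node1, tree2, node2)`.
#' @return Numeric length-2 vector `c(c1, c0)`; `Inf` marks an impossible
#'   state (only at extant leaf pairs).
#' @export
cell_value <- function(ctx, p) {
  key <- pair_key(p[1], p[2], p[3], p[4])
  hit <- get0(key, envir = ctx$memo, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  d <- dispatch_cell(ctx, p)
  v <- c(min_alts(ctx, d$alts1), min_alts(ctx, d$alts0))
  assign(key, v, envir = ctx$memo)
  v
}

min_alts <- function(ctx, alts) {
  best <- Inf
  for (a in alts) {
    val <- eval_alt(ctx, a)
    if (val < best) best <- val
  }
  best
}

eval_alt <- function(ctx, a) {
  tot <- a$k
  if (!is.finite(tot)) return(Inf)
  for (ch in a$ch) {
    vv <- cell_value(ctx, ch$p)
    tot <- tot + vv[if (ch$s == 1) 1L else 2L]
    if (!is.finite(tot)) return(Inf)
  }
  tot
}

# -- case dispatch ----------------------------------------------------------

dispatch_cell <- function(ctx, p) {
  tu <- ctx$trees[[p[1]]]; tv <- ctx$trees[[p[3]]]
  u <- p[2]; v <- p[4]
  eu <- tu$event[u]; ev <- tv$event[v]
  su <- tu$slice[u]; sv <- tv$slice[v]
  if (tu$species[u] != tv$species[v]) {
    abort(paste0("internal: cell for nodes in different species (",
                 tu$species[u], " vs ", tv$species[v], ")"))
  }
  G <- ctx$costs$gain; B <- ctx$costs$breakage

  # Case 2: a lost gene ends the pair at no cost, whatever the other event
  if (eu == "Loss" || ev == "Loss") {
    return(list(kind = "loss", alts1 = list(alt_(0)), alts0 = list(alt_(0))))
  }
  # Case 1: two extant genes; the state is fixed by the input adjacencies
  if (eu == "Extant" && ev == "Extant") {
    hit <- is_extant_adjacency(ctx, tu$label[u], tv$label[v])
    return(list(kind = "extant",
                alts1 = list(alt_(if (hit) 0 else Inf)),
                alts0 = list(alt_(if (hit) Inf else 0))))
  }
  # Staggered slices: events happen in chronological order, so the side in
  # the earlier slice acts alone (its partner has no node there yet). In
  # particular a lagging NoEvent lineage catches up before the later side's
  # SpeciationOut is resolved, which is what lets co-transfers pair up.
  if (su != sv) {
    side <- if (su < sv) 1L else 2L
    e_early <- if (side == 1) eu else ev
    if (e_early == "NoEvent") {
      q <- if (side == 1) c(p[1], tu$children[[u]][1], p[3], v)
           else c(p[1], u, p[3], tv$children[[v]][1])
      return(list(kind = "cross1", alts1 = flip_alts1(q, B),
                  alts0 = flip_alts0(q, G)))
    }
    if (e_early == "Dup") {
      return(c(list(kind = "dup"), case4(ctx, p, side, G, B)))
    }
    if (e_early == "SpecOut") {
      return(case7(ctx, p, side))
    }
    abort(paste0("internal: unreachable staggered event combination ", eu,
                 "/", ev, " (slices ", su, "/", sv, ")"))
  }
  # Cases 4/5: within a slice, duplications are resolved first
  # (simultaneously when both sides duplicate)
  if (eu == "Dup" || ev == "Dup") {
    if (eu == "Dup" && ev == "Dup") {
      return(case5(ctx, p, G, B))
    }
    return(c(list(kind = "dup"), case4(ctx, p, if (eu == "Dup") 1L else 2L,
                                       G, B)))
  }
  # Case 9: co-arriving transfers; other transfer pairings root new classes
  if (eu == "Trans" || ev == "Trans") {
    if (eu == "Trans" && ev == "Trans") {
      q <- c(p[1], tu$children[[u]][1], p[3], tv$children[[v]][1])
      return(list(kind = "transfer", alts1 = flip_alts1(q, B),
                  alts0 = flip_alts0(q, G)))
    }
    abort(paste0("internal: Transfer paired with ",
                 if (eu == "Trans") ev else eu,
                 " cannot be recursed (roots a new class)"))
  }
  # Cases 7/8: speciation out of the species tree
  if (eu == "SpecOut" || ev == "SpecOut") {
    if (eu == "SpecOut" && ev == "SpecOut") {
      in_u <- inside_child(tu, u); out_u <- outside_child(tu, u)
      in_v <- inside_child(tv, v); out_v <- outside_child(tv, v)
      if (tu$event[out_u] == "Trans" && tv$event[out_v] == "Trans" &&
          tu$species[out_u] == tv$species[out_v] &&
          tu$slice[out_u] == tv$slice[out_v]) {
        qin <- c(p[1], in_u, p[3], in_v)
        qout <- c(p[1], out_u, p[3], out_v)
        meta <- list(
          donor = tu$species[u], recipient = tu$species[out_u],
          departure_slice = su, arrival_slice = tu$slice[out_u],
          genes = c(tu$label[out_u], tv$label[out_v])
        )
        return(list(
          kind = "specout2",
          alts1 = list(
            alt_(0, list(ce_(qin, 1), ce_(qout, 1)), tag = "cotransfer",
                 meta = meta),
            alt_(B, list(ce_(qin, 1), ce_(qout, 0, "Break")))
          ),
          alts0 = list(
            alt_(0, list(ce_(qin, 0), ce_(qout, 0))),
            alt_(G, list(ce_(qin, 0), ce_(qout, 1, "Gain")))
          )
        ))
      }
    }
    # Case 7: resolve one SpeciationOut; the adjacency follows the inside
    # child (the lone transferred copy cannot carry it). With nested
    # same-slice SpeciationOuts, resolve the side whose transfer cannot
    # pair with the partner's chain, so a deeper co-transfer pairing is
    # preserved.
    side <- if (eu != "SpecOut") 2L
            else if (ev != "SpecOut") 1L
            else specout_resolve_side(ctx$trees[[p[1]]], p[2],
                                      ctx$trees[[p[3]]], p[4])
    return(case7(ctx, p, side))
  }
  # Case 6: paired speciation; children pair up by species
  if (eu == "Spec" && ev == "Spec") {
    ku <- tu$children[[u]]; kv <- tv$children[[v]]
    kv <- kv[match(tu$species[ku], tv$species[kv])]
    if (anyNA(kv)) {
      abort("internal: speciation children do not pair up by species")
    }
    q1 <- c(p[1], ku[1], p[3], kv[1])
    q2 <- c(p[1], ku[2], p[3], kv[2])
    return(list(
      kind = "spec",
      alts1 = list(
        alt_(0, list(ce_(q1, 1), ce_(q2, 1))),
        alt_(B, list(ce_(q1, 1), ce_(q2, 0, "Break"))),
        alt_(B, list(ce_(q1, 0, "Break"), ce_(q2, 1))),
        alt_(2 * B, list(ce_(q1, 0, "Break"), ce_(q2, 0, "Break")))
      ),
      alts0 = list(
        alt_(0, list(ce_(q1, 0), ce_(q2, 0))),
        alt_(G, list(ce_(q1, 1, "Gain"), ce_(q2, 0))),
        alt_(G, list(ce_(q1, 0), ce_(q2, 1, "Gain"))),
        alt_(2 * G, list(ce_(q1, 1, "Gain"), ce_(q2, 1, "Gain")))
      )
    ))
  }
  # Case 3: both lineages cross a slice boundary without an event
  if (eu == "NoEvent" && ev == "NoEvent") {
    q <- c(p[1], tu$children[[u]][1], p[3], tv$children[[v]][1])
    return(list(kind = "cross", alts1 = flip_alts1(q, B),
                alts0 = flip_alts0(q, G)))
  }
  abort(paste0("internal: unreachable event combination ", eu, "/", ev,
               " (slices ", su, "/", sv, ")"))
}

# Transfer coordinates (recipient species / arrival slice) of the chain of
# same-species same-slice SpeciationOut nodes starting at `u` and walking
# down inside children.
specout_out_coords <- function(tree, u) {
  sp <- tree$species[u]; sl <- tree$slice[u]
  out <- character(0)
  w <- u
  while (!is.na(w) && tree$event[w] == "SpecOut" &&
         tree$species[w] == sp && tree$slice[w] == sl) {
    o <- outside_child(tree, w)
    if (tree$event[o] == "Trans") {
      out <- c(out, paste(tree$species[o], tree$slice[o]))
    }
    w <- inside_child(tree, w)
  }
  out
}

# Which of two same-slice SpeciationOut nodes to resolve first (Case 7)
# when their own transfers do not pair: resolve the partner of a side whose
# transfer matches deeper in the other side's SpecOut chain, keeping that
# pairing reachable. Defaults to side 1.
specout_resolve_side <- function(tu, u, tv, v) {
  cu <- specout_out_coords(tu, u)
  cv <- specout_out_coords(tv, v)
  if (length(cu) && cu[1] %in% cv[-1]) return(2L)
  if (length(cv) && cv[1] %in% cu[-1]) return(1L)
  1L
}

# Case 7: one SpeciationOut resolves; the adjacency stays with the inside
# child at no cost in either state.
case7 <- function(ctx, p, side) {
  tr <- ctx$trees[[p[2 * side - 1]]]
  q <- if (side == 1) c(p[1], inside_child(tr, p[2]), p[3], p[4])
       else c(p[1], p[2], p[3], inside_child(tr, p[4]))
  list(kind = "specout1",
       alts1 = list(alt_(0, list(ce_(q, 1)))),
       alts0 = list(alt_(0, list(ce_(q, 0)))))
}

flip_alts1 <- function(q, B) {
  list(alt_(0, list(ce_(q, 1))), alt_(B, list(ce_(q, 0, "Break"))))
}
flip_alts0 <- function(q, G) {
  list(alt_(0, list(ce_(q, 0))), alt_(G, list(ce_(q, 1, "Gain"))))
}

inside_child <- function(tree, u) {
  kids <- tree$children[[u]]
  kids[tree$species[kids] == tree$species[u]][1]
}
outside_child <- function(tree, u) {
  kids <- tree$children[[u]]
  kids[tree$species[kids] != tree$species[u]][1]
}

# Case 4: the duplication on `side` resolves first; the adjacency follows
# exactly one copy for free, keeping both costs a gain, losing both a
# breakage.
case4 <- function(ctx, p, side, G, B) {
  if (side == 1) {
    tr <- ctx$trees[[p[1]]]
    kids <- tr$children[[p[2]]]
    q1 <- c(p[1], kids[1], p[3], p[4])
    q2 <- c(p[1], kids[2], p[3], p[4])
  } else {
    tr <- ctx$trees[[p[3]]]
    kids <- tr$children[[p[4]]]
    q1 <- c(p[1], p[2], p[3], kids[1])
    q2 <- c(p[1], p[2], p[3], kids[2])
  }
  list(
    alts1 = list(
      alt_(0, list(ce_(q1, 1), ce_(q2, 0))),
      alt_(0, list(ce_(q1, 0), ce_(q2, 1))),
      alt_(G, list(ce_(q1, 1), ce_(q2, 1, "Gain"))),
      alt_(B, list(ce_(q1, 0, "Break"), ce_(q2, 0)))
    ),
    alts0 = list(
      alt_(0, list(ce_(q1, 0), ce_(q2, 0))),
      alt_(G, list(ce_(q1, 0), ce_(q2, 1, "Gain"))),
      alt_(G, list(ce_(q1, 1, "Gain"), ce_(q2, 0))),
      alt_(2 * G, list(ce_(q1, 1, "Gain"), ce_(q2, 1, "Gain")))
    )
  )
}

# Case 5: both sides duplicate in one slice; the minimum is over resolving
# a first, b first, or both simultaneously (the 16-configuration term).
case5 <- function(ctx, p, G, B) {
  a_first <- case4(ctx, p, 1L, G, B)
  b_first <- case4(ctx, p, 2L, G, B)
  tu <- ctx$trees[[p[1]]]; tv <- ctx$trees[[p[3]]]
  ku <- tu$children[[p[2]]]; kv <- tv$children[[p[4]]]
  gp <- list(
    p11 = c(p[1], ku[1], p[3], kv[1]),
    p22 = c(p[1], ku[2], p[3], kv[2]),
    p12 = c(p[1], ku[1], p[3], kv[2]),
    p21 = c(p[1], ku[2], p[3], kv[1])
  )
  meta <- list(species = tu$species[p[2]], slice = tu$slice[p[2]],
               genes = c(tu$label[p[2]], tv$label[p[4]]))
  cfg <- d12_configurations(G, B)
  sim_alts <- vector("list", nrow(cfg))
  for (i in seq_len(nrow(cfg))) {
    st <- c(cfg$p11[i], cfg$p22[i], cfg$p12[i], cfg$p21[i])
    matched <- cfg$matching[[i]]
    ch <- lapply(1:4, function(j) {
      evj <- if (matched[j] && st[j] == 0) "Break"
             else if (!matched[j] && st[j] == 1) "Gain"
             else NA_character_
      ce_(gp[[j]], st[j], evj)
    })
    sim_alts[[i]] <- alt_(cfg$cost[i], ch, tag = "codup", meta = meta)
  }
  list(
    kind = "dupdup",
    alts1 = c(a_first$alts1, b_first$alts1, sim_alts),
    alts0 = c(a_first$alts0, b_first$alts0)
  )
}

#' The 16 configurations of the simultaneous-duplication term
#'
#' When both extremities of an adjacency duplicate simultaneously, the four
#' child pairs (two matched pairings times two cross pairings) can each
#' carry the adjacency or not: 2^4 = 16 configurations. The rearrangement
#' cost of a configuration is the cheaper, over the two perfect matchings
#' of copies, of one breakage per absent matched pair plus one gain per
#' present unmatched pair.
#'
#' @param gain_cost,break_cost Costs of a gain and a breakage.
#' @return A 16-row tibble with the presence pattern (`p11`, `p22`, `p12`,
#'   `p21`), the chosen `matching` (logical length-4 list column marking
#'   which child pairs descend for free) and the configuration `cost`.
#' @export
d12_configurations <- function(gain_cost = 1, break_cost = 1) {
  grid <- expand.grid(p11 = 0:1, p22 = 0:1, p12 = 0:1, p21 = 0:1)
  grid <- grid[order(-grid$p11, -grid$p22, -grid$p12, -grid$p21), ]
  matchings <- list(c(TRUE, TRUE, FALSE, FALSE), c(FALSE, FALSE, TRUE, TRUE))
  cost <- numeric(nrow(grid))
  pick <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    st <- as.integer(grid[i, ])
    costs <- vapply(matchings, function(m) {
      break_cost * sum(m & st == 0) + gain_cost * sum(!m & st == 1)
    }, numeric(1))
    j <- which.min(costs)
    cost[i] <- costs[j]
    pick[[i]] <- matchings[[j]]
  }
  out <- as_tibble(grid)
  out$matching <- pick
  out$cost <- cost
  out
}

#' Fill the dynamic-programming matrix for one class
#'
#' Computes every cell needed to evaluate the class root, in joint
#' post-order via memoised recursion.
#'
#' @param cls A class from [build_classes()].
#' @param ctx A [dp_context()] (shared across classes of one run).
#' @return The context, invisibly; use [dp_cells()] to inspect the cells.
#' @export
fill_matrix <- function(cls, ctx) {
  cell_value(ctx, cls$root)
  invisible(ctx)
}

#' Computed DP cells as a tibble
#' @param ctx A [dp_context()] after [fill_matrix()].
#' @return Tibble with one row per computed cell: node references, `c1`,
#'   `c0`.
#' @export
dp_cells <- function(ctx) {
  keys <- ls(envir = ctx$memo)
  rows <- lapply(keys, function(k) {
    p <- pair_from_key(k)
    v <- get(k, envir = ctx$memo)
    tibble(tree1 = p[1], node1 = p[2], tree2 = p[3], node2 = p[4],
           c1 = v[1], c0 = v[2])
  })
  dplyr::bind_rows(rows)
}
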