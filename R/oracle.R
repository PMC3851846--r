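# Exhaustive minimum-cost history search on tiny instances, used in tests
# as the independent correctness reference for the dynamic program.
#
# The oracle enumerates every assignment of presence/absence over the node
# pairs reachable from a class root under the propagation-rule structure,
# and scores each full assignment globally: a gain for every present
# adjacency without a present rule parent, a breakage for every present
# adjacency whose rule child is absent, extant pairs pinned to the input.
# There is no memoisation and no minimisation over subproblems - the search
# is a flat scan of all histories - so agreement with the dynamic program
# checks the recurrence decomposition, which is the algorithmic content.

#' Exhaustive minimum history cost for one class
#'
#' @param cls A class from [build_classes()] (only its `root` is used).
#' @param trees List of subdivided `recon_gene_tree` objects.
#' @param costs A [cost_params()].
#' @param extant_adjacencies Tibble with canonical `gene1`, `gene2`.
#' @param max_pairs Refuse instances with more than this many free
#'   presence/absence variables (guard against exponential blowup).
#' @return The minimum cost (numeric scalar).
#' @export
brute_force_min_cost <- function(cls, trees, costs, extant_adjacencies,
                                 max_pairs = 16L) {
  G <- costs$gain
  B <- costs$breakage
  ex <- new.env(parent = emptyenv())
  if (nrow(extant_adjacencies)) {
    for (i in seq_len(nrow(extant_adjacencies))) {
      assign(paste(extant_adjacencies$gene1[i], extant_adjacencies$gene2[i],
                   sep = "|"), TRUE, envir = ex)
      assign(paste(extant_adjacencies$gene2[i], extant_adjacencies$gene1[i],
                   sep = "|"), TRUE, envir = ex)
    }
  }

  # ---- walk the propagation structure from the root --------------------
  pairs <- character(0)          # pair keys, in discovery order
  fixed <- list()                # key -> 0/1 for extant pairs
  steps <- list()

  key_of <- function(p) pair_key(p[1], p[2], p[3], p[4])
  add_pair <- function(p) {
    k <- key_of(p)
    if (!(k %in% pairs)) pairs <<- c(pairs, k)
    k
  }
  ev_at <- function(p, side) {
    tr <- trees[[p[2 * side - 1]]]
    tr$event[p[2 * side]]
  }
  sl_at <- function(p, side) {
    tr <- trees[[p[2 * side - 1]]]
    tr$slice[p[2 * side]]
  }
  kids_of <- function(p, side) {
    tr <- trees[[p[2 * side - 1]]]
    tr$children[[p[2 * side]]]
  }
  with_side <- function(p, side, node) {
    if (side == 1) c(p[1], node, p[3], p[4]) else c(p[1], p[2], p[3], node)
  }

  queue <- list(cls$root)
  root_key <- add_pair(cls$root)
  seen <- new.env(parent = emptyenv())
  assign(root_key, TRUE, envir = seen)

  while (length(queue)) {
    p <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    k <- key_of(p)
    e1 <- ev_at(p, 1); e2 <- ev_at(p, 2)
    s1 <- sl_at(p, 1); s2 <- sl_at(p, 2)
    push <- function(q) {
      qk <- add_pair(q)
      if (!exists(qk, envir = seen)) {
        assign(qk, TRUE, envir = seen)
        queue[[length(queue) + 1L]] <<- q
      }
      qk
    }

    if (e1 == "Loss" || e2 == "Loss") {
      next
    } else if (e1 == "Extant" && e2 == "Extant") {
      t1 <- trees[[p[1]]]; t2 <- trees[[p[3]]]
      hit <- exists(paste(t1$label[p[2]], t2$label[p[4]], sep = "|"),
                    envir = ex)
      fixed[[k]] <- if (hit) 1L else 0L
    } else if (s1 != s2) {
      # chronological order: the side in the earlier slice acts alone
      side <- if (s1 < s2) 1L else 2L
      e_early <- if (side == 1) e1 else e2
      if (e_early == "NoEvent") {
        q <- push(with_side(p, side, kids_of(p, side)[1]))
        steps[[length(steps) + 1L]] <- list(type = "flip", p = k, q = q)
      } else if (e_early == "Dup") {
        kk <- kids_of(p, side)
        q1 <- push(with_side(p, side, kk[1]))
        q2 <- push(with_side(p, side, kk[2]))
        steps[[length(steps) + 1L]] <- list(type = "dup", p = k,
                                            q1 = q1, q2 = q2)
      } else if (e_early == "SpecOut") {
        tr <- trees[[p[2 * side - 1]]]
        kk <- kids_of(p, side)
        ins <- kk[tr$species[kk] == tr$species[p[2 * side]]][1]
        q <- push(with_side(p, side, ins))
        steps[[length(steps) + 1L]] <- list(type = "forced", p = k, q = q)
      } else {
        abort(paste0("oracle: unreachable staggered combination ", e1, "/",
                     e2))
      }
    } else if (e1 == "Dup" || e2 == "Dup") {
      both <- e1 == "Dup" && e2 == "Dup"
      if (both && s1 == s2) {
        ku <- kids_of(p, 1); kv <- kids_of(p, 2)
        i1 <- add_pair(with_side(p, 1, ku[1]))
        i2 <- add_pair(with_side(p, 1, ku[2]))
        j1 <- add_pair(with_side(p, 2, kv[1]))
        j2 <- add_pair(with_side(p, 2, kv[2]))
        g11 <- push(c(p[1], ku[1], p[3], kv[1]))
        g22 <- push(c(p[1], ku[2], p[3], kv[2]))
        g12 <- push(c(p[1], ku[1], p[3], kv[2]))
        g21 <- push(c(p[1], ku[2], p[3], kv[1]))
        steps[[length(steps) + 1L]] <- list(
          type = "dupdup", p = k, i1 = i1, i2 = i2, j1 = j1, j2 = j2,
          g11 = g11, g22 = g22, g12 = g12, g21 = g21)
      } else {
        side <- if (e1 == "Dup" && (e2 != "Dup" || s1 <= s2)) 1L else 2L
        kk <- kids_of(p, side)
        q1 <- push(with_side(p, side, kk[1]))
        q2 <- push(with_side(p, side, kk[2]))
        steps[[length(steps) + 1L]] <- list(type = "dup", p = k,
                                            q1 = q1, q2 = q2)
      }
    } else if (e1 == "Trans" || e2 == "Trans") {
      if (e1 == "Trans" && e2 == "Trans" && s1 == s2) {
        q <- push(c(p[1], kids_of(p, 1)[1], p[3], kids_of(p, 2)[1]))
        steps[[length(steps) + 1L]] <- list(type = "flip", p = k, q = q)
      } else {
        abort("oracle: transfer paired with a non-transfer inside a class")
      }
    } else if (e1 == "SpecOut" || e2 == "SpecOut") {
      t1 <- trees[[p[1]]]; t2 <- trees[[p[3]]]
      so_pairable <- FALSE
      if (e1 == "SpecOut" && e2 == "SpecOut" && s1 == s2) {
        k1 <- kids_of(p, 1); k2 <- kids_of(p, 2)
        in1 <- k1[t1$species[k1] == t1$species[p[2]]][1]
        out1 <- k1[t1$species[k1] != t1$species[p[2]]][1]
        in2 <- k2[t2$species[k2] == t2$species[p[4]]][1]
        out2 <- k2[t2$species[k2] != t2$species[p[4]]][1]
        if (t1$event[out1] == "Trans" && t2$event[out2] == "Trans" &&
            t1$species[out1] == t2$species[out2] &&
            t1$slice[out1] == t2$slice[out2]) {
          so_pairable <- TRUE
          qin <- push(c(p[1], in1, p[3], in2))
          qout <- push(c(p[1], out1, p[3], out2))
          steps[[length(steps) + 1L]] <- list(type = "specout2", p = k,
                                              qin = qin, qout = qout)
        }
      }
      if (!so_pairable) {
        # nested same-slice SpecOuts: keep the side whose transfer can
        # still pair deeper in the partner's chain (same rule as the
        # recurrences, walked independently here)
        chain_coords <- function(tr, w) {
          sp <- tr$species[w]; sl <- tr$slice[w]
          cc <- character(0)
          while (!is.na(w) && tr$event[w] == "SpecOut" &&
                 tr$species[w] == sp && tr$slice[w] == sl) {
            kk <- tr$children[[w]]
            oo <- kk[tr$species[kk] != sp][1]
            if (tr$event[oo] == "Trans") {
              cc <- c(cc, paste(tr$species[oo], tr$slice[oo]))
            }
            w <- kk[tr$species[kk] == sp][1]
          }
          cc
        }
        side <- if (e1 == "SpecOut" && e2 == "SpecOut") {
          t1 <- trees[[p[1]]]; t2 <- trees[[p[3]]]
          c1c <- chain_coords(t1, p[2])
          c2c <- chain_coords(t2, p[4])
          if (length(c1c) && c1c[1] %in% c2c[-1]) 2L
          else if (length(c2c) && c2c[1] %in% c1c[-1]) 1L
          else 1L
        } else if (e1 == "SpecOut") 1L else 2L
        tr <- trees[[p[2 * side - 1]]]
        kk <- kids_of(p, side)
        ins <- kk[tr$species[kk] == tr$species[p[2 * side]]][1]
        q <- push(with_side(p, side, ins))
        steps[[length(steps) + 1L]] <- list(type = "forced", p = k, q = q)
      }
    } else if (e1 == "Spec" && e2 == "Spec") {
      t1 <- trees[[p[1]]]; t2 <- trees[[p[3]]]
      ku <- kids_of(p, 1); kv <- kids_of(p, 2)
      kv <- kv[match(t1$species[ku], t2$species[kv])]
      q1 <- push(c(p[1], ku[1], p[3], kv[1]))
      q2 <- push(c(p[1], ku[2], p[3], kv[2]))
      steps[[length(steps) + 1L]] <- list(type = "spec", p = k,
                                          q1 = q1, q2 = q2)
    } else if (e1 == "NoEvent" && e2 == "NoEvent" && s1 == s2) {
      q <- push(c(p[1], kids_of(p, 1)[1], p[3], kids_of(p, 2)[1]))
      steps[[length(steps) + 1L]] <- list(type = "flip", p = k, q = q)
    } else if (e1 == "NoEvent" && s1 < s2) {
      q <- push(with_side(p, 1, kids_of(p, 1)[1]))
      steps[[length(steps) + 1L]] <- list(type = "flip", p = k, q = q)
    } else if (e2 == "NoEvent" && s2 < s1) {
      q <- push(with_side(p, 2, kids_of(p, 2)[1]))
      steps[[length(steps) + 1L]] <- list(type = "flip", p = k, q = q)
    } else {
      abort(paste0("oracle: unreachable event combination ", e1, "/", e2))
    }
  }

  free <- setdiff(pairs, names(fixed))
  if (length(free) > max_pairs) {
    abort(paste0("oracle refuses: ", length(free),
                 " free pairs exceed the guard of ", max_pairs))
  }

  # ---- enumerate and score ---------------------------------------------
  n_assign <- 2^length(free)
  A <- matrix(0L, nrow = n_assign, ncol = length(pairs),
              dimnames = list(NULL, pairs))
  if (length(free)) {
    for (j in seq_along(free)) {
      period <- 2^(j - 1)
      A[, free[j]] <- rep(rep(0:1, each = period),
                          length.out = n_assign)
    }
  }
  for (fk in names(fixed)) A[, fk] <- fixed[[fk]]

  cost <- rep(0, n_assign)
  valid <- rep(TRUE, n_assign)

  dup_cost <- function(P, Q1, Q2) {
    ksum <- Q1 + Q2
    ifelse(P == 1,
           ifelse(ksum == 0, B, ifelse(ksum == 2, G, 0)),
           ksum * G)
  }
  flip_cost <- function(P, Q) {
    B * (P == 1 & Q == 0) + G * (P == 0 & Q == 1)
  }

  for (st in steps) {
    switch(st$type,
      flip = {
        cost <- cost + flip_cost(A[, st$p], A[, st$q])
      },
      forced = {
        valid <- valid & (A[, st$p] == A[, st$q])
      },
      specout2 = {
        valid <- valid & (A[, st$p] == A[, st$qin])
        cost <- cost + flip_cost(A[, st$p], A[, st$qout])
      },
      spec = {
        cost <- cost + flip_cost(A[, st$p], A[, st$q1]) +
          flip_cost(A[, st$p], A[, st$q2])
      },
      dup = {
        cost <- cost + dup_cost(A[, st$p], A[, st$q1], A[, st$q2])
      },
      dupdup = {
        P <- A[, st$p]
        I1 <- A[, st$i1]; I2 <- A[, st$i2]
        J1 <- A[, st$j1]; J2 <- A[, st$j2]
        g11 <- A[, st$g11]; g22 <- A[, st$g22]
        g12 <- A[, st$g12]; g21 <- A[, st$g21]
        mode_a <- dup_cost(P, I1, I2) + dup_cost(I1, g11, g12) +
          dup_cost(I2, g21, g22)
        mode_a[J1 == 1 | J2 == 1] <- Inf
        mode_b <- dup_cost(P, J1, J2) + dup_cost(J1, g11, g21) +
          dup_cost(J2, g12, g22)
        mode_b[I1 == 1 | I2 == 1] <- Inf
        m1 <- B * ((g11 == 0) + (g22 == 0)) + G * (g12 + g21)
        m2 <- B * ((g12 == 0) + (g21 == 0)) + G * (g11 + g22)
        mode_s <- pmin(m1, m2)
        mode_s[P == 0 | I1 == 1 | I2 == 1 | J1 == 1 | J2 == 1] <- Inf
        cost <- cost + pmin(mode_a, mode_b, mode_s)
      }
    )
  }
  # a present root adjacency has no rule parent: it is a gain
  cost <- cost + G * A[, root_key]
  cost[!valid] <- Inf
  min(cost)
}
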