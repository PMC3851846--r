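# Forward simulator of gene and adjacency evolution along a random ranked
# species tree. Produces the same three inputs the reconstruction consumes
# (dated species tree, reconciled gene trees, extant adjacencies) plus the
# ground-truth event history, so every stage of the pipeline is testable
# without external data.

#' Simulate gene and adjacency evolution with ground truth
#'
#' Evolves a circular root genome forward, slice by slice, along a random
#' ranked species tree. Genes duplicate (tandem with probability
#' `tandem_prob`, creating the copy-copy adjacency), are lost (their
#' adjacencies vanish at no rearrangement cost), and transfer out through a
#' `SpecOut`/`Trans` pair into a uniformly chosen later-or-equal slice on
#' another living branch, optionally as a contiguous block of 2-4 genes
#' whose internal adjacencies ride along. Adjacencies additionally break
#' (per adjacency per slice) and are gained (one random new adjacency per
#' branch per slice). Non-tandem duplicate copies and arriving transferred
#' blocks are integrated into the host chromosome with probability
#' `integration_prob` by breaking one adjacency and gaining flanking ones
#' (a rearrangement); otherwise they float without adjacencies.
#'
#' @param n_species Number of extant genomes (>= 2).
#' @param n_genes Number of genes in the circular root genome; each root
#'   gene founds one family.
#' @param dup_rate,loss_rate,transfer_rate Per-gene per-slice event
#'   probabilities.
#' @param gain_rate Per-branch per-slice probability of gaining one
#'   adjacency between two random non-adjacent genes.
#' @param break_rate Per-adjacency per-slice breakage probability.
#' @param block_prob Probability that a triggered transfer takes a
#'   contiguous run of 2-4 genes.
#' @param tandem_prob Probability that a duplication is tandem.
#' @param integration_prob Probability that a floating copy or arriving
#'   block is spliced into the host chromosome (one breakage, two gains).
#' @param seed Integer seed; the same seed reproduces the output exactly.
#' @return A list with components `bundle` (list: `species_tree`,
#'   `gene_trees`, `adjacencies`), `truth` (list: `cost` under unit costs,
#'   `n_gains`, `n_breaks`, `events`, `ancestral_adjacencies`,
#'   `ancestral_genes`, `transfers`) and `params`.
#' @export
simulate_adjacency_evolution <- function(n_species,
                                         n_genes = 10,
                                         dup_rate = 0.02,
                                         loss_rate = 0.02,
                                         transfer_rate = 0.02,
                                         gain_rate = 0.05,
                                         break_rate = 0.01,
                                         block_prob = 0.3,
                                         tandem_prob = 0.5,
                                         integration_prob = 1,
                                         seed = 1L) {
  for (p in c(dup_rate, loss_rate, transfer_rate, gain_rate, break_rate,
              block_prob, tandem_prob, integration_prob)) {
    if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1) {
      abort("all event probabilities must be single numbers in [0, 1]")
    }
  }
  if (n_species < 2) abort("need at least 2 species")
  if (n_genes < 1) abort("need at least 1 root gene")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))

  stree <- sim_species_tree(n_species)
  sim_core(stree, n_genes, dup_rate, loss_rate, transfer_rate, gain_rate,
           break_rate, block_prob, tandem_prob, integration_prob,
           seed = seed)
}

# Random ranked species tree: at each rank a uniformly chosen living
# lineage speciates. Only the rank order matters to the reconstruction.
sim_species_tree <- function(n_species) {
  name <- character(0); parent <- character(0); rank <- integer(0)
  active_parent <- NA_character_  # parent name of each active lineage
  active <- list(NA_character_)
  for (k in 0:(n_species - 2L)) {
    i <- if (length(active) == 1) 1L else sample.int(length(active), 1L)
    nm <- paste0("n", k)
    name <- c(name, nm); parent <- c(parent, active[[i]])
    rank <- c(rank, k)
    active <- c(active[-i], list(nm), list(nm))
  }
  for (j in seq_along(active)) {
    name <- c(name, paste0("sp", j)); parent <- c(parent, active[[j]])
    rank <- c(rank, NA_integer_)
  }
  dated_species_tree(tibble(name = name, parent = parent, rank = rank))
}

sim_core <- function(stree, n_genes, dup_rate, loss_rate, transfer_rate,
                     gain_rate, break_rate, block_prob, tandem_prob,
                     integration_prob, seed) {
  s <- stree$n_species
  s_last <- s - 1L
  snodes <- stree$nodes
  rank_of <- stats::setNames(snodes$rank, snodes$name)

  # per-family growing node stores
  fams <- paste0("fam", seq_len(n_genes))
  store <- new.env(parent = emptyenv())
  for (f in fams) {
    assign(f, list(parent = integer(0), species = character(0),
                   event = character(0), slice = integer(0),
                   label = character(0)), envir = store)
  }
  add_node <- function(fam, parent, species, event, slice, label = NA) {
    st <- get(fam, envir = store)
    id <- length(st$parent) + 1L
    st$parent <- c(st$parent, as.integer(parent))
    st$species <- c(st$species, species)
    st$event <- c(st$event, event)
    st$slice <- c(st$slice, as.integer(slice))
    st$label <- c(st$label,
                  if (is.na(label)) paste0(fam, ".n", id) else label)
    assign(fam, st, envir = store)
    id
  }

  # lineage registry: handle -> c(fam, parent node id as character)
  lin <- new.env(parent = emptyenv())
  lin_n <- 0L
  new_lineage <- function(fam, parent_node) {
    lin_n <<- lin_n + 1L
    h <- sprintf("L%06d", lin_n)
    assign(h, list(fam = fam, parent = parent_node), envir = lin)
    h
  }
  lin_get <- function(h) get(h, envir = lin)

  adj_key <- function(a, b) {
    paste(pmin(a, b), pmax(a, b), sep = "|")
  }
  adj_split <- function(k) strsplit(k, "|", fixed = TRUE)

  # genome per live branch: list(genes = handles, adj = keys)
  genomes <- new.env(parent = emptyenv())

  # truth accounting
  n_gains <- 0L; n_breaks <- 0L
  ev_species <- character(0); ev_slice <- integer(0); ev_type <- character(0)
  record_event <- function(type, species, slice, times = 1L) {
    if (times <= 0) return(invisible())
    if (type == "Gain") n_gains <<- n_gains + times
    else n_breaks <<- n_breaks + times
    ev_type <<- c(ev_type, rep(type, times))
    ev_species <<- c(ev_species, rep(species, times))
    ev_slice <<- c(ev_slice, rep(as.integer(slice), times))
  }
  anc_adj <- list(); anc_genes <- list()
  transfer_log <- list()
  arrivals <- list()  # per slice: list of arrival records

  # initial circular genome on the root branch
  root_branch <- stree$root
  h0 <- vapply(fams, function(f) new_lineage(f, NA_integer_), character(1))
  adj0 <- character(0)
  if (n_genes >= 2) {
    ring <- c(seq_len(n_genes), 1L)
    adj0 <- unique(vapply(seq_len(n_genes), function(i) {
      adj_key(h0[ring[i]], h0[ring[i + 1]])
    }, character(1)))
  }
  assign(root_branch, list(genes = unname(h0), adj = adj0), envir = genomes)

  branches_alive <- function(t) {
    snodes$name[snodes$first_slice <= t & snodes$last_slice >= t]
  }

  handle_labels <- function(handles, node_ids) {
    vapply(seq_along(handles), function(i) {
      l <- lin_get(handles[i])
      st <- get(l$fam, envir = store)
      st$label[node_ids[i]]
    }, character(1))
  }

  integrate_into <- function(g, members, branch, t) {
    # members: ordered handles of a path; splice into a random adjacency
    # not involving the members themselves
    cand <- g$adj[!vapply(adj_split(g$adj), function(uv)
      any(uv %in% members), logical(1))]
    if (length(cand) >= 1 && stats::runif(1) < integration_prob) {
      k <- cand[sample.int(length(cand), 1L)]
      uv <- adj_split(k)[[1]]
      g$adj <- setdiff(g$adj, k)
      record_event("Break", branch, t)
      g$adj <- union(g$adj, c(adj_key(uv[1], members[1]),
                              adj_key(members[length(members)], uv[2])))
      record_event("Gain", branch, t, 2L)
    }
    g
  }

  for (t in 0:(s_last - 1L)) {
    # 1) speciation at the internal node of rank t
    x <- snodes$name[!snodes$is_leaf & snodes$rank == t]
    gx <- get(x, envir = genomes)
    kids <- species_children(stree, x)
    spec_ids <- integer(0); spec_labels <- character(0)
    map1 <- character(0); map2 <- character(0)
    for (j in seq_along(gx$genes)) {
      h <- gx$genes[j]
      l <- lin_get(h)
      nid <- add_node(l$fam, l$parent, x, "Spec", t)
      spec_ids <- c(spec_ids, nid)
      h1 <- new_lineage(l$fam, nid)
      h2 <- new_lineage(l$fam, nid)
      map1[h] <- h1; map2[h] <- h2
    }
    spec_labels <- handle_labels(gx$genes, spec_ids)
    anc_genes[[length(anc_genes) + 1L]] <-
      tibble(species = x, slice = t, gene = spec_labels)
    if (length(gx$adj)) {
      prs <- do.call(rbind, adj_split(gx$adj))
      lab1 <- spec_labels[match(prs[, 1], gx$genes)]
      lab2 <- spec_labels[match(prs[, 2], gx$genes)]
      cadj <- canonical_adjacency(lab1, lab2)
      anc_adj[[length(anc_adj) + 1L]] <-
        tibble(species = x, slice = t, gene1 = cadj$gene1,
               gene2 = cadj$gene2)
    }
    remap <- function(m) {
      function(k) {
        uv <- adj_split(k)[[1]]
        adj_key(m[[uv[1]]], m[[uv[2]]])
      }
    }
    for (side in 1:2) {
      m <- if (side == 1) map1 else map2
      assign(kids[side], list(
        genes = unname(m[gx$genes]),
        adj = if (length(gx$adj))
          vapply(gx$adj, remap(m), character(1), USE.NAMES = FALSE)
        else character(0)
      ), envir = genomes)
    }
    rm(list = x, envir = genomes)
    if (t == 0L) {
      # root-genome adjacencies are the original gains
      record_event("Gain", x, 0L, times = length(gx$adj))
    }

    live <- setdiff(branches_alive(t), stree$root)
    # 2) scheduled transfer arrivals for this slice
    key_t <- as.character(t)
    if (!is.null(arrivals[[key_t]])) {
      for (ar in arrivals[[key_t]]) {
        if (!ar$recipient %in% live) next
        g <- get(ar$recipient, envir = genomes)
        g$genes <- c(g$genes, ar$members)
        g$adj <- union(g$adj, ar$block_adj)
        if (length(ar$members)) {
          g <- integrate_into(g, ar$members, ar$recipient, t)
        }
        assign(ar$recipient, g, envir = genomes)
      }
      arrivals[[key_t]] <- NULL
    }

    # 3) events within slice t, branch by branch
    for (b in sort(live)) {
      g <- get(b, envir = genomes)
      if (!length(g$genes)) { assign(b, g, envir = genomes); next }

      # losses
      die <- stats::runif(length(g$genes)) < loss_rate
      if (any(die)) {
        for (h in g$genes[die]) {
          l <- lin_get(h)
          add_node(l$fam, l$parent, b, "Loss", t)
        }
        dead <- g$genes[die]
        g$genes <- g$genes[!die]
        if (length(g$adj)) {
          prs <- do.call(rbind, adj_split(g$adj))
          g$adj <- g$adj[!(prs[, 1] %in% dead | prs[, 2] %in% dead)]
        }
      }

      # duplications
      dup <- stats::runif(length(g$genes)) < dup_rate
      for (h in g$genes[dup]) {
        l <- lin_get(h)
        nid <- add_node(l$fam, l$parent, b, "Dup", t)
        h1 <- new_lineage(l$fam, nid)
        h2 <- new_lineage(l$fam, nid)
        nbr_keys <- g$adj[grepl(h, g$adj, fixed = TRUE)]
        g$adj <- setdiff(g$adj, nbr_keys)
        others <- vapply(nbr_keys, function(k) {
          uv <- adj_split(k)[[1]]
          if (uv[1] == h) uv[2] else uv[1]
        }, character(1), USE.NAMES = FALSE)
        g$genes <- c(setdiff(g$genes, h), h1, h2)
        if (stats::runif(1) < tandem_prob) {
          # tandem: neighbours split between the copies, copy adjacency gained
          if (length(others)) {
            half <- stats::runif(length(others)) < 0.5
            g$adj <- union(g$adj, c(
              if (any(half)) adj_key(others[half], rep(h1, sum(half))),
              if (any(!half)) adj_key(others[!half], rep(h2, sum(!half)))
            ))
          }
          g$adj <- union(g$adj, adj_key(h1, h2))
          record_event("Gain", b, t)
        } else {
          # copy 1 stays in place; copy 2 is integrated elsewhere (or floats)
          if (length(others)) {
            g$adj <- union(g$adj, adj_key(others, rep(h1, length(others))))
          }
          g <- integrate_into(g, h2, b, t)
        }
      }

      # transfers
      tra <- stats::runif(length(g$genes)) < transfer_rate
      used_arrivals <- character(0)
      for (h in g$genes[tra]) {
        if (!(h %in% g$genes)) next  # already moved as part of a block
        # distinct transfer events from one donor slice take distinct
        # (arrival slice, recipient) coordinates: in the model, transfers
        # sharing all four coordinates are one co-transfer event, and in
        # continuous time independent collisions have measure zero
        t_ok <- Filter(function(tt) {
          rr <- setdiff(branches_alive(tt), c(b, stree$root))
          any(!(paste(tt, rr) %in% used_arrivals))
        }, seq(t, s_last - 1L))
        if (!length(t_ok)) next
        t_arr <- if (length(t_ok) == 1L) t_ok[[1]] else
          t_ok[[sample.int(length(t_ok), 1L)]]
        recip <- setdiff(branches_alive(t_arr), c(b, stree$root))
        recip <- recip[!(paste(t_arr, recip) %in% used_arrivals)]
        if (!length(recip)) next
        r <- recip[sample.int(length(recip), 1L)]
        used_arrivals <- c(used_arrivals, paste(t_arr, r))
        members <- h
        if (stats::runif(1) < block_prob) {
          len <- sample(2:4, 1L)
          while (length(members) < len) {
            endh <- members[length(members)]
            nbr_keys <- g$adj[grepl(endh, g$adj, fixed = TRUE)]
            nbrs <- setdiff(unlist(adj_split(nbr_keys)), members)
            nbrs <- intersect(sort(nbrs), g$genes)
            if (!length(nbrs)) break
            members <- c(members, nbrs[1])
          }
        }
        # a donor adjacency between co-transferred genes that is NOT on the
        # block path (e.g. the closing junction of a fully transferred
        # circle) cannot arrive with the linear block: one breakage on the
        # transferred side
        if (length(members) > 1) {
          path_keys <- vapply(seq_len(length(members) - 1L), function(i)
            adj_key(members[i], members[i + 1L]), character(1))
          within_keys <- g$adj[vapply(adj_split(g$adj), function(uv)
            all(uv %in% members), logical(1))]
          record_event("Break", r, t_arr,
                       as.integer(sum(!(within_keys %in% path_keys))))
        }
        arr_members <- character(0); trans_labels <- character(0)
        inside_map <- character(0)
        for (m in members) {
          l <- lin_get(m)
          so <- add_node(l$fam, l$parent, b, "SpecOut", t)
          hin <- new_lineage(l$fam, so)
          tn <- add_node(l$fam, so, r, "Trans", t_arr)
          hout <- new_lineage(l$fam, tn)
          inside_map[m] <- hin
          arr_members <- c(arr_members, hout)
          st <- get(l$fam, envir = store)
          trans_labels <- c(trans_labels, st$label[tn])
        }
        # donor genome: members replaced by their inside continuations
        g$genes[match(members, g$genes)] <- unname(inside_map[members])
        if (length(g$adj)) {
          g$adj <- vapply(g$adj, function(k) {
            uv <- adj_split(k)[[1]]
            u <- if (uv[1] %in% members) inside_map[[uv[1]]] else uv[1]
            v <- if (uv[2] %in% members) inside_map[[uv[2]]] else uv[2]
            adj_key(u, v)
          }, character(1), USE.NAMES = FALSE)
        }
        # block-internal adjacencies ride along (no gain)
        block_adj <- character(0)
        if (length(members) > 1) {
          for (i in seq_len(length(members) - 1L)) {
            block_adj <- c(block_adj,
                           adj_key(arr_members[i], arr_members[i + 1L]))
          }
        }
        transfer_log[[length(transfer_log) + 1L]] <- tibble(
          donor = b, recipient = r, departure_slice = t,
          arrival_slice = t_arr, n_genes = length(members),
          members = paste(sort(trans_labels), collapse = ",")
        )
        rec <- list(recipient = r, members = arr_members,
                    block_adj = block_adj)
        if (t_arr == t) {
          gr_now <- if (r %in% sort(live) && exists(r, envir = genomes))
            get(r, envir = genomes) else NULL
          if (!is.null(gr_now)) {
            gr_now$genes <- c(gr_now$genes, rec$members)
            gr_now$adj <- union(gr_now$adj, rec$block_adj)
            gr_now <- integrate_into(gr_now, rec$members, r, t)
            assign(r, gr_now, envir = genomes)
            if (r == b) g <- get(b, envir = genomes)
          }
        } else {
          key <- as.character(t_arr)
          arrivals[[key]] <- c(arrivals[[key]], list(rec))
        }
      }

      # breakages
      if (length(g$adj)) {
        broken <- stats::runif(length(g$adj)) < break_rate
        if (any(broken)) {
          record_event("Break", b, t, sum(broken))
          g$adj <- g$adj[!broken]
        }
      }

      # gains
      if (length(g$genes) >= 2 && stats::runif(1) < gain_rate) {
        cand <- sort(g$genes)
        pick <- sample(cand, 2L)
        k <- adj_key(pick[1], pick[2])
        if (!(k %in% g$adj)) {
          g$adj <- union(g$adj, k)
          record_event("Gain", b, t)
        }
      }

      assign(b, g, envir = genomes)
    }
  }

  # extant slice: close every surviving lineage
  extant_rows <- list()
  for (b in snodes$name[snodes$is_leaf]) {
    g <- get(b, envir = genomes)
    cnt <- 0L
    labmap <- character(0)
    for (h in g$genes) {
      cnt <- cnt + 1L
      l <- lin_get(h)
      lab <- paste0(b, "_", l$fam, "_", cnt)
      add_node(l$fam, l$parent, b, "Extant", s_last, label = lab)
      labmap[h] <- lab
    }
    if (length(g$adj)) {
      prs <- do.call(rbind, adj_split(g$adj))
      extant_rows[[length(extant_rows) + 1L]] <-
        canonical_adjacency(labmap[prs[, 1]], labmap[prs[, 2]]) |>
        dplyr::mutate(species = b)
    }
  }
  extant_adj <- if (length(extant_rows)) dplyr::bind_rows(extant_rows) else
    tibble(gene1 = character(), gene2 = character(), species = character())

  # assemble gene trees (families may have died out entirely)
  gene_trees <- list()
  for (f in fams) {
    st <- get(f, envir = store)
    if (!length(st$parent)) next
    nodes <- tibble(id = seq_along(st$parent), parent = st$parent,
                    label = st$label, species = st$species,
                    event = st$event, slice = st$slice)
    tr <- recon_gene_tree(nodes, f)
    tr <- fill_node_labels(tr)
    validate_gene_tree(tr, stree)
    gene_trees[[length(gene_trees) + 1L]] <- tr
  }

  truth_events <- tibble(type = ev_type, species = ev_species,
                         slice = ev_slice)
  list(
    bundle = list(species_tree = stree, gene_trees = gene_trees,
                  adjacencies = extant_adj),
    truth = list(
      cost = n_gains + n_breaks,
      n_gains = n_gains,
      n_breaks = n_breaks,
      events = truth_events,
      ancestral_adjacencies = if (length(anc_adj))
        dplyr::bind_rows(anc_adj) else
          tibble(species = character(), slice = integer(),
                 gene1 = character(), gene2 = character()),
      ancestral_genes = if (length(anc_genes))
        dplyr::bind_rows(anc_genes) else
          tibble(species = character(), slice = integer(),
                 gene = character()),
      transfers = if (length(transfer_log)) dplyr::bind_rows(transfer_log)
        else tibble(donor = character(), recipient = character(),
                    departure_slice = integer(), arrival_slice = integer(),
                    n_genes = integer(), members = character())
    ),
    params = list(n_species = stree$n_species, n_genes = n_genes,
                  dup_rate = dup_rate, loss_rate = loss_rate,
                  transfer_rate = transfer_rate, gain_rate = gain_rate,
                  break_rate = break_rate, block_prob = block_prob,
                  tandem_prob = tandem_prob,
                  integration_prob = integration_prob, seed = seed)
  )
}
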