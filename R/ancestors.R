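# reference ordering of family labels (operon order, then anything else)
family_order <- function(labels) {
  ref <- c(letters[1:10], "k")
  c(intersect(ref, labels), sort(setdiff(labels, ref)))
}

# copy vector (named, reference order) and counted sub-block count of a block
block_profile <- function(block, count_pseudo = FALSE) {
  bg <- block_genes(as_gene_block(block), count_pseudo)
  ct <- copy_table(bg$genes)
  list(copies = ct[family_order(names(ct))], nseg = length(bg$segments))
}

# flat numeric profile of a block over a fixed family universe; lets the
# reconstruction's inner loops score many block pairs cheaply (the totals
# equal event_distance(); asserted in the test suite)
block_fast_profile <- function(block, fams, count_pseudo = FALSE) {
  bg <- block_genes(as_gene_block(block), count_pseudo)
  copies <- stats::setNames(integer(length(fams)), fams)
  ct <- copy_table(bg$genes)
  ct <- ct[names(ct) %in% fams]
  copies[names(ct)] <- ct
  segmat <- if (length(bg$segments))
    do.call(rbind, lapply(bg$segments, function(s) fams %in% s))
  else matrix(FALSE, 0, length(fams))
  list(copies = copies, pres = copies > 0L, segmat = segmat)
}

profile_dist <- function(a, b) {
  sh <- a$pres & b$pres
  del <- sum(a$pres != b$pres)
  dup <- if (any(sh)) sum(abs(a$copies[sh] - b$copies[sh])) else 0L
  ra <- if (nrow(a$segmat)) sum(rowSums(a$segmat[, sh, drop = FALSE]) > 0) else 0L
  rb <- if (nrow(b$segmat)) sum(rowSums(b$segmat[, sh, drop = FALSE]) > 0) else 0L
  del + dup + abs(ra - rb)
}

# dense pairwise profile_dist matrix, vectorized over states
profile_cost_matrix <- function(profs) {
  nc <- length(profs)
  P <- do.call(rbind, lapply(profs, function(p) p$pres)) + 0
  C <- do.call(rbind, lapply(profs, function(p) p$copies))
  A <- P %*% t(1 - P)
  del <- A + t(A)
  dup <- matrix(0, nc, nc)
  for (f in seq_len(ncol(P))) {
    sh <- outer(P[, f] > 0, P[, f] > 0, `&`)
    dup <- dup + abs(outer(C[, f], C[, f], `-`)) * sh
  }
  nseg <- vapply(profs, function(p) nrow(p$segmat), 0L)
  if (sum(nseg) > 0) {
    S <- do.call(rbind, lapply(profs[nseg > 0], function(p) p$segmat)) + 0
    grp <- rep(which(nseg > 0), nseg[nseg > 0])
    T <- (S %*% t(P) > 0) + 0            # segment x state: holds shared gene
    R <- matrix(0, nc, nc)
    R[sort(unique(grp)), ] <- rowsum(T, grp)
    splits <- abs(R - t(R))
  } else splits <- matrix(0, nc, nc)
  del + dup + splits
}

# cached profiles for an enumerated local block space, relative to the
# instance's family universe
local_enum_profiles <- function(fams_l, maxc, maxs, fams) {
  ck <- paste("prof", paste(sort(fams_l), collapse = ""), maxc, maxs,
              paste(fams, collapse = ""), sep = "_")
  if (is.null(.oracle_cache[[ck]]))
    .oracle_cache[[ck]] <- lapply(enumerate_blocks(fams_l, maxc, maxs),
                                  block_fast_profile, fams = fams)
  .oracle_cache[[ck]]
}

# deterministic realization: genes in reference order, cut into nseg
# near-equal contiguous sub-blocks
realize_block <- function(copies, nseg, genome_id = NA_character_) {
  copies <- copies[copies > 0]
  total <- sum(copies)
  if (total == 0)
    return(structure(list(genome_id = genome_id, segments = list(),
                          statuses = list()), class = "gene_block"))
  genes <- rep(names(copies)[order(match(names(copies),
                                         family_order(names(copies))))],
               copies[order(match(names(copies),
                                  family_order(names(copies))))])
  s <- max(1L, min(nseg, total))
  base <- total %/% s
  sizes <- rep(base, s)
  if (total %% s > 0) sizes[seq_len(total %% s)] <- base + 1L
  cut <- c(0L, cumsum(sizes))
  segs <- lapply(seq_len(s), function(i) genes[(cut[i] + 1):cut[i + 1]])
  gene_block(segs, genome_id = genome_id)
}

# generic Sankoff over integer states on a rooted tree; cost_fun(x, y) gives
# the cost of a parent-child change; `prefer` orders states for tie-breaking
sankoff_int <- function(tree, leaf_states, states, cost_fun, prefer) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  ns <- length(states)
  cost <- outer(states, states, Vectorize(cost_fun))
  dp <- matrix(Inf, nn, ns)
  for (i in seq_len(nt))
    dp[i, ] <- ifelse(states == leaf_states[[tree$tip.label[i]]], 0, Inf)
  po <- ape::reorder.phylo(tree, "postorder")
  for (v in unique(po$edge[, 1])) dp[v, ] <- 0
  for (r in seq_len(nrow(po$edge))) {
    par <- po$edge[r, 1]; ch <- po$edge[r, 2]
    inc <- apply(cost + matrix(dp[ch, ], ns, ns, byrow = TRUE), 1, min)
    dp[par, ] <- dp[par, ] + inc
  }
  ord <- order(match(states, prefer))
  assign_state <- integer(nn)
  root <- nt + 1L
  root_choice <- ord[which.min(dp[root, ord])]
  assign_state[root] <- states[root_choice]
  pre <- rev(seq_len(nrow(po$edge)))
  for (r in pre) {
    par <- po$edge[r, 1]; ch <- po$edge[r, 2]
    ps <- assign_state[par]
    tot <- cost[match(ps, states), ] + dp[ch, ]
    choice <- ord[which.min(tot[ord])]
    assign_state[ch] <- states[choice]
  }
  assign_state
}

#' Maximum-parsimony reconstruction of ancestral gene blocks
#'
#' Assigns a gene block to every internal node of a rooted tree so that the
#' summed event-based distance ([event_distance()]) over all edges is
#' minimized. The problem is first decomposed into independent characters --
#' per-family copy number (Sankoff states 0..max copies; a presence change
#' costs one deletion-category event, a copy change one duplication-category
#' event per copy) and counted sub-block number (Sankoff, cost = absolute
#' difference) -- whose solutions seed a candidate block set; an exact
#' Sankoff pass over that candidate set with full event-distance edge costs
#' then picks the final assignment, which captures interactions the
#' decomposition misses (a family loss can absorb a segmentation change).
#' Ties prefer presence, lower copy number, fewer sub-blocks, then reference
#' gene order; ancestral segmentation is realized in reference gene order.
#'
#' @param tree rooted `phylo` tree whose tip labels index `leaf_blocks`.
#' @param leaf_blocks named list of [gene_block()]s or block strings
#'   (possibly empty blocks).
#' @param count_pseudo count pseudogenes as gene copies (default `FALSE`).
#' @return object of class `block_reconstruction`: `tree`, `node_blocks`
#'   (one block per node, leaves first, in `ape` node order), `edge_events`
#'   (per-edge event triples), `node_cumulative` (events in the subtree below
#'   each node, columns deletions/duplications/splits), `total_events`, and
#'   `node_pseudo_a` (reconstructed presence of a cyp115 fragment).
#' @export
reconstruct_blocks <- function(tree, leaf_blocks, count_pseudo = FALSE) {
  if (!ape::is.rooted(tree))
    stop("reconstruct_blocks: tree must be rooted")
  if (!all(tree$tip.label %in% names(leaf_blocks)))
    stop("reconstruct_blocks: missing leaf blocks: ",
         paste(setdiff(tree$tip.label, names(leaf_blocks)), collapse = ", "))
  leaf_blocks <- lapply(leaf_blocks, as_gene_block)
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  root <- nt + 1L

  profs <- lapply(leaf_blocks[tree$tip.label], block_profile, count_pseudo)
  fams <- family_order(unique(unlist(lapply(profs, function(p)
    names(p$copies)))))

  # --- character decomposition to seed candidates ---------------------------
  node_copies <- matrix(0L, nn, length(fams),
                        dimnames = list(NULL, fams))
  for (f in fams) {
    leaf_f <- lapply(profs, function(p)
      if (f %in% names(p$copies)) p$copies[[f]] else 0L)
    maxc <- max(unlist(leaf_f), 1L)
    cost_fun <- function(x, y) {
      if (x == y) 0
      else if (xor(x == 0, y == 0)) 1
      else abs(x - y)
    }
    node_copies[, f] <- sankoff_int(tree, leaf_f, 0:maxc, cost_fun,
                                    prefer = c(1:maxc, 0L))
  }
  leaf_nseg <- lapply(profs, function(p) p$nseg)
  max_s <- max(unlist(leaf_nseg), 1L)
  node_nseg <- sankoff_int(tree, leaf_nseg, 0:max_s,
                           function(x, y) abs(x - y),
                           prefer = c(1:max_s, 0L))

  # --- candidate blocks -----------------------------------------------------
  cand <- list()
  seen <- character(0)
  push <- function(bl) {
    key <- render_block(bl)
    if (key %in% seen) return(invisible())
    seen <<- c(seen, key)
    cand[[length(cand) + 1L]] <<- bl
  }
  for (i in seq_len(nt)) {
    bg <- block_genes(leaf_blocks[[tree$tip.label[i]]], count_pseudo)
    push(if (length(bg$segments)) gene_block(bg$segments) else
      realize_block(integer(0), 0L))
  }
  cv_set <- unique(lapply(seq_len(nn), function(v)
    node_copies[v, , drop = TRUE]))
  ns_set <- sort(unique(c(unlist(leaf_nseg), node_nseg)))
  for (cv in cv_set) for (s in ns_set)
    push(realize_block(cv, s))
  push(realize_block(integer(0), 0L))

  # --- iterated exact DP over a growing candidate pool ----------------------
  # A Sankoff pass over the pool is globally optimal for that pool; after
  # each pass every internal node contributes its locally optimal blocks
  # (over the enumerable block space spanned by its current neighbors) to the
  # pool, and the DP is repeated until neither the total nor the pool
  # improves. This captures optima whose segment compositions are not
  # reference-order cuts (e.g. a family loss absorbing a segmentation
  # change).
  pool <- cand
  pool_keys <- vapply(pool, function(b)
    state_key(block_genes(b, count_pseudo)$segments), "")
  profs <- lapply(pool, block_fast_profile, fams = fams,
                  count_pseudo = count_pseudo)
  cost <- profile_cost_matrix(profs)
  leaf_idx <- vapply(seq_len(nt), function(i) {
    k <- state_key(block_genes(leaf_blocks[[tree$tip.label[i]]],
                               count_pseudo)$segments)
    match(k, pool_keys)
  }, 0L)
  po <- ape::reorder.phylo(tree, "postorder")

  run_dp <- function() {
    nc <- length(pool)
    dp <- matrix(Inf, nn, nc)
    for (i in seq_len(nt)) {
      dp[i, ] <- Inf
      dp[i, leaf_idx[i]] <- 0
    }
    for (v in unique(po$edge[, 1])) dp[v, ] <- 0
    for (r in seq_len(nrow(po$edge))) {
      par <- po$edge[r, 1]; ch <- po$edge[r, 2]
      inc <- apply(cost + matrix(dp[ch, ], nc, nc, byrow = TRUE), 1, min)
      dp[par, ] <- dp[par, ] + inc
    }
    nfam <- vapply(profs, function(p) sum(p$pres), 0L)
    ncop <- vapply(profs, function(p) sum(p$copies), 0L)
    nsg <- vapply(profs, function(p) nrow(p$segmat), 0L)
    ord <- order(-nfam, ncop, nsg, vapply(pool, render_block, ""))
    assign_idx <- integer(nn)
    assign_idx[root] <- ord[which.min(dp[root, ord])]
    for (r in rev(seq_len(nrow(po$edge)))) {
      par <- po$edge[r, 1]; ch <- po$edge[r, 2]
      tot <- cost[assign_idx[par], ] + dp[ch, ]
      assign_idx[ch] <- ord[which.min(tot[ord])]
    }
    list(assign = assign_idx, total = min(dp[root, ]))
  }

  nb_of <- lapply(seq_len(nn), function(v)
    c(tree$edge[tree$edge[, 2] == v, 1], tree$edge[tree$edge[, 1] == v, 2]))
  prev_total <- Inf
  for (iter in 1:8) {
    fit <- run_dp()
    grew <- FALSE
    if (fit$total == 0) break
    for (v in (nt + 1L):nn) {
      nb_prof <- profs[fit$assign[nb_of[[v]]]]
      fams_l <- family_order(fams[Reduce(`|`, lapply(nb_prof,
                                                     function(p) p$pres))])
      maxc_l <- max(1L, unlist(lapply(nb_prof, function(p) max(p$copies))))
      maxs_l <- max(1L, vapply(nb_prof, function(p) nrow(p$segmat), 0L))
      if (length(fams_l) == 0 || length(fams_l) > 5 || maxc_l > 2 ||
          maxs_l > 2) next
      lpool <- enumerate_blocks(fams_l, maxc_l, maxs_l)
      lprof <- local_enum_profiles(fams_l, maxc_l, maxs_l, fams)
      lcost <- vapply(lprof, function(p)
        sum(vapply(nb_prof, profile_dist, 0, a = p)), 0)
      for (w in which(lcost <= min(lcost) + 2)) {
        k <- state_key(lpool[[w]]$segments)
        if (!(k %in% pool_keys)) {
          pool[[length(pool) + 1L]] <- lpool[[w]]
          pool_keys <- c(pool_keys, k)
          profs[[length(profs) + 1L]] <- lprof[[w]]
          grew <- TRUE
        }
      }
    }
    if (grew) cost <- profile_cost_matrix(profs)
    if (!grew && fit$total >= prev_total) break
    if (fit$total < prev_total) prev_total <- fit$total
    if (!grew) break
  }
  fit <- run_dp()
  assign_idx <- fit$assign
  current <- lapply(seq_len(nn), function(v)
    if (v <= nt) leaf_blocks[[tree$tip.label[v]]] else pool[[assign_idx[v]]])

  node_lab <- c(tree$tip.label, paste0("n", (nt + 1):nn))
  node_blocks <- lapply(seq_len(nn), function(v) {
    b <- if (v <= nt) leaf_blocks[[tree$tip.label[v]]] else current[[v]]
    b$genome_id <- node_lab[v]
    b
  })
  names(node_blocks) <- node_lab

  edge_events <- t(vapply(seq_len(nrow(tree$edge)), function(r) {
    event_distance(current[[tree$edge[r, 1]]],
                   current[[tree$edge[r, 2]]], count_pseudo)[1:3]
  }, c(deletions = 0L, duplications = 0L, splits = 0L)))

  cum <- matrix(0L, nn, 3,
                dimnames = list(node_lab,
                                c("deletions", "duplications", "splits")))
  for (r in seq_len(nrow(po$edge))) {
    par <- po$edge[r, 1]; ch <- po$edge[r, 2]
    er <- which(tree$edge[, 1] == par & tree$edge[, 2] == ch)
    cum[par, ] <- cum[par, ] + cum[ch, ] + edge_events[er, ]
  }

  # cyp115-fragment presence, reconstructed as its own unordered character
  leaf_pa <- lapply(leaf_blocks[tree$tip.label], function(b)
    as.integer(any(unlist(b$segments) == "a" & unlist(b$statuses) == "pseudo")))
  node_pa <- if (length(fams))
    sankoff_int(tree, leaf_pa, 0:1, function(x, y) as.numeric(x != y),
                prefer = c(0L, 1L)) else rep(0L, nn)

  structure(list(tree = tree, node_blocks = node_blocks,
                 edge_events = edge_events, node_cumulative = cum,
                 total_events = sum(cum[root, ]),
                 node_pseudo_a = stats::setNames(node_pa == 1L, node_lab),
                 count_pseudo = count_pseudo),
            class = "block_reconstruction")
}

#' @export
print.block_reconstruction <- function(x, ...) {
  cat("<block_reconstruction> ", length(x$tree$tip.label), " leaves, total ",
      x$total_events, " events (",
      paste(x$node_cumulative[length(x$tree$tip.label) + 1L, ],
            collapse = ", "), ")\n", sep = "")
  invisible(x)
}

.oracle_cache <- new.env(parent = emptyenv())

# full oracle state space over a family set, with a dense pairwise
# event-distance matrix computed from state profiles (copy vectors and
# per-segment family membership); cached per family set
oracle_state_space <- function(fams) {
  key <- paste(sort(fams), collapse = "")
  if (!is.null(.oracle_cache[[key]])) return(.oracle_cache[[key]])
  states <- enumerate_blocks(fams, 2L, 2L)
  ns <- length(states)
  nf <- length(fams)
  copies <- matrix(0L, ns, nf, dimnames = list(NULL, fams))
  segmask <- vector("list", ns)  # per state: segments x families membership
  for (i in seq_len(ns)) {
    ct <- copy_table(unlist(states[[i]]$segments))
    copies[i, names(ct)] <- ct
    segmask[[i]] <- do.call(rbind, lapply(states[[i]]$segments, function(s)
      fams %in% s))
  }
  pres <- copies > 0L
  cost <- matrix(0, ns, ns)
  for (i in seq_len(ns)) {
    if (i >= ns) break
    for (j in (i + 1):ns) {
      sh <- pres[i, ] & pres[j, ]
      del <- sum(xor(pres[i, ], pres[j, ]))
      dup <- if (any(sh)) sum(abs(copies[i, sh] - copies[j, sh])) else 0L
      ri <- if (is.null(segmask[[i]])) 0L else
        sum(segmask[[i]][, sh, drop = FALSE] %*% rep(1, sum(sh)) > 0)
      rj <- if (is.null(segmask[[j]])) 0L else
        sum(segmask[[j]][, sh, drop = FALSE] %*% rep(1, sum(sh)) > 0)
      cost[i, j] <- cost[j, i] <- del + dup + abs(ri - rj)
    }
  }
  out <- list(states = states,
              keys = vapply(states, function(b) state_key(b$segments), ""),
              cost = cost)
  .oracle_cache[[key]] <- out
  out
}

# enumerate every block over `fams` with <= max_copy copies per family and
# <= max_seg sub-blocks (all multiset partitions of the genes); memoised
enumerate_blocks <- function(fams, max_copy = 2L, max_seg = 2L) {
  memo_key <- paste("enum", paste(sort(fams), collapse = ""), max_copy,
                    max_seg, sep = "_")
  if (!is.null(.oracle_cache[[memo_key]])) return(.oracle_cache[[memo_key]])
  grids <- expand.grid(rep(list(0:max_copy), length(fams)),
                       KEEP.OUT.ATTRS = FALSE)
  names(grids) <- fams
  out <- list(structure(list(genome_id = NA_character_, segments = list(),
                             statuses = list()), class = "gene_block"))
  for (r in seq_len(nrow(grids))) {
    cv <- unlist(grids[r, , drop = FALSE])
    genes <- rep(fams, cv)
    if (length(genes) == 0) next
    out[[length(out) + 1L]] <- gene_block(list(genes))
    if (max_seg >= 2 && length(genes) >= 2) {
      for (sp in segment_splits(genes))
        out[[length(out) + 1L]] <- gene_block(sp)
    }
  }
  .oracle_cache[[memo_key]] <- out
  out
}

#' Exhaustive oracle for maximum-parsimony reconstruction
#'
#' Minimizes the summed [event_distance()] over all edges by exact dynamic
#' programming over the complete state space of ancestral blocks (every block
#' over the observed families with at most `max_copy` copies and `max_seg`
#' sub-blocks, in every segment composition). Feasible only for tiny
#' instances; validates [reconstruct_blocks()].
#'
#' @param tree rooted `phylo` (at most 6 leaves).
#' @param leaf_blocks named list of blocks (at most 4 families, 2 copies per
#'   family, 2 sub-blocks).
#' @param count_pseudo see [event_distance()].
#' @return minimal total event count (numeric scalar).
#' @export
oracle_reconstruct <- function(tree, leaf_blocks, count_pseudo = FALSE) {
  if (!ape::is.rooted(tree)) stop("oracle_reconstruct: tree must be rooted")
  nt <- length(tree$tip.label)
  if (nt > 6) stop("oracle_reconstruct: instance too large (leaves)")
  leaf_blocks <- lapply(leaf_blocks, as_gene_block)
  profs <- lapply(leaf_blocks[tree$tip.label], block_profile, count_pseudo)
  fams <- family_order(unique(unlist(lapply(profs, function(p)
    names(p$copies)))))
  if (length(fams) > 4) stop("oracle_reconstruct: instance too large (families)")
  if (any(unlist(lapply(profs, function(p) p$copies)) > 2))
    stop("oracle_reconstruct: instance too large (copies)")
  if (any(vapply(profs, function(p) p$nseg, 0L) > 2))
    stop("oracle_reconstruct: instance too large (sub-blocks)")

  space <- oracle_state_space(fams)
  states <- space$states
  keys <- space$keys
  cost <- space$cost
  ns <- length(states)
  nn <- nt + tree$Nnode
  dp <- matrix(Inf, nn, ns)
  for (i in seq_len(nt)) {
    bg <- block_genes(leaf_blocks[[tree$tip.label[i]]], count_pseudo)
    k <- state_key(bg$segments)
    hit <- which(keys == k)
    if (length(hit) == 0)
      stop("oracle_reconstruct: leaf block outside the state space")
    dp[i, ] <- Inf
    dp[i, hit[1]] <- 0
  }
  po <- ape::reorder.phylo(tree, "postorder")
  for (v in unique(po$edge[, 1])) dp[v, ] <- 0
  for (r in seq_len(nrow(po$edge))) {
    par <- po$edge[r, 1]; ch <- po$edge[r, 2]
    inc <- apply(cost + matrix(dp[ch, ], ns, ns, byrow = TRUE), 1, min)
    dp[par, ] <- dp[par, ] + inc
  }
  min(dp[nt + 1L, ])
}

#' Compare parsimony totals across alternative phylogenies
#'
#' Runs [reconstruct_blocks()] on the same leaf blocks under each tree and
#' tabulates the total event counts, sorted ascending (the most parsimonious
#' tree first). This is the operon-tree versus species-tree contrast used to
#' argue for horizontal transfer: if the gene block travelled between
#' lineages, a tree built from the block itself explains the leaf blocks with
#' fewer events than the species tree does.
#'
#' @param leaf_blocks named list of blocks covering every tree's leaves.
#' @param trees named list of rooted `phylo` trees over the same leaf set.
#' @param count_pseudo see [event_distance()].
#' @return data frame with columns `tree`, `total_events`, `deletions`,
#'   `duplications`, `splits`, ordered by `total_events`.
#' @export
compare_trees <- function(leaf_blocks, trees, count_pseudo = FALSE) {
  if (is.null(names(trees)))
    names(trees) <- paste0("tree", seq_along(trees))
  sets <- lapply(trees, function(t) sort(t$tip.label))
  if (length(unique(vapply(sets, paste, "", collapse = "|"))) != 1L)
    stop("compare_trees: trees have different leaf sets")
  rows <- lapply(names(trees), function(nm) {
    rec <- reconstruct_blocks(trees[[nm]], leaf_blocks, count_pseudo)
    root <- length(trees[[nm]]$tip.label) + 1L
    data.frame(tree = nm, total_events = rec$total_events,
               deletions = rec$node_cumulative[root, "deletions"],
               duplications = rec$node_cumulative[root, "duplications"],
               splits = rec$node_cumulative[root, "splits"],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$total_events, out$tree), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-node annotation flags of a reconstruction
#'
#' `*` marks nodes whose block holds a full-length cyp115 (family `a`), `!`
#' nodes carrying a cyp115 truncation/fragment, `?` nodes whose block holds
#' ggps2 (family `k`).
#'
#' @param rec a [reconstruct_blocks()] result.
#' @return data frame with columns `node`, `block`, `flags`.
#' @export
annotate_flags <- function(rec) {
  nodes <- names(rec$node_blocks)
  flags <- vapply(nodes, function(nd) {
    b <- rec$node_blocks[[nd]]
    lab <- unlist(b$segments)
    st <- unlist(b$statuses)
    paste0(if (any(lab == "a" & st == "full")) "*" else "",
           if (any(lab == "a" & st == "pseudo") || rec$node_pseudo_a[[nd]])
             "!" else "",
           if (any(lab == "k")) "?" else "")
  }, "")
  data.frame(node = nodes,
             block = vapply(rec$node_blocks, render_block, ""),
             flags = flags, row.names = NULL, stringsAsFactors = FALSE)
}
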