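#' Event-based distance between two gene blocks
#'
#' The distance counts the minimum number of pairwise events separating two
#' orthologous gene blocks, in three categories:
#' \describe{
#'   \item{deletions}{families present in exactly one block (unordered
#'     presence changes; gene gains fall in this category too);}
#'   \item{duplications}{sum over families present in both blocks of the
#'     absolute copy-number difference;}
#'   \item{splits}{absolute difference of the sub-block counts after each
#'     block is restricted to the families shared by both (sub-blocks left
#'     empty by the restriction are dropped).}
#' }
#' Gene order within a sub-block does not contribute. Pseudogenes are
#' excluded by default (a truncated fragment is not a functional copy).
#'
#' @param A,B [gene_block()] objects or block strings.
#' @param count_pseudo include pseudogenes as gene copies (default `FALSE`).
#' @return named integer vector `c(deletions, duplications, splits, total)`.
#' @examples
#' event_distance("abcdefghij", "bcdefghi")  # 2 deletions
#' event_distance("bcdefghi|j", "bcdefghij") # 1 split
#' @export
event_distance <- function(A, B, count_pseudo = FALSE) {
  a <- block_genes(as_gene_block(A), count_pseudo)
  b <- block_genes(as_gene_block(B), count_pseudo)
  ca <- copy_table(a$genes)
  cb <- copy_table(b$genes)
  fam_a <- names(ca)
  fam_b <- names(cb)
  shared <- intersect(fam_a, fam_b)
  deletions <- length(setdiff(fam_a, fam_b)) + length(setdiff(fam_b, fam_a))
  duplications <- if (length(shared))
    sum(abs(ca[shared] - cb[shared])) else 0L
  splits <- abs(restricted_segments(a$segments, shared) -
                restricted_segments(b$segments, shared))
  out <- c(deletions = as.integer(deletions),
           duplications = as.integer(duplications),
           splits = as.integer(splits))
  c(out, total = sum(out))
}

# genes and segments of a block after dropping (or keeping) pseudogenes
block_genes <- function(block, count_pseudo = FALSE) {
  segs <- lapply(seq_along(block$segments), function(i) {
    keep <- if (count_pseudo) rep(TRUE, length(block$segments[[i]]))
            else block$statuses[[i]] == "full"
    block$segments[[i]][keep]
  })
  segs <- segs[lengths(segs) > 0L]
  list(genes = unlist(segs), segments = segs)
}

copy_table <- function(genes) {
  if (is.null(genes) || length(genes) == 0L)
    return(integer(0))
  tab <- table(genes)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

# number of sub-blocks still holding at least one gene of a shared family
restricted_segments <- function(segments, shared) {
  if (length(segments) == 0L) return(0L)
  sum(vapply(segments, function(s) any(s %in% shared), TRUE))
}

#' Pairwise event-distance matrix over a set of blocks
#'
#' @param blocks named list of [gene_block()]s or block strings.
#' @param count_pseudo see [event_distance()].
#' @return a data frame with one row per unordered pair: `id1`, `id2`,
#'   `deletions`, `duplications`, `splits`, `total`.
#' @export
event_matrix <- function(blocks, count_pseudo = FALSE) {
  ids <- names(blocks)
  if (is.null(ids)) ids <- paste0("block", seq_along(blocks))
  n <- length(blocks)
  rows <- list()
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- event_distance(blocks[[i]], blocks[[j]], count_pseudo)
    rows[[length(rows) + 1L]] <- data.frame(
      id1 = ids[i], id2 = ids[j], deletions = d[["deletions"]],
      duplications = d[["duplications"]], splits = d[["splits"]],
      total = d[["total"]], stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# ---- exhaustive oracle -----------------------------------------------------

# canonical key of a block state: segments as sorted multisets, sorted
state_key <- function(segs) {
  if (length(segs) == 0L) return("(empty)")
  paste(sort(vapply(segs, function(s) paste(sort(s), collapse = ""), "")),
        collapse = "|")
}

# integer partitions of n (n <= 3 is all the oracle needs)
int_partitions <- function(n) {
  if (n == 0L) return(list(integer(0)))
  out <- list()
  recurse <- function(rest, maxpart, acc) {
    if (rest == 0L) { out[[length(out) + 1L]] <<- acc; return(invisible()) }
    for (p in seq_len(min(rest, maxpart))) recurse(rest - p, p, c(acc, p))
  }
  recurse(n, n, integer(0))
  out
}

# all placements of k copies of family f over existing segments / new segments
gain_configs <- function(segs, f, k) {
  nseg <- length(segs)
  out <- list()
  alloc <- if (nseg > 0)
    expand.grid(rep(list(0:k), nseg), KEEP.OUT.ATTRS = FALSE)
  else data.frame(row.names = 1)
  for (r in seq_len(nrow(alloc))) {
    counts <- if (nseg > 0) as.integer(alloc[r, ]) else integer(0)
    if (sum(counts) > k) next
    rem <- k - sum(counts)
    for (newparts in int_partitions(rem)) {
      ns <- segs
      for (i in seq_len(nseg)) if (counts[i] > 0)
        ns[[i]] <- c(ns[[i]], rep(f, counts[i]))
      for (p in newparts) ns[[length(ns) + 1L]] <- rep(f, p)
      out[[length(out) + 1L]] <- ns
    }
  }
  out
}

# all ways to split one multiset segment into two non-empty parts
segment_splits <- function(seg) {
  n <- length(seg)
  out <- list()
  seen <- character(0)
  for (m in 1:(2^n - 2)) {
    take <- as.logical(bitwAnd(m, 2^(seq_len(n) - 1L)))
    a <- sort(seg[take]); b <- sort(seg[!take])
    key <- paste(paste(a, collapse = ""), paste(b, collapse = ""), sep = "/")
    alt <- paste(paste(b, collapse = ""), paste(a, collapse = ""), sep = "/")
    if (!(key %in% seen) && !(alt %in% seen)) {
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- list(a, b)
    }
  }
  out
}

#' Exhaustive oracle for the event-based distance
#'
#' Independent validation of [event_distance()]: a uniform-cost search over
#' sequences of atomic edits transforming block `A` until it matches `B`'s
#' family copy numbers and its sub-block count restricted to the families the
#' pair shares. Atomic edits are: delete a family (all its copies; sub-blocks
#' emptied by the deletion vanish), gain an absent family (its copies arrive
#' together as a new sub-block), add one copy of a present family in tandem,
#' remove one copy (the sub-block must keep a gene of a shared family), and
#' split or join sub-blocks. A family is never deleted and regained along one
#' path: every difference is explained by one presence event. Intended for
#' tiny instances only.
#'
#' @param A,B blocks or block strings; at most 6 families, 3 copies each.
#' @return named integer vector as in [event_distance()], giving one
#'   minimizing edit composition (the total is the distance; when several
#'   compositions reach the same minimum the first found is reported).
#' @export
oracle_distance <- function(A, B) {
  a <- block_genes(as_gene_block(A))
  b <- block_genes(as_gene_block(B))
  fams <- union(unique(a$genes), unique(b$genes))
  if (length(fams) > 6) stop("oracle_distance: instance too large (families)")
  if ((length(a$genes) && max(copy_table(a$genes)) > 3) ||
      (length(b$genes) && max(copy_table(b$genes)) > 3))
    stop("oracle_distance: instance too large (copies)")

  goal_copies <- copy_table(b$genes)
  goal_fams <- names(goal_copies)
  # segmentation is compared on the families the original pair shares:
  # sub-blocks holding only unshared families are invisible to the distance
  shared0 <- intersect(unique(a$genes), unique(b$genes))
  goal_rseg <- restricted_segments(b$segments, shared0)

  # remaining difference between a state and the goal; every atomic edit
  # changes it by at most one, so it never overestimates the remaining cost
  # and a state with h = 0 is a goal state
  h_fun <- function(segs) {
    ct <- copy_table(unlist(segs))
    pres <- names(ct)
    h <- length(setdiff(pres, goal_fams)) + length(setdiff(goal_fams, pres))
    sh <- intersect(pres, shared0)
    if (length(sh)) h <- h + sum(abs(ct[sh] - goal_copies[sh]))
    h + abs(restricted_segments(segs, shared0) - goal_rseg)
  }

  # per-family copy caps and a segment cap: a minimal edit path has no use
  # for more copies, or more sub-blocks, than either endpoint exhibits
  ca0 <- copy_table(a$genes)
  copy_cap <- vapply(fams, function(f)
    max(if (f %in% names(ca0)) ca0[[f]] else 0L,
        if (f %in% names(goal_copies)) goal_copies[[f]] else 0L, 1L),
    1L)
  names(copy_cap) <- fams
  seg_cap <- max(length(a$segments), length(b$segments)) +
    length(setdiff(goal_fams, names(ca0))) + 1L
  depth_cap <- h_fun(a$segments) + 1L

  neighbors <- function(segs) {
    out <- list()
    add <- function(new_segs, kind) {
      new_segs <- new_segs[lengths(new_segs) > 0L]
      if (length(new_segs) > seg_cap) return(invisible())
      out[[length(out) + 1L]] <- list(segs = new_segs, kind = kind)
      out <<- out
    }
    present <- unique(unlist(segs))
    ct <- copy_table(unlist(segs))
    # delete a family the goal lacks (deleting a goal family is a dead end:
    # a deleted family is never regained)
    for (f in setdiff(present, goal_fams)) {
      ns <- lapply(segs, function(s) s[s != f])
      add(ns, "deletions")
    }
    # gain a goal family; its copies arrive as one new sub-block (placement
    # of an unshared family is invisible to the distance)
    for (f in setdiff(goal_fams, present))
      add(c(segs, list(rep(f, goal_copies[[f]]))), "deletions")
    # copy-number moves (duplication events); a new copy arises in tandem
    for (f in present) {
      if (ct[[f]] < copy_cap[[f]]) {
        for (i in seq_along(segs)) {
          if (!(f %in% segs[[i]])) next
          ns <- segs; ns[[i]] <- c(ns[[i]], f)
          add(ns, "duplications")
        }
      }
      if (ct[[f]] > 1L) {
        # remove one copy; the sub-block must keep at least one gene of a
        # shared family, else the move would hide a segmentation change
        for (i in seq_along(segs)) {
          if (f %in% segs[[i]] && length(segs[[i]]) > 1L) {
            ns <- segs
            ns[[i]] <- ns[[i]][-match(f, ns[[i]])]
            if (!any(ns[[i]] %in% shared0)) next
            add(ns, "duplications")
          }
        }
      }
    }
    # split a sub-block / join two sub-blocks
    for (i in seq_along(segs)) {
      if (length(segs[[i]]) >= 2L) {
        for (sp in segment_splits(segs[[i]]))
          add(c(segs[-i], sp), "splits")
      }
    }
    if (length(segs) >= 2L) {
      for (i in 1:(length(segs) - 1L)) for (j in (i + 1):length(segs))
        add(c(segs[-c(i, j)], list(c(segs[[i]], segs[[j]]))), "splits")
    }
    out
  }

  start <- a$segments
  seen <- new.env(parent = emptyenv())
  k0 <- state_key(start)
  assign(k0, TRUE, seen)
  zero <- c(deletions = 0L, duplications = 0L, splits = 0L)
  frontier <- list(list(segs = start, triple = zero))
  if (h_fun(start) == 0L) return(c(zero, total = 0L))
  depth <- 0L
  while (length(frontier) > 0L && depth <= depth_cap) {
    depth <- depth + 1L
    nxt <- list()
    for (node in frontier) {
      for (nb in neighbors(node$segs)) {
        k <- state_key(nb$segs)
        if (exists(k, seen)) next
        assign(k, TRUE, seen)
        tr <- node$triple
        tr[nb$kind] <- tr[nb$kind] + 1L
        h <- h_fun(nb$segs)
        if (h == 0L) return(c(tr, total = sum(tr)))
        if (depth + h > depth_cap) next   # cannot beat the canonical script
        nxt[[length(nxt) + 1L]] <- list(segs = nb$segs, triple = tr)
      }
    }
    frontier <- nxt
  }
  stop("oracle_distance: search exhausted without reaching the goal")
}
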