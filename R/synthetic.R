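#' Reference gene families of the gibberellin operon
#'
#' Single-letter labels for the ten operon genes of the reference taxon
#' (cyp115, cyp112, cyp114, fd, sdr, cyp117, ggps, cps, ks, idi) plus the
#' accessory GGPP synthase ggps2 (`k`). Label `a` (cyp115) and `k` (ggps2)
#' follow the published figure legends; `b`..`j` follow operon gene order.
#'
#' @param query_lengths optional named numeric vector of query gene lengths
#'   (bp or residues, one unit used consistently); defaults to the simulator
#'   template lengths.
#' @return data frame with columns `label`, `name`, `query_length`.
#' @export
reference_families <- function(query_lengths = NULL) {
  fam <- data.frame(
    label = c("a", "b", "c", "d", "e", "f", "g", "h", "i", "j", "k"),
    name = c("cyp115", "cyp112", "cyp114", "fd", "sdr", "cyp117", "ggps",
             "cps", "ks", "idi", "ggps2"),
    query_length = unname(default_template_lengths()),
    stringsAsFactors = FALSE)
  if (!is.null(query_lengths)) {
    idx <- match(fam$label, names(query_lengths))
    fam$query_length[!is.na(idx)] <- query_lengths[idx[!is.na(idx)]]
  }
  fam
}

default_template_lengths <- function() {
  c(a = 1200, b = 1200, c = 1200, d = 300, e = 750, f = 1200, g = 900,
    h = 1500, i = 900, j = 350, k = 900)
}

#' Simulation configuration for gene-block evolution
#'
#' Defines the generative scenario: a pure-birth tree, a root gene block, and
#' per-gene event rates (expected events per unit branch length per root-block
#' gene) for deletion, duplication, split, gain and pseudogenizing
#' truncation, plus a per-branch-length rate of whole-block horizontal
#' transfer. Operon DNA is emitted at `gc_operon`, the genomic background at
#' `gc_background`; intra-block gaps stay at or below the 500-bp neighbor
#' threshold while split gaps exceed it.
#'
#' @param n_leaves number of extant genomes (>= 2).
#' @param birth_rate Yule birth rate per unit time.
#' @param root_block block string or [gene_block()] at the root.
#' @param rate_deletion,rate_duplication,rate_split,rate_gain,rate_pseudogenize
#'   per-gene per-branch-length event rates (>= 0).
#' @param rate_hgt per-branch-length rate of whole-block replacement from a
#'   contemporaneous donor lineage.
#' @param gc_background,gc_operon GC fractions in `[0, 1]`.
#' @param marker_sub_rate,operon_sub_rate substitutions per site per unit
#'   branch length for the marker gene and the operon genes.
#' @param intra_block_gap length-2 range (bp) for gaps inside a sub-block;
#'   max must be <= 500.
#' @param split_gap length-2 range (bp) for gaps at splits; min must be > 500.
#' @param template_lengths named vector of operon gene template lengths (bp).
#' @param marker_length marker gene length (bp).
#' @param alphabet gene families available to gain events.
#' @param sequences simulate nucleotide sequences (set `FALSE` to evolve
#'   blocks only, which is much faster).
#' @param seed integer seed; identical seeds give identical simulations.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_leaves = 12, birth_rate = 1.0,
                       root_block = "abcdefghij",
                       rate_deletion = 0.2, rate_duplication = 0.02,
                       rate_split = 0.05, rate_gain = 0.02, rate_hgt = 0,
                       rate_pseudogenize = 0.05,
                       gc_background = 0.60, gc_operon = 0.68,
                       marker_sub_rate = 0.15, operon_sub_rate = 0.05,
                       intra_block_gap = c(50, 400),
                       split_gap = c(600, 2000),
                       template_lengths = default_template_lengths(),
                       marker_length = 1200,
                       alphabet = c(letters[1:10], "k"),
                       sequences = TRUE, seed = 1L) {
  rates <- c(rate_deletion, rate_duplication, rate_split, rate_gain,
             rate_hgt, rate_pseudogenize)
  if (any(rates < 0)) stop("sim_config: rates must be >= 0")
  if (gc_background < 0 || gc_background > 1 || gc_operon < 0 || gc_operon > 1)
    stop("sim_config: GC fractions must lie in [0, 1]")
  if (n_leaves < 2) stop("sim_config: n_leaves must be >= 2")
  if (max(intra_block_gap) > 500)
    stop("sim_config: intra_block_gap must not exceed the 500-bp threshold")
  if (min(split_gap) <= 500)
    stop("sim_config: split_gap must exceed the 500-bp threshold")
  root_block <- as_gene_block(root_block)
  structure(list(
    n_leaves = as.integer(n_leaves), birth_rate = birth_rate,
    root_block = root_block, rate_deletion = rate_deletion,
    rate_duplication = rate_duplication, rate_split = rate_split,
    rate_gain = rate_gain, rate_hgt = rate_hgt,
    rate_pseudogenize = rate_pseudogenize, gc_background = gc_background,
    gc_operon = gc_operon, marker_sub_rate = marker_sub_rate,
    operon_sub_rate = operon_sub_rate, intra_block_gap = intra_block_gap,
    split_gap = split_gap, template_lengths = template_lengths,
    marker_length = marker_length, alphabet = alphabet,
    sequences = isTRUE(sequences), seed = as.integer(seed)),
    class = "sim_config")
}

#' Sample a pure-birth (Yule) species tree
#'
#' @param n_leaves number of leaves (>= 2).
#' @param birth_rate birth rate per unit time.
#' @param seed integer seed.
#' @return an `ape` `phylo` tree with leaves `g01`, `g02`, ... and strictly
#'   positive branch lengths; deterministic under `seed`.
#' @export
sample_tree <- function(n_leaves, birth_rate = 1.0, seed = 1L) {
  if (n_leaves < 2) stop("sample_tree: n_leaves must be >= 2")
  set.seed(as.integer(seed))
  tree <- ape::rphylo(n_leaves, birth = birth_rate, death = 0)
  tree$tip.label <- sprintf("g%02d", seq_len(n_leaves))
  # guard against zero-length edges from coalescing event times
  tree$edge.length[tree$edge.length <= 0] <- min(
    tree$edge.length[tree$edge.length > 0]) / 100
  tree
}

# random nucleotide sequence with expected GC content
random_seq <- function(n, gc) {
  sample(c("A", "T", "G", "C"), n, replace = TRUE,
         prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

# substitutions at `rate` per site over duration dt, GC-biased base choice
mutate_seq <- function(seq, rate, dt, gc) {
  if (dt <= 0 || rate <= 0) return(seq)
  n <- rpois(1, rate * dt * length(seq))
  if (n == 0) return(seq)
  pos <- sample.int(length(seq), n, replace = TRUE)
  seq[pos] <- random_seq(n, gc)
  seq
}

#' Per-family nucleotide templates for the simulator
#'
#' @param config a [sim_config()].
#' @return named list of character vectors (one per family) plus a `marker`
#'   entry; drawn at the configured operon/background GC.
#' @export
make_family_templates <- function(config) {
  set.seed(config$seed)
  tpl <- lapply(config$template_lengths, function(n)
    random_seq(n, config$gc_operon))
  tpl$marker <- random_seq(config$marker_length, config$gc_background)
  tpl
}

# internal mutable block state: ordered segments of (label, status)
new_state <- function(block) {
  list(segments = block$segments, statuses = block$statuses)
}
state_to_block <- function(st, genome_id = NA_character_) {
  if (length(st$segments) == 0L)
    return(structure(list(genome_id = genome_id, segments = list(),
                          statuses = list()), class = "gene_block"))
  gene_block(st$segments, st$statuses, genome_id)
}
state_families <- function(st) unique(unlist(st$segments))

apply_deletion <- function(st, family) {
  keep <- lapply(st$segments, function(s) s != family)
  st$segments <- mapply(function(s, k) s[k], st$segments, keep,
                        SIMPLIFY = FALSE)
  st$statuses <- mapply(function(s, k) s[k], st$statuses, keep,
                        SIMPLIFY = FALSE)
  nz <- lengths(st$segments) > 0L
  st$segments <- st$segments[nz]
  st$statuses <- st$statuses[nz]
  st
}

apply_duplication <- function(st, family, seg, pos) {
  s <- st$segments[[seg]]
  st$segments[[seg]] <- append(s, family, after = pos)
  st$statuses[[seg]] <- append(st$statuses[[seg]],
                               st$statuses[[seg]][pos], after = pos)
  st
}

apply_split <- function(st, seg, pos) {
  s <- st$segments[[seg]]; q <- st$statuses[[seg]]
  st$segments <- append(st$segments[-seg],
                        list(s[1:pos], s[(pos + 1):length(s)]), after = seg - 1L)
  st$statuses <- append(st$statuses[-seg],
                        list(q[1:pos], q[(pos + 1):length(q)]), after = seg - 1L)
  st
}

apply_gain <- function(st, family, seg) {
  if (length(st$segments) == 0L) {
    st$segments <- list(family)
    st$statuses <- list("full")
  } else {
    st$segments[[seg]] <- c(st$segments[[seg]], family)
    st$statuses[[seg]] <- c(st$statuses[[seg]], "full")
  }
  st
}

apply_pseudogenize <- function(st, seg, pos) {
  st$statuses[[seg]][pos] <- "pseudo"
  st
}

#' Simulate gene-block evolution along a tree
#'
#' Events arrive on each branch as Poisson counts with mean
#' rate x branch length x root-block size (whole-block HGT:
#' rate x branch length), are placed at uniform times, and are applied in
#' global time order so an HGT event copies the donor lineage's current block
#' (and sequences) at the moment of transfer. Deletions remove every copy of
#' one extant family; duplications insert a tandem copy; splits cut a
#' sub-block; gains append one absent family to a sub-block end; pseudogenize
#' marks one full-length gene as a truncated fragment.
#'
#' @param tree a rooted `phylo` tree, e.g. from [sample_tree()].
#' @param config a [sim_config()].
#' @return list with `leaf_blocks` (named [gene_block()]s), `node_blocks`
#'   (true internal-node blocks), `log` (event data frame replayable by
#'   [replay_event_log()]), `leaf_seqs` (per-leaf per-family nucleotide
#'   vectors, if `config$sequences`), `marker` (per-leaf marker gene),
#'   `templates`, `tree`, `config`.
#' @export
evolve_blocks <- function(tree, config) {
  if (length(unlist(config$root_block$segments)) == 0L)
    stop("evolve_blocks: root block must be non-empty")
  set.seed(config$seed)
  templates <- if (config$sequences) make_family_templates(config) else NULL
  set.seed(config$seed + 1L)

  nt <- length(tree$tip.label)
  node_time <- ape::node.depth.edgelength(tree)
  node_lab <- c(tree$tip.label, paste0("n", (nt + 1):(nt + tree$Nnode)))
  root <- nt + 1L
  edges <- data.frame(parent = tree$edge[, 1], child = tree$edge[, 2],
                      len = tree$edge.length)
  edges$t0 <- node_time[edges$parent]
  edges$t1 <- node_time[edges$child]

  n0 <- length(unlist(config$root_block$segments))
  rates <- c(deletion = config$rate_deletion,
             duplication = config$rate_duplication,
             split = config$rate_split, gain = config$rate_gain,
             pseudogenize = config$rate_pseudogenize)

  ev <- list()
  for (r in seq_len(nrow(edges))) {
    for (type in names(rates)) {
      k <- rpois(1, rates[[type]] * edges$len[r] * n0)
      if (k > 0) ev[[length(ev) + 1L]] <- data.frame(
        time = runif(k, edges$t0[r], edges$t1[r]), edge = edges$child[r],
        kind = "event", type = type, stringsAsFactors = FALSE)
    }
    k <- rpois(1, config$rate_hgt * edges$len[r])
    if (k > 0) ev[[length(ev) + 1L]] <- data.frame(
      time = runif(k, edges$t0[r], edges$t1[r]), edge = edges$child[r],
      kind = "event", type = "hgt", stringsAsFactors = FALSE)
  }
  arrivals <- data.frame(time = node_time[edges$child], edge = edges$child,
                         kind = "arrive", type = "", stringsAsFactors = FALSE)
  queue <- rbind(do.call(rbind, ev), arrivals)
  queue <- queue[order(queue$time, queue$kind), , drop = FALSE]

  # lineage states, indexed by the child node of the live edge
  states <- vector("list", nt + tree$Nnode)
  root_state <- new_state(config$root_block)
  root_seqs <- if (config$sequences)
    templates[intersect(names(templates), state_families(root_state))]
  marker0 <- if (config$sequences) templates$marker else NULL
  for (child in edges$child[edges$parent == root])
    states[[child]] <- list(st = root_state, seqs = root_seqs,
                            marker = marker0, last_t = 0)

  log_rows <- list()
  node_blocks <- list()
  node_blocks[[node_lab[root]]] <- state_to_block(config$root_block,
                                                  node_lab[root])
  leaf_blocks <- list()
  leaf_seqs <- list()
  leaf_marker <- list()

  advance <- function(lin, t) {
    dt <- t - lin$last_t
    if (config$sequences && dt > 0) {
      lin$seqs <- lapply(lin$seqs, mutate_seq, config$operon_sub_rate, dt,
                         config$gc_operon)
      lin$marker <- mutate_seq(lin$marker, config$marker_sub_rate, dt,
                               config$gc_background)
    }
    lin$last_t <- t
    lin
  }

  log_event <- function(time, edge, type, family = NA, seg = NA, pos = NA,
                        donor = NA) {
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      time = time, branch = node_lab[edge], type = type,
      family = as.character(family), seg = as.integer(seg),
      pos = as.integer(pos), donor = as.character(donor),
      stringsAsFactors = FALSE)
  }

  for (q in seq_len(nrow(queue))) {
    row <- queue[q, ]
    e <- row$edge
    lin <- states[[e]]
    if (is.null(lin)) next  # edge replaced by processing order (never expected)
    lin <- advance(lin, row$time)

    if (row$kind == "arrive") {
      states[[e]] <- lin
      if (e <= nt) {
        leaf_blocks[[tree$tip.label[e]]] <- state_to_block(lin$st,
                                                           tree$tip.label[e])
        leaf_seqs[[tree$tip.label[e]]] <- lin$seqs
        leaf_marker[[tree$tip.label[e]]] <- lin$marker
      } else {
        node_blocks[[node_lab[e]]] <- state_to_block(lin$st, node_lab[e])
        for (child in edges$child[edges$parent == e])
          states[[child]] <- lin
        states[e] <- list(NULL)
      }
      next
    }

    st <- lin$st
    if (row$type == "deletion") {
      fams <- state_families(st)
      if (length(fams)) {
        f <- if (length(fams) == 1L) fams else sample(fams, 1)
        st <- apply_deletion(st, f)
        lin$seqs <- lin$seqs[names(lin$seqs) != f]
        log_event(row$time, e, "deletion", family = f)
      }
    } else if (row$type == "duplication") {
      hits <- which(unlist(lapply(st$statuses,
                                  function(s) s == "full")) %in% TRUE)
      if (length(hits)) {
        flat <- cbind(rep(seq_along(st$segments), lengths(st$segments)),
                      unlist(lapply(lengths(st$segments), seq_len)))
        pick <- flat[if (length(hits) == 1L) hits else sample(hits, 1), ,
                     drop = FALSE]
        f <- st$segments[[pick[1]]][pick[2]]
        st <- apply_duplication(st, f, pick[1], pick[2])
        log_event(row$time, e, "duplication", family = f, seg = pick[1],
                  pos = pick[2])
      }
    } else if (row$type == "split") {
      cand <- which(lengths(st$segments) >= 2L)
      if (length(cand)) {
        sg <- if (length(cand) == 1L) cand else sample(cand, 1)
        pos <- sample.int(length(st$segments[[sg]]) - 1L, 1)
        st <- apply_split(st, sg, pos)
        log_event(row$time, e, "split", seg = sg, pos = pos)
      }
    } else if (row$type == "gain") {
      absent <- setdiff(config$alphabet, state_families(st))
      if (length(absent)) {
        f <- if (length(absent) == 1L) absent else sample(absent, 1)
        sg <- if (length(st$segments)) sample.int(length(st$segments), 1) else 1L
        st <- apply_gain(st, f, sg)
        if (config$sequences && f %in% names(templates))
          lin$seqs[[f]] <- templates[[f]]
        log_event(row$time, e, "gain", family = f, seg = sg)
      }
    } else if (row$type == "pseudogenize") {
      full <- which(unlist(lapply(st$statuses,
                                  function(s) s == "full")) %in% TRUE)
      if (length(full)) {
        flat <- cbind(rep(seq_along(st$segments), lengths(st$segments)),
                      unlist(lapply(lengths(st$segments), seq_len)))
        pick <- flat[if (length(full) == 1L) full else sample(full, 1), ,
                     drop = FALSE]
        st <- apply_pseudogenize(st, pick[1], pick[2])
        log_event(row$time, e, "pseudogenize",
                  family = st$segments[[pick[1]]][pick[2]],
                  seg = pick[1], pos = pick[2])
      }
    } else if (row$type == "hgt") {
      alive <- edges$child[edges$t0 < row$time & row$time < edges$t1 &
                             edges$child != e]
      alive <- alive[!vapply(states[alive], is.null, TRUE)]
      if (length(alive)) {
        donor <- if (length(alive) == 1L) alive else sample(alive, 1)
        dlin <- advance(states[[donor]], row$time)
        states[[donor]] <- dlin
        st <- dlin$st
        lin$seqs <- dlin$seqs
        log_event(row$time, e, "hgt", donor = node_lab[donor])
      }
    }
    lin$st <- st
    states[[e]] <- lin
  }

  log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(time = numeric(0), branch = character(0), type = character(0),
               family = character(0), seg = integer(0), pos = integer(0),
               donor = character(0), stringsAsFactors = FALSE)
  list(leaf_blocks = leaf_blocks[tree$tip.label],
       node_blocks = node_blocks, log = log,
       leaf_seqs = if (config$sequences) leaf_seqs[tree$tip.label],
       marker = if (config$sequences) leaf_marker[tree$tip.label],
       templates = templates, tree = tree, config = config)
}

#' Neighbor-joining trees from a simulation's sequences
#'
#' Builds the species tree from the marker-gene alignment and the operon tree
#' from the concatenated conserved operon genes (see [concat_operon()]),
#' using the simulator's indel-free sequences directly. Genomes missing any
#' concatenation family are dropped from both trees; both trees are rooted on
#' the alphabetically first shared genome so parsimony totals are comparable.
#'
#' @param sim result of [evolve_blocks()] with `sequences = TRUE`.
#' @return named list of rooted `phylo` trees (`species`, and `operon` when
#'   at least three genomes retain the full concatenation set).
#' @export
sim_nj_trees <- function(sim) {
  if (is.null(sim$leaf_seqs))
    stop("sim_nj_trees: simulation was run without sequences")
  marker <- vapply(sim$marker, paste, "", collapse = "")
  trees <- list(species = nj_tree(p_distance(as_alignment_matrix(marker))))
  seqs <- lapply(sim$leaf_seqs, function(s) lapply(s, paste, collapse = ""))
  co <- concat_operon(seqs)
  if (length(co$sequences) >= 3)
    trees$operon <- nj_tree(p_distance(as_alignment_matrix(co$sequences)))
  shared <- Reduce(intersect, lapply(trees, function(t) t$tip.label))
  if (length(shared) < 3)
    stop("sim_nj_trees: fewer than 3 genomes shared by the trees")
  og <- sort(shared)[1]
  lapply(trees, function(t)
    root_with_outgroup(ape::keep.tip(t, shared), og))
}

#' Replay an event log from the root block
#'
#' Deterministically re-applies a simulation's logged events (in time order,
#' with the logged families, positions and HGT donors) down the tree and
#' returns the resulting leaf blocks. Replaying [evolve_blocks()] output must
#' reproduce its leaf blocks exactly.
#'
#' @param tree the tree the log was generated on.
#' @param root_block the root [gene_block()] (or block string).
#' @param log event data frame from [evolve_blocks()].
#' @return named list of leaf [gene_block()]s.
#' @export
replay_event_log <- function(tree, root_block, log) {
  root_block <- as_gene_block(root_block)
  nt <- length(tree$tip.label)
  node_lab <- c(tree$tip.label, paste0("n", (nt + 1):(nt + tree$Nnode)))
  node_time <- ape::node.depth.edgelength(tree)
  root <- nt + 1L
  edges <- data.frame(parent = tree$edge[, 1], child = tree$edge[, 2])
  edges$t1 <- node_time[edges$child]

  queue <- rbind(
    data.frame(time = log$time, edge = match(log$branch, node_lab),
               kind = "event", idx = seq_len(nrow(log))),
    data.frame(time = edges$t1, edge = edges$child, kind = "arrive", idx = NA))
  queue <- queue[order(queue$time, queue$kind), , drop = FALSE]

  states <- vector("list", nt + tree$Nnode)
  for (child in edges$child[edges$parent == root])
    states[[child]] <- new_state(root_block)
  leaf_blocks <- list()

  for (q in seq_len(nrow(queue))) {
    row <- queue[q, ]
    e <- row$edge
    st <- states[[e]]
    if (row$kind == "arrive") {
      if (e <= nt) {
        leaf_blocks[[tree$tip.label[e]]] <- state_to_block(st,
                                                           tree$tip.label[e])
      } else {
        for (child in edges$child[edges$parent == e]) states[[child]] <- st
      }
      next
    }
    rec <- log[row$idx, ]
    states[[e]] <- switch(rec$type,
      deletion = apply_deletion(st, rec$family),
      duplication = apply_duplication(st, rec$family, rec$seg, rec$pos),
      split = apply_split(st, rec$seg, rec$pos),
      gain = apply_gain(st, rec$family, rec$seg),
      pseudogenize = apply_pseudogenize(st, rec$seg, rec$pos),
      hgt = states[[match(rec$donor, node_lab)]],
      st)
  }
  leaf_blocks[tree$tip.label]
}
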