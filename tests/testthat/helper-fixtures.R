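# Shared fixture builders. The block enumeration here is written from
# scratch (bitmask subsets) so the tests do not lean on package internals.

# every block over `fams` with at most `max_copy` copies per family and at
# most two sub-blocks, as block objects
enum_blocks_fixture <- function(fams, max_copy = 2) {
  grids <- expand.grid(rep(list(0:max_copy), length(fams)))
  out <- list()
  for (r in seq_len(nrow(grids))) {
    genes <- rep(fams, unlist(grids[r, ]))
    if (length(genes) == 0) next
    out[[length(out) + 1]] <- gene_block(list(genes))
    if (length(genes) >= 2) {
      n <- length(genes)
      seen <- character(0)
      for (m in 1:(2^n - 2)) {
        take <- as.logical(bitwAnd(m, 2^(seq_len(n) - 1)))
        a <- sort(genes[take]); b <- sort(genes[!take])
        key <- paste(paste(a, collapse = ""), paste(b, collapse = ""))
        alt <- paste(paste(b, collapse = ""), paste(a, collapse = ""))
        if (!(key %in% seen) && !(alt %in% seen)) {
          seen <- c(seen, key)
          out[[length(out) + 1]] <- gene_block(list(a, b))
        }
      }
    }
  }
  out
}

# random block over `fams` (uses the current RNG stream)
rand_block_fixture <- function(fams = c("a", "b", "c", "d"), max_copy = 2,
                               p_split = 0.4, allow_empty = TRUE) {
  cv <- sample(0:max_copy, length(fams), replace = TRUE,
               prob = c(0.35, rep(0.65 / max_copy, max_copy)))
  genes <- rep(fams, cv)
  if (length(genes) == 0) {
    if (allow_empty) return(gene_block(list())) else genes <- fams[1]
  }
  if (length(genes) >= 2 && runif(1) < p_split) {
    cut <- sample(length(genes) - 1, 1)
    genes <- sample(genes)
    gene_block(list(sort(genes[1:cut]), sort(genes[(cut + 1):length(genes)])))
  } else gene_block(list(genes))
}

# genome with one contig and the given called features laid out left to
# right; gaps[i] is the intergenic distance before feature i+1
make_test_genome <- function(labels, gaps, strand = "+", len = 300,
                             genome_id = "gt", statuses = NULL) {
  n <- length(labels)
  stopifnot(length(gaps) == n - 1)
  if (length(strand) == 1) strand <- rep(strand, n)
  if (is.null(statuses)) statuses <- rep("full", n)
  start <- integer(n); end <- integer(n)
  pos <- 100L
  for (i in seq_len(n)) {
    start[i] <- pos; end[i] <- pos + len
    pos <- end[i] + if (i < n) gaps[i] else 0L
  }
  contig <- paste(rep("A", max(end) + 100L), collapse = "")
  feats <- data.frame(feature_id = sprintf("%s_f%02d", genome_id, seq_len(n)),
                      contig_id = "c1", start = start, end = end,
                      strand = strand, stringsAsFactors = FALSE)
  g <- genome(genome_id, c(c1 = contig), feats)
  calls <- data.frame(subject_feature_id = feats$feature_id, labels = labels,
                      status = statuses, evalue = 1e-50, identity = 0.9,
                      stringsAsFactors = FALSE)
  list(genome = g, calls = calls)
}

# sum of root-to-leaf path lengths by an explicit edge walk (tree oracle)
leaf_depth_oracle <- function(tree) {
  nt <- length(tree$tip.label)
  depth <- function(node) {
    d <- 0
    repeat {
      row <- which(tree$edge[, 2] == node)
      if (length(row) == 0) return(d)
      d <- d + tree$edge.length[row]
      node <- tree$edge[row, 1]
    }
  }
  sum(vapply(seq_len(nt), depth, 0))
}

# leaf bipartitions of every internal (non-root) edge of an unrooted tree,
# canonicalized; written independently of ape::prop.clades
bipartitions_fixture <- function(tree) {
  nt <- length(tree$tip.label)
  unrooted <- ape::unroot(tree)
  labs <- sort(unrooted$tip.label)
  out <- character(0)
  for (r in seq_len(nrow(unrooted$edge))) {
    child <- unrooted$edge[r, 2]
    if (child <= nt) next
    tips <- ape::extract.clade(unrooted, child)$tip.label
    side <- sort(tips)
    other <- sort(setdiff(labs, side))
    key <- if (paste(side, collapse = ",") < paste(other, collapse = ","))
      paste(side, collapse = ",") else paste(other, collapse = ",")
    out <- c(out, key)
  }
  out
}
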