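#' Concatenate conserved operon gene sequences per genome
#'
#' Builds the concatenated-operon sequence used for the operon tree from the
#' uniformly conserved families cyp112, cyp114, fd, sdr, cyp117, cps and ks
#' (labels `b,c,d,e,f,h,i`), in that fixed order. Genomes missing any of the
#' required families are excluded and reported rather than failing. A fusion
#' sequence can be supplied pre-split via `fusion_split()`.
#'
#' @param seqs named list (per genome) of named lists/vectors of sequences
#'   keyed by family label.
#' @param families family labels to concatenate, in order.
#' @return list with `sequences` (named character vector) and `excluded`
#'   (data frame of genome, missing families).
#' @export
concat_operon <- function(seqs, families = c("b", "c", "d", "e", "f",
                                             "h", "i")) {
  out <- character(0)
  excl <- list()
  for (gid in names(seqs)) {
    have <- seqs[[gid]]
    missing <- setdiff(families, names(have))
    if (length(missing)) {
      excl[[length(excl) + 1L]] <- data.frame(
        genome = gid, missing = paste(missing, collapse = ","),
        stringsAsFactors = FALSE)
      next
    }
    out[gid] <- paste(vapply(families, function(f)
      paste(have[[f]], collapse = ""), ""), collapse = "")
  }
  list(sequences = out,
       excluded = if (length(excl)) do.call(rbind, excl) else
         data.frame(genome = character(0), missing = character(0)))
}

#' Split a fusion gene sequence into its constituent family slots
#'
#' Uses the fusion-family hit span on the subject to cut the fused sequence:
#' the span aligned by the fusion-family query becomes that family's
#' sequence, the remainder stays with the partner family.
#'
#' @param fused_seq the fusion feature's sequence (character scalar).
#' @param subject_start,subject_end 1-based span of the fusion-family query's
#'   alignment on the subject.
#' @param fusion_family,partner family labels (e.g. `"d"` and `"e"`).
#' @return named list of two sequences.
#' @export
fusion_split <- function(fused_seq, subject_start, subject_end,
                         fusion_family = "d", partner = "e") {
  n <- nchar(fused_seq)
  stopifnot(subject_start >= 1, subject_end <= n, subject_start <= subject_end)
  part_d <- substr(fused_seq, subject_start, subject_end)
  rest <- paste0(substr(fused_seq, 1, subject_start - 1),
                 substr(fused_seq, subject_end + 1, n))
  stats::setNames(list(part_d, rest), c(fusion_family, partner))
}

#' Uncorrected p-distance with pairwise gap deletion
#'
#' `d(i, j)` is the fraction of mismatching residues over columns where
#' neither row has a gap (`-`, `.`) or missing character.
#'
#' @param aln character matrix (rows = sequences) or named character vector.
#' @return symmetric distance matrix with zero diagonal.
#' @export
p_distance <- function(aln) {
  if (!is.matrix(aln)) aln <- as_alignment_matrix(aln)
  n <- nrow(aln)
  if (is.null(rownames(aln))) rownames(aln) <- paste0("s", seq_len(n))
  gap <- aln == "-" | aln == "." | is.na(aln)
  d <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  if (n < 2) return(d)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ok <- !gap[i, ] & !gap[j, ]
    if (!any(ok))
      stop("p_distance: no comparable columns for ", rownames(aln)[i],
           " vs ", rownames(aln)[j])
    d[i, j] <- d[j, i] <- mean(aln[i, ok] != aln[j, ok])
  }
  d
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei agglomeration via `ape::nj()`, with taxa pre-sorted by
#' identifier for a deterministic result and negative branch lengths clamped
#' to zero.
#'
#' @param D symmetric distance matrix (>= 3 taxa) with row/column names.
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(D) {
  if (nrow(D) < 3) stop("nj_tree: need at least 3 taxa")
  ord <- order(rownames(D))
  D <- D[ord, ord]
  tree <- ape::nj(stats::as.dist(D))
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Root a tree on an outgroup's pendant edge
#'
#' The root is placed at the midpoint of the outgroup's terminal branch.
#'
#' @param tree a `phylo` tree.
#' @param outgroup a leaf label.
#' @return a rooted `phylo`.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  if (!(outgroup %in% tree$tip.label))
    stop("root_with_outgroup: leaf not found: ", outgroup)
  tip <- which(tree$tip.label == outgroup)
  pend <- tree$edge.length[tree$edge[, 2] == tip]
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  root <- length(rooted$tip.label) + 1L
  root_edges <- which(rooted$edge[, 1] == root)
  tip2 <- which(rooted$tip.label == outgroup)
  out_edge <- root_edges[rooted$edge[root_edges, 2] == tip2]
  if (length(out_edge) == 1L && length(root_edges) == 2L) {
    other <- setdiff(root_edges, out_edge)
    shift <- rooted$edge.length[out_edge] - pend / 2
    rooted$edge.length[out_edge] <- pend / 2
    rooted$edge.length[other] <- rooted$edge.length[other] + shift
  }
  rooted
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Alignment columns are resampled with replacement; a NJ tree is built per
#' replicate and the share of replicates containing each internal bipartition
#' of the reference tree (built from the full alignment) is recorded as a
#' percentage in `node.label`.
#'
#' @param aln character matrix or named character vector (see [p_distance()]).
#' @param n_replicates number of bootstrap replicates (>= 1).
#' @param seed integer seed.
#' @param return_replicates attach the replicate trees as attribute
#'   `replicates` (for support recounts).
#' @return the reference NJ tree with `node.label` support values in
#'   `[0, 100]` (the root label is `NA`).
#' @export
bootstrap_support <- function(aln, n_replicates = 100, seed = 1L,
                              return_replicates = FALSE) {
  if (n_replicates < 1) stop("bootstrap_support: n_replicates must be >= 1")
  if (!is.matrix(aln)) aln <- as_alignment_matrix(aln)
  set.seed(as.integer(seed))
  ref <- nj_tree(p_distance(aln))
  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cols <- sample.int(ncol(aln), ncol(aln), replace = TRUE)
    reps[[r]] <- nj_tree(p_distance(aln[, cols, drop = FALSE]))
  }
  counts <- ape::prop.clades(ref, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  ref$node.label <- round(100 * counts / n_replicates, 1)
  ref$node.label[1] <- NA  # root of an unrooted tree carries no bipartition
  if (return_replicates) attr(ref, "replicates") <- reps
  ref
}

# total branch length spanned by a leaf subset (its Steiner subtree)
subset_pd <- function(tree, leaves) {
  if (length(leaves) < 2) return(0)
  sub <- ape::keep.tip(tree, leaves)
  sum(sub$edge.length)
}

#' Reduce a taxon set by greedy phylogenetic-diversity maximization
#'
#' Starts from the pair of leaves with the greatest path length (after any
#' mandatory keeps) and repeatedly adds the leaf contributing the most new
#' branch length; for phylogenetic diversity on trees this greedy strategy is
#' optimal. Ties break alphabetically.
#'
#' @param tree a `phylo` tree with branch lengths.
#' @param k number of leaves to keep (2 <= k <= number of leaves).
#' @param keep labels that must be retained (e.g. reference and outgroup).
#' @return character vector of `k` leaf labels, sorted.
#' @export
pd_reduce <- function(tree, k, keep = character(0)) {
  labs <- tree$tip.label
  if (k < 2 || k > length(labs)) stop("pd_reduce: k out of range")
  if (!all(keep %in% labs)) stop("pd_reduce: unknown keep labels")
  if (length(keep) > k) stop("pd_reduce: more mandatory keeps than k")
  chosen <- sort(keep)
  dmat <- ape::cophenetic.phylo(tree)
  if (length(chosen) < 2) {
    if (length(chosen) == 1) {
      far <- labs[order(-dmat[chosen, labs], labs)][1]
      chosen <- c(chosen, far)
    } else {
      idx <- which(dmat == max(dmat), arr.ind = TRUE)
      pairs <- apply(idx, 1, function(r)
        paste(sort(c(rownames(dmat)[r[1]], colnames(dmat)[r[2]])),
              collapse = "\r"))
      chosen <- strsplit(sort(pairs)[1], "\r", fixed = TRUE)[[1]]
    }
  }
  while (length(chosen) < k) {
    rest <- sort(setdiff(labs, chosen))
    gain <- vapply(rest, function(l)
      subset_pd(tree, c(chosen, l)), 0)
    chosen <- c(chosen, rest[which.max(gain)])
  }
  sort(chosen)
}
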