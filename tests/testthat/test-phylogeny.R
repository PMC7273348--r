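test_that("p-distance counts mismatches over gap-free columns", {
  m <- as_alignment_matrix(c(s1 = "MKL", s2 = "MKL"))
  expect_equal(p_distance(m)["s1", "s2"], 0)
  m2 <- as_alignment_matrix(c(s1 = "MKL", s2 = "MTL"))
  expect_equal(p_distance(m2)["s1", "s2"], 1 / 3)
  m3 <- as_alignment_matrix(c(s1 = "M-LK", s2 = "MTLR"))
  expect_equal(p_distance(m3)["s1", "s2"], 1 / 3)  # gap column skipped
  expect_error(p_distance(as_alignment_matrix(c(a = "--", b = "AA"))),
               "comparable")

  set.seed(31)
  aln <- matrix(sample(c("A", "C", "D", "E", "-"), 500, replace = TRUE),
                10, 50, dimnames = list(paste0("s", 1:10), NULL))
  d <- p_distance(aln)
  for (i in 1:9) for (j in (i + 1):10) {
    mm <- 0; ok <- 0
    for (col in 1:50) {
      x <- aln[i, col]; y <- aln[j, col]
      if (x != "-" && y != "-") { ok <- ok + 1; mm <- mm + (x != y) }
    }
    expect_equal(as.numeric(d[i, j]), as.numeric(mm / ok))
  }
})

test_that("three-taxon NJ branch lengths match the closed form", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t <- nj_tree(D)
  pend <- function(lab) t$edge.length[t$edge[, 2] == match(lab, t$tip.label)]
  expect_equal(pend("A"), (3 + 4 - 5) / 2)
  expect_equal(pend("B"), (3 + 5 - 4) / 2)
  expect_equal(pend("C"), (4 + 5 - 3) / 2)
  expect_error(nj_tree(D[1:2, 1:2]), "3 taxa")
})

test_that("NJ recovers an additive four-taxon matrix exactly", {
  labs <- c("A", "B", "C", "D")
  D <- matrix(4, 4, 4, dimnames = list(labs, labs))
  diag(D) <- 0
  D["A", "B"] <- D["B", "A"] <- 2
  D["C", "D"] <- D["D", "C"] <- 2
  t <- nj_tree(D)
  paths <- ape::cophenetic.phylo(t)[labs, labs]
  expect_equal(paths, D)
  internal <- t$edge.length[t$edge[, 2] > 4]
  expect_equal(internal, 2)
})

test_that("taxon input order only relabels the NJ tree", {
  set.seed(33)
  tr <- ape::rtree(8)
  D <- ape::cophenetic.phylo(tr)
  perm <- sample(8)
  t1 <- nj_tree(D)
  t2 <- nj_tree(D[perm, perm])
  expect_true(ape::all.equal.phylo(ape::unroot(t1), ape::unroot(t2),
                                   use.edge.length = FALSE))
})

test_that("outgroup rooting splits the pendant edge and is reversible", {
  set.seed(34)
  tr <- ape::rtree(7)
  rooted <- root_with_outgroup(tr, "t3")
  expect_true(ape::is.rooted(rooted))
  root <- length(rooted$tip.label) + 1L
  kids <- rooted$edge[rooted$edge[, 1] == root, 2]
  expect_true(match("t3", rooted$tip.label) %in% kids)
  pend_orig <- tr$edge.length[tr$edge[, 2] == match("t3", tr$tip.label)]
  pend_new <- rooted$edge.length[rooted$edge[, 1] == root &
                                   rooted$edge[, 2] ==
                                   match("t3", rooted$tip.label)]
  expect_equal(pend_new, pend_orig / 2)
  expect_true(ape::all.equal.phylo(ape::unroot(rooted), ape::unroot(tr),
                                   use.edge.length = FALSE))
  expect_error(root_with_outgroup(tr, "nope"), "not found")
})

test_that("bootstrap support is seeded and matches a bipartition recount", {
  set.seed(35)
  grp1 <- replicate(4, paste(sample(c("A", "C"), 60, TRUE), collapse = ""))
  grp2 <- replicate(4, paste(sample(c("G", "T"), 60, TRUE), collapse = ""))
  aln <- stats::setNames(c(grp1, grp2), paste0("s", 1:8))
  t1 <- bootstrap_support(aln, n_replicates = 50, seed = 42)
  t2 <- bootstrap_support(aln, n_replicates = 50, seed = 42)
  expect_identical(t1$node.label, t2$node.label)
  # the split separating the two sequence groups is unambiguous
  expect_true(any(stats::na.omit(t1$node.label) == 100))

  t3 <- bootstrap_support(aln, n_replicates = 40, seed = 7,
                          return_replicates = TRUE)
  reps <- attr(t3, "replicates")
  rep_parts <- lapply(reps, bipartitions_fixture)
  nt <- length(t3$tip.label)
  unrooted <- ape::unroot(t3)
  for (r in seq_len(nrow(unrooted$edge))) {
    child <- unrooted$edge[r, 2]
    if (child <= nt) next
    side <- sort(ape::extract.clade(unrooted, child)$tip.label)
    other <- sort(setdiff(t3$tip.label, side))
    key <- if (paste(side, collapse = ",") < paste(other, collapse = ","))
      paste(side, collapse = ",") else paste(other, collapse = ",")
    manual <- 100 * mean(vapply(rep_parts, function(p) key %in% p, TRUE))
    stored <- unrooted$node.label[child - nt]
    if (!is.na(stored)) expect_equal(stored, round(manual, 1))
  }
})

test_that("greedy phylogenetic-diversity reduction is optimal", {
  set.seed(36)
  tr <- ape::rtree(12)
  # k = n keeps everything, PD = total branch length
  all_k <- pd_reduce(tr, 12)
  expect_setequal(all_k, tr$tip.label)

  # k = 2 picks the farthest pair (all-pairs oracle)
  pair <- pd_reduce(tr, 2)
  D <- ape::cophenetic.phylo(tr)
  expect_equal(D[pair[1], pair[2]], max(D))

  # greedy equals the exhaustive-subset maximum on small trees
  pd_of <- function(tree, leaves)
    sum(ape::keep.tip(tree, leaves)$edge.length)
  for (i in 1:5) {
    tri <- ape::rtree(8)
    for (k in 3:5) {
      greedy <- pd_reduce(tri, k)
      combos <- utils::combn(tri$tip.label, k)
      best <- max(apply(combos, 2, function(s) pd_of(tri, s)))
      expect_equal(pd_of(tri, greedy), best)
    }
  }

  # mandatory keeps survive
  sel <- pd_reduce(tr, 5, keep = c("t1", "t2"))
  expect_true(all(c("t1", "t2") %in% sel))
  expect_error(pd_reduce(tr, 1), "range")
  expect_error(pd_reduce(tr, 13), "range")
})

test_that("operon concatenation uses the seven conserved families in order", {
  seqs <- list(
    gA = list(b = "BB", c = "CC", d = "DD", e = "EE", f = "FF", h = "HH",
              i = "II", j = "JJ"),
    gB = list(b = "BB", c = "CC", d = "DD", e = "EE", f = "FF", i = "II"))
  co <- concat_operon(seqs)
  expect_equal(unname(co$sequences["gA"]), "BBCCDDEEFFHHII")
  expect_equal(co$excluded$genome, "gB")
  expect_equal(co$excluded$missing, "h")

  # a fusion sequence split at the hit boundary fills both slots
  fs <- fusion_split("DDDEEEEE", 1, 3, "d", "e")
  expect_equal(fs$d, "DDD")
  expect_equal(fs$e, "EEEEE")
})
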