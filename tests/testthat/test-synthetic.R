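test_that("tree sampling is seeded, binary, and additive", {
  t2 <- sample_tree(2, 1.0, 7)
  expect_equal(length(t2$tip.label), 2)
  expect_gt(sum(t2$edge.length), 0)
  expect_error(sample_tree(1, 1.0, 7), "n_leaves")

  a <- ape::write.tree(sample_tree(8, 1.0, 7))
  b <- ape::write.tree(sample_tree(8, 1.0, 7))
  expect_identical(a, b)

  tr <- sample_tree(8, 1.0, 7)
  depths <- ape::node.depth.edgelength(tr)[seq_len(8)]
  expect_equal(sum(depths), leaf_depth_oracle(tr))
})

test_that("a null process copies the root block to every leaf", {
  tr <- sample_tree(8, 1.0, 3)
  cfg <- sim_config(n_leaves = 8, rate_deletion = 0, rate_duplication = 0,
                    rate_split = 0, rate_gain = 0, rate_hgt = 0,
                    rate_pseudogenize = 0, sequences = FALSE, seed = 3)
  sim <- evolve_blocks(tr, cfg)
  expect_true(all(vapply(sim$leaf_blocks, render_block, "") == "abcdefghij"))
  expect_equal(nrow(sim$log), 0)
})

test_that("a deletion-only process loses families and logs only deletions", {
  tr <- sample_tree(8, 1.0, 3)
  cfg <- sim_config(n_leaves = 8, rate_deletion = 1.2, rate_duplication = 0,
                    rate_split = 0, rate_gain = 0, rate_hgt = 0,
                    rate_pseudogenize = 0, sequences = FALSE, seed = 5)
  sim <- evolve_blocks(tr, cfg)
  expect_true(all(sim$log$type == "deletion"))
  root_fams <- unique(unlist(cfg$root_block$segments))
  lost <- vapply(sim$leaf_blocks, function(b)
    length(setdiff(root_fams, unlist(b$segments))) > 0, TRUE)
  expect_true(any(lost))
})

test_that("replaying the event log reproduces every leaf block", {
  set.seed(31)
  for (i in 1:100) {
    seed <- sample.int(10000, 1)
    tr <- sample_tree(sample(4:10, 1), 1.0, seed)
    cfg <- sim_config(n_leaves = length(tr$tip.label),
                      rate_deletion = runif(1, 0, 0.4),
                      rate_duplication = runif(1, 0, 0.1),
                      rate_split = runif(1, 0, 0.15),
                      rate_gain = runif(1, 0, 0.1),
                      rate_hgt = runif(1, 0, 0.3),
                      rate_pseudogenize = runif(1, 0, 0.1),
                      sequences = FALSE, seed = seed)
    sim <- evolve_blocks(tr, cfg)
    replayed <- replay_event_log(tr, cfg$root_block, sim$log)
    expect_identical(vapply(replayed, render_block, ""),
                     vapply(sim$leaf_blocks, render_block, ""))
  }
})

test_that("deletion counts recover the configured rate", {
  tr <- sample_tree(8, 1.0, 5)
  tr$edge.length <- tr$edge.length / sum(tr$edge.length)  # total length 1
  counts <- vapply(1:500, function(s) {
    cfg <- sim_config(n_leaves = 8, rate_deletion = 0.3, rate_duplication = 0,
                      rate_split = 0, rate_gain = 0, rate_hgt = 0,
                      rate_pseudogenize = 0, sequences = FALSE, seed = s)
    nrow(evolve_blocks(tr, cfg)$log)
  }, 0L)
  expected <- 0.3 * 1 * 10  # rate x total length x root families
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("emitted genomes honor templates, truncation, gaps and GC", {
  tr <- sample_tree(6, 1.0, 9)
  cfg <- sim_config(n_leaves = 6, rate_deletion = 0, rate_duplication = 0,
                    rate_split = 0, rate_gain = 0, rate_hgt = 0,
                    rate_pseudogenize = 0, operon_sub_rate = 0,
                    marker_sub_rate = 0, gc_background = 0.5, gc_operon = 0.5,
                    seed = 9)
  sim <- evolve_blocks(tr, cfg)
  em <- emit_genomes(sim, cfg, flank = 1000)
  g <- em$genomes[[1]]
  f1 <- g$features[g$features$family_truth == "b", ][1, ]
  expect_identical(feature_seq(g, f1$feature_id),
                   paste(sim$templates[["b"]], collapse = ""))

  # gap geometry: neighbors <= 500 apart within the contiguous root block
  ord <- g$features[order(g$features$start), ]
  gaps <- ord$start[-1] - ord$end[-nrow(ord)]
  expect_true(all(gaps >= 50 & gaps <= 400))

  # pseudogenized gene truncated below the 60% rule
  cfg2 <- sim_config(n_leaves = 6, rate_deletion = 0, rate_duplication = 0,
                     rate_split = 0, rate_gain = 0, rate_hgt = 0,
                     rate_pseudogenize = 0.6, sequences = TRUE, seed = 12)
  sim2 <- evolve_blocks(tr, cfg2)
  em2 <- emit_genomes(sim2, cfg2, flank = 500)
  found <- FALSE
  for (gid in names(em2$genomes)) {
    feats <- em2$genomes[[gid]]$features
    ps <- feats[feats$status_truth == "pseudo", ]
    for (r in seq_len(nrow(ps))) {
      found <- TRUE
      tpl_len <- length(sim2$templates[[ps$family_truth[r]]])
      expect_lt(ps$end[r] - ps$start[r], 0.60 * tpl_len)
    }
  }
  expect_true(found)

  # GC control on >= 10 kb segments
  cfg3 <- sim_config(n_leaves = 6, rate_deletion = 0, rate_duplication = 0,
                     rate_split = 0, rate_gain = 0, rate_hgt = 0,
                     rate_pseudogenize = 0, gc_background = 0.60,
                     gc_operon = 0.68, seed = 21)
  sim3 <- evolve_blocks(tr, cfg3)
  em3 <- emit_genomes(sim3, cfg3, flank = 10000)
  g3 <- em3$genomes[[1]]
  chars <- strsplit(g3$contigs[[1]], "")[[1]]
  gc_of <- function(x) mean(x %in% c("G", "C"))
  span <- em3$operon_span[[1]]
  expect_lt(abs(gc_of(chars[1:10000]) - 0.60), 0.02)
  expect_lt(abs(gc_of(chars[(span[1] + 1):span[2]]) - 0.68), 0.02)
})

test_that("the simulation is byte-deterministic under its seed", {
  tr <- sample_tree(6, 1.0, 13)
  cfg <- sim_config(n_leaves = 6, rate_hgt = 0.2, seed = 13)
  s1 <- evolve_blocks(tr, cfg)
  s2 <- evolve_blocks(tr, cfg)
  expect_identical(vapply(s1$leaf_blocks, render_block, ""),
                   vapply(s2$leaf_blocks, render_block, ""))
  expect_identical(s1$log, s2$log)
  expect_identical(s1$leaf_seqs, s2$leaf_seqs)
  e1 <- emit_genomes(s1, cfg, flank = 500)
  e2 <- emit_genomes(s2, cfg, flank = 500)
  expect_identical(e1$genomes[[3]]$contigs, e2$genomes[[3]]$contigs)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(rate_deletion = -1), "rates")
  expect_error(sim_config(gc_operon = 1.2), "GC")
  expect_error(sim_config(intra_block_gap = c(50, 600)), "intra_block_gap")
  expect_error(sim_config(split_gap = c(400, 2000)), "split_gap")
  expect_error(sim_config(root_block = ""), "empty")
})
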