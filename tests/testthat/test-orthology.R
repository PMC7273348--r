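mk_hit <- function(query, subject, evalue, identity = 0.9, qs = 1, qe = 100,
                   ss = 1, se = 100) {
  data.frame(query_label = query, subject_feature_id = subject,
             identity = identity, aligned_length = qe - qs + 1,
             query_start = qs, query_end = qe, subject_start = ss,
             subject_end = se, evalue = evalue, bitscore = 100,
             stringsAsFactors = FALSE)
}

test_that("the E-value cutoff is inclusive at 1e-10", {
  fam <- reference_families()
  keep <- call_orthologs(mk_hit("g", "f1", 1e-10), fam)
  expect_equal(nrow(keep), 1)
  drop <- call_orthologs(mk_hit("g", "f1", 1e-9), fam)
  expect_equal(nrow(drop), 0)
  expect_equal(nrow(call_orthologs(mk_hit("g", "f1", 1e-300)[0, ], fam)), 0)
})

test_that("each feature gets its single best family deterministically", {
  fam <- reference_families()
  hits <- rbind(mk_hit("k", "f1", 1e-12), mk_hit("g", "f1", 1e-30))
  cl <- call_orthologs(hits, fam)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$labels, "g")
  # ties on E-value break by identity, then label order
  hits2 <- rbind(mk_hit("k", "f1", 1e-20, identity = 0.8),
                 mk_hit("g", "f1", 1e-20, identity = 0.9))
  expect_equal(call_orthologs(hits2, fam)$labels, "g")
  hits3 <- rbind(mk_hit("k", "f1", 1e-20), mk_hit("g", "f1", 1e-20))
  expect_equal(call_orthologs(hits3, fam)$labels, "g")
  # input order never matters
  set.seed(4)
  big <- do.call(rbind, lapply(1:20, function(i)
    mk_hit(sample(fam$label, 1), paste0("f", sample(5, 1)),
           10^-sample(11:40, 1), identity = runif(1, 0.6, 1))))
  ref <- call_orthologs(big, fam)
  for (i in 1:5)
    expect_identical(call_orthologs(big[sample(nrow(big)), ], fam), ref)
})

test_that("relaxing the cutoff never removes a call", {
  fam <- reference_families()
  set.seed(5)
  hits <- do.call(rbind, lapply(1:30, function(i)
    mk_hit(sample(fam$label, 1), paste0("f", sample(8, 1)),
           10^-sample(2:40, 1))))
  strict <- call_orthologs(hits, fam, evalue_max = 1e-10)
  loose <- call_orthologs(hits, fam, evalue_max = 1e-5)
  expect_true(all(strict$subject_feature_id %in% loose$subject_feature_id))
})

test_that("the pseudogene rule uses strict <60% length and >50% identity", {
  fam <- reference_families()
  qlen <- fam$query_length[fam$label == "a"]
  base <- call_orthologs(mk_hit("a", "f1", 1e-20, identity = 0.60), fam)
  expect_equal(classify_pseudo(base, c(f1 = 0.55 * qlen), fam)$status, "pseudo")
  expect_equal(classify_pseudo(base, c(f1 = 0.90 * qlen), fam)$status, "full")
  expect_equal(classify_pseudo(base, c(f1 = 0.60 * qlen), fam)$status, "full")
  low_id <- call_orthologs(mk_hit("a", "f1", 1e-20, identity = 0.50), fam)
  expect_equal(classify_pseudo(low_id, c(f1 = 0.55 * qlen), fam)$status,
               "full")
  # only configured families are screened
  other <- call_orthologs(mk_hit("b", "f2", 1e-20, identity = 0.9), fam)
  expect_equal(classify_pseudo(other, c(f2 = 10), fam)$status, "full")
  expect_equal(classify_pseudo(other, c(f2 = 10), fam,
                               pseudo_families = "b")$status, "pseudo")
  bad <- fam; bad$query_length[1] <- 0
  expect_error(classify_pseudo(base, c(f1 = 10), bad), "invalid")
})

test_that("ferredoxin fusions are detected from hit span coverage", {
  fam <- reference_families()
  dlen <- fam$query_length[fam$label == "d"]
  calls <- call_orthologs(rbind(mk_hit("c", "f1", 1e-40),
                                mk_hit("e", "f2", 1e-40)), fam)
  # d-query covers 80% of its length inside the e-called feature
  dhit <- mk_hit("d", "f2", 1e-15, qs = 1, qe = ceiling(0.8 * dlen))
  fused <- detect_fusions(calls, rbind(dhit), fam)
  expect_equal(fused$labels[fused$subject_feature_id == "f2"], "d,e")
  expect_equal(fused$status[fused$subject_feature_id == "f2"], "fusion")
  # same evidence against the c-called feature gives a cyp114-fd fusion
  dhit_c <- mk_hit("d", "f1", 1e-15, qs = 1, qe = ceiling(0.8 * dlen))
  fused_c <- detect_fusions(calls, rbind(dhit_c), fam)
  expect_equal(fused_c$labels[fused_c$subject_feature_id == "f1"], "c,d")

  # a standalone d call suppresses fusion detection
  with_d <- call_orthologs(rbind(mk_hit("c", "f1", 1e-40),
                                 mk_hit("e", "f2", 1e-40),
                                 mk_hit("d", "f3", 1e-40)), fam)
  expect_true(all(detect_fusions(with_d, rbind(dhit), fam)$status == "full"))

  # 30% coverage is below the majority threshold
  weak <- mk_hit("d", "f2", 1e-15, qs = 1, qe = ceiling(0.3 * dlen))
  expect_true(all(detect_fusions(calls, rbind(weak), fam)$status == "full"))
})

test_that("hit tables round-trip through the outfmt-6 representation", {
  hits <- rbind(mk_hit("a", "f1", 1e-20, identity = 0.875),
                mk_hit("g", "f2", 1e-30))
  path <- tempfile(fileext = ".tsv")
  write_hits(hits, path)
  back <- read_hits(path)
  expect_equal(back$query_label, hits$query_label)
  expect_equal(back$identity, hits$identity, tolerance = 1e-4)
  expect_equal(back$evalue, hits$evalue, tolerance = 1e-6)
})

test_that("classification on simulated genomes recovers the ground truth", {
  tr <- sample_tree(6, 1.0, 23)
  cfg <- sim_config(n_leaves = 6, rate_deletion = 0.1, rate_duplication = 0.02,
                    rate_split = 0.04, rate_gain = 0.03, rate_hgt = 0,
                    rate_pseudogenize = 0.08, operon_sub_rate = 0.03,
                    seed = 23)
  sim <- evolve_blocks(tr, cfg)
  em <- emit_genomes(sim, cfg, flank = 1000)
  fam <- reference_families(vapply(sim$templates[names(sim$templates) !=
                                                   "marker"], length, 0))
  queries <- lapply(sim$templates[names(sim$templates) != "marker"],
                    paste, collapse = "")
  labels <- c(letters[1:10], "k")
  for (gid in names(em$genomes)[1:3]) {
    g <- em$genomes[[gid]]
    if (nrow(g$features) == 0) next
    hits <- align_hits(g, queries)
    cl <- call_orthologs(hits, fam)
    slen <- stats::setNames(g$features$end - g$features$start,
                            g$features$feature_id)
    cl <- classify_pseudo(cl, slen, fam, pseudo_families = labels)
    truth <- g$features
    expect_equal(nrow(cl), nrow(truth))
    m <- match(truth$feature_id, cl$subject_feature_id)
    expect_equal(cl$labels[m], truth$family_truth)
    expect_equal(cl$status[m], truth$status_truth)
  }
})
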