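quartet <- ape::read.tree(text = "((L1:1,L2:1):1,(L3:1,L4:1):1);")

test_that("identical leaf blocks reconstruct with zero events", {
  rec <- reconstruct_blocks(quartet, list(L1 = "abc", L2 = "abc",
                                          L3 = "abc", L4 = "abc"))
  expect_equal(rec$total_events, 0)
  expect_true(all(vapply(rec$node_blocks, render_block, "") == "abc"))
  expect_true(all(rec$node_cumulative == 0))
})

test_that("a single presence change is placed once, root keeps the family", {
  rec <- reconstruct_blocks(quartet, list(L1 = "abc", L2 = "abc",
                                          L3 = "bc", L4 = "bc"))
  expect_equal(rec$total_events, 1)
  root_block <- render_block(rec$node_blocks[["n5"]])
  expect_equal(root_block, "abc")  # tie resolved toward presence
  expect_equal(oracle_reconstruct(quartet, list(L1 = "abc", L2 = "abc",
                                                L3 = "bc", L4 = "bc")), 1)
  expect_error(reconstruct_blocks(ape::unroot(ape::rtree(5)),
                                  stats::setNames(as.list(rep("ab", 5)),
                                                  paste0("t", 1:5))),
               "rooted")
})

test_that("cumulative counts never decrease from leaves to root", {
  set.seed(41)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n, tip.label = paste0("L", 1:n))
    lbs <- stats::setNames(lapply(1:n, function(i)
      rand_block_fixture(allow_empty = FALSE)), tr$tip.label)
    rec <- reconstruct_blocks(tr, lbs)
    for (r in seq_len(nrow(tr$edge))) {
      par <- tr$edge[r, 1]; ch <- tr$edge[r, 2]
      expect_true(all(rec$node_cumulative[par, ] >= rec$node_cumulative[ch, ]))
    }
    root <- n + 1
    expect_equal(rec$total_events, sum(rec$node_cumulative[root, ]))
    expect_equal(sum(rec$edge_events), rec$total_events)
  }
})

test_that("the true simulated history bounds the parsimony total", {
  set.seed(42)
  for (i in 1:20) {
    seed <- sample.int(10000, 1)
    tr <- sample_tree(8, 1.0, seed)
    cfg <- sim_config(n_leaves = 8, rate_deletion = 0.05,
                      rate_duplication = 0.01, rate_split = 0.02,
                      rate_gain = 0.01, rate_hgt = 0, rate_pseudogenize = 0,
                      sequences = FALSE, seed = seed)
    sim <- evolve_blocks(tr, cfg)
    rec <- reconstruct_blocks(tr, sim$leaf_blocks)
    expect_lte(rec$total_events, nrow(sim$log))
    # the explicit true assignment is a feasible solution
    truth_total <- sum(vapply(seq_len(nrow(tr$edge)), function(r) {
      labs <- c(tr$tip.label, paste0("n", 9:15))
      get_block <- function(v) if (v <= 8) sim$leaf_blocks[[labs[v]]] else
        sim$node_blocks[[labs[v]]]
      event_distance(get_block(tr$edge[r, 1]),
                     get_block(tr$edge[r, 2]))[["total"]]
    }, 0))
    expect_lte(rec$total_events, truth_total)
  }
})

test_that("fast profile distance agrees with the block distance", {
  set.seed(43)
  fams <- c("a", "b", "c", "d", "e")
  for (i in 1:300) {
    A <- rand_block_fixture(fams)
    B <- rand_block_fixture(fams)
    expect_identical(
      as.integer(blockevol:::profile_dist(
        blockevol:::block_fast_profile(A, fams),
        blockevol:::block_fast_profile(B, fams))),
      as.integer(event_distance(A, B)[["total"]]))
  }
})

test_that("the oracle's state-space costs agree with the block distance", {
  sp <- blockevol:::oracle_state_space(c("a", "b", "c"))
  set.seed(44)
  idx <- sample(length(sp$states), 40)
  for (i in idx) for (j in sample(length(sp$states), 10)) {
    expect_identical(as.integer(sp$cost[i, j]),
                     as.integer(event_distance(sp$states[[i]],
                                               sp$states[[j]])[["total"]]))
  }
})

test_that("tree comparison tabulates totals in ascending order", {
  lbs <- list(L1 = "abc", L2 = "abc", L3 = "bc", L4 = "bc")
  cmp <- compare_trees(lbs, list(one = quartet, two = quartet))
  expect_equal(cmp$total_events, c(1, 1))
  single <- compare_trees(lbs, list(only = quartet))
  expect_equal(nrow(single), 1)
  other <- ape::read.tree(text = "((L1:1,L3:1):1,(L2:1,L9:1):1);")
  expect_error(compare_trees(lbs, list(a = quartet, b = other)),
               "leaf sets")
  expect_true(all(diff(cmp$total_events) >= 0))
})

test_that("node flags mark cyp115 state and ggps2 presence", {
  rec <- reconstruct_blocks(quartet, list(L1 = "abc", L2 = "abc",
                                          L3 = "abc", L4 = "abc"))
  fl <- annotate_flags(rec)
  expect_equal(fl$flags[fl$node == "n5"], "*")

  rec2 <- reconstruct_blocks(quartet, list(L1 = "a~bc", L2 = "a~bc",
                                           L3 = "a~bc", L4 = "a~bc"))
  fl2 <- annotate_flags(rec2)
  expect_equal(fl2$flags[fl2$node == "L1"], "!")
  expect_equal(fl2$flags[fl2$node == "n5"], "!")

  rec3 <- reconstruct_blocks(quartet, list(L1 = "bck", L2 = "bck",
                                           L3 = "bc", L4 = "bc"))
  fl3 <- annotate_flags(rec3)
  with_k <- vapply(rec3$node_blocks, function(b)
    "k" %in% unlist(b$segments), TRUE)
  expect_equal(grepl("?", fl3$flags, fixed = TRUE), unname(with_k))
})
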