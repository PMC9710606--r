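test_that("rank_references orders by distance or count with seeded ties", {
  st <- fake_stats(c("A", "B"), s = c(5, 9), d = c(0.1, 0.3))
  expect_equal(rank_references(st, "distance"), c("A", "B"))
  expect_equal(rank_references(st, "count"), c("B", "A"))

  tied <- fake_stats(c("A", "B", "C"), s = c(4, 4, 4), d = c(0.1, 0.1, 0.1))
  r1 <- rank_references(tied, "distance", seed = 1)
  r2 <- rank_references(tied, "distance", seed = 1)
  expect_identical(r1, r2)
  winners <- vapply(1:20, function(s) {
    rank_references(tied, "distance", seed = s)[1]
  }, character(1))
  expect_gt(length(unique(winners)), 1L)  # "chosen randomly" across seeds
})

test_that("leaf heuristics land on the pendant edge of the best reference", {
  tr <- study_tree()
  st <- fake_stats(c("A", "B", "C"), s = c(12, 3, 1), d = c(0.30, 0.10, 0.50))
  by_d <- place_min_dist(st, tr, query_id = "q")
  expect_equal(by_d$edge_num, parent_edge(tr, "B")$edge_num)
  by_s <- place_spam_count(st, tr, query_id = "q")
  expect_equal(by_s$edge_num, parent_edge(tr, "A")$edge_num)
  # leaf heuristics always return pendant edges of leaves
  for (pl in list(by_d, by_s)) {
    child <- tree_edges(tr)$child_label[tree_edges(tr)$edge_num == pl$edge_num]
    expect_false(is.na(child))
  }
})

test_that("lca heuristics land on the stem edge above the LCA", {
  tr <- study_tree()
  # A and B form a cherry: their LCA's parent edge
  st <- fake_stats(c("A", "B", "H"), s = c(9, 8, 1), d = c(0.1, 0.12, 0.6))
  pl <- place_lca(st, tr, by = "count", query_id = "q")
  v <- lca(tr, "A", "B")
  expect_equal(pl$edge_num, parent_edge(tr, v)$edge_num)
  child <- tree_edges(tr)$child_label[tree_edges(tr)$edge_num == pl$edge_num]
  expect_true(is.na(child))  # an internal edge

  # S1 and S2 on opposite sides of the root: child edge of root toward S1
  st2 <- fake_stats(c("A", "H"), s = c(9, 8), d = c(0.1, 0.12))
  pl2 <- place_lca(st2, tr, by = "count", query_id = "q")
  rc <- tr$children[[tr$root]][1]  # the side containing A
  expect_equal(pl2$edge_num, tr$edge_num[rc])

  # a single usable reference degrades to the leaf heuristic
  st3 <- fake_stats("C", s = 5, d = 0.2)
  pl3 <- place_lca(st3, tr, by = "distance", query_id = "q")
  expect_true(pl3$degraded)
  expect_equal(pl3$edge_num, parent_edge(tr, "C")$edge_num)
})

test_that("the spam-x rule follows the printed inequality", {
  expect_equal(decide_spam_x(10, 2, 4), "leaf")   # 8 > 3
  expect_equal(decide_spam_x(7, 7, 4), "lca")     # 0 > positive is false
  # X = 1 can never route to the leaf: |s1-s2| <= s1+s2 always
  for (s1 in 0:50) {
    for (s2 in 0:s1) {
      expect_equal(decide_spam_x(s1, s2, 1), "lca")
    }
  }
})

test_that("spam-x composes spam-count and lca-count", {
  tr <- study_tree()
  st_far <- fake_stats(c("A", "B"), s = c(40, 2), d = c(0.05, 0.40))
  via_x <- place_query(st_far, tr, placement_config("spam-x"), "q")
  via_count <- place_query(st_far, tr, placement_config("spam-count"), "q")
  expect_equal(via_x$edge_num, via_count$edge_num)

  st_tie <- fake_stats(c("A", "B"), s = c(7, 7), d = c(0.1, 0.1))
  via_x2 <- place_query(st_tie, tr, placement_config("spam-x"), "q")
  via_lca <- place_query(st_tie, tr, placement_config("lca-count"), "q")
  expect_equal(via_x2$edge_num, via_lca$edge_num)
})

test_that("spam-x with X = 1 is edge-identical to lca-count", {
  tr <- study_tree()
  set.seed(33)
  leaves <- tree_leaves(tr)
  for (i in 1:25) {
    n <- sample(2:5, 1)
    refs <- sample(leaves, n)
    s <- sample(0:50, n, replace = TRUE)
    if (all(s == 0)) s[1] <- 1L
    st <- fake_stats(refs, s = s, d = 0.05 + 0.01 * seq_len(n))
    st <- st[st$s > 0, ]
    a <- place_query(st, tr, placement_config("spam-x", X = 1, seed = i), "q")
    b <- place_query(st, tr, placement_config("lca-count", seed = i), "q")
    expect_equal(a$edge_num, b$edge_num)
  }
})

test_that("queries with no filtered SpaMs fall back to the root", {
  tr <- study_tree()
  pl <- place_query(NULL, tr, placement_config(), "q")
  expect_true(pl$fallback_root)
  rc <- tr$children[[tr$root]][1]
  expect_equal(pl$edge_num, tr$edge_num[rc])
  expect_equal(pl$pendant_length, 0)
  empty <- fake_stats(character(0), integer(0), numeric(0))
  expect_true(place_query(empty, tr, placement_config(), "q")$fallback_root)
})

test_that("branch-length assignment splits at the midpoint and clamps", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  st <- fake_stats("C", s = 10, d = 0.30)
  st$d <- 0.30
  pl <- place_query(st, tr, placement_config("minimum-distance"), "q")
  # C's pendant edge has length 2: distal = 1; attachment -> C path = 1
  expect_equal(pl$distal_length, 1)
  expect_equal(pl$pendant_length, 0)  # 0.30 - 1 clamped at 0

  # exact-substring case: d = 0 means pendant 0
  st0 <- fake_stats("C", s = 10, d = 0)
  pl0 <- place_query(st0, tr, placement_config("minimum-distance"), "q")
  expect_equal(pl0$pendant_length, 0)

  # pendant = d - path length when positive: shrink the tree
  tr_small <- parse_newick("((A:0.05,B:0.05):0.05,C:0.2);")
  st1 <- fake_stats("C", s = 10, d = 0.30)
  pl1 <- place_query(st1, tr_small, placement_config("minimum-distance"), "q")
  expect_equal(pl1$distal_length, 0.1)
  expect_equal(pl1$pendant_length, 0.30 - 0.1, tolerance = 1e-12)
})

test_that("placement lengths always conserve the split edge", {
  tr <- study_tree()
  set.seed(34)
  leaves <- tree_leaves(tr)
  ed <- tree_edges(tr)
  for (i in 1:20) {
    n <- sample(1:4, 1)
    st <- fake_stats(sample(leaves, n), s = sample(1:30, n),
                     d = runif(n, 0, 0.5))
    pl <- place_query(st, tr,
                      placement_config(sample(c("spam-x", "minimum-distance",
                                                "spam-count", "lca-distance",
                                                "lca-count"), 1)), "q")
    len <- ed$length[ed$edge_num == pl$edge_num]
    expect_gte(pl$pendant_length, 0)
    expect_gte(pl$distal_length, 0)
    expect_lte(pl$distal_length, len + 1e-12)
    # the two pieces of the split edge sum to the original length
    tri <- insert_query_edge(tr, edge_by_number(tr, pl$edge_num),
                             0.5, pl$pendant_length, "Q*")
    expect_equal(sum(tri$brlen, na.rm = TRUE),
                 sum(tr$brlen, na.rm = TRUE) + pl$pendant_length,
                 tolerance = 1e-9)
  }
})
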