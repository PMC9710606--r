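test_that("sequence simulation follows the Jukes-Cantor expectation", {
  tr <- parse_newick("(X:0,Y:0.1);")
  seqs <- simulate_sequences(tr, 100000, seed = 17)
  # zero branch: child identical to parent (X equals the root sequence)
  seqs0 <- simulate_sequences(parse_newick("(X:0,Y:0);"), 500, seed = 17)
  expect_equal(seqs0[["X"]], seqs0[["Y"]])
  # observed mismatch fraction close to (3/4)(1 - exp(-4 d / 3))
  x <- strsplit(seqs[["X"]], "")[[1]]
  y <- strsplit(seqs[["Y"]], "")[[1]]
  expect_equal(mean(x != y), jc_expected_mismatch(0.1), tolerance = 0.005 /
                 jc_expected_mismatch(0.1))
  # frozen closed-form value: 0.75 * (1 - exp(-0.4 / 3))
  expect_equal(jc_expected_mismatch(0.1), 0.09362001, tolerance = 1e-7)
  # seeded determinism
  expect_identical(simulate_sequences(tr, 200, seed = 3),
                   simulate_sequences(tr, 200, seed = 3))
})

test_that("fragmentation cuts non-overlapping segments with remainder rule", {
  expect_length(fragment_reads(strrep("A", 450), 150), 3L)
  r <- fragment_reads(strrep("A", 400), 150)
  expect_equal(nchar(r), c(150L, 150L, 100L), ignore_attr = TRUE)
  expect_message(
    short <- fragment_reads(strrep("A", 40), 150, min_len = 44),
    "dropped")
  expect_length(short, 0L)
})

test_that("read bags hit the coverage-determined read count", {
  set.seed(51)
  s <- rand_seq(15000)
  bag <- sample_read_bag(s, 150, coverage = 1, seed = 1)
  expect_length(bag, 100L)
  expect_true(all(nchar(bag) == 150L))
  # hiv-scale genome at the lowest coverages: ceiling(0.0625*9096/150) = 4
  s2 <- rand_seq(9096)
  expect_length(sample_read_bag(s2, 150, coverage = 0.0625, seed = 1), 4L)
  expect_identical(sample_read_bag(s, 150, 0.5, seed = 9),
                   sample_read_bag(s, 150, 0.5, seed = 9))
})

test_that("the PAC harness self-test scores the oracle placer at 0", {
  tr <- study_tree()
  seqs <- simulate_sequences(tr, 2000, seed = 4)
  res <- pac_run(tr, seqs, read_len = 150, seed = 2, placer = "oracle")
  expect_equal(res$grand_mean_nd, 0)
  expect_true(all(res$per_pruning$mean_nd == 0))
})

test_that("pac results expose tidy, glance and autoplot views", {
  tr <- study_tree()
  seqs <- simulate_sequences(tr, 2000, seed = 4)
  res <- pac_run(tr, seqs, read_len = 150, n_prunings = 2, seed = 2)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2L)
  gl <- glance(res)
  expect_equal(gl$n_prunings, 2L)
  expect_equal(gl$grand_mean_nd, res$grand_mean_nd)
  expect_s3_class(autoplot(res), "ggplot")
})

test_that("longer reads do not hurt placement accuracy", {
  tr <- study_tree()
  seqs <- simulate_sequences(tr, 6000, seed = 8)
  nd150 <- pac_run(tr, seqs, read_len = 150, n_prunings = 3,
                   seed = 5)$grand_mean_nd
  nd300 <- pac_run(tr, seqs, read_len = 300, n_prunings = 3,
                   seed = 5)$grand_mean_nd
  expect_lte(nd300, nd150 + 0.1)
})

test_that("control baselines measure root and midpoint placements", {
  tr <- study_tree()
  rc <- tr$children[[tr$root]][1]
  root_edge <- tr$edge_num[rc]
  cb <- control_baselines(tr, root_edge)
  expect_equal(unname(cb["root_nd"]), 0L)

  # 2-leaf symmetric tree: midpoint exactly at the root; tie resolves to
  # the lower edge number
  tr2 <- parse_newick("(A:1,B:1);")
  expect_equal(midpoint_edge(tr2), 0L)

  # brute-force check on random trees: the midpoint edge halves the
  # longest leaf-to-leaf path
  set.seed(52)
  for (i in 1:3) {
    phy <- ape::rtree(sample(5:9, 1))
    tri <- parse_newick(ape::write.tree(phy))
    me <- midpoint_edge(tri)
    leaves <- tree_leaves(tri)
    dmat <- outer(seq_along(leaves), seq_along(leaves), Vectorize(function(a, b) {
      oracle_weighted_dist(tri, leaves[a], leaves[b])
    }))
    dm <- max(dmat)
    # the midpoint edge must touch a point at distance dm/2 from both ends
    pair <- which(dmat == dm, arr.ind = TRUE)[1, ]
    ed <- tree_edges(tri)
    child <- ed$child[ed$edge_num == me]
    parent <- ed$parent[ed$edge_num == me]
    a <- .resolve_label(tri, leaves[pair[1]])
    d_child <- oracle_weighted_dist(tri, child, a)
    d_parent <- oracle_weighted_dist(tri, parent, a)
    expect_lte(min(d_child, d_parent) - 1e-9, dm / 2)
    expect_gte(max(d_child, d_parent) + 1e-9, dm / 2)
  }
})

test_that("coverage-controlled bag references degrade gracefully", {
  # higher reference coverage should not be less accurate than much lower
  # coverage (direction-only check, seeded)
  tr <- study_tree()
  seqs <- simulate_sequences(tr, 3000, seed = 13)
  mean_nd_at <- function(coverage, rep_seed) {
    coverage_pac_run(tr, seqs, coverage, read_len = 150, leaves = "C",
                     seed = rep_seed)$grand_mean_nd
  }
  hi <- mean(vapply(1:2, function(r) mean_nd_at(4, 1000 * r), numeric(1)))
  lo <- mean(vapply(1:2, function(r) mean_nd_at(0.25, 1000 * r), numeric(1)))
  expect_lte(hi, lo + 1e-9)
})
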