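test_that("occurrence enumeration yields spaced words over match positions", {
  p <- parse_pattern("1101001")
  # window at position 1 carries A,T at positions 1,2, G at 4, C at 7:
  # the spaced word AT*G**C with key "ATGC"
  occ <- enumerate_occurrences("ATCGAACC", p)
  expect_equal(occ$key[occ$pos == 1], "ATGC")
  expect_equal(nchar(occ$dontcare[1]), 3L)

  # sequence shorter than the pattern: no window fits
  expect_equal(nrow(enumerate_occurrences("ACG", p)), 0L)

  # brute-force count: "AAAAAAAA" with pattern "11" has 7 windows
  occ2 <- enumerate_occurrences("AAAAAAAA", parse_pattern("11"))
  expect_equal(nrow(occ2), 7L)
  expect_true(all(occ2$key == "AA"))
})

test_that("windows containing non-ACGT characters are skipped and counted", {
  occ <- enumerate_occurrences("AANTT", parse_pattern("11"))
  expect_equal(occ$pos, c(1L, 4L))
  expect_equal(attr(occ, "skipped"), 2L)
})

test_that("reverse-strand occurrences enumerate the reverse complement", {
  p <- parse_pattern("11")
  fwd <- enumerate_occurrences("AACGT", p)
  rev <- enumerate_occurrences(reverse_complement("AACGT"), p)
  expect_identical(enumerate_occurrences("AACGT", p, "reverse"), rev)
  expect_false(identical(fwd$key, rev$key))
})

test_that("occurrence lists are key-sorted with contiguous blocks", {
  set.seed(11)
  seqs <- c(s1 = rand_seq(60), s2 = rand_seq(60), s3 = rand_seq(60))
  L <- build_occurrence_list(seqs, parse_pattern("101"))
  expect_true(all(diff(rank(L$key, ties.method = "min")) >= 0))
  # block contiguity against a grouping oracle: same-key rows are adjacent
  runs <- rle(L$key)
  expect_equal(length(runs$values), length(unique(L$key)))
  expect_error(build_occurrence_list(c(a = "ACGT", a = "ACGT"),
                                     parse_pattern("11")),
               "duplicate")
})

test_that("score_spam applies the HOXD70 table over don't-care columns", {
  expect_equal(score_spam("A", "A"), list(score = 91, mismatches = 0L))
  expect_equal(score_spam("A", "G"), list(score = -31, mismatches = 1L))
  expect_equal(score_spam("", ""), list(score = 0, mismatches = 0L))
  expect_equal(score_spam("ACG", "ATG")$score,
               hoxd70()["A", "A"] + hoxd70()["C", "T"] + hoxd70()["G", "G"])
  expect_error(score_spam("AC", "A"), "equal length")
})

test_that("jukes_cantor matches the closed form and handles saturation", {
  expect_equal(jukes_cantor(0), 0)
  expect_equal(jukes_cantor(0.1), -0.75 * log(1 - 4 * 0.1 / 3))
  expect_equal(jukes_cantor(0.1), 0.10732563, tolerance = 1e-7)
  expect_warning(d <- jukes_cantor(0.75), "saturation")
  expect_equal(d, 5)
  expect_error(jukes_cantor(-0.01), "\\[0, 1\\]")
  expect_error(jukes_cantor(1.01), "\\[0, 1\\]")
})

test_that("match_and_filter equals the all-position-pairs oracle", {
  set.seed(42)
  pat_texts <- c("11", "1101001", "1010011", "110000101")
  for (i in 1:8) {
    pt <- sample(pat_texts, 1)
    t <- sample(c(-50, 0, 50), 1)
    ref <- rand_seq(sample(80:160, 1))
    qry <- rand_seq(sample(60:120, 1))
    p <- parse_pattern(pt)
    L1 <- build_occurrence_list(c(R = ref), p)
    L2 <- build_occurrence_list(c(Q = qry), p)
    got <- match_and_filter(L1, L2, match_config(p, threshold = t),
                            keep_matches = TRUE)
    want <- oracle_spam_strand(ref, qry, pt, t)
    if (want$s == 0) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got$s, want$s)
      expect_equal(got$dc_columns, want$dc_columns)
      expect_equal(got$dc_mismatches, want$dc_mismatches)
      expect_equal(got$p, want$p)
      expect_equal(got$d, want$d)
      m <- attr(got, "matches")
      expect_setequal(paste(m$ref_pos, m$query_pos),
                      paste(want$matches[, "i1"], want$matches[, "i2"]))
    }
  }
})

test_that("match_and_filter rejects lists built with different patterns", {
  L1 <- build_occurrence_list(c(a = "ACGTACGT"), parse_pattern("11"))
  L2 <- build_occurrence_list(c(b = "ACGTACGT"), parse_pattern("101"))
  expect_error(match_and_filter(L1, L2), "different patterns")
})

test_that("identical sequences give p = 0 and d = 0", {
  set.seed(5)
  s <- rand_seq(300)
  st <- compute_pair_stats(c(R = s), c(Q = s))
  expect_equal(nrow(st), 1L)
  expect_gt(st$s, 0)
  expect_equal(st$p, 0)
  expect_equal(st$d, 0)
})

test_that("an exact substring places at distance 0 on its source", {
  set.seed(6)
  ref <- rand_seq(2000)
  q <- substr(ref, 501, 650)
  st <- compute_pair_stats(c(R = ref), c(Q = q))
  expect_gte(st$s[st$ref_id == "R"], 1)
  expect_equal(st$d[st$ref_id == "R"], 0)
})

test_that("reverse-complemented queries yield identical pair statistics", {
  set.seed(7)
  ref <- rand_seq(1500)
  q <- substr(ref, 101, 280)
  fwd <- compute_pair_stats(c(R = ref), c(Q = q))
  rev <- compute_pair_stats(c(R = ref), c(Q = reverse_complement(q)))
  expect_equal(fwd[, c("s", "dc_columns", "dc_mismatches", "p", "d")],
               rev[, c("s", "dc_columns", "dc_mismatches", "p", "d")])
  expect_equal(fwd$strand, "forward")
  expect_equal(rev$strand, "reverse")
})

test_that("pair statistics are invariant to batch size and query order", {
  set.seed(8)
  refs <- c(R1 = rand_seq(800), R2 = rand_seq(800))
  qs <- setNames(vapply(1:7, function(i) {
    substr(refs[[1 + i %% 2]], 50 * i, 50 * i + 149)
  }, character(1)), paste0("q", 1:7))
  a <- compute_pair_stats(refs, qs, match_config(batch_size = 1))
  b <- compute_pair_stats(refs, qs, match_config(batch_size = 1000))
  c <- compute_pair_stats(refs, qs[sample(names(qs))],
                          match_config(batch_size = 3))
  expect_equal(a, b, ignore_attr = TRUE)
  expect_equal(a, c, ignore_attr = TRUE)
})

test_that("raising the threshold never increases any SpaM count", {
  set.seed(9)
  ref <- rand_seq(400)
  q <- substr(ref, 101, 250)
  thresholds <- c(-100, -10, 0, 50, 200)
  counts <- vapply(thresholds, function(t) {
    st <- compute_pair_stats(c(R = ref), c(Q = q),
                             match_config(threshold = t))
    if (nrow(st)) st$s else 0L
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("empty query sets give an empty result, not an error", {
  st <- compute_pair_stats(c(R = "ACGTACGTACGT"), character(0))
  expect_equal(nrow(st), 0L)
})

test_that("multiple patterns pool counts before forming p", {
  set.seed(10)
  ref <- rand_seq(500)
  q <- substr(ref, 101, 300)
  ps <- generate_pattern_set(2, 6, 8, seed = 3)
  both <- compute_pair_stats(c(R = ref), c(Q = q), match_config(ps))
  one <- compute_pair_stats(c(R = ref), c(Q = q), match_config(ps[[1]]))
  two <- compute_pair_stats(c(R = ref), c(Q = q),
                            match_config(pattern_set(render_pattern(ps[[2]]))))
  expect_equal(both$s, one$s + two$s)
  expect_equal(both$dc_columns, one$dc_columns + two$dc_columns)
  expect_equal(both$dc_mismatches, one$dc_mismatches + two$dc_mismatches)
})
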