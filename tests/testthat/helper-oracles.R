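# Independent oracles used to cross-check the implementation. These are
# deliberately naive (loops, brute force) and share no code with the
# package internals.

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_naive <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

# Brute force over all position pairs (i1, i2) on one strand: every window
# pair matching at all match positions is a SpaM; score/mismatches are
# summed over don't-care columns; SpaMs with score > t are kept.
oracle_spam_strand <- function(refseq, qryseq, pattern_text, t = 0,
                               mat = NULL) {
  if (is.null(mat)) {
    mat <- matrix(c(91, -114, -31, -123,
                    -114, 100, -125, -31,
                    -31, -125, 100, -114,
                    -123, -31, -114, 91), 4, 4, byrow = TRUE,
                  dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T")))
  }
  pc <- strsplit(pattern_text, "")[[1]]
  l <- length(pc)
  mp <- which(pc == "1")
  dp <- which(pc == "0")
  r <- strsplit(refseq, "")[[1]]
  q <- strsplit(qryseq, "")[[1]]
  ok <- c("A", "C", "G", "T")
  # spaced word (match-position string) and validity of every window
  windows <- function(ch) {
    n <- length(ch)
    if (n < l) return(list(key = character(0), valid = logical(0)))
    ns <- n - l + 1L
    key <- character(ns)
    valid <- logical(ns)
    for (i in seq_len(ns)) {
      w <- ch[i:(i + l - 1)]
      valid[i] <- all(w %in% ok)
      key[i] <- paste(w[mp], collapse = "")
    }
    list(key = key, valid = valid)
  }
  wr <- windows(r)
  wq <- windows(q)
  matches <- list()
  s <- 0L
  mism <- 0L
  if (length(wr$key) && length(wq$key)) {
    eq <- outer(wr$key, wq$key, "==") & outer(wr$valid, wq$valid, "&")
    hits <- which(eq, arr.ind = TRUE)
    for (h in seq_len(nrow(hits))) {
      i1 <- unname(hits[h, 1])
      i2 <- unname(hits[h, 2])
      sc <- if (length(dp)) {
        sum(mat[cbind(r[i1 + dp - 1], q[i2 + dp - 1])])
      } else 0
      if (sc > t) {
        s <- s + 1L
        mm <- sum(r[i1 + dp - 1] != q[i2 + dp - 1])
        mism <- mism + mm
        matches[[length(matches) + 1L]] <-
          c(i1 = i1, i2 = i2, score = sc, mismatches = mm)
      }
    }
  }
  cols <- as.numeric(s) * length(dp)
  # pooled mismatch proportion; a pattern without don't-care positions
  # carries no mismatch evidence, so p = 0 by convention when s > 0
  p <- if (s == 0) NA_real_ else if (cols > 0) mism / cols else 0
  d <- if (is.na(p)) NA_real_ else if (p >= 0.75) 5 else -0.75 * log(1 - 4 * p / 3)
  list(s = s, dc_columns = cols, dc_mismatches = as.numeric(mism),
       p = p, d = d,
       matches = if (length(matches)) do.call(rbind, matches) else NULL)
}

# Best-strand oracle mirroring the pipeline contract: stats per strand,
# keep the strand with the larger s (tie -> forward).
oracle_spam <- function(refseq, qryseq, pattern_text, t = 0) {
  fwd <- oracle_spam_strand(refseq, qryseq, pattern_text, t)
  rev <- oracle_spam_strand(refseq, revcomp_naive(qryseq), pattern_text, t)
  if (rev$s > fwd$s) c(rev, strand = "reverse") else c(fwd, strand = "forward")
}

.resolve_label <- function(tree, x) {
  if (is.character(x)) match(x, tree$label) else x
}

# BFS oracle for the node distance between edges: edges are vertices of a
# graph, adjacent iff they share a tree node; the distance is the number
# of hops, which equals the number of nodes on the connecting path.
oracle_edge_distance <- function(tree, e1, e2) {
  ed <- tree_edges(tree)
  n <- nrow(ed)
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    ni <- c(ed$parent[i], ed$child[i])
    adj[[i]] <- setdiff(which(ed$parent %in% ni | ed$child %in% ni), i)
  }
  src <- which(ed$edge_num == e1)
  dst <- which(ed$edge_num == e2)
  if (src == dst) return(0L)
  dist <- rep(NA_integer_, n)
  dist[src] <- 0L
  frontier <- src
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- nxt
  }
  dist[dst]
}

# Path-set LCA oracle: the shared node of the two root paths with maximum
# depth.
oracle_lca <- function(tree, a, b) {
  path_to_root <- function(v) {
    out <- v
    while (!is.na(tree$parent[v])) {
      v <- tree$parent[v]
      out <- c(out, v)
    }
    out
  }
  pa <- path_to_root(.resolve_label(tree, a))
  pb <- path_to_root(.resolve_label(tree, b))
  shared <- intersect(pa, pb)
  shared[which.max(tree$depth[shared])]
}

# Weighted path length between two nodes: sum of branch lengths along the
# two root paths up to their deepest shared node.
oracle_weighted_dist <- function(tree, a, b) {
  u <- .resolve_label(tree, a)
  v <- .resolve_label(tree, b)
  anc <- oracle_lca(tree, u, v)
  d <- 0
  while (u != anc) {
    d <- d + tree$brlen[u]
    u <- tree$parent[u]
  }
  while (v != anc) {
    d <- d + tree$brlen[v]
    v <- tree$parent[v]
  }
  d
}

# Balanced 8-leaf study tree: all branch lengths 0.05.
study_tree <- function() {
  parse_newick(paste0(
    "(((A:0.05,B:0.05):0.05,(C:0.05,D:0.05):0.05):0.05,",
    "((E:0.05,F:0.05):0.05,(G:0.05,H:0.05):0.05):0.05);"
  ))
}

# One-row-per-reference stats table for placement unit tests.
fake_stats <- function(ref_id, s, d) {
  ndc <- 32
  tibble::tibble(
    query_id = "q", ref_id = ref_id, strand = "forward",
    s = as.integer(s), dc_columns = as.numeric(s) * ndc,
    dc_mismatches = round(jc_expected_mismatch(pmin(d, 4.9)) * s * ndc),
    p = jc_expected_mismatch(pmin(d, 4.9)), d = d
  )
}
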