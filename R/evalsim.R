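# Synthetic data and pruning-based accuracy (PAC) evaluation.
#
# Sequences are evolved along the reference tree under the Jukes-Cantor
# model: branch lengths are expected substitutions per site, so a site
# changes state along a branch of length b with probability
# p(b) = (3/4) (1 - exp(-4 b / 3)), to a uniformly chosen different base.
# Query reads are made by cutting a taxon's sequence into fixed-length
# segments, or by sampling coverage-controlled read bags from both strands.
# The PAC harness prunes one leaf at a time, places that leaf's reads on
# the pruned tree, and scores each read by the topological node distance
# to the edge where the leaf used to attach.

#' Expected mismatch proportion at a Jukes-Cantor distance
#'
#' `p = (3/4) (1 - exp(-4 d / 3))`, the inverse of [jukes_cantor()].
#'
#' @param d Jukes-Cantor distance(s) (expected substitutions per site).
#' @return Expected proportion(s) of differing sites.
#' @export
jc_expected_mismatch <- function(d) {
  stopifnot(all(d >= 0))
  0.75 * (1 - exp(-4 * d / 3))
}

#' Simulate leaf sequences along a reference tree
#'
#' The root sequence is uniform over A, C, G, T; each child sequence is
#' derived from its parent by substituting every site independently with
#' probability `jc_expected_mismatch(l(branch))` to a uniformly chosen
#' different base. Seeded and reproducible.
#'
#' @param tree A `ref_tree` with branch lengths in expected substitutions
#'   per site.
#' @param root_length Root sequence length (>= pattern length to be usable
#'   for matching).
#' @param seed Integer seed.
#' @return Named character vector: one sequence per leaf label.
#' @export
simulate_sequences <- function(tree, root_length, seed = 1L) {
  stopifnot(inherits(tree, "ref_tree"), root_length >= 1)
  with_seed(seed, {
    n <- length(tree$parent)
    seqs <- vector("list", n)
    seqs[[tree$root]] <- sample.int(4L, root_length, replace = TRUE) - 1L
    for (v in tree$preorder) {
      if (v == tree$root) next
      parent_seq <- seqs[[tree$parent[v]]]
      p <- jc_expected_mismatch(tree$brlen[v])
      child <- parent_seq
      if (p > 0) {
        hit <- which(stats::runif(root_length) < p)
        if (length(hit)) {
          child[hit] <- (child[hit] +
                           sample.int(3L, length(hit), replace = TRUE)) %% 4L
        }
      }
      seqs[[v]] <- child
    }
    tips <- which(tree$is_tip)
    out <- vapply(tips, function(v) decode_codes(seqs[[v]]), character(1))
    names(out) <- tree$label[tips]
    out
  })
}

#' Fragment a sequence into fixed-length reads
#'
#' Consecutive, non-overlapping segments of `read_len`; a final shorter
#' remainder is kept only if it is at least `min_len` long (shorter
#' fragments cannot contain a single spaced-word occurrence).
#'
#' @param seq A nucleotide string.
#' @param read_len Segment length (>= 1).
#' @param min_len Minimum length of a kept remainder; default 44, the
#'   default pattern length.
#' @param prefix Read-name prefix.
#' @return Named character vector of reads (possibly empty). Attribute
#'   `dropped` counts remainder fragments discarded for being too short.
#' @export
#' @examples
#' length(fragment_reads(strrep("A", 450), 150))  # 3
fragment_reads <- function(seq, read_len, min_len = 44L, prefix = "read") {
  stopifnot(read_len >= 1)
  n <- nchar(seq)
  starts <- seq(1L, n, by = read_len)
  ends <- pmin(starts + read_len - 1L, n)
  keep <- (ends - starts + 1L) >= min(min_len, read_len)
  dropped <- sum(!keep)
  starts <- starts[keep]
  ends <- ends[keep]
  reads <- if (length(starts)) substring(seq, starts, ends) else character(0)
  names(reads) <- if (length(reads)) {
    sprintf("%s_%d", prefix, seq_along(reads))
  } else {
    character(0)
  }
  if (dropped > 0L) {
    message(dropped, " remainder fragment(s) shorter than ", min_len,
            " nt dropped")
  }
  attr(reads, "dropped") <- dropped
  reads
}

#' Sample a coverage-controlled bag of reads
#'
#' Draws `ceiling(coverage * |seq| / read_len)` reads of length `read_len`
#' with uniformly random start positions, each from a uniformly random
#' strand. Seeded and reproducible.
#'
#' @param seq A nucleotide string with `|seq| >= read_len`.
#' @param read_len Read length.
#' @param coverage Target sequencing coverage (> 0).
#' @param seed Integer seed.
#' @param prefix Read-name prefix.
#' @return Named character vector of reads.
#' @export
sample_read_bag <- function(seq, read_len, coverage, seed = 1L,
                            prefix = "bag") {
  stopifnot(coverage > 0, nchar(seq) >= read_len)
  n <- nchar(seq)
  n_reads <- as.integer(ceiling(coverage * n / read_len))
  with_seed(seed, {
    starts <- sample.int(n - read_len + 1L, n_reads, replace = TRUE)
    rev <- stats::runif(n_reads) < 0.5
    reads <- substring(seq, starts, starts + read_len - 1L)
    reads[rev] <- vapply(reads[rev], reverse_complement, character(1))
    names(reads) <- sprintf("%s_%d", prefix, seq_len(n_reads))
    reads
  })
}

#' Pruning-based accuracy (PAC) evaluation
#'
#' For each pruning, one seeded-randomly chosen leaf is removed from the
#' tree (the resulting degree-2 node is suppressed and the attachment is
#' remembered as the merged edge), the leaf's sequence is fragmented into
#' reads, the reads are placed on the pruned tree, and each read is scored
#' by the node distance between its chosen edge and the true attachment
#' edge. The mean over a pruning's reads measures that pruning's accuracy;
#' the grand mean over prunings summarises the run.
#'
#' @param tree A `ref_tree` with at least 4 leaves.
#' @param leaf_seqs Named character vector of leaf sequences (names must
#'   cover the tree's leaves).
#' @param read_len Read length for fragmentation; default 150.
#' @param match_config A [match_config()].
#' @param placement_config A [placement_config()].
#' @param n_prunings Number of prunings; if equal to the number of leaves,
#'   every leaf is pruned exactly once, otherwise a seeded random subset.
#' @param seed Integer seed for the pruning choice.
#' @param placer `"spam"` (the real pipeline) or `"oracle"`, which places
#'   every read exactly on the true edge — a harness self-test that must
#'   score 0.
#' @return An object of class `pac_result`: list with `per_pruning` (tibble:
#'   `pruning`, `leaf`, `true_edges` list-column, `n_reads`, `mean_nd`),
#'   `per_read` (tibble: `pruning`, `leaf`, `query_id`, `edge_num`, `nd`),
#'   and `grand_mean_nd`.
#' @export
pac_run <- function(tree, leaf_seqs, read_len = 150L,
                    match_config = swplace::match_config(),
                    placement_config = swplace::placement_config(),
                    n_prunings = tree$n_tip, seed = 1L,
                    placer = c("spam", "oracle")) {
  placer <- match.arg(placer)
  stopifnot(inherits(tree, "ref_tree"))
  if (tree$n_tip < 4L) stop("PAC needs a tree with >= 4 leaves", call. = FALSE)
  leaves <- tree_leaves(tree)
  missing <- setdiff(leaves, names(leaf_seqs))
  if (length(missing)) {
    stop("no sequence for leaf/leaves: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  chosen <- if (n_prunings >= length(leaves)) {
    leaves
  } else {
    with_seed(seed, sample(leaves, n_prunings))
  }
  min_len <- min(vapply(match_config$pattern_set, function(p) p$length,
                        integer(1)))
  per_pruning <- list()
  per_read <- list()
  for (k in seq_along(chosen)) {
    leaf <- chosen[k]
    pr <- prune_leaf(tree, leaf)
    reads <- fragment_reads(leaf_seqs[[leaf]], read_len, min_len = min_len,
                            prefix = paste0(leaf, "_read"))
    if (length(reads) == 0L) {
      warning("leaf ", leaf, " produced no reads; skipping pruning",
              call. = FALSE)
      next
    }
    refs <- leaf_seqs[tree_leaves(pr$tree)]
    if (placer == "oracle") {
      nd <- rep(0L, length(reads))
      edges <- rep(pr$true_edges[1], length(reads))
    } else {
      stats <- compute_pair_stats(refs, reads, match_config)
      edges <- integer(length(reads))
      nd <- integer(length(reads))
      for (i in seq_along(reads)) {
        qs <- stats[stats$query_id == names(reads)[i], , drop = FALSE]
        pl <- place_query(qs, pr$tree, placement_config, names(reads)[i])
        edges[i] <- pl$edge_num
        nd[i] <- min(vapply(pr$true_edges, function(te) {
          node_distance(pr$tree, pl$edge_num, te)
        }, integer(1)))
      }
    }
    per_read[[k]] <- tibble::tibble(
      pruning = k, leaf = leaf, query_id = names(reads),
      edge_num = edges, nd = nd
    )
    per_pruning[[k]] <- tibble::tibble(
      pruning = k, leaf = leaf, true_edges = list(pr$true_edges),
      n_reads = length(reads), mean_nd = mean(nd)
    )
  }
  per_pruning <- dplyr::bind_rows(per_pruning)
  structure(
    list(per_pruning = per_pruning,
         per_read = dplyr::bind_rows(per_read),
         grand_mean_nd = mean(per_pruning$mean_nd)),
    class = "pac_result"
  )
}

#' @export
print.pac_result <- function(x, ...) {
  cat("<pac_result> ", nrow(x$per_pruning), " pruning(s), grand mean ND = ",
      format(x$grand_mean_nd, digits = 4), "\n", sep = "")
  print(x$per_pruning)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy pac_result
#' @export
tidy.pac_result <- function(x, ...) x$per_pruning

#' @method glance pac_result
#' @export
glance.pac_result <- function(x, ...) {
  tibble::tibble(
    n_prunings = nrow(x$per_pruning),
    n_reads = sum(x$per_pruning$n_reads),
    grand_mean_nd = x$grand_mean_nd,
    max_mean_nd = max(x$per_pruning$mean_nd)
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method autoplot pac_result
#' @export
autoplot.pac_result <- function(object, ...) {
  dat <- object$per_pruning
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$leaf, y = .data$mean_nd)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$grand_mean_nd, linetype = 2) +
    ggplot2::labs(x = "pruned leaf", y = "mean node distance",
                  title = "Pruning-based placement accuracy") +
    ggplot2::theme_minimal()
}

#' Leave-one-out evaluation with bag-of-reads references
#'
#' Emulates placement against unassembled references: every reference
#' taxon is represented by a coverage-controlled bag of reads sampled from
#' its sequence ([sample_read_bag()]) instead of the contiguous sequence.
#' For each evaluated leaf, the leaf is pruned, bags are sampled for the
#' remaining leaves and pooled onto their taxa via a record-to-leaf map,
#' the pruned leaf's own bag is placed, and the mean node distance to the
#' true attachment edge is recorded.
#'
#' @param tree A `ref_tree`.
#' @param leaf_seqs Named character vector of leaf sequences.
#' @param coverage Sequencing coverage of the reference (and query) bags.
#' @param read_len Read length; default 150.
#' @param leaves Leaves to evaluate (default: all).
#' @param match_config A [match_config()].
#' @param placement_config A [placement_config()].
#' @param seed Integer seed for the bag sampling.
#' @return A `pac_result` whose per-pruning rows carry the mean node
#'   distance of the bag queries of each evaluated leaf.
#' @export
coverage_pac_run <- function(tree, leaf_seqs, coverage, read_len = 150L,
                             leaves = tree_leaves(tree),
                             match_config = swplace::match_config(),
                             placement_config = swplace::placement_config(),
                             seed = 1L) {
  stopifnot(inherits(tree, "ref_tree"), coverage > 0)
  per_pruning <- list()
  per_read <- list()
  for (k in seq_along(leaves)) {
    leaf <- leaves[k]
    pr <- prune_leaf(tree, leaf)
    keep <- tree_leaves(pr$tree)
    recs <- character(0)
    map <- character(0)
    for (j in seq_along(keep)) {
      bag <- sample_read_bag(leaf_seqs[[keep[j]]], read_len, coverage,
                             seed = seed + 13L * k + j,
                             prefix = paste0(keep[j], "_rec"))
      recs <- c(recs, bag)
      map <- c(map, stats::setNames(rep(keep[j], length(bag)), names(bag)))
    }
    queries <- sample_read_bag(leaf_seqs[[leaf]], read_len, coverage,
                               seed = seed + 101L * k,
                               prefix = paste0(leaf, "_q"))
    res <- place_sequences(queries, recs, pr$tree,
                           match_config = match_config,
                           placement_config = placement_config,
                           taxon_map = map)
    nd <- vapply(res$placements$edge_num, function(e) {
      min(vapply(pr$true_edges, function(te) {
        node_distance(pr$tree, e, te)
      }, integer(1)))
    }, integer(1))
    per_read[[k]] <- tibble::tibble(
      pruning = k, leaf = leaf, query_id = res$placements$query_id,
      edge_num = res$placements$edge_num, nd = nd
    )
    per_pruning[[k]] <- tibble::tibble(
      pruning = k, leaf = leaf, true_edges = list(pr$true_edges),
      n_reads = length(queries), mean_nd = mean(nd)
    )
  }
  per_pruning <- dplyr::bind_rows(per_pruning)
  structure(
    list(per_pruning = per_pruning,
         per_read = dplyr::bind_rows(per_read),
         grand_mean_nd = mean(per_pruning$mean_nd)),
    class = "pac_result"
  )
}

#' Control baselines: root and midpoint placement
#'
#' Node distances from a true attachment edge to (a) the root's first child
#' edge (the "place everything at the root" control) and (b) the edge
#' containing the tree's midpoint — the point halving the longest weighted
#' leaf-to-leaf path; when that point falls exactly on a node, the incident
#' path edge with the lower edge number is chosen.
#'
#' @param tree A `ref_tree`.
#' @param true_edge The true attachment edge (`sw_edge_ref` or number).
#' @return Named numeric vector `c(root_nd = ..., midpoint_nd = ...)`.
#' @export
control_baselines <- function(tree, true_edge) {
  rc <- tree$children[[tree$root]][1]
  root_edge <- tree$edge_num[rc]
  mid_edge <- midpoint_edge(tree)
  c(root_nd = node_distance(tree, true_edge, root_edge),
    midpoint_nd = node_distance(tree, true_edge, mid_edge))
}

#' Edge containing the tree's midpoint
#'
#' @param tree A `ref_tree`.
#' @return The 0-based edge number of the midpoint edge.
#' @export
midpoint_edge <- function(tree) {
  tips <- which(tree$is_tip)
  best <- c(NA_integer_, NA_integer_)
  best_d <- -Inf
  for (i in seq_along(tips)) {
    for (j in seq_along(tips)) {
      if (j <= i) next
      d <- .weighted_node_dist(tree, tips[i], tips[j])
      if (d > best_d + 1e-12) {
        best_d <- d
        best <- c(tips[i], tips[j])
      }
    }
  }
  a <- best[1]
  b <- best[2]
  v <- lca(tree, a, b)
  up <- integer(0)     # nodes from a up to v
  x <- a
  while (x != v) {
    up <- c(up, x)
    x <- tree$parent[x]
  }
  down <- integer(0)   # nodes from v down to b (exclusive of v)
  x <- b
  while (x != v) {
    down <- c(down, x)
    x <- tree$parent[x]
  }
  path <- c(up, v, rev(down))  # node sequence a ... b
  # edge k on the path connects path[k] and path[k+1]; its child node is
  # whichever of the two is deeper
  edge_nodes <- vapply(seq_len(length(path) - 1L), function(k) {
    if (tree$depth[path[k]] > tree$depth[path[k + 1L]]) path[k] else path[k + 1L]
  }, integer(1))
  lens <- tree$brlen[edge_nodes]
  cum <- cumsum(c(0, lens))
  half <- best_d / 2
  eps <- 1e-12
  cand <- which(cum[-length(cum)] <= half + eps & half <= cum[-1] + eps)
  min(tree$edge_num[edge_nodes[cand]])
}
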