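# Placement heuristics. Given per-reference pair statistics for one query,
# choose an attachment edge in the reference tree:
#   minimum-distance — pendant edge of the leaf with the smallest d(Q,S);
#   spam-count       — pendant edge of the leaf with the largest s(Q,S);
#   lca-distance     — parent edge of the LCA of the two closest leaves;
#   lca-count        — parent edge of the LCA of the two highest-count leaves;
#   spam-x           — spam-count when the top two counts differ strongly
#                      (|s1-s2| > (s1+s2)/X), lca-count otherwise.
# Queries without any filtered SpaM are recorded at the root.

#' Placement configuration
#'
#' @param heuristic One of `"spam-x"` (default), `"minimum-distance"`,
#'   `"spam-count"`, `"lca-distance"`, `"lca-count"`.
#' @param X Positive ratio parameter of the spam-x rule; default 4.
#' @param seed Integer seed for tie-breaking. Each query derives its own
#'   tie-break stream from (seed, query id), so results do not depend on
#'   the order in which queries are processed.
#' @return A list of class `sw_placement_config`.
#' @export
placement_config <- function(heuristic = c("spam-x", "minimum-distance",
                                           "spam-count", "lca-distance",
                                           "lca-count"),
                             X = 4, seed = 42L) {
  heuristic <- match.arg(heuristic)
  stopifnot(X > 0)
  structure(list(heuristic = heuristic, X = X, seed = as.integer(seed)),
            class = "sw_placement_config")
}

#' Rank references for one query
#'
#' References with at least one filtered SpaM, ordered by the chosen
#' criterion (ascending distance or descending count). Ties are broken by a
#' seeded uniform draw, reproducible for a fixed seed.
#'
#' @param stats Pair-statistics tibble for a single query (columns
#'   `ref_id`, `s`, `d`; rows with `s = 0` must be absent, as produced by
#'   [compute_pair_stats()]).
#' @param by `"distance"` or `"count"`.
#' @param seed Integer tie-break seed.
#' @return Character vector of reference ids, best first (possibly empty).
#' @export
rank_references <- function(stats, by = c("distance", "count"), seed = 42L) {
  by <- match.arg(by)
  if (is.null(stats) || nrow(stats) == 0L) return(character(0))
  tie <- with_seed(seed, stats::runif(nrow(stats)))
  ord <- if (by == "distance") {
    order(stats$d, tie)
  } else {
    order(-stats$s, tie)
  }
  stats$ref_id[ord]
}

#' Decide the spam-x branch from the two best counts
#'
#' Routes to the leaf heuristic (spam-count) iff
#' `|s1 - s2| > (s1 + s2) / X`; otherwise to lca-count. With `X = 1` the
#' inequality can never hold (|s1 - s2| <= s1 + s2), so every query is
#' routed to lca-count; as X grows the rule approaches pure spam-count
#' whenever the counts differ.
#'
#' @param s1,s2 The two largest filtered-SpaM counts, `s1 >= s2 >= 0`.
#' @param X Positive ratio parameter.
#' @return `"leaf"` or `"lca"`.
#' @export
#' @examples
#' decide_spam_x(10, 2, 4)  # "leaf": 8 > 3
#' decide_spam_x(5, 5, 4)   # "lca"
decide_spam_x <- function(s1, s2, X = 4) {
  stopifnot(s1 >= s2, s2 >= 0, X > 0)
  if (abs(s1 - s2) > (s1 + s2) / X) "leaf" else "lca"
}

.new_placement <- function(query_id, edge, tree, heuristic,
                           fallback_root = FALSE, degraded = FALSE,
                           best_ref = NA_character_, s_best = NA_integer_,
                           d_best = NA_real_) {
  tibble::tibble(
    query_id = query_id,
    edge_num = edge$edge_num,
    distal_length = NA_real_,
    pendant_length = NA_real_,
    heuristic = heuristic,
    fallback_root = fallback_root,
    degraded = degraded,
    best_ref = best_ref,
    s_best = s_best,
    d_best = d_best
  )
}

.leaf_edge <- function(tree, label) parent_edge(tree, label)

.stats_row <- function(stats, ref) {
  stats[match(ref, stats$ref_id), , drop = FALSE]
}

# Child edge of the root on the path toward node v.
.root_child_edge_toward <- function(tree, v) {
  for (c in tree$children[[tree$root]]) {
    if (.in_clade(tree, v, c)) return(edge_ref(tree$edge_num[c], c))
  }
  stop("internal error: node not in tree", call. = FALSE)
}

.place_leaf <- function(stats, tree, config, by, query_id, heuristic) {
  ranked <- rank_references(stats, by, seed_for_id(config$seed, query_id))
  best <- ranked[1]
  row <- .stats_row(stats, best)
  pl <- .new_placement(query_id, .leaf_edge(tree, best), tree, heuristic,
                       best_ref = best, s_best = row$s, d_best = row$d)
  assign_branch_lengths(pl, stats, tree)
}

#' Place a query on the pendant edge of its closest reference
#'
#' @param stats Pair statistics for one query (see [rank_references()]);
#'   must contain at least one reference with `s > 0`.
#' @param tree A `ref_tree` whose leaves are the reference ids.
#' @param config A [placement_config()].
#' @param query_id Query identifier (used for tie-break seeding and output).
#' @return A one-row placement tibble (see [place_query()]).
#' @export
place_min_dist <- function(stats, tree, config = placement_config(),
                           query_id = "query") {
  .place_leaf(stats, tree, config, "distance", query_id, "minimum-distance")
}

#' Place a query on the pendant edge of the reference with most SpaMs
#'
#' @inheritParams place_min_dist
#' @return A one-row placement tibble.
#' @export
place_spam_count <- function(stats, tree, config = placement_config(),
                             query_id = "query") {
  .place_leaf(stats, tree, config, "count", query_id, "spam-count")
}

#' Place a query above the LCA of its two best references
#'
#' The two references with the smallest distances (or largest counts) are
#' identified; the chosen edge connects their lowest common ancestor v to
#' its parent. If v is the root (S1 and S2 on opposite sides), the root has
#' no parent edge and the root's child edge on the path toward S1 is used
#' instead. If only one reference has any filtered SpaM the method degrades
#' to the corresponding leaf heuristic (flagged in the output).
#'
#' @inheritParams place_min_dist
#' @param by `"distance"` (lca-distance) or `"count"` (lca-count).
#' @return A one-row placement tibble.
#' @export
place_lca <- function(stats, tree, config = placement_config(),
                      by = c("distance", "count"), query_id = "query") {
  by <- match.arg(by)
  heuristic <- if (by == "distance") "lca-distance" else "lca-count"
  ranked <- rank_references(stats, by, seed_for_id(config$seed, query_id))
  if (length(ranked) < 2L) {
    pl <- .place_leaf(stats, tree, config, by, query_id, heuristic)
    pl$degraded <- TRUE
    return(pl)
  }
  s1 <- ranked[1]
  s2 <- ranked[2]
  v <- lca(tree, s1, s2)
  e <- if (v == tree$root) {
    .root_child_edge_toward(tree, .resolve_node(tree, s1))
  } else {
    parent_edge(tree, v)
  }
  row <- .stats_row(stats, s1)
  pl <- .new_placement(query_id, e, tree, heuristic,
                       best_ref = s1, s_best = row$s, d_best = row$d)
  assign_branch_lengths(pl, stats, tree)
}

#' Place one query read
#'
#' Dispatches to the configured heuristic. Queries with no filtered SpaM to
#' any reference are recorded at the root: the placement lands on the first
#' child edge of the root with pendant length 0 and `fallback_root = TRUE`.
#' The spam-x heuristic composes [decide_spam_x()] with
#' [place_spam_count()] / [place_lca()] on counts.
#'
#' @param stats Pair statistics for this query (possibly empty).
#' @param tree A `ref_tree`.
#' @param config A [placement_config()].
#' @param query_id Query identifier.
#' @return A one-row tibble: `query_id`, `edge_num`, `distal_length`,
#'   `pendant_length`, `heuristic`, `fallback_root`, `degraded`,
#'   `best_ref`, `s_best`, `d_best`.
#' @export
place_query <- function(stats, tree, config = placement_config(),
                        query_id = "query") {
  if (is.null(stats) || nrow(stats) == 0L || all(stats$s == 0L)) {
    rc <- tree$children[[tree$root]][1]
    e <- edge_ref(tree$edge_num[rc], rc)
    pl <- .new_placement(query_id, e, tree, config$heuristic,
                         fallback_root = TRUE)
    pl$distal_length <- 0.5 * tree$brlen[rc]
    pl$pendant_length <- 0
    return(pl)
  }
  stats <- stats[stats$s > 0L, , drop = FALSE]
  switch(config$heuristic,
    "minimum-distance" = place_min_dist(stats, tree, config, query_id),
    "spam-count" = place_spam_count(stats, tree, config, query_id),
    "lca-distance" = place_lca(stats, tree, config, "distance", query_id),
    "lca-count" = place_lca(stats, tree, config, "count", query_id),
    "spam-x" = {
      ss <- sort(stats$s, decreasing = TRUE)
      s1 <- ss[1]
      s2 <- if (length(ss) >= 2L) ss[2] else 0L
      if (decide_spam_x(s1, s2, config$X) == "leaf" || length(ss) < 2L) {
        pl <- place_spam_count(stats, tree, config, query_id)
      } else {
        pl <- place_lca(stats, tree, config, "count", query_id)
      }
      pl$heuristic <- "spam-x"
      pl
    }
  )
}

#' Assign distal and pendant lengths to a chosen placement edge
#'
#' The chosen edge is split at its midpoint (distal length = half the edge
#' length, measured toward the child endpoint), conserving the original
#' edge length exactly. The pendant length is the estimated distance to the
#' best-ranked reference minus the path length from the attachment point to
#' that reference's leaf, clamped at 0; when no finite distance is
#' available the pendant length is 0. This is a documented package rule
#' satisfying the length-conservation constraint; it is not derived from an
#' external procedure.
#'
#' @param placement A one-row placement tibble with `edge_num` set.
#' @param stats Pair statistics for the query.
#' @param tree A `ref_tree`.
#' @return The placement with `distal_length` and `pendant_length` filled.
#' @export
assign_branch_lengths <- function(placement, stats, tree) {
  child <- .edge_child(tree, placement$edge_num)
  len <- tree$brlen[child]
  placement$distal_length <- 0.5 * len
  placement$pendant_length <- 0
  best <- placement$best_ref
  if (!is.na(best)) {
    row <- .stats_row(stats, best)
    d1 <- row$d
    if (length(d1) == 1L && is.finite(d1)) {
      leaf <- .resolve_node(tree, best)
      path_len <- if (.in_clade(tree, leaf, child)) {
        placement$distal_length + .weighted_node_dist(tree, child, leaf)
      } else {
        (len - placement$distal_length) +
          .weighted_node_dist(tree, tree$parent[child], leaf)
      }
      placement$pendant_length <- max(0, d1 - path_len)
    }
  }
  placement
}
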