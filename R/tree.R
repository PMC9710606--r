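# Rooted, edge-weighted reference tree with stable edge numbering.
#
# Internal representation: parallel vectors indexed by node id (tips and
# internal nodes share one id space). Every non-root node owns the edge to
# its parent; edge numbers are assigned 0-based in preorder (children in
# input order), the order jplace consumers expect to find in the braced
# tree string. ape does the Newick parsing/serialisation heavy lifting;
# numbering, LCA, node distances, insertion and pruning are implemented
# here so that edge identities stay stable and documented.

.rebuild_index <- function(tr) {
  n <- length(tr$parent)
  depth <- integer(n)
  preorder <- integer(n)
  edge_num <- tr$edge_num
  k <- 0L
  stack <- tr$root
  while (length(stack)) {
    v <- stack[[1]]
    stack <- stack[-1]
    k <- k + 1L
    preorder[k] <- v
    ch <- tr$children[[v]]
    if (length(ch)) {
      depth[ch] <- depth[v] + 1L
      stack <- c(ch, stack)
    }
  }
  tr$preorder <- preorder[seq_len(k)]
  tr$depth <- depth
  # edge -> child-node lookup
  has_edge <- !is.na(edge_num)
  child_of <- integer(sum(has_edge))
  child_of[edge_num[has_edge] + 1L] <- which(has_edge)
  tr$edge_child <- child_of
  tr
}

.assign_edge_numbers <- function(tr) {
  num <- rep(NA_integer_, length(tr$parent))
  k <- -1L
  stack <- tr$root
  while (length(stack)) {
    v <- stack[[1]]
    stack <- stack[-1]
    if (v != tr$root) {
      k <- k + 1L
      num[v] <- k
    }
    stack <- c(tr$children[[v]], stack)
  }
  tr$edge_num <- num
  .rebuild_index(tr)
}

.ref_tree_from_phylo <- function(phy) {
  n_tip <- length(phy$tip.label)
  n <- n_tip + phy$Nnode
  parent <- rep(NA_integer_, n)
  children <- vector("list", n)
  for (i in seq_len(n)) children[[i]] <- integer(0)
  for (r in seq_len(nrow(phy$edge))) {
    p <- phy$edge[r, 1]
    c <- phy$edge[r, 2]
    parent[c] <- p
    children[[p]] <- c(children[[p]], c)
  }
  root <- n_tip + 1L
  brlen <- rep(NA_real_, n)
  if (is.null(phy$edge.length)) {
    warning("tree has no branch lengths; defaulting all to 0", call. = FALSE)
    phy$edge.length <- rep(0, nrow(phy$edge))
  }
  if (anyNA(phy$edge.length)) {
    warning("missing branch lengths defaulted to 0", call. = FALSE)
    phy$edge.length[is.na(phy$edge.length)] <- 0
  }
  brlen[phy$edge[, 2]] <- phy$edge.length
  label <- rep(NA_character_, n)
  label[seq_len(n_tip)] <- phy$tip.label
  if (!is.null(phy$node.label) && length(phy$node.label)) {
    lbl <- phy$node.label
    lbl[lbl == ""] <- NA_character_
    label[n_tip + seq_along(lbl)] <- lbl
  }
  tr <- structure(
    list(parent = parent, children = children, label = label,
         is_tip = c(rep(TRUE, n_tip), rep(FALSE, n - n_tip)),
         brlen = brlen, root = root, n_tip = n_tip),
    class = "ref_tree"
  )
  .assign_edge_numbers(tr)
}

#' Parse a Newick reference tree
#'
#' Accepts a Newick string or a path to a Newick file. The tree must be
#' rooted or will be interpreted as rooted at its basal (multifurcating)
#' node; leaf labels must be unique. Edge numbers are assigned 0-based in
#' preorder with children in input order, deterministically: the same text
#' always yields the same numbering. Missing branch lengths default to 0
#' with a warning.
#'
#' @param x Newick text (containing parentheses) or a file path.
#' @return An object of class `ref_tree`.
#' @export
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' n_edges(tr)  # 4
parse_newick <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  phy <- if (grepl("(", x, fixed = TRUE)) {
    ape::read.tree(text = x)
  } else {
    if (!file.exists(x)) stop("file not found: ", x, call. = FALSE)
    ape::read.tree(file = x)
  }
  if (is.null(phy)) stop("could not parse Newick input", call. = FALSE)
  if (anyDuplicated(phy$tip.label)) {
    stop("duplicate leaf labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
               collapse = ", "), call. = FALSE)
  }
  .ref_tree_from_phylo(phy)
}

#' @export
print.ref_tree <- function(x, ...) {
  cat("<ref_tree> ", x$n_tip, " leaves, ", n_edges(x), " edges\n", sep = "")
  cat("  ", write_newick(x), "\n", sep = "")
  invisible(x)
}

#' Number of edges in a reference tree
#' @param tree A `ref_tree`.
#' @return Integer edge count.
#' @export
n_edges <- function(tree) sum(!is.na(tree$edge_num))

#' Leaf labels of a reference tree
#' @param tree A `ref_tree`.
#' @return Character vector of leaf labels in tip-id order.
#' @export
tree_leaves <- function(tree) tree$label[tree$is_tip]

#' Edge table of a reference tree
#'
#' @param tree A `ref_tree`.
#' @return A tibble with one row per edge: `edge_num`, `parent`, `child`
#'   (node ids), `length`, and `child_label` (NA for internal children).
#' @export
tree_edges <- function(tree) {
  child <- which(!is.na(tree$edge_num))
  ord <- order(tree$edge_num[child])
  child <- child[ord]
  tibble::tibble(
    edge_num = tree$edge_num[child],
    parent = tree$parent[child],
    child = child,
    length = tree$brlen[child],
    child_label = tree$label[child]
  )
}

# ---- node / edge resolution -------------------------------------------------

.resolve_node <- function(tree, x) {
  if (is.character(x)) {
    i <- match(x, tree$label)
    if (anyNA(i)) {
      stop("unknown label(s): ", paste(x[is.na(i)], collapse = ", "),
           call. = FALSE)
    }
    return(i)
  }
  x <- as.integer(x)
  if (any(x < 1L | x > length(tree$parent))) {
    stop("node id out of range", call. = FALSE)
  }
  x
}

#' Reference to one edge of a tree
#'
#' An edge is identified by its stable edge number and, redundantly, by the
#' node id of its child endpoint.
#'
#' @param edge_num Integer edge number (0-based).
#' @param child Node id of the child endpoint.
#' @return An object of class `sw_edge_ref`.
#' @export
edge_ref <- function(edge_num, child) {
  structure(list(edge_num = as.integer(edge_num), child = as.integer(child)),
            class = "sw_edge_ref")
}

#' @export
print.sw_edge_ref <- function(x, ...) {
  cat("<edge ", x$edge_num, " above node ", x$child, ">\n", sep = "")
  invisible(x)
}

# Accepts an sw_edge_ref or a bare edge number; returns the child node id.
.edge_child <- function(tree, e) {
  if (inherits(e, "sw_edge_ref")) {
    child <- tree$edge_child[e$edge_num + 1L]
    if (child != e$child) {
      stop("edge reference does not resolve in this tree", call. = FALSE)
    }
    return(child)
  }
  e <- as.integer(e)
  if (e < 0L || e >= n_edges(tree)) stop("edge number out of range", call. = FALSE)
  tree$edge_child[e + 1L]
}

#' Look up an edge by number
#' @param tree A `ref_tree`.
#' @param edge_num 0-based edge number.
#' @return An `sw_edge_ref`.
#' @export
edge_by_number <- function(tree, edge_num) {
  edge_ref(edge_num, .edge_child(tree, as.integer(edge_num)))
}

#' Lowest common ancestor of two leaves (or nodes)
#'
#' @param tree A `ref_tree`.
#' @param a,b Leaf labels or node ids. `lca(tree, x, x)` is `x` itself.
#' @return The node id of the deepest node ancestral to both.
#' @export
lca <- function(tree, a, b) {
  u <- .resolve_node(tree, a)
  v <- .resolve_node(tree, b)
  while (tree$depth[u] > tree$depth[v]) u <- tree$parent[u]
  while (tree$depth[v] > tree$depth[u]) v <- tree$parent[v]
  while (u != v) {
    u <- tree$parent[u]
    v <- tree$parent[v]
  }
  u
}

#' Parent edge of a node
#'
#' The unique edge connecting a node to its parent (toward the root).
#'
#' @param tree A `ref_tree`.
#' @param node Node id or leaf label.
#' @return An `sw_edge_ref`, or `NULL` if `node` is the root (the root has
#'   no parent edge; callers must handle this case).
#' @export
parent_edge <- function(tree, node) {
  v <- .resolve_node(tree, node)
  if (v == tree$root) return(NULL)
  edge_ref(tree$edge_num[v], v)
}

# Number of edges on the node path between two nodes.
.node_path_len <- function(tree, u, v) {
  d <- 0L
  while (tree$depth[u] > tree$depth[v]) {
    u <- tree$parent[u]
    d <- d + 1L
  }
  while (tree$depth[v] > tree$depth[u]) {
    v <- tree$parent[v]
    d <- d + 1L
  }
  while (u != v) {
    u <- tree$parent[u]
    v <- tree$parent[v]
    d <- d + 2L
  }
  d
}

#' Topological node distance between two edges
#'
#' The number of nodes on the path connecting the two edges: 0 for the same
#' edge, 1 for edges sharing a node, and generally one more than the number
#' of edges strictly between them. This is the accuracy metric of the
#' pruning-based evaluation.
#'
#' @param tree A `ref_tree`.
#' @param e1,e2 Edges (`sw_edge_ref` or 0-based edge numbers).
#' @return Non-negative integer.
#' @export
node_distance <- function(tree, e1, e2) {
  c1 <- .edge_child(tree, e1)
  c2 <- .edge_child(tree, e2)
  if (c1 == c2) return(0L)
  p1 <- tree$parent[c1]
  p2 <- tree$parent[c2]
  best <- min(.node_path_len(tree, c1, c2),
              .node_path_len(tree, c1, p2),
              .node_path_len(tree, p1, c2),
              .node_path_len(tree, p1, p2))
  best + 1L
}

# Weighted (branch-length) distance between two nodes.
.weighted_node_dist <- function(tree, u, v) {
  a <- lca(tree, u, v)
  d <- 0
  while (u != a) {
    d <- d + tree$brlen[u]
    u <- tree$parent[u]
  }
  while (v != a) {
    d <- d + tree$brlen[v]
    v <- tree$parent[v]
  }
  d
}

# Is node `x` in the clade below node `top` (inclusive)?
.in_clade <- function(tree, x, top) {
  while (!is.na(x)) {
    if (x == top) return(TRUE)
    x <- tree$parent[x]
  }
  FALSE
}

# Labels of the tips below a node (inclusive).
.clade_leafset <- function(tree, node) {
  out <- character(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[1]]
    stack <- stack[-1]
    if (tree$is_tip[v]) out <- c(out, tree$label[v])
    stack <- c(tree$children[[v]], stack)
  }
  sort(out)
}

#' Insert a query leaf into an edge
#'
#' Splits edge `e` into a distal piece (toward the original child, length
#' `split * l(e)`) and a proximal piece (toward the parent, length
#' `(1 - split) * l(e)`; lengths are conserved exactly), inserts a new
#' internal node between them, and attaches a new leaf `label` with an edge
#' of length `pendant`. Untouched edges keep their edge numbers; the
#' proximal piece inherits the split edge's number, and the distal piece
#' and the pendant edge receive the next free numbers.
#'
#' @param tree A `ref_tree`.
#' @param e Edge to split (`sw_edge_ref` or edge number).
#' @param split Fraction of the edge length assigned to the distal piece,
#'   in `[0, 1]`.
#' @param pendant Pendant edge length, `>= 0`.
#' @param label Label of the new leaf (must not collide with existing ones).
#' @return A new `ref_tree` with one more leaf and two more edges.
#' @export
insert_query_edge <- function(tree, e, split, pendant, label) {
  stopifnot(split >= 0, split <= 1, pendant >= 0)
  if (label %in% tree$label[tree$is_tip]) {
    stop("leaf label already present: ", label, call. = FALSE)
  }
  child <- .edge_child(tree, e)
  p <- tree$parent[child]
  len <- tree$brlen[child]
  n <- length(tree$parent)
  u <- n + 1L
  q <- n + 2L
  tr <- tree
  tr$parent <- c(tr$parent, p, u)
  tr$parent[child] <- u
  tr$children <- c(tr$children, list(c(child, q), integer(0)))
  slot <- which(tr$children[[p]] == child)
  tr$children[[p]][slot] <- u
  tr$label <- c(tr$label, NA_character_, label)
  tr$is_tip <- c(tr$is_tip, FALSE, TRUE)
  tr$n_tip <- tr$n_tip + 1L
  nxt <- n_edges(tree)
  tr$brlen <- c(tr$brlen, (1 - split) * len, pendant)
  tr$brlen[child] <- split * len
  tr$edge_num <- c(tr$edge_num, tr$edge_num[child], nxt + 1L)
  tr$edge_num[child] <- nxt
  .rebuild_index(tr)
}

# ---- serialisation ----------------------------------------------------------

.newick_node <- function(tree, v, edge_numbers) {
  ch <- tree$children[[v]]
  lab <- if (!is.na(tree$label[v])) tree$label[v] else ""
  body <- if (length(ch) == 0L) {
    lab
  } else {
    paste0("(", paste(vapply(ch, function(c) {
      .newick_node(tree, c, edge_numbers)
    }, character(1)), collapse = ","), ")", if (v != tree$root) lab else lab)
  }
  if (v == tree$root) return(paste0(body, ";"))
  s <- paste0(body, ":", sprintf("%.12g", tree$brlen[v]))
  if (edge_numbers) s <- paste0(s, "{", tree$edge_num[v], "}")
  s
}

#' Serialise a reference tree to Newick
#'
#' @param tree A `ref_tree`.
#' @param file Optional path; if given the text is written there.
#' @param edge_numbers If TRUE, append `{edge_num}` after each branch
#'   length, the edge-annotated form used inside jplace documents.
#' @return The Newick string (invisibly if `file` is given).
#' @export
write_newick <- function(tree, file = NULL, edge_numbers = FALSE) {
  txt <- .newick_node(tree, tree$root, edge_numbers)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

# ---- pruning (evaluation support) -------------------------------------------

#' Prune one leaf and report the true attachment edge(s)
#'
#' Removes a leaf, suppresses the resulting degree-2 node, and returns the
#' pruned tree (fresh preorder edge numbering) together with the edge
#' number(s) in the pruned tree where the leaf used to attach. When the
#' suppressed node merges two edges, both map to the single merged edge;
#' when the pruned leaf hung off the root, the surviving child becomes the
#' new root and every child edge of that new root counts as the
#' attachment (node distance 0 to any of them).
#'
#' @param tree A `ref_tree` with at least 3 leaves.
#' @param label Leaf label to remove.
#' @return A list with `tree` (the pruned `ref_tree`) and `true_edges`
#'   (integer vector of edge numbers).
#' @export
prune_leaf <- function(tree, label) {
  t_node <- .resolve_node(tree, label)
  if (!tree$is_tip[t_node]) stop("not a leaf: ", label, call. = FALSE)
  if (tree$n_tip < 3L) stop("pruning would leave fewer than 2 leaves", call. = FALSE)
  p <- tree$parent[t_node]
  tr <- tree
  tr$children[[p]] <- setdiff(tr$children[[p]], t_node)

  cand_sets <- list()
  if (length(tr$children[[p]]) == 1L) {
    sib <- tr$children[[p]][1]
    if (p == tree$root) {
      # new root is the sibling subtree; attachment maps to its child edges
      tr$root <- sib
      tr$parent[sib] <- NA_integer_
      tr$brlen[sib] <- NA_real_
      cand_sets <- lapply(tree$children[[sib]], function(c) {
        .clade_leafset(tree, c)
      })
      if (length(cand_sets) == 0L) {
        stop("pruning would leave a single leaf", call. = FALSE)
      }
    } else {
      pp <- tree$parent[p]
      slot <- which(tr$children[[pp]] == p)
      tr$children[[pp]][slot] <- sib
      tr$parent[sib] <- pp
      tr$brlen[sib] <- tr$brlen[sib] + tr$brlen[p]
      cand_sets <- list(.clade_leafset(tree, sib))
    }
  } else {
    # multifurcating parent: attachment neighbourhood is every edge at p
    cand_sets <- lapply(tr$children[[p]], function(c) .clade_leafset(tree, c))
    if (p != tree$root) {
      cand_sets <- c(cand_sets,
                     list(setdiff(.clade_leafset(tree, p), tree$label[t_node])))
    }
  }

  pruned <- parse_newick(write_newick(tr))
  edges <- tree_edges(pruned)
  key_of <- vapply(edges$child, function(c) {
    paste(.clade_leafset(pruned, c), collapse = "\r")
  }, character(1))
  keys <- vapply(cand_sets, paste, character(1), collapse = "\r")
  true_edges <- edges$edge_num[match(keys, key_of)]
  true_edges <- sort(unique(true_edges[!is.na(true_edges)]))
  if (length(true_edges) == 0L) {
    stop("internal error: could not locate the pruned attachment edge",
         call. = FALSE)
  }
  list(tree = pruned, true_edges = true_edges)
}
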