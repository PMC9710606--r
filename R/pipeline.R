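# High-level pipeline: sequences in, placements out.

#' @importFrom rlang .data
NULL

#' Place query reads onto a reference tree
#'
#' Runs the full pipeline: spaced-word matching between queries and
#' references ([compute_pair_stats()]), optional pooling of bag-of-reads
#' reference records onto tree leaves ([pool_reference_stats()]), and
#' per-query edge selection ([place_query()]). Deterministic for fixed
#' seeds: the result is independent of batch size, thread count and the
#' order of the query sequences.
#'
#' @param queries Named character vector of query reads (or a FASTA/FASTQ
#'   path).
#' @param references Named character vector of reference sequences (or a
#'   FASTA/FASTQ path). Record names must match tree leaves, or be mapped
#'   onto them via `taxon_map`.
#' @param tree A `ref_tree` (or a Newick string / file path).
#' @param match_config A [match_config()].
#' @param placement_config A [placement_config()].
#' @param taxon_map Optional record-to-leaf map (named character vector or
#'   TSV path) for unassembled references.
#' @return An object of class `sw_placement_result`: list with
#'   `placements` (tibble, one row per query), `stats` (per-leaf pair
#'   statistics), `tree`, and `meta`. Use [write_jplace()] to serialise.
#' @export
place_sequences <- function(queries, references, tree,
                            match_config = swplace::match_config(),
                            placement_config = swplace::placement_config(),
                            taxon_map = NULL) {
  if (is.character(tree)) tree <- parse_newick(tree)
  if (length(references) == 1L && is.null(names(references)) &&
      file.exists(references)) {
    references <- read_sequences(references)
  }
  if (length(queries) == 1L && is.null(names(queries)) &&
      file.exists(queries)) {
    queries <- read_sequences(queries)
  }
  if (is.character(taxon_map) && length(taxon_map) == 1L &&
      file.exists(taxon_map)) {
    taxon_map <- read_taxon_map(taxon_map)
  }
  leaves <- tree_leaves(tree)
  if (is.null(taxon_map)) {
    bad <- setdiff(names(references), leaves)
    if (length(bad)) {
      stop("reference record(s) without a matching tree leaf: ",
           paste(bad, collapse = ", "),
           " (supply a taxon map for bag-of-reads references)",
           call. = FALSE)
    }
  }
  stats <- compute_pair_stats(references, queries, match_config)
  stats <- pool_reference_stats(stats, taxon_map, tree)
  qids <- sort(names(queries))
  placements <- dplyr::bind_rows(lapply(qids, function(q) {
    place_query(stats[stats$query_id == q, , drop = FALSE],
                tree, placement_config, q)
  }))
  structure(
    list(
      placements = placements,
      stats = stats,
      tree = tree,
      meta = list(
        heuristic = placement_config$heuristic,
        X = placement_config$X,
        threshold = match_config$threshold,
        patterns = paste(vapply(match_config$pattern_set, render_pattern,
                                character(1)), collapse = ","),
        seed = placement_config$seed,
        n_queries = length(queries),
        n_fallback = sum(placements$fallback_root),
        skipped_windows = attr(stats, "skipped_windows") %||% 0L
      )
    ),
    class = "sw_placement_result"
  )
}

#' @export
print.sw_placement_result <- function(x, ...) {
  cat("<sw_placement_result> ", nrow(x$placements), " query read(s) placed (",
      x$meta$n_fallback, " at root), heuristic ", x$meta$heuristic,
      "\n", sep = "")
  print(x$placements)
  invisible(x)
}

#' @method tidy sw_placement_result
#' @export
tidy.sw_placement_result <- function(x, ...) x$placements

#' @method glance sw_placement_result
#' @export
glance.sw_placement_result <- function(x, ...) {
  tibble::tibble(
    n_queries = nrow(x$placements),
    n_fallback_root = sum(x$placements$fallback_root),
    n_leaf_edges = sum(!is.na(x$placements$best_ref) &
                         x$placements$heuristic %in%
                           c("minimum-distance", "spam-count")),
    mean_pendant = mean(x$placements$pendant_length),
    heuristic = x$meta$heuristic
  )
}

#' @method autoplot sw_placement_result
#' @export
autoplot.sw_placement_result <- function(object, ...) {
  counts <- dplyr::count(object$placements, .data$edge_num)
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = factor(.data$edge_num), y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "edge number", y = "reads placed",
                  title = "Placements per reference-tree edge") +
    ggplot2::theme_minimal()
}
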