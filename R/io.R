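# Sequence input, reference-to-leaf mapping (including "bag of reads"
# references, where one taxon is represented by many unassembled records),
# and jplace / TSV output.

#' Read nucleotide sequences from FASTA or FASTQ
#'
#' Record ids are the first whitespace-delimited token of each header;
#' sequences are upper-cased and U is converted to T (FASTQ qualities are
#' ignored).
#'
#' @param path Path to the sequence file.
#' @param format `"auto"` (by extension / first character), `"fasta"` or
#'   `"fastq"`.
#' @return Named character vector (id -> sequence).
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.f(ast)?q$", path, ignore.case = TRUE)) {
      "fastq"
    } else {
      first <- substr(readLines(path, n = 1L), 1, 1)
      if (identical(first, "@")) "fastq" else "fasta"
    }
  }
  set <- Biostrings::readBStringSet(path, format = format)
  if (length(set) == 0L) stop("no sequence records in ", path, call. = FALSE)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- chartr("Uu", "Tt", as.character(set))
  seqs <- toupper(seqs)
  names(seqs) <- ids
  seqs
}

#' Read a record-to-leaf mapping file
#'
#' Two tab-separated columns: record id, leaf label. Used for unassembled
#' ("bag of reads") references, where many sequence records represent one
#' reference taxon. Without a mapping, record ids must equal leaf labels.
#'
#' @param path Path to the TSV file (no header).
#' @return Named character vector (record id -> leaf label).
#' @export
read_taxon_map <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "")
  if (ncol(tab) != 2L) {
    stop("taxon map must have exactly two tab-separated columns", call. = FALSE)
  }
  if (anyDuplicated(tab[[1]])) {
    stop("duplicate record ids in taxon map", call. = FALSE)
  }
  stats::setNames(as.character(tab[[2]]), as.character(tab[[1]]))
}

#' Pool per-record pair statistics to per-leaf statistics
#'
#' For bag-of-reads references each tree leaf is represented by several
#' sequence records. Filtered-SpaM counts and don't-care column counts are
#' summed over the records of a leaf, and the mismatch proportion and
#' Jukes-Cantor distance are recomputed from the pooled counts.
#'
#' @param stats Pair-statistics tibble from [compute_pair_stats()] (per
#'   record).
#' @param taxon_map Named character vector (record id -> leaf label), or
#'   `NULL` for the identity mapping.
#' @param tree Optional `ref_tree`; if given, mapped leaf labels are
#'   validated against its leaves.
#' @return Pair-statistics tibble keyed by (query_id, leaf).
#' @export
pool_reference_stats <- function(stats, taxon_map = NULL, tree = NULL) {
  if (is.null(taxon_map)) return(stats)
  mapped <- taxon_map[stats$ref_id]
  if (anyNA(mapped)) {
    offenders <- unique(stats$ref_id[is.na(mapped)])
    stop("records not present in taxon map: ",
         paste(offenders, collapse = ", "), call. = FALSE)
  }
  if (!is.null(tree)) {
    bad <- setdiff(unique(taxon_map), tree_leaves(tree))
    if (length(bad)) {
      stop("taxon map targets absent from the tree: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  stats$ref_id <- unname(mapped)
  grp <- dplyr::group_by(stats, .data$query_id, .data$ref_id)
  out <- dplyr::summarise(grp,
                          s = as.integer(sum(.data$s)),
                          dc_columns = sum(.data$dc_columns),
                          dc_mismatches = sum(.data$dc_mismatches),
                          .groups = "drop")
  out$strand <- NA_character_
  out$p <- ifelse(out$dc_columns > 0, out$dc_mismatches / out$dc_columns, 0)
  out$d <- suppressWarnings(jukes_cantor(out$p))
  out[order(out$query_id, out$ref_id),
      c("query_id", "ref_id", "strand", "s", "dc_columns",
        "dc_mismatches", "p", "d")]
}

#' Write placements to a jplace (version 3) file
#'
#' The document pairs an edge-annotated Newick string (edge numbers in
#' braces after each branch length) with one placement record per query.
#' Fields are `edge_num`, `likelihood`, `like_weight_ratio`,
#' `distal_length`, `pendant_length`; a single placement is reported per
#' query, so likelihood is recorded as 0 and the like-weight ratio as 1.
#'
#' @param tree A `ref_tree` (or an `sw_placement_result`, in which case
#'   `placements` and metadata are taken from it).
#' @param placements Placement tibble as produced by [place_query()].
#' @param path Output path.
#' @param meta Named list stored under `metadata` (program, parameters...).
#' @return `path`, invisibly.
#' @export
write_jplace <- function(tree, placements = NULL, path, meta = list()) {
  if (inherits(tree, "sw_placement_result")) {
    res <- tree
    tree <- res$tree
    placements <- res$placements
    meta <- utils::modifyList(res$meta, meta)
  }
  stopifnot(inherits(tree, "ref_tree"))
  precs <- lapply(seq_len(NROW(placements)), function(i) {
    list(
      p = list(list(
        jsonlite::unbox(as.integer(placements$edge_num[i])),
        jsonlite::unbox(0),
        jsonlite::unbox(1),
        jsonlite::unbox(placements$distal_length[i]),
        jsonlite::unbox(placements$pendant_length[i])
      )),
      n = list(jsonlite::unbox(placements$query_id[i]))
    )
  })
  doc <- list(
    version = jsonlite::unbox(3L),
    tree = jsonlite::unbox(write_newick(tree, edge_numbers = TRUE)),
    fields = c("edge_num", "likelihood", "like_weight_ratio",
               "distal_length", "pendant_length"),
    placements = precs,
    metadata = c(list(program = jsonlite::unbox("swplace")),
                 lapply(meta, jsonlite::unbox))
  )
  jsonlite::write_json(doc, path, digits = NA, null = "null")
  invisible(path)
}

#' Read a jplace file back into a placement table
#'
#' @param path Path to a jplace (version 3) document.
#' @return A list with `tree` (the edge-annotated Newick string), `fields`,
#'   and `placements`, a tibble with one row per (query, placement):
#'   `query_id`, `edge_num`, `likelihood`, `like_weight_ratio`,
#'   `distal_length`, `pendant_length`.
#' @export
read_jplace <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (f in c("version", "tree", "fields", "placements")) {
    if (is.null(doc[[f]])) stop("jplace document lacks '", f, "'", call. = FALSE)
  }
  fields <- unlist(doc$fields)
  rows <- list()
  for (rec in doc$placements) {
    nm <- unlist(rec$n %||% rec$nm)
    for (p in rec$p) {
      v <- stats::setNames(as.numeric(unlist(p)), fields)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        query_id = nm[1],
        edge_num = as.integer(v[["edge_num"]]),
        likelihood = v[["likelihood"]],
        like_weight_ratio = v[["like_weight_ratio"]],
        distal_length = v[["distal_length"]],
        pendant_length = v[["pendant_length"]]
      )
    }
  }
  placements <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble::tibble(query_id = character(0), edge_num = integer(0),
                   likelihood = numeric(0), like_weight_ratio = numeric(0),
                   distal_length = numeric(0), pendant_length = numeric(0))
  }
  list(tree = doc$tree, fields = fields, placements = placements)
}

#' Write a human-readable placement summary TSV
#'
#' One row per query: query id, chosen edge, best reference, distance,
#' filtered-SpaM count, heuristic and whether the root fallback fired.
#'
#' @param placements Placement tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_placement_tsv <- function(placements, path) {
  cols <- c("query_id", "edge_num", "distal_length", "pendant_length",
            "best_ref", "d_best", "s_best", "heuristic", "fallback_root")
  cols <- intersect(cols, names(placements))
  utils::write.table(placements[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
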