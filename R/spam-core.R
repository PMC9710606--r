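# Spaced-word matching core. All spaced-word occurrences in the references
# (list L1) and in a batch of query reads (list L2) are sorted by the
# nucleotides at the match positions; equal-key blocks are then crossed to
# enumerate every spaced-word match (SpaM). Each SpaM is scored over its
# don't-care columns with a substitution matrix and discarded unless its
# score exceeds the threshold t; surviving ("filtered") SpaMs are treated
# as putatively homologous. Per (query, reference) pair we accumulate the
# filtered-SpaM count s, the pooled number of don't-care columns and
# mismatching columns, the mismatch proportion p, and the Jukes-Cantor
# distance d.

#' Matching configuration
#'
#' @param pattern_set Patterns to use: an `sw_pattern_set`, a single
#'   `sw_pattern`, or a character vector of binary strings. Default: the
#'   single weight-12, length-44 [default_pattern()].
#' @param threshold Score cutoff t. A SpaM is kept iff its don't-care score
#'   is strictly greater than `threshold`; default 0.
#' @param batch_size Queries processed per batch (memory control only; the
#'   result is independent of the batch size). Default 512.
#' @param seed Integer seed for downstream tie-breaking. Default 42.
#' @param matrix 4x4 symmetric substitution matrix; default [hoxd70()].
#' @param query_strands Strands enumerated for queries; references are
#'   always enumerated on the forward strand. Default both.
#' @param threads Accepted for interface compatibility; the matcher is
#'   serial and deterministic, so the value does not affect results.
#' @return A list of class `sw_match_config`.
#' @export
match_config <- function(pattern_set = default_pattern(),
                         threshold = 0,
                         batch_size = 512L,
                         seed = 42L,
                         matrix = hoxd70(),
                         query_strands = c("forward", "reverse"),
                         threads = 1L) {
  stopifnot(batch_size >= 1, threads >= 1)
  query_strands <- match.arg(query_strands, several.ok = TRUE)
  structure(
    list(
      pattern_set = as_pattern_set(pattern_set),
      threshold = threshold,
      batch_size = as.integer(batch_size),
      seed = as.integer(seed),
      matrix = matrix,
      query_strands = query_strands,
      threads = as.integer(threads)
    ),
    class = "sw_match_config"
  )
}

# ---- occurrence enumeration (internal, integer-encoded) ---------------------

# enc: integer codes (NA for non-ACGT). Returns positions (1-based), keys
# (base-4 value of the match-position nucleotides, exact as a double), and
# the don't-care columns as an integer matrix; windows containing any
# non-ACGT character are skipped and counted.
.sw_occurrences <- function(enc, pattern) {
  l <- pattern$length
  n <- length(enc)
  empty <- list(pos = integer(0),
                key = numeric(0),
                dc = matrix(integer(0), nrow = 0, ncol = l - pattern$weight),
                skipped = 0L)
  if (n < l) return(empty)
  ns <- n - l + 1L
  bad <- cumsum(c(0L, is.na(enc)))
  valid <- (bad[seq_len(ns) + l] - bad[seq_len(ns)]) == 0L
  pos <- which(valid)
  if (length(pos) == 0L) {
    empty$skipped <- ns
    return(empty)
  }
  key <- numeric(length(pos))
  for (j in pattern$match_positions) {
    key <- key * 4 + enc[pos + (j - 1L)]
  }
  ndc <- l - pattern$weight
  dc <- matrix(0L, nrow = length(pos), ncol = ndc)
  k <- 0L
  for (j in pattern$dontcare_positions) {
    k <- k + 1L
    dc[, k] <- enc[pos + (j - 1L)]
  }
  list(pos = pos, key = key, dc = dc, skipped = ns - length(pos))
}

# All (ref index, query index) pairs whose keys are equal, fully vectorised:
# both key vectors are ordered, equal-key runs located with rle/match, and
# the cross product of each run pair expanded with rep/sequence.
.key_pairs <- function(rkey, qkey) {
  if (length(rkey) == 0L || length(qkey) == 0L) return(NULL)
  ro <- order(rkey)
  qo <- order(qkey)
  rr <- rle(rkey[ro])
  qr <- rle(qkey[qo])
  m <- match(rr$values, qr$values)
  keep <- which(!is.na(m))
  if (length(keep) == 0L) return(NULL)
  nr <- rr$lengths[keep]
  nq <- qr$lengths[m[keep]]
  if (sum(as.numeric(nr) * as.numeric(nq)) > 2^31 - 1) {
    stop("spaced-word match explosion (low-complexity input?): ",
         "more than 2^31 candidate SpaMs in one block set", call. = FALSE)
  }
  rstart <- cumsum(c(0L, rr$lengths))[keep]
  qstart <- cumsum(c(0L, qr$lengths))[m[keep]]
  p <- nr * nq
  block <- rep.int(seq_along(p), p)
  within <- sequence(p) - 1L
  list(ri = ro[rstart[block] + (within %% nr[block]) + 1L],
       qi = qo[qstart[block] + (within %/% nr[block]) + 1L])
}

# Score SpaMs over their don't-care columns. rdc/qdc: integer matrices with
# one row per SpaM. Returns numeric score and integer mismatch count.
.score_dc <- function(rdc, qdc, svec) {
  n <- nrow(rdc)
  ndc <- ncol(rdc)
  if (ndc == 0L) {
    return(list(score = numeric(n), mismatches = integer(n)))
  }
  idx <- rdc * 4L + qdc + 1L
  sc <- svec[idx]
  dim(sc) <- dim(idx)
  list(score = rowSums(sc),
       mismatches = as.integer(rowSums(rdc != qdc)))
}

# ---- exported single-operation surface --------------------------------------

#' Enumerate spaced-word occurrences in one sequence
#'
#' A spaced word occurs at position i if the window `[i, i + length - 1]`
#' fits in the sequence and contains only A, C, G, T. The occurrence's key
#' is the string of nucleotides at the pattern's match positions; the
#' nucleotides at the don't-care positions are retained for later scoring.
#' For the reverse strand, occurrences are enumerated over the reverse
#' complement of the sequence and positions refer to that reverse-complement
#' coordinate system.
#'
#' @param seq A single nucleotide string.
#' @param pattern An `sw_pattern`.
#' @param strand `"forward"` or `"reverse"`.
#' @return A tibble with columns `pos` (1-based), `key` and `dontcare`
#'   (nucleotide strings), and attribute `skipped` counting windows dropped
#'   because of non-ACGT characters.
#' @export
#' @examples
#' enumerate_occurrences("ATCGAACC", parse_pattern("1101001"))
enumerate_occurrences <- function(seq, pattern,
                                  strand = c("forward", "reverse")) {
  strand <- match.arg(strand)
  stopifnot(inherits(pattern, "sw_pattern"))
  s <- if (strand == "reverse") reverse_complement(seq) else seq
  occ <- .sw_occurrences(encode_seq(s), pattern)
  w <- pattern$weight
  keys <- vapply(seq_along(occ$pos), function(i) {
    decode_codes(.decode_key(occ$key[i], w))
  }, character(1))
  dcs <- vapply(seq_along(occ$pos), function(i) {
    decode_codes(occ$dc[i, ])
  }, character(1))
  out <- tibble::tibble(pos = occ$pos, key = keys, dontcare = dcs)
  attr(out, "skipped") <- occ$skipped
  out
}

.decode_key <- function(key, weight) {
  codes <- integer(weight)
  for (j in rev(seq_len(weight))) {
    codes[j] <- as.integer(key %% 4)
    key <- (key - codes[j]) / 4
  }
  codes
}

#' Build a sorted spaced-word occurrence list for a set of sequences
#'
#' Occurrences of all sequences (and requested strands) are concatenated and
#' sorted lexicographically by key, so all occurrences of one spaced word
#' form a contiguous block. Ties within a key are ordered by (seq_id,
#' strand, pos) so runs are reproducible.
#'
#' @param seqs Named character vector (id -> nucleotide sequence).
#' @param pattern An `sw_pattern`.
#' @param strands Strands to enumerate (`"forward"`, `"reverse"`).
#' @return An object of class `sw_occurrence_list`: a tibble with columns
#'   `seq_id`, `strand`, `pos`, `key`, `dontcare`, sorted by `key`, with the
#'   pattern attached as attribute `pattern`.
#' @export
build_occurrence_list <- function(seqs, pattern, strands = "forward") {
  stopifnot(inherits(pattern, "sw_pattern"), is.character(seqs))
  ids <- names(seqs)
  if (is.null(ids) || any(ids == "") || anyNA(ids)) {
    stop("sequences must be named", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  strands <- match.arg(strands, c("forward", "reverse"), several.ok = TRUE)
  parts <- list()
  for (st in strands) {
    for (id in ids) {
      occ <- enumerate_occurrences(seqs[[id]], pattern, st)
      if (nrow(occ) > 0L) {
        parts[[length(parts) + 1L]] <-
          tibble::tibble(seq_id = id, strand = st,
                         pos = occ$pos, key = occ$key, dontcare = occ$dontcare)
      }
    }
  }
  out <- if (length(parts)) dplyr::bind_rows(parts) else {
    tibble::tibble(seq_id = character(0), strand = character(0),
                   pos = integer(0), key = character(0), dontcare = character(0))
  }
  out <- out[order(out$key, out$seq_id, out$strand, out$pos), , drop = FALSE]
  out <- structure(out, pattern = pattern,
                   class = c("sw_occurrence_list", class(out)))
  out
}

#' Score one spaced-word match over its don't-care columns
#'
#' @param ref_dc,query_dc Equal-length nucleotide strings: the don't-care
#'   columns of the reference and query occurrence.
#' @param matrix 4x4 substitution matrix, default [hoxd70()].
#' @return A list with `score` (sum of substitution scores over the
#'   don't-care columns) and `mismatches` (number of differing columns).
#' @export
#' @examples
#' score_spam("A", "A")  # score 91, 0 mismatches
#' score_spam("A", "G")  # score -31, 1 mismatch
score_spam <- function(ref_dc, query_dc, matrix = hoxd70()) {
  if (nchar(ref_dc) != nchar(query_dc)) {
    stop("don't-care strings must have equal length", call. = FALSE)
  }
  if (nchar(ref_dc) == 0L) return(list(score = 0, mismatches = 0L))
  r <- encode_seq(ref_dc)
  q <- encode_seq(query_dc)
  if (anyNA(r) || anyNA(q)) {
    stop("don't-care strings may contain only A, C, G, T", call. = FALSE)
  }
  res <- .score_dc(matrix(r, nrow = 1), matrix(q, nrow = 1), .score_vec(matrix))
  list(score = res$score[1], mismatches = res$mismatches[1])
}

#' Jukes-Cantor distance from a mismatch proportion
#'
#' `d = -(3/4) * log(1 - (4/3) * p)` for `p < 0.75`. At or beyond the
#' saturation boundary `p >= 0.75` the formula is undefined and the
#' documented sentinel distance (default 5) is returned with a warning;
#' such pairs still participate in distance minimisation but can never win
#' against an unsaturated pair in realistic data.
#'
#' @param p Mismatch proportion(s) in `[0, 1]`.
#' @param saturation Sentinel distance returned for `p >= 0.75`.
#' @return Jukes-Cantor distance(s), `>= 0`.
#' @export
#' @examples
#' jukes_cantor(0)    # 0
#' jukes_cantor(0.1)  # ~0.1073
jukes_cantor <- function(p, saturation = 5) {
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("mismatch proportion must lie in [0, 1]", call. = FALSE)
  }
  d <- numeric(length(p))
  sat <- p >= 0.75
  if (any(sat)) {
    warning(sum(sat), " mismatch proportion(s) at or beyond the ",
            "Jukes-Cantor saturation boundary (p >= 0.75); returning ",
            "sentinel distance ", saturation, call. = FALSE)
    d[sat] <- saturation
  }
  d[!sat] <- -0.75 * log(1 - (4 / 3) * p[!sat])
  d
}

# ---- pair statistics --------------------------------------------------------

# Internal block-matching over encoded occurrence sets.
# refs: list(key, dc, sid) pooled across reference sequences;
# qrys: list(key, dc, sid, strand) pooled across a query batch.
# Returns an aggregate matrix keyed by gid = ((q-1)*NR + (r-1))*2 + strand.
.match_aggregate <- function(refs, qrys, n_ref, threshold, svec) {
  pr <- .key_pairs(refs$key, qrys$key)
  if (is.null(pr)) return(NULL)
  sc <- .score_dc(refs$dc[pr$ri, , drop = FALSE],
                  qrys$dc[pr$qi, , drop = FALSE], svec)
  keep <- sc$score > threshold
  if (!any(keep)) return(NULL)
  ri <- refs$sid[pr$ri[keep]]
  qi <- qrys$sid[pr$qi[keep]]
  st <- qrys$strand[pr$qi[keep]]
  ndc <- ncol(refs$dc)
  gid <- ((as.numeric(qi) - 1) * n_ref + (ri - 1)) * 2 + st
  agg <- rowsum(cbind(s = rep(1, sum(keep)),
                      cols = rep(ndc, sum(keep)),
                      mism = sc$mismatches[keep]),
                group = gid)
  cbind(gid = as.numeric(rownames(agg)), agg)
}

#' Filter and aggregate spaced-word matches between two occurrence lists
#'
#' Traverses two occurrence lists built with the same pattern, scores every
#' cross pair within each equal-key block, discards SpaMs with score `<=
#' threshold`, and pools the survivors per (query, reference, strand):
#' filtered-SpaM count `s`, total and mismatching don't-care columns, the
#' pooled mismatch proportion `p`, and the Jukes-Cantor distance `d`. A
#' query occurrence may match many reference occurrences and vice versa.
#'
#' @param L1 Reference occurrence list (from [build_occurrence_list()]).
#' @param L2 Query occurrence list built with the same pattern.
#' @param config An [match_config()] (only `threshold` and `matrix` used).
#' @param keep_matches If TRUE, attach the individual filtered SpaMs as
#'   attribute `"matches"` (a tibble with positions, scores, mismatches).
#' @return A tibble with one row per (query_id, ref_id, strand) pair having
#'   `s > 0`: columns `query_id`, `ref_id`, `strand`, `s`, `dc_columns`,
#'   `dc_mismatches`, `p`, `d`.
#' @export
match_and_filter <- function(L1, L2, config = match_config(),
                             keep_matches = FALSE) {
  stopifnot(inherits(L1, "sw_occurrence_list"),
            inherits(L2, "sw_occurrence_list"))
  p1 <- attr(L1, "pattern")
  p2 <- attr(L2, "pattern")
  if (render_pattern(p1) != render_pattern(p2)) {
    stop("occurrence lists were built with different patterns", call. = FALSE)
  }
  svec <- .score_vec(config$matrix)
  rkey <- L1$key
  qkey <- L2$key
  pr <- .key_pairs(rkey, qkey)
  out0 <- tibble::tibble(query_id = character(0), ref_id = character(0),
                         strand = character(0), s = integer(0),
                         dc_columns = numeric(0), dc_mismatches = numeric(0),
                         p = numeric(0), d = numeric(0))
  if (is.null(pr)) return(out0)
  ndc <- p1$length - p1$weight
  enc_rows <- function(x) {
    if (ndc == 0L) return(matrix(integer(0), nrow = length(x), ncol = 0))
    m <- vapply(x, function(s) encode_seq(s), integer(ndc))
    matrix(m, nrow = length(x), ncol = ndc, byrow = TRUE)
  }
  rdc <- enc_rows(L1$dontcare[pr$ri])
  qdc <- enc_rows(L2$dontcare[pr$qi])
  sc <- .score_dc(rdc, qdc, svec)
  keep <- sc$score > config$threshold
  if (!any(keep)) return(out0)
  det <- tibble::tibble(
    query_id = L2$seq_id[pr$qi[keep]],
    ref_id = L1$seq_id[pr$ri[keep]],
    strand = L2$strand[pr$qi[keep]],
    query_pos = L2$pos[pr$qi[keep]],
    ref_pos = L1$pos[pr$ri[keep]],
    score = sc$score[keep],
    mismatches = sc$mismatches[keep]
  )
  grp <- dplyr::group_by(det, .data$query_id, .data$ref_id, .data$strand)
  out <- dplyr::summarise(grp,
                          s = dplyr::n(),
                          dc_columns = as.numeric(dplyr::n()) * ndc,
                          dc_mismatches = as.numeric(sum(.data$mismatches)),
                          .groups = "drop")
  out$p <- ifelse(out$dc_columns > 0, out$dc_mismatches / out$dc_columns, 0)
  out$d <- suppressWarnings(jukes_cantor(out$p))
  out <- out[order(out$query_id, out$ref_id, out$strand), , drop = FALSE]
  if (keep_matches) attr(out, "matches") <- det
  out
}

#' Compute per-pair statistics between queries and references
#'
#' The full matching pipeline: reference occurrence lists are built once per
#' pattern; queries are processed in batches; counts are accumulated across
#' all patterns in the set (s, don't-care columns and mismatches are summed
#' before the pooled mismatch proportion is formed). Queries are enumerated
#' on the requested strands and, per (query, reference) pair, the strand
#' with the larger filtered-SpaM count is kept (ties go to the forward
#' strand). The result is independent of batch size, thread count and input
#' order.
#'
#' @param references Named character vector of reference sequences.
#' @param queries Named character vector of query reads (may be empty).
#' @param config An [match_config()].
#' @return A tibble with one row per (query, reference) pair with `s > 0`:
#'   `query_id`, `ref_id`, `strand`, `s`, `dc_columns`, `dc_mismatches`,
#'   `p`, `d`, sorted by (query_id, ref_id). Pairs without any filtered
#'   SpaM are absent (their distance is treated as infinite downstream).
#'   Attribute `"skipped_windows"` counts windows dropped for non-ACGT
#'   characters.
#' @export
compute_pair_stats <- function(references, queries, config = match_config()) {
  stopifnot(is.character(references), length(references) >= 1)
  ids_r <- names(references)
  if (is.null(ids_r) || anyDuplicated(ids_r)) {
    stop("references must be uniquely named", call. = FALSE)
  }
  empty <- tibble::tibble(query_id = character(0), ref_id = character(0),
                          strand = character(0), s = integer(0),
                          dc_columns = numeric(0), dc_mismatches = numeric(0),
                          p = numeric(0), d = numeric(0))
  if (length(queries) == 0L) {
    attr(empty, "skipped_windows") <- 0L
    return(empty)
  }
  ids_q <- names(queries)
  if (is.null(ids_q) || anyDuplicated(ids_q)) {
    stop("queries must be uniquely named", call. = FALSE)
  }
  svec <- .score_vec(config$matrix)
  n_ref <- length(references)
  skipped <- 0L
  # stable global query indexing: sorted ids, so results are order-invariant
  q_order <- order(ids_q)
  strand_codes <- c(forward = 0L, reverse = 1L)
  use_strands <- strand_codes[config$query_strands]

  enc_refs <- lapply(references, encode_seq)
  aggs <- list()
  for (pat in config$pattern_set) {
    # pooled reference occurrences for this pattern
    rocc <- vector("list", n_ref)
    for (i in seq_len(n_ref)) {
      o <- .sw_occurrences(enc_refs[[i]], pat)
      skipped <- skipped + o$skipped
      rocc[[i]] <- o
    }
    refs <- list(
      key = unlist(lapply(rocc, `[[`, "key"), use.names = FALSE),
      dc = do.call(rbind, lapply(rocc, `[[`, "dc")),
      sid = rep(seq_len(n_ref),
                vapply(rocc, function(o) length(o$pos), integer(1)))
    )
    if (length(refs$key) == 0L) next
    # batched queries
    batch_starts <- seq(1L, length(queries), by = config$batch_size)
    for (b in batch_starts) {
      idx <- q_order[seq(b, min(b + config$batch_size - 1L, length(queries)))]
      qparts <- list()
      for (qi in idx) {
        for (st in use_strands) {
          s <- if (st == 1L) reverse_complement(queries[[qi]]) else queries[[qi]]
          o <- .sw_occurrences(encode_seq(s), pat)
          skipped <- skipped + o$skipped
          if (length(o$pos) > 0L) {
            qparts[[length(qparts) + 1L]] <-
              list(key = o$key, dc = o$dc,
                   sid = rep(qi, length(o$pos)),
                   strand = rep(st, length(o$pos)))
          }
        }
      }
      if (length(qparts) == 0L) next
      qrys <- list(
        key = unlist(lapply(qparts, `[[`, "key"), use.names = FALSE),
        dc = do.call(rbind, lapply(qparts, `[[`, "dc")),
        sid = unlist(lapply(qparts, `[[`, "sid"), use.names = FALSE),
        strand = unlist(lapply(qparts, `[[`, "strand"), use.names = FALSE)
      )
      a <- .match_aggregate(refs, qrys, n_ref, config$threshold, svec)
      if (!is.null(a)) aggs[[length(aggs) + 1L]] <- a
    }
  }

  if (length(aggs) == 0L) {
    attr(empty, "skipped_windows") <- skipped
    return(empty)
  }
  all <- do.call(rbind, aggs)
  agg <- rowsum(all[, c("s", "cols", "mism"), drop = FALSE], group = all[, "gid"])
  gid <- as.numeric(rownames(agg))
  strand <- gid %% 2
  qr <- (gid - strand) / 2
  ri <- (qr %% n_ref) + 1
  qi <- (qr - (ri - 1)) / n_ref + 1
  res <- tibble::tibble(
    query_id = ids_q[qi],
    ref_id = ids_r[ri],
    strand = ifelse(strand == 0, "forward", "reverse"),
    s = as.integer(unname(agg[, "s"])),
    dc_columns = unname(agg[, "cols"]),
    dc_mismatches = unname(agg[, "mism"])
  )
  # best strand per (query, ref): larger s wins, tie -> forward
  res <- res[order(res$query_id, res$ref_id,
                   -res$s, res$strand != "forward"), , drop = FALSE]
  res <- res[!duplicated(res[, c("query_id", "ref_id")]), , drop = FALSE]
  res$p <- ifelse(res$dc_columns > 0, res$dc_mismatches / res$dc_columns, 0)
  res$d <- suppressWarnings(jukes_cantor(res$p))
  res <- res[order(res$query_id, res$ref_id), , drop = FALSE]
  attr(res, "skipped_windows") <- skipped
  res
}
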