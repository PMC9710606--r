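# The HOXD70 empirical nucleotide substitution score matrix (Chiaromonte,
# Yap & Miller 2002). High-scoring don't-care columns separate homologous
# spaced-word matches from the random background.

#' HOXD70 nucleotide substitution matrix
#'
#' Symmetric 4x4 integer score table over A, C, G, T. Diagonal entries are
#' 91 (A,T) and 100 (C,G); transitions score -31 (A:G) and -31 (C:T);
#' transversions -114 (A:C, G:T), -123 (A:T) and -125 (C:G).
#'
#' @return A 4x4 integer matrix with dimnames A,C,G,T.
#' @export
#' @examples
#' hoxd70()["A", "A"]  # 91
#' hoxd70()["A", "G"]  # -31
hoxd70 <- function() {
  m <- matrix(
    c(  91, -114,  -31, -123,
      -114,  100, -125,  -31,
       -31, -125,  100, -114,
      -123,  -31, -114,   91),
    nrow = 4, byrow = TRUE,
    dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
  )
  storage.mode(m) <- "integer"
  m
}

#' Read a user substitution matrix from a 16-entry table file
#'
#' The file holds a whitespace-delimited 4x4 numeric table in A, C, G, T
#' row/column order (optionally with row/column labels). The matrix must be
#' symmetric.
#'
#' @param path Path to the table file.
#' @return A 4x4 numeric matrix with dimnames A,C,G,T.
#' @export
read_score_matrix <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) == 5L) tab <- tab[, -1, drop = FALSE]     # row labels
  if (!all(vapply(tab, is.numeric, logical(1)))) {
    tab <- tab[-1, , drop = FALSE]                         # header row slipped in
    tab[] <- lapply(tab, as.numeric)
  }
  if (nrow(tab) != 4L || ncol(tab) != 4L) {
    stop("substitution matrix file must contain a 4x4 table (16 entries)",
         call. = FALSE)
  }
  m <- as.matrix(tab)
  dimnames(m) <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
  if (!isSymmetric(unname(m))) {
    stop("substitution matrix must be symmetric", call. = FALSE)
  }
  m
}

# Flatten a 4x4 score matrix into the length-16 lookup used by the matcher:
# index = ref_code * 4 + query_code + 1, codes A=0 C=1 G=2 T=3.
.score_vec <- function(matrix) {
  stopifnot(is.matrix(matrix), all(dim(matrix) == c(4L, 4L)))
  as.numeric(t(matrix))
}
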