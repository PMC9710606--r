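# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. Keeps user-visible RNG untouched and
# makes every seeded operation independent of call order.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# Deterministic small hash of a string, folded with a base seed. Used to give
# each query its own tie-breaking stream regardless of processing order.
seed_for_id <- function(seed, id) {
  h <- 0
  for (v in utf8ToInt(id)) h <- (h * 131 + v) %% 2147483563
  as.integer((h + as.numeric(seed)) %% 2147483563) + 1L
}

# Nucleotide encoding: A=0, C=1, G=2, T=3, anything else NA.
.nt_codes <- local({
  x <- rep(NA_integer_, 256L)
  x[utf8ToInt("A")] <- 0L
  x[utf8ToInt("C")] <- 1L
  x[utf8ToInt("G")] <- 2L
  x[utf8ToInt("T")] <- 3L
  x[utf8ToInt("a")] <- 0L
  x[utf8ToInt("c")] <- 1L
  x[utf8ToInt("g")] <- 2L
  x[utf8ToInt("t")] <- 3L
  x
})

.nt_letters <- c("A", "C", "G", "T")

encode_seq <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) return(integer(0))
  .nt_codes[utf8ToInt(seq)]
}

decode_codes <- function(codes) {
  if (length(codes) == 0L) return("")
  paste(.nt_letters[codes + 1L], collapse = "")
}

#' Reverse complement of a nucleotide string
#'
#' Complements IUPAC nucleotide codes and reverses the sequence. Characters
#' outside the IUPAC alphabet are left unchanged (they can never seed a
#' spaced-word occurrence anyway).
#'
#' @param seq A single character string.
#' @return The reverse-complemented string.
#' @export
#' @examples
#' reverse_complement("ACGT")
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  comp <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                 "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", seq)
  intToUtf8(rev(utf8ToInt(comp)))
}
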