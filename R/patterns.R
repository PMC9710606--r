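# Binary spaced-seed patterns: a template over {match, don't-care} positions.
# Match positions ('1') force nucleotide identity between two sequences; the
# don't-care positions ('0') tolerate mismatches and carry the filtering
# signal. The number of match positions is the pattern's weight.

new_pattern <- function(template) {
  structure(
    list(
      template = template,
      length = length(template),
      weight = sum(template),
      match_positions = which(template),
      dontcare_positions = which(!template)
    ),
    class = "sw_pattern"
  )
}

#' Parse a binary pattern string
#'
#' A pattern is written as a string of '1' (match position) and '0'
#' (don't-care position), e.g. `"1101001"`. Canonical form requires the
#' first character to be '1': a leading don't-care position is equivalent to
#' a shorter, shifted pattern and is rejected to avoid duplicate semantics.
#'
#' @param text A non-empty string over `{0,1}` starting with '1'.
#' @return An object of class `sw_pattern` with fields `template`, `length`,
#'   `weight`, `match_positions` and `dontcare_positions` (1-based).
#' @export
#' @examples
#' p <- parse_pattern("1101001")
#' p$weight           # 4
#' p$match_positions  # 1 2 4 7
parse_pattern <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (nchar(text) == 0L) stop("pattern string must be non-empty", call. = FALSE)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  if (!all(chars %in% c("0", "1"))) {
    stop("pattern string may contain only '0' and '1': ", text, call. = FALSE)
  }
  template <- chars == "1"
  if (!template[1]) {
    stop("pattern must start with a match position ('1'); got: ", text,
         call. = FALSE)
  }
  new_pattern(template)
}

#' Render a pattern back to its binary string
#'
#' @param pattern An `sw_pattern`.
#' @return The binary string such that `parse_pattern(render_pattern(p))`
#'   reproduces `p`.
#' @export
render_pattern <- function(pattern) {
  stopifnot(inherits(pattern, "sw_pattern"))
  paste(ifelse(pattern$template, "1", "0"), collapse = "")
}

#' @export
print.sw_pattern <- function(x, ...) {
  cat("<sw_pattern> ", render_pattern(x),
      "  (length ", x$length, ", weight ", x$weight, ")\n", sep = "")
  invisible(x)
}

#' @export
format.sw_pattern <- function(x, ...) render_pattern(x)

# The default template: weight 12, 32 don't-care positions (length 44),
# first and last positions are matches. The arrangement of the interior
# match positions is an arbitrary fixed literal; placement accuracy is
# insensitive to the particular arrangement.
.default_pattern_literal <-
  "10001000100001000100001000100010001001001001"

#' The default spaced-seed pattern
#'
#' A fixed pattern of length 44 with 12 match positions and 32 don't-care
#' positions, the default used throughout the package. Pure constant:
#' repeated calls return identical objects.
#'
#' @return An `sw_pattern` of weight 12 and length 44.
#' @export
#' @examples
#' default_pattern()$weight  # 12
default_pattern <- function() {
  parse_pattern(.default_pattern_literal)
}

#' Generate a seeded set of distinct canonical patterns
#'
#' Interior match positions are sampled uniformly; the first and last
#' positions are always matches, so every generated pattern is canonical and
#' no shorter shifted duplicate can occur. With `n = 1`, `weight = 12` and
#' `dontcare = 32` the set is pinned to [default_pattern()] so the single-
#' pattern default is reproducible.
#'
#' @param n Number of distinct patterns (>= 1).
#' @param weight Number of match positions per pattern (>= 2).
#' @param dontcare Number of don't-care positions per pattern (>= 0).
#' @param seed Integer seed; the same seed always yields the same set.
#' @return A `sw_pattern_set`: a list of `sw_pattern`s, pairwise distinct,
#'   all of the same weight.
#' @export
#' @examples
#' ps <- generate_pattern_set(3, 8, 10, seed = 7)
#' length(ps)
generate_pattern_set <- function(n, weight, dontcare, seed = 42L) {
  stopifnot(n >= 1, weight >= 2, dontcare >= 0)
  len <- weight + dontcare
  # Distinct canonical patterns with fixed ends: choose weight-2 interior
  # match positions out of len-2 slots.
  capacity <- choose(len - 2L, weight - 2L)
  if (n > capacity) {
    stop("requested ", n, " patterns but only ", capacity,
         " distinct canonical patterns of weight ", weight,
         " and length ", len, " exist", call. = FALSE)
  }
  if (n == 1L && weight == 12L && dontcare == 32L) {
    return(new_pattern_set(list(default_pattern())))
  }
  pats <- with_seed(seed, {
    seen <- character(0)
    out <- vector("list", n)
    k <- 0L
    while (k < n) {
      template <- logical(len)
      template[1L] <- TRUE
      template[len] <- TRUE
      if (weight > 2L && len > 2L) {
        template[sample(seq(2L, len - 1L), weight - 2L)] <- TRUE
      }
      key <- paste(as.integer(template), collapse = "")
      if (!key %in% seen) {
        k <- k + 1L
        seen <- c(seen, key)
        out[[k]] <- new_pattern(template)
      }
    }
    out
  })
  new_pattern_set(pats)
}

new_pattern_set <- function(patterns) {
  stopifnot(length(patterns) >= 1)
  w <- vapply(patterns, function(p) p$weight, integer(1))
  if (length(unique(w)) != 1L) {
    stop("all patterns in a set must have the same weight", call. = FALSE)
  }
  keys <- vapply(patterns, render_pattern, character(1))
  if (anyDuplicated(keys)) {
    stop("patterns in a set must be pairwise distinct", call. = FALSE)
  }
  structure(patterns, class = "sw_pattern_set")
}

#' Build a pattern set from explicit binary strings
#'
#' @param texts Character vector of binary pattern strings.
#' @return A `sw_pattern_set`.
#' @export
pattern_set <- function(texts) {
  new_pattern_set(lapply(texts, parse_pattern))
}

#' @export
print.sw_pattern_set <- function(x, ...) {
  cat("<sw_pattern_set> ", length(x), " pattern(s), weight ",
      x[[1]]$weight, "\n", sep = "")
  for (p in x) cat("  ", render_pattern(p), "\n", sep = "")
  invisible(x)
}

as_pattern_set <- function(x) {
  if (inherits(x, "sw_pattern_set")) return(x)
  if (inherits(x, "sw_pattern")) return(new_pattern_set(list(x)))
  if (is.character(x)) return(pattern_set(x))
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as a pattern set", call. = FALSE)
}
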