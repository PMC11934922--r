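#' Construct a secondary structure
#'
#' A nested (pseudoknot-free) RNA secondary structure: a set of base pairs
#' `(i, j)` with `1 <= i < j <= length`, each index in at most one pair, no
#' crossing pairs, and at least `min_hairpin` unpaired nucleotides enclosed by
#' every pair.
#'
#' @param length Number of nucleotides (positive integer).
#' @param pairs Two-column integer matrix of base pairs (one row per pair,
#'   `i < j`), or `NULL`/zero-row matrix for the open chain.
#' @param sequence Optional nucleotide string (RNA alphabet) of length
#'   `length`.
#' @param min_hairpin Minimal number of unpaired nucleotides in a hairpin
#'   loop (default 3).
#' @return An object of class `secondary_structure` with fields `length`,
#'   `pairs` (sorted two-column matrix) and `sequence`.
#' @export
secondary_structure <- function(length, pairs = NULL, sequence = NULL,
                                min_hairpin = 3L) {
  length <- as.integer(length)
  if (is.na(length) || length < 1L) stop("length must be a positive integer")
  if (is.null(pairs) || NROW(pairs) == 0L) {
    pairs <- matrix(integer(0), ncol = 2L)
  } else {
    pairs <- matrix(as.integer(pairs), ncol = 2L)
    bad <- pairs[, 1L] >= pairs[, 2L] | pairs[, 1L] < 1L | pairs[, 2L] > length
    if (any(bad)) stop("invalid base pair indices")
    idx <- c(pairs)
    if (anyDuplicated(idx)) stop("an index occurs in more than one pair")
    if (any(pairs[, 2L] - pairs[, 1L] - 1L < min_hairpin))
      stop("hairpin loop shorter than min_hairpin")
    pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
    if (NROW(pairs) > 1L) {
      # nestedness: with pairs sorted by i, a crossing is j_k in (i_l, j_l)
      # for some enclosing-open pair l < k with i_l < i_k < j_l < j_k
      op <- pairs[, 1L]; cl <- pairs[, 2L]
      for (k in seq_len(NROW(pairs) - 1L)) {
        inner <- which(op > op[k] & op < cl[k])
        if (any(cl[inner] > cl[k])) stop("crossing base pairs (not nested)")
      }
    }
  }
  if (!is.null(sequence)) {
    sequence <- toupper(gsub("T", "U", as.character(sequence)[1L]))
    if (nchar(sequence) != length)
      stop("sequence length does not match declared length")
  }
  structure(list(length = length, pairs = pairs, sequence = sequence),
            class = "secondary_structure")
}

#' Parse a dot-bracket string
#'
#' @param text String over the alphabet `.`, `(`, `)`.
#' @param sequence Optional nucleotide string attached to the result.
#' @return A [secondary_structure()].
#' @export
#' @examples
#' parse_dotbracket("((...))")
parse_dotbracket <- function(text, sequence = NULL) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c(".", "(", ")"))
  if (length(bad))
    stop("invalid dot-bracket character at index ", bad[1L])
  stack <- integer(0)
  pairs <- matrix(integer(0), ncol = 2L)
  for (k in seq_along(chars)) {
    if (chars[k] == "(") {
      stack <- c(stack, k)
    } else if (chars[k] == ")") {
      if (!length(stack))
        stop("unbalanced dot-bracket string at index ", k)
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pairs <- rbind(pairs, c(i, k))
    }
  }
  if (length(stack))
    stop("unbalanced dot-bracket string at index ", stack[1L])
  secondary_structure(length(chars), pairs, sequence = sequence,
                      min_hairpin = 0L)
}

#' Serialize a structure to dot-bracket notation
#'
#' @param x A [secondary_structure()].
#' @return A dot-bracket string.
#' @export
as_dotbracket <- function(x) {
  stopifnot(inherits(x, "secondary_structure"))
  out <- rep(".", x$length)
  if (NROW(x$pairs)) {
    out[x$pairs[, 1L]] <- "("
    out[x$pairs[, 2L]] <- ")"
  }
  paste(out, collapse = "")
}

#' Pairing partner vector
#'
#' @param x A [secondary_structure()].
#' @return Integer vector `p` with `p[i]` the partner of position `i`, or 0
#'   when unpaired.
#' @export
partner_vector <- function(x) {
  stopifnot(inherits(x, "secondary_structure"))
  p <- integer(x$length)
  if (NROW(x$pairs)) {
    p[x$pairs[, 1L]] <- x$pairs[, 2L]
    p[x$pairs[, 2L]] <- x$pairs[, 1L]
  }
  p
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat("Secondary structure:", x$length, "nt,", NROW(x$pairs), "base pairs\n")
  if (!is.null(x$sequence)) cat(x$sequence, "\n")
  cat(as_dotbracket(x), "\n")
  invisible(x)
}

#' Base-pair distance between two structures
#'
#' The size of the symmetric difference of the two pair sets — the standard
#' metric on secondary structures of the same molecule.
#'
#' @param s1,s2 [secondary_structure()] objects of equal length.
#' @return Nonnegative integer.
#' @export
bp_distance <- function(s1, s2) {
  stopifnot(inherits(s1, "secondary_structure"),
            inherits(s2, "secondary_structure"))
  if (s1$length != s2$length) stop("structures have different lengths")
  k1 <- .pair_keys(s1)
  k2 <- .pair_keys(s2)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

.pair_keys <- function(s) {
  if (!NROW(s$pairs)) return(integer(0))
  (s$pairs[, 1L] - 1L) * s$length + s$pairs[, 2L]
}
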