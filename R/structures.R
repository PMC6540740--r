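#' RNA sequence object
#'
#' Creates a validated RNA sequence. `T`/`t` are silently converted to `U`
#' and lowercase letters are uppercased, so DNA-alphabet FASTA deposits are
#' accepted. Any character outside `A,U,G,C,T` (either case) is rejected:
#' the pairing-matrix encoding has no wildcard semantics, so ambiguity codes
#' such as `N` cannot be given a pairing weight.
#'
#' @param bases Character scalar, the sequence.
#' @param id Identifier string.
#' @return An object of class `rna_sequence` with elements `id`, `bases`
#'   (normalized string) and `n` (length). All indices in this package are
#'   1-based.
#' @export
#' @examples
#' rna_sequence("gattc", id = "x")$bases  # "GAUUC"
rna_sequence <- function(bases, id = "seq") {
  stopifnot(is.character(bases), length(bases) == 1L, !is.na(bases))
  b <- toupper(bases)
  b <- gsub("T", "U", b, fixed = TRUE)
  bad <- regmatches(b, regexpr("[^AUGC]", b))
  if (length(bad) > 0) {
    stop("invalid base '", bad, "' in sequence '", id,
         "': alphabet is A, U, G, C (T accepted and converted to U)")
  }
  n <- nchar(b)
  if (n < 1L) stop("empty sequence '", id, "'")
  structure(list(id = as.character(id), bases = b, n = n),
            class = "rna_sequence")
}

#' @export
print.rna_sequence <- function(x, ...) {
  cat(sprintf("<rna_sequence> %s (%d nt)\n", x$id, x$n))
  cat(x$bases, "\n")
  invisible(x)
}

# Integer codes 1..4 for A,U,G,C; used by the encoder and generators.
.BASE_ALPHABET <- c("A", "U", "G", "C")

base_codes <- function(seq) {
  match(strsplit(seq$bases, "", fixed = TRUE)[[1]], .BASE_ALPHABET)
}

#' RNA secondary structure object
#'
#' A secondary structure is a set of base pairs `(i, j)` with
#' `1 <= i < j <= n`, at most one partner per position. Structures are
#' nested unless explicitly flagged pseudoknotted; plain dot-bracket
#' serialization is only defined for nested structures.
#'
#' @param pairs Two-column matrix (or empty) of 1-based pair indices; rows
#'   are normalized so the first column is the smaller index.
#' @param n Sequence length.
#' @return An object of class `rna_structure` with elements `pairs` (sorted
#'   two-column integer matrix), `n` and `pseudoknotted` (logical, computed
#'   from the pair set).
#' @export
rna_structure <- function(pairs, n) {
  n <- as.integer(n)
  if (is.null(pairs) || length(pairs) == 0L) {
    pairs <- matrix(integer(0), ncol = 2)
  }
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (nrow(pairs) > 0) {
    pairs <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
    if (any(pairs[, 1] < 1L) || any(pairs[, 2] > n)) {
      stop("pair index outside [1, ", n, "]")
    }
    if (any(pairs[, 1] == pairs[, 2])) stop("a base cannot pair with itself")
    idx <- c(pairs)
    if (anyDuplicated(idx)) {
      stop("position ", idx[duplicated(idx)][1],
           " participates in more than one pair")
    }
    pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  }
  structure(list(pairs = pairs, n = n,
                 pseudoknotted = is_pseudoknotted(pairs)),
            class = "rna_structure")
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(sprintf("<rna_structure> n=%d, %d pairs%s\n", x$n, nrow(x$pairs),
              if (x$pseudoknotted) " (pseudoknotted)" else ""))
  if (!x$pseudoknotted) cat(to_dotbracket(x), "\n")
  invisible(x)
}

#' Detect pseudoknots (crossing base pairs)
#'
#' Two pairs `(i, j)` and `(k, l)` cross when `i < k < j < l`; a structure
#' containing a crossing cannot be drawn as a nested set of arcs nor written
#' in plain dot-bracket notation. This is the quadratic all-pairs check.
#'
#' @param pairs Two-column matrix of pair indices (or an `rna_structure`).
#' @return `TRUE` if any two pairs cross.
#' @export
#' @examples
#' is_pseudoknotted(rbind(c(1, 10), c(2, 9)))  # FALSE, nested
#' is_pseudoknotted(rbind(c(1, 5), c(3, 8)))   # TRUE, crossing
is_pseudoknotted <- function(pairs) {
  if (inherits(pairs, "rna_structure")) pairs <- pairs$pairs
  if (is.null(pairs) || length(pairs) == 0L) return(FALSE)
  pairs <- matrix(as.integer(pairs), ncol = 2)
  p <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  m <- nrow(p)
  if (m < 2L) return(FALSE)
  for (a in seq_len(m - 1L)) {
    i <- p[a, 1]; j <- p[a, 2]
    k <- p[-seq_len(a), 1, drop = TRUE]
    l <- p[-seq_len(a), 2, drop = TRUE]
    if (any((i < k & k < j & j < l) | (k < i & i < l & l < j))) return(TRUE)
  }
  FALSE
}

#' Parse dot-bracket notation
#'
#' Matches brackets with a stack: each `)` closes the most recent open `(`.
#'
#' @param text A string over the alphabet `(`, `)`, `.`.
#' @return An [rna_structure] with `n = nchar(text)`.
#' @export
#' @examples
#' parse_dotbracket("((..))")$pairs
parse_dotbracket <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c("(", ")", "."))
  if (length(bad) > 0) {
    stop("invalid dot-bracket character '", chars[bad[1]],
         "' at position ", bad[1])
  }
  stack <- integer(0)
  open <- integer(0)
  close <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0L) {
        stop("malformed structure: unmatched ')' at position ", i)
      }
      open <- c(open, stack[length(stack)])
      close <- c(close, i)
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack) > 0L) {
    stop("malformed structure: unmatched '(' at position ", stack[1])
  }
  rna_structure(cbind(open, close), n = length(chars))
}

#' Serialize a nested structure to dot-bracket notation
#'
#' @param s An [rna_structure]; must not be pseudoknotted (plain dot-bracket
#'   cannot represent crossing pairs).
#' @return A string of length `s$n`.
#' @export
to_dotbracket <- function(s) {
  stopifnot(inherits(s, "rna_structure"))
  if (s$pseudoknotted) {
    stop("cannot serialize a pseudoknotted structure to plain dot-bracket ",
         "notation (crossing pairs are not representable)")
  }
  out <- rep(".", s$n)
  if (nrow(s$pairs) > 0) {
    out[s$pairs[, 1]] <- "("
    out[s$pairs[, 2]] <- ")"
  }
  paste(out, collapse = "")
}

# Label codes shared by the classifier and the decoder:
# 1 = "(" (opens a pair), 2 = ")" (closes a pair), 3 = "." (unpaired).
.STRUCT_LABELS <- c("(", ")", ".")

#' Per-base structural labels
#'
#' Converts a nested structure into the per-base three-class labels used to
#' train the classifier: `(` for pair-opening bases, `)` for pair-closing
#' bases, `.` for unpaired bases.
#'
#' @param s An [rna_structure], not pseudoknotted.
#' @return Integer vector of length `s$n` with values 1 (`(`), 2 (`)`),
#'   3 (`.`); levels are in `attr(, "labels")`.
#' @export
labels_from_structure <- function(s) {
  stopifnot(inherits(s, "rna_structure"))
  if (s$pseudoknotted) {
    stop("labels are only defined for nested structures")
  }
  lab <- rep(3L, s$n)
  if (nrow(s$pairs) > 0) {
    lab[s$pairs[, 1]] <- 1L
    lab[s$pairs[, 2]] <- 2L
  }
  attr(lab, "labels") <- .STRUCT_LABELS
  lab
}
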