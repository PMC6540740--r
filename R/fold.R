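#' Folding configuration
#'
#' Constraints on the structures the decoder may emit.
#'
#' @param min_loop Minimum number of unpaired bases enclosed by a hairpin's
#'   closing pair (`j - i - 1 >= min_loop`). Default 3, the standard steric
#'   constraint; 0 reproduces the unconstrained recursion.
#' @param allowed_pairs Character vector of pairable base combinations,
#'   symmetric; default A-U, G-C and the G-U wobble.
#' @return A list of class `fold_config`.
#' @export
fold_config <- function(min_loop = 3L,
                        allowed_pairs = c("AU", "GC", "GU")) {
  min_loop <- as.integer(min_loop)
  stopifnot(min_loop >= 0L)
  ap <- toupper(allowed_pairs)
  if (!all(grepl("^[AUGC][AUGC]$", ap))) {
    stop("allowed_pairs must be two-letter combinations over A,U,G,C")
  }
  structure(list(min_loop = min_loop, allowed_pairs = ap),
            class = "fold_config")
}

# 4x4 logical lookup: can bases (code a, code b) pair under cfg?
allowed_pair_table <- function(cfg) {
  ok <- matrix(FALSE, 4, 4, dimnames = list(.BASE_ALPHABET, .BASE_ALPHABET))
  for (p in cfg$allowed_pairs) {
    a <- substr(p, 1, 1); b <- substr(p, 2, 2)
    ok[a, b] <- TRUE
    ok[b, a] <- TRUE
  }
  ok
}

check_probs <- function(seq, probs) {
  probs <- as.matrix(probs)
  if (nrow(probs) != seq$n || ncol(probs) != 3L) {
    stop("probability table must have one row per base (", seq$n,
         ") and 3 columns (p_left, p_right, p_point); got ",
         nrow(probs), "x", ncol(probs))
  }
  if (any(probs < 0)) stop("probabilities must be non-negative")
  unname(probs)
}

#' Maximum probability sum folding
#'
#' Decodes per-base label probabilities into the valid nested structure
#' whose summed label probability is maximal. `N(i, j)` is the best score
#' attainable on the subsequence `i..j`, filled by interval length with
#' base cases `N(i, i) = p_point(i)` and `N(i, j) = 0` for `j < i`, and
#' the four-way recursion: leave `i` unpaired (`N(i+1, j) + p_point(i)`),
#' leave `j` unpaired (`N(i, j-1) + p_point(j)`), close the pair `i.j`
#' (`N(i+1, j-1) + delta(i, j)`), or split the interval
#' (`max_k N(i, k) + N(k+1, j)`). `delta(i, j)` is
#' `p_left(i) + p_right(j)` when bases `i, j` may pair (allowed combination
#' and `j - i - 1 >= min_loop`), else `p_point(i) + p_point(j)`. This is the
#' Nussinov recursion with the pair count replaced by label probabilities.
#'
#' Traceback is deterministic: candidates are evaluated in the order
#' unpair-i, unpair-j, pair, split (smallest `k` first) and the first one
#' achieving the maximum is taken. Probabilities are used as given (no
#' re-normalisation), so any non-negative per-base scores work.
#'
#' @param seq An [rna_sequence].
#' @param probs `n x 3` matrix of per-base scores
#'   (`p_left`, `p_right`, `p_point`), e.g. from [predict_probs].
#' @param cfg A [fold_config].
#' @return A list of class `fold_result`: `structure` ([rna_structure]),
#'   `score` (`N(1, n)`) and `table` (the upper-triangular DP matrix).
#' @export
#' @examples
#' seq <- rna_sequence("GAAAC")
#' probs <- rbind(c(.9, .05, .05), c(0, 0, 1), c(0, 0, 1), c(0, 0, 1),
#'                c(.05, .9, .05))
#' mps_fold(seq, probs)  # "(...)" with score 4.8
mps_fold <- function(seq, probs, cfg = fold_config()) {
  stopifnot(inherits(seq, "rna_sequence"), inherits(cfg, "fold_config"))
  probs <- check_probs(seq, probs)
  n <- seq$n
  codes <- base_codes(seq)
  ok <- allowed_pair_table(cfg)
  pl <- probs[, 1]; pr <- probs[, 2]; pp <- probs[, 3]
  pairable <- ok[codes, codes, drop = FALSE]

  N <- matrix(0, n, n)
  diag(N) <- pp
  delta <- function(i, j) {
    if (pairable[i, j] && (j - i - 1L) >= cfg$min_loop) pl[i] + pr[j]
    else pp[i] + pp[j]
  }
  if (n >= 2L) {
    for (len in 2:n) {
      for (i in 1:(n - len + 1L)) {
        j <- i + len - 1L
        best <- N[i + 1L, j] + pp[i]
        c2 <- N[i, j - 1L] + pp[j]
        if (c2 > best) best <- c2
        c3 <- (if (len > 2L) N[i + 1L, j - 1L] else 0) + delta(i, j)
        if (c3 > best) best <- c3
        if (len > 2L) {
          ks <- (i + 1L):(j - 1L)
          c4 <- max(N[i, ks] + N[cbind(ks + 1L, j)])
          if (c4 > best) best <- c4
        }
        N[i, j] <- best
      }
    }
  }

  # traceback: stack of intervals, first maximising case in fixed order
  open <- integer(0); close <- integer(0)
  stack <- list(c(1L, n))
  while (length(stack) > 0L) {
    iv <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- iv[1]; j <- iv[2]
    while (i <= j) {
      if (i == j) break  # single base: unpaired
      v <- N[i, j]
      if (N[i + 1L, j] + pp[i] == v) { i <- i + 1L; next }
      if (N[i, j - 1L] + pp[j] == v) { j <- j - 1L; next }
      len <- j - i + 1L
      inner <- if (len > 2L) N[i + 1L, j - 1L] else 0
      if (inner + delta(i, j) == v) {
        # a real pair only when admissible; the delta fallback assigns the
        # unpaired label to both ends
        if (pairable[i, j] && (j - i - 1L) >= cfg$min_loop) {
          open <- c(open, i); close <- c(close, j)
        }
        i <- i + 1L; j <- j - 1L
        next
      }
      for (k in (i + 1L):(j - 1L)) {
        if (N[i, k] + N[k + 1L, j] == v) {
          stack[[length(stack) + 1L]] <- c(k + 1L, j)
          j <- k
          break
        }
      }
    }
  }

  structure(list(structure = rna_structure(cbind(open, close), n),
                 score = N[1L, n], table = N),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf("<fold_result> score %.4f\n", x$score))
  cat(to_dotbracket(x$structure), "\n")
  invisible(x)
}

#' Score a structure under per-base label probabilities
#'
#' Sum over bases of the probability of the label the structure assigns:
#' `p_left` for pair-opening bases, `p_right` for pair-closing bases,
#' `p_point` for unpaired bases.
#'
#' @param seq An [rna_sequence].
#' @param probs `n x 3` score matrix as in [mps_fold].
#' @param s An [rna_structure] (nested, valid for the sequence length).
#' @return The scalar score.
#' @export
score_structure <- function(seq, probs, s) {
  stopifnot(inherits(seq, "rna_sequence"), inherits(s, "rna_structure"))
  probs <- check_probs(seq, probs)
  if (s$n != seq$n) stop("structure length ", s$n,
                         " does not match sequence length ", seq$n)
  lab <- labels_from_structure(s)
  sum(probs[cbind(seq_len(seq$n), lab)])
}

#' Enumerate all valid nested structures (test oracle)
#'
#' Exhaustively generates every nested structure compatible with the
#' sequence under the folding constraints, each exactly once. Interval
#' recursion: base `i` is either unpaired, or paired with some admissible
#' `k` (pairable bases, `k - i - 1 >= min_loop`), combining all structures
#' of the enclosed and remaining intervals. Intended as a brute-force
#' oracle for small `n`.
#'
#' @param seq An [rna_sequence] with `seq$n <= guard`.
#' @param cfg A [fold_config].
#' @param guard Refuse sequences longer than this (default 16): the count
#'   grows exponentially.
#' @return List of [rna_structure] objects.
#' @export
enumerate_structures <- function(seq, cfg = fold_config(), guard = 16L) {
  stopifnot(inherits(seq, "rna_sequence"))
  if (seq$n > guard) {
    stop("enumeration is exponential; refusing n = ", seq$n, " > ", guard)
  }
  codes <- base_codes(seq)
  ok <- allowed_pair_table(cfg)
  memo <- new.env(parent = emptyenv())
  # returns a list of 2-column pair matrices for interval [i, j]
  enum <- function(i, j) {
    if (i >= j) return(list(matrix(integer(0), ncol = 2)))
    key <- paste0(i, ":", j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- enum(i + 1L, j)  # i unpaired
    for (k in (i + 1L):j) {
      if (ok[codes[i], codes[k]] && (k - i - 1L) >= cfg$min_loop) {
        inner <- enum(i + 1L, k - 1L)
        rest <- enum(k + 1L, j)
        for (a in inner) for (b in rest) {
          out[[length(out) + 1L]] <- rbind(c(i, k), a, b)
        }
      }
    }
    memo[[key]] <- out
    out
  }
  lapply(enum(1L, seq$n), rna_structure, n = seq$n)
}
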