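# Independent oracles, written against the public problem definitions only
# (never against the package internals they check).

# Brute-force optimum: enumerate every valid nested structure and score it.
brute_force_best <- function(seq, probs, cfg = fold_config()) {
  structs <- enumerate_structures(seq, cfg)
  scores <- vapply(structs, function(s) score_structure(seq, probs, s),
                   numeric(1))
  list(score = max(scores), structures = structs, scores = scores)
}

# Classic Nussinov maximum-matching count: independent O(n^3) DP maximizing
# the number of admissible pairs (not the package's probability DP).
nussinov_max_pairs <- function(seq, cfg = fold_config(min_loop = 0L)) {
  bases <- strsplit(seq$bases, "")[[1]]
  ok <- matrix(FALSE, 4, 4, dimnames = list(c("A","U","G","C"),
                                            c("A","U","G","C")))
  for (p in cfg$allowed_pairs) {
    ok[substr(p, 1, 1), substr(p, 2, 2)] <- TRUE
    ok[substr(p, 2, 2), substr(p, 1, 1)] <- TRUE
  }
  n <- seq$n
  M <- matrix(0L, n, n)
  if (n < 2) return(0L)
  for (len in 2:n) {
    for (i in 1:(n - len + 1)) {
      j <- i + len - 1
      best <- max(M[i + 1, j], M[i, j - 1])
      if (ok[bases[i], bases[j]] && (j - i - 1) >= cfg$min_loop) {
        inner <- if (len > 2) M[i + 1, j - 1] else 0L
        best <- max(best, inner + 1L)
      }
      if (len > 2) {
        for (k in (i + 1):(j - 1)) {
          best <- max(best, M[i, k] + M[k + 1, j])
        }
      }
      M[i, j] <- best
    }
  }
  M[1, n]
}

# Independent count of valid nested structures by the interval recursion
# C(i,j) = C(i+1,j) + sum_k pairable(i,k) C(i+1,k-1) C(k+1,j).
count_structures_dp <- function(seq, cfg = fold_config()) {
  bases <- strsplit(seq$bases, "")[[1]]
  ok <- matrix(FALSE, 4, 4, dimnames = list(c("A","U","G","C"),
                                            c("A","U","G","C")))
  for (p in cfg$allowed_pairs) {
    ok[substr(p, 1, 1), substr(p, 2, 2)] <- TRUE
    ok[substr(p, 2, 2), substr(p, 1, 1)] <- TRUE
  }
  n <- seq$n
  memo <- new.env(parent = emptyenv())
  cnt <- function(i, j) {
    if (i >= j) return(1)
    key <- paste0(i, ":", j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    total <- cnt(i + 1, j)
    for (k in (i + 1):j) {
      if (ok[bases[i], bases[k]] && (k - i - 1) >= cfg$min_loop) {
        total <- total + cnt(i + 1, k - 1) * cnt(k + 1, j)
      }
    }
    memo[[key]] <- total
    total
  }
  cnt(1, n)
}

# Numerical gradient of the batch cross-entropy loss w.r.t. one parameter
# matrix, for checking the analytic backprop on tiny cases.
batch_loss <- function(params, x, labels) {
  p <- mpsfold:::cnn_forward(params, x)$probs
  -mean(log(p[cbind(labels, seq_along(labels))]))
}
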