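# Programmatic fixtures shared across test files.

# A trivially separable three-class window set: the class is determined by
# where the mass sits in the centre row (left half / right half / nowhere).
make_toy_windows <- function(n_per_class, d = 5L, L = 24L, seed = 1L,
                             noise = 0.05) {
  set.seed(seed)
  N <- 3L * n_per_class
  x <- array(stats::rnorm(d * L * N, sd = noise), dim = c(d, L, N))
  labels <- rep(1:3, each = n_per_class)
  mid <- (d + 1L) %/% 2L
  half <- L %/% 2L
  for (i in seq_len(N)) {
    if (labels[i] == 1L) {
      x[mid, seq_len(half), i] <- x[mid, seq_len(half), i] + 3
    } else if (labels[i] == 2L) {
      x[mid, (half + 1L):L, i] <- x[mid, (half + 1L):L, i] + 3
    }
  }
  idx <- sample.int(N)
  window_set(x[, , idx, drop = FALSE], labels[idx])
}

# Random (sequence, structure, probability) instance for fold testing.
random_fold_instance <- function(n, min_loop = 3L, eps = 0.3) {
  s <- random_structure(n, min_loop = min_loop, pair_density = 0.5)
  seq <- sequence_for_structure(s, gu_fraction = 0.15)
  probs <- probs_from_structure(s, eps = eps)
  list(seq = seq, structure = s, probs = probs)
}

# Dirichlet(1,1,1) probability rows, the "uninformative" instance family.
random_dirichlet_probs <- function(n) {
  g <- matrix(stats::rgamma(3L * n, shape = 1), n, 3L)
  g / rowSums(g)
}

tmpfile <- function(ext = "") tempfile(fileext = ext)
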