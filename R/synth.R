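#' Synthetic data configuration
#'
#' Controls the synthetic sequence/structure generator used for testing the
#' full pipeline without external data. Defaults emulate a 5sRNA-like
#' family: lengths between 60 and 120 nt, minimum hairpin loop 3, roughly
#' half of feasible positions opening a pair, a 10% wobble fraction and
#' mild label noise.
#'
#' @param n_range Length interval `c(min, max)`.
#' @param min_loop Minimum hairpin loop length of generated structures.
#' @param pair_density Probability in `[0, 1]` that a position opens a pair
#'   when it feasibly can.
#' @param gu_fraction Fraction of pairs drawn as G-U wobbles.
#' @param label_noise Probability mass moved off the true label when
#'   generating probability tables.
#' @param seed Integer seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_range = c(60L, 120L), min_loop = 3L,
                         pair_density = 0.5, gu_fraction = 0.1,
                         label_noise = 0.1, seed = 1L) {
  stopifnot(length(n_range) == 2L, n_range[1] >= 1L, n_range[2] >= n_range[1],
            min_loop >= 0L,
            pair_density >= 0, pair_density <= 1,
            gu_fraction >= 0, gu_fraction <= 1,
            label_noise >= 0, label_noise <= 1)
  structure(list(n_range = as.integer(n_range), min_loop = as.integer(min_loop),
                 pair_density = pair_density, gu_fraction = gu_fraction,
                 label_noise = label_noise, seed = as.integer(seed)),
            class = "synth_config")
}

#' Draw a random valid nested structure
#'
#' Recursive generation: scanning left to right, each position opens a pair
#' with probability `pair_density` whenever a partner respecting `min_loop`
#' fits in the remaining interval; the partner is drawn uniformly among the
#' feasible positions and generation recurses inside and after the pair.
#' Every draw is a valid nested structure.
#'
#' @param n Sequence length.
#' @param min_loop Minimum hairpin loop.
#' @param pair_density Pair-opening probability (0 gives the all-unpaired
#'   structure).
#' @param seed Optional integer seed.
#' @return An [rna_structure].
#' @export
random_structure <- function(n, min_loop = 3L, pair_density = 0.5,
                             seed = NULL) {
  stopifnot(n >= 1L, min_loop >= 0L, pair_density >= 0, pair_density <= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  open <- integer(0); close <- integer(0)
  gen <- function(l, r) {
    pos <- l
    while (pos <= r) {
      lo <- pos + min_loop + 1L
      if (lo <= r && stats::runif(1) < pair_density) {
        j <- if (lo == r) r else sample(lo:r, 1L)
        open <<- c(open, pos); close <<- c(close, j)
        gen(pos + 1L, j - 1L)
        pos <- j + 1L
      } else {
        pos <- pos + 1L
      }
    }
  }
  gen(1L, as.integer(n))
  rna_structure(cbind(open, close), n = as.integer(n))
}

#' Draw a sequence compatible with a structure
#'
#' Paired positions receive a Watson-Crick pair (A-U, U-A, G-C or C-G,
#' uniformly) with probability `1 - gu_fraction` and a wobble (G-U or U-G)
#' otherwise; unpaired positions are uniform over A, U, G, C. The result is
#' always fully compatible with the structure under the default folding
#' constraints.
#'
#' @param s An [rna_structure].
#' @param gu_fraction Wobble-pair fraction.
#' @param seed Optional integer seed.
#' @param id Identifier of the generated sequence.
#' @return An [rna_sequence].
#' @export
sequence_for_structure <- function(s, gu_fraction = 0.1, seed = NULL,
                                   id = "synth") {
  stopifnot(inherits(s, "rna_structure"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  bases <- sample(.BASE_ALPHABET, s$n, replace = TRUE)
  wc <- rbind(c("A", "U"), c("U", "A"), c("G", "C"), c("C", "G"))
  gu <- rbind(c("G", "U"), c("U", "G"))
  for (r in seq_len(nrow(s$pairs))) {
    pick <- if (stats::runif(1) < gu_fraction) gu[sample.int(2, 1L), ]
            else wc[sample.int(4, 1L), ]
    bases[s$pairs[r, 1]] <- pick[1]
    bases[s$pairs[r, 2]] <- pick[2]
  }
  rna_sequence(paste(bases, collapse = ""), id = id)
}

#' Noisy probability tables for a known structure
#'
#' Each base's probability triple puts mass `1 - eps` on its true label and
#' `eps/2` on each other label, then is perturbed by a seeded Dirichlet draw
#' (shape `concentration * triple`) and renormalised. `eps = 0` yields exact
#' one-hot rows (zero-shape gamma components are exactly zero), so the
#' decoder recovers the source structure perfectly.
#'
#' @param s An [rna_structure] (nested).
#' @param eps Label noise in `[0, 1]`.
#' @param seed Optional integer seed.
#' @param concentration Dirichlet concentration (larger = less noise);
#'   default 50.
#' @return An `n x 3` matrix with columns `p_left`, `p_right`, `p_point`,
#'   rows summing to 1.
#' @export
probs_from_structure <- function(s, eps = 0, seed = NULL,
                                 concentration = 50) {
  stopifnot(inherits(s, "rna_structure"), eps >= 0, eps <= 1,
            concentration > 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  lab <- labels_from_structure(s)
  base <- matrix(eps / 2, s$n, 3L)
  base[cbind(seq_len(s$n), lab)] <- 1 - eps
  g <- matrix(stats::rgamma(3L * s$n, shape = concentration * base),
              s$n, 3L)
  out <- g / rowSums(g)
  colnames(out) <- c("p_left", "p_right", "p_point")
  out
}

#' Perfect hairpin record (planted ground truth)
#'
#' Builds a hairpin of `stem` stacked G-C pairs around a loop of `loop`
#' unpaired A's — e.g. `hairpin_record(4, 4)` is `GGGGAAAACCCC` with
#' structure `((((....))))`. The planted stem length is exact, so dataset
#' statistics and the stem signature of the encoding can be tested against
#' known truth.
#'
#' @param stem Number of stacked pairs.
#' @param loop Loop length (must be >= the steric minimum you intend to
#'   test with).
#' @param id,family Record annotations.
#' @return A [dataset_record].
#' @export
hairpin_record <- function(stem, loop, id = "hairpin", family = "synthetic") {
  stopifnot(stem >= 1L, loop >= 1L)
  n <- 2L * stem + loop
  seq <- rna_sequence(paste0(strrep("G", stem), strrep("A", loop),
                             strrep("C", stem)), id = id)
  pairs <- cbind(seq_len(stem), n + 1L - seq_len(stem))
  dataset_record(seq, rna_structure(pairs, n = n), family = family)
}

#' Simulate a synthetic dataset
#'
#' Draws `n_records` independent (structure, sequence) pairs under a
#' [synth_config]; reproducible given `cfg$seed`.
#'
#' @param n_records Number of records.
#' @param cfg A [synth_config].
#' @param family Family label for the records.
#' @param id_prefix Identifier prefix.
#' @return List of [dataset_record].
#' @export
simulate_dataset <- function(n_records, cfg = synth_config(),
                             family = "synthetic", id_prefix = "synth") {
  stopifnot(n_records >= 1L)
  set.seed(cfg$seed)
  out <- vector("list", n_records)
  for (k in seq_len(n_records)) {
    n <- if (cfg$n_range[1] == cfg$n_range[2]) cfg$n_range[1]
         else sample(cfg$n_range[1]:cfg$n_range[2], 1L)
    s <- random_structure(n, cfg$min_loop, cfg$pair_density)
    seq <- sequence_for_structure(s, cfg$gu_fraction,
                                  id = sprintf("%s_%04d", id_prefix, k))
    out[[k]] <- dataset_record(seq, s, family = family)
  }
  out
}
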