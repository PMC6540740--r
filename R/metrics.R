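#' Base-pair confusion counts
#'
#' Compares predicted and reference structures at the base-pair level.
#' A true positive is an exactly matching pair `(i, j)`; no slip tolerance
#' is applied by default (`slip = 0`). With `slip = 1`, a predicted pair
#' counts as correct when one of its ends may differ by one position
#' (`(i, j)` matches a reference `(i, j±1)` or `(i±1, j)`), a convention
#' some of the folding literature uses.
#'
#' @param predicted,reference [rna_structure] objects of equal length.
#' @param slip 0 (exact, default) or 1.
#' @return Named integer vector `c(tp, fp, fn)`.
#' @export
#' @examples
#' compare_pairs(parse_dotbracket("((...))"), parse_dotbracket("((...))"))
compare_pairs <- function(predicted, reference, slip = 0L) {
  stopifnot(inherits(predicted, "rna_structure"),
            inherits(reference, "rna_structure"))
  if (predicted$n != reference$n) {
    stop("length mismatch: predicted n = ", predicted$n,
         ", reference n = ", reference$n)
  }
  key <- function(p) paste(p[, 1], p[, 2])
  pk <- key(predicted$pairs)
  rk <- key(reference$pairs)
  if (slip == 0L) {
    tp <- sum(pk %in% rk)
  } else {
    rp <- reference$pairs
    slipped <- c(rk,
                 paste(rp[, 1], rp[, 2] + 1L), paste(rp[, 1], rp[, 2] - 1L),
                 paste(rp[, 1] + 1L, rp[, 2]), paste(rp[, 1] - 1L, rp[, 2]))
    tp <- sum(pk %in% slipped)
  }
  c(tp = tp, fp = length(pk) - tp, fn = length(rk) - sum(rk %in% pk))
}

#' F-score from sensitivity and specificity
#'
#' Harmonic mean `2 * sens * spec / (sens + spec)`. Here sensitivity is the
#' fraction of reference base pairs that were predicted (recall) and
#' specificity the fraction of predicted base pairs that are correct
#' (precision/PPV, the convention of the folding literature — not the
#' true-negative rate).
#'
#' @param sensitivity,specificity Values in `[0, 1]` (vectorised).
#' @return The F-score; 0 with a warning when both inputs are 0.
#' @export
#' @examples
#' round(f_score(0.932, 0.916), 3)  # 0.924
f_score <- function(sensitivity, specificity) {
  stopifnot(all(sensitivity >= 0 & sensitivity <= 1, na.rm = TRUE),
            all(specificity >= 0 & specificity <= 1, na.rm = TRUE))
  s <- sensitivity + specificity
  out <- ifelse(s > 0, 2 * sensitivity * specificity / s, 0)
  if (any(s == 0, na.rm = TRUE)) {
    warning("sensitivity and specificity both zero; F-score reported as 0")
  }
  out
}

#' Evaluate predicted structures against references
#'
#' Per-sequence base-pair sensitivity, specificity (PPV) and F-score, plus
#' two aggregates: `micro` pools tp/fp/fn over all sequences before the
#' ratios, `macro` averages the per-sequence scores (sequences with no
#' reference pairs contribute `NA` sensitivity and are dropped from the
#' macro means). Both are reported because published tables rarely say
#' which pooling they used.
#'
#' @param predicted,reference Lists of [rna_structure] of equal length.
#' @param ids Optional sequence identifiers.
#' @param slip Slip tolerance passed to [compare_pairs].
#' @return List of class `eval_report`: `per_sequence` (data.frame),
#'   `micro` and `macro` (named numeric vectors with sensitivity,
#'   specificity, f_score).
#' @export
evaluate_structures <- function(predicted, reference, ids = NULL, slip = 0L) {
  stopifnot(length(predicted) == length(reference), length(predicted) > 0)
  if (is.null(ids)) ids <- sprintf("seq%d", seq_along(predicted))
  counts <- t(mapply(function(p, r) compare_pairs(p, r, slip = slip),
                     predicted, reference))
  sens <- ifelse(counts[, "tp"] + counts[, "fn"] > 0,
                 counts[, "tp"] / (counts[, "tp"] + counts[, "fn"]), NA_real_)
  spec <- ifelse(counts[, "tp"] + counts[, "fp"] > 0,
                 counts[, "tp"] / (counts[, "tp"] + counts[, "fp"]), NA_real_)
  fs <- ifelse(!is.na(sens) & !is.na(spec) & (sens + spec) > 0,
               2 * sens * spec / (sens + spec),
               ifelse(!is.na(sens) & !is.na(spec), 0, NA_real_))
  per <- data.frame(id = ids, tp = counts[, "tp"], fp = counts[, "fp"],
                    fn = counts[, "fn"], sensitivity = sens,
                    specificity = spec, f_score = fs,
                    row.names = NULL, stringsAsFactors = FALSE)
  tot <- colSums(counts)
  msens <- if (tot["tp"] + tot["fn"] > 0) tot[["tp"]] / (tot[["tp"]] + tot[["fn"]]) else NA_real_
  mspec <- if (tot["tp"] + tot["fp"] > 0) tot[["tp"]] / (tot[["tp"]] + tot[["fp"]]) else NA_real_
  micro <- c(sensitivity = msens, specificity = mspec,
             f_score = if (!is.na(msens) && !is.na(mspec) && msens + mspec > 0)
               2 * msens * mspec / (msens + mspec) else 0)
  macro <- c(sensitivity = mean(sens, na.rm = TRUE),
             specificity = mean(spec, na.rm = TRUE),
             f_score = mean(fs, na.rm = TRUE))
  structure(list(per_sequence = per, micro = micro, macro = macro),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d sequences\n", nrow(x$per_sequence)))
  cat(sprintf("  micro: sensitivity %.3f, specificity %.3f, F-score %.3f\n",
              x$micro[1], x$micro[2], x$micro[3]))
  cat(sprintf("  macro: sensitivity %.3f, specificity %.3f, F-score %.3f\n",
              x$macro[1], x$macro[2], x$macro[3]))
  invisible(x)
}
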