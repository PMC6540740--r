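#' Build a labeled window collection from dataset records
#'
#' Encodes every record (pairing matrix, sliding windows, length rescaling)
#' and attaches each base's structural label, producing the training input
#' of [mps_train].
#'
#' @param records List of [dataset_record] (nested structures).
#' @param cfg An [encoding_config].
#' @return A [window_set]; `ids` are `<sequence id>:<position>`.
#' @export
windows_from_records <- function(records, cfg = encoding_config()) {
  stopifnot(length(records) > 0L)
  total <- sum(vapply(records, function(r) r$seq$n, integer(1)))
  x <- array(0, dim = c(cfg$window_height, cfg$target_length, total))
  labels <- integer(total)
  ids <- character(total)
  at <- 0L
  for (r in records) {
    n <- r$seq$n
    x[, , at + seq_len(n)] <- encode_windows(r$seq, cfg)
    labels[at + seq_len(n)] <- labels_from_structure(r$structure)
    ids[at + seq_len(n)] <- sprintf("%s:%d", r$seq$id, seq_len(n))
    at <- at + n
  }
  window_set(x, labels, ids)
}

#' Train a structure predictor on dataset records
#'
#' End-to-end training wrapper: encode all records into labeled windows,
#' balance the three label classes by upsampling, and fit the classifier.
#'
#' @param records Training [dataset_record] list.
#' @param encoding An [encoding_config].
#' @param model_cfg A [model_config].
#' @param balance Upsample-balance the classes before training
#'   (default TRUE).
#' @return An `mps_model`.
#' @export
train_on_records <- function(records, encoding = encoding_config(),
                             model_cfg = model_config(), balance = TRUE) {
  ws <- windows_from_records(records, encoding)
  if (balance) ws <- upsample_balance(ws, seed = model_cfg$seed)
  mps_train(ws, model_cfg, encoding = encoding)
}

#' Predict and decode structures for sequences
#'
#' Runs the classifier on each sequence and decodes the probability table
#' with the maximum-probability-sum dynamic program.
#'
#' @param model An `mps_model`.
#' @param seqs List of [rna_sequence].
#' @param fold_cfg A [fold_config].
#' @return List of [rna_structure], one per sequence.
#' @export
predict_structures <- function(model, seqs, fold_cfg = fold_config()) {
  lapply(seqs, function(s) {
    mps_fold(s, predict_probs(model, s), fold_cfg)$structure
  })
}
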