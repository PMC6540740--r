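#' Model configuration
#'
#' Architecture and optimisation settings of the per-base label classifier.
#' The reference single-family configuration uses 3 conv blocks, batch 256
#' and 400 iterations with 11x120 inputs; the general multi-family
#' configuration uses 2 conv blocks, batch 512 and 2000 iterations with
#' 19x128 inputs. Each conv block is 16 3x3 kernels (same padding, ReLU)
#' followed by 3x3 max pooling with stride 2; two 32-node ReLU dense layers
#' and a 3-way softmax complete the network. Weights are Xavier-initialised
#' and trained by plain mini-batch SGD on the categorical cross-entropy.
#'
#' @param conv_blocks Number of conv+pool blocks (3 single-family,
#'   2 general).
#' @param kernels Kernels per convolutional layer (default 16).
#' @param dense_nodes Nodes in each of the two dense layers (default 32).
#' @param batch_size Mini-batch size (256 or 512 in the reference setups).
#' @param iterations Number of optimiser steps, i.e. batches drawn (400 or
#'   2000 in the reference setups).
#' @param learning_rate SGD learning rate (default 0.01).
#' @param eval_every Record loss/accuracy every this many steps.
#' @param seed Integer seed; training is bit-reproducible given
#'   (seed, config, data).
#' @return A list of class `model_config`.
#' @export
model_config <- function(conv_blocks = 3L, kernels = 16L, dense_nodes = 32L,
                         batch_size = 256L, iterations = 400L,
                         learning_rate = 0.01, eval_every = 10L, seed = 1L) {
  stopifnot(conv_blocks >= 1L, kernels >= 1L, dense_nodes >= 1L,
            batch_size >= 1L, iterations >= 1L, learning_rate > 0)
  structure(list(conv_blocks = as.integer(conv_blocks),
                 kernels = as.integer(kernels),
                 dense_nodes = as.integer(dense_nodes),
                 batch_size = as.integer(batch_size),
                 iterations = as.integer(iterations),
                 learning_rate = learning_rate,
                 eval_every = as.integer(eval_every),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Labeled window collection
#'
#' Container pairing model-input windows with their structural labels.
#'
#' @param x A `d x L x N` array of windows.
#' @param labels Integer vector of length `N` with values 1 (`(`),
#'   2 (`)`), 3 (`.`); or a character vector over those symbols.
#' @param ids Optional per-window identifiers.
#' @return A list of class `window_set` with elements `x`, `labels`, `ids`.
#' @export
window_set <- function(x, labels, ids = NULL) {
  stopifnot(is.array(x), length(dim(x)) == 3L)
  if (is.character(labels)) labels <- match(labels, .STRUCT_LABELS)
  labels <- as.integer(labels)
  if (length(labels) != dim(x)[3]) {
    stop("need one label per window: ", dim(x)[3], " windows but ",
         length(labels), " labels")
  }
  if (length(labels) == 0L) stop("empty window collection")
  if (any(is.na(labels)) || any(labels < 1L) || any(labels > 3L)) {
    stop("labels must be 1/2/3 or one of '(', ')', '.'")
  }
  structure(list(x = x, labels = labels, ids = ids), class = "window_set")
}

subset_window_set <- function(ws, idx) {
  window_set(ws$x[, , idx, drop = FALSE], ws$labels[idx],
             if (!is.null(ws$ids)) ws$ids[idx])
}

#' Balance classes by upsampling
#'
#' Resamples minority classes with replacement until every present class
#' matches the majority count. All original windows are retained (they come
#' first, duplicates are appended), so no information is discarded.
#'
#' @param ws A [window_set].
#' @param seed Integer seed for the resampling.
#' @return A balanced [window_set].
#' @export
upsample_balance <- function(ws, seed = 1L) {
  stopifnot(inherits(ws, "window_set"))
  counts <- table(factor(ws$labels, levels = 1:3))
  present <- which(counts > 0)
  if (length(present) <= 1L) {
    warning("only one class present; nothing to balance")
    return(ws)
  }
  target <- max(counts)
  set.seed(as.integer(seed))
  extra <- integer(0)
  for (cl in present) {
    deficit <- target - counts[[cl]]
    if (deficit > 0L) {
      pool <- which(ws$labels == cl)
      extra <- c(extra, sample(pool, deficit, replace = TRUE))
    }
  }
  if (length(extra) == 0L) return(ws)
  subset_window_set(ws, c(seq_along(ws$labels), extra))
}

#' Train the per-base label classifier
#'
#' Mini-batch SGD on categorical cross-entropy over a labeled window
#' collection. Fully deterministic given `cfg$seed`, the configuration and
#' the data.
#'
#' @param ws A [window_set] of training windows.
#' @param cfg A [model_config].
#' @param encoding An [encoding_config] recorded with the model so that
#'   prediction can verify it is fed identically-encoded inputs. Its
#'   `window_height`/`target_length` must match the window shape.
#' @param validation Optional [window_set] evaluated at every history point.
#' @return An object of class `mps_model`: list with `params`, `cfg`,
#'   `encoding`, and `history` (data.frame: step, loss, accuracy, and
#'   validation accuracy when supplied).
#' @export
mps_train <- function(ws, cfg = model_config(),
                      encoding = encoding_config(), validation = NULL) {
  stopifnot(inherits(ws, "window_set"), inherits(cfg, "model_config"))
  d <- dim(ws$x)[1]; L <- dim(ws$x)[2]; N <- dim(ws$x)[3]
  if (!is.null(encoding)) {
    if (encoding$window_height != d || encoding$target_length != L) {
      stop("encoding config (", encoding$window_height, "x",
           encoding$target_length, ") does not match window shape (",
           d, "x", L, ")")
    }
  }
  set.seed(cfg$seed)
  params <- cnn_init(d, L, cfg$conv_blocks, cfg$kernels, cfg$dense_nodes)
  hist <- list()
  for (step in seq_len(cfg$iterations)) {
    idx <- sample.int(N, cfg$batch_size, replace = cfg$batch_size > N)
    st <- cnn_sgd_step(params, ws$x[, , idx, drop = FALSE], ws$labels[idx],
                       cfg$learning_rate)
    params <- st$params
    if (step %% cfg$eval_every == 0L || step == cfg$iterations) {
      row <- data.frame(step = step, loss = st$loss, accuracy = st$acc)
      if (!is.null(validation)) {
        vp <- predict_window_set(list(params = params), validation$x)
        row$val_accuracy <- mean(max.col(vp, ties.method = "first") ==
                                   validation$labels)
      }
      hist[[length(hist) + 1L]] <- row
    }
  }
  structure(list(params = params, cfg = cfg, encoding = encoding,
                 history = do.call(rbind, hist)),
            class = "mps_model")
}

#' @export
print.mps_model <- function(x, ...) {
  h <- x$history
  cat(sprintf(
    "<mps_model> %d conv blocks, input %dx%d; %d steps, final loss %.4f, acc %.3f\n",
    x$cfg$conv_blocks, x$params$d, x$params$L, x$cfg$iterations,
    h$loss[nrow(h)], h$accuracy[nrow(h)]))
  invisible(x)
}

# Forward pass over a window array in memory-bounded chunks; rows = windows.
predict_window_set <- function(model, x, chunk = 1024L) {
  N <- dim(x)[3]
  out <- matrix(NA_real_, N, 3L,
                dimnames = list(NULL, c("p_left", "p_right", "p_point")))
  for (s in seq(1L, N, by = chunk)) {
    e <- min(s + chunk - 1L, N)
    out[s:e, ] <- t(cnn_forward(model$params,
                                x[, , s:e, drop = FALSE])$probs)
  }
  out
}

#' Predict per-base label probabilities for a sequence
#'
#' Encodes the sequence (pairing matrix, sliding windows, length rescaling)
#' with the configuration the model was trained under and runs the forward
#' pass. Probabilities are returned in full (no argmax collapsing) because
#' the structure decoder consumes the whole distribution.
#'
#' @param model An `mps_model` from [mps_train].
#' @param seq An [rna_sequence].
#' @param cfg Encoding configuration; must equal the one recorded in the
#'   model (default: use the model's own).
#' @return An `n x 3` matrix with columns `p_left`, `p_right`, `p_point`;
#'   each row sums to 1.
#' @export
predict_probs <- function(model, seq, cfg = model$encoding) {
  stopifnot(inherits(model, "mps_model"), inherits(seq, "rna_sequence"))
  if (!identical(unclass(cfg), unclass(model$encoding))) {
    stop("encoding config mismatch: the model was trained under a ",
         "different encoding configuration")
  }
  predict_window_set(model, encode_windows(seq, cfg))
}

#' Save / load a trained model
#'
#' The checkpoint is a single serialized file plus a JSON sidecar recording
#' the encoding configuration; loading verifies the two agree so a model is
#' never applied to differently-encoded inputs.
#'
#' @param model An `mps_model`.
#' @param path Checkpoint path; the sidecar is written at `<path>.json`.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "mps_model"))
  saveRDS(model, path)
  jsonlite::write_json(unclass(model$encoding), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop("missing encoding sidecar ", sidecar)
  }
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  enc <- unclass(model$encoding)
  for (f in names(enc)) {
    if (!isTRUE(all.equal(as.numeric(side[[f]]), as.numeric(enc[[f]])))) {
      stop("encoding sidecar disagrees with checkpoint on '", f, "'")
    }
  }
  model
}
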