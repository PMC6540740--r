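test_that("window sets validate labels and shapes", {
  x <- array(0, c(3, 4, 2))
  expect_error(window_set(x, c(1L)), "one label per window")
  expect_error(window_set(x, c(1L, 4L)), "labels must be")
  ws <- window_set(x, c("(", ".")) # character labels accepted
  expect_equal(ws$labels, c(1L, 3L))
})

test_that("upsampling balances class counts without discarding originals", {
  set.seed(1)
  x <- array(rnorm(3 * 4 * 20), c(3, 4, 20))
  labels <- rep(c(3L, 1L, 2L), c(10, 5, 5))
  ws <- window_set(x, labels, ids = sprintf("w%02d", 1:20))
  bal <- upsample_balance(ws, seed = 9)
  expect_equal(as.integer(table(bal$labels)), c(10L, 10L, 10L))
  # originals all retained, in order, at the front
  expect_equal(bal$ids[1:20], ws$ids)
  expect_true(all(bal$ids %in% ws$ids))
  # already balanced input is a fixed point
  even <- window_set(x[, , 1:12], rep(1:3, each = 4))
  expect_identical(upsample_balance(even, seed = 2)$labels, even$labels)
  # single-class input warns and is returned unchanged
  mono <- window_set(x[, , 1:7], rep(3L, 7))
  expect_warning(out <- upsample_balance(mono), "one class")
  expect_identical(out$labels, mono$labels)
})

test_that("training is bit-reproducible given seed, config and data", {
  ws <- make_toy_windows(20, d = 5, L = 24, seed = 3)
  cfg <- model_config(conv_blocks = 2, batch_size = 16, iterations = 8,
                      seed = 42)
  enc <- encoding_config(window_height = 5, target_length = 24)
  m1 <- mps_train(ws, cfg, enc)
  m2 <- mps_train(ws, cfg, enc)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
})

test_that("both reference architectures accept their stated input sizes", {
  set.seed(8)
  for (spec in list(list(d = 11L, L = 120L, blocks = 3L),
                    list(d = 19L, L = 128L, blocks = 2L))) {
    ws <- window_set(array(rnorm(spec$d * spec$L * 12), c(spec$d, spec$L, 12)),
                     rep(1:3, 4))
    cfg <- model_config(conv_blocks = spec$blocks, batch_size = 6,
                        iterations = 2)
    enc <- encoding_config(window_height = spec$d, target_length = spec$L)
    m <- mps_train(ws, cfg, enc)
    p <- mpsfold:::predict_window_set(m, ws$x)
    expect_equal(dim(p), c(12L, 3L))
    expect_equal(rowSums(p), rep(1, 12), tolerance = 1e-9)
  }
})

test_that("analytic gradients match numerical differentiation on a tiny net", {
  set.seed(21)
  d <- 5L; L <- 8L; B <- 4L
  params <- mpsfold:::cnn_init(d, L, conv_blocks = 1L, kernels = 2L,
                               dense_nodes = 4L)
  x <- array(rnorm(d * L * B), c(d, L, B))
  labels <- c(1L, 2L, 3L, 1L)
  # analytic step with lr so update = -lr * grad recovers the gradient
  lr <- 1
  st <- mpsfold:::cnn_sgd_step(params, x, labels, lr)
  eps <- 1e-6
  check_param <- function(get, set, idx) {
    for (ii in idx) {
      p2 <- params
      v <- get(p2); v[ii] <- v[ii] + eps; p2 <- set(p2, v)
      up <- batch_loss(p2, x, labels)
      p2 <- params
      v <- get(p2); v[ii] <- v[ii] - eps; p2 <- set(p2, v)
      dn <- batch_loss(p2, x, labels)
      num <- (up - dn) / (2 * eps)
      ana <- (get(params)[ii] - get(st$params)[ii]) / lr
      expect_equal(ana, num, tolerance = 1e-4)
    }
  }
  check_param(function(p) p$conv[[1]]$K,
              function(p, v) { p$conv[[1]]$K <- v; p }, c(1, 7, 18))
  check_param(function(p) p$W1, function(p, v) { p$W1 <- v; p }, c(2, 11))
  check_param(function(p) p$W3, function(p, v) { p$W3 <- v; p }, c(1, 6))
  check_param(function(p) p$b3, function(p, v) { p$b3 <- v; p }, 1:3)
})

test_that("the classifier learns a separable toy family without gross overfit", {
  train <- make_toy_windows(120, d = 5, L = 24, seed = 10)
  heldout <- make_toy_windows(40, d = 5, L = 24, seed = 11)
  cfg <- model_config(conv_blocks = 2, batch_size = 64, iterations = 150,
                      learning_rate = 0.05, seed = 1)
  enc <- encoding_config(window_height = 5, target_length = 24)
  m <- mps_train(train, cfg, enc)
  acc_of <- function(ws) {
    p <- mpsfold:::predict_window_set(m, ws$x)
    mean(max.col(p, ties.method = "first") == ws$labels)
  }
  train_acc <- acc_of(train)
  held_acc <- acc_of(heldout)
  expect_gt(train_acc, 0.95)
  expect_gt(held_acc, 0.9)
  expect_lt(abs(train_acc - held_acc), 0.10)
})

test_that("the forward pass is pure and prediction matches the contract", {
  ws <- make_toy_windows(10, d = 5, L = 24, seed = 5)
  enc <- encoding_config(window_height = 5, target_length = 24)
  m <- mps_train(ws, model_config(conv_blocks = 1, batch_size = 8,
                                  iterations = 4), enc)
  p1 <- mpsfold:::predict_window_set(m, ws$x)
  p2 <- mpsfold:::predict_window_set(m, ws$x)
  expect_identical(p1, p2)
  set.seed(19)
  for (n in c(10, 57, 200)) {
    seq <- rna_sequence(paste(sample(c("A", "U", "G", "C"), n, TRUE),
                              collapse = ""))
    probs <- predict_probs(m, seq)
    expect_equal(nrow(probs), n)
    expect_equal(rowSums(probs), rep(1, n), tolerance = 1e-6)
    expect_true(all(probs >= 0))
  }
  # encoding mismatch is refused
  expect_error(predict_probs(m, rna_sequence("GGAAACC"),
                             cfg = encoding_config(window_height = 5,
                                                   target_length = 24,
                                                   gu_weight = 1.2)),
               "mismatch")
})

test_that("checkpoints round-trip and verify their encoding sidecar", {
  ws <- make_toy_windows(8, d = 5, L = 24, seed = 6)
  enc <- encoding_config(window_height = 5, target_length = 24)
  m <- mps_train(ws, model_config(conv_blocks = 1, batch_size = 8,
                                  iterations = 2), enc)
  path <- tmpfile(".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(m$params, m2$params)
  # tampered sidecar is detected
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  side$gu_weight <- 1.5
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  expect_error(load_model(path), "sidecar disagrees")
})

test_that("training refuses inconsistent shapes and empty data", {
  expect_error(window_set(array(0, c(2, 3, 0)), integer(0)), "empty")
  ws <- make_toy_windows(5, d = 5, L = 24)
  expect_error(
    mps_train(ws, model_config(iterations = 1),
              encoding_config(window_height = 11, target_length = 120)),
    "does not match")
})
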