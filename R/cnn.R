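# Minimal convolutional network: orchestration in R, layer primitives in
# C++ (src/cnn.cpp).
#
# Layout conventions: feature maps are arrays [H, W, C, B] (height, width,
# channels, batch); dense activations are matrices (units x B). Convolutions
# are 3x3 with same-padding, realised as im2col + one GEMM; max-pooling is
# 3x3 with stride 2 and TF-style SAME padding (output size ceiling(in/2)).
# All forward passes are pure functions of (params, input).

conv_forward <- function(x, K, b) {
  r <- .conv3_fwd(x, K, b)
  list(y = r$y, cols = r$cols, in_dim = dim(x))
}

conv_backward <- function(dy, K, cache) {
  r <- .conv3_bwd(dy, K, cache$cols, cache$in_dim)
  list(dx = r$dx, dK = r$dK, db = as.numeric(r$db))
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

pool_forward <- function(x) {
  r <- .pool3s2_fwd(x)
  list(y = r$y, am = r$argmax, in_dim = dim(x))
}

pool_backward <- function(dy, cache) {
  .pool3s2_bwd(dy, cache$am, cache$in_dim)
}

xavier <- function(nr, nc, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# Shape bookkeeping + Xavier-initialised parameters for a network of
# `conv_blocks` (conv 3x3 same -> ReLU -> maxpool 3x3/2) blocks followed by
# two ReLU dense layers and a 3-way softmax output.
cnn_init <- function(d, L, conv_blocks, kernels, dense_nodes) {
  H <- as.integer(d); W <- as.integer(L); C <- 1L
  conv <- vector("list", conv_blocks)
  for (bk in seq_len(conv_blocks)) {
    fan_in <- C * 9L
    fan_out <- kernels * 9L
    conv[[bk]] <- list(K = xavier(kernels, C * 9L, fan_in, fan_out),
                       b = numeric(kernels))
    C <- kernels
    H <- as.integer(ceiling(H / 2)); W <- as.integer(ceiling(W / 2))
    if (H < 1L || W < 1L) {
      stop("input ", d, "x", L, " collapses before ", conv_blocks,
           " pooling stages")
    }
  }
  flat <- H * W * C
  list(conv = conv,
       W1 = xavier(dense_nodes, flat, flat, dense_nodes), b1 = numeric(dense_nodes),
       W2 = xavier(dense_nodes, dense_nodes, dense_nodes, dense_nodes),
       b2 = numeric(dense_nodes),
       W3 = xavier(3L, dense_nodes, dense_nodes, 3L), b3 = numeric(3L),
       flat = flat, conv_blocks = conv_blocks, d = as.integer(d),
       L = as.integer(L))
}

softmax_cols <- function(z) {
  z <- sweep(z, 2L, apply(z, 2L, max), "-")
  e <- exp(z)
  sweep(e, 2L, colSums(e), "/")
}

# Forward pass; x is [d, L, B]. Returns 3 x B probabilities and, when
# training, the caches needed for backprop.
cnn_forward <- function(params, x, training = FALSE) {
  stopifnot(length(dim(x)) == 3L)
  B <- dim(x)[3]
  if (dim(x)[1] != params$d || dim(x)[2] != params$L) {
    stop("window shape ", dim(x)[1], "x", dim(x)[2],
         " does not match the model input ", params$d, "x", params$L)
  }
  a <- array(x, dim = c(params$d, params$L, 1L, B))
  caches <- list()
  for (bk in seq_along(params$conv)) {
    cv <- conv_forward(a, params$conv[[bk]]$K, params$conv[[bk]]$b)
    z <- cv$y
    r <- relu(z)
    pl <- pool_forward(r)
    a <- pl$y
    if (training) {
      caches[[bk]] <- list(conv = cv[c("cols", "in_dim")], pre_relu = z,
                           pool = pl[c("am", "in_dim")])
    }
  }
  flat <- matrix(a, nrow = params$flat, ncol = B)
  z1 <- params$W1 %*% flat + params$b1
  a1 <- relu(z1)
  z2 <- params$W2 %*% a1 + params$b2
  a2 <- relu(z2)
  z3 <- params$W3 %*% a2 + params$b3
  probs <- softmax_cols(z3)
  if (!training) return(list(probs = probs))
  list(probs = probs, caches = caches, flat = flat, z1 = z1, a1 = a1,
       z2 = z2, a2 = a2, pool_out_dim = dim(a))
}

# One SGD step on a batch: categorical cross-entropy gradient through the
# whole stack. labels are integers in 1..3. Returns updated params and the
# batch loss/accuracy.
cnn_sgd_step <- function(params, x, labels, lr) {
  B <- length(labels)
  fw <- cnn_forward(params, x, training = TRUE)
  p <- fw$probs
  picked <- p[cbind(labels, seq_len(B))]
  loss <- -mean(log(pmax(picked, 1e-12)))
  acc <- mean(max.col(t(p), ties.method = "first") == labels)

  dz3 <- p
  dz3[cbind(labels, seq_len(B))] <- dz3[cbind(labels, seq_len(B))] - 1
  dz3 <- dz3 / B
  dW3 <- tcrossprod(dz3, fw$a2); db3 <- rowSums(dz3)
  da2 <- crossprod(params$W3, dz3)
  dz2 <- da2 * (fw$z2 > 0)
  dW2 <- tcrossprod(dz2, fw$a1); db2 <- rowSums(dz2)
  da1 <- crossprod(params$W2, dz2)
  dz1 <- da1 * (fw$z1 > 0)
  dW1 <- tcrossprod(dz1, fw$flat); db1 <- rowSums(dz1)
  dflat <- crossprod(params$W1, dz1)
  da <- array(dflat, dim = fw$pool_out_dim)

  for (bk in rev(seq_along(params$conv))) {
    ch <- fw$caches[[bk]]
    dr <- pool_backward(da, ch$pool)
    dz <- dr * (ch$pre_relu > 0)
    cb <- conv_backward(dz, params$conv[[bk]]$K, ch$conv)
    params$conv[[bk]]$K <- params$conv[[bk]]$K - lr * cb$dK
    params$conv[[bk]]$b <- params$conv[[bk]]$b - lr * cb$db
    da <- cb$dx
  }
  params$W1 <- params$W1 - lr * dW1; params$b1 <- params$b1 - lr * db1
  params$W2 <- params$W2 - lr * dW2; params$b2 <- params$b2 - lr * db2
  params$W3 <- params$W3 - lr * dW3; params$b3 <- params$b3 - lr * db3
  list(params = params, loss = loss, acc = acc)
}
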