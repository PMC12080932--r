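# Small dense feed-forward network (tanh hidden layers, linear output)
# trained by full-batch Adam. Deliberately minimal: the signaling surrogate
# is a 14-input scalar-output regression net, and full-batch training with a
# fixed seed keeps donor models bit-reproducible.

# Glorot-scaled initialization; deterministic given the RNG state
nn_init <- function(n_in, hidden, n_out = 1L) {
  sizes <- c(n_in, hidden, n_out)
  W <- vector("list", length(sizes) - 1)
  b <- vector("list", length(sizes) - 1)
  for (l in seq_along(W)) {
    s <- sqrt(2 / (sizes[l] + sizes[l + 1]))
    W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1], sd = s),
                     sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  list(W = W, b = b, sizes = sizes)
}

# forward pass; X is n x n_in, returns n x n_out
nn_forward <- function(net, X) {
  A <- X
  nl <- length(net$W)
  for (l in seq_len(nl)) {
    Z <- A %*% net$W[[l]] + matrix(net$b[[l]], nrow(A), ncol(net$W[[l]]),
                                   byrow = TRUE)
    A <- if (l < nl) tanh(Z) else Z
  }
  A
}

# Adam on weighted mean squared error with a step-decayed learning rate;
# full-batch by default, minibatch SGD when batch_size > 0. sample_w:
# optional per-row weights (used to emphasize the basal record).
# noise_cols/noise_sd: per-epoch jitter injected into the given input
# columns (denoising augmentation) - teaches the one-step map to contract
# toward the trace manifold, which stabilizes closed-loop rollouts; the
# jitter amplitude decays by `noise_decay` over the run so late epochs
# fine-tune on clean inputs. The epoch loop runs in C++ (nn_train_cpp),
# seeded from R's RNG.
nn_train <- function(net, X, y, epochs = 1000L, lr = 5e-3,
                     sample_w = NULL, noise_cols = integer(0),
                     noise_sd = 0, noise_decay = 0.1, batch_size = 0L) {
  n <- nrow(X)
  if (is.null(sample_w)) sample_w <- rep(1, n)
  res <- nn_train_cpp(net$W, net$b, X, as.numeric(y), sample_w,
                      as.integer(epochs), lr, as.integer(noise_cols),
                      noise_sd, noise_decay, as.integer(batch_size))
  net$W <- res$W
  net$b <- lapply(res$b, as.numeric)
  net$loss <- as.numeric(res$loss)
  net
}
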