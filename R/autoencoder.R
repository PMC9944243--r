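# Dense autoencoder (input -> hidden(ReLU) -> bottleneck(ReLU) ->
# hidden(ReLU) -> input(linear)) trained full-batch with Adam on MSE.
# Written in base R; gradients are exact (verified against numerical
# differentiation in the test suite).

ae_init <- function(n_in, d_hidden, d_out, seed) {
  set.seed(seed)
  he <- function(n1, n2) matrix(stats::rnorm(n1 * n2, 0, sqrt(2 / n1)),
                                n1, n2)
  list(W1 = he(n_in, d_hidden),   b1 = rep(0, d_hidden),
       W2 = he(d_hidden, d_out),  b2 = rep(0, d_out),
       W3 = he(d_out, d_hidden),  b3 = rep(0, d_hidden),
       W4 = he(d_hidden, n_in),   b4 = rep(0, n_in))
}

ae_forward <- function(p, X) {
  Z1 <- sweep(X %*% p$W1, 2, p$b1, "+");  A1 <- pmax(Z1, 0)
  Z2 <- sweep(A1 %*% p$W2, 2, p$b2, "+"); A2 <- pmax(Z2, 0)
  Z3 <- sweep(A2 %*% p$W3, 2, p$b3, "+"); A3 <- pmax(Z3, 0)
  Y  <- sweep(A3 %*% p$W4, 2, p$b4, "+")
  list(A1 = A1, A2 = A2, A3 = A3, Y = Y)
}

ae_backward <- function(p, X, fw) {
  n <- nrow(X)
  # objective: squared error summed over features, averaged over samples
  dY <- 2 * (fw$Y - X) / n
  g <- list()
  g$W4 <- crossprod(fw$A3, dY); g$b4 <- colSums(dY)
  dA3 <- dY %*% t(p$W4); dZ3 <- dA3 * (fw$A3 > 0)
  g$W3 <- crossprod(fw$A2, dZ3); g$b3 <- colSums(dZ3)
  dA2 <- dZ3 %*% t(p$W3); dZ2 <- dA2 * (fw$A2 > 0)
  g$W2 <- crossprod(fw$A1, dZ2); g$b2 <- colSums(dZ2)
  dA1 <- dZ2 %*% t(p$W2); dZ1 <- dA1 * (fw$A1 > 0)
  g$W1 <- crossprod(X, dZ1); g$b1 <- colSums(dZ1)
  g
}

# Adam optimizer over an arbitrary named list of arrays. Moments live in
# one flat vector (one allocation per update instead of one per parameter);
# the elementwise update formula is the textbook one.
adam_init <- function(params) {
  sizes <- vapply(params, length, integer(1))
  list(m = numeric(sum(sizes)), v = numeric(sum(sizes)), t = 0,
       sizes = sizes, ends = cumsum(sizes))
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  g <- unlist(grads[names(params)], use.names = FALSE)
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g * g
  step <- lr * (state$m / (1 - beta1^state$t)) /
    (sqrt(state$v / (1 - beta2^state$t)) + eps)
  p <- unlist(params, use.names = FALSE) - step
  start <- 1L
  for (k in seq_along(params)) {
    params[[k]][] <- p[start:state$ends[k]]
    start <- state$ends[k] + 1L
  }
  list(params = params, state = state)
}

#' Train a dense autoencoder and return bottleneck embeddings
#'
#' Trained with mini-batch Adam (seeded shuffling each epoch): on these
#' data sizes full-batch updates plateau in dead-ReLU regions for some
#' initializations, while small batches converge reliably. A
#' \code{batch_size} of \code{nrow(X)} or more recovers full-batch
#' training.
#'
#' @param X samples x features matrix.
#' @param d_hidden hidden width (default 512).
#' @param d_out bottleneck width (default 256).
#' @param epochs training epochs (default 100).
#' @param lr Adam learning rate.
#' @param batch_size mini-batch size (default 32).
#' @param seed RNG seed for initialization and batch shuffling.
#' @return list: \code{embedding} (samples x d_out bottleneck activations),
#'   \code{loss_trace} (per-epoch full-data MSE), \code{params}.
#' @export
train_autoencoder <- function(X, d_hidden = 512, d_out = 256, epochs = 100,
                              lr = 1e-3, batch_size = 32, seed = 1) {
  X <- as.matrix(X)
  p <- ae_init(ncol(X), d_hidden, d_out, seed)
  st <- adam_init(p)
  set.seed(seed)
  n <- nrow(X)
  trace <- numeric(epochs)
  for (e in seq_len(epochs)) {
    trace[e] <- mean((ae_forward(p, X)$Y - X)^2)
    ord <- if (batch_size < n) sample.int(n) else seq_len(n)
    for (b in split(ord, ceiling(seq_along(ord) / batch_size))) {
      Xb <- X[b, , drop = FALSE]
      fw <- ae_forward(p, Xb)
      g <- ae_backward(p, Xb, fw)
      upd <- adam_step(p, g, st, lr = lr)
      p <- upd$params; st <- upd$state
    }
  }
  emb <- ae_forward(p, X)$A2
  rownames(emb) <- rownames(X)
  list(embedding = emb, loss_trace = trace, params = p)
}
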