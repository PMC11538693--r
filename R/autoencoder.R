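#' Autoencoder configuration
#'
#' Settings for the node-embedding autoencoders. The embedding dimension `d`
#' is shared by species and sample autoencoders so both node types enter the
#' transformer with equal width.
#'
#' @param hidden_dim Embedding width d (default 64).
#' @param epochs Training epochs (default 200).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param seed RNG seed for weight initialisation.
#' @return List of class `"ae_config"`.
#' @export
ae_config <- function(hidden_dim = 64L, epochs = 200L,
                      learning_rate = 1e-3, seed = 1L) {
  if (hidden_dim <= 0) stop("hidden_dim must be positive")
  stopifnot(epochs >= 1, learning_rate > 0)
  structure(list(hidden_dim = as.integer(hidden_dim),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "ae_config")
}

# Single-hidden-layer autoencoder: X -> ReLU(X W1 + b1) -> X W2 + b2,
# mean-square-error reconstruction loss, Adam optimiser. Returns the hidden
# activations (one embedding row per input row) plus the loss trace.
train_autoencoder <- function(X, cfg) {
  stopifnot(is.matrix(X), nrow(X) >= 1)
  n <- nrow(X); p <- ncol(X); d <- cfg$hidden_dim
  if (d > min(dim(X)))
    warning(sprintf("hidden_dim %d exceeds min(dim(X)) = %d", d, min(dim(X))))
  set.seed(cfg$seed)
  sd1 <- sqrt(2 / (p + d))
  W1 <- matrix(stats::rnorm(p * d, sd = sd1), p, d)
  b1 <- numeric(d)
  W2 <- matrix(stats::rnorm(d * p, sd = sd1), d, p)
  b2 <- numeric(p)
  adam <- adam_state(length(W1) + length(b1) + length(W2) + length(b2),
                     lr = cfg$learning_rate)
  trace <- numeric(cfg$epochs + 1L)
  for (epoch in 0:cfg$epochs) {
    Z1 <- sweep(X %*% W1, 2L, b1, "+")
    H <- pmax(Z1, 0)
    R <- sweep(H %*% W2, 2L, b2, "+")
    E <- R - X
    trace[epoch + 1L] <- mean(E^2)
    if (epoch == cfg$epochs) break
    dR <- 2 * E / length(E)
    gW2 <- crossprod(H, dR); gb2 <- colSums(dR)
    dH <- dR %*% t(W2)
    dZ1 <- dH * (Z1 > 0)
    gW1 <- crossprod(X, dZ1); gb1 <- colSums(dZ1)
    g <- c(gW1, gb1, gW2, gb2)
    th <- adam_step(adam, c(W1, b1, W2, b2), g)
    W1[] <- th[seq_along(W1)]
    b1 <- th[length(W1) + seq_len(d)]
    W2[] <- th[length(W1) + d + seq_along(W2)]
    b2 <- th[length(W1) + d + length(W2) + seq_len(p)]
  }
  list(embedding = pmax(sweep(X %*% W1, 2L, b1, "+"), 0),
       loss_trace = trace, config = cfg)
}

#' Initial node embeddings from denoising-free autoencoders
#'
#' Trains one autoencoder per node type: the species autoencoder reconstructs
#' each species' length-N abundance profile, the sample autoencoder each
#' sample's length-M profile. The hidden-layer activations become the initial
#' d-dimensional node embeddings of the graph transformer.
#'
#' @param A Preprocessed species x sample matrix.
#' @param cfg An [ae_config()].
#' @return List with `species` (M x d) and `sample` (N x d) embedding
#'   matrices, each carrying attribute `loss_trace`.
#' @export
initial_embeddings <- function(A, cfg = ae_config()) {
  validate_abundance(A)
  if (nrow(A) < 2) stop("need at least 2 species")
  sp <- train_autoencoder(A, cfg)                 # rows = species profiles
  sa <- train_autoencoder(t(A), cfg)              # rows = sample profiles
  es <- sp$embedding; rownames(es) <- rownames(A)
  ep <- sa$embedding; rownames(ep) <- colnames(A)
  attr(es, "loss_trace") <- sp$loss_trace
  attr(ep, "loss_trace") <- sa$loss_trace
  list(species = es, sample = ep)
}

# Adam optimiser kept in an environment; theta and grad are flat vectors.
adam_state <- function(n, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  e <- new.env(parent = emptyenv())
  e$m <- numeric(n); e$v <- numeric(n); e$t <- 0L
  e$lr <- lr; e$b1 <- beta1; e$b2 <- beta2; e$eps <- eps
  e
}

adam_step <- function(state, theta, grad) {
  state$t <- state$t + 1L
  state$m <- state$b1 * state$m + (1 - state$b1) * grad
  state$v <- state$b2 * state$v + (1 - state$b2) * grad^2
  mhat <- state$m / (1 - state$b1^state$t)
  vhat <- state$v / (1 - state$b2^state$t)
  theta - state$lr * mhat / (sqrt(vhat) + state$eps)
}
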