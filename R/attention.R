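# Self-attention branch, implemented directly in base R.
#
# The pooled embedding of a record is treated as a single token: Q, K and
# V projections are applied, attention scores Q K^T / d_k pass through a
# softmax — which over a single key is identically 1, so the attended
# representation equals the value projection and the query/key weights
# receive no gradient — and a one-hidden-layer feed-forward head with a
# sigmoid output produces the branch probability. Trained full-batch with
# Adam under binary cross-entropy. This degenerate single-token form is
# deliberate and documented: with one token per record, self-attention
# reduces to projection + feed-forward.

attention_init <- function(width, d_model, d_hidden, seed) {
  withr::with_seed(seed, {
    g <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sqrt(1 / nr)),
                                 nr, nc)
    list(Wq = g(width, d_model), Wk = g(width, d_model),
         Wv = g(width, d_model),
         W1 = g(d_model, d_hidden), b1 = numeric(d_hidden),
         W2 = g(d_hidden, 1L), b2 = 0)
  })
}

attention_forward <- function(par, X, d_k) {
  Q <- X %*% par$Wq
  K <- X %*% par$Wk
  V <- X %*% par$Wv
  # one token per record: the softmax over a single key is exactly 1
  score <- rowSums(Q * K) / d_k
  att_w <- rep(1, nrow(X))
  Tm <- V * att_w
  H <- Tm %*% par$W1
  H <- sweep(H, 2L, par$b1, "+")
  A <- pmax(H, 0)
  z <- drop(A %*% par$W2) + par$b2
  p <- 1 / (1 + exp(-z))
  list(Q = Q, K = K, V = V, score = score, att_w = att_w,
       Tm = Tm, H = H, A = A, z = z, p = p)
}

attention_backward <- function(par, X, y, fw) {
  n <- nrow(X)
  dz <- (fw$p - y) / n                     # BCE + sigmoid
  dW2 <- crossprod(fw$A, dz)
  db2 <- sum(dz)
  dA <- tcrossprod(dz, drop(par$W2))
  dH <- dA * (fw$H > 0)
  dW1 <- crossprod(fw$Tm, dH)
  db1 <- colSums(dH)
  dT <- dH %*% t(par$W1)
  # attention weight is the constant 1: the gradient flows only through V
  dWv <- crossprod(X, dT)
  list(Wq = 0 * par$Wq, Wk = 0 * par$Wk, Wv = dWv,
       W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
}

adam_step <- function(state, par, grad, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(par)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grad[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grad[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, par = par)
}

#' Train the self-attention branch
#'
#' Fits the single-token self-attention classifier on an embedding matrix:
#' Q/K/V projections (the scaling constant `d_k` defaults to the embedding
#' width), feed-forward head, sigmoid output; optimized full-batch with
#' Adam (learning rate 0.001) for 128 epochs under binary cross-entropy,
#' from a seeded initialization. No early stopping.
#'
#' @param E Embedding matrix (rows = records).
#' @param y Binary 0/1 labels.
#' @param d_model Projection width (default 32).
#' @param d_hidden Feed-forward hidden width (default 32).
#' @param d_k Attention scaling constant (default `ncol(E)`).
#' @param lr Adam learning rate.
#' @param epochs Training epochs.
#' @param seed Integer seed for the initialization.
#' @return Object of class `attention_branch` with the learned parameters,
#'   configuration and final training loss.
#' @export
train_attention <- function(E, y, d_model = 32L, d_hidden = 32L,
                            d_k = ncol(E), lr = 0.001, epochs = 128L,
                            seed = 1L) {
  stopifnot(is.matrix(E), nrow(E) == length(y))
  if (nrow(E) < 20L) stop("attention branch needs at least 20 records")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  width <- ncol(E)
  par <- attention_init(width, d_model, d_hidden, seed)
  state <- list(m = lapply(par, function(p) 0 * p),
                v = lapply(par, function(p) 0 * p))
  loss <- NA_real_
  for (t in seq_len(epochs)) {
    fw <- attention_forward(par, E, d_k)
    p <- pmin(pmax(fw$p, 1e-12), 1 - 1e-12)
    loss <- -mean(y * log(p) + (1 - y) * log(1 - p))
    grad <- attention_backward(par, E, y, fw)
    upd <- adam_step(state, par, grad, lr, t)
    state <- upd$state; par <- upd$par
  }
  structure(list(par = par, width = width, d_model = d_model,
                 d_hidden = d_hidden, d_k = d_k, lr = lr, epochs = epochs,
                 seed = seed, final_loss = loss),
            class = "attention_branch")
}

#' Predict probabilities from the attention branch
#'
#' @param object An `attention_branch`.
#' @param newdata Embedding matrix with the trained width.
#' @param ... Unused.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict.attention_branch <- function(object, newdata, ...) {
  if (ncol(newdata) != object$width) {
    stop("embedding width ", ncol(newdata), " does not match the trained ",
         "width ", object$width)
  }
  fw <- attention_forward(object$par, newdata, object$d_k)
  pmin(pmax(fw$p, 1e-9), 1 - 1e-9)
}

#' Attention weights for a batch
#'
#' Returns the per-record attention weight rows (each row sums to 1; with
#' the single-token input every row is the scalar 1).
#'
#' @param object An `attention_branch`.
#' @param newdata Embedding matrix.
#' @return Matrix of attention weights, one row per record.
#' @export
attention_weights <- function(object, newdata) {
  fw <- attention_forward(object$par, newdata, object$d_k)
  matrix(fw$att_w, ncol = 1L,
         dimnames = list(rownames(newdata), "token1"))
}
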