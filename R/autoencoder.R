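#' Train a single-hidden-layer autoencoder
#'
#' Reconstructs a continuous feature block through one tanh hidden layer of
#' width `K` (linear output), minimizing mean squared reconstruction error
#' by full-batch Adam with seeded Glorot initialization. Columns are
#' standardized internally to zero mean / unit variance before training.
#'
#' @param block Numeric matrix or feature table of continuous features
#'   (no missing values; screening runs before any block merging).
#' @param K Hidden width; default `min(32, ceiling(G / 8))` with G inputs,
#'   a deliberately tight bottleneck so hidden capacity is spent on shared
#'   variance structure rather than per-feature noise.
#' @param epochs Training epochs (default 200); `0` returns the seeded
#'   untrained model, flagged in its training trace.
#' @param learning_rate Adam step size.
#' @param seed Integer seed for initialization.
#' @return An object of class `drp_autoencoder` with weights `W_in`
#'   (G x K), `W_out` (K x G), biases, and a training trace.
#' @export
train_autoencoder <- function(block, K = NULL, epochs = 200,
                              learning_rate = 0.01, seed = 1) {
  x <- if (is.data.frame(block)) feature_matrix(block) else as.matrix(block)
  if (anyNA(x) || any(!is.finite(x))) abort("Autoencoder input must be finite with no missing values.")
  g <- ncol(x)
  # a real bottleneck is essential: spare hidden capacity gets spent on
  # idiosyncratic noise and dilutes the contributions of co-varying features
  if (is.null(K)) K <- max(1L, min(32L, as.integer(ceiling(g / 8))))
  if (K >= g) abort("Hidden width K must be smaller than the number of inputs (compression).")
  std <- standardize_columns(x)
  x <- std$values
  n <- nrow(x)
  with_seed(seed, {
    lim1 <- sqrt(6 / (g + K)); lim2 <- sqrt(6 / (K + g))
    W1 <- matrix(runif(g * K, -lim1, lim1), g, K)
    W2 <- matrix(runif(K * g, -lim2, lim2), K, g)
    b1 <- numeric(K); b2 <- numeric(g)
    params <- list(W1 = W1, W2 = W2, b1 = b1, b2 = b2)
    m1 <- v1 <- lapply(params, function(p) p * 0)
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    loss_trace <- numeric(0)
    if (epochs > 0) {
      for (t in seq_len(epochs)) {
        h <- tanh(sweep(x %*% params$W1, 2, params$b1, "+"))
        xhat <- sweep(h %*% params$W2, 2, params$b2, "+")
        err <- xhat - x
        loss_trace[t] <- mean(err^2)
        grads <- list(
          W1 = crossprod(x, (err %*% t(params$W2)) * (1 - h^2)) / n,
          W2 = crossprod(h, err) / n,
          b1 = colMeans((err %*% t(params$W2)) * (1 - h^2)),
          b2 = colMeans(err)
        )
        for (nm in names(params)) {
          m1[[nm]] <- beta1 * m1[[nm]] + (1 - beta1) * grads[[nm]]
          v1[[nm]] <- beta2 * v1[[nm]] + (1 - beta2) * grads[[nm]]^2
          mhat <- m1[[nm]] / (1 - beta1^t)
          vhat <- v1[[nm]] / (1 - beta2^t)
          params[[nm]] <- params[[nm]] - learning_rate * mhat / (sqrt(vhat) + eps)
        }
      }
    }
    structure(list(
      G = g, K = K,
      W_in = params$W1, W_out = params$W2, b_in = params$b1, b_out = params$b2,
      feature_ids = colnames(x),
      trace = list(epochs = epochs, loss = loss_trace,
                   final_loss = if (epochs > 0) loss_trace[epochs] else NA_real_,
                   trained = epochs > 0),
      seed = as.integer(seed)
    ), class = "drp_autoencoder")
  })
}

#' Connection-weight input contributions (Gedeon method)
#'
#' Propagates normalized absolute connection weights through the hidden
#' layer: `P_in[i, k] = |W_in[i, k]| / sum_i |W_in[i, k]|` (each hidden
#' unit's column sums to 1), `P_out[k, j]` analogously over hidden units,
#' `Q = P_in %*% P_out`, and the total contribution of input `i` is
#' `q_i = sum_j Q[i, j] / sum_i Q[i, j]`. The column-stochastic
#' normalization makes `sum_i q_i = G` an algebraic identity.
#'
#' Absolute weights are used: signed weights can cancel in the denominator
#' and make contributions non-monotone in weight magnitude.
#'
#' @param model A `drp_autoencoder`.
#' @return A list of class `drp_contributions`: `P_in`, `P_out`, `Q`, and
#'   the tibble `scores` (`feature`, `q`).
#' @export
input_contributions <- function(model) {
  stopifnot(inherits(model, "drp_autoencoder"))
  a_in <- abs(model$W_in)
  a_out <- abs(model$W_out)
  col_in <- colSums(a_in)
  dead <- col_in == 0
  if (any(dead)) {
    warn(paste0(sum(dead), " hidden unit(s) have all-zero incoming weights; ",
                "their contribution columns are left at zero."))
    col_in[dead] <- 1
  }
  p_in <- sweep(a_in, 2, col_in, "/")
  col_out <- colSums(a_out)
  col_out[col_out == 0] <- 1
  p_out <- sweep(a_out, 2, col_out, "/")
  q_mat <- p_in %*% p_out
  denom <- colSums(q_mat)
  denom[denom == 0] <- 1
  q <- rowSums(sweep(q_mat, 2, denom, "/"))
  structure(list(
    P_in = p_in, P_out = p_out, Q = q_mat,
    scores = tibble::tibble(feature = model$feature_ids %||% paste0("x", seq_len(model$G)),
                            q = unname(q))
  ), class = "drp_contributions")
}
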