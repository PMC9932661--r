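# Feed-forward network head: tanh hidden layers with dropout, RMSE loss,
# mini-batch gradient descent with momentum.

#' Fit a feed-forward regression network
#'
#' Hidden layers use tanh activation with (inverted) dropout active only
#' during training; the output is linear. Inputs and the target are
#' standardized internally (recorded for prediction). Training minimizes
#' RMSE by seeded mini-batch gradient descent with momentum. The default
#' architecture is four hidden layers of 1000, 800, 500 and 100 units;
#' scale the widths down for small problems.
#'
#' @param tbl Feature table (or numeric matrix); missing values are
#'   median-imputed with recorded medians.
#' @param y Numeric response or response tibble.
#' @param widths Hidden-layer widths.
#' @param dropout_rate Per-hidden-layer dropout probability in `[0, 1)`.
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size (capped at `n`).
#' @param learning_rate,momentum Optimizer settings.
#' @param seed Integer seed.
#' @return An object of class `drp_mlp` with weights and an RMSE trace.
#' @export
fit_mlp <- function(tbl, y, widths = c(1000, 800, 500, 100), dropout_rate = 0.1,
                    epochs = 100, batch_size = 32, learning_rate = 0.01,
                    momentum = 0.9, seed = 1) {
  if (is.data.frame(y)) y <- align_samples(tbl, y)$y
  if (dropout_rate < 0 || dropout_rate >= 1) abort("dropout_rate must be in [0, 1).")
  dm <- if (is.data.frame(tbl)) design_matrix(tbl) else
    list(x = cbind(1, as.matrix(tbl)), impute = NULL)
  x_raw <- dm$x[, -1, drop = FALSE]
  xs <- standardize_columns(x_raw)
  ys_mean <- mean(y); ys_sd <- sd(y)
  if (!is.finite(ys_sd) || ys_sd == 0) ys_sd <- 1
  yt <- (y - ys_mean) / ys_sd
  n <- nrow(xs$values)
  batch_size <- min(batch_size, n)
  sizes <- c(ncol(x_raw), widths, 1)
  n_layers <- length(sizes) - 1
  with_seed(seed, {
    w <- vector("list", n_layers); b <- vector("list", n_layers)
    vw <- vector("list", n_layers); vb <- vector("list", n_layers)
    for (l in seq_len(n_layers)) {
      lim <- sqrt(6 / (sizes[l] + sizes[l + 1]))
      w[[l]] <- matrix(runif(sizes[l] * sizes[l + 1], -lim, lim), sizes[l], sizes[l + 1])
      b[[l]] <- numeric(sizes[l + 1])
      vw[[l]] <- w[[l]] * 0; vb[[l]] <- b[[l]] * 0
    }
    trace <- numeric(epochs)
    forward_train <- function(xb) {
      acts <- list(xb)          # post-dropout inputs to each layer
      raws <- list()            # tanh outputs before dropout (for tanh')
      masks <- list()
      for (l in seq_len(n_layers)) {
        z <- sweep(acts[[l]] %*% w[[l]], 2, b[[l]], "+")
        if (l < n_layers) {
          t_out <- tanh(z)
          raws[[l]] <- t_out
          if (dropout_rate > 0) {
            mask <- matrix(runif(length(t_out)) >= dropout_rate, nrow(t_out)) / (1 - dropout_rate)
            masks[[l]] <- mask
            acts[[l + 1]] <- t_out * mask
          } else {
            acts[[l + 1]] <- t_out
          }
        } else {
          acts[[l + 1]] <- z
        }
      }
      list(acts = acts, raws = raws, masks = masks)
    }
    if (epochs > 0) {
      for (ep in seq_len(epochs)) {
        idx <- sample.int(n)
        batches <- split(idx, ceiling(seq_along(idx) / batch_size))
        for (bt in batches) {
          fw <- forward_train(xs$values[bt, , drop = FALSE])
          pred <- fw$acts[[n_layers + 1]][, 1]
          resid <- pred - yt[bt]
          r <- sqrt(mean(resid^2))
          if (!is.finite(r)) abort("Training diverged (non-finite RMSE); lower the learning rate.")
          # dRMSE/dpred = resid / (m * rmse); guard the zero-loss case
          delta <- matrix(resid / (length(bt) * max(r, 1e-12)), ncol = 1)
          for (l in rev(seq_len(n_layers))) {
            gw <- crossprod(fw$acts[[l]], delta)
            gb <- colSums(delta)
            if (l > 1) {
              back <- delta %*% t(w[[l]])
              if (dropout_rate > 0) back <- back * fw$masks[[l - 1]]
              delta <- back * (1 - fw$raws[[l - 1]]^2)
            }
            vw[[l]] <- momentum * vw[[l]] - learning_rate * gw
            vb[[l]] <- momentum * vb[[l]] - learning_rate * gb
            w[[l]] <- w[[l]] + vw[[l]]
            b[[l]] <- b[[l]] + vb[[l]]
          }
        }
        full <- xs$values
        for (l in seq_len(n_layers)) {
          full <- sweep(full %*% w[[l]], 2, b[[l]], "+")
          if (l < n_layers) full <- tanh(full)
        }
        trace[ep] <- sqrt(mean((full[, 1] - yt)^2))
        if (!is.finite(trace[ep])) abort("Training diverged (non-finite RMSE); lower the learning rate.")
      }
    }
    structure(list(
      weights = w, biases = b, widths = widths, dropout_rate = dropout_rate,
      x_center = xs$center, x_scale = xs$scale, y_center = ys_mean, y_scale = ys_sd,
      impute = dm$impute, feature_ids = colnames(x_raw),
      trace = list(epochs = epochs, rmse = trace * ys_sd,
                   trained = epochs > 0),
      seed = as.integer(seed)
    ), class = "drp_mlp")
  })
}

#' Predict from a fitted network
#'
#' Deterministic forward pass with dropout disabled (inference mode);
#' predictions are returned on the original response scale.
#'
#' @param model A `drp_mlp`.
#' @param newdata Feature table or matrix with the training columns.
#' @return Numeric predictions.
#' @export
predict_mlp <- function(model, newdata) {
  stopifnot(inherits(model, "drp_mlp"))
  x <- if (is.data.frame(newdata)) {
    missing_cols <- setdiff(model$feature_ids, names(newdata))
    if (length(missing_cols)) abort(paste0("newdata lacks feature(s): ",
                                           paste(head(missing_cols, 5), collapse = ", ")))
    design_matrix(newdata[, c("sample_id", model$feature_ids)], impute = model$impute)$x[, -1, drop = FALSE]
  } else as.matrix(newdata)
  if (ncol(x) != length(model$x_center)) abort("Column count does not match training data.")
  a <- sweep(sweep(x, 2, model$x_center), 2, model$x_scale, "/")
  n_layers <- length(model$weights)
  for (l in seq_len(n_layers)) {
    a <- sweep(a %*% model$weights[[l]], 2, model$biases[[l]], "+")
    if (l < n_layers) a <- tanh(a)
  }
  a[, 1] * model$y_scale + model$y_center
}

#' @export
predict.drp_mlp <- function(object, newdata, ...) predict_mlp(object, newdata)
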