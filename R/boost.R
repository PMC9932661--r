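# Layer 3: from-scratch second-order gradient-boosted regression trees with
# learned default directions for missing values, and gain-based selection.

#' Second-order split gain
#'
#' Objective reduction of splitting a node into left/right children with
#' optimal L2-regularized leaf weights `w* = -G / (H + lambda)`:
#' `gain = 1/2 [G_L^2/(H_L+lambda) + G_R^2/(H_R+lambda)
#'              - (G_L+G_R)^2/(H_L+H_R+lambda)] - gamma`.
#'
#' @param g_left,h_left,g_right,h_right Summed gradients/hessians per side.
#' @param lambda L2 penalty on leaf weights (>= 0).
#' @param gamma_penalty Per-leaf complexity cost (>= 0).
#' @return The gain (can be negative).
#' @export
split_gain <- function(g_left, h_left, g_right, h_right, lambda = 1, gamma_penalty = 0) {
  term <- function(g, h) {
    d <- h + lambda
    ifelse(d > 0, g^2 / d, 0)
  }
  0.5 * (term(g_left, h_left) + term(g_right, h_right) -
           term(g_left + g_right, h_left + h_right)) - gamma_penalty
}

# Best split for one node. Exact greedy over sorted unique values per
# feature; missing-value samples are tried on both sides and the higher-gain
# side becomes the default direction (ties -> left). Ties between splits
# break to lowest feature index, then lowest threshold. Returns NULL when
# the best gain is <= 0.
best_split <- function(x, node_idx, g, h, lambda, gamma_penalty) {
  best <- NULL
  best_gain <- 0
  gi <- g[node_idx]; hi <- h[node_idx]
  g_tot <- sum(gi); h_tot <- sum(hi)
  xn <- x[node_idx, , drop = FALSE]
  for (j in seq_len(ncol(x))) {
    xv <- xn[, j]
    obs <- !is.na(xv)
    if (sum(obs) < 1 || all(!obs)) next
    xo <- xv[obs]
    ux <- sort(unique(xo))
    if (length(ux) < 2) next
    ord <- order(xo)
    xs <- xo[ord]
    gs <- cumsum(gi[obs][ord])
    hs <- cumsum(hi[obs][ord])
    g_miss <- g_tot - gs[length(gs)]
    h_miss <- h_tot - hs[length(hs)]
    # candidate cut after each run of equal values (except the last)
    cut_pos <- which(diff(xs) > 0)
    if (!length(cut_pos)) next
    g_l <- gs[cut_pos]; h_l <- hs[cut_pos]
    g_r <- gs[length(gs)] - g_l; h_r <- hs[length(hs)] - h_l
    gain_left <- split_gain(g_l + g_miss, h_l + h_miss, g_r, h_r, lambda, gamma_penalty)
    gain_right <- split_gain(g_l, h_l, g_r + g_miss, h_r + h_miss, lambda, gamma_penalty)
    take_left <- gain_left >= gain_right
    gain <- pmax(gain_left, gain_right)
    k <- which.max(gain)
    if (gain[k] > best_gain + 1e-12) {
      best_gain <- gain[k]
      best <- list(
        feature = j,
        threshold = (xs[cut_pos[k]] + xs[cut_pos[k] + 1]) / 2,
        default_left = take_left[k],
        gain = gain[k]
      )
    }
  }
  best
}

# Depth-first tree growth; returns a list of node records.
grow_tree <- function(x, g, h, max_depth, lambda, gamma_penalty) {
  nodes <- list()
  new_node <- function(rec) {
    nodes[[length(nodes) + 1L]] <<- rec
    length(nodes)
  }
  build <- function(idx, depth) {
    leaf_weight <- -sum(g[idx]) / (sum(h[idx]) + lambda)
    if (depth >= max_depth || length(idx) < 2) {
      return(new_node(list(leaf = TRUE, weight = leaf_weight, n = length(idx))))
    }
    sp <- best_split(x, idx, g, h, lambda, gamma_penalty)
    if (is.null(sp)) {
      return(new_node(list(leaf = TRUE, weight = leaf_weight, n = length(idx))))
    }
    xv <- x[idx, sp$feature]
    go_left <- ifelse(is.na(xv), sp$default_left, xv < sp$threshold)
    id <- new_node(list(leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
                        default_left = sp$default_left, gain = sp$gain,
                        left = NA_integer_, right = NA_integer_, n = length(idx)))
    left_id <- build(idx[go_left], depth + 1L)
    right_id <- build(idx[!go_left], depth + 1L)
    nodes[[id]]$left <<- left_id
    nodes[[id]]$right <<- right_id
    id
  }
  root <- build(seq_len(nrow(x)), 0L)
  list(nodes = nodes, root = root)
}

predict_tree <- function(tree, x) {
  n <- nrow(x)
  out <- numeric(n)
  route <- function(node_id, idx) {
    node <- tree$nodes[[node_id]]
    if (isTRUE(node$leaf)) {
      out[idx] <<- node$weight
      return(invisible(NULL))
    }
    xv <- x[idx, node$feature]
    go_left <- ifelse(is.na(xv), node$default_left, xv < node$threshold)
    if (any(go_left)) route(node$left, idx[go_left])
    if (any(!go_left)) route(node$right, idx[!go_left])
  }
  if (n) route(tree$root, seq_len(n))
  out
}

#' Fit a second-order gradient-boosted tree ensemble
#'
#' Squared-error loss, so per-sample gradients are `g_i = F(x_i) - y_i` and
#' hessians `h_i = 1`. The base score is `mean(y)`; each round grows one
#' tree depth-first with exact greedy splits (see [split_gain()]), leaf
#' weights `-G/(H+lambda)`, and learned default directions for missing
#' values; predictions are updated with the shrinkage factor. The training
#' loss is checked to be non-increasing across rounds.
#'
#' @param tbl Feature table (missing values allowed).
#' @param y Numeric response aligned to rows, or a response tibble.
#' @param rounds Number of boosting rounds `M` (default 50).
#' @param max_depth Maximum tree depth (default 4).
#' @param lambda L2 leaf-weight penalty (default 1).
#' @param gamma_penalty Per-leaf cost (default 0).
#' @param shrinkage Learning rate in (0, 1] (default 0.3).
#' @return An object of class `drp_boost`.
#' @export
fit_boosted_trees <- function(tbl, y, rounds = 50, max_depth = 4, lambda = 1,
                              gamma_penalty = 0, shrinkage = 0.3) {
  if (is.data.frame(y)) y <- align_samples(tbl, y)$y
  if (rounds < 0) abort("rounds must be non-negative.")
  if (shrinkage <= 0 || shrinkage > 1) abort("shrinkage must be in (0, 1].")
  x <- feature_matrix(tbl)
  n <- nrow(x)
  if (n < 2) abort("Need at least 2 samples.")
  base_score <- mean(y)
  pred <- rep(base_score, n)
  trees <- vector("list", rounds)
  loss <- numeric(rounds)
  prev_loss <- mean((y - pred)^2)
  for (m in seq_len(rounds)) {
    g <- pred - y
    h <- rep(1, n)
    tree <- grow_tree(x, g, h, max_depth, lambda, gamma_penalty)
    trees[[m]] <- tree
    pred <- pred + shrinkage * predict_tree(tree, x)
    loss[m] <- mean((y - pred)^2)
    stopifnot(loss[m] <= prev_loss + 1e-10)
    prev_loss <- loss[m]
  }
  structure(list(
    trees = trees, feature_ids = colnames(x), base_score = base_score,
    params = list(rounds = rounds, max_depth = max_depth, lambda = lambda,
                  gamma_penalty = gamma_penalty, shrinkage = shrinkage),
    train_loss = loss
  ), class = "drp_boost")
}

#' @export
predict.drp_boost <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) {
    missing_cols <- setdiff(object$feature_ids, names(newdata))
    if (length(missing_cols)) abort(paste0("newdata lacks feature(s): ",
                                           paste(head(missing_cols, 5), collapse = ", ")))
    feature_matrix(newdata[, c("sample_id", object$feature_ids)])
  } else as.matrix(newdata)
  pred <- rep(object$base_score, nrow(x))
  for (tree in object$trees) {
    pred <- pred + object$params$shrinkage * predict_tree(tree, x)
  }
  pred
}

#' Per-feature total split gain
#'
#' Sums recorded split gains per feature over all trees; features never used
#' in a split have importance 0.
#'
#' @param ensemble A `drp_boost`.
#' @return Tibble `feature`, `gain`, sorted by decreasing gain (ties by
#'   original column order).
#' @export
feature_importance_gain <- function(ensemble) {
  stopifnot(inherits(ensemble, "drp_boost"))
  gain <- setNames(numeric(length(ensemble$feature_ids)), ensemble$feature_ids)
  for (tree in ensemble$trees) {
    for (node in tree$nodes) {
      if (!isTRUE(node$leaf)) gain[node$feature] <- gain[node$feature] + node$gain
    }
  }
  tibble::tibble(feature = ensemble$feature_ids, gain = unname(gain)) |>
    dplyr::arrange(dplyr::desc(.data$gain), match(.data$feature, ensemble$feature_ids))
}

#' @exportS3Method generics::tidy
tidy.drp_boost <- function(x, ...) feature_importance_gain(x)

#' Third-layer selection by boosted-tree gain
#'
#' Fits a boosted ensemble and keeps features with positive total split
#' gain, capped at `cap` (top gains; ties to the lowest original index).
#'
#' @inheritParams fit_boosted_trees
#' @param cap Maximum number of surviving features (default 40).
#' @param ... Passed to [fit_boosted_trees()].
#' @return A list: `features` (reduced table), `report` (`drp_selection`
#'   with per-feature gains), `ensemble` (the fitted `drp_boost`).
#' @export
select_layer3 <- function(tbl, y, cap = 40, ...) {
  if (is.data.frame(y)) y <- align_samples(tbl, y)$y
  ensemble <- fit_boosted_trees(tbl, y, ...)
  imp <- feature_importance_gain(ensemble)
  ids <- feature_cols(tbl)
  positive <- imp$feature[imp$gain > 0]
  if (!length(positive)) {
    abort("All split gains are zero; increase rounds or max_depth.")
  }
  kept <- intersect(ids, head(positive, cap))
  out <- setdiff(ids, kept)
  dropped <- tibble::tibble(
    feature = out,
    reason = ifelse(out %in% positive, "over cap", "zero gain")
  )
  rep <- new_selection_report(3L, kept, dropped,
                              tibble::tibble(feature = imp$feature, q = imp$gain))
  list(features = tbl[, c("sample_id", kept)], report = rep, ensemble = ensemble)
}
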