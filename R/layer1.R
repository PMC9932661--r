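# Layer 1: contribution-ranking screen + correlation dedup + MUT merge.

new_selection_report <- function(layer, kept, dropped, scores) {
  structure(list(layer = layer, kept = kept, dropped = dropped, scores = scores),
            class = "drp_selection")
}

#' @export
print.drp_selection <- function(x, ...) {
  cat("<selection report, layer ", x$layer, ">\n",
      "  kept:    ", length(x$kept), " feature(s)\n",
      "  dropped: ", nrow(x$dropped), " feature(s)\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.drp_selection <- function(x, ...) x$scores

#' Rank features by contribution and keep a fraction
#'
#' Sorts features by total contribution `q` in descending order and retains
#' exactly `ceiling(keep_fraction * G)` of them. The default keeps the top
#' of the ranking (a screen should retain influential inputs); set
#' `direction = "bottom"` for the opposite convention. Ties are broken by
#' original column order.
#'
#' @param scores A tibble with columns `feature` and `q` (e.g. from
#'   [input_contributions()]), or a named numeric vector.
#' @param keep_fraction Fraction of features to keep, in `(0, 1]`
#'   (default 0.5).
#' @param direction `"top"` (default) or `"bottom"` end of the ranking.
#' @return A `drp_selection` report (layer 1).
#' @export
rank_and_cut <- function(scores, keep_fraction = 0.5, direction = c("top", "bottom")) {
  direction <- match.arg(direction)
  if (is.numeric(scores)) scores <- tibble::tibble(feature = names(scores), q = unname(scores))
  if (keep_fraction <= 0 || keep_fraction > 1) abort("keep_fraction must be in (0, 1].")
  g <- nrow(scores)
  n_keep <- as.integer(ceiling(keep_fraction * g))
  ord <- order_desc_stable(scores$q)
  kept_idx <- sort(if (direction == "top") head(ord, n_keep) else tail(ord, n_keep))
  kept <- scores$feature[kept_idx]
  dropped <- tibble::tibble(feature = scores$feature[setdiff(seq_len(g), kept_idx)],
                            reason = "below contribution cut")
  new_selection_report(1L, kept, dropped, scores)
}

#' Deduplicate highly correlated features
#'
#' Builds a graph with an edge between every feature pair whose absolute
#' Pearson correlation (pairwise-complete) exceeds `threshold` (strictly),
#' and keeps one representative per connected component: the member with
#' the highest contribution `q`, ties to the lowest original index.
#' Constant (zero-variance) features have undefined correlations and form
#' singleton components, with a warning.
#'
#' @param block Feature table or numeric matrix of the retained continuous
#'   features.
#' @param scores Tibble (`feature`, `q`) covering the block's features.
#' @param threshold Absolute-correlation threshold (default 0.8).
#' @return A `drp_selection` report; `$components` maps each feature to its
#'   component id.
#' @export
correlation_dedup <- function(block, scores, threshold = 0.8) {
  x <- if (is.data.frame(block)) feature_matrix(block) else as.matrix(block)
  ids <- colnames(x)
  g <- ncol(x)
  q <- scores$q[match(ids, scores$feature)]
  if (anyNA(q)) abort("scores must cover every feature in the block.")
  cm <- suppressWarnings(cor(x, use = "pairwise.complete.obs"))
  if (anyNA(diag(cm)) || any(apply(x, 2, sd, na.rm = TRUE) == 0, na.rm = TRUE)) {
    warn("Zero-variance feature(s): correlation undefined; treated as singleton components.")
  }
  cm[is.na(cm)] <- 0
  adj <- abs(cm) > threshold
  diag(adj) <- FALSE
  comp <- integer(g); cur <- 0L
  for (i in seq_len(g)) {
    if (comp[i] == 0L) {
      cur <- cur + 1L
      queue <- i
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        if (comp[v] == 0L) {
          comp[v] <- cur
          queue <- c(queue, which(adj[v, ] & comp == 0L))
        }
      }
    }
  }
  keep_idx <- vapply(split(seq_len(g), comp), function(members) {
    members[order_desc_stable(q[members])[1]]
  }, integer(1))
  kept <- ids[sort(keep_idx)]
  dropped_ids <- setdiff(ids, kept)
  dropped <- tibble::tibble(
    feature = dropped_ids,
    reason = paste0("correlated with ", ids[keep_idx[comp[match(dropped_ids, ids)]]])
  )
  rep <- new_selection_report(1L, kept, dropped,
                              tibble::tibble(feature = ids, q = q))
  rep$components <- setNames(comp, ids)
  rep
}

#' First-layer screen: contribution cut, dedup, MUT merge
#'
#' Runs one autoencoder per continuous kind (RNA and CNV), scores features
#' by connection-weight contributions, keeps the top `keep_fraction` per
#' kind, deduplicates correlated survivors, and merges the result with all
#' MUT (and FP, if present) features untouched.
#'
#' @param tbl A feature table with RNA and/or CNV blocks (no missing values
#'   in the continuous blocks).
#' @param keep_fraction,direction Passed to [rank_and_cut()].
#' @param cor_threshold Passed to [correlation_dedup()].
#' @param K,epochs Passed to [train_autoencoder()] (per-kind `K` is
#'   recomputed from that block's width when `NULL`).
#' @param seed Integer seed.
#' @inheritParams feature_kinds
#' @return A list: `features` (screened feature table) and `report`
#'   (`drp_selection` with per-kind sub-reports in `$by_kind`).
#' @export
screen_layer1 <- function(tbl, keep_fraction = 0.5, direction = "top",
                          cor_threshold = 0.8, K = NULL, epochs = 200,
                          seed = 1, kind_map = default_kind_map) {
  validate_feature_table(tbl, kind_map)
  kinds <- feature_kinds(tbl, kind_map)
  by_kind <- list()
  kept <- character(0)
  dropped <- tibble::tibble(feature = character(0), reason = character(0))
  scores_all <- tibble::tibble(feature = character(0), q = numeric(0))
  for (kind in c("RNA", "CNV")) {
    ids <- names(kinds)[kinds == kind]
    if (!length(ids)) next
    if (length(ids) < 2) {
      warn(paste0("Kind ", kind, " has fewer than 2 features; screening skipped."))
      kept <- c(kept, ids)
      next
    }
    block <- tbl[, c("sample_id", ids)]
    ae <- train_autoencoder(block, K = K, epochs = epochs, seed = seed)
    contrib <- input_contributions(ae)
    cut_rep <- rank_and_cut(contrib$scores, keep_fraction, direction)
    dedup_rep <- correlation_dedup(tbl[, c("sample_id", cut_rep$kept)],
                                   contrib$scores, cor_threshold)
    by_kind[[kind]] <- list(cut = cut_rep, dedup = dedup_rep)
    kept <- c(kept, dedup_rep$kept)
    dropped <- dplyr::bind_rows(dropped, cut_rep$dropped, dedup_rep$dropped)
    scores_all <- dplyr::bind_rows(scores_all, contrib$scores)
  }
  passthrough <- names(kinds)[kinds %in% c("MUT", "FP")]
  kept_ordered <- intersect(feature_cols(tbl), c(kept, passthrough))
  report <- new_selection_report(1L, kept_ordered, dropped, scores_all)
  report$by_kind <- by_kind
  list(features = tbl[, c("sample_id", kept_ordered)], report = report)
}
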