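# Layer 2: plug-in mutual information + greedy mRMR selection.

# Discretize one variable into equal-frequency bins. Variables with at most
# `bins` distinct values keep their observed levels (binary stays binary).
# Returns integer codes (NA preserved) and the level count.
discretize <- function(x, bins) {
  ux <- sort(unique(x[!is.na(x)]))
  if (length(ux) <= bins) {
    return(list(codes = match(x, ux), levels = length(ux)))
  }
  breaks <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1), na.rm = TRUE))
  if (length(breaks) < 3) {
    # massive ties collapse the quantile grid: fall back to distinct values
    return(list(codes = match(x, ux), levels = length(ux)))
  }
  codes <- as.integer(cut(x, breaks, include.lowest = TRUE))
  list(codes = codes, levels = length(breaks) - 1L)
}

# Plug-in MI (nats) from integer code vectors; complete pairs only.
mi_from_codes <- function(cx, cy, lx, ly) {
  ok <- !is.na(cx) & !is.na(cy)
  n <- sum(ok)
  if (n == 0) abort("No complete pairs for mutual information.")
  cx <- cx[ok]; cy <- cy[ok]
  joint <- tabulate((cx - 1L) * ly + cy, nbins = lx * ly) / n
  px <- tabulate(cx, lx) / n
  py <- tabulate(cy, ly) / n
  pos <- which(joint > 0)
  i <- (pos - 1L) %/% ly + 1L
  j <- (pos - 1L) %% ly + 1L
  list(value = sum(joint[pos] * log(joint[pos] / (px[i] * py[j]))), n = n)
}

#' Plug-in mutual information between two variables
#'
#' Discretizes continuous variables into equal-frequency bins (binary and
#' low-cardinality variables keep their observed levels), then computes the
#' plug-in mutual information of the joint histogram in natural-log units.
#' Missing pairs are dropped (pairwise-complete). Deterministic.
#'
#' @param x,y Numeric vectors of equal length.
#' @param bins Target bin count for continuous variables (default 10,
#'   reduced to 5 when fewer than 100 complete pairs remain).
#' @return One-row tibble: `value` (nats), `bins_x`, `bins_y`, `n`.
#' @export
mutual_information <- function(x, y, bins = 10) {
  if (length(x) != length(y)) abort("x and y must have equal length.")
  n_ok <- sum(!is.na(x) & !is.na(y))
  if (!n_ok) abort("No complete pairs for mutual information.")
  if (n_ok < 100 && bins > 5) bins <- 5L
  if (n_ok < bins) {
    warn("Fewer complete pairs than bins; reducing bin count.")
    bins <- max(2L, n_ok)
  }
  dx <- discretize(x, bins); dy <- discretize(y, bins)
  mi <- mi_from_codes(dx$codes, dy$codes, dx$levels, dy$levels)
  tibble::tibble(value = mi$value, bins_x = dx$levels, bins_y = dy$levels, n = mi$n)
}

#' Greedy minimum-redundancy--maximum-relevance selection
#'
#' Step 1 selects the feature with maximal relevance `I(Y, X_i)` (the
#' redundancy term is defined as 0 while the selected set is empty); each
#' later step adds the candidate maximizing
#' `I(Y, X_i) - mean_{s in S} I(X_s, X_i)`. Every pair's mutual information
#' is computed once and accumulated in a running redundancy sum. Ties break
#' to the lowest original column index; selection order is recorded.
#' Missing data are handled pairwise-complete.
#'
#' @param tbl A feature table.
#' @param y Numeric response vector aligned to `tbl` rows, or a response
#'   tibble (joined on `sample_id`).
#' @param m Number of features to select.
#' @param bins Discretization bins (see [mutual_information()]).
#' @return A `drp_selection` report (layer 2); `$scores` holds relevance
#'   per feature and `$path` the selection order with winning scores.
#' @export
mrmr_select <- function(tbl, y, m, bins = 10) {
  if (is.data.frame(y)) y <- align_samples(tbl, y)$y
  if (m <= 0) abort("m must be positive.")
  ids <- feature_cols(tbl)
  p <- length(ids)
  if (m > p) abort("m exceeds the number of candidate features.")
  x <- feature_matrix(tbl)
  n <- nrow(x)
  if (n < 100 && bins > 5) bins <- 5L
  dy <- discretize(y, bins)
  disc <- lapply(seq_len(p), function(jj) discretize(x[, jj], bins))
  codes <- vapply(disc, `[[`, integer(n), "codes")
  levels_vec <- vapply(disc, `[[`, integer(1), "levels")

  relevance <- vapply(seq_len(p), function(jj)
    mi_from_codes(dy$codes, codes[, jj], dy$levels, levels_vec[jj])$value, numeric(1))

  selected <- integer(0)
  red_sum <- numeric(p)        # sum over selected s of I(X_s, X_i)
  path_score <- numeric(m)
  for (step in seq_len(m)) {
    cand <- setdiff(seq_len(p), selected)
    score <- if (step == 1) relevance[cand] else
      relevance[cand] - red_sum[cand] / length(selected)
    best <- order_desc_stable(score)[1]
    pick <- cand[best]
    path_score[step] <- score[best]
    selected <- c(selected, pick)
    remaining <- setdiff(seq_len(p), selected)
    if (length(remaining) && step < m) {
      red_sum[remaining] <- red_sum[remaining] + vapply(remaining, function(jj)
        mi_from_codes(codes[, pick], codes[, jj], levels_vec[pick], levels_vec[jj])$value,
        numeric(1))
    }
  }
  kept <- ids[selected]
  dropped <- tibble::tibble(feature = setdiff(ids, kept), reason = "not selected by mRMR")
  rep <- new_selection_report(2L, kept, dropped,
                              tibble::tibble(feature = ids, q = relevance))
  rep$path <- tibble::tibble(step = seq_len(m), feature = kept, score = path_score)
  rep
}
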