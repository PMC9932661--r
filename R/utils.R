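# Internal helpers shared across modules.

# Names of feature columns (everything except the sample id column).
feature_cols <- function(tbl) setdiff(names(tbl), "sample_id")

# Numeric matrix of feature values, sample ids as rownames.
feature_matrix <- function(tbl) {
  m <- as.matrix(tbl[, feature_cols(tbl), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- tbl$sample_id
  m
}

matrix_to_table <- function(m, sample_ids = rownames(m)) {
  out <- tibble::as_tibble(as.data.frame(m))
  dplyr::bind_cols(tibble::tibble(sample_id = sample_ids), out)
}

# Deterministic scoped RNG: every stochastic operation takes an integer
# seed and restores the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Stable ranking index: descending by score, ties by original position.
order_desc_stable <- function(score) {
  order(-score, seq_along(score))
}

r_squared <- function(truth, estimate) {
  ss_tot <- sum((truth - mean(truth))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((truth - estimate)^2) / ss_tot
}

rmse <- function(truth, estimate) {
  sqrt(mean((truth - estimate)^2))
}

# Column standardization that tolerates constant columns (sd -> 1).
standardize_columns <- function(m) {
  mu <- colMeans(m)
  s <- apply(m, 2, sd)
  s[!is.finite(s) | s == 0] <- 1
  list(values = sweep(sweep(m, 2, mu), 2, s, "/"), center = mu, scale = s)
}
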