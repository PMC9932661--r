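#' Simulate a cell-line drug-response dataset
#'
#' Generates a feature table with the statistical structure the pipeline
#' assumes: RNA and CNV features drawn from correlated Gaussian blocks,
#' sparse binary MUT features, binary FP (fingerprint-bit) features, and a
#' strictly positive response `y_i ~ Gamma(shape_k, scale = mu_i / shape_k)`
#' whose mean follows a log-linear model `mu_i = exp(beta0 + sum_j beta_j
#' x_ij)` over a small set of informative features. Informative features are
#' placed inside the correlated RNA/CNV blocks first (so that correlated
#' near-duplicates of signal exist, as in co-expressed gene modules), then
#' among MUT bits if more are requested.
#'
#' Effect sizes default to magnitudes drawn uniformly from 0.3 to 1.0 with
#' random signs: detectable but not trivial at the sample sizes typical of
#' per-drug pharmacogenomic panels (tens of cell lines).
#'
#' @param n_samples,n_rna,n_cnv,n_mut,n_fp Dimensions of each block.
#' @param n_informative Number of features truly driving the response.
#' @param shape_k Gamma shape parameter (> 0); variance is `mu^2 / shape_k`.
#' @param block_rho Pairwise correlation within declared RNA/CNV blocks.
#' @param block_size Number of features per correlated block.
#' @param beta0 Intercept of the log-linear mean model.
#' @param beta_range Magnitude range for informative coefficients.
#' @param mut_prob Bernoulli rate for MUT bits; `fp_prob` for FP bits.
#' @param seed Integer seed; all randomness flows from it.
#' @return A list: `features` (feature table), `response` (tibble
#'   `sample_id`, `response`), and `truth` (informative ids, coefficients,
#'   shape, block memberships, seed).
#' @export
simulate_dataset <- function(n_samples, n_rna = 0, n_cnv = 0, n_mut = 0, n_fp = 0,
                             n_informative = 0, shape_k = 5, block_rho = 0.7,
                             block_size = 5, beta0 = 1,
                             beta_range = c(0.3, 1.0),
                             mut_prob = 0.1, fp_prob = 0.3, seed = 1) {
  total <- n_rna + n_cnv + n_mut + n_fp
  if (total < 1 || n_samples < 1) abort("Need at least one sample and one feature.")
  if (n_informative > total) abort("n_informative exceeds the total feature count.")
  if (shape_k <= 0) abort("shape_k must be positive.")
  with_seed(seed, {
    blocks <- list()
    gauss_block <- function(n_feat, prefix) {
      if (n_feat == 0) return(NULL)
      n_blocks <- ceiling(n_feat / block_size)
      membership <- rep(seq_len(n_blocks), each = block_size)[seq_len(n_feat)]
      m <- matrix(0, n_samples, n_feat)
      for (b in seq_len(n_blocks)) {
        idx <- which(membership == b)
        shared <- rnorm(n_samples)
        # equicorrelated construction: x = sqrt(rho) z_shared + sqrt(1-rho) z_own
        m[, idx] <- sqrt(block_rho) * shared +
          sqrt(1 - block_rho) * matrix(rnorm(n_samples * length(idx)), n_samples)
      }
      colnames(m) <- paste0(prefix, "_g", seq_len(n_feat))
      blocks[[prefix]] <<- split(colnames(m), membership)
      m
    }
    rna <- gauss_block(n_rna, "rna")
    cnv <- gauss_block(n_cnv, "cnv")
    mut <- if (n_mut) matrix(rbinom(n_samples * n_mut, 1, mut_prob), n_samples,
                             dimnames = list(NULL, paste0("mut_g", seq_len(n_mut)))) else NULL
    fp <- if (n_fp) matrix(rbinom(n_samples * n_fp, 1, fp_prob), n_samples,
                           dimnames = list(NULL, paste0("fp_", seq_len(n_fp)))) else NULL
    x <- do.call(cbind, Filter(Negate(is.null), list(rna, cnv, mut, fp)))

    # informative ids: lead features of successive RNA/CNV blocks first,
    # so the signal sits inside correlated modules; MUT bits afterwards.
    continuous_leads <- unlist(lapply(c(blocks[["rna"]], blocks[["cnv"]]), `[`, 1),
                               use.names = FALSE)
    candidates <- unique(c(continuous_leads,
                           if (n_mut) paste0("mut_g", seq_len(n_mut)),
                           colnames(x)))
    informative <- head(candidates, n_informative)
    beta <- numeric(0)
    eta <- rep(beta0, n_samples)
    if (n_informative > 0) {
      beta <- runif(n_informative, beta_range[1], beta_range[2]) *
        sample(c(-1, 1), n_informative, replace = TRUE)
      names(beta) <- informative
      eta <- eta + as.vector(x[, informative, drop = FALSE] %*% beta)
    }
    mu <- exp(eta)
    y <- rgamma(n_samples, shape = shape_k, scale = mu / shape_k)
    sample_ids <- sprintf("s%0*d", nchar(n_samples), seq_len(n_samples))
    features <- matrix_to_table(x, sample_ids)
    list(
      features = features,
      response = tibble::tibble(sample_id = sample_ids, response = y),
      truth = list(informative_ids = informative, beta = beta, beta0 = beta0,
                   shape_k = shape_k, mu = setNames(mu, sample_ids),
                   correlation_blocks = blocks, seed = as.integer(seed))
    )
  })
}

#' Inject missing values into selected feature kinds
#'
#' Sets a seeded random subset of cells to `NA`, restricted to features of
#' the named kinds; everything else is untouched. Emulates the missingness
#' that arises when heterogeneous feature blocks are merged across drugs.
#'
#' @param tbl A feature table.
#' @param rate Per-cell missingness probability in `[0, 1)`.
#' @param kinds Character subset of `c("RNA", "CNV", "MUT", "FP")`.
#' @param seed Integer seed.
#' @inheritParams feature_kinds
#' @return The feature table with `NA`s injected.
#' @export
inject_missing <- function(tbl, rate, kinds = c("RNA", "CNV", "MUT", "FP"),
                           seed = 1, kind_map = default_kind_map) {
  if (rate < 0 || rate >= 1) abort("rate must be in [0, 1).")
  if (rate == 0) return(tbl)
  k <- feature_kinds(tbl, kind_map)
  target <- names(k)[k %in% kinds]
  with_seed(seed, {
    for (id in target) {
      hit <- runif(nrow(tbl)) < rate
      tbl[[id]][hit] <- NA
    }
  })
  tbl
}
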