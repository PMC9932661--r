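# Fixture builders used across the suite. Everything is generated in code;
# no stored data files.

# Small feature table with all four kinds.
toy_table <- function(n = 6, seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(
      sample_id = paste0("s", seq_len(n)),
      rna_g1 = rnorm(n), rna_g2 = rnorm(n),
      cnv_g1 = rnorm(n),
      mut_g1 = rbinom(n, 1, 0.4),
      fp_1 = rbinom(n, 1, 0.5)
    )
  })
}

# Continuous block with `n_blocks` equicorrelated modules (the first member
# of each is the "lead") plus independent noise features, all tagged rna_.
# Used for contribution-enrichment checks: module members share variance
# structure the autoencoder can compress, noise features do not.
make_module_table <- function(n = 500, n_blocks = 10, block_size = 5,
                              n_noise = 150, rho = 0.7, seed = 1) {
  withr::with_seed(seed, {
    cols <- list()
    leads <- character(n_blocks)
    for (b in seq_len(n_blocks)) {
      shared <- rnorm(n)
      for (j in seq_len(block_size)) {
        nm <- paste0("rna_b", b, "m", j)
        if (j == 1) leads[b] <- nm
        cols[[nm]] <- sqrt(rho) * shared + sqrt(1 - rho) * rnorm(n)
      }
    }
    for (j in seq_len(n_noise)) cols[[paste0("rna_n", j)]] <- rnorm(n)
    tbl <- dplyr::bind_cols(tibble::tibble(sample_id = paste0("s", seq_len(n))),
                            tibble::as_tibble(cols))
    list(table = tbl, leads = leads)
  })
}

# Brute-force split oracle for the second-order tree objective: enumerates
# every feature, every threshold between distinct observed values, and both
# missing-direction assignments, scoring with the leaf-objective reduction.
brute_force_best_split <- function(x, g, h, lambda, gamma_penalty) {
  leaf_obj <- function(gs, hs) -0.5 * sum(gs)^2 / (sum(hs) + lambda)
  best <- NULL
  root_obj <- leaf_obj(g, h)
  for (j in seq_len(ncol(x))) {
    xv <- x[, j]
    obs <- which(!is.na(xv))
    miss <- which(is.na(xv))
    ux <- sort(unique(xv[obs]))
    if (length(ux) < 2) next
    thresholds <- (head(ux, -1) + tail(ux, -1)) / 2
    for (thr in thresholds) {
      for (miss_left in c(TRUE, FALSE)) {
        left <- c(obs[xv[obs] < thr], if (miss_left) miss)
        right <- setdiff(seq_along(g), left)
        if (!length(left) || !length(right)) next
        gain <- root_obj - leaf_obj(g[left], h[left]) - leaf_obj(g[right], h[right]) -
          gamma_penalty
        if (is.null(best) || gain > best$gain + 1e-12) {
          best <- list(feature = j, threshold = thr, default_left = miss_left,
                       gain = gain)
        }
      }
    }
  }
  best
}

# Independent plug-in MI oracle: explicit double loop over the joint table.
brute_force_mi <- function(x, y) {
  ux <- sort(unique(x)); uy <- sort(unique(y))
  n <- length(x)
  total <- 0
  for (a in ux) {
    for (b in uy) {
      pxy <- sum(x == a & y == b) / n
      if (pxy > 0) {
        total <- total + pxy * log(pxy / ((sum(x == a) / n) * (sum(y == b) / n)))
      }
    }
  }
  total
}
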