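test_that("a rank-1 pattern is reconstructed by a single hidden unit", {
  withr::with_seed(42, {
    u <- rnorm(80)
    v <- rnorm(12)
    x <- outer(u, v)
    colnames(x) <- paste0("rna_g", seq_len(12))
  })
  ae <- train_autoencoder(x, K = 1, epochs = 400, seed = 1)
  # inputs are standardized to unit variance, so loss < 0.1 means < 10% of
  # the input variance is unexplained
  expect_lt(ae$trace$final_loss, 0.1)
})

test_that("training is seeded and epochs = 0 returns a flagged untrained model", {
  x <- matrix(rnorm(200), 20, dimnames = list(NULL, paste0("rna_g", 1:10)))
  a <- train_autoencoder(x, K = 2, epochs = 20, seed = 7)
  b <- train_autoencoder(x, K = 2, epochs = 20, seed = 7)
  expect_identical(a$W_in, b$W_in)
  raw <- train_autoencoder(x, K = 2, epochs = 0, seed = 7)
  expect_false(raw$trace$trained)
  expect_true(is.matrix(raw$W_in))
  expect_error(train_autoencoder(x, K = 10), "compression")
  x[1, 1] <- NA
  expect_error(train_autoencoder(x, K = 2), "missing")
})

test_that("contributions match the two-input hand computation and sum to G", {
  model <- structure(list(
    G = 2L, K = 1L,
    W_in = matrix(c(1, 3), 2, 1), W_out = matrix(c(2, -5), 1, 2),
    feature_ids = c("rna_a", "rna_b")
  ), class = "drp_autoencoder")
  ct <- input_contributions(model)
  expect_equal(unname(ct$P_in[, 1]), c(0.25, 0.75))
  expect_equal(ct$scores$q, c(0.5, 1.5))
  expect_equal(sum(ct$scores$q), 2)

  # identical weight patterns across inputs give uniform contributions
  sym <- structure(list(
    G = 3L, K = 2L,
    W_in = matrix(1.5, 3, 2), W_out = matrix(rnorm(6), 2, 3),
    feature_ids = paste0("rna_", 1:3)
  ), class = "drp_autoencoder")
  expect_equal(input_contributions(sym)$scores$q, rep(1, 3))

  # algebraic identity on a trained model
  x <- matrix(rnorm(600), 30, dimnames = list(NULL, paste0("rna_g", 1:20)))
  trained <- train_autoencoder(x, K = 4, epochs = 50, seed = 3)
  ctt <- input_contributions(trained)
  expect_equal(sum(ctt$scores$q), 20, tolerance = 1e-8)
  expect_equal(unname(colSums(ctt$P_in)), rep(1, 4), tolerance = 1e-12)
  expect_equal(unname(colSums(ctt$P_out)), rep(1, 20), tolerance = 1e-12)
})

test_that("the contribution cut keeps exactly the requested fraction", {
  q <- withr::with_seed(1, runif(200))
  scores <- tibble::tibble(feature = paste0("rna_g", 1:200), q = q)
  rep1 <- rank_and_cut(scores, 0.5)
  expect_length(rep1$kept, 100)
  expect_setequal(c(rep1$kept, rep1$dropped$feature), scores$feature)
  expect_true(min(q[match(rep1$kept, scores$feature)]) >=
                max(q[match(rep1$dropped$feature, scores$feature)]))

  ties <- tibble::tibble(feature = paste0("f", 1:7), q = rep(1, 7))
  expect_identical(rank_and_cut(ties, 0.5)$kept, paste0("f", 1:4))
  expect_length(rank_and_cut(scores, 1)$kept, 200)
  expect_error(rank_and_cut(scores, 0), "keep_fraction")
})

test_that("correlation dedup keeps one survivor per duplicate component", {
  withr::with_seed(5, {
    base <- matrix(rnorm(300), 100, 3)
    x <- base[, rep(1:3, each = 3)] + matrix(rnorm(900, sd = 1e-6), 100)
    colnames(x) <- paste0("rna_g", 1:9)
  })
  q <- c(1, 5, 2, 3, 1, 2, 9, 9, 1)  # best of each triplet: g2, g4, g7 (tie g7/g8 -> g7)
  scores <- tibble::tibble(feature = colnames(x), q = q)
  rep1 <- correlation_dedup(x, scores, 0.8)
  expect_identical(rep1$kept, c("rna_g2", "rna_g4", "rna_g7"))
  expect_equal(length(unique(rep1$components)), 3)

  indep <- withr::with_seed(6, matrix(rnorm(500), 100, 5,
                                      dimnames = list(NULL, paste0("rna_g", 1:5))))
  scores5 <- tibble::tibble(feature = colnames(indep), q = 1:5)
  expect_length(correlation_dedup(indep, scores5, 0.8)$kept, 5)
  # strict inequality: exact threshold 1 never fires without exact duplicates
  expect_length(correlation_dedup(indep, scores5, 1.0)$kept, 5)
})

test_that("layer-1 screen composes the cut, dedup and MUT passthrough", {
  mut_only <- toy_table()[, c("sample_id", "mut_g1")]
  out <- screen_layer1(mut_only)
  expect_identical(out$features, mut_only)

  sim <- simulate_dataset(100, n_rna = 200, n_cnv = 200, n_mut = 10,
                          block_rho = 0, seed = 31)
  res <- screen_layer1(sim$features, epochs = 60, seed = 1)
  # independent features: no dedup removals expected, so ceil(100)+ceil(100)+10
  expect_equal(length(res$report$kept), 210)
  expect_true(all(grepl("^mut_", setdiff(res$report$kept,
                                         grep("^(rna|cnv)_", res$report$kept, value = TRUE)))))

  res2 <- screen_layer1(sim$features, epochs = 60, seed = 1)
  expect_identical(res$report$kept, res2$report$kept)
})

test_that("contribution screening is enriched for structured informative features", {
  hits <- vapply(1:5, function(s) {
    mod <- make_module_table(n = 500, n_blocks = 10, block_size = 5,
                             n_noise = 150, rho = 0.7, seed = s)
    res <- screen_layer1(mod$table, epochs = 80, seed = s)
    sum(mod$leads %in% res$report$kept)
  }, numeric(1))
  expect_gte(sum(hits >= 7), 4)
})
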