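test_that("split gain matches hand computations and limits", {
  expect_equal(split_gain(0, 2, 0, 3, lambda = 1, gamma_penalty = 0.5), -0.5)
  # g = (-2,-2,2,2), h = 1, middle split, lambda 1, gamma 0
  expect_equal(split_gain(-4, 2, 4, 2, lambda = 1), 16 / 3, tolerance = 1e-12)
  # heavy regularization drives the gain to -gamma monotonically
  gains <- vapply(c(1, 10, 100, 1e4, 1e8), function(l)
    split_gain(-4, 2, 4, 2, lambda = l, gamma_penalty = 0.25), numeric(1))
  expect_true(all(diff(gains) < 0))
  expect_equal(gains[5], -0.25, tolerance = 1e-6)
})

test_that("best split equals brute-force enumeration incl. missing directions", {
  # toy where the missing sample belongs on the right
  x <- matrix(c(1, 2, 3, 10, 11, NA), ncol = 1)
  g <- c(-2, -2, -2, 3, 3, 3)
  h <- rep(1, 6)
  got <- drpred:::best_split(x, 1:6, g, h, lambda = 0, gamma_penalty = 0)
  oracle <- brute_force_best_split(x, g, h, 0, 0)
  expect_false(got$default_left)
  expect_equal(got$gain, oracle$gain, tolerance = 1e-10)
  expect_equal(got$threshold, oracle$threshold)

  # without missing values both direction trials tie -> left by convention
  x2 <- matrix(c(1, 2, 3, 4), ncol = 1)
  got2 <- drpred:::best_split(x2, 1:4, c(-1, -1, 1, 1), rep(1, 4), 1, 0)
  expect_true(got2$default_left)

  # all-missing feature is skipped
  x3 <- cbind(c(NA, NA, NA, NA), c(1, 2, 3, 4))
  got3 <- drpred:::best_split(x3, 1:4, c(-1, -1, 1, 1), rep(1, 4), 1, 0)
  expect_equal(got3$feature, 2)

  # randomized oracle equivalence on tiny instances
  for (s in 1:25) {
    withr::with_seed(s, {
      n <- sample(4:8, 1)
      p <- sample(1:3, 1)
      xr <- matrix(rnorm(n * p), n, p)
      xr[withr::with_seed(s + 100, runif(n * p)) < 0.2] <- NA
      gr <- rnorm(n)
    })
    hr <- rep(1, n)
    mine <- drpred:::best_split(xr, seq_len(n), gr, hr, lambda = 0.5, gamma_penalty = 0)
    oracle <- brute_force_best_split(xr, gr, hr, 0.5, 0)
    if (is.null(oracle) || oracle$gain <= 0) {
      expect_null(mine)
    } else {
      expect_equal(mine$gain, oracle$gain, tolerance = 1e-10)
    }
  }
})

test_that("boosting drives training loss down monotonically to interpolation", {
  tbl <- tibble::tibble(sample_id = paste0("s", 1:8),
                        rna_g1 = c(0, 0, 0, 0, 1, 1, 1, 1))
  y <- c(1, 1, 1, 1, 5, 5, 5, 5)
  fit0 <- fit_boosted_trees(tbl, y, rounds = 0)
  expect_equal(predict(fit0, tbl), rep(3, 8))

  fit1 <- fit_boosted_trees(tbl, y, rounds = 1, max_depth = 1, lambda = 0,
                            shrinkage = 1)
  expect_equal(predict(fit1, tbl), y, tolerance = 1e-12)

  sim <- simulate_dataset(60, n_rna = 10, n_informative = 3, seed = 2)
  fit20 <- fit_boosted_trees(sim$features, sim$response, rounds = 20)
  expect_true(all(diff(fit20$train_loss) <= 1e-10))
  expect_error(fit_boosted_trees(tbl, y, rounds = -1), "non-negative")
})

test_that("leaf weights are optimal for the regularized objective", {
  sim <- simulate_dataset(40, n_rna = 5, n_informative = 2, seed = 13)
  y <- sim$response$response
  fit <- fit_boosted_trees(sim$features, y, rounds = 1, max_depth = 2, lambda = 1)
  tree <- fit$trees[[1]]
  g <- rep(fit$base_score, 40) - y
  h <- rep(1, 40)
  x <- drpred:::feature_matrix(sim$features)
  # recover each sample's leaf and check +/- eps perturbation raises the objective
  leaf_of <- function(i) {
    node <- tree$root
    repeat {
      nd <- tree$nodes[[node]]
      if (isTRUE(nd$leaf)) return(node)
      xv <- x[i, nd$feature]
      node <- if (is.na(xv)) {
        if (nd$default_left) nd$left else nd$right
      } else if (xv < nd$threshold) nd$left else nd$right
    }
  }
  leaves <- vapply(1:40, leaf_of, numeric(1))
  objective <- function(weights) {
    f <- weights[match(leaves, unique(leaves))]
    sum(g * f + 0.5 * h * f^2) + 0.5 * 1 * sum(weights^2)
  }
  w0 <- vapply(unique(leaves), function(l) tree$nodes[[l]]$weight, numeric(1))
  base <- objective(w0)
  for (j in seq_along(w0)) {
    for (eps in c(-1e-4, 1e-4)) {
      w <- w0; w[j] <- w[j] + eps
      expect_gt(objective(w), base)
    }
  }
})

test_that("gain-based importance recovers informative features", {
  hits <- vapply(1:5, function(s) {
    sim <- simulate_dataset(500, n_rna = 100, n_informative = 5, block_rho = 0,
                            beta_range = c(0.5, 1), seed = s + 40)
    # log scale makes the signal additive, the natural setting for gain ranking
    fit <- fit_boosted_trees(sim$features, log(sim$response$response),
                             rounds = 30, max_depth = 3)
    imp <- feature_importance_gain(fit)
    sum(sim$truth$informative_ids %in% imp$feature[1:5])
  }, numeric(1))
  expect_gte(sum(hits == 5), 4)

  sim <- simulate_dataset(30, n_rna = 5, seed = 3)
  fit0 <- fit_boosted_trees(sim$features, sim$response, rounds = 0)
  expect_true(all(feature_importance_gain(fit0)$gain == 0))
})

test_that("layer-3 selection caps the surviving feature count", {
  sim <- simulate_dataset(120, n_rna = 60, n_informative = 5, seed = 17)
  res <- select_layer3(sim$features, sim$response, cap = 10, rounds = 25)
  expect_lte(length(res$report$kept), 10)
  expect_true(all(res$report$scores$q[match(res$report$kept,
                                            res$report$scores$feature)] > 0))

  # a generous cap returns exactly the positive-gain set
  res2 <- select_layer3(sim$features, sim$response, cap = 1000, rounds = 25)
  expect_setequal(res2$report$kept,
                  res2$report$scores$feature[res2$report$scores$q > 0])

  expect_identical(select_layer3(sim$features, sim$response, cap = 10, rounds = 25)$report$kept,
                   res$report$kept)

  const <- tibble::tibble(sample_id = paste0("s", 1:10), rna_g1 = rep(1, 10))
  fitc <- fit_boosted_trees(const, rep(1:2, 5), rounds = 5)
  expect_true(all(feature_importance_gain(fitc)$gain == 0))
  expect_error(select_layer3(const, rep(1:2, 5), rounds = 5), "gains")
})
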