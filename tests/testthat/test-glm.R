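test_that("intercept-only gamma fit recovers the sample mean", {
  y <- withr::with_seed(1, rgamma(200, shape = 4, scale = 0.5))
  fit <- fit_glm(matrix(numeric(0), 200, 0), y, family = "gamma")
  expect_equal(unname(exp(fit$beta[1])), mean(y), tolerance = 1e-8)
  expect_true(all(fit$fitted > 0))
})

test_that("coefficients are recovered from a known gamma GLM", {
  sim <- simulate_dataset(2000, n_rna = 5, n_informative = 3, shape_k = 5,
                          block_rho = 0, seed = 77)
  fit <- fit_glm(sim$features, sim$response, family = "gamma")
  est <- tidy(fit)
  truth <- c(`(Intercept)` = sim$truth$beta0, sim$truth$beta)
  for (nm in names(truth)) {
    row <- est[est$term == nm, ]
    expect_lt(abs(row$estimate - truth[[nm]]), 3 * row$std.error)
  }
  expect_equal(fit$shape, 5, tolerance = 0.25)
  # deterministic IRLS: bitwise identical refit
  refit <- fit_glm(sim$features, sim$response, family = "gamma")
  expect_identical(fit$beta, refit$beta)
})

test_that("the exponential fit is the gamma likelihood at k = 1", {
  sim <- simulate_dataset(300, n_rna = 4, n_informative = 2, shape_k = 2, seed = 5)
  ga <- fit_glm(sim$features, sim$response, family = "gamma")
  ex <- fit_glm(sim$features, sim$response, family = "exponential")
  expect_equal(ga$beta, ex$beta, tolerance = 1e-10)
  expect_equal(ex$loglik, drpred:::gamma_loglik(drpred:::align_samples(
    sim$features, sim$response)$y, ga$fitted, 1), tolerance = 1e-8)
  expect_equal(ex$aic, 2 * length(ex$beta) - 2 * ex$loglik)
})

test_that("profile-ML shape agrees with the reference estimator", {
  sim <- simulate_dataset(400, n_rna = 3, n_informative = 2, shape_k = 3, seed = 14)
  df <- as.data.frame(sim$features[, -1])
  df$y <- sim$response$response
  ref <- stats::glm(y ~ ., data = df, family = Gamma(link = "log"))
  expect_equal(drpred:::gamma_shape_ml(df$y, stats::fitted(ref)),
               MASS::gamma.shape(ref)$alpha, tolerance = 1e-4)
})

test_that("rank deficiency and non-positive responses are rejected", {
  tbl <- tibble::tibble(sample_id = paste0("s", 1:20),
                        rna_g1 = rnorm(20), rna_g2 = 0)
  expect_error(fit_glm(tbl, rexp(20) + 0.1), "rank deficient")
  expect_error(fit_glm(tbl[, 1:2], c(rexp(19) + 0.1, -1)), "y > 0")
})

test_that("AIC selects the generating family", {
  wins <- vapply(1:10, function(s) {
    sim <- simulate_dataset(1000, n_rna = 3, n_informative = 2, shape_k = 5,
                            seed = s + 500)
    best <- select_family_by_aic(sim$features, sim$response)
    best$family
  }, character(1))
  expect_gte(sum(wins == "gamma"), 8)

  near <- vapply(1:10, function(s) {
    sim <- simulate_dataset(1000, n_rna = 3, n_informative = 2, shape_k = 1,
                            seed = s + 900)
    best <- select_family_by_aic(sim$features, sim$response)
    best$family %in% c("gamma", "exponential")
  }, logical(1))
  expect_gte(sum(near), 9)

  sim <- simulate_dataset(200, n_rna = 3, seed = 2)
  single <- select_family_by_aic(sim$features, sim$response, candidates = "gamma")
  expect_identical(single$family, "gamma")
})

test_that("noise columns rarely improve AIC beyond the parameter penalty", {
  deltas <- vapply(1:50, function(s) {
    sim <- simulate_dataset(200, n_rna = 2, n_informative = 1, shape_k = 4,
                            seed = s + 2000)
    with_noise <- dplyr::mutate(sim$features,
                                rna_noise = withr::with_seed(s, rnorm(200)))
    fit0 <- fit_glm(sim$features, sim$response, family = "gamma")
    fit1 <- fit_glm(with_noise, sim$response, family = "gamma")
    fit1$aic - fit0$aic
  }, numeric(1))
  expect_gt(mean(deltas), -2)
})

test_that("prediction intervals match closed forms and the CDF-inversion oracle", {
  y <- withr::with_seed(3, rexp(100, rate = 0.5))
  fit <- fit_glm(matrix(numeric(0), 100, 0), y, family = "exponential")
  mu <- unname(exp(fit$beta[1]))
  pi1 <- prediction_interval(fit, matrix(numeric(0), 1, 0), level = 0.95)
  expect_equal(pi1$lower, -mu * log(0.975), tolerance = 1e-8)
  expect_equal(pi1$upper, -mu * log(0.025), tolerance = 1e-8)

  # gamma k = 5, mu = 2: bisect the CDF independently of qgamma
  fake <- structure(list(family = "gamma", link = "log",
                         beta = c(`(Intercept)` = log(2)), shape = 5,
                         impute = NULL, feature_ids = character(0)),
                    class = "drp_glm")
  pi2 <- prediction_interval(fake, matrix(numeric(0), 1, 0), level = 0.95)
  bisect <- function(p) {
    lo <- 0; hi <- 50
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (pgamma(mid, shape = 5, scale = 2 / 5) < p) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  expect_equal(pi2$lower, bisect(0.025), tolerance = 1e-6)
  expect_equal(pi2$upper, bisect(0.975), tolerance = 1e-6)

  widths <- vapply(c(0.5, 0.8, 0.95, 0.99), function(lv) {
    pi_lv <- prediction_interval(fake, matrix(numeric(0), 1, 0), level = lv)
    pi_lv$upper - pi_lv$lower
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
  expect_error(prediction_interval(fake, matrix(numeric(0), 1, 0), level = 1.2),
               "level")
})

test_that("PICP counts closed-interval coverage", {
  iv <- tibble::tibble(sample_id = c("a", "b"), point = c(1, 1),
                       lower = c(0, 0), upper = c(Inf, Inf), level = 0.95)
  expect_equal(picp(iv, c(0.1, 100)), 1)
  iv2 <- dplyr::mutate(iv, upper = c(0.05, 0.05))
  expect_equal(picp(iv2, c(0.1, 100)), 0)
  expect_error(picp(iv[0, ], numeric(0)), "No intervals")
})

test_that("intervals are calibrated under the generating model", {
  sim <- simulate_dataset(1000, n_rna = 10, n_informative = 5, shape_k = 5,
                          beta_range = c(0.5, 0.5), block_rho = 0, seed = 404)
  train <- seq_len(500); test <- 501:1000
  fit <- fit_glm(sim$features[train, ], sim$response$response[train], family = "gamma")
  iv <- prediction_interval(fit, sim$features[test, ], level = 0.95)
  cover <- picp(iv, sim$response$response[test])
  expect_lt(abs(cover - 0.95), 3 * sqrt(0.95 * 0.05 / 500))
})

test_that("inverse-Gaussian fits expose a valid density and intervals", {
  withr::with_seed(8, {
    mu <- 2; lambda <- 6
    nu <- rnorm(400)^2
    xq <- mu + mu^2 * nu / (2 * lambda) -
      mu / (2 * lambda) * sqrt(4 * mu * lambda * nu + mu^2 * nu^2)
    u <- runif(400)
    y <- ifelse(u <= mu / (mu + xq), xq, mu^2 / xq)
  })
  fit <- fit_glm(matrix(numeric(0), 400, 0), y, family = "inverse_gaussian")
  expect_equal(unname(exp(fit$beta[1])), mean(y), tolerance = 1e-6)
  iv <- prediction_interval(fit, matrix(numeric(0), 1, 0), level = 0.9)
  expect_true(iv$lower > 0 && iv$upper > iv$lower)
})
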