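# Evaluation: k-fold CV with R^2 / RMSE / PICP, variance-homogeneity
# testing between predictive distributions, and the interval-based drug
# recommendation rule.

#' k-fold cross-validation of the prediction pipeline
#'
#' Partitions the samples into `k` near-equal seeded folds, refits the
#' requested pipeline on each training split, and pools the out-of-fold
#' predictions before computing metrics: `RMSE`, `R^2 = 1 - SS_res/SS_tot`,
#' and (for the GLM head) PICP of the prediction intervals.
#'
#' By default the feature-selection layers are refit inside every fold, so
#' no information from a test fold can leak into selection. Setting
#' `selection = "global"` performs selection once on all samples before CV
#' (the workflow many published pipelines use); this is optimistic and a
#' leakage warning is logged.
#'
#' @param tbl Feature table.
#' @param y Response vector or tibble.
#' @param config A [pipeline_config()]; governs which layers run and the
#'   head (`"glm"` or `"mlp"`).
#' @param k Fold count (default 10).
#' @param seed Integer seed for the fold partition (and any stochastic
#'   stages).
#' @param selection `"inside"` (default) or `"global"`.
#' @return An object of class `drp_cv`: fold assignments, pooled
#'   predictions tibble (`sample_id`, `truth`, `estimate`, `lower`,
#'   `upper`, `fold`), and `metrics`.
#' @export
kfold_cv <- function(tbl, y, config = pipeline_config(), k = 10, seed = 1,
                     selection = c("inside", "global")) {
  selection <- match.arg(selection)
  if (is.data.frame(y)) {
    al <- align_samples(tbl, y)
    tbl <- al$features; y <- al$y
  }
  n <- nrow(tbl)
  if (k < 2) abort("k must be at least 2.")
  if (k > n) abort("k exceeds the sample count.")
  folds <- with_seed(seed, {
    rep(seq_len(k), length.out = n)[sample.int(n)]
  })
  stopifnot(sort(unique(folds)) %in% seq_len(k), length(folds) == n)
  if (selection == "global") {
    inform("Global selection before CV: selection sees the test folds (optimistic).")
    tbl <- run_selection(tbl, y, config)$features
  }
  preds <- vector("list", k)
  for (fold in seq_len(k)) {
    test <- folds == fold
    train_tbl <- tbl[!test, , drop = FALSE]
    test_tbl <- tbl[test, , drop = FALSE]
    y_train <- y[!test]
    work <- train_tbl
    if (selection == "inside") {
      work <- run_selection(train_tbl, y_train, config)$features
      test_tbl <- test_tbl[, c("sample_id", feature_cols(work)), drop = FALSE]
    }
    if (config$head == "glm") {
      fit <- if (length(config$glm_candidates) > 1)
        select_family_by_aic(work, y_train, config$glm_candidates, config$glm_link)
      else fit_glm(work, y_train, config$glm_candidates, config$glm_link)
      pi_tbl <- prediction_interval(fit, test_tbl, config$interval_level)
      preds[[fold]] <- tibble::tibble(
        sample_id = test_tbl$sample_id, truth = y[test],
        estimate = pi_tbl$point, lower = pi_tbl$lower, upper = pi_tbl$upper,
        fold = fold
      )
    } else {
      fit <- fit_mlp(work, y_train, widths = config$mlp_widths,
                     dropout_rate = config$mlp_dropout, epochs = config$mlp_epochs,
                     batch_size = config$mlp_batch_size,
                     learning_rate = config$mlp_learning_rate, seed = seed + fold)
      preds[[fold]] <- tibble::tibble(
        sample_id = test_tbl$sample_id, truth = y[test],
        estimate = predict_mlp(fit, test_tbl),
        lower = NA_real_, upper = NA_real_, fold = fold
      )
    }
  }
  pooled <- dplyr::bind_rows(preds)
  stopifnot(nrow(pooled) == n, !anyDuplicated(pooled$sample_id))
  metrics <- tibble::tibble(
    k = k,
    r2 = r_squared(pooled$truth, pooled$estimate),
    rmse = rmse(pooled$truth, pooled$estimate),
    picp = if (config$head == "glm") picp(pooled, pooled$truth) else NA_real_
  )
  structure(list(k = k, folds = folds, predictions = pooled, metrics = metrics,
                 head = config$head, seed = as.integer(seed), selection = selection),
            class = "drp_cv")
}

#' @export
print.drp_cv <- function(x, ...) {
  cat("<", x$k, "-fold CV, ", x$head, " head, selection ", x$selection, ">\n", sep = "")
  print(x$metrics)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.drp_cv <- function(x, ...) x$predictions

#' @exportS3Method generics::glance
glance.drp_cv <- function(x, ...) x$metrics

#' Homogeneity-of-variance test between two samples
#'
#' Levene's test with median centering (robust for skewed IC50-like data;
#' the default) or Bartlett's test. Use [predictive_draws()] to turn two
#' fitted predictive distributions into samples first when comparing the
#' stability of two drugs' predictions.
#'
#' @param sample_a,sample_b Numeric samples (each length >= 2).
#' @param method `"levene"` or `"bartlett"`.
#' @return One-row tibble: `method`, `statistic`, `p_value`, `n_a`, `n_b`.
#' @export
variance_homogeneity_test <- function(sample_a, sample_b,
                                      method = c("levene", "bartlett")) {
  method <- match.arg(method)
  if (length(sample_a) < 2 || length(sample_b) < 2) abort("Each sample needs >= 2 values.")
  if (sd(sample_a) == 0 && sd(sample_b) == 0) {
    warn("Both samples have zero variance; degenerate test.")
    return(tibble::tibble(method = method, statistic = 0, p_value = 1,
                          n_a = length(sample_a), n_b = length(sample_b)))
  }
  values <- c(sample_a, sample_b)
  group <- factor(rep(c("a", "b"), c(length(sample_a), length(sample_b))))
  if (method == "levene") {
    lt <- car::leveneTest(values ~ group, center = median)
    stat <- lt[1, "F value"]; p <- lt[1, "Pr(>F)"]
  } else {
    bt <- bartlett.test(values, group)
    stat <- unname(bt$statistic); p <- bt$p.value
  }
  tibble::tibble(method = method, statistic = stat, p_value = p,
                 n_a = length(sample_a), n_b = length(sample_b))
}

#' Compare the stability of two fitted predictive distributions
#'
#' Draws seeded Monte-Carlo samples from each plug-in predictive
#' distribution (model-based predictive variance `mu^2 / k` for the gamma
#' family) and applies Levene's test to the draws.
#'
#' @param fit_a,fit_b Fitted `drp_glm` objects.
#' @param newdata_a,newdata_b New-sample rows for each fit.
#' @param n_draws Draws per sample.
#' @param seed Integer seed.
#' @return One-row tibble as in [variance_homogeneity_test()], with
#'   `method = "gamma_variance_ratio"`.
#' @export
predictive_stability_test <- function(fit_a, fit_b, newdata_a, newdata_b,
                                      n_draws = 2000, seed = 1) {
  draws_a <- predictive_draws(fit_a, newdata_a, n_draws, seed)
  draws_b <- predictive_draws(fit_b, newdata_b, n_draws, seed + 1)
  out <- variance_homogeneity_test(draws_a, draws_b, "levene")
  out$method <- "gamma_variance_ratio"
  out
}

#' Interval-based drug recommendation
#'
#' Encodes the interval-reading rule: candidates are ranked by point
#' prediction ascending (lower predicted IC50 = more potent); when the
#' leading candidates' point predictions are comparable (within
#' `margin` relative difference of the best), the one with the shortest
#' prediction interval is preferred (less fluctuation = more reliable
#' efficacy). Candidates whose lower *and* upper bounds exceed every
#' competitor's are flagged aggressive/high-risk. The result is invariant
#' to the input ordering.
#'
#' @param candidates Tibble with columns `drug`, `point`, `lower`, `upper`,
#'   `level` (one row per drug, intervals at a common level), e.g. built
#'   from [prediction_interval()] rows.
#' @param margin Relative margin within which point predictions count as
#'   comparable (default 0.2).
#' @return An object of class `drp_recommendation`: the annotated candidate
#'   tibble, the recommended drug, and a rationale string.
#' @export
recommend_drug <- function(candidates, margin = 0.2) {
  needed <- c("drug", "point", "lower", "upper", "level")
  if (!all(needed %in% names(candidates))) {
    abort(paste0("candidates needs columns: ", paste(needed, collapse = ", ")))
  }
  if (length(unique(candidates$level)) != 1) abort("All intervals must share one level.")
  cand <- candidates |>
    dplyr::mutate(width = .data$upper - .data$lower) |>
    dplyr::arrange(.data$point, .data$width, .data$drug)
  n <- nrow(cand)
  high_risk <- vapply(seq_len(n), function(i) {
    others <- cand[-i, ]
    nrow(others) > 0 &&
      all(cand$lower[i] > others$lower) && all(cand$upper[i] > others$upper)
  }, logical(1))
  cand$high_risk <- high_risk
  if (n == 1) {
    recommended <- cand$drug[1]
    rationale <- "Single candidate; recommended unconditionally."
  } else {
    comparable <- cand$point <= cand$point[1] * (1 + margin)
    pool <- cand[comparable, ]
    pick <- pool[order(pool$width, pool$point, pool$drug)[1], ]
    recommended <- pick$drug
    rationale <- if (sum(comparable) > 1) {
      paste0("Points within ", margin * 100, "% of the best are comparable; `",
             recommended, "` has the shortest ", pick$level * 100,
             "% interval (width ", signif(pick$width, 4), ") among them.")
    } else {
      paste0("`", recommended, "` has the clearly lowest predicted IC50 (next candidate > ",
             margin * 100, "% higher).")
    }
    if (any(high_risk)) {
      rationale <- paste0(rationale, " Flagged aggressive/high-risk (both bounds above all others): ",
                          paste(cand$drug[high_risk], collapse = ", "), ".")
    }
  }
  structure(list(candidates = cand, recommended = recommended, rationale = rationale,
                 margin = margin),
            class = "drp_recommendation")
}

#' @export
print.drp_recommendation <- function(x, ...) {
  cat("<drug recommendation>\n  recommended: ", x$recommended, "\n  ",
      x$rationale, "\n", sep = "")
  print(x$candidates)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.drp_recommendation <- function(x, ...) x$candidates
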