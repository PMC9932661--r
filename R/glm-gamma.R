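# GLM head: exponential-family fits, AIC family selection, plug-in gamma
# prediction intervals, and PICP.

# Design matrix from a feature table: median-impute remaining missing
# values (recording the medians for reuse at predict time) and add an
# intercept column.
design_matrix <- function(tbl, impute = NULL) {
  x <- feature_matrix(tbl)
  if (is.null(impute)) {
    impute <- apply(x, 2, median, na.rm = TRUE)
    impute[!is.finite(impute)] <- 0
  }
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) x[miss, j] <- impute[j]
  }
  list(x = cbind(`(Intercept)` = 1, x), impute = impute)
}

# Profile maximum-likelihood gamma shape given fitted means: Newton on
# d/dk loglik = n (log k + 1 - digamma(k)) + sum(log(y/mu) - y/mu).
gamma_shape_ml <- function(y, mu, max_iter = 50, tol = 1e-10) {
  n <- length(y)
  s <- sum(log(y / mu) - y / mu)
  # moment start from squared coefficient of variation of Pearson residuals
  k <- max(1 / mean(((y - mu) / mu)^2), 1e-3)
  for (i in seq_len(max_iter)) {
    score <- n * (log(k) + 1 - digamma(k)) + s
    info <- n * (1 / k - trigamma(k))
    step <- score / info
    k_new <- k - step
    if (k_new <= 0) k_new <- k / 2
    if (abs(k_new - k) < tol * (abs(k) + tol)) {
      k <- k_new
      break
    }
    k <- k_new
  }
  k
}

gamma_loglik <- function(y, mu, k) {
  sum(dgamma(y, shape = k, scale = mu / k, log = TRUE))
}

invgauss_loglik <- function(y, mu, lambda) {
  sum(0.5 * log(lambda / (2 * pi * y^3)) - lambda * (y - mu)^2 / (2 * mu^2 * y))
}

# Damped IRLS with step halving and a clamped linear predictor. glm.fit's
# unguarded steps can overflow exp(eta) on skewed high-leverage designs even
# though the log-link gamma log-likelihood is concave in beta; halving the
# step until the deviance is finite and non-increasing restores convergence.
irls_guarded <- function(x, y, fam, max_iter = 100, tol = 1e-8) {
  n <- length(y)
  clamp <- function(e) pmin(pmax(e, -30), 30)
  is_log <- fam$link == "log"
  eta <- if (is_log) clamp(qr.fitted(qr(x), log(y))) else fam$linkfun(rep(mean(y), n))
  beta <- qr.coef(qr(x), eta)
  beta[is.na(beta)] <- 0
  dev_of <- function(b) {
    e <- drop(x %*% b)
    if (is_log) e <- clamp(e)
    mu <- fam$linkinv(e)
    if (any(!is.finite(mu)) || any(mu <= 0)) return(Inf)
    sum(fam$dev.resids(y, mu, rep(1, n)))
  }
  dev_old <- dev_of(beta)
  converged <- FALSE
  iter <- 0L
  wqr <- NULL
  for (iter in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    if (is_log) eta <- clamp(eta)
    mu <- fam$linkinv(eta)
    me <- fam$mu.eta(eta)
    w <- me^2 / fam$variance(mu)
    z <- eta + (y - mu) / me
    wqr <- qr(x * sqrt(w))
    beta_prop <- qr.coef(wqr, z * sqrt(w))
    beta_prop[is.na(beta_prop)] <- 0
    step <- 1
    repeat {
      cand <- beta + step * (beta_prop - beta)
      dev_new <- dev_of(cand)
      if (is.finite(dev_new) && dev_new <= dev_old + 1e-8) break
      step <- step / 2
      if (step < 1e-12) {
        cand <- beta
        dev_new <- dev_old
        break
      }
    }
    rel <- abs(dev_new - dev_old) / (abs(dev_new) + 0.1)
    beta <- cand
    dev_old <- dev_new
    if (rel < tol) {
      converged <- TRUE
      break
    }
  }
  eta <- drop(x %*% beta)
  if (is_log) eta <- clamp(eta)
  list(coefficients = setNames(as.vector(beta), colnames(x)),
       fitted.values = fam$linkinv(eta),
       converged = converged, iter = iter, qr = wqr)
}

#' Fit an exponential-family GLM for positive responses
#'
#' Coefficients are estimated by iteratively reweighted least squares (via
#' `stats::glm.fit`, relative tolerance `1e-8`, up to 200 iterations;
#' a damped step-halving IRLS takes over if the unguarded steps overflow). The
#' gamma shape `k` is then estimated by one-dimensional Newton iteration on
#' the profile log-likelihood (digamma/trigamma); the exponential family is
#' the gamma with `k` fixed at 1 (identical coefficients under either
#' link, since the shape scales out of the score equations); the inverse
#' Gaussian dispersion has a closed-form ML estimate. AIC is
#' `2p - 2 loglik` with `p` counting coefficients plus the shape/dispersion
#' parameter where estimated. Remaining missing feature values are
#' median-imputed, with the medians recorded for prediction.
#'
#' @param tbl Feature table (or numeric matrix) of predictors.
#' @param y Strictly positive response vector, or a response tibble.
#' @param family `"gamma"`, `"exponential"`, or `"inverse_gaussian"`.
#' @param link `"log"` (default; keeps the mean positive for any
#'   coefficient vector) or `"inverse"`.
#' @param max_iter,tol IRLS controls.
#' @return An object of class `drp_glm`.
#' @export
fit_glm <- function(tbl, y, family = c("gamma", "exponential", "inverse_gaussian"),
                    link = c("log", "inverse"), max_iter = 200, tol = 1e-8) {
  family <- match.arg(family)
  link <- match.arg(link)
  if (is.data.frame(y)) y <- align_samples(tbl, y)$y
  if (any(y <= 0)) {
    bad <- which(y <= 0)
    abort(paste0("Gamma-family fitting needs y > 0; offending sample index(es): ",
                 paste(head(bad, 5), collapse = ", "),
                 ". Use the log1p transform for log-scale responses."))
  }
  dm <- if (is.data.frame(tbl)) design_matrix(tbl) else
    list(x = cbind(`(Intercept)` = 1, as.matrix(tbl)), impute = NULL)
  x <- dm$x
  if (qr(x)$rank < ncol(x)) abort("Design matrix is rank deficient; drop collinear or constant features.")
  fam <- if (family == "inverse_gaussian") inverse.gaussian(link = link) else Gamma(link = link)
  # a least-squares start on the link scale stabilizes IRLS far from the
  # default mustart = y initialization on skewed high-dimensional designs
  etastart <- if (link == "log") {
    qr.fitted(qr(x), log(y))
  } else {
    pmax(qr.fitted(qr(x), 1 / y), 1e-8)
  }
  # IRLS step-halving notes are routine; convergence is reported explicitly
  fit <- tryCatch(
    withCallingHandlers(
      glm.fit(x, y, family = fam, etastart = etastart,
              control = list(epsilon = tol, maxit = max_iter)),
      warning = function(w) {
        if (grepl("step size truncated|algorithm did not converge|stopped at boundary",
                  conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    ),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$converged) {
    fit <- irls_guarded(x, y, fam, max_iter = max_iter, tol = tol)
  }
  if (!fit$converged) warn(paste0("IRLS did not converge in ", max_iter, " iterations."))
  beta <- coef(fit)
  mu <- fit$fitted.values
  p <- length(beta)
  if (family == "gamma") {
    shape <- gamma_shape_ml(y, mu)
    ll <- gamma_loglik(y, mu, shape)
    n_par <- p + 1
    dispersion <- 1 / shape
  } else if (family == "exponential") {
    shape <- 1
    ll <- gamma_loglik(y, mu, 1)
    n_par <- p
    dispersion <- 1
  } else {
    lambda <- 1 / mean((y - mu)^2 / (mu^2 * y))
    shape <- NA_real_
    ll <- invgauss_loglik(y, mu, lambda)
    n_par <- p + 1
    dispersion <- 1 / lambda
  }
  # covariance of beta from the IRLS weighted crossproduct, scaled by the
  # estimated dispersion (likelihood-based for gamma/exponential)
  qr_r <- qr.R(fit$qr)
  cov_unscaled <- tryCatch(chol2inv(qr_r), error = function(e) NULL)
  structure(list(
    family = family, link = link, beta = beta,
    shape = shape, dispersion = dispersion,
    loglik = ll, aic = 2 * n_par - 2 * ll, n_par = n_par,
    converged = fit$converged, iterations = fit$iter,
    impute = dm$impute, feature_ids = setdiff(colnames(x), "(Intercept)"),
    fitted = mu, y = y, cov_unscaled = cov_unscaled
  ), class = "drp_glm")
}

#' @export
print.drp_glm <- function(x, ...) {
  cat("<", x$family, " GLM, ", x$link, " link, ", length(x$beta) - 1,
      " feature(s)>\n  shape: ", format(x$shape, digits = 4),
      "  loglik: ", format(x$loglik, digits = 6),
      "  AIC: ", format(x$aic, digits = 6), "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.drp_glm <- function(x, ...) {
  se <- if (!is.null(x$cov_unscaled))
    sqrt(diag(x$cov_unscaled) * x$dispersion) else rep(NA_real_, length(x$beta))
  tibble::tibble(term = names(x$beta), estimate = unname(x$beta), std.error = se)
}

#' @exportS3Method generics::glance
glance.drp_glm <- function(x, ...) {
  tibble::tibble(family = x$family, link = x$link, shape = x$shape,
                 logLik = x$loglik, AIC = x$aic, converged = x$converged,
                 iterations = x$iterations)
}

#' @export
predict.drp_glm <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) {
    design_matrix(newdata[, c("sample_id", object$feature_ids)], impute = object$impute)$x
  } else cbind(`(Intercept)` = 1, as.matrix(newdata))
  eta <- as.vector(x %*% object$beta)
  if (object$link == "log") exp(eta) else 1 / eta
}

#' Select the response family by AIC
#'
#' Fits every candidate family and returns the fit with minimal AIC; all
#' AICs are kept in `$aic_table`. Candidates that fail to converge are
#' excluded with a warning.
#'
#' @inheritParams fit_glm
#' @param candidates Character vector of families to try.
#' @return The winning `drp_glm`, with an `aic_table` tibble attached.
#' @export
select_family_by_aic <- function(tbl, y, candidates = c("exponential", "gamma", "inverse_gaussian"),
                                 link = "log") {
  stopifnot(length(candidates) >= 1)
  fits <- list()
  for (fam in candidates) {
    fits[[fam]] <- tryCatch(fit_glm(tbl, y, family = fam, link = link),
                            error = function(e) {
                              warn(paste0("Family ", fam, " failed: ", conditionMessage(e)))
                              NULL
                            })
  }
  fits <- Filter(Negate(is.null), fits)
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (any(!ok)) {
    warn(paste0("Excluding non-converged family fit(s): ",
                paste(names(fits)[!ok], collapse = ", ")))
    fits <- fits[ok]
  }
  if (!length(fits)) abort("No candidate family produced a converged fit.")
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  best <- fits[[which.min(aics)]]
  best$aic_table <- tibble::tibble(family = names(aics), aic = unname(aics)) |>
    dplyr::arrange(.data$aic)
  best
}

# Inverse Gaussian quantile by monotone root finding on the closed-form CDF.
qinvgauss <- function(p, mu, lambda) {
  cdf <- function(q) {
    pnorm(sqrt(lambda / q) * (q / mu - 1)) +
      exp(2 * lambda / mu) * pnorm(-sqrt(lambda / q) * (q / mu + 1))
  }
  vapply(p, function(pp) {
    if (pp <= 0) return(0)
    if (pp >= 1) return(Inf)
    upper <- mu
    while (cdf(upper) < pp) upper <- upper * 2
    uniroot(function(q) cdf(q) - pp, c(1e-12, upper), tol = 1e-10)$root
  }, numeric(1))
}

#' Plug-in prediction intervals for new samples
#'
#' Central intervals of the fitted predictive distribution: for the gamma
#' family, `[Q(alpha/2; k, mu/k), Q(1-alpha/2; k, mu/k)]` with
#' `alpha = 1 - level` and `mu` the predicted mean. Parameter-estimation
#' uncertainty is deliberately not propagated (plug-in contract).
#'
#' @param fit A `drp_glm`.
#' @param newdata Feature table (or matrix) of new samples.
#' @param level Interval level in (0, 1), default 0.95.
#' @return Tibble of class `drp_intervals`: `sample_id` (if available),
#'   `point`, `lower`, `upper`, `level`.
#' @export
prediction_interval <- function(fit, newdata, level = 0.95) {
  stopifnot(inherits(fit, "drp_glm"))
  if (level <= 0 || level >= 1) abort("level must be in (0, 1).")
  mu <- predict(fit, newdata)
  alpha <- 1 - level
  if (fit$family %in% c("gamma", "exponential")) {
    k <- fit$shape
    lower <- qgamma(alpha / 2, shape = k, scale = mu / k)
    upper <- qgamma(1 - alpha / 2, shape = k, scale = mu / k)
  } else {
    lambda <- 1 / fit$dispersion
    lower <- qinvgauss(alpha / 2, mu, lambda)
    upper <- qinvgauss(1 - alpha / 2, mu, lambda)
  }
  ids <- if (is.data.frame(newdata) && "sample_id" %in% names(newdata))
    newdata$sample_id else as.character(seq_along(mu))
  out <- tibble::tibble(sample_id = ids, point = mu, lower = lower,
                        upper = upper, level = level)
  class(out) <- c("drp_intervals", class(out))
  out
}

#' Prediction interval coverage probability
#'
#' Fraction of true responses falling inside their (closed) intervals.
#'
#' @param intervals A `drp_intervals` tibble (columns `lower`, `upper`).
#' @param y_true Positive response values, same length.
#' @return A single number in `[0, 1]`.
#' @export
picp <- function(intervals, y_true) {
  if (!nrow(intervals)) abort("No intervals supplied.")
  if (nrow(intervals) != length(y_true)) abort("intervals and y_true lengths differ.")
  mean(intervals$lower <= y_true & y_true <= intervals$upper)
}

#' Seeded draws from a fitted predictive distribution
#'
#' Monte-Carlo draws from the plug-in predictive distribution at the given
#' new samples; used to compare the stability (variance) of two drugs'
#' predictive distributions.
#'
#' @param fit A `drp_glm`.
#' @param newdata Feature table or matrix of new samples.
#' @param n_draws Draws per sample (default 2000).
#' @param seed Integer seed.
#' @return Numeric vector of length `n_draws * nrow(newdata)`.
#' @export
predictive_draws <- function(fit, newdata, n_draws = 2000, seed = 1) {
  mu <- predict(fit, newdata)
  with_seed(seed, {
    if (fit$family %in% c("gamma", "exponential")) {
      as.vector(vapply(mu, function(m)
        rgamma(n_draws, shape = fit$shape, scale = m / fit$shape), numeric(n_draws)))
    } else {
      # IG draws via the transform method of Michael, Schucany & Haas
      as.vector(vapply(mu, function(m) {
        lambda <- 1 / fit$dispersion
        nu <- rnorm(n_draws)^2
        xq <- m + m^2 * nu / (2 * lambda) -
          m / (2 * lambda) * sqrt(4 * m * lambda * nu + m^2 * nu^2)
        u <- runif(n_draws)
        ifelse(u <= m / (m + xq), xq, m^2 / xq)
      }, numeric(n_draws)))
    }
  })
}
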