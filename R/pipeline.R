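# Pipeline orchestration: per-drug path (layer1 -> mRMR -> boosted
# selection -> GLM) and combined path (stacked drugs + fingerprints).

#' Pipeline configuration
#'
#' All tunables with documented defaults. Serializes losslessly to YAML via
#' [write_config()] / [read_config()].
#'
#' @param keep_fraction Layer-1 contribution-cut fraction (default 0.5).
#' @param cut_direction Keep the `"top"` or `"bottom"` of the contribution
#'   ranking (default top).
#' @param cor_threshold Layer-1 correlation-dedup threshold (default 0.8).
#' @param ae_hidden Autoencoder hidden width (`NULL` = `min(64, G/4)`).
#' @param ae_epochs Autoencoder training epochs (default 200).
#' @param mi_bins Mutual-information bins (default 10; 5 when n < 100).
#' @param mrmr_m Features selected by mRMR (default 500).
#' @param boost_rounds,boost_max_depth,boost_lambda,boost_gamma,boost_shrinkage
#'   Boosted-tree parameters (defaults 50, 4, 1, 0, 0.3).
#' @param cap Maximum features surviving layer 3 (default 40).
#' @param glm_candidates Families tried by AIC (default all three).
#' @param glm_link GLM link (default log).
#' @param head `"glm"` or `"mlp"`.
#' @param mlp_widths,mlp_dropout,mlp_epochs,mlp_batch_size,mlp_learning_rate
#'   Network-head parameters.
#' @param cv_k CV fold count (default 10).
#' @param interval_level Prediction-interval level (default 0.95).
#' @param transform Label transform for the combined path (default log1p,
#'   which keeps gamma support when log IC50 would go non-positive).
#' @param combined_space `"per_drug_mrmr_union"` (default) or
#'   `"all_features"`: pre-mRMR feature space of the combined path.
#' @param layers Which selection layers run, in order.
#' @param seed Integer seed.
#' @return A list of class `drp_config`.
#' @export
pipeline_config <- function(keep_fraction = 0.5, cut_direction = "top",
                            cor_threshold = 0.8, ae_hidden = NULL, ae_epochs = 200,
                            mi_bins = 10, mrmr_m = 500,
                            boost_rounds = 50, boost_max_depth = 4, boost_lambda = 1,
                            boost_gamma = 0, boost_shrinkage = 0.3, cap = 40,
                            glm_candidates = c("exponential", "gamma", "inverse_gaussian"),
                            glm_link = "log", head = "glm",
                            mlp_widths = c(1000, 800, 500, 100), mlp_dropout = 0.1,
                            mlp_epochs = 100, mlp_batch_size = 32,
                            mlp_learning_rate = 0.01,
                            cv_k = 10, interval_level = 0.95, transform = "log1p",
                            combined_space = "per_drug_mrmr_union",
                            layers = c("layer1", "mrmr", "boost"), seed = 1) {
  cfg <- as.list(environment())
  structure(cfg, class = "drp_config")
}

#' Write / read a pipeline configuration (YAML)
#'
#' @param config A `drp_config`.
#' @param path File path.
#' @return `read_config()` returns the `drp_config`; `write_config()` the
#'   path, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(pipeline_config, raw)
  cfg
}

# Run the configured selection layers in order; returns reduced features
# plus the per-layer reports.
run_selection <- function(tbl, y, config) {
  reports <- list()
  current <- tbl
  for (layer in config$layers) {
    if (layer == "layer1") {
      res <- screen_layer1(current, keep_fraction = config$keep_fraction,
                           direction = config$cut_direction,
                           cor_threshold = config$cor_threshold,
                           K = config$ae_hidden, epochs = config$ae_epochs,
                           seed = config$seed)
      reports$layer1 <- res$report
      current <- res$features
    } else if (layer == "mrmr") {
      m <- min(config$mrmr_m, length(feature_cols(current)))
      rep2 <- mrmr_select(current, y, m = m, bins = config$mi_bins)
      reports$mrmr <- rep2
      current <- current[, c("sample_id", rep2$kept)]
    } else if (layer == "boost") {
      res3 <- select_layer3(current, y, cap = config$cap,
                            rounds = config$boost_rounds,
                            max_depth = config$boost_max_depth,
                            lambda = config$boost_lambda,
                            gamma_penalty = config$boost_gamma,
                            shrinkage = config$boost_shrinkage)
      reports$boost <- res3$report
      current <- res3$features
    } else {
      abort(paste0("Unknown selection layer `", layer, "`."))
    }
  }
  list(features = current, reports = reports)
}

stage_dims <- function(tbl, reports) {
  dims <- tibble::tibble(stage = "input", n_features = length(feature_cols(tbl)))
  for (nm in names(reports)) {
    dims <- dplyr::bind_rows(dims, tibble::tibble(stage = nm,
                                                  n_features = length(reports[[nm]]$kept)))
  }
  dims
}

#' Run the per-drug pipeline
#'
#' Layer 1 (contribution screen on the continuous genomic blocks) then
#' mRMR (default m = 500) then boosted-tree selection (default cap 40),
#' followed by the GLM head with AIC family selection. Labels stay on
#' their original positive scale. Stage errors are rethrown with the stage
#' name attached.
#'
#' @param tbl Feature table (genomic blocks).
#' @param y Response vector or tibble (positive IC50).
#' @param config A [pipeline_config()].
#' @param cv Also run [kfold_cv()] on the selected features? (default
#'   FALSE).
#' @return An object of class `drp_run`: config snapshot, per-stage
#'   reports, stage dimensions, fitted model, prediction intervals for the
#'   training samples, and optionally a `drp_cv`.
#' @export
run_per_drug <- function(tbl, y, config = pipeline_config(), cv = FALSE) {
  if (is.data.frame(y)) {
    al <- align_samples(tbl, y)
    tbl <- al$features; y <- al$y
  }
  res <- tryCatch(
    run_selection(tbl, y, config),
    error = function(e) abort(paste0("Stage `selection` failed: ", conditionMessage(e)))
  )
  stage <- if (config$head == "glm") "glm" else "mlp"
  fit <- tryCatch({
    if (config$head == "glm") {
      select_family_by_aic(res$features, y, config$glm_candidates, config$glm_link)
    } else {
      fit_mlp(res$features, y, widths = config$mlp_widths,
              dropout_rate = config$mlp_dropout, epochs = config$mlp_epochs,
              batch_size = config$mlp_batch_size,
              learning_rate = config$mlp_learning_rate, seed = config$seed)
    }
  }, error = function(e) abort(paste0("Stage `", stage, "` failed: ", conditionMessage(e))))
  intervals <- if (inherits(fit, "drp_glm"))
    prediction_interval(fit, res$features, config$interval_level) else NULL
  cv_report <- if (cv) kfold_cv(tbl, y, config, k = config$cv_k, seed = config$seed) else NULL
  structure(list(
    config = config, reports = res$reports, dims = stage_dims(tbl, res$reports),
    features = res$features, fit = fit, intervals = intervals, cv = cv_report,
    seed = as.integer(config$seed)
  ), class = "drp_run")
}

#' @export
print.drp_run <- function(x, ...) {
  cat("<pipeline run>\n")
  print(x$dims)
  if (!is.null(x$cv)) print(x$cv$metrics)
  invisible(x)
}

#' Run the combined multi-drug pipeline
#'
#' Stacks the (cell line, drug) pairs of all drugs, appends each drug's
#' fingerprint bits as `fp_*` columns, applies the label transform
#' (default log1p), and runs mRMR then boosted selection then the chosen
#' head. Stacking heterogeneous per-drug feature spaces creates missing
#' values, which flow through the boosted trees' native missing handling
#' and the GLM-stage median imputation. By default the pre-mRMR feature
#' space is the union of per-drug layer-1 + mRMR survivors
#' (`combined_space = "per_drug_mrmr_union"`); `"all_features"` keeps
#' every screened feature instead.
#'
#' @param tables Named list of per-drug feature tables.
#' @param responses Named list of per-drug response tibbles (raw IC50).
#' @param fingerprints Named list (same names) of 0/1 fingerprint vectors.
#' @param config A [pipeline_config()].
#' @param cv Also cross-validate? (default FALSE)
#' @return A `drp_run` whose `$stacked` holds the stacked table.
#' @export
run_combined <- function(tables, responses, fingerprints, config = pipeline_config(),
                         cv = FALSE) {
  drugs <- names(tables)
  if (is.null(drugs) || !setequal(drugs, names(responses))) {
    abort("tables and responses must be named lists over the same drugs.")
  }
  missing_fp <- setdiff(drugs, names(fingerprints))
  if (length(missing_fp)) {
    abort(paste0("No fingerprint block for drug(s): ", paste(missing_fp, collapse = ", ")))
  }
  per_drug <- lapply(drugs, function(d) {
    al <- align_samples(tables[[d]], responses[[d]])
    feats <- al$features
    if (config$combined_space == "per_drug_mrmr_union") {
      cfg_sel <- config
      cfg_sel$layers <- intersect(config$layers, c("layer1", "mrmr"))
      feats <- run_selection(feats, al$y, cfg_sel)$features
    }
    fp <- fingerprints[[d]]
    fp_tbl <- tibble::as_tibble(as.list(setNames(as.numeric(fp),
                                                 paste0("fp_", seq_along(fp)))))
    dplyr::bind_cols(
      tibble::tibble(sample_id = paste0(d, ":", feats$sample_id)),
      feats[, feature_cols(feats), drop = FALSE],
      fp_tbl[rep(1, nrow(feats)), , drop = FALSE]
    )
  })
  stacked <- dplyr::bind_rows(per_drug)
  y_raw <- unlist(lapply(drugs, function(d) {
    al <- align_samples(tables[[d]], responses[[d]])
    al$y
  }), use.names = FALSE)
  y <- switch(config$transform, none = y_raw, log = log(y_raw), log1p = log1p(y_raw))
  if (any(y <= 0)) abort("Transformed labels are not all positive; use log1p for the gamma head.")
  # constant columns (e.g. fingerprint bits shared by every stacked drug)
  const <- vapply(feature_cols(stacked), function(id) {
    v <- stacked[[id]][!is.na(stacked[[id]])]
    length(unique(v)) < 2
  }, logical(1))
  if (any(const)) {
    warn(paste0("Dropping ", sum(const), " zero-variance column(s) after stacking."))
    stacked <- stacked[, c("sample_id", feature_cols(stacked)[!const])]
  }
  cfg <- config
  cfg$layers <- intersect(config$layers, c("mrmr", "boost"))
  run <- run_per_drug(stacked, y, cfg, cv = cv)
  run$stacked <- stacked
  run
}

#' Serialize a pipeline run manifest to JSON
#'
#' Writes the config, seed, stage dimensions and per-layer kept features —
#' enough to audit or re-run a pipeline — as pretty-printed JSON.
#'
#' @param run A `drp_run`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(run, path) {
  manifest <- list(
    config = unclass(run$config),
    seed = run$seed,
    dims = run$dims,
    kept = lapply(run$reports, `[[`, "kept"),
    head = if (inherits(run$fit, "drp_glm")) {
      list(type = "glm", family = run$fit$family, link = run$fit$link,
           beta = as.list(run$fit$beta), shape = run$fit$shape, aic = run$fit$aic)
    } else list(type = "mlp")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
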