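#' Feature tables and response tables
#'
#' A feature table is a tibble with a `sample_id` character column followed
#' by one numeric column per feature. Feature *kind* (RNA, CNV, MUT, FP) is
#' carried by the column name prefix (`rna_`, `cnv_`, `mut_`, `fp_` by
#' default) so that tables survive any dplyr manipulation without losing
#' metadata. Missing values are plain `NA`. MUT (somatic mutation) and FP
#' (fingerprint bit) columns must be exactly 0/1 where observed.
#'
#' @name feature-table
NULL

default_kind_map <- c(rna = "RNA", cnv = "CNV", mut = "MUT", fp = "FP")

#' Feature kinds from column-name prefixes
#'
#' @param tbl A feature table (tibble with `sample_id` plus feature columns).
#' @param kind_map Named character vector mapping name prefixes (before the
#'   first underscore) to kinds `RNA`, `CNV`, `MUT`, `FP`.
#' @return A named character vector: kind per feature column.
#' @export
feature_kinds <- function(tbl, kind_map = default_kind_map) {
  ids <- feature_cols(tbl)
  prefix <- sub("_.*$", "", ids)
  kinds <- unname(kind_map[prefix])
  if (anyNA(kinds)) {
    bad <- ids[is.na(kinds)]
    abort(paste0(
      "Cannot assign a feature kind to: ", paste(head(bad, 5), collapse = ", "),
      if (length(bad) > 5) ", ..." else "",
      ". Use column-name prefixes ", paste(names(kind_map), collapse = "/"),
      " or supply `kind_map`."
    ))
  }
  setNames(kinds, ids)
}

validate_feature_table <- function(tbl, kind_map = default_kind_map) {
  if (!"sample_id" %in% names(tbl)) abort("Feature table needs a `sample_id` column.")
  if (anyDuplicated(tbl$sample_id)) {
    abort(paste0("Duplicate sample ids: ",
                 paste(unique(tbl$sample_id[duplicated(tbl$sample_id)]), collapse = ", ")))
  }
  all_ids <- names(tbl)[names(tbl) != "sample_id"]
  if (anyDuplicated(all_ids)) {
    abort(paste0("Duplicate feature ids: ",
                 paste(unique(all_ids[duplicated(all_ids)]), collapse = ", ")))
  }
  ids <- feature_cols(tbl)
  kinds <- feature_kinds(tbl, kind_map)
  binary_kinds <- names(kinds)[kinds %in% c("MUT", "FP")]
  for (id in binary_kinds) {
    v <- tbl[[id]]
    bad <- which(!is.na(v) & v != 0 & v != 1)
    if (length(bad)) {
      abort(paste0("Non-binary value in ", kinds[[id]], " feature `", id, "` at sample(s) ",
                   paste(tbl$sample_id[head(bad, 5)], collapse = ", "),
                   " (value ", paste(v[head(bad, 5)], collapse = ", "), ")."))
    }
  }
  invisible(tbl)
}

#' Read a feature table from delimited text
#'
#' Expects a header row of feature ids and a first column of sample ids.
#' Empty cells and `NA` are recorded as missing. Kinds are assigned by the
#' column-name prefix rule and validated (MUT/FP must be 0/1).
#'
#' @param path Path to a CSV or TSV file (delimiter sniffed from extension).
#' @inheritParams feature_kinds
#' @return A feature table tibble.
#' @export
read_feature_table <- function(path, kind_map = default_kind_map) {
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           na = c("", "NA"), name_repair = "minimal")
  names(tbl)[1] <- "sample_id"
  tbl$sample_id <- as.character(tbl$sample_id)
  validate_feature_table(tbl, kind_map)
  tbl
}

#' Write a feature table to delimited text
#'
#' Round-trips through [read_feature_table()] bit-exactly (missing cells are
#' written as empty fields).
#'
#' @param tbl A feature table.
#' @param path Output path (`.tsv` for tab-delimited, otherwise CSV).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(tbl, path) {
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  readr::write_delim(tbl, path, delim = delim, na = "")
  invisible(path)
}

#' Read an IC50 response table
#'
#' Two columns: sample id and a strictly positive response (IC50). The
#' requested transform is applied and recorded in the `transform` attribute.
#' `log` can produce non-positive values (IC50 below 1), which are fine for
#' the network head but violate gamma support; [fit_glm()] checks this at
#' fit time. `log1p` keeps values positive and is the default transform for
#' the combined, gamma-modelled path.
#'
#' @param path Path to a two-column CSV/TSV file.
#' @param transform One of `"none"`, `"log"`, `"log1p"`.
#' @return A tibble with `sample_id` and `response`, with attribute
#'   `transform` recording the transform applied.
#' @export
read_response_table <- function(path, transform = c("none", "log", "log1p")) {
  transform <- match.arg(transform)
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE, na = c("", "NA"))
  names(tbl)[1:2] <- c("sample_id", "response")
  tbl$sample_id <- as.character(tbl$sample_id)
  make_response(tbl$sample_id, tbl$response, transform)
}

make_response <- function(sample_ids, values, transform = "none") {
  if (any(!is.finite(values)) || any(values <= 0)) {
    bad <- sample_ids[!is.finite(values) | values <= 0]
    abort(paste0("IC50 values must be positive and finite; offending sample(s): ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  values <- switch(transform, none = values, log = log(values), log1p = log1p(values))
  out <- tibble::tibble(sample_id = as.character(sample_ids), response = values)
  attr(out, "transform") <- transform
  out
}

#' Align a feature table and a response table by sample id
#'
#' An inner join on `sample_id`; row order of either input is irrelevant.
#'
#' @param features A feature table.
#' @param response A response tibble (`sample_id`, `response`).
#' @return A list with the aligned `features` table and numeric `y` vector.
#' @export
align_samples <- function(features, response) {
  common <- intersect(features$sample_id, response$sample_id)
  if (!length(common)) abort("No shared sample ids between features and response.")
  f <- features[match(common, features$sample_id), , drop = FALSE]
  y <- response$response[match(common, response$sample_id)]
  list(features = f, y = y)
}
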