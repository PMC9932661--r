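#' Encode a molecule as a folded circular fingerprint
#'
#' Computes an ECFP-style circular (Morgan-family) fingerprint for a SMILES
#' string via the ChemmineR/ChemmineOB Open Babel bindings and folds it to
#' `n_bits` bits by OR-ing positions modulo `n_bits`. Deterministic for a
#' fixed structure and settings. This is a thin optional interface: the
#' pipeline is fully usable with precomputed `fp_*` feature blocks.
#'
#' @param smiles A single SMILES string.
#' @param n_bits Folded width in bits (default 256).
#' @param type Open Babel fingerprint type (default `"ECFP4"`).
#' @return Integer 0/1 vector of length `n_bits`, named `fp_1 ... fp_n`.
#' @export
fingerprint_encode <- function(smiles, n_bits = 256, type = "ECFP4") {
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE)) {
    abort("Optional dependency missing: fingerprint encoding needs ChemmineR + ChemmineOB. Supply precomputed fp_* columns instead.")
  }
  stopifnot(length(smiles) == 1, n_bits >= 1)
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) abort(paste0("Could not parse structure `", smiles, "`: ", conditionMessage(e)))
  )
  if (!length(ChemmineR::sdfid(sdf))) abort(paste0("Could not parse structure `", smiles, "`."))
  fp <- ChemmineR::fingerprintOB(sdf, type)
  raw <- as.numeric(ChemmineR::as.matrix(fp)[1, ])
  if (all(raw == 0)) abort(paste0("Could not parse structure `", smiles, "` (empty fingerprint)."))
  folded <- integer(n_bits)
  on <- which(raw != 0) - 1L
  folded[(on %% n_bits) + 1L] <- 1L
  setNames(folded, paste0("fp_", seq_len(n_bits)))
}
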