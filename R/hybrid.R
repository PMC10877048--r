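#' Apply the motif override to model probabilities
#'
#' The hybrid rule: wherever a location-specific motif was found in the
#' query (`hits` flag 1), the final probability for that location is forced
#' to 1; everywhere else the model probability passes through unchanged.
#' The override can therefore never lower a probability.
#'
#' @param proba Numeric matrix of model probabilities (rows x 6 locations).
#' @param hits Integer/logical matrix of motif hit flags, same shape.
#' @return Numeric matrix of final probabilities.
#' @export
apply_motif_override <- function(proba, hits) {
  stopifnot(all(dim(proba) == dim(hits)))
  final <- proba
  final[hits == 1L] <- 1
  final
}

#' Hybrid prediction: composition model plus motif override
#'
#' Featurizes the query sequences, scores them with the six per-location
#' classifiers, scans them against the per-location motif sets, applies
#' the override, and thresholds the final probabilities at the model's
#' per-location decision thresholds.
#'
#' @param records Data.frame with `id` and `seq`.
#' @param model A fitted `mlsubloc_model`.
#' @param motif_sets Named list of motif data.frames per location; `NULL`
#'   for model-only prediction.
#' @param config A [kmer_config()] matching the one used at training.
#' @return A data.frame of class `mlsubloc_predictions` with one row per
#'   sequence: `id`, then per location `<loc>_proba` (model),
#'   `<loc>_motif` (hit flag), `<loc>_final` (post-override) and
#'   `<loc>_call` (final >= threshold), plus a comma-separated
#'   `predicted_locations` string.
#' @export
hybrid_predict <- function(records, model, motif_sets = NULL,
                           config = kmer_config()) {
  X <- featurize(records, config)
  P <- predict_proba(model, X)
  if (is.null(motif_sets)) {
    H <- matrix(0L, nrow(P), 6L, dimnames = dimnames(P))
  } else {
    H <- scan_motifs_all(records, motif_sets)
  }
  FP <- apply_motif_override(P, H)
  calls <- t(t(FP) >= model$thresholds[locations()]) * 1L
  out <- data.frame(id = records$id, stringsAsFactors = FALSE)
  for (loc in locations()) {
    out[[paste0(loc, "_proba")]] <- unname(P[, loc])
    out[[paste0(loc, "_motif")]] <- unname(H[, loc])
    out[[paste0(loc, "_final")]] <- unname(FP[, loc])
    out[[paste0(loc, "_call")]] <- unname(calls[, loc])
  }
  out$predicted_locations <- apply(calls, 1L, function(v) {
    paste(locations()[v == 1L], collapse = ",")
  })
  class(out) <- c("mlsubloc_predictions", "data.frame")
  out
}

#' Extract a per-location matrix from a prediction table
#'
#' @param predictions Output of [hybrid_predict()].
#' @param what One of `"proba"`, `"motif"`, `"final"`, `"call"`.
#' @return Numeric matrix (sequences x 6 locations).
#' @export
prediction_matrix <- function(predictions,
                              what = c("final", "proba", "motif", "call")) {
  what <- match.arg(what)
  M <- as.matrix(predictions[, paste0(locations(), "_", what)])
  dimnames(M) <- list(predictions$id, locations())
  M
}

#' Write predictions to TSV
#'
#' @param predictions Output of [hybrid_predict()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  utils::write.table(predictions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
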