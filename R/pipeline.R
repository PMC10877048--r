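#' Full training workflow: split, cross-validate, fit, validate
#'
#' Implements the standard workflow: an 80:20 multi-label-stratified
#' split; k-fold cross-validation on the training portion yielding
#' out-of-fold probabilities; per-location decision thresholds chosen on
#' the pooled out-of-fold predictions by sensitivity/specificity
#' balancing, then frozen; a final fit on the whole training portion;
#' and evaluation on the held-out portion. When `discover` is TRUE,
#' discriminative motifs are discovered on the training portion only and
#' the held-out evaluation uses the hybrid (motif-override) probabilities.
#'
#' @param records Data.frame with `id` and `seq`.
#' @param Y Label matrix aligned with `records`.
#' @param config A [model_config()].
#' @param kmer A [kmer_config()].
#' @param motif A [motif_config()] (used when `discover = TRUE`).
#' @param discover Whether to run motif discovery and hybrid evaluation.
#' @param test_fraction Held-out fraction (default 0.2).
#' @param k Number of CV folds (default 5).
#' @param seed Seed for the split and fold assignment.
#' @return List with elements `model` (thresholds set), `motif_sets`
#'   (NULL unless `discover`), `cv_report` (per-fold average),
#'   `validation_report`, `split` (train/test indices) and
#'   `oof_scores` (out-of-fold probability matrix on the training rows).
#' @export
train_pipeline <- function(records, Y, config = model_config(),
                           kmer = kmer_config(), motif = motif_config(),
                           discover = FALSE, test_fraction = 0.2, k = 5L,
                           seed = 1L) {
  stopifnot(identical(rownames(Y), records$id))
  X <- featurize(records, kmer)
  split <- stratified_split(Y, test_fraction, seed)
  Xtr <- X[split$train, , drop = FALSE]
  Ytr <- Y[split$train, , drop = FALSE]
  folds <- kfold(Ytr, k, seed)

  oof <- matrix(NA_real_, nrow(Xtr), 6L,
                dimnames = list(rownames(Xtr), locations()))
  fold_metrics <- vector("list", k)
  for (f in seq_len(k)) {
    hold <- folds[[f]]
    m <- train_model(Xtr[-hold, , drop = FALSE],
                     Ytr[-hold, , drop = FALSE], config)
    oof[hold, ] <- predict_proba(m, Xtr[hold, , drop = FALSE])
  }
  thresholds <- vapply(locations(), function(loc) {
    choose_threshold(oof[, loc], Ytr[, loc])
  }, numeric(1))
  for (f in seq_len(k)) {
    hold <- folds[[f]]
    fold_metrics[[f]] <- evaluate_multilabel(oof[hold, , drop = FALSE],
                                             Ytr[hold, , drop = FALSE],
                                             thresholds)
  }
  cv_report <- fold_metrics[[1L]]
  for (col in names(cv_report)[-1L]) {
    cv_report[[col]] <- rowMeans(vapply(fold_metrics, `[[`,
                                        numeric(nrow(cv_report)), col))
  }

  model <- train_model(Xtr, Ytr, config)
  model$thresholds <- thresholds

  motif_sets <- NULL
  if (discover) {
    motif_sets <- discover_motif_sets(records[split$train, , drop = FALSE],
                                      Ytr, motif)
  }
  preds <- hybrid_predict(records[split$test, , drop = FALSE], model,
                          motif_sets, kmer)
  validation_report <- evaluate_multilabel(
    prediction_matrix(preds, "final"),
    Y[split$test, , drop = FALSE], thresholds)

  list(model = model, motif_sets = motif_sets, cv_report = cv_report,
       validation_report = validation_report, split = split,
       oof_scores = oof)
}
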