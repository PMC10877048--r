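#' Multi-label iterative stratification
#'
#' Greedy fold assignment that balances every label's prevalence across
#' folds (Sechidis-style): repeatedly take the label with the fewest
#' remaining unassigned positives, and place each of its samples into the
#' fold with the largest remaining demand for that label, breaking ties by
#' overall remaining capacity and then at random (seeded). Samples with no
#' positive labels are distributed by remaining capacity.
#'
#' @param Y Label matrix (rows = samples, 0/1 entries).
#' @param proportions Numeric vector of fold proportions summing to 1.
#' @param seed Integer seed; the assignment is deterministic given it.
#' @return Integer vector of fold indices (1-based), one per row of `Y`.
#' @keywords internal
iterative_stratification <- function(Y, proportions, seed) {
  stopifnot(abs(sum(proportions) - 1) < 1e-8)
  n <- nrow(Y)
  k <- length(proportions)
  set.seed(seed)
  fold <- rep(NA_integer_, n)
  # remaining desired sample counts per fold, and per fold x label
  cap <- proportions * n
  demand <- outer(proportions, colSums(Y))
  unassigned <- rep(TRUE, n)
  repeat {
    remaining <- colSums(Y[unassigned, , drop = FALSE])
    remaining[remaining == 0] <- NA
    if (all(is.na(remaining))) break
    lab <- which.min(remaining)
    idx <- which(unassigned & Y[, lab] == 1L)
    idx <- sample(idx)  # seeded shuffle so ties don't follow input order
    for (i in idx) {
      best <- which(demand[, lab] == max(demand[, lab]))
      if (length(best) > 1L) best <- best[cap[best] == max(cap[best])]
      if (length(best) > 1L) best <- sample(best, 1L)
      fold[i] <- best
      unassigned[i] <- FALSE
      cap[best] <- cap[best] - 1
      pos <- which(Y[i, ] == 1L)
      demand[best, pos] <- demand[best, pos] - 1
    }
  }
  for (i in sample(which(unassigned))) {
    best <- which(cap == max(cap))
    if (length(best) > 1L) best <- sample(best, 1L)
    fold[i] <- best
    cap[best] <- cap[best] - 1
  }
  fold
}

#' Stratified multi-label train/test split
#'
#' @param Y Label matrix.
#' @param test_fraction Fraction of samples assigned to the test set
#'   (default 0.2 for an 80:20 split).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
stratified_split <- function(Y, test_fraction = 0.2, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  fold <- iterative_stratification(Y, c(1 - test_fraction, test_fraction),
                                   seed)
  list(train = which(fold == 1L), test = which(fold == 2L))
}

#' Stratified multi-label k-fold partition
#'
#' @param Y Label matrix.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return List of `k` integer index vectors partitioning `1:nrow(Y)`.
#' @export
kfold <- function(Y, k = 5L, seed = 1L) {
  stopifnot(k >= 2L)
  if (k > nrow(Y)) stop("k = ", k, " exceeds the number of samples")
  fold <- iterative_stratification(Y, rep(1 / k, k), seed)
  lapply(seq_len(k), function(f) which(fold == f))
}

#' Choose a decision threshold balancing sensitivity and specificity
#'
#' Candidate thresholds are the distinct scores, the midpoints between
#' consecutive distinct scores, and one candidate beyond each extreme.
#' The returned threshold minimizes |sensitivity - specificity| for the
#' rule `call = score >= threshold`; ties go to the smallest threshold.
#'
#' @param scores Numeric prediction scores.
#' @param truth 0/1 truth vector with at least one positive and one
#'   negative.
#' @return The selected threshold.
#' @export
choose_threshold <- function(scores, truth) {
  stopifnot(length(scores) == length(truth))
  if (sum(truth == 1L) == 0L || sum(truth == 0L) == 0L) {
    stop("truth must contain at least one positive and one negative")
  }
  u <- sort(unique(scores))
  step <- if (length(u) > 1L) min(diff(u)) / 2 else 0.5
  cands <- sort(unique(c(u, u[-length(u)] + diff(u) / 2,
                         u[1L] - step, u[length(u)] + step)))
  gap <- vapply(cands, function(t) {
    call <- as.integer(scores >= t)
    sens <- sum(call == 1L & truth == 1L) / sum(truth == 1L)
    spec <- sum(call == 0L & truth == 0L) / sum(truth == 0L)
    abs(sens - spec)
  }, numeric(1))
  cands[which.min(gap)]  # which.min takes the first, i.e. smallest, on ties
}

#' Rank-based AUROC with tie correction
#'
#' The Mann-Whitney estimator: the probability that a random positive
#' outscores a random negative, with ties counted half.
#'
#' @param scores Numeric scores.
#' @param truth 0/1 truth vector.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, truth) {
  n1 <- sum(truth == 1L)
  n0 <- sum(truth == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("AUROC undefined: truth has a single class")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Threshold-dependent metrics plus AUROC for one location
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy, F1
#' TP/(TP + 0.5(FN+FP)) and the Matthews correlation coefficient
#' (0 when its denominator vanishes), evaluated at `call = score >=
#' threshold`, together with the threshold-free rank AUROC.
#'
#' @param scores Numeric scores.
#' @param truth 0/1 truth vector with both classes present.
#' @param threshold Decision threshold.
#' @return One-row data.frame: sensitivity, specificity, accuracy, mcc,
#'   f1, auroc, threshold.
#' @export
compute_metrics <- function(scores, truth, threshold) {
  call <- as.integer(scores >= threshold)
  tp <- sum(call == 1L & truth == 1L)
  fp <- sum(call == 1L & truth == 0L)
  fn <- sum(call == 0L & truth == 1L)
  tn <- sum(call == 0L & truth == 0L)
  denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  f1_den <- tp + 0.5 * (fn + fp)
  data.frame(sensitivity = tp / (tp + fn),
             specificity = tn / (tn + fp),
             accuracy = (tp + tn) / (tp + tn + fp + fn),
             mcc = mcc,
             f1 = if (f1_den == 0) 0 else tp / f1_den,
             auroc = auroc(scores, truth),
             threshold = threshold)
}

#' Per-location metrics report with an Average row
#'
#' @param scores Matrix of scores (samples x 6 locations).
#' @param Y Truth label matrix aligned with `scores` (same IDs, same
#'   order).
#' @param thresholds Named vector of per-location thresholds.
#' @return Data.frame with one row per location plus an unweighted
#'   `Average` row; columns location, sensitivity, specificity, accuracy,
#'   mcc, f1, auroc, threshold.
#' @export
evaluate_multilabel <- function(scores, Y, thresholds) {
  if (!is.null(rownames(scores)) && !is.null(rownames(Y)) &&
      !identical(rownames(scores), rownames(Y))) {
    stop("score and truth IDs do not match")
  }
  rows <- lapply(locations(), function(loc) {
    cbind(location = loc,
          compute_metrics(scores[, loc], Y[, loc], thresholds[[loc]]))
  })
  tab <- do.call(rbind, rows)
  avg <- cbind(location = "Average",
               as.data.frame(t(colMeans(tab[, -1L]))))
  rbind(tab, avg)
}

#' Write a metrics report as TSV
#'
#' @param report Data.frame from [evaluate_multilabel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
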