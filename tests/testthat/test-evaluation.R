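test_that("metrics on perfect and inverted confusion tables", {
  perfect <- compute_metrics(c(0.9, 0.1), c(1, 0), 0.5)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$mcc, 1)

  inverted <- compute_metrics(c(0.1, 0.9), c(1, 0), 0.5)
  expect_equal(inverted$sensitivity, 0)
  expect_equal(inverted$specificity, 0)
  expect_equal(inverted$f1, 0)
  expect_equal(inverted$mcc, -1)
})

test_that("metrics match direct-formula oracles on random score sets", {
  set.seed(101)
  for (i in 1:50) {
    n <- sample(10:60, 1)
    truth <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(truth)) < 2) truth[1:2] <- c(0, 1)
    scores <- round(runif(n), sample(1:3, 1))  # rounding induces ties
    thr <- runif(1)
    got <- compute_metrics(scores, truth, thr)
    call <- as.integer(scores >= thr)
    tp <- sum(call & truth); fp <- sum(call & !truth)
    fn <- sum(!call & truth); tn <- sum(!call & !truth)
    expect_equal(got$sensitivity, tp / (tp + fn))
    expect_equal(got$specificity, tn / (tn + fp))
    expect_equal(got$accuracy, (tp + tn) / n)
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    expect_equal(got$mcc, ifelse(den == 0, 0, (tp * tn - fp * fn) / den),
                 tolerance = 1e-12)
    expect_equal(got$auroc, oracle_auroc(scores, truth), tolerance = 1e-12)
  }
})

test_that("rank AUROC agrees with pROC and survives monotone transforms", {
  skip_if_not_installed("pROC")
  set.seed(55)
  for (i in 1:10) {
    n <- sample(30:80, 1)
    truth <- c(0, 1, rbinom(n - 2, 1, 0.4))
    scores <- rnorm(n) + truth
    a <- auroc(scores, truth)
    expect_equal(a, as.numeric(pROC::auc(pROC::roc(truth, scores,
                                                   quiet = TRUE,
                                                   direction = "<"))),
                 tolerance = 1e-12)
    expect_equal(auroc(exp(scores), truth), a, tolerance = 1e-12)
    expect_equal(auroc(rank(scores), truth), a, tolerance = 1e-12)
  }
  expect_error(auroc(c(1, 2), c(1, 1)), "single class")
})

test_that("threshold balancing minimizes |sens - spec| over candidates", {
  # perfect separation: smallest candidate inside the separating interval
  expect_equal(choose_threshold(c(0.1, 0.9), c(0, 1)), 0.5)
  # degenerate scores: tie-break to the smallest candidate
  # all candidates tie at gap 1; tie-break returns the smallest
  expect_equal(choose_threshold(c(0.5, 0.5), c(0, 1)), 0)
  set.seed(77)
  truth <- rbinom(200, 1, 0.5)
  scores <- rnorm(200, mean = truth)
  thr <- choose_threshold(scores, truth)
  gap_at <- function(t) {
    call <- as.integer(scores >= t)
    abs(sum(call & truth) / sum(truth) -
          sum(!call & !truth) / sum(!truth))
  }
  u <- sort(unique(scores))
  cands <- c(u, u[-length(u)] + diff(u) / 2, u[1] - 1, u[length(u)] + 1)
  expect_true(all(gap_at(thr) <= vapply(cands, gap_at, numeric(1)) + 1e-12))
})

test_that("stratified split balances every label and is deterministic", {
  set.seed(33)
  Y <- vapply(c(0.3, 0.15, 0.5, 0.7, 0.1, 0.45),
              function(p) rbinom(100, 1, p), integer(100))
  colnames(Y) <- locations()
  sp <- stratified_split(Y, 0.2, seed = 9)
  expect_equal(sort(c(sp$train, sp$test)), 1:100)
  expect_equal(length(sp$test), 20L)
  for (loc in locations()) {
    tol <- max(0.02, 1 / length(sp$test))
    expect_lte(abs(mean(Y[sp$test, loc]) - mean(Y[, loc])), tol)
  }
  sp2 <- stratified_split(Y, 0.2, seed = 9)
  expect_identical(sp, sp2)
  expect_false(identical(sp, stratified_split(Y, 0.2, seed = 10)))
})

test_that("k-fold partition is exhaustive, disjoint and balanced", {
  sim <- simulate_dataset(sim_config(n_sequences = 500,
                                     composition_effect = 0, seed = 21))
  folds <- kfold(sim$Y, 5, seed = 3)
  sizes <- lengths(folds)
  expect_true(all(abs(sizes - 100) <= 1))
  expect_equal(sort(unlist(folds)), 1:500)
  for (f in folds) {
    for (loc in locations()) {
      tol <- max(0.02, 1 / length(f))
      expect_lte(abs(mean(sim$Y[f, loc]) - mean(sim$Y[, loc])), tol)
    }
  }
  expect_error(kfold(sim$Y[1:4, ], 5), "exceeds")
})

test_that("multilabel report has six location rows plus their mean", {
  set.seed(42)
  n <- 80
  Y <- vapply(rep(0.5, 6), function(p) rbinom(n, 1, p), integer(n))
  colnames(Y) <- locations()
  scores <- matrix(runif(n * 6), n, dimnames = list(NULL, locations()))
  thr <- setNames(rep(0.5, 6), locations())
  rep_ <- evaluate_multilabel(scores, Y, thr)
  expect_equal(rep_$location, c(locations(), "Average"))
  for (col in c("sensitivity", "specificity", "accuracy", "mcc", "f1",
                "auroc")) {
    expect_equal(rep_[[col]][7], mean(rep_[[col]][1:6]), tolerance = 1e-12)
  }
  # perfect scores give an all-ones diagonal of metrics
  perfect <- evaluate_multilabel(Y + 0.0, Y, thr)
  expect_true(all(perfect$auroc == 1))
  expect_true(all(perfect$sensitivity == 1))
  # constant scores carry no ranking information
  const <- evaluate_multilabel(matrix(0.5, n, 6,
                                      dimnames = list(NULL, locations())),
                               Y, thr)
  expect_true(all(abs(const$auroc - 0.5) < 1e-12))
})
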