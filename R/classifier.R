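#' Model configuration
#'
#' Defaults follow the boosted-tree settings used for the published
#' composition model: 1000 rounds, learning rate 0.01, max_delta_step 1,
#' seed 1. `n_rounds` scales down for quick experiments; backend
#' `"logistic"` swaps in a plain logistic regression per location behind
#' the same train/predict contract.
#'
#' @param n_rounds Number of boosting rounds (default 1000).
#' @param learning_rate Shrinkage per round (default 0.01).
#' @param random_seed Seed controlling all training randomness (default 1).
#' @param max_delta_step Maximum delta step per leaf, stabilizes updates
#'   under class imbalance (default 1).
#' @param backend `"xgboost"` (default) or `"logistic"`.
#' @return A list of class `model_config`.
#' @export
model_config <- function(n_rounds = 1000L, learning_rate = 0.01,
                         random_seed = 1L, max_delta_step = 1,
                         backend = c("xgboost", "logistic")) {
  stopifnot(n_rounds >= 1L, learning_rate > 0)
  structure(list(n_rounds = as.integer(n_rounds),
                 learning_rate = learning_rate,
                 random_seed = as.integer(random_seed),
                 max_delta_step = max_delta_step,
                 backend = match.arg(backend)),
            class = "model_config")
}

#' Train the multi-label localization model
#'
#' Binary relevance: six independent binary classifiers, one per location,
#' all fitted on the same feature matrix with that location's label column
#' as target. Training is deterministic given `config$random_seed`
#' (single-threaded boosting).
#'
#' @param X Feature matrix from [featurize()] (columns named).
#' @param Y Label matrix, same rows as `X`, six 0/1 columns in canonical
#'   order.
#' @param config A [model_config()].
#' @return An object of class `mlsubloc_model` with per-location fitted
#'   classifiers, the feature name list, the config, and per-location
#'   decision thresholds (initialized to 0.5 until set by the evaluation
#'   workflow).
#' @export
train_model <- function(X, Y, config = model_config()) {
  stopifnot(nrow(X) == nrow(Y), nrow(X) >= 2L, ncol(Y) == 6L)
  colnames(Y) <- locations()
  for (loc in locations()) {
    npos <- sum(Y[, loc] == 1L)
    if (npos == 0L || npos == nrow(Y)) {
      stop("location '", loc, "' has no ",
           if (npos == 0L) "positive" else "negative",
           " examples in the training data")
    }
  }
  fits <- lapply(locations(), function(loc) {
    y <- as.numeric(Y[, loc])
    if (config$backend == "xgboost") {
      params <- list(objective = "binary:logistic",
                     eta = config$learning_rate,
                     max_delta_step = config$max_delta_step,
                     seed = config$random_seed,
                     nthread = 1L)
      xgboost::xgb.train(params = params,
                         data = xgboost::xgb.DMatrix(X, label = y),
                         nrounds = config$n_rounds, verbose = 0)
    } else {
      df <- data.frame(.y = y, X, check.names = FALSE)
      suppressWarnings(stats::glm(.y ~ ., data = df,
                                  family = stats::binomial()))
    }
  })
  names(fits) <- locations()
  structure(list(fits = fits,
                 feature_names = colnames(X),
                 config = config,
                 thresholds = stats::setNames(rep(0.5, 6L), locations())),
            class = "mlsubloc_model")
}

#' Predict per-location probabilities
#'
#' @param model A fitted `mlsubloc_model`.
#' @param X Feature matrix with exactly the model's feature columns, in
#'   the same order.
#' @return Numeric matrix (rows of `X` x 6 locations) of probabilities.
#' @export
predict_proba <- function(model, X) {
  check_feature_columns(model, X)
  if (nrow(X) == 0L) {
    return(matrix(numeric(0), 0L, 6L,
                  dimnames = list(NULL, locations())))
  }
  P <- vapply(locations(), function(loc) {
    fit <- model$fits[[loc]]
    if (model$config$backend == "xgboost") {
      stats::predict(fit, xgboost::xgb.DMatrix(X))
    } else {
      as.numeric(stats::predict(fit,
                                newdata = data.frame(X, check.names = FALSE),
                                type = "response"))
    }
  }, numeric(nrow(X)))
  P <- matrix(P, nrow = nrow(X), dimnames = list(rownames(X), locations()))
  P
}

check_feature_columns <- function(model, X) {
  missing <- setdiff(model$feature_names, colnames(X))
  extra <- setdiff(colnames(X), model$feature_names)
  if (length(missing) > 0L || length(extra) > 0L ||
      !identical(colnames(X), model$feature_names)) {
    stop("feature columns do not match the model",
         if (length(missing) > 0L)
           paste0("; missing: ", paste(utils::head(missing, 5L),
                                       collapse = ", ")),
         if (length(extra) > 0L)
           paste0("; unexpected: ", paste(utils::head(extra, 5L),
                                          collapse = ", ")))
  }
}

#' Save a model artifact
#'
#' Writes a directory with one file per location classifier plus a JSON
#' manifest (config, feature names, thresholds, location order, and the
#' checksums of any bundled motif files), so a prediction run is fully
#' reconstructable.
#'
#' @param model A `mlsubloc_model`.
#' @param dir Output directory (created).
#' @param motif_dir Optional directory of motif files to bundle.
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir, motif_dir = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (loc in locations()) {
    f <- file.path(dir, paste0(loc, ".model"))
    if (model$config$backend == "xgboost") {
      xgboost::xgb.save(model$fits[[loc]], paste0(f, ".json"))
    } else {
      saveRDS(model$fits[[loc]], paste0(f, ".rds"))
    }
  }
  motif_checksums <- NULL
  if (!is.null(motif_dir)) {
    write_motif_sets(read_motif_sets(motif_dir), file.path(dir, "motifs"))
    files <- list.files(file.path(dir, "motifs"), full.names = TRUE)
    motif_checksums <- as.list(stats::setNames(
      vapply(files, function(f) unname(tools::md5sum(f)), character(1)),
      basename(files)))
  }
  manifest <- list(package = "mlsubloc",
                   location_order = locations(),
                   config = unclass(model$config),
                   thresholds = as.list(model$thresholds),
                   feature_names = model$feature_names,
                   motif_checksums = motif_checksums)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Load a model artifact
#'
#' @param dir Directory written by [save_model()].
#' @return A `mlsubloc_model`.
#' @export
load_model <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  config <- do.call(model_config, mf$config[c("n_rounds", "learning_rate",
                                              "random_seed",
                                              "max_delta_step", "backend")])
  fits <- lapply(locations(), function(loc) {
    f <- file.path(dir, paste0(loc, ".model"))
    if (config$backend == "xgboost") {
      xgboost::xgb.load(paste0(f, ".json"))
    } else {
      readRDS(paste0(f, ".rds"))
    }
  })
  names(fits) <- locations()
  structure(list(fits = fits,
                 feature_names = mf$feature_names,
                 config = config,
                 thresholds = unlist(mf$thresholds)[locations()]),
            class = "mlsubloc_model")
}
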