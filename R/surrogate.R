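# Surrogate models mapping sequence features to TE or mRNA level.
# Four model classes are supported (random forest, elastic net,
# single regression tree, SVM); evaluation is 5-fold cross-validated
# Spearman correlation between predicted and actual targets, and the
# final model is refit on all data. The fitted surrogate provides the
# genetic algorithm's fitness function.

MODEL_SPECS <- c("random_forest", "linear_l1l2", "single_tree", "svm")

fit_one <- function(model_spec, X, y, n_trees = 500L) {
  switch(model_spec,
    random_forest = randomForest::randomForest(x = X, y = y,
                                               ntree = n_trees),
    linear_l1l2 = glmnet::cv.glmnet(X, y, alpha = 0.5, nfolds = 5L),
    single_tree = {
      df <- as.data.frame(X); df$.y <- y
      rpart::rpart(.y ~ ., data = df, method = "anova")
    },
    svm = e1071::svm(x = X, y = y),
    stop("unknown model_spec: '", model_spec, "'", call. = FALSE)
  )
}

predict_one <- function(model_spec, fit, X) {
  switch(model_spec,
    random_forest = unname(predict(fit, X)),
    linear_l1l2 = as.numeric(predict(fit, newx = X, s = "lambda.min")),
    single_tree = unname(predict(fit, as.data.frame(X))),
    svm = unname(predict(fit, X))
  )
}

# Seeded shuffle of 1..n, assigned round-robin to n_folds folds.
make_folds <- function(n, n_folds, seed) {
  idx <- withr::with_seed(seed, sample.int(n))
  fold <- integer(n)
  fold[idx] <- rep(seq_len(n_folds), length.out = n)
  fold
}

spearman <- function(a, b) cor(a, b, method = "spearman")

#' Train a surrogate model with cross-validated evaluation
#'
#' Rows are split into `n_folds` non-overlapping test folds by a
#' seeded shuffle; for each fold the model is trained on the remaining
#' rows and Spearman correlation (average ranks) between predicted and
#' actual targets is recorded. The returned model is refit on all
#' rows. Targets are log-transformed (`log2(y + 1e-3)`) before
#' regression by default because TE and RPKM are right-skewed;
#' predictions are returned on the original scale.
#'
#' @param X Feature matrix from [featurize_matrix()].
#' @param y Target vector (TE or mRNA level), length `nrow(X)`.
#' @param target `"TE"` or `"mRNA"` (bookkeeping label).
#' @param model_spec One of `r paste(MODEL_SPECS, collapse = ", ")`.
#' @param n_folds Number of CV folds (default 5).
#' @param seed Integer seed; the whole procedure is deterministic
#'   given it.
#' @param log_transform Log-transform targets before fitting?
#' @param n_trees Trees for the random forest (default 500).
#' @param folds Optional precomputed fold assignment (integer vector
#'   in `1..n_folds`), used by [compare_models()] to share folds.
#' @return Object of class `surrogate_model` with elements `fit`,
#'   `model_spec`, `target`, `schema_hash`, `cv_spearman` (per fold),
#'   `cv_folds`, `seed`.
#' @export
train_surrogate <- function(X, y, target = c("TE", "mRNA"),
                            model_spec = "random_forest", n_folds = 5L,
                            seed = 1L, log_transform = TRUE,
                            n_trees = 500L, folds = NULL) {
  target <- match.arg(target)
  model_spec <- match.arg(model_spec, MODEL_SPECS)
  stopifnot(is.matrix(X), nrow(X) == length(y))
  if (any(!is.finite(X)) || any(!is.finite(y))) {
    stop("X and y must be finite with no missing values", call. = FALSE)
  }
  if (nrow(X) < 10L * n_folds) {
    stop("need at least ", 10L * n_folds, " rows for ", n_folds,
         "-fold cross-validation", call. = FALSE)
  }
  schema_hash <- attr(X, "schema_hash")
  if (is.null(schema_hash)) schema_hash <- rlang::hash(colnames(X))
  yt <- if (log_transform) log2(y + 1e-3) else y
  if (is.null(folds)) folds <- make_folds(nrow(X), n_folds, seed)
  stopifnot(length(folds) == nrow(X), setequal(unique(folds),
                                               seq_len(n_folds)))
  cv <- withr::with_seed(seed + 1L, vapply(seq_len(n_folds), function(f) {
    test <- folds == f
    fit <- fit_one(model_spec, X[!test, , drop = FALSE], yt[!test], n_trees)
    pred <- predict_one(model_spec, fit, X[test, , drop = FALSE])
    spearman(pred, yt[test])
  }, numeric(1)))
  fit <- withr::with_seed(seed + 2L, fit_one(model_spec, X, yt, n_trees))
  structure(list(fit = fit, model_spec = model_spec, target = target,
                 schema_hash = schema_hash, cv_spearman = cv,
                 cv_folds = folds, seed = seed,
                 log_transform = log_transform),
            class = "surrogate_model")
}

#' @export
print.surrogate_model <- function(x, ...) {
  cat("surrogate_model:", x$model_spec, "->", x$target, "\n")
  cat(sprintf("  CV Spearman (per fold): %s\n",
              paste(sprintf("%.3f", x$cv_spearman), collapse = " ")))
  cat(sprintf("  mean CV Spearman: %.3f\n", mean(x$cv_spearman)))
  invisible(x)
}

#' Predict from a surrogate model
#'
#' Refuses feature input whose schema hash does not match the one the
#' model was trained with.
#'
#' @param object A `surrogate_model`.
#' @param newdata Feature matrix (or single named feature vector).
#' @param ... Unused.
#' @return Predictions on the original target scale.
#' @export
predict.surrogate_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) {
    nm <- names(newdata)
    newdata <- matrix(newdata, nrow = 1L, dimnames = list(NULL, nm))
  }
  hash <- attr(newdata, "schema_hash")
  if (is.null(hash)) hash <- rlang::hash(colnames(newdata))
  if (!identical(hash, object$schema_hash)) {
    stop("feature schema mismatch: model was trained on a different ",
         "feature configuration", call. = FALSE)
  }
  pred <- predict_one(object$model_spec, object$fit, newdata)
  if (object$log_transform) pmax(2^pred - 1e-3, 0) else pred
}

#' Compare surrogate model classes under shared CV folds
#'
#' Trains one surrogate per model class with an identical fold
#' assignment and returns the mean CV Spearman of each, sorted
#' descending.
#'
#' @inheritParams train_surrogate
#' @param specs Model classes to compare (default all four).
#' @return data.frame with columns `model_spec`, `mean_cv_spearman`,
#'   sorted descending; attribute `models` holds the fitted
#'   surrogates.
#' @export
compare_models <- function(X, y, target = "TE", specs = MODEL_SPECS,
                           n_folds = 5L, seed = 1L, log_transform = TRUE,
                           n_trees = 500L) {
  folds <- make_folds(nrow(X), n_folds, seed)
  models <- lapply(specs, function(sp)
    train_surrogate(X, y, target = target, model_spec = sp,
                    n_folds = n_folds, seed = seed,
                    log_transform = log_transform, n_trees = n_trees,
                    folds = folds))
  names(models) <- specs
  out <- data.frame(
    model_spec = specs,
    mean_cv_spearman = vapply(models, function(m) mean(m$cv_spearman),
                              numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out <- out[order(-out$mean_cv_spearman), ]
  rownames(out) <- NULL
  attr(out, "models") <- models
  out
}

#' Predict protein expression from paired surrogates
#'
#' Protein expression is modeled as mRNA level times translation
#' efficiency; this returns `predict(model_rna, fv) *
#' predict(model_te, fv)`.
#'
#' @param model_te,model_rna Surrogates for TE and mRNA sharing one
#'   feature schema.
#' @param fv Feature vector or matrix.
#' @return Predicted expression value(s).
#' @export
predict_expression <- function(model_te, model_rna, fv) {
  if (!identical(model_te$schema_hash, model_rna$schema_hash)) {
    stop("TE and mRNA surrogates use different feature schemas",
         call. = FALSE)
  }
  predict(model_rna, fv) * predict(model_te, fv)
}
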