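# The screening classifier: gradient-boosted trees over a 22-dimensional
# feature vector (age, orientation-task score, 20 modulation-spectrum
# components), with dementia as the positive class.

feature_signature <- function() c("age", "score", sprintf("ms_%02d", 1:20))

POSITIVE_CLASS <- "dementia"
NEGATIVE_CLASS <- "cognitively_normal"
MODEL_FORMAT_VERSION <- 1L

#' Assemble the classifier feature vector
#'
#' Combines age, the orientation-task score and the 20 acoustic components
#' into the fixed-order length-22 vector the screener consumes:
#' `(age, score, ms_01..ms_20)`. Ages outside \[20, 100) are excluded, as
#' in the study population.
#'
#' @param age Age in years, in \[20, 100).
#' @param score Orientation-task score: integer 0-4, or an
#'   `orientation_result`.
#' @param acoustic A `modspec_features` object or numeric vector of
#'   length 20.
#' @return Named numeric vector of length 22.
#' @export
assemble_features <- function(age, score, acoustic) {
  if (!is.numeric(age) || length(age) != 1L || !is.finite(age))
    vs_invalid("age must be a single finite number")
  if (age < 20 || age >= 100)
    vs_exclusion(sprintf("age %.0f outside the study range [20, 100)", age))
  if (inherits(score, "orientation_result")) score <- score$score
  if (!is_count(score) || score < 0 || score > 4)
    vs_invalid("score must be an integer in 0..4")
  if (inherits(acoustic, "modspec_features")) acoustic <- acoustic$components
  if (!is.numeric(acoustic) || length(acoustic) != 20L)
    vs_dimension(sprintf("acoustic features must have length 20, got %d",
                         length(acoustic)))
  if (!all(is.finite(acoustic))) vs_validation("acoustic features must be finite")
  stats::setNames(c(age, score, acoustic), feature_signature())
}

#' Gradient-boosting hyperparameters
#'
#' Defaults (300 trees of depth 3 at learning rate 0.05) are conservative
#' choices for small tabular problems; all are overridable.
#'
#' @param nrounds Number of boosting rounds.
#' @param max_depth Maximum tree depth.
#' @param eta Learning rate.
#' @param subsample Row subsampling fraction per round.
#' @param ... Further parameters passed to `xgboost::xgb.train()`.
#' @return A list of class `screener_params`.
#' @export
screener_params <- function(nrounds = 300L, max_depth = 3L, eta = 0.05,
                            subsample = 1, ...) {
  structure(list(nrounds = as.integer(nrounds),
                 max_depth = as.integer(max_depth),
                 eta = eta, subsample = subsample, extra = list(...)),
            class = "screener_params")
}

as_feature_matrix <- function(x) {
  sig <- feature_signature()
  if (is.numeric(x) && is.null(dim(x))) {
    if (length(x) != 22L)
      vs_dimension(sprintf("feature vector must have length 22, got %d",
                           length(x)))
    x <- matrix(x, nrow = 1L, dimnames = list(NULL, sig))
  }
  if (is.data.frame(x)) x <- as.matrix(x[, intersect(sig, names(x)), drop = FALSE])
  if (!is.matrix(x) || ncol(x) != 22L ||
      (!is.null(colnames(x)) && !identical(colnames(x), sig)))
    vs_dimension("features must be a 22-column matrix in canonical order (age, score, ms_01..ms_20)")
  colnames(x) <- sig
  storage.mode(x) <- "double"
  x
}

#' Fit the voice-screening classifier
#'
#' Trains a gradient-boosting ensemble to separate dementia from
#' cognitively normal speakers. Training is deterministic for a fixed
#' `(features, labels, params, seed)` (single-threaded, seeded).
#'
#' @param features Matrix or data frame of feature vectors (columns `age`,
#'   `score`, `ms_01`..`ms_20`), one row per participant.
#' @param labels Character/factor vector with levels `"dementia"` and
#'   `"cognitively_normal"`; both classes must be present with at least 10
#'   examples each.
#' @param params A [screener_params()] list.
#' @param seed Training seed.
#' @param threshold Decision threshold on the dementia probability
#'   (label is dementia iff probability >= threshold).
#' @return An object of class `screener`.
#' @export
fit_screener <- function(features, labels, params = screener_params(),
                         seed = 1L, threshold = 0.5) {
  X <- as_feature_matrix(features)
  labels <- as.character(labels)
  if (nrow(X) != length(labels))
    vs_validation("features and labels must have the same length")
  if (!all(labels %in% c(POSITIVE_CLASS, NEGATIVE_CLASS)))
    vs_validation(sprintf("labels must be '%s' or '%s'",
                          POSITIVE_CLASS, NEGATIVE_CLASS))
  if (anyNA(X) || !all(is.finite(X)))
    vs_validation("features contain missing or non-finite values")
  counts <- table(factor(labels, levels = c(POSITIVE_CLASS, NEGATIVE_CLASS)))
  if (any(counts == 0L))
    vs_degenerate("training data must contain both classes")
  if (any(counts < 10L))
    vs_degenerate("need at least 10 examples per class")
  if (threshold < 0 || threshold > 1) vs_invalid("threshold must be in [0, 1]")

  y <- as.integer(labels == POSITIVE_CLASS)
  set.seed(seed)
  booster <- xgboost::xgb.train(
    params = c(list(objective = "binary:logistic",
                    max_depth = params$max_depth, eta = params$eta,
                    subsample = params$subsample,
                    nthread = 1L, seed = seed),
               params$extra),
    data = xgboost::xgb.DMatrix(X, label = y),
    nrounds = params$nrounds, verbose = 0)
  structure(list(booster = booster, params = params,
                 signature = feature_signature(), seed = as.integer(seed),
                 threshold = threshold,
                 n_train = nrow(X), class_counts = as.list(counts),
                 version = MODEL_FORMAT_VERSION),
            class = "screener")
}

#' Predict dementia probability and label
#'
#' @param object A fitted `screener`.
#' @param newdata A feature vector (length 22), matrix or data frame with
#'   the canonical columns.
#' @param type `"response"` for a data frame of probability and label,
#'   `"prob"` or `"label"` for the bare vector.
#' @param ... Unused.
#' @return Data frame with columns `probability` and `label`, or the
#'   requested vector.
#' @export
predict.screener <- function(object, newdata,
                             type = c("response", "prob", "label"), ...) {
  type <- match.arg(type)
  X <- as_feature_matrix(newdata)
  if (!identical(colnames(X), object$signature))
    vs_dimension("feature signature mismatch with the fitted model")
  prob <- stats::predict(object$booster, xgboost::xgb.DMatrix(X))
  label <- ifelse(prob >= object$threshold, POSITIVE_CLASS, NEGATIVE_CLASS)
  switch(type,
         prob = prob,
         label = label,
         response = data.frame(probability = prob, label = label,
                               stringsAsFactors = FALSE))
}

#' @export
print.screener <- function(x, ...) {
  cat("Voice-screening gradient-boosting classifier\n")
  cat(sprintf("  trained on %d records (%s %d / %s %d), seed %d\n",
              x$n_train, POSITIVE_CLASS, x$class_counts[[POSITIVE_CLASS]],
              NEGATIVE_CLASS, x$class_counts[[NEGATIVE_CLASS]], x$seed))
  cat(sprintf("  %d rounds, depth %d, eta %.3g; threshold %.2f on P(%s)\n",
              x$params$nrounds, x$params$max_depth, x$params$eta,
              x$threshold, POSITIVE_CLASS))
  invisible(x)
}

#' Summarize a fitted screener
#'
#' @param object A fitted `screener`.
#' @param ... Unused.
#' @return The object, invisibly, after printing hyperparameters and the
#'   gain-based feature importances (which sum to 1).
#' @export
summary.screener <- function(object, ...) {
  print(object)
  imp <- feature_importance(object)
  cat("Top feature importances (gain):\n")
  print(utils::head(imp, 8L), row.names = FALSE)
  invisible(object)
}

#' Gain-based feature importance
#'
#' @param model A fitted `screener`.
#' @return Data frame of features and normalized gain (sums to 1 over
#'   features used by the ensemble).
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "screener"))
  imp <- xgboost::xgb.importance(model = model$booster)
  data.frame(feature = imp$Feature, gain = imp$Gain,
             stringsAsFactors = FALSE)
}

#' Save / load a fitted screener
#'
#' The ensemble is serialized in xgboost's raw format inside an RDS
#' container, with a human-readable JSON sidecar (`<path>.json`) recording
#' the format version, hyperparameters, feature signature, seed and
#' threshold. Loading verifies the version and that the binary
#' deserializes; a truncated or incompatible file raises a compatibility
#' error.
#'
#' @param model A fitted `screener`.
#' @param path Destination path for the model binary.
#' @return `save_screener`: `path`, invisibly. `load_screener`: the
#'   restored `screener`.
#' @export
save_screener <- function(model, path) {
  stopifnot(inherits(model, "screener"))
  payload <- list(version = model$version,
                  booster_raw = xgboost::xgb.save.raw(model$booster),
                  params = unclass(model$params),
                  signature = model$signature, seed = model$seed,
                  threshold = model$threshold,
                  n_train = model$n_train, class_counts = model$class_counts)
  saveRDS(payload, path)
  sidecar <- payload[setdiff(names(payload), "booster_raw")]
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_screener
#' @export
load_screener <- function(path) {
  if (!file.exists(path)) vs_not_found(sprintf("model not found: %s", path))
  payload <- tryCatch(readRDS(path), error = function(e)
    vs_compat(sprintf("cannot read model file %s: %s", path,
                      conditionMessage(e))))
  if (!is.list(payload) || is.null(payload$version) ||
      payload$version != MODEL_FORMAT_VERSION)
    vs_compat("model file has an unsupported format version")
  booster <- tryCatch(xgboost::xgb.load.raw(payload$booster_raw),
                      error = function(e)
    vs_compat(sprintf("cannot deserialize model ensemble: %s",
                      conditionMessage(e))))
  structure(list(booster = booster,
                 params = structure(payload$params, class = "screener_params"),
                 signature = payload$signature, seed = payload$seed,
                 threshold = payload$threshold,
                 n_train = payload$n_train, class_counts = payload$class_counts,
                 version = payload$version),
            class = "screener")
}
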