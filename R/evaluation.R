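## Evaluation: balanced accuracy, the class-weighted linear SVM contract, and
## cross-validated hyperparameter selection over the (k, epsilon) grid.

#' Subset trials
#'
#' `epochs[i]` keeps trials `i` (channels and samples are never subset; the
#' channel order is part of every downstream contract).
#'
#' @param x an [EEGEpochs-class] object.
#' @param i trial indices.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "EEGEpochs", function(x, i, j, ..., drop = FALSE) {
  eegEpochs(x@data[i, , , drop = FALSE], x@labels[i], x@fs, x@channelNames)
})

#' Balanced accuracy
#'
#' Mean of the per-class recalls, i.e. (sensitivity + specificity) / 2 for two
#' classes. Chance level is 0.5 regardless of class imbalance: an
#' always-majority predictor scores exactly 0.5.
#'
#' @param yTrue true labels (both classes must be present).
#' @param yPred predicted labels, same length.
#' @return A number in `[0, 1]`.
#' @export
balancedAccuracy <- function(yTrue, yPred) {
  if (length(yTrue) != length(yPred))
    stopUsage("yTrue and yPred must have equal length")
  cls <- unique(yTrue)
  if (length(cls) < 2L)
    stopData("yTrue contains a single class; balanced accuracy undefined")
  mean(vapply(cls, function(c) mean(yPred[yTrue == c] == c), numeric(1L)))
}

#' Class-weighted linear classifier
#'
#' @slot fit the underlying support-vector machine fit.
#' @slot classes the two class labels, sorted.
#' @slot weights named per-class misclassification penalties.
#' @export
setClass("WeightedClassifier", representation(
  fit = "ANY",
  classes = "integer",
  weights = "numeric"
))

setMethod("show", "WeightedClassifier", function(object) {
  cat(sprintf("WeightedClassifier (linear SVM): classes %s, weights %s\n",
              paste(object@classes, collapse = "/"),
              paste(sprintf("%.3g", object@weights), collapse = "/")))
})

#' Train a class-weighted soft-margin linear classifier
#'
#' Linear maximum-margin classifier (support-vector machine, unit base cost)
#' with per-class misclassification penalties inversely proportional to class
#' frequency: `w_c = n_total / (2 * n_c)`, so the minority:majority penalty
#' ratio equals the inverse of the class-size ratio. This keeps the decision
#' boundary from collapsing onto the majority class under heavy imbalance.
#' Deterministic given fixed inputs.
#'
#' @param features numeric matrix `[n_trials, n_features]`, finite.
#' @param labels per-trial labels, both classes present.
#' @return A [WeightedClassifier-class] object.
#' @seealso [predictLabels()], [classWeights()]
#' @export
trainWeightedClassifier <- function(features, labels) {
  labels <- as.integer(labels)
  if (any(!is.finite(features))) stopData("features contain non-finite values")
  cls <- sort(unique(labels))
  if (length(cls) != 2L) stopData("need exactly two classes in labels")
  n <- vapply(cls, function(c) sum(labels == c), integer(1L))
  w <- length(labels) / (2 * n)
  names(w) <- as.character(cls)
  fit <- e1071::svm(x = features, y = factor(labels, levels = cls),
                    kernel = "linear", cost = 1, class.weights = w,
                    scale = TRUE)
  new("WeightedClassifier", fit = fit, classes = cls, weights = w)
}

#' @rdname predictLabels
#' @export
setGeneric("predictLabels", function(object, features) standardGeneric("predictLabels"))

#' Predict labels for new feature rows
#'
#' @param object a [WeightedClassifier-class].
#' @param features numeric matrix with the training feature columns.
#' @return Integer labels on the training label scale.
#' @export
setMethod("predictLabels", "WeightedClassifier", function(object, features) {
  as.integer(as.character(stats::predict(object@fit, features)))
})

#' @rdname classWeights
#' @export
setGeneric("classWeights", function(object) standardGeneric("classWeights"))

#' Per-class penalty weights of a fitted classifier
#'
#' @param object a [WeightedClassifier-class].
#' @return Named numeric vector of per-class penalties.
#' @export
setMethod("classWeights", "WeightedClassifier", function(object) object@weights)

## Stratified fold assignment: per class, shuffle then deal round-robin.
stratifiedFolds <- function(labels, nFolds, seed) {
  folds <- integer(length(labels))
  withSeed(seed, {
    for (c in unique(labels)) {
      idx <- which(labels == c)
      if (length(idx) < nFolds)
        stopData("class ", c, " has fewer trials (", length(idx),
                 ") than folds (", nFolds, ")")
      folds[sample(idx)] <- rep_len(seq_len(nFolds), length(idx))
    }
  })
  folds
}

#' Cross-validated selection of k and epsilon
#'
#' Stratified `nFolds`-fold cross-validation over the grid of FIR half-orders
#' and regularization scalars: for each pair, fit the filter bank on the
#' training folds, extract log-variance features, train the weighted
#' classifier, and score the held-out fold. The chosen pair maximizes the mean
#' held-out score; ties are broken toward smaller `k`, then larger `epsilon`
#' (the simpler, more regularized model). Fold assignment is governed by
#' `seed` (default 0) and is independent of the grid.
#'
#' @param epochs training [EEGEpochs-class].
#' @param kGrid candidate half-orders (default `c(0, 1, 3, 5)`).
#' @param epsGrid candidate regularization scalars
#'   (default `c(1e-4, 1e-5, 1e-6)`).
#' @param m filter pairs (default 3).
#' @param nFolds folds (default 5).
#' @param metric `"accuracy"` (balanced designs) or `"balanced_accuracy"`
#'   (imbalanced designs).
#' @param seed fold-assignment seed (default 0).
#' @return A [CVResult-class] object.
#' @export
crossValidateSelect <- function(epochs, kGrid = c(0L, 1L, 3L, 5L),
                                epsGrid = c(1e-4, 1e-5, 1e-6), m = 3L,
                                nFolds = 5L,
                                metric = c("accuracy", "balanced_accuracy"),
                                seed = 0L) {
  metric <- match.arg(metric)
  if (nFolds < 2L) stopUsage("nFolds must be >= 2")
  labels <- trialLabels(epochs)
  folds <- stratifiedFolds(labels, nFolds, seed)
  grid <- expand.grid(k = as.integer(kGrid), epsilon = as.numeric(epsGrid),
                      KEEP.OUT.ATTRS = FALSE)
  scoreFun <- if (metric == "accuracy") function(yt, yp) mean(yt == yp)
              else balancedAccuracy
  foldScores <- matrix(NA_real_, nrow(grid), nFolds)
  for (p in seq_len(nrow(grid))) {
    for (f in seq_len(nFolds)) {
      tr <- epochs[folds != f]
      te <- epochs[folds == f]
      model <- fitCCSSP(tr, k = grid$k[p], epsilon = grid$epsilon[p], m = m)
      clf <- trainWeightedClassifier(extractFeatures(model, tr), trialLabels(tr))
      pred <- predictLabels(clf, extractFeatures(model, te))
      foldScores[p, f] <- scoreFun(trialLabels(te), pred)
    }
  }
  meanScores <- rowMeans(foldScores)
  best <- max(meanScores)
  tied <- which(meanScores >= best - 1e-12)
  tied <- tied[order(grid$k[tied], -grid$epsilon[tied])]
  chosen <- tied[1L]
  new("CVResult", grid = grid, meanScores = meanScores,
      foldScores = foldScores, chosenK = grid$k[chosen],
      chosenEpsilon = grid$epsilon[chosen], metricName = metric)
}
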