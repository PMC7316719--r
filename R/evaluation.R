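#' ROC curve and AUC of a score vector
#'
#' Builds the receiver operating characteristic by sweeping a threshold
#' over the distinct score values (ties grouped into a single step):
#' sensitivity TP/(TP+FN) against fall-out FP/(FP+TN). The area under the
#' curve is integrated with the trapezoidal rule and equals the
#' Mann-Whitney concordance probability (ties counted 1/2).
#'
#' @param scores numeric score vector.
#' @param labels 0/1 (or logical) vector of true classes, same length.
#' @return a list with class `RocCurve`: `thresholds` (decreasing, with
#'   leading `Inf`), `tpr`, `fpr` (both starting at 0 and ending at 1)
#'   and `auc`.
#' @examples
#' r <- rocCurve(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))
#' r$auc
#' @export
rocCurve <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  nPos <- sum(labels == 1L)
  nNeg <- sum(labels == 0L)
  if (nPos == 0L || nNeg == 0L) {
    stop("ROC requires both classes to be present")
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  # group tied scores into single thresholds
  isNew <- c(TRUE, s[-1] != s[-length(s)])
  grp <- cumsum(isNew)
  tpCum <- cumsum(y == 1L)
  fpCum <- cumsum(y == 0L)
  last <- which(c(isNew[-1], TRUE))   # last index of each tie group
  tpr <- c(0, tpCum[last] / nPos)
  fpr <- c(0, fpCum[last] / nNeg)
  thresholds <- c(Inf, s[last])
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = thresholds, tpr = tpr, fpr = fpr, auc = auc),
            class = "RocCurve")
}

#' @export
print.RocCurve <- function(x, ...) {
  cat("RocCurve:", length(x$thresholds) - 1L, "threshold steps, AUC =",
      format(x$auc, digits = 4), "\n")
  invisible(x)
}

#' Classification accuracy at a threshold
#'
#' Fraction of correct hard classifications: a score at or above the
#' threshold predicts the positive class.
#'
#' @param scores numeric score vector.
#' @param labels 0/1 vector of true classes.
#' @param threshold decision threshold (default 0.5).
#' @return accuracy in `[0, 1]`.
#' @export
accuracyScore <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), length(scores) > 0L,
            all(labels %in% c(0L, 1L)))
  mean((scores >= threshold) == (labels == 1L))
}

#' Average distance map of one class
#'
#' Elementwise mean of the 10 x 10 distance matrices of all samples with
#' the requested label; the analogue of the average bonded / non-bonded
#' heatmaps that motivate the featurization (bonded pairs show uniformly
#' shorter inter-residue blocks).
#'
#' @param data a [PairDataset-class] object.
#' @param label which class to average: 1 (bonded) or 0 (non-bonded).
#' @return symmetric 10 x 10 matrix with zero diagonal, atom names on
#'   both margins.
#' @export
meanDistanceMap <- function(data, label = 1L) {
  stopifnot(is(data, "PairDataset"), label %in% c(0L, 1L))
  sel <- which(data@labels == as.integer(label))
  if (length(sel) == 0L) stop("no samples with label ", label)
  unflattenDistances(colMeans(data@features[sel, , drop = FALSE]))
}

#' Relevance of the 45 distance features
#'
#' Fits a seeded random-forest regression of the 0/1 label on the 45
#' distance features over the training split and reports impurity-based
#' importances normalized to sum 1, keyed by feature name. Distances
#' internal to one residue are nearly constant (bonded geometry) and
#' receive near-zero importance; inter-residue distances carry the
#' signal.
#'
#' @param data a [PairDataset-class] object.
#' @param seed integer seed for the forest.
#' @param nTrees number of trees (default 200).
#' @return named numeric vector of length 45, non-negative, summing to 1.
#' @export
featureRelevance <- function(data, seed = 1L, nTrees = 200L) {
  stopifnot(is(data, "PairDataset"))
  X <- data@features[data@split == "train", , drop = FALSE]
  y <- as.numeric(data@labels[data@split == "train"])
  if (nrow(X) == 0L) {
    X <- data@features
    y <- as.numeric(data@labels)
  }
  # regression mode on the 0/1 label is intended; silence the forest's
  # few-unique-values advisory
  fit <- .withSeed(seed, suppressWarnings(randomForest::randomForest(
    x = as.data.frame(X), y = y, ntree = as.integer(nTrees)
  )))
  imp <- randomForest::importance(fit)[, 1]
  imp <- pmax(imp, 0)
  total <- sum(imp)
  if (total <= 0) {
    # no split ever reduced impurity (e.g. constant label); uniform weights
    imp <- rep(1 / length(imp), length(imp))
  } else {
    imp <- imp / total
  }
  names(imp) <- featureNames()
  imp
}

#' Summarize ranks of known engineered bonds
#'
#' Given per-case absolute and relative ranks (as produced by matching
#' known engineered bonds against a prediction report), recomputes the
#' average and median of each, the summary used to compare site-ranking
#' methods.
#'
#' @param absRanks integer vector of absolute ranks (0-based).
#' @param relRanks numeric vector of relative ranks in `[0, 1]`.
#' @return list with `absRanks`, `relRanks`, `meanAbs`, `medianAbs`,
#'   `meanRel`, `medianRel`.
#' @export
rankSummary <- function(absRanks, relRanks) {
  stopifnot(length(absRanks) == length(relRanks), length(absRanks) > 0L,
            all(absRanks >= 0L), all(relRanks >= 0), all(relRanks <= 1))
  list(absRanks = absRanks, relRanks = relRanks,
       meanAbs = mean(absRanks), medianAbs = stats::median(absRanks),
       meanRel = mean(relRanks), medianRel = stats::median(relRanks))
}
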