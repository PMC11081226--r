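# Distance functions and the k-nearest-neighbour classifier. The classifier
# is used standalone and as the fitness evaluator of the GA wrapper, so the
# distance code is vectorised over whole query sets.

#' Distance specification
#'
#' Describes the metric used by the KNN classifier: the Chebyshev (L-inf)
#' distance, or the weighted Minkowski distance
#' L_p(x, y) = (sum_l |w_l x_l - w_l y_l|^p)^(1/p). Weights default to all
#' ones; for Chebyshev the weighted coordinate differences are maximised
#' instead of summed.
#'
#' @param kind `"minkowski"` or `"chebyshev"`.
#' @param p Minkowski order, a real >= 1 (ignored for Chebyshev).
#' @param weights optional non-negative per-feature weights with at least
#'   one positive entry; `NULL` means unit weights.
#' @return An object of class `DistanceSpec`.
#' @examples
#' vectorDistance(c(0, 0), c(3, 4), distanceSpec("minkowski", p = 2)) # 5
#' vectorDistance(c(0, 0), c(3, 4), distanceSpec("chebyshev"))        # 4
#' @export
distanceSpec <- function(kind = c("minkowski", "chebyshev"), p = 2,
                         weights = NULL) {
  kind <- match.arg(kind)
  if (kind == "minkowski") assertScalarNumber(p, "p", lower = 1)
  if (!is.null(weights)) {
    if (!is.numeric(weights) || any(!is.finite(weights)) || any(weights < 0) ||
        !any(weights > 0)) {
      stop("weights must be non-negative with at least one positive entry",
           call. = FALSE)
    }
  }
  structure(list(kind = kind, p = p, weights = weights),
            class = "DistanceSpec")
}

checkSpecDim <- function(spec, d) {
  if (!is.null(spec$weights) && length(spec$weights) != d) {
    stop("weights length (", length(spec$weights),
         ") does not match dimension (", d, ")", call. = FALSE)
  }
}

#' Distance between two feature vectors
#'
#' @param x,y numeric vectors of equal length with finite entries.
#' @param spec a [distanceSpec()].
#' @return The non-negative distance.
#' @export
vectorDistance <- function(x, y, spec = distanceSpec()) {
  if (length(x) != length(y)) stop("x and y differ in length", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("coordinates must be finite (impute missing values first)",
         call. = FALSE)
  }
  checkSpecDim(spec, length(x))
  w <- spec$weights %||% rep(1, length(x))
  a <- abs(w * x - w * y)
  if (spec$kind == "chebyshev") max(a) else sum(a^spec$p)^(1 / spec$p)
}

## Distances from every row of `X` (n x d) to every row of `Q` (m x d);
## returns an n x m matrix.
distanceMatrix <- function(X, Q, spec) {
  d <- ncol(X)
  checkSpecDim(spec, d)
  w <- spec$weights %||% rep(1, d)
  Xw <- X * rep(w, each = nrow(X))
  Qw <- Q * rep(w, each = nrow(Q))
  D <- matrix(0, nrow(X), nrow(Q))
  for (j in seq_len(nrow(Q))) {
    A <- abs(Xw - rep(Qw[j, ], each = nrow(X)))
    D[, j] <- if (spec$kind == "chebyshev") {
      do.call(pmax, lapply(seq_len(d), function(l) A[, l]))
    } else if (spec$p == 1) {
      rowSums(A)
    } else {
      rowSums(A^spec$p)^(1 / spec$p)
    }
  }
  D
}

#' The k nearest training neighbours of a query point
#'
#' Distance ties are broken by keeping the lower training index.
#'
#' @param train a complete (no missing entries) [LabeledDataset-class].
#' @param query numeric feature vector of length `nFeatures(train)`.
#' @param k neighbourhood size, between 1 and `nSamples(train)`.
#' @param spec a [distanceSpec()].
#' @return A list with `indices` (training row indices), `distances`
#'   (non-decreasing) and `labels` (their classes).
#' @export
neighborhood <- function(train, query, k, spec = distanceSpec()) {
  n <- nSamples(train)
  if (k < 1 || k > n) stop("k must be between 1 and ", n, call. = FALSE)
  m <- featureMatrix(train)
  if (anyNA(m) || anyNA(query)) {
    stop("missing entries are not permitted; impute first", call. = FALSE)
  }
  d <- distanceMatrix(m, matrix(query, nrow = 1L), spec)[, 1L]
  ord <- order(d, seq_along(d))[seq_len(k)]
  list(indices = ord, distances = d[ord],
       labels = as.character(sampleLabels(train))[ord])
}

## Plurality vote with the package's deterministic tie rules: among tied
## classes prefer the one whose nearest member is closest, then the
## lexicographically smallest label. `ord` is the full index order by
## ascending distance.
voteLabels <- function(labels, dists) {
  votes <- table(labels)
  top <- names(votes)[votes == max(votes)]
  if (length(top) > 1L) {
    nearest <- vapply(top, function(cl) min(dists[labels == cl]), numeric(1))
    top <- top[nearest == min(nearest)]
    top <- sort(top)
  }
  top[1L]
}

#' Classify one query point by k-nearest-neighbour vote
#'
#' The label with the plurality vote among the k nearest training samples
#' ("the minority follows the majority"). Vote ties go to the tied class
#' with the closest nearest member, then to the lexicographically smallest
#' label.
#'
#' @inheritParams neighborhood
#' @return The predicted class label (character).
#' @export
knnPredict <- function(train, query, k = 7, spec = distanceSpec()) {
  nb <- neighborhood(train, query, k, spec)
  voteLabels(nb$labels, nb$distances)
}

## Batch prediction for a query matrix; one distance matrix, then votes.
knnPredictBatch <- function(trainX, trainLabels, queryX, k, spec) {
  D <- distanceMatrix(trainX, queryX, spec)
  labs <- as.character(trainLabels)
  n <- nrow(trainX)
  vapply(seq_len(ncol(D)), function(j) {
    ord <- order(D[, j], seq_len(n))[seq_len(k)]
    voteLabels(labs[ord], D[ord, j])
  }, character(1))
}

#' Neighbourhood misclassification rate
#'
#' Fraction of neighbourhood labels that differ from the predicted label;
#' complements the agreement fraction exactly (rate + agreement = 1).
#'
#' @param nb a neighbourhood as returned by [neighborhood()].
#' @param predicted a class label.
#' @return The rate in \[0, 1\].
#' @export
misclassificationRate <- function(nb, predicted) {
  if (length(nb$labels) == 0L) stop("empty neighbourhood", call. = FALSE)
  mean(nb$labels != as.character(predicted))
}

#' Evaluate KNN accuracy of a train/test pair
#'
#' @param train,test complete [LabeledDataset-class] objects over the same
#'   features.
#' @param k neighbourhood size (default 7, the package's default operating
#'   point for expression-style data).
#' @param spec a [distanceSpec()].
#' @return A list with `accuracy`, `predicted` labels and the per-class
#'   contingency `table` of predicted vs true labels.
#' @export
evaluateKnn <- function(train, test, k = 7, spec = distanceSpec()) {
  trX <- featureMatrix(train); teX <- featureMatrix(test)
  if (anyNA(trX) || anyNA(teX)) {
    stop("missing entries are not permitted; impute first", call. = FALSE)
  }
  pred <- knnPredictBatch(trX, sampleLabels(train), teX, k, spec)
  truth <- as.character(sampleLabels(test))
  list(accuracy = mean(pred == truth), predicted = pred,
       table = table(predicted = pred, truth = truth))
}

#' Recognition rate across a grid of k values
#'
#' Classifies the validation set at each k and reports the accuracy
#' ("recognition rate"). The default grid is the odd values 1, 3, ..., 15,
#' since odd k avoids binary vote ties.
#'
#' @param train,validation complete [LabeledDataset-class] objects.
#' @param kValues integer vector of neighbourhood sizes, each in
#'   `[1, nSamples(train)]`.
#' @param spec a [distanceSpec()].
#' @return A data frame with columns `k` and `recognitionRate`.
#' @export
scanK <- function(train, validation, kValues = seq(1L, 15L, by = 2L),
                  spec = distanceSpec()) {
  if (length(kValues) == 0L) stop("kValues is empty", call. = FALSE)
  if (any(kValues < 1L | kValues > nSamples(train))) {
    stop("each k must be in [1, ", nSamples(train), "]", call. = FALSE)
  }
  trX <- featureMatrix(train); vaX <- featureMatrix(validation)
  D <- distanceMatrix(trX, vaX, spec)
  labs <- as.character(sampleLabels(train))
  truth <- as.character(sampleLabels(validation))
  n <- nrow(trX)
  rate <- vapply(kValues, function(k) {
    pred <- vapply(seq_len(ncol(D)), function(j) {
      ord <- order(D[, j], seq_len(n))[seq_len(k)]
      voteLabels(labs[ord], D[ord, j])
    }, character(1))
    mean(pred == truth)
  }, numeric(1))
  data.frame(k = as.integer(kValues), recognitionRate = rate)
}
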