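# GA-KNN wrapper feature selection: per-feature weight chromosomes evolved
# on the MGA grid, scored by KNN validation accuracy under the weighted
# Minkowski distance. Five encoding schemes: binary (0/1 masks), decimal
# (0, 0.1, ..., 1.0 grid), real ([0,1] continuous), gaussian (N(0.5, 0.2)
# initialisation clipped to [0,1]) and adaptive (continuous weights with a
# per-generation decode threshold tracking the current best individual).

gaSchemes <- c("binary", "decimal", "real", "gaussian", "adaptive")

#' Decode a weight chromosome into a feature subset
#'
#' Keeps the features whose weight strictly exceeds the threshold. Binary
#' chromosomes use the fixed threshold 0.5; continuous schemes default to
#' 0.5 as well, the adaptive scheme re-derives the threshold during
#' evolution. An all-below-threshold chromosome decodes to the empty set
#' (handled as zero fitness during evolution, not an error).
#'
#' @param weights numeric weight vector in \[0, 1\].
#' @param threshold decode cut-off.
#' @return Integer vector of selected feature indices (possibly empty).
#' @examples
#' decodeChromosome(c(1, 0, 1)) # 1, 3
#' @export
decodeChromosome <- function(weights, threshold = 0.5) {
  which(weights > threshold)
}

#' KNN validation accuracy of a weight chromosome
#'
#' The wrapper's fitness: the chromosome is decoded into a feature subset,
#' and the validation set is classified with the weighted Minkowski distance
#' restricted to that subset, the surviving weights acting as distance
#' weights. An empty subset scores 0.
#'
#' @param weights numeric weight vector, one per feature of `train`.
#' @param train,validation complete [LabeledDataset-class] objects over the
#'   same features.
#' @param k KNN neighbourhood size.
#' @param p Minkowski order.
#' @param threshold decode threshold.
#' @return Validation accuracy in \[0, 1\].
#' @export
chromosomeFitness <- function(weights, train, validation, k = 7, p = 2,
                              threshold = 0.5) {
  sel <- decodeChromosome(weights, threshold)
  if (length(sel) == 0L) return(0)
  spec <- distanceSpec("minkowski", p = p, weights = weights[sel])
  pred <- knnPredictBatch(featureMatrix(train)[, sel, drop = FALSE],
                          sampleLabels(train),
                          featureMatrix(validation)[, sel, drop = FALSE],
                          k, spec)
  mean(pred == as.character(sampleLabels(validation)))
}

## Scheme-specific MGA operators over [0,1]^D chromosomes.
schemeOps <- function(scheme, D) {
  grid <- seq(0, 1, by = 0.1)
  switch(scheme,
    binary = NULL,   # engine's native binary operators
    decimal = list(
      init = function(n, d) matrix(sample(grid, n * d, replace = TRUE), n, d),
      crossover = function(a, b) {
        pick <- stats::runif(length(a)) < 0.5
        ifelse(pick, a, b)
      },
      mutate = function(x, rate) {
        hit <- stats::runif(length(x)) < rate
        if (any(hit)) x[hit] <- sample(grid, sum(hit), replace = TRUE)
        x
      }),
    gaussian = list(
      init = function(n, d) {
        matrix(pmin(pmax(stats::rnorm(n * d, 0.5, 0.2), 0), 1), n, d)
      }),
    NULL)   # real / adaptive: engine's native continuous operators
}

#' Wrapper feature selection with the GA-KNN algorithm
#'
#' Splits the data into an internal training and validation portion
#' (stratified, seeded), evolves a matrix population of per-feature weight
#' chromosomes with the MGA engine (minimizing 1 - validation accuracy),
#' and decodes the best chromosome ever evaluated into the selected subset.
#' `accBefore` is the validation accuracy of the all-features unit-weight
#' chromosome; `history` records the best-so-far accuracy per generation
#' and is non-decreasing.
#'
#' @param ds a complete [LabeledDataset-class] with >= 2 classes.
#' @param scheme encoding scheme: `"binary"`, `"decimal"`, `"real"`,
#'   `"gaussian"` or `"adaptive"`.
#' @param gaConfig an [mgaConfig()] (its `seed` is ignored; use `seed`).
#' @param k,p KNN neighbourhood size and Minkowski order for the fitness.
#' @param trainFraction internal train/validation split fraction.
#' @param threshold decode threshold for the non-adaptive schemes.
#' @param seed integer seed controlling the split and the evolution.
#' @return A `SelectionResult`: list with `scheme`, `weights`, `threshold`,
#'   `selected` (feature indices), `nBefore`, `nAfter`, `accBefore`,
#'   `accAfter` and `history`.
#' @export
selectFeaturesGA <- function(ds, scheme = c("binary", "decimal", "real",
                                            "gaussian", "adaptive"),
                             gaConfig = mgaConfig(generations = 40L),
                             k = 7, p = 2, trainFraction = 0.7,
                             threshold = 0.5, seed = 1) {
  scheme <- match.arg(scheme)
  if (nlevels(sampleLabels(ds)) < 2L) stop("need >= 2 classes", call. = FALSE)
  if (anyNA(featureMatrix(ds))) {
    stop("missing entries are not permitted; impute first", call. = FALSE)
  }
  D <- nFeatures(ds)
  split <- stratifiedSplit(ds, trainFraction, seed = deriveSeed(seed, 1L))
  train <- split$train; val <- split$test
  k <- min(k, nSamples(train))

  state <- new.env(parent = emptyenv())
  state$threshold <- if (scheme == "binary") 0.5 else threshold
  state$bestAcc <- -1; state$bestW <- NULL; state$bestTh <- state$threshold

  objective <- function(w) {
    acc <- chromosomeFitness(w, train, val, k = k, p = p,
                             threshold = state$threshold)
    if (acc > state$bestAcc) {
      state$bestAcc <- acc
      state$bestW <- w
      state$bestTh <- state$threshold
    }
    1 - acc
  }

  problem <- optimizationProblem(objective, D, lower = 0, upper = 1,
                                 type = if (scheme == "binary") "binary"
                                        else "continuous",
                                 ops = schemeOps(scheme, D))
  accBefore <- chromosomeFitness(rep(1, D), train, val, k = k, p = p,
                                 threshold = 0.5)
  history <- withSeed(deriveSeed(seed, 2L), {
    pop <- mgaInit(problem, gaConfig)
    h <- state$bestAcc
    for (g in seq_len(gaConfig$generations)) {
      if (scheme == "adaptive" && !is.null(state$bestW)) {
        state$threshold <- mean(state$bestW)
      }
      pop <- mgaStep(pop, problem, gaConfig)
      h <- c(h, state$bestAcc)
    }
    h
  })
  selected <- sort(decodeChromosome(state$bestW, state$bestTh))
  structure(list(scheme = scheme, weights = state$bestW,
                 threshold = state$bestTh, selected = selected,
                 nBefore = D, nAfter = length(selected),
                 accBefore = accBefore, accAfter = state$bestAcc,
                 history = history, k = k, p = p, seed = seed),
            class = "SelectionResult")
}

#' @export
print.SelectionResult <- function(x, ...) {
  cat(sprintf("GA-KNN selection (%s encoding)\n", x$scheme))
  cat(sprintf("  features: %d -> %d\n", x$nBefore, x$nAfter))
  cat(sprintf("  validation accuracy: %.4f -> %.4f\n",
              x$accBefore, x$accAfter))
  invisible(x)
}

#' Tabulate selection results
#'
#' One row per result: encoding scheme, feature count and validation
#' accuracy before and after selection (accuracies to 4 decimals).
#'
#' @param results a `SelectionResult` or a list of them.
#' @return A data frame with columns `scheme`, `nBefore`, `accBefore`,
#'   `nAfter`, `accAfter`.
#' @export
selectionReport <- function(results) {
  if (inherits(results, "SelectionResult")) results <- list(results)
  do.call(rbind, lapply(results, function(r) {
    data.frame(scheme = r$scheme, nBefore = r$nBefore,
               accBefore = round(r$accBefore, 4), nAfter = r$nAfter,
               accAfter = round(r$accAfter, 4))
  }))
}
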