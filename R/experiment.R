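# Experiment protocol runner: repeated seeded 70/30 splits, the pipeline
# impute -> chi-square filter -> GA-KNN selection -> GP construction ->
# KNN evaluation, and aggregation of mean/max accuracy and mean selected
# feature count across repeats.

#' Experiment configuration
#'
#' Stages run in the fixed order impute, filter, select, construct,
#' evaluate; a `NULL` stage is skipped. Per-repeat seeds are derived from
#' the master seed by a counter and recorded in the per-repeat results.
#'
#' @param repeats number of repetitions (default 50); each repeat re-splits
#'   the data with a fresh derived seed.
#' @param trainFraction train fraction of the per-repeat stratified split.
#' @param seed master seed.
#' @param impute `NULL` to skip, or a list with `k` (imputation runs once,
#'   before splitting).
#' @param filter `NULL` to skip, or a list with `topM` or `alpha` (and
#'   optionally `bins`) for the chi-square filter, fitted on the training
#'   portion.
#' @param select `NULL` to skip, or a list with `scheme`, `generations`,
#'   `rows`, `cols` for GA-KNN selection on the training portion.
#' @param construct `NULL` to skip, or a list with `runs`, `generations`,
#'   `populationSize`, `maxDepth` for GP construction.
#' @param k,p KNN evaluation parameters.
#' @return An object of class `ExperimentConfig`.
#' @export
experimentConfig <- function(repeats = 50L, trainFraction = 0.7, seed = 1L,
                             impute = NULL, filter = NULL, select = NULL,
                             construct = NULL, k = 7, p = 2) {
  stopifnot(repeats >= 1, trainFraction > 0, trainFraction < 1)
  structure(list(repeats = as.integer(repeats),
                 trainFraction = trainFraction, seed = seed,
                 impute = impute, filter = filter, select = select,
                 construct = construct, k = k, p = p),
            class = "ExperimentConfig")
}

runRepeat <- function(ds, cfg, repSeed) {
  split <- stratifiedSplit(ds, cfg$trainFraction, seed = repSeed)
  train <- split$train; test <- split$test
  keep <- seq_len(nFeatures(ds))

  if (!is.null(cfg$filter)) {
    ranked <- rankFeaturesChi2(train, bins = cfg$filter$bins %||% 2L)
    keep <- chi2Select(ranked, topM = cfg$filter$topM,
                       alpha = cfg$filter$alpha)
    if (length(keep) < 2L) keep <- ranked$index[1:2]
    train <- train[, keep]; test <- test[, keep]
  }
  nSelected <- length(keep)

  if (!is.null(cfg$select)) {
    sel <- selectFeaturesGA(
      train,
      scheme = cfg$select$scheme %||% "binary",
      gaConfig = mgaConfig(rows = cfg$select$rows %||% 5L,
                           cols = cfg$select$cols %||% 5L,
                           generations = cfg$select$generations %||% 40L),
      k = cfg$k, p = cfg$p, seed = deriveSeed(repSeed, 3L))
    if (sel$nAfter >= 1L) {
      train <- train[, sel$selected]
      test <- test[, sel$selected]
      nSelected <- sel$nAfter
    }
  }

  trees <- list()
  if (!is.null(cfg$construct)) {
    inner <- stratifiedSplit(train, cfg$trainFraction,
                             seed = deriveSeed(repSeed, 5L))
    gcfg <- gpConfig(
      populationSize = cfg$construct$populationSize %||% 200L,
      generations = cfg$construct$generations %||% 20L,
      maxDepth = cfg$construct$maxDepth %||% 19L,
      runs = cfg$construct$runs %||% 1L,
      seed = deriveSeed(repSeed, 7L))
    trees <- constructMulti(inner$train, inner$test, cfg = gcfg, k = cfg$k)
  }

  acc <- if (length(trees) > 0) {
    validateConstructed(train, test, trees, k = cfg$k)$accWith
  } else {
    evaluateKnn(train, test, k = min(cfg$k, nSamples(train)),
                spec = distanceSpec("minkowski", p = cfg$p))$accuracy
  }
  list(accuracy = acc, nFeatures = nSelected)
}

#' Run the repeated-split experiment protocol
#'
#' For each repeat: a fresh seeded stratified split, the configured
#' pipeline stages, and KNN test accuracy. Stage failures are caught: the
#' repeat is marked failed and the summary reports the completed count.
#' Fully deterministic given the master seed.
#'
#' @param ds a [LabeledDataset-class].
#' @param cfg an [experimentConfig()].
#' @param logFile optional path; when given, a machine-readable JSON log
#'   (seeds, package version, stage parameters, per-repeat rows) is
#'   written there.
#' @return A list of class `ExperimentSummary` with `meanAccuracy`,
#'   `maxAccuracy`, `meanFeatureCount`, `completed`, `repeats` and the
#'   per-repeat data frame `perRepeat`.
#' @export
runExperiment <- function(ds, cfg = experimentConfig(), logFile = NULL) {
  if (!is.null(cfg$impute)) {
    ds <- imputeKNN(ds, k = cfg$impute$k %||% 7)
  } else if (anyNA(featureMatrix(ds))) {
    stop("dataset has missing entries; enable the impute stage",
         call. = FALSE)
  }
  seeds <- vapply(seq_len(cfg$repeats), function(r) deriveSeed(cfg$seed, r),
                  integer(1))
  rows <- lapply(seq_len(cfg$repeats), function(r) {
    res <- tryCatch(runRepeat(ds, cfg, seeds[r]),
                    error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(repeat. = r, seed = seeds[r], accuracy = NA_real_,
                 nFeatures = NA_integer_, status = conditionMessage(res))
    } else {
      data.frame(repeat. = r, seed = seeds[r], accuracy = res$accuracy,
                 nFeatures = res$nFeatures, status = "ok")
    }
  })
  perRepeat <- do.call(rbind, rows)
  ok <- perRepeat$status == "ok"
  summary <- structure(list(
    meanAccuracy = mean(perRepeat$accuracy[ok]),
    maxAccuracy = if (any(ok)) max(perRepeat$accuracy[ok]) else NA_real_,
    meanFeatureCount = mean(perRepeat$nFeatures[ok]),
    completed = sum(ok), repeats = cfg$repeats,
    perRepeat = perRepeat), class = "ExperimentSummary")
  if (!is.null(logFile)) {
    log <- list(
      package = "MGAselect",
      version = as.character(utils::packageVersion("MGAselect")),
      masterSeed = cfg$seed, repeatSeeds = seeds,
      config = cfg[c("repeats", "trainFraction", "k", "p", "impute",
                     "filter", "select", "construct")],
      summary = summary[c("meanAccuracy", "maxAccuracy",
                          "meanFeatureCount", "completed")],
      perRepeat = perRepeat)
    jsonlite::write_json(log, logFile, auto_unbox = TRUE, digits = NA,
                         null = "null", force = TRUE)
  }
  summary
}

#' @export
print.ExperimentSummary <- function(x, ...) {
  cat(sprintf("Experiment: %d/%d repeats completed\n", x$completed,
              x$repeats))
  cat(sprintf("  mean accuracy: %.4f   max accuracy: %.4f\n",
              x$meanAccuracy, x$maxAccuracy))
  cat(sprintf("  mean selected features: %.1f\n", x$meanFeatureCount))
  invisible(x)
}
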