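# Delimited-text I/O, standardization, stratified splitting and accuracy
# accounting for LabeledDataset objects.

#' Read a labelled dataset from delimited text
#'
#' Reads a CSV (comma) or TSV (tab, auto-detected from a `.tsv` extension)
#' file with a header row: one row per sample, one column per feature, and
#' one label column. Cells equal to `missingToken` become missing entries
#' (`NA`); every other cell must parse as a real number.
#'
#' @param path path to the delimited file.
#' @param labelColumn name of the label column (default `"label"`).
#' @param missingToken string standing for a missing measurement
#'   (default `"NA"`).
#' @param sep field separator; `NULL` (default) picks tab for `.tsv`
#'   files and comma otherwise.
#' @return A [LabeledDataset-class].
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("label,g1,g2", "A,1,2", "B,3,4", "A,5,NA"), tf)
#' ds <- readLabeledDataset(tf)
#' featureMatrix(ds)
#' @export
readLabeledDataset <- function(path, labelColumn = "label",
                               missingToken = "NA", sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  if (!labelColumn %in% names(df)) {
    stop("label column '", labelColumn, "' not found in header", call. = FALSE)
  }
  if (nrow(df) == 0L) stop("no samples: file contains a header only",
                           call. = FALSE)
  labels <- df[[labelColumn]]
  if (any(is.na(labels) | labels == "")) {
    stop("missing label in row ", which(is.na(labels) | labels == "")[1L],
         call. = FALSE)
  }
  featNames <- names(df)[names(df) != labelColumn]
  if (anyDuplicated(featNames)) {
    stop("duplicate feature name: ",
         featNames[duplicated(featNames)][1L], call. = FALSE)
  }
  feat <- df[, names(df) != labelColumn, drop = FALSE]
  names(feat) <- featNames
  m <- matrix(NA_real_, nrow(feat), ncol(feat),
              dimnames = list(NULL, names(feat)))
  for (j in seq_along(feat)) {
    cell <- feat[[j]]
    isMissing <- is.na(cell) | cell == missingToken
    val <- suppressWarnings(as.numeric(cell))
    bad <- which(!isMissing & is.na(val))
    if (length(bad)) {
      stop(sprintf("cannot parse cell '%s' at row %d, column '%s'",
                   cell[bad[1L]], bad[1L], names(feat)[j]), call. = FALSE)
    }
    val[isMissing] <- NA_real_
    m[, j] <- val
  }
  LabeledDataset(m, labels)
}

#' Write a labelled dataset to delimited text
#'
#' Inverse of [readLabeledDataset()]: writes a header row, the label column
#' first, and one row per sample; missing entries become `missingToken`.
#'
#' @param ds a [LabeledDataset-class].
#' @param path output file path (`.tsv` extension selects tab separation).
#' @param labelColumn name for the label column.
#' @param missingToken token written for missing entries.
#' @return `path`, invisibly.
#' @export
writeLabeledDataset <- function(ds, path, labelColumn = "label",
                                missingToken = "NA") {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  m <- featureMatrix(ds)
  out <- data.frame(as.character(sampleLabels(ds)), m,
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out) <- c(labelColumn, colnames(m))
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     col.names = TRUE, quote = FALSE, na = missingToken)
  invisible(path)
}

#' Standardize a dataset feature-wise
#'
#' Centers and scales every feature to zero mean and unit (population)
#' standard deviation, computed over observed entries only. Missing entries
#' stay missing. The returned parameters invert the transform exactly via
#' [destandardize()]. Constant features get a floored standard deviation of
#' `sigmaFloor` so their standardized values are zero.
#'
#' @param ds a [LabeledDataset-class]; every feature needs at least one
#'   observed value.
#' @param sigmaFloor lower bound on the per-feature standard deviation.
#' @return A list with elements `dataset` (standardized) and `params`
#'   (list with numeric vectors `mu` and `sigma`).
#' @examples
#' ds <- LabeledDataset(cbind(g = c(1, 2, 3)), c("A", "B", "A"))
#' standardizeDataset(ds)$dataset
#' @export
standardizeDataset <- function(ds, sigmaFloor = 1e-8) {
  m <- featureMatrix(ds)
  nObs <- colSums(!is.na(m))
  if (any(nObs == 0L)) {
    stop("feature '", colnames(m)[which(nObs == 0L)[1L]],
         "' has no observed values", call. = FALSE)
  }
  mu <- colMeans(m, na.rm = TRUE)
  ## population standard deviation (divide by N, not N-1)
  sigma <- sqrt(colMeans(sweep(m, 2L, mu)^2, na.rm = TRUE))
  sigma <- pmax(sigma, sigmaFloor)
  z <- sweep(sweep(m, 2L, mu), 2L, sigma, "/")
  params <- list(mu = mu, sigma = sigma)
  list(dataset = LabeledDataset(z, sampleLabels(ds)), params = params)
}

#' Undo a standardization
#'
#' @param ds a standardized [LabeledDataset-class].
#' @param params the `params` element returned by [standardizeDataset()].
#' @return The de-standardized [LabeledDataset-class].
#' @export
destandardize <- function(ds, params) {
  z <- featureMatrix(ds)
  stopifnot(length(params$mu) == ncol(z), length(params$sigma) == ncol(z))
  m <- sweep(sweep(z, 2L, params$sigma, "*"), 2L, params$mu, "+")
  LabeledDataset(m, sampleLabels(ds))
}

#' Stratified train/test split
#'
#' Partitions a dataset into a training and a test portion while preserving
#' per-class proportions. The per-class training count is
#' `floor(trainFraction * classSize)`; remaining slots up to
#' `round(trainFraction * N)` are assigned to classes by decreasing
#' fractional part, ties broken by class label order. Deterministic for a
#' fixed seed.
#'
#' @param ds a [LabeledDataset-class]; every class needs at least 2 samples.
#' @param trainFraction fraction of samples assigned to training,
#'   strictly between 0 and 1.
#' @param seed integer seed controlling the within-class shuffle.
#' @return A list with `train` and `test` [LabeledDataset-class] objects.
#' @examples
#' ds <- LabeledDataset(matrix(rnorm(40), 20, 2), rep(c("A", "B"), 10))
#' sp <- stratifiedSplit(ds, 0.7, seed = 1)
#' nSamples(sp$train); nSamples(sp$test)
#' @export
stratifiedSplit <- function(ds, trainFraction = 0.7, seed = 1) {
  assertScalarNumber(trainFraction, "trainFraction")
  if (trainFraction <= 0 || trainFraction >= 1) {
    stop("trainFraction must be strictly between 0 and 1", call. = FALSE)
  }
  labs <- sampleLabels(ds)
  classes <- levels(labs)
  counts <- table(labs)
  if (any(counts < 2L)) {
    stop("class '", names(counts)[which(counts < 2L)[1L]],
         "' has fewer than 2 samples; cannot stratify", call. = FALSE)
  }
  n <- nSamples(ds)
  target <- round(trainFraction * n)
  base <- floor(trainFraction * as.numeric(counts))
  frac <- trainFraction * as.numeric(counts) - base
  deficit <- target - sum(base)
  take <- base
  if (deficit > 0) {
    ord <- order(-frac, seq_along(classes))
    take[ord[seq_len(deficit)]] <- take[ord[seq_len(deficit)]] + 1L
  }
  ## keep at least one sample of each class on both sides
  take <- pmin(pmax(take, 1L), as.numeric(counts) - 1L)
  trainIdx <- integer(0)
  withSeed(seed, {
    for (ci in seq_along(classes)) {
      idx <- which(labs == classes[ci])
      trainIdx <- c(trainIdx, sample(idx)[seq_len(take[ci])])
    }
  })
  trainIdx <- sort(trainIdx)
  testIdx <- setdiff(seq_len(n), trainIdx)
  list(train = ds[trainIdx, ], test = ds[testIdx, ])
}

#' Confusion counts for binary classification
#'
#' Tallies true/false positives and negatives of predicted against true
#' labels for a designated positive class.
#'
#' @param predicted,truth label vectors of equal length.
#' @param positive the label counted as the positive class.
#' @return A list with integer elements `tp`, `tn`, `fp`, `fn`.
#' @export
confusionCounts <- function(predicted, truth, positive) {
  predicted <- as.character(predicted); truth <- as.character(truth)
  stopifnot(length(predicted) == length(truth))
  list(tp = sum(predicted == positive & truth == positive),
       tn = sum(predicted != positive & truth != positive),
       fp = sum(predicted == positive & truth != positive),
       fn = sum(predicted != positive & truth == positive))
}

#' Classification accuracy from confusion counts
#'
#' Accuracy = (TP + TN) / (TP + TN + FP + FN). For multi-class problems the
#' same quantity is the plain fraction of correct predictions; confusion
#' counts apply to the binary case and one-vs-rest reductions.
#'
#' @param counts a list with non-negative integer elements
#'   `tp`, `tn`, `fp`, `fn` (as from [confusionCounts()]).
#' @return Accuracy in \[0, 1\].
#' @examples
#' accuracy(list(tp = 30, tn = 45, fp = 10, fn = 15)) # 0.75
#' @export
accuracy <- function(counts) {
  with(counts, {
    vals <- c(tp, tn, fp, fn)
    if (any(vals < 0)) stop("counts must be non-negative", call. = FALSE)
    total <- sum(vals)
    if (total == 0) stop("no evaluated samples (total count is 0)",
                         call. = FALSE)
    (tp + tn) / total
  })
}
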