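#' @import methods
NULL

#' LabeledDataset: a labelled sample-by-feature matrix
#'
#' The central container of the package: a numeric matrix with one row per
#' sample and one column per feature, plus a class label for every sample.
#' Missing entries are stored as `NA`. Feature names (column names) must be
#' unique; sample identifiers are the row names.
#'
#' @slot exprs numeric matrix, samples in rows, features in columns;
#'   `NA` marks a missing measurement.
#' @slot labels factor of length `nrow(exprs)` giving each sample's class.
#'
#' @seealso [LabeledDataset()] for construction,
#'   [readLabeledDataset()] for delimited-text input.
#' @exportClass LabeledDataset
setClass("LabeledDataset",
  representation(exprs = "matrix", labels = "factor"))

setValidity("LabeledDataset", function(object) {
  msg <- character()
  m <- object@exprs
  if (!is.numeric(m)) msg <- c(msg, "matrix must be numeric")
  if (nrow(m) != length(object@labels)) {
    msg <- c(msg, "row count must equal the number of labels")
  }
  if (is.null(colnames(m)) || anyDuplicated(colnames(m))) {
    msg <- c(msg, "feature names must be present and unique")
  }
  if (is.null(rownames(m)) || anyDuplicated(rownames(m))) {
    msg <- c(msg, "sample ids must be present and unique")
  }
  if (any(is.infinite(m))) msg <- c(msg, "matrix entries must be finite or NA")
  if (length(msg)) msg else TRUE
})

#' Construct a LabeledDataset
#'
#' @param exprs numeric matrix (samples x features); `NA` = missing.
#' @param labels vector of class labels, one per row of `exprs`. Coerced to
#'   factor; labels are treated as opaque categories, never as numbers.
#' @param featureNames optional character vector of unique feature names;
#'   defaults to existing column names or `f1..fD`.
#' @param sampleIds optional character vector of unique sample identifiers;
#'   defaults to existing row names or `s1..sN`.
#' @return A [LabeledDataset-class] object.
#' @examples
#' ds <- LabeledDataset(matrix(rnorm(12), 4, 3), c("A", "B", "A", "B"))
#' nSamples(ds); nFeatures(ds)
#' @export
LabeledDataset <- function(exprs, labels, featureNames = NULL,
                           sampleIds = NULL) {
  exprs <- as.matrix(exprs)
  storage.mode(exprs) <- "double"
  if (is.null(featureNames)) {
    featureNames <- colnames(exprs) %||% paste0("f", seq_len(ncol(exprs)))
  }
  if (is.null(sampleIds)) {
    sampleIds <- rownames(exprs) %||% paste0("s", seq_len(nrow(exprs)))
  }
  dimnames(exprs) <- list(as.character(sampleIds), as.character(featureNames))
  new("LabeledDataset", exprs = exprs, labels = factor(labels))
}

#' @describeIn LabeledDataset number of samples
#' @param x,object a `LabeledDataset`
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname LabeledDataset
#' @export
setMethod("nSamples", "LabeledDataset", function(x) nrow(x@exprs))

#' @describeIn LabeledDataset number of features
#' @export
setGeneric("nFeatures", function(x) standardGeneric("nFeatures"))

#' @rdname LabeledDataset
#' @export
setMethod("nFeatures", "LabeledDataset", function(x) ncol(x@exprs))

#' @describeIn LabeledDataset the sample-by-feature numeric matrix
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname LabeledDataset
#' @export
setMethod("featureMatrix", "LabeledDataset", function(x) x@exprs)

#' @describeIn LabeledDataset per-sample class labels (factor)
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))

#' @rdname LabeledDataset
#' @export
setMethod("sampleLabels", "LabeledDataset", function(x) x@labels)

#' @describeIn LabeledDataset sample identifiers
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname LabeledDataset
#' @export
setMethod("sampleIds", "LabeledDataset", function(x) rownames(x@exprs))

#' @describeIn LabeledDataset feature names
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' @rdname LabeledDataset
#' @export
setMethod("featureNames", "LabeledDataset", function(x) colnames(x@exprs))

#' @describeIn LabeledDataset subset samples (i) and/or features (j)
#' @param i,j sample / feature indices
#' @param ... ignored
#' @param drop ignored (always `FALSE`)
#' @export
setMethod("[", "LabeledDataset", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@exprs))
  if (missing(j)) j <- seq_len(ncol(x@exprs))
  new("LabeledDataset",
      exprs = x@exprs[i, j, drop = FALSE],
      labels = droplevels(x@labels[i]))
})

setMethod("show", "LabeledDataset", function(object) {
  m <- object@exprs
  nmiss <- sum(is.na(m))
  cat(sprintf("LabeledDataset: %d samples x %d features\n", nrow(m), ncol(m)))
  tab <- table(object@labels)
  cat("classes:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
      "\n")
  if (nmiss > 0) {
    cat(sprintf("missing entries: %d (%.1f%%)\n", nmiss,
                100 * nmiss / length(m)))
  }
  invisible(NULL)
})
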