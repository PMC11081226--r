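# KNN missing-value imputation: neighbours are ranked by the taxicab (L1)
# distance averaged over co-observed coordinates of standardized data,
# missing standardized values are estimated as an inverse-distance-weighted
# average over the neighbour set, and the estimates are mapped back to the
# original scale by the affine inverse of the standardization.

#' Masked taxicab distance between two sample rows
#'
#' Mean absolute difference over coordinates observed in both rows:
#' d(x_i, x_j) = sum_n Z_in Z_jn |x_in - x_jn| / sum_n Z_in Z_jn,
#' where Z marks observed entries. When no coordinate is co-observed the
#' distance is undefined and `NA` is returned as the sentinel.
#'
#' @param xi,xj numeric rows of equal length (`NA` = missing).
#' @param zi,zj optional logical observation masks; default `!is.na(.)`.
#' @return The distance, or `NA` if the masks are disjoint.
#' @examples
#' maskedTaxicabDistance(c(1, 2, NA), c(1, 4, 9)) # 1
#' @export
maskedTaxicabDistance <- function(xi, xj, zi = !is.na(xi), zj = !is.na(xj)) {
  if (length(xi) != length(xj)) stop("rows differ in length", call. = FALSE)
  both <- zi & zj
  if (!any(both)) return(NA_real_)
  mean(abs(xi[both] - xj[both]))
}

#' Inverse-distance neighbour weights
#'
#' beta_j = (1 / (d_j + eps)) / sum_j' (1 / (d_j' + eps)), eps = 1e-8:
#' non-negative, summing to one, and larger for closer neighbours.
#'
#' @param distances non-negative finite neighbour distances.
#' @param eps stabiliser preventing division by zero.
#' @return Numeric weight vector summing to 1.
#' @examples
#' neighborWeights(c(1, 3)) # 0.75, 0.25
#' @export
neighborWeights <- function(distances, eps = 1e-8) {
  if (length(distances) == 0L) stop("no neighbour distances", call. = FALSE)
  if (any(!is.finite(distances)) || any(distances < 0)) {
    stop("distances must be finite and non-negative", call. = FALSE)
  }
  w <- 1 / (distances + eps)
  w / sum(w)
}

#' KNN imputation of missing entries
#'
#' Standardizes the data (per-feature mean/population-SD over observed
#' entries), then for every row with missing values: ranks all other rows by
#' the co-observation-masked taxicab distance, takes the k nearest rows with
#' a defined distance as the adjacent set, and estimates each missing
#' standardized value as the inverse-distance-weighted average over
#' neighbours that observe that feature (weights re-normalised over those).
#' If no neighbour in the adjacent set observes the feature, the nearest
#' eligible donor outside the set is used. Estimates are mapped back to the
#' original scale (x = x* sigma + mu); observed entries are returned
#' unchanged.
#'
#' @param ds a [LabeledDataset-class], possibly with missing entries.
#' @param k size of the adjacent neighbour set (default 7), capped at the
#'   number of rows with a defined distance.
#' @return A complete [LabeledDataset-class].
#' @export
imputeKNN <- function(ds, k = 7) {
  assertScalarNumber(k, "k", lower = 1)
  m <- featureMatrix(ds)
  if (!anyNA(m)) return(ds)
  nObsFeat <- colSums(!is.na(m))
  if (any(nObsFeat == 0L)) {
    stop("feature '", colnames(m)[which(nObsFeat == 0L)[1L]],
         "' has no observed values (no donors)", call. = FALSE)
  }
  std <- standardizeDataset(ds)
  z <- featureMatrix(std$dataset)
  obs <- !is.na(z)
  n <- nrow(z)
  zFill <- z; zFill[!obs] <- 0
  result <- z
  for (i in which(rowSums(obs) < ncol(z))) {
    ## masked L1 distances from row i to all rows, vectorised over rows
    co <- obs & rep(obs[i, ], each = n)          # co-observation masks
    diffs <- abs(zFill - rep(zFill[i, ], each = n)) * co
    nco <- rowSums(co)
    d <- ifelse(nco > 0, rowSums(diffs) / nco, NA_real_)
    d[i] <- NA_real_
    defined <- which(!is.na(d))
    if (length(defined) == 0L) {
      stop("sample '", rownames(m)[i],
           "' co-observes nothing with any other row", call. = FALSE)
    }
    ord <- defined[order(d[defined], defined)]
    theta <- ord[seq_len(min(k, length(ord)))]
    beta <- neighborWeights(d[theta])
    for (feat in which(!obs[i, ])) {
      donors <- theta[obs[theta, feat]]
      if (length(donors) > 0L) {
        b <- beta[match(donors, theta)]
        b <- b / sum(b)
        result[i, feat] <- sum(b * z[donors, feat])
      } else {
        outside <- ord[obs[ord, feat]]
        if (length(outside) == 0L) {
          stop("no donor with a defined distance observes feature '",
               colnames(m)[feat], "' for sample '", rownames(m)[i], "'",
               call. = FALSE)
        }
        result[i, feat] <- z[outside[1L], feat]
      }
    }
  }
  filled <- sweep(sweep(result, 2L, std$params$sigma, "*"),
                  2L, std$params$mu, "+")
  filled[!is.na(m)] <- m[!is.na(m)]   # observed entries bit-identical
  LabeledDataset(filled, sampleLabels(ds))
}
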