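# Chi-square relevance filtering: the goodness-of-fit statistic
# chi2 = sum_i (f_i - n p_i)^2 / (n p_i), its 2x2 independence
# specialisation chi2 = n (ad - bc)^2 / [(a+c)(b+d)(a+b)(c+d)], per-feature
# ranking against the class labels, and top-m / p-threshold selection.

#' General chi-square goodness-of-fit statistic
#'
#' chi2 = sum_i (f_i - n p_i)^2 / (n p_i) for observed counts f_i against
#' expected proportions p_i (n = total count). Zero iff the observed counts
#' match the expectation exactly; larger values mean stronger departure.
#'
#' @param observed non-negative counts.
#' @param expectedProbs expected proportions, same length, summing to 1;
#'   every expected count `n * p_i` must be positive.
#' @return The non-negative statistic.
#' @examples
#' chi2General(c(60, 40), c(0.5, 0.5)) # 4
#' @export
chi2General <- function(observed, expectedProbs) {
  if (length(observed) != length(expectedProbs)) {
    stop("observed and expectedProbs differ in length", call. = FALSE)
  }
  if (abs(sum(expectedProbs) - 1) > 1e-9) {
    stop("expected proportions must sum to 1", call. = FALSE)
  }
  n <- sum(observed)
  expected <- n * expectedProbs
  if (any(expected <= 0)) stop("zero expected cell", call. = FALSE)
  sum((observed - expected)^2 / expected)
}

#' 2x2 contingency chi-square test
#'
#' For the table with cells a, b (first row) and c, d (second row):
#' chi2 = n (ad - bc)^2 / \[(a+c)(b+d)(a+b)(c+d)\], n = a+b+c+d, with one
#' degree of freedom and the upper-tail p-value. No continuity correction by
#' default; `yates = TRUE` applies the Yates-corrected variant for
#' comparison.
#'
#' @param a,b,c,d non-negative cell counts; all four marginals must be
#'   positive.
#' @param yates apply the continuity correction?
#' @return A list with `statistic`, `df` (always 1) and `p.value`.
#' @examples
#' chi2TwoByTwo(105, 95, 120, 180)$statistic # about 7.576
#' @export
chi2TwoByTwo <- function(a, b, c, d, yates = FALSE) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("cell counts must be non-negative", call. = FALSE)
  n <- sum(cells)
  marg <- c(a + c, b + d, a + b, c + d)
  if (any(marg == 0)) stop("degenerate table: zero marginal", call. = FALSE)
  num <- if (yates) max(abs(a * d - b * c) - n / 2, 0)^2 else (a * d - b * c)^2
  stat <- n * num / prod(marg)
  list(statistic = stat, df = 1L,
       p.value = stats::pchisq(stat, df = 1L, lower.tail = FALSE))
}

## r x c independence statistic via the goodness-of-fit form with expected
## proportions from the marginals; df = (r-1)(c-1).
chi2Independence <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  if (any(expected <= 0)) return(NULL)
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

## Default discretizer: above/below the feature median ("Exist"/"Absent");
## bins > 2 uses quantile bins.
discretizeFeature <- function(x, bins = 2L) {
  if (bins == 2L) {
    factor(ifelse(x > stats::median(x), "Exist", "Absent"),
           levels = c("Exist", "Absent"))
  } else {
    qs <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1)))
    if (length(qs) < 2L) return(factor(rep("b1", length(x))))
    cut(x, breaks = qs, include.lowest = TRUE,
        labels = paste0("b", seq_len(length(qs) - 1L)))
  }
}

#' Rank features by chi-square association with the class labels
#'
#' Each feature is discretized (default: median split into "Exist"/"Absent"
#' levels), cross-tabulated against the classes, and scored with the
#' independence chi-square; features are sorted by decreasing statistic
#' (larger statistic = stronger association), ties keeping feature order.
#' Features constant after discretization get statistic 0 and p-value 1
#' with a warning.
#'
#' @param ds a complete [LabeledDataset-class].
#' @param bins number of discretization levels per feature (default 2 =
#'   median split; more uses quantile bins).
#' @param adjust p-value adjustment method passed to [stats::p.adjust()];
#'   default `"none"` (raw p-values), `"BH"` available.
#' @return A data frame ordered by decreasing statistic with columns
#'   `feature`, `index`, `statistic`, `df`, `p.value`.
#' @export
rankFeaturesChi2 <- function(ds, bins = 2L, adjust = "none") {
  m <- featureMatrix(ds)
  if (anyNA(m)) stop("missing entries are not permitted; impute first",
                     call. = FALSE)
  labs <- sampleLabels(ds)
  if (nlevels(labs) < 2L) stop("need at least 2 classes", call. = FALSE)
  D <- ncol(m)
  stat <- numeric(D); df <- integer(D); pv <- numeric(D)
  constant <- character(0)
  for (j in seq_len(D)) {
    lev <- discretizeFeature(m[, j], bins)
    tab <- table(lev, labs)
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    if (nrow(tab) < 2L) {
      stat[j] <- 0; df[j] <- 1L; pv[j] <- 1
      constant <- c(constant, colnames(m)[j])
      next
    }
    res <- chi2Independence(tab)
    stat[j] <- res$statistic; df[j] <- res$df; pv[j] <- res$p.value
  }
  if (length(constant)) {
    warning(length(constant), " feature(s) constant after discretization ",
            "assigned statistic 0", call. = FALSE)
  }
  pv <- stats::p.adjust(pv, method = adjust)
  ord <- order(-stat, seq_len(D))
  data.frame(feature = colnames(m)[ord], index = ord, statistic = stat[ord],
             df = df[ord], p.value = pv[ord], row.names = NULL)
}

#' Select features from a chi-square ranking
#'
#' Either the top `topM` features of the ranking, or all features with
#' p-value below `alpha` (exactly one of the two must be given).
#'
#' @param ranked a ranking from [rankFeaturesChi2()].
#' @param topM number of top-ranked features to keep.
#' @param alpha significance level; keeps features whose p-value does not
#'   exceed `alpha` (so `alpha = 1` keeps every feature, including those
#'   whose discrete median-split p-value is exactly 1).
#' @return Integer vector of selected feature indices (columns of the
#'   original dataset), in ranking order.
#' @export
chi2Select <- function(ranked, topM = NULL, alpha = NULL) {
  if (is.null(topM) == is.null(alpha)) {
    stop("give exactly one of topM or alpha", call. = FALSE)
  }
  if (!is.null(topM)) {
    if (topM > nrow(ranked)) {
      stop("topM (", topM, ") exceeds the number of features (",
           nrow(ranked), ")", call. = FALSE)
    }
    ranked$index[seq_len(topM)]
  } else {
    ranked$index[ranked$p.value <= alpha]
  }
}
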