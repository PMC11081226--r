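# Seeded generators of microarray-like labelled matrices with planted
# structure: informative features (class-conditional Gaussians with
# separated means), redundant features (noisy copies of informative ones),
# pure-noise features, optionally imbalanced classes and MCAR missingness.
# Every generator returns the ground truth so planted-recovery tests can
# score selectors against it.

#' Generate a labelled dataset with planted structure
#'
#' Informative features are class-conditional Gaussians whose class centers
#' are spaced `effectSize` standard deviations apart (center order randomly
#' permuted per feature); redundant features are noisy copies of randomly
#' chosen informative features (correlation about 0.97 with the defaults);
#' all remaining features are class-independent Gaussian noise. Labels are
#' drawn from `classWeights`, re-drawn until every class has at least two
#' samples so the result is always splittable.
#'
#' @param nSamples,nFeatures dataset shape.
#' @param nInformative,nRedundant planted feature counts
#'   (`nInformative + nRedundant <= nFeatures`).
#' @param nClasses number of classes (>= 2).
#' @param classWeights class probabilities summing to 1; default uniform.
#' @param effectSize separation between adjacent class centers, in noise
#'   SDs (default 2).
#' @param noiseSd within-class standard deviation (default 1).
#' @param redundantNoiseSd SD of the noise added to redundant copies.
#' @param missingRate MCAR missingness rate in \[0, 1) (default 0).
#' @param seed integer RNG seed.
#' @return A list with `dataset` (a [LabeledDataset-class]) and `truth`
#'   (list with `informative` indices and a `redundantMap` data frame
#'   mapping each redundant feature to its source).
#' @examples
#' gen <- makeSyntheticDataset(nSamples = 30, nFeatures = 50,
#'                             nInformative = 5, seed = 1)
#' gen$truth$informative
#' @export
makeSyntheticDataset <- function(nSamples = 70, nFeatures = 1800,
                                 nInformative = 10, nRedundant = 10,
                                 nClasses = 3, classWeights = NULL,
                                 effectSize = 2, noiseSd = 1,
                                 redundantNoiseSd = 0.3, missingRate = 0,
                                 seed = 1) {
  stopifnot(nInformative + nRedundant <= nFeatures, nClasses >= 2,
            nSamples >= 2 * nClasses, missingRate >= 0, missingRate < 1)
  classWeights <- classWeights %||% rep(1 / nClasses, nClasses)
  stopifnot(length(classWeights) == nClasses,
            abs(sum(classWeights) - 1) < 1e-9)
  out <- withSeed(seed, {
    classes <- paste0("c", seq_len(nClasses))
    for (attempt in 1:100) {
      labels <- sample(classes, nSamples, replace = TRUE, prob = classWeights)
      if (all(table(factor(labels, levels = classes)) >= 2L)) break
    }
    if (any(table(factor(labels, levels = classes)) < 2L)) {
      stop("could not draw >= 2 samples per class; adjust classWeights",
           call. = FALSE)
    }
    classIdx <- match(labels, classes)
    m <- matrix(stats::rnorm(nSamples * nFeatures, 0, noiseSd),
                nSamples, nFeatures)
    informative <- seq_len(nInformative)
    centers0 <- effectSize * noiseSd * (seq_len(nClasses) -
                                          (nClasses + 1) / 2)
    for (f in informative) {
      centers <- centers0[sample(nClasses)]
      m[, f] <- m[, f] + centers[classIdx]
    }
    redundant <- if (nRedundant > 0) nInformative + seq_len(nRedundant)
                 else integer(0)
    src <- if (nRedundant > 0) {
      sample(informative, nRedundant, replace = TRUE)
    } else integer(0)
    for (r in seq_along(redundant)) {
      m[, redundant[r]] <- m[, src[r]] +
        stats::rnorm(nSamples, 0, redundantNoiseSd)
    }
    ds <- LabeledDataset(m, labels)
    truth <- list(informative = informative,
                  redundantMap = data.frame(redundant = redundant,
                                            source = src))
    list(dataset = ds, truth = truth)
  })
  if (missingRate > 0) {
    inj <- injectMissingness(out$dataset, missingRate,
                             seed = deriveSeed(seed, 77L))
    out$complete <- out$dataset
    out$dataset <- inj$dataset
    out$mask <- inj$mask
  }
  out
}

#' Shape presets for the synthetic generator
#'
#' Named presets matching the shapes of common public expression datasets
#' (features x samples x classes): `colon-like` 1800 x 70 x 3, `srbct-like`
#' 2200 x 80 x 5, `lymphoma-like` 7100 x 60 x 4, `cns-like` 7100 x 50 x 3,
#' `ovarian-like` 15100 x 260 x 4. Presets use imbalanced class weights
#' (proportional to K..1) and plant 20 informative plus 40 redundant
#' features, emulating the high-dimensional, redundant, few-sample,
#' imbalanced character of such data — matched shapes, not matched content.
#'
#' @param name preset name.
#' @param seed integer RNG seed.
#' @param ... overrides passed on to [makeSyntheticDataset()].
#' @return As [makeSyntheticDataset()].
#' @export
syntheticPreset <- function(name = c("colon-like", "srbct-like",
                                     "lymphoma-like", "cns-like",
                                     "ovarian-like"),
                            seed = 1, ...) {
  name <- match.arg(name)
  shape <- switch(name,
    "colon-like"    = c(1800, 70, 3),
    "srbct-like"    = c(2200, 80, 5),
    "lymphoma-like" = c(7100, 60, 4),
    "cns-like"      = c(7100, 50, 3),
    "ovarian-like"  = c(15100, 260, 4))
  K <- shape[3]
  w <- rev(seq_len(K)); w <- w / sum(w)
  args <- list(nSamples = shape[2], nFeatures = shape[1],
               nInformative = 20, nRedundant = 40, nClasses = K,
               classWeights = w, seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(makeSyntheticDataset, args)
}

#' Generate a low-rank dataset for imputation benchmarks
#'
#' Samples a rank-`rank` matrix U V' plus Gaussian noise; the latent
#' structure lets nearest-neighbour imputation beat column-mean filling.
#' Labels (two classes, from the sign of the first latent factor) are
#' attached so the result is a valid [LabeledDataset-class]; imputation
#' ignores them.
#'
#' @param nSamples,nFeatures matrix shape.
#' @param rank latent rank (default 2).
#' @param noiseSd additive noise SD.
#' @param seed integer RNG seed.
#' @return A list with `dataset` and `truth` (the noise-free complete
#'   matrix plus the noisy complete matrix `observedComplete`).
#' @export
makeLowRankDataset <- function(nSamples = 200, nFeatures = 50, rank = 2,
                               noiseSd = 0.1, seed = 1) {
  withSeed(seed, {
    U <- matrix(stats::rnorm(nSamples * rank), nSamples, rank)
    V <- matrix(stats::rnorm(nFeatures * rank), nFeatures, rank)
    signal <- U %*% t(V)
    m <- signal + matrix(stats::rnorm(nSamples * nFeatures, 0, noiseSd),
                         nSamples, nFeatures)
    labels <- ifelse(U[, 1] > 0, "A", "B")
    list(dataset = LabeledDataset(m, labels),
         truth = list(signal = signal, observedComplete = m))
  })
}

#' Generate interaction-structured (XOR-like) data
#'
#' The first two features take values near -1 or +1 (cluster centers plus
#' Gaussian jitter) and the class is the sign of their product plus small
#' noise — the classic XOR structure: neither feature separates the classes
#' marginally, only their interaction does. The remaining features are pure
#' standard-Gaussian noise, so a plain distance-based classifier on the raw
#' columns is degraded by the nuisance dimensions while a multiplicative
#' constructed feature restores the signal.
#'
#' @param nSamples number of samples.
#' @param clusterSd jitter SD around the -1/+1 cluster centers.
#' @param noiseSd SD of the noise added to the product before taking the
#'   sign (default 0.1; occasional label flips).
#' @param nNoise number of pure-noise features (default 14, which leaves a
#'   plain KNN on the raw columns at roughly 0.7 accuracy so that both
#'   degradation and restoration are measurable).
#' @param seed integer RNG seed.
#' @return A list with `dataset` and `truth` (`interacting` = c(1, 2)).
#' @export
makeXorDataset <- function(nSamples = 150, clusterSd = 0.35, noiseSd = 0.1,
                           nNoise = 14, seed = 1) {
  withSeed(seed, {
    f1 <- sample(c(-1, 1), nSamples, replace = TRUE) +
      stats::rnorm(nSamples, 0, clusterSd)
    f2 <- sample(c(-1, 1), nSamples, replace = TRUE) +
      stats::rnorm(nSamples, 0, clusterSd)
    score <- f1 * f2 + stats::rnorm(nSamples, 0, noiseSd)
    labels <- ifelse(score >= 0, "A", "B")
    m <- cbind(f1, f2)
    if (nNoise > 0) {
      m <- cbind(m, matrix(stats::rnorm(nSamples * nNoise),
                           nSamples, nNoise))
    }
    colnames(m) <- paste0("f", seq_len(ncol(m)))
    list(dataset = LabeledDataset(m, labels),
         truth = list(interacting = c(1L, 2L)))
  })
}

#' Inject missing-completely-at-random entries
#'
#' Masks each entry independently with probability `rate`, re-drawing the
#' mask (up to 100 times) until every row and every feature keeps at least
#' one observed entry.
#'
#' @param ds a [LabeledDataset-class].
#' @param rate missingness probability in \[0, 1).
#' @param seed integer RNG seed.
#' @return A list with `dataset` (entries replaced by `NA`) and `mask`
#'   (logical matrix, `TRUE` = observed).
#' @export
injectMissingness <- function(ds, rate, seed = 1) {
  assertScalarNumber(rate, "rate", lower = 0)
  if (rate >= 1) stop("rate must be < 1", call. = FALSE)
  m <- featureMatrix(ds)
  if (rate == 0) {
    return(list(dataset = ds,
                mask = matrix(TRUE, nrow(m), ncol(m), dimnames = dimnames(m))))
  }
  withSeed(seed, {
    for (attempt in 1:100) {
      mask <- matrix(stats::runif(length(m)) >= rate, nrow(m), ncol(m))
      if (all(rowSums(mask) >= 1L) && all(colSums(mask) >= 1L)) {
        dimnames(mask) <- dimnames(m)
        out <- m
        out[!mask] <- NA_real_
        return(list(dataset = LabeledDataset(out, sampleLabels(ds)),
                    mask = mask))
      }
    }
    stop("rate ", rate, " makes the every-row/every-feature observation ",
         "guarantee infeasible", call. = FALSE)
  })
}
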