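# Shared fixtures and independently-written reference implementations used
# as oracles against the package's own code paths.

tinyDataset <- function(m, labels) {
  LabeledDataset(m, labels)
}

randomDataset <- function(n, d, nClasses = 2, seed = 1) {
  set.seed(seed)
  LabeledDataset(matrix(rnorm(n * d), n, d),
                 sample(paste0("c", seq_len(nClasses)), n, replace = TRUE))
}

## Reference KNN: an exhaustive, loop-based implementation written
## independently of the package's vectorised path. Replicates the package's
## contract: distance ties keep the lower training index; vote ties go to
## the tied class with the closest nearest member, then the
## lexicographically smallest label.
referenceKnn <- function(trainX, trainLabels, query, k, spec) {
  n <- nrow(trainX)
  w <- if (is.null(spec$weights)) rep(1, ncol(trainX)) else spec$weights
  d <- numeric(n)
  for (i in seq_len(n)) {
    diffs <- abs(w * trainX[i, ] - w * query)
    d[i] <- if (spec$kind == "chebyshev") max(diffs)
            else sum(diffs^spec$p)^(1 / spec$p)
  }
  ord <- order(d, seq_len(n))
  nb <- ord[seq_len(k)]
  labs <- as.character(trainLabels)[nb]
  counts <- sort(table(labs), decreasing = TRUE)
  winners <- names(counts)[counts == counts[1]]
  if (length(winners) == 1L) return(winners)
  nearest <- sapply(winners, function(cl) min(d[nb][labs == cl]))
  winners <- winners[nearest == min(nearest)]
  sort(winners)[1]
}

## Plain single-population GA baseline (crossover with a random mate,
## same operators and elitism as the MGA defaults) for the convergence
## comparison.
plainGaMinimize <- function(problem, popSize, generations, crossoverRate,
                            mutationRate, seed) {
  set.seed(seed)
  d <- problem$dims
  genes <- matrix(runif(popSize * d, rep(problem$lower, each = popSize),
                        rep(problem$upper, each = popSize)), popSize, d)
  fit <- apply(genes, 1, problem$objective)
  bestF <- min(fit)
  for (g in seq_len(generations)) {
    eliteIdx <- which.min(fit)
    newGenes <- genes; newFit <- fit
    for (i in seq_len(popSize)) {
      if (i == eliteIdx) next
      child <- genes[i, ]
      if (runif(1) < crossoverRate) {
        mate <- genes[sample.int(popSize, 1), ]
        alpha <- runif(1)
        child <- alpha * child + (1 - alpha) * mate
      }
      hit <- runif(d) < mutationRate
      if (any(hit)) {
        sd <- 0.1 * (problem$upper - problem$lower)
        child[hit] <- child[hit] + rnorm(sum(hit), 0, sd[hit])
        child <- pmin(pmax(child, problem$lower), problem$upper)
      }
      newGenes[i, ] <- child
      newFit[i] <- problem$objective(child)
    }
    genes <- newGenes; fit <- newFit
    bestF <- min(bestF, min(fit))
  }
  bestF
}
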