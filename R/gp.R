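# Genetic-programming feature construction: new features are arithmetic
# expression trees over a selected feature subset, evolved by tournament
# selection, subtree crossover and subtree mutation, and scored by the KNN
# accuracy obtained when the tree's output is appended to the data as one
# extra standardized column. Division is protected so tree evaluation is
# total on every real input.

#' GP configuration
#'
#' Defaults follow the package's standard operating point for
#' expression-style data: population 600, 55 generations, crossover rate
#' 1.0, reproduction rate 0.2, mutation rate 0.2 (applied as a per-offspring
#' categorical choice with probabilities proportional to these three
#' rates), tournament ("championship") selection of size 7, maximum tree
#' depth 19 and elitism of 1.
#'
#' @param populationSize number of trees per generation.
#' @param generations evolution steps.
#' @param crossoverRate,reproductionRate,mutationRate non-negative operator
#'   weights; offspring pick an operator with probability proportional to
#'   these.
#' @param tournamentSize tournament size (>= 2, <= population).
#' @param maxDepth hard cap on tree depth (a lone leaf has depth 1);
#'   offspring violating it are rejected and the parent retained.
#' @param constProb probability that a leaf is an ephemeral random constant
#'   (uniform in \[-1, 1\]) rather than a feature.
#' @param runs number of independent repetitions for [constructMulti()].
#' @param seed integer RNG seed.
#' @return An object of class `GPConfig`.
#' @export
gpConfig <- function(populationSize = 600L, generations = 55L,
                     crossoverRate = 1.0, reproductionRate = 0.2,
                     mutationRate = 0.2, tournamentSize = 7L,
                     maxDepth = 19L, constProb = 0.1, runs = 1L,
                     seed = NULL) {
  stopifnot(populationSize >= tournamentSize, tournamentSize >= 2,
            maxDepth >= 1, runs >= 1,
            crossoverRate >= 0, reproductionRate >= 0, mutationRate >= 0,
            crossoverRate + reproductionRate + mutationRate > 0)
  structure(list(populationSize = as.integer(populationSize),
                 generations = as.integer(generations),
                 crossoverRate = crossoverRate,
                 reproductionRate = reproductionRate,
                 mutationRate = mutationRate,
                 tournamentSize = as.integer(tournamentSize),
                 maxDepth = as.integer(maxDepth), constProb = constProb,
                 runs = as.integer(runs), seed = seed),
            class = "GPConfig")
}

## -- tree primitives ---------------------------------------------------

gpOperators <- c("+", "-", "*", "/")

featLeaf <- function(index) list(type = "feat", index = as.integer(index))
constLeaf <- function(value) list(type = "const", value = value)
opNode <- function(op, l, r) list(type = "op", op = op, l = l, r = r)

#' Depth of an expression tree
#'
#' A lone leaf has depth 1; an internal node is 1 + the deeper child.
#'
#' @param tree an expression tree.
#' @return Integer depth.
#' @export
treeDepth <- function(tree) {
  if (tree$type != "op") return(1L)
  1L + max(treeDepth(tree$l), treeDepth(tree$r))
}

#' Serialize a tree to a prefix-notation string
#'
#' Features print as `x<i>`, constants as numbers, operators in prefix
#' form, e.g. `"(+ x3 (* x1 0.52))"`.
#'
#' @param tree an expression tree.
#' @return A character scalar.
#' @export
treeToString <- function(tree) {
  switch(tree$type,
    feat = paste0("x", tree$index),
    const = format(tree$value, digits = 6),
    op = paste0("(", tree$op, " ", treeToString(tree$l), " ",
                treeToString(tree$r), ")"))
}

#' Evaluate an expression tree on samples
#'
#' Recursive arithmetic over feature columns; division is protected
#' (`x / y` = 1 when `|y| < 1e-9`) and any non-finite intermediate result
#' (arithmetic overflow) is replaced by 1, so evaluation is total and
#' finite on every real input.
#'
#' @param tree an expression tree whose feature leaves index columns of `x`.
#' @param x a numeric sample vector (length D) or a samples x D matrix.
#' @return A numeric vector with one value per sample.
#' @examples
#' tree <- list(type = "op", op = "/",
#'              l = list(type = "feat", index = 1L),
#'              r = list(type = "feat", index = 2L))
#' evaluateTree(tree, c(5, 0)) # 1 (protected division)
#' @export
evaluateTree <- function(tree, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  n <- nrow(x); D <- ncol(x)
  rec <- function(node) {
    switch(node$type,
      feat = {
        if (node$index < 1L || node$index > D) {
          stop("leaf feature index ", node$index, " out of range 1..", D,
               call. = FALSE)
        }
        x[, node$index]
      },
      const = rep(node$value, n),
      op = {
        a <- rec(node$l); b <- rec(node$r)
        r <- switch(node$op,
          "+" = a + b, "-" = a - b, "*" = a * b,
          "/" = ifelse(abs(b) < 1e-9, 1, a / b))
        r[!is.finite(r)] <- 1
        r
      })
  }
  rec(tree)
}

## Grow a random tree: "full" puts operators at every level above `depth`,
## "grow" may stop early at any node.
growTree <- function(terminals, depth, method, constProb) {
  makeLeaf <- function() {
    if (stats::runif(1) < constProb) constLeaf(stats::runif(1, -1, 1))
    else featLeaf(terminals[sample.int(length(terminals), 1L)])
  }
  rec <- function(d) {
    if (d <= 1L || (method == "grow" && d < depth && stats::runif(1) < 0.3)) {
      return(makeLeaf())
    }
    opNode(sample(gpOperators, 1L), rec(d - 1L), rec(d - 1L))
  }
  rec(depth)
}

#' Generate a random expression tree
#'
#' Ramped half-and-half initialisation: target depth uniform between 2 and
#' `min(6, maxDepth)`, alternating between "full" and "grow" construction.
#' Leaves are features from `terminals` or, with probability `constProb`,
#' ephemeral constants uniform in \[-1, 1\].
#'
#' @param cfg a [gpConfig()].
#' @param terminals non-empty integer vector of usable feature indices.
#' @return An expression tree respecting `cfg$maxDepth`.
#' @export
randomTree <- function(cfg, terminals) {
  if (length(terminals) == 0L) stop("terminals is empty", call. = FALSE)
  maxInit <- min(6L, cfg$maxDepth)
  depth <- if (maxInit <= 2L) maxInit else sample(2:maxInit, 1L)
  method <- sample(c("full", "grow"), 1L)
  growTree(terminals, depth, method, cfg$constProb)
}

## -- subtree surgery ---------------------------------------------------

## Paths to all nodes as integer vectors (1 = left child, 2 = right child).
allPaths <- function(tree) {
  if (tree$type != "op") return(list(integer(0)))
  c(list(integer(0)),
    lapply(allPaths(tree$l), function(p) c(1L, p)),
    lapply(allPaths(tree$r), function(p) c(2L, p)))
}

getSubtree <- function(tree, path) {
  for (step in path) tree <- if (step == 1L) tree$l else tree$r
  tree
}

setSubtree <- function(tree, path, sub) {
  if (length(path) == 0L) return(sub)
  if (path[1L] == 1L) {
    tree$l <- setSubtree(tree$l, path[-1L], sub)
  } else {
    tree$r <- setSubtree(tree$r, path[-1L], sub)
  }
  tree
}

subtreeCrossover <- function(a, b, maxDepth) {
  pa <- sample(allPaths(a), 1L)[[1L]]
  pb <- sample(allPaths(b), 1L)[[1L]]
  child <- setSubtree(a, pa, getSubtree(b, pb))
  if (treeDepth(child) > maxDepth) a else child
}

subtreeMutation <- function(a, terminals, cfg) {
  pa <- sample(allPaths(a), 1L)[[1L]]
  sub <- growTree(terminals, sample(2:4, 1L), "grow", cfg$constProb)
  child <- setSubtree(a, pa, sub)
  if (treeDepth(child) > cfg$maxDepth) a else child
}

tournamentPick <- function(fitness, size) {
  cand <- sample.int(length(fitness), size, replace = TRUE)
  cand[which.max(fitness[cand])]
}

## Fitness of a tree: KNN validation accuracy (Euclidean) with the tree
## output appended as one extra column, standardized by training-set
## statistics. The squared distances over the original columns are
## precomputed once per run (`baseD2`, train x val); each tree only adds
## its own column's contribution.
treeFitness <- function(tree, trainX, valX, baseD2, trainCodes, valCodes,
                        nLevels, k) {
  zTr <- evaluateTree(tree, trainX)
  mu <- mean(zTr)
  sd <- max(sqrt(mean((zTr - mu)^2)), 1e-8)
  zTr <- (zTr - mu) / sd
  zVa <- (evaluateTree(tree, valX) - mu) / sd
  D2 <- baseD2 + outer(zTr, zVa, "-")^2
  n <- nrow(D2)
  correct <- 0L
  for (j in seq_len(ncol(D2))) {
    ord <- order(D2[, j], seq_len(n))[seq_len(k)]
    votes <- tabulate(trainCodes[ord], nLevels)
    top <- which(votes == max(votes))
    if (length(top) > 1L) {
      nearest <- vapply(top, function(cl) {
        min(D2[ord, j][trainCodes[ord] == cl])
      }, numeric(1))
      top <- top[nearest == min(nearest)][1L]
    }
    if (top[1L] == valCodes[j]) correct <- correct + 1L
  }
  correct / ncol(D2)
}

#' Construct one feature by genetic programming
#'
#' Evolves a population of arithmetic expression trees over the terminal
#' feature set. Offspring are produced by a categorical operator choice
#' (crossover / reproduction / mutation with probabilities proportional to
#' the configured rates), parents picked by tournament selection; the best
#' tree is copied unchanged each generation, so best-so-far fitness is
#' non-decreasing. Fitness is the KNN validation accuracy with the tree
#' output appended as one standardized extra column.
#'
#' @param train,validation complete [LabeledDataset-class] objects over the
#'   same features.
#' @param terminals integer vector of feature indices the trees may use
#'   (default: all features).
#' @param cfg a [gpConfig()]; `cfg$seed` makes the run deterministic.
#' @param k KNN neighbourhood size for the fitness classifier.
#' @return A list with `tree` (the best tree), `fitness`, the serialized
#'   `expression` string and the per-generation best-fitness `history`.
#' @export
constructFeature <- function(train, validation,
                             terminals = seq_len(nFeatures(train)),
                             cfg = gpConfig(), k = 7) {
  stopifnot(all(terminals >= 1L), all(terminals <= nFeatures(train)))
  trX <- featureMatrix(train); vaX <- featureMatrix(validation)
  if (anyNA(trX) || anyNA(vaX)) {
    stop("missing entries are not permitted; impute first", call. = FALSE)
  }
  labLevels <- union(levels(sampleLabels(train)),
                     levels(sampleLabels(validation)))
  trCodes <- match(as.character(sampleLabels(train)), labLevels)
  vaCodes <- match(as.character(sampleLabels(validation)), labLevels)
  k <- min(k, nrow(trX))
  baseD2 <- distanceMatrix(trX, vaX, distanceSpec("minkowski", p = 2))^2
  probs <- c(cfg$crossoverRate, cfg$reproductionRate, cfg$mutationRate)
  probs <- probs / sum(probs)
  withSeed(cfg$seed, {
    pop <- replicate(cfg$populationSize, randomTree(cfg, terminals),
                     simplify = FALSE)
    fit <- vapply(pop, treeFitness, numeric(1), trX, vaX, baseD2,
                  trCodes, vaCodes, length(labLevels), k)
    bestIdx <- which.max(fit)
    best <- list(tree = pop[[bestIdx]], fitness = fit[bestIdx])
    history <- best$fitness
    for (g in seq_len(cfg$generations)) {
      newPop <- vector("list", cfg$populationSize)
      newFit <- numeric(cfg$populationSize)
      newPop[[1L]] <- best$tree; newFit[1L] <- best$fitness  # elitism
      for (s in 2:cfg$populationSize) {
        op <- sample.int(3L, 1L, prob = probs)
        child <- if (op == 1L) {
          a <- pop[[tournamentPick(fit, cfg$tournamentSize)]]
          b <- pop[[tournamentPick(fit, cfg$tournamentSize)]]
          subtreeCrossover(a, b, cfg$maxDepth)
        } else if (op == 2L) {
          pop[[tournamentPick(fit, cfg$tournamentSize)]]
        } else {
          subtreeMutation(pop[[tournamentPick(fit, cfg$tournamentSize)]],
                          terminals, cfg)
        }
        newPop[[s]] <- child
        newFit[s] <- treeFitness(child, trX, vaX, baseD2, trCodes, vaCodes,
                                 length(labLevels), k)
      }
      pop <- newPop; fit <- newFit
      bestIdx <- which.max(fit)
      if (fit[bestIdx] > best$fitness) {
        best <- list(tree = pop[[bestIdx]], fitness = fit[bestIdx])
      }
      history <- c(history, best$fitness)
    }
    list(tree = best$tree, fitness = best$fitness,
         expression = treeToString(best$tree), history = history)
  })
}

#' Construct a set of features by repeated GP runs
#'
#' Runs [constructFeature()] `cfg$runs` times with derived seeds and
#' returns the winning trees, duplicates (by serialized expression)
#' removed.
#'
#' @inheritParams constructFeature
#' @return A list of class `ConstructedFeatureSet`: each element has
#'   `tree`, `fitness` and `expression`.
#' @export
constructMulti <- function(train, validation,
                           terminals = seq_len(nFeatures(train)),
                           cfg = gpConfig(), k = 7) {
  seeds <- vapply(seq_len(cfg$runs), function(r) {
    deriveSeed(cfg$seed %||% 0L, r)
  }, integer(1))
  winners <- lapply(seq_len(cfg$runs), function(r) {
    cfgR <- cfg; cfgR$seed <- seeds[r]
    res <- constructFeature(train, validation, terminals, cfgR, k)
    res[c("tree", "fitness", "expression")]
  })
  exprs <- vapply(winners, `[[`, character(1), "expression")
  structure(winners[!duplicated(exprs)], class = "ConstructedFeatureSet")
}

## Append the trees' outputs to a dataset as standardized extra columns;
## `stats` carries training-set mean/sd so test data never leak their own.
augmentDataset <- function(ds, trees, stats = NULL) {
  if (inherits(trees, "ConstructedFeatureSet") ||
      (length(trees) > 0 && !is.null(trees[[1L]]$tree))) {
    trees <- lapply(trees, `[[`, "tree")
  }
  m <- featureMatrix(ds)
  if (length(trees) == 0L) return(list(dataset = ds, stats = stats))
  fitStats <- is.null(stats)
  if (fitStats) stats <- vector("list", length(trees))
  cols <- matrix(0, nrow(m), length(trees))
  for (t in seq_along(trees)) {
    z <- evaluateTree(trees[[t]], m)
    if (fitStats) {
      mu <- mean(z); sd <- max(sqrt(mean((z - mu)^2)), 1e-8)
      stats[[t]] <- c(mu = mu, sd = sd)
    }
    cols[, t] <- (z - stats[[t]][["mu"]]) / stats[[t]][["sd"]]
  }
  colnames(cols) <- paste0("constructed", seq_along(trees))
  aug <- cbind(m, cols)
  list(dataset = LabeledDataset(aug, sampleLabels(ds)), stats = stats)
}

#' Test-set validation of constructed features
#'
#' Applies the same trees to the training and test sets (constructed
#' columns standardized with training-set statistics only, so nothing leaks
#' from the test set) and reports the KNN test accuracy before and after
#' augmentation.
#'
#' @param train,test complete [LabeledDataset-class] objects over the same
#'   features.
#' @param trees a `ConstructedFeatureSet`, a list of trees, or an empty
#'   list (then both accuracies coincide).
#' @param k KNN neighbourhood size.
#' @return A list with `accWithout` and `accWith`.
#' @export
validateConstructed <- function(train, test, trees, k = 7) {
  spec <- distanceSpec("minkowski", p = 2)
  base <- evaluateKnn(train, test, k = k, spec = spec)$accuracy
  if (length(trees) == 0L) {
    return(list(accWithout = base, accWith = base))
  }
  augTr <- augmentDataset(train, trees)
  augTe <- augmentDataset(test, trees, stats = augTr$stats)
  withAcc <- evaluateKnn(augTr$dataset, augTe$dataset, k = k,
                         spec = spec)$accuracy
  list(accWithout = base, accWith = withAcc)
}
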