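leaf <- function(i) list(type = "feat", index = as.integer(i))
konst <- function(v) list(type = "const", value = v)
node <- function(op, l, r) list(type = "op", op = op, l = l, r = r)

test_that("tree evaluation matches hand arithmetic and protects division", {
  expect_equal(evaluateTree(leaf(1), c(7, 2)), 7)
  t2 <- node("*", node("+", leaf(1), leaf(2)), leaf(1))
  expect_equal(evaluateTree(t2, c(2, 3)), 10)
  expect_equal(evaluateTree(node("/", leaf(1), leaf(2)), c(5, 0)), 1)
  expect_equal(evaluateTree(node("/", leaf(1), leaf(2)), c(5, 2)), 2.5)
  # vectorised over a sample matrix
  X <- rbind(c(1, 2), c(3, 4))
  expect_equal(evaluateTree(node("-", leaf(2), leaf(1)), X), c(1, 1))
  expect_error(evaluateTree(leaf(5), c(1, 2)), "out of range")
})

test_that("random trees respect the depth bound and terminal set", {
  cfg <- gpConfig(populationSize = 10, generations = 1, maxDepth = 5)
  set.seed(91)
  depths <- replicate(1000, treeDepth(randomTree(cfg, 1:4)))
  expect_true(all(depths <= 5))
  expect_true(all(depths >= 1))

  collectLeaves <- function(tr) {
    if (tr$type == "feat") return(tr$index)
    if (tr$type == "const") return(integer(0))
    c(collectLeaves(tr$l), collectLeaves(tr$r))
  }
  set.seed(92)
  for (i in 1:50) {
    idx <- collectLeaves(randomTree(cfg, terminals = 3L))
    expect_true(all(idx == 3L))
  }
  set.seed(93); a <- randomTree(cfg, 1:4)
  set.seed(93); b <- randomTree(cfg, 1:4)
  expect_identical(a, b)
  expect_error(randomTree(cfg, integer(0)), "empty")
})

test_that("tree evaluation is total and finite on random programs", {
  cfg <- gpConfig(populationSize = 10, generations = 0)
  set.seed(94)
  for (i in 1:10000) {
    tr <- randomTree(cfg, 1:5)
    v <- evaluateTree(tr, matrix(runif(10, -100, 100), 2, 5))
    expect_true(all(is.finite(v)))
  }
})

test_that("offspring never exceed the depth cap", {
  cfg <- gpConfig(populationSize = 10, generations = 1, maxDepth = 6)
  set.seed(95)
  for (i in 1:200) {
    a <- randomTree(cfg, 1:3)
    b <- randomTree(cfg, 1:3)
    expect_lte(treeDepth(MGAselect:::subtreeCrossover(a, b, 6)), 6)
    expect_lte(treeDepth(MGAselect:::subtreeMutation(a, 1:3, cfg)), 6)
  }
})

test_that("tournament selection prefers fitter individuals monotonically", {
  fit <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  set.seed(96)
  picks <- tabulate(replicate(1e5, MGAselect:::tournamentPick(fit, 3)), 5)
  expect_false(is.unsorted(picks))   # higher rank, picked more often
  expect_gt(picks[5], picks[1])
})

test_that("prefix serialization reflects the tree structure", {
  tr <- node("+", leaf(3), node("*", leaf(1), konst(0.5)))
  expect_equal(treeToString(tr), "(+ x3 (* x1 0.5))")
})

test_that("construction is elitist, seeded, and handles degenerate targets", {
  gen <- makeXorDataset(nSamples = 60, nNoise = 2, seed = 97)
  sp <- stratifiedSplit(gen$dataset, 0.7, seed = 1)
  cfg <- gpConfig(populationSize = 30, generations = 5, seed = 7)
  res <- constructFeature(sp$train, sp$test, cfg = cfg)
  expect_false(is.unsorted(res$history))
  expect_length(res$history, 6L)
  expect_lte(treeDepth(res$tree), cfg$maxDepth)
  res2 <- constructFeature(sp$train, sp$test, cfg = cfg)
  expect_identical(res2$expression, res$expression)

  cfg0 <- gpConfig(populationSize = 20, generations = 0, seed = 8)
  res0 <- constructFeature(sp$train, sp$test, cfg = cfg0)
  expect_length(res0$history, 1L)

  # constant labels: any tree classifies perfectly
  const <- LabeledDataset(matrix(rnorm(40), 20, 2), rep("A", 20))
  resC <- constructFeature(const, const, cfg = cfg0)
  expect_equal(resC$fitness, 1.0)
})

test_that("multi-construction dedupes winners and augments conservatively", {
  gen <- makeXorDataset(nSamples = 60, nNoise = 2, seed = 98)
  sp <- stratifiedSplit(gen$dataset, 0.7, seed = 2)
  cfg1 <- gpConfig(populationSize = 20, generations = 2, runs = 1, seed = 9)
  set1 <- constructMulti(sp$train, sp$test, cfg = cfg1)
  expect_length(set1, 1L)

  cfg5 <- gpConfig(populationSize = 20, generations = 2, runs = 5, seed = 9)
  set5 <- constructMulti(sp$train, sp$test, cfg = cfg5)
  expect_lte(length(set5), 5L)
  for (w in set5) expect_lte(treeDepth(w$tree), cfg5$maxDepth)

  aug <- MGAselect:::augmentDataset(gen$dataset, set5)
  expect_equal(nFeatures(aug$dataset),
               nFeatures(gen$dataset) + length(set5))
})

test_that("validation applies train statistics to the test set (no leakage)", {
  gen <- makeXorDataset(nSamples = 80, nNoise = 2, seed = 99)
  sp <- stratifiedSplit(gen$dataset, 0.7, seed = 3)
  tr <- node("*", leaf(1), leaf(2))
  v <- validateConstructed(sp$train, sp$test, list(list(tree = tr)))
  expect_true(v$accWith >= 0 && v$accWith <= 1)

  # empty tree set: both accuracies coincide
  v0 <- validateConstructed(sp$train, sp$test, list())
  expect_equal(v0$accWithout, v0$accWith)

  # train-derived vs test-derived statistics give different matrices
  augTrain <- MGAselect:::augmentDataset(sp$train, list(tr))
  augTestTrainStats <- MGAselect:::augmentDataset(sp$test, list(tr),
                                                  stats = augTrain$stats)
  augTestOwnStats <- MGAselect:::augmentDataset(sp$test, list(tr))
  expect_false(isTRUE(all.equal(
    featureMatrix(augTestTrainStats$dataset),
    featureMatrix(augTestOwnStats$dataset))))
})
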