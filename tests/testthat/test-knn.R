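test_that("distances match hand values and reject bad input", {
  mink1 <- distanceSpec("minkowski", p = 1)
  mink2 <- distanceSpec("minkowski", p = 2)
  cheb <- distanceSpec("chebyshev")
  x <- c(0.3, -1.2, 4)
  expect_equal(vectorDistance(x, x, mink2), 0)
  expect_equal(vectorDistance(x, x, cheb), 0)
  expect_equal(vectorDistance(c(0, 0), c(1, 1), mink1), 2)
  expect_equal(vectorDistance(c(0, 0), c(3, 4), mink2), 5)
  expect_equal(vectorDistance(c(0, 0), c(3, 4), cheb), 4)
  # weights scale coordinates inside the absolute difference
  wspec <- distanceSpec("minkowski", p = 2, weights = c(2, 0))
  expect_equal(vectorDistance(c(0, 0), c(3, 4), wspec), 6)
  expect_error(vectorDistance(c(1, 2), c(1, 2, 3), mink2), "length")
  expect_error(vectorDistance(c(1, NA), c(1, 2), mink2), "finite")
  expect_error(distanceSpec("minkowski", p = 0.5))
  expect_error(distanceSpec(weights = c(0, 0)))
})

test_that("metric axioms hold on random vectors", {
  set.seed(21)
  for (rep in 1:50) {
    p <- sample(c(1, 1.5, 2, 3), 1)
    spec <- distanceSpec("minkowski", p = p)
    x <- runif(6); y <- runif(6); z <- runif(6)
    dxy <- vectorDistance(x, y, spec)
    expect_identical(dxy, vectorDistance(y, x, spec))
    expect_lte(dxy,
               vectorDistance(x, z, spec) + vectorDistance(z, y, spec) + 1e-9)
  }
  # cross-check against stats::dist
  set.seed(22)
  X <- matrix(runif(12), 2, 6)
  for (p in c(1, 2, 3.5)) {
    expect_equal(vectorDistance(X[1, ], X[2, ], distanceSpec("minkowski", p = p)),
                 as.numeric(dist(X, method = "minkowski", p = p)),
                 tolerance = 1e-9)
  }
})

test_that("high-order Minkowski approaches the Chebyshev distance", {
  # L_p is sandwiched between L_inf and d^(1/p) L_inf and converges
  # monotonically from above as p grows
  set.seed(23)
  for (rep in 1:20) {
    x <- runif(8); y <- runif(8)
    dInf <- vectorDistance(x, y, distanceSpec("chebyshev"))
    d64 <- vectorDistance(x, y, distanceSpec("minkowski", p = 64))
    d512 <- vectorDistance(x, y, distanceSpec("minkowski", p = 512))
    expect_gte(d64, dInf - 1e-12)
    expect_lte(d64, dInf * 8^(1 / 64) + 1e-12)
    expect_lte(abs(d512 - dInf), abs(d64 - dInf) + 1e-12)
    expect_lt(abs(d512 - dInf), 1e-2)
  }
})

test_that("neighbourhood returns the k closest with index tie-breaks", {
  train <- tinyDataset(cbind(x = c(1, 2, 3, -2, -1)),
                       c("A", "A", "B", "B", "A"))
  nb <- neighborhood(train, 0, k = 3)
  expect_equal(nb$indices, c(1L, 5L, 2L))   # |1|,|-1| tie -> lower index first
  expect_equal(nb$distances, c(1, 1, 2))
  expect_false(is.unsorted(nb$distances))

  expect_equal(sort(neighborhood(train, 0, k = 5)$indices), 1:5)
  single <- tinyDataset(cbind(x = 4), "A")
  expect_warning(nb1 <- neighborhood(single, 0, k = 1), NA)
  expect_equal(nb1$indices, 1L)
  expect_error(neighborhood(train, 0, k = 6), "between 1 and 5")
  expect_error(neighborhood(train, 0, k = 0), "between 1 and 5")
})

test_that("knn vote follows the majority with deterministic ties", {
  train <- tinyDataset(cbind(x = c(0.1, 0.2, 0.9)), c("A", "A", "B"))
  expect_equal(knnPredict(train, 0, k = 3), "A")       # strict majority
  expect_equal(knnPredict(train, 0.95, k = 1), "B")    # nearest neighbour
  # 2-2 vote tie: B's nearest member is closer
  train2 <- tinyDataset(cbind(x = c(0.5, 0.6, 0.4, 0.7)),
                        c("A", "A", "B", "B"))
  expect_equal(knnPredict(train2, 0.4, k = 4), "B")
  # fully symmetric tie: lexicographically smallest label
  train3 <- tinyDataset(cbind(x = c(-1, 1)), c("B", "A"))
  expect_equal(knnPredict(train3, 0, k = 2), "A")
})

test_that("misclassification rate complements agreement exactly", {
  nb <- list(labels = c("A", "A", "B"), distances = c(1, 2, 3))
  expect_equal(misclassificationRate(nb, "A"), 1 / 3)
  expect_equal(misclassificationRate(nb, "B"), 2 / 3)
  expect_equal(misclassificationRate(nb, "A") +
                 mean(nb$labels == "A"), 1)
  nbAll <- list(labels = rep("A", 5), distances = 1:5)
  expect_equal(misclassificationRate(nbAll, "A"), 0)
})

test_that("knn agrees with the exhaustive reference on small datasets", {
  specs <- list(distanceSpec("minkowski", p = 1),
                distanceSpec("minkowski", p = 2),
                distanceSpec("chebyshev"))
  for (seed in 1:3) {
    set.seed(seed)
    n <- sample(5:30, 1)
    train <- randomDataset(n, 4, nClasses = 3, seed = seed + 100)
    queries <- matrix(rnorm(5 * 4), 5, 4)
    spec <- specs[[(seed %% 3) + 1]]
    for (k in seq_len(nSamples(train))) {
      for (q in 1:5) {
        expect_identical(
          knnPredict(train, queries[q, ], k, spec),
          referenceKnn(featureMatrix(train), sampleLabels(train),
                       queries[q, ], k, spec))
      }
    }
  }
})

test_that("k = N predicts the global majority class everywhere", {
  train <- randomDataset(21, 3, seed = 31)
  labs <- c(rep("A", 12), rep("B", 9))
  train <- LabeledDataset(featureMatrix(train), labs)
  for (q in 1:5) {
    expect_equal(knnPredict(train, rnorm(3), k = 21), "A")
  }
})

test_that("scanK reports the recognition rate per k", {
  # memorization: validation == train with distinct points
  train <- randomDataset(20, 3, seed = 41)
  expect_equal(scanK(train, train, kValues = 1)$recognitionRate, 1.0)
  one <- scanK(train, train, kValues = 3)
  expect_equal(nrow(one), 1L)
  expect_equal(one$k, 3L)

  # two well-separated Gaussian classes classify near-perfectly at k = 1
  set.seed(42)
  m <- rbind(matrix(rnorm(100 * 2, 0), 100, 2),
             matrix(rnorm(100 * 2, 6), 100, 2))
  ds <- LabeledDataset(m, rep(c("A", "B"), each = 100))
  sp <- stratifiedSplit(ds, 0.7, seed = 1)
  grid <- scanK(sp$train, sp$test)
  expect_equal(grid$k, seq(1L, 15L, 2L))
  expect_gte(grid$recognitionRate[grid$k == 1], 0.95)
  expect_error(scanK(sp$train, sp$test, kValues = integer(0)), "empty")
  expect_error(scanK(sp$train, sp$test, kValues = 10000), "\\[1, ")
})

test_that("evaluateKnn refuses missing entries", {
  m <- matrix(c(1, NA, 3, 4), 2, 2)
  ds <- LabeledDataset(m, c("A", "B"))
  ok <- randomDataset(4, 2, seed = 3)
  expect_error(evaluateKnn(ds, ok), "impute")
  expect_error(evaluateKnn(ok, ds), "impute")
})
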