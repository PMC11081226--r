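test_that("goodness-of-fit statistic matches hand values and the library", {
  expect_equal(chi2General(c(50, 50), c(0.5, 0.5)), 0)
  expect_equal(chi2General(c(60, 40), c(0.5, 0.5)), 4.0)
  set.seed(61)
  for (rep in 1:20) {
    k <- sample(2:6, 1)
    obs <- rpois(k, 30) + 1
    probs <- runif(k); probs <- probs / sum(probs)
    ours <- chi2General(obs, probs)
    ref <- suppressWarnings(chisq.test(obs, p = probs))
    expect_equal(ours, unname(ref$statistic), tolerance = 1e-9)
  }
  expect_error(chi2General(c(1, 2), c(0.7, 0.4)), "sum to 1")
  expect_error(chi2General(c(1, 2), c(1, 0)), "zero expected")
})

test_that("2x2 statistic matches the uncorrected independence test", {
  res <- chi2TwoByTwo(105, 95, 120, 180)
  expect_equal(res$df, 1L)
  ref <- chisq.test(matrix(c(105, 120, 95, 180), 2, 2), correct = FALSE)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-6)
  expect_equal(res$p.value, unname(ref$p.value), tolerance = 1e-9)

  expect_equal(chi2TwoByTwo(10, 10, 10, 10)$statistic, 0)
  expect_error(chi2TwoByTwo(0, 5, 0, 7), "degenerate")
  # Yates variant shrinks the statistic
  expect_lt(chi2TwoByTwo(10, 5, 3, 12, yates = TRUE)$statistic,
            chi2TwoByTwo(10, 5, 3, 12)$statistic)
})

test_that("marginal-product form equals the goodness-of-fit form", {
  set.seed(62)
  for (rep in 1:500) {
    cells <- rpois(4, 20) + 1   # positive cells => positive marginals
    a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
    n <- a + b + c + d
    # expected proportions from the marginals, cells ordered a, b, c, d
    pr <- c((a + b) * (a + c), (a + b) * (b + d),
            (c + d) * (a + c), (c + d) * (b + d)) / n^2
    expect_equal(chi2TwoByTwo(a, b, c, d)$statistic,
                 chi2General(c(a, b, c, d), pr), tolerance = 1e-9)
  }
})

test_that("2x2 statistic is swap-invariant and scales linearly", {
  set.seed(63)
  for (rep in 1:20) {
    t <- rpois(4, 15) + 1
    s <- chi2TwoByTwo(t[1], t[2], t[3], t[4])$statistic
    # simultaneous row and column swap
    expect_equal(chi2TwoByTwo(t[4], t[3], t[2], t[1])$statistic, s,
                 tolerance = 1e-12)
    m <- sample(2:5, 1)
    expect_equal(chi2TwoByTwo(m * t[1], m * t[2], m * t[3], m * t[4])$statistic,
                 m * s, tolerance = 1e-9)
  }
})

test_that("degrees of freedom are (r-1)(c-1) for r, c up to 6", {
  set.seed(64)
  for (r in 2:6) for (cc in 2:6) {
    tab <- matrix(rpois(r * cc, 10) + 1, r, cc)
    res <- MGAselect:::chi2Independence(tab)
    expect_equal(res$df, (r - 1L) * (cc - 1L))
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-9)
  }
})

test_that("ranking puts a strongly planted feature above pure noise", {
  wins <- 0L
  for (seed in 1:20) {
    gen <- makeSyntheticDataset(nSamples = 60, nFeatures = 40,
                                nInformative = 1, nRedundant = 0,
                                nClasses = 2, effectSize = 3, seed = seed)
    ranked <- rankFeaturesChi2(gen$dataset)
    if (ranked$index[1] == gen$truth$informative) wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})

test_that("null features give uniform-ish p-values and stable ties", {
  set.seed(65)
  x <- rnorm(60); labs <- rep(c("A", "B"), 30)
  ps <- replicate(200, {
    ds <- LabeledDataset(cbind(f = sample(x)), labs)
    rankFeaturesChi2(ds)$p.value[1]
  })
  expect_gte(mean(ps), 0.4)
  expect_lte(mean(ps), 0.6)

  # identical features: identical statistics, stable input order
  m <- cbind(a = x, b = x, c = rnorm(60))
  ranked <- rankFeaturesChi2(LabeledDataset(m, labs))
  sa <- ranked$statistic[ranked$feature == "a"]
  sb <- ranked$statistic[ranked$feature == "b"]
  expect_identical(sa, sb)
  expect_lt(which(ranked$feature == "a"), which(ranked$feature == "b"))

  # constant feature: statistic 0 with a warning
  mc <- cbind(k = rep(1, 60), f = x)
  expect_warning(rc <- rankFeaturesChi2(LabeledDataset(mc, labs)),
                 "constant")
  expect_equal(rc$statistic[rc$feature == "k"], 0)
})

test_that("selection honours topM, alpha and their edge cases", {
  gen <- makeSyntheticDataset(nSamples = 40, nFeatures = 25,
                              nInformative = 3, nRedundant = 0,
                              nClasses = 2, seed = 66)
  ranked <- rankFeaturesChi2(gen$dataset)
  expect_setequal(chi2Select(ranked, topM = 25), 1:25)
  expect_setequal(chi2Select(ranked, alpha = 1.0), 1:25)
  expect_length(chi2Select(ranked, topM = 5), 5)
  expect_error(chi2Select(ranked, topM = 26), "exceeds")
  expect_error(chi2Select(ranked), "exactly one")
  expect_error(chi2Select(ranked, topM = 3, alpha = 0.1), "exactly one")

  # under the null, alpha = 0.05 keeps roughly 5% of features
  set.seed(67)
  noise <- LabeledDataset(matrix(rnorm(60 * 500), 60, 500),
                          rep(c("A", "B"), 30))
  nsel <- length(chi2Select(rankFeaturesChi2(noise), alpha = 0.05))
  expect_gte(nsel, 10L)
  expect_lte(nsel, 45L)
})
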