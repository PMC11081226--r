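test_that("delimited read handles labels, missing tokens and bad input", {
  tf <- tempfile(fileext = ".csv")
  writeLines(c("label,g1,g2", "A,1,2", "B,3,4", "A,5,NA"), tf)
  ds <- readLabeledDataset(tf)
  expect_s4_class(ds, "LabeledDataset")
  expect_equal(nSamples(ds), 3L)
  expect_equal(nFeatures(ds), 2L)
  expect_equal(as.character(sampleLabels(ds)), c("A", "B", "A"))
  expect_true(is.na(featureMatrix(ds)[3, 2]))

  writeLines(c("label,g1,g2", "A,1,?", "B,3,4"), tf)
  ds2 <- readLabeledDataset(tf, missingToken = "?")
  expect_true(is.na(featureMatrix(ds2)[1, 2]))

  writeLines("label,g1,g2", tf)
  expect_error(readLabeledDataset(tf), "no samples")
  writeLines(c("label,g1,g1", "A,1,2", "B,3,4"), tf)
  expect_error(readLabeledDataset(tf), "duplicate feature")
  writeLines(c("label,g1,g2", "A,1,oops", "B,3,4"), tf)
  expect_error(readLabeledDataset(tf), "row 1.*g2")
  writeLines(c("label,g1", "A,1"), tf)
  expect_error(readLabeledDataset(tf, labelColumn = "class"), "not found")
})

test_that("write then read round-trips matrix, labels and missing mask", {
  set.seed(11)
  m <- matrix(round(rnorm(40), 6), 10, 4)
  m[sample(length(m), 5)] <- NA
  ds <- LabeledDataset(m, sample(c("x", "y"), 10, replace = TRUE))
  tf <- tempfile(fileext = ".tsv")
  writeLabeledDataset(ds, tf)
  back <- readLabeledDataset(tf)
  expect_equal(featureMatrix(back), featureMatrix(ds), tolerance = 1e-12)
  expect_identical(is.na(featureMatrix(back)), is.na(featureMatrix(ds)))
  expect_equal(as.character(sampleLabels(back)),
               as.character(sampleLabels(ds)))
})

test_that("standardization matches the population formula and inverts", {
  ds <- tinyDataset(cbind(g = c(1, 2, 3)), c("A", "B", "A"))
  std <- standardizeDataset(ds)
  expect_equal(as.numeric(featureMatrix(std$dataset)),
               c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_equal(unname(std$params$mu), 2)
  expect_equal(unname(std$params$sigma), 0.8165, tolerance = 1e-4)

  # constant feature: floored sigma, all-zero column
  dsc <- tinyDataset(cbind(g = c(5, 5, 5)), c("A", "B", "A"))
  stdc <- standardizeDataset(dsc)
  expect_equal(as.numeric(featureMatrix(stdc$dataset)), c(0, 0, 0))
  expect_gt(unname(stdc$params$sigma), 0)

  # round trip on a matrix with missing entries
  set.seed(3)
  m <- matrix(rnorm(60, 5, 3), 12, 5)
  m[sample(length(m), 6)] <- NA
  dsm <- LabeledDataset(m, rep(c("A", "B"), 6))
  stdm <- standardizeDataset(dsm)
  back <- destandardize(stdm$dataset, stdm$params)
  obs <- !is.na(m)
  expect_equal(featureMatrix(back)[obs], m[obs], tolerance = 1e-12)
  expect_identical(unname(is.na(featureMatrix(stdm$dataset))), !obs)

  dsBad <- LabeledDataset(cbind(a = c(1, 2), b = c(NA, NA)), c("A", "B"))
  expect_error(standardizeDataset(dsBad), "'b'")
})

test_that("stratified split preserves class proportions deterministically", {
  set.seed(5)
  ds <- LabeledDataset(matrix(rnorm(300), 100, 3),
                       rep(c("A", "B"), each = 50))
  sp <- stratifiedSplit(ds, 0.7, seed = 9)
  expect_equal(nSamples(sp$train), 70L)
  expect_equal(as.integer(table(sampleLabels(sp$train))), c(35L, 35L))
  # union is a partition
  expect_setequal(c(sampleIds(sp$train), sampleIds(sp$test)), sampleIds(ds))
  expect_length(intersect(sampleIds(sp$train), sampleIds(sp$test)), 0)
  # determinism
  sp2 <- stratifiedSplit(ds, 0.7, seed = 9)
  expect_identical(sampleIds(sp2$train), sampleIds(sp$train))

  # rounding rule: 7/3 classes at 0.7 -> 5 and 2 in train
  ds10 <- LabeledDataset(matrix(rnorm(20), 10, 2),
                         c(rep("A", 7), rep("B", 3)))
  sp10 <- stratifiedSplit(ds10, 0.7, seed = 1)
  expect_equal(as.integer(table(sampleLabels(sp10$train))), c(5L, 2L))

  ds1 <- LabeledDataset(matrix(rnorm(6), 3, 2), c("A", "A", "B"))
  expect_error(stratifiedSplit(ds1, 0.7), "fewer than 2")
})

test_that("split class frequencies stay near the input frequencies", {
  for (seed in 1:5) {
    gen <- makeSyntheticDataset(nSamples = 90, nFeatures = 10,
                                nInformative = 2, nRedundant = 0,
                                nClasses = 3, classWeights = c(.5, .3, .2),
                                seed = seed)
    ds <- gen$dataset
    sp <- stratifiedSplit(ds, 0.7, seed = seed)
    fIn <- table(sampleLabels(ds)) / nSamples(ds)
    fTr <- table(sampleLabels(sp$train)) / nSamples(sp$train)
    bound <- 1 / min(table(sampleLabels(ds)))
    expect_true(all(abs(fIn - fTr) < bound))
  }
})

test_that("accuracy is the exact confusion-count ratio", {
  expect_equal(accuracy(list(tp = 5, tn = 5, fp = 0, fn = 0)), 1.0)
  expect_equal(accuracy(list(tp = 0, tn = 0, fp = 3, fn = 7)), 0.0)
  expect_equal(accuracy(list(tp = 30, tn = 45, fp = 10, fn = 15)), 0.75)
  expect_error(accuracy(list(tp = 0, tn = 0, fp = 0, fn = 0)), "total")
  cc <- confusionCounts(c("A", "A", "B"), c("A", "B", "B"), positive = "A")
  expect_equal(cc, list(tp = 1L, tn = 1L, fp = 1L, fn = 0L))
  expect_equal(accuracy(cc), 2 / 3)
})
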