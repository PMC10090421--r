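test_that("threshold metrics match their closed forms", {
  m <- classMetrics(c(TP = 82, FP = 0, TN = 82, FN = 0))
  expect_equal(unname(m), c(1, 1, 1, 1))

  m <- classMetrics(c(TP = 45, FP = 10, TN = 40, FN = 5))
  expect_equal(m[["se"]], 0.90)
  expect_equal(m[["sp"]], 0.80)
  expect_equal(m[["acc"]], 0.85)
  expect_equal(m[["mcc"]], 1750 / sqrt(50 * 55 * 50 * 45), tolerance = 1e-12)

  expect_error(classMetrics(c(TP = 0, FP = 0, TN = 0, FN = 0)), "empty")
  # no actual positives: SE and MCC are both undefined, each with a warning
  w <- capture_warnings(m <- classMetrics(c(TP = 0, FP = 3, TN = 7, FN = 0)))
  expect_length(w, 2L)
  expect_match(w, "undefined", all = TRUE)
  expect_true(is.nan(m[["se"]]))
  expect_true(is.nan(m[["mcc"]]))
  expect_equal(m[["sp"]], 0.7)
})

test_that("metrics agree with brute-force recounting on random tables", {
  set.seed(11)
  for (i in 1:1000) {
    cnt <- sample.int(60, 4)  # all marginals positive
    m <- classMetrics(c(TP = cnt[1], FP = cnt[2], TN = cnt[3], FN = cnt[4]))
    o <- oracleMetricsFromCounts(cnt[1], cnt[2], cnt[3], cnt[4])
    expect_equal(unname(m), unname(o), tolerance = 1e-12)
  }
})

test_that("metrics do not overflow on Train-500-sized counts", {
  m <- classMetrics(c(TP = 225, FP = 23, TN = 227, FN = 25))
  expect_true(is.finite(m[["mcc"]]))
  expect_equal(m[["mcc"]],
               (225 * 227 - 23 * 25) / sqrt(250 * 248 * 250 * 252),
               tolerance = 1e-12)
})

test_that("AUC follows the Mann-Whitney pair convention", {
  expect_equal(aucScore(c(0.9, 0.8, 0.4, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(aucScore(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(aucScore(rep(0.3, 10), rep(c(1, 0), 5)), 0.5)
  expect_error(aucScore(c(0.1, 0.9), c(1, 1)), "both classes")

  set.seed(21)
  for (i in 1:50) {
    n <- sample(6:40, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.5))
    scores <- round(runif(n), 2)  # rounding induces ties
    expect_equal(aucScore(scores, labels), oracleAUCpairs(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC equals trapezoidal ROC integration on tie-free scores", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(6:60, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.5))
    scores <- sample(seq_len(1000), n) / 1000  # distinct scores
    expect_equal(aucScore(scores, labels), trapezoidAUC(scores, labels),
                 tolerance = 1e-12)
    if (requireNamespace("pROC", quietly = TRUE)) {
      ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                            direction = "<")))
      expect_equal(aucScore(scores, labels), ref, tolerance = 1e-12)
    }
  }
})

test_that("cross-validation stratifies folds and is seed-reproducible", {
  ds <- generateFixture(250, 250, seed = 1)
  fm <- encodeDataset(ds, list(encoder188()))
  rep1 <- crossValidate(fm, k = 10, seed = 5)
  folds <- perFoldReports(rep1)
  expect_equal(nrow(folds), 10L)
  expect_true(all(folds$n == 50L))  # 25 ACP + 25 non-ACP held out per fold

  rep2 <- crossValidate(fm, k = 10, seed = 5)
  expect_identical(evalMetrics(rep1), evalMetrics(rep2))
  expect_identical(confusionCounts(rep1), confusionCounts(rep2))

  rep3 <- crossValidate(fm, k = 10, seed = 6)
  expect_false(identical(evalMetrics(rep1)[["auc"]],
                         evalMetrics(rep3)[["auc"]]))
})

test_that("leave-one-out is the k = n boundary of stratified CV", {
  ds <- generateFixture(5, 5, seed = 2, bias = c(K = 6, R = 6))
  rep <- crossValidate(ds, list(encoder188()), k = 5, seed = 1)
  expect_equal(nrow(perFoldReports(rep)), 5L)
  expect_equal(sum(perFoldReports(rep)$n), 10L)
  expect_error(crossValidate(ds, list(encoder188()), k = 6), "at least k")
  expect_error(crossValidate(ds, list(encoder188()), k = 1), "at least 2")
})

test_that("pooled CV accuracy equals the count-weighted mean of fold ACC", {
  ds <- generateFixture(30, 30, seed = 3, bias = c(K = 3, R = 3))
  rep <- crossValidate(ds, miniEncoders(), k = 6, seed = 2)
  folds <- perFoldReports(rep)
  expect_equal(evalMetrics(rep)[["acc"]],
               sum(folds$acc * folds$n) / sum(folds$n), tolerance = 1e-12)
})

test_that("independent testing fits once on train and flags overlap", {
  train <- generateFixture(30, 30, seed = 4, bias = c(K = 4, R = 4),
                           name = "trainset")
  test <- generateFixture(15, 15, seed = 5, bias = c(K = 4, R = 4),
                          name = "testset")
  rep <- independentTest(train, test, miniEncoders())
  expect_identical(rep@protocol, "independent")
  expect_gt(evalMetrics(rep)[["acc"]], 0.5)
  expect_length(rep@notes, 0L)

  expect_warning(resub <- independentTest(train, train, miniEncoders()),
                 "resubstitution")
  expect_match(resub@notes, "resubstitution")
})

test_that("report tables use the paper-style percent layout", {
  rep <- evalReportForTest()
  tab <- reportTable(list(model = rep))
  expect_identical(colnames(tab), c("SE", "SP", "ACC", "MCC", "AUC"))
  expect_equal(tab$ACC, 85.0)
  tsv <- tempfile(fileext = ".tsv")
  writeReportTSV(list(model = rep), tsv)
  expect_identical(read.delim(tsv)$model, "model")
})

test_that("the sweep harness runs multiple classifiers on one encoding", {
  ds <- generateFixture(20, 20, seed = 6, bias = c(K = 4, R = 4))
  reps <- sweepClassifiers(
    ds, list(gbdt = modelConfig(nTrees = 20L),
             rf = modelConfig(nTrees = 20L, classifier = "random_forest")),
    list(encoder188()), k = 4, seed = 1)
  tab <- reportTable(reps)
  expect_identical(rownames(tab), c("gbdt", "rf"))
  expect_true(all(tab$AUC > 50))
})
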