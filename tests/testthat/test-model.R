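biasedFixture <- function(n = 40, seed = 1)
  generateFixture(n / 2, n / 2, seed = seed, bias = c(K = 3, R = 3))

test_that("training on separable data beats chance and resubstitutes well", {
  ds <- biasedFixture(60)
  fm <- encodeDataset(ds, miniEncoders())
  fit <- acpTrain(fm, modelConfig())
  pred <- acpPredict(fit, fm)
  acc <- mean(pred$call == peptideLabels(ds))
  expect_gt(acc, 0.5)
  expect_gte(acc, 0.9)
  expect_true(all(pred$score >= 0 & pred$score <= 1))
})

test_that("training is deterministic under a fixed seed", {
  train <- biasedFixture(40, seed = 2)
  held <- biasedFixture(20, seed = 3)
  fmTrain <- encodeDataset(train, miniEncoders())
  fmHeld <- encodeDataset(held, miniEncoders())
  p1 <- acpPredict(acpTrain(fmTrain, modelConfig()), fmHeld)
  p2 <- acpPredict(acpTrain(fmTrain, modelConfig()), fmHeld)
  expect_identical(p1$score, p2$score)
})

test_that("degenerate training input is rejected", {
  ds <- generateFixture(6, 0, seed = 1)
  fm <- encodeDataset(ds, list(encoder188()))
  expect_error(acpTrain(fm), "both classes")
  fm2 <- encodeDataset(generateFixture(3, 3, seed = 1), list(encoder188()))
  fm2@values[1, 1] <- NaN
  expect_error(acpTrain(fm2), "non-finite")
  unlabeled <- encodeDataset(
    PeptideSet(c(a = "ACDEFGHIKL", b = "KKRRWWYYVV")), list(encoder188()))
  expect_error(acpTrain(unlabeled), "label")
})

test_that("prediction guards the feature layout and handles edge rows", {
  ds <- biasedFixture(30)
  fit <- acpTrain(encodeDataset(ds, list(encoder188())), modelConfig())
  other <- encodeDataset(ds, miniEncoders())
  expect_error(acpPredict(fit, other), "layout mismatch.*d188")

  emptyFm <- encodeDataset(generateFixture(0, 0, seed = 1),
                           list(encoder188()))
  expect_equal(nrow(acpPredict(fit, emptyFm)), 0L)
})

test_that("a score of exactly 0.5 is called positive", {
  ds <- biasedFixture(20)
  fm <- encodeDataset(ds, list(encoder188()))
  fit <- acpTrain(fm, modelConfig())
  fakeScore <- c(0.5, 0.4999, 0.5001)
  call <- ifelse(fakeScore >= 0.5, "ACP", "non-ACP")
  expect_identical(call, c("ACP", "non-ACP", "ACP"))
  # and the exported path uses the same rule
  pred <- acpPredict(fit, fm)
  expect_identical(as.character(pred$call),
                   ifelse(pred$score >= 0.5, "ACP", "non-ACP"))
})

test_that("prediction is row-independent", {
  ds <- biasedFixture(24)
  fm <- encodeDataset(ds, miniEncoders())
  fit <- acpTrain(fm, modelConfig())
  batch <- acpPredict(fit, fm)
  oneByOne <- vapply(seq_len(nrow(fm)),
                     function(i) acpPredict(fit, fm[i])$score, numeric(1))
  expect_equal(batch$score, oneByOne, tolerance = 1e-12)
})

test_that("every comparison classifier runs through the shared interface", {
  ds <- biasedFixture(40, seed = 5)
  fm <- encodeDataset(ds, list(encoder188()))
  kinds <- c("gbdt", "xgboost", "random_forest", "adaboost",
             "decision_tree", "knn", "logistic_regression", "gaussian_nb")
  for (kind in kinds) {
    cfg <- modelConfig(nTrees = 30L, classifier = kind,
                       standardize = kind %in% c("knn",
                                                 "logistic_regression"))
    fit <- acpTrain(fm, cfg)
    pred <- acpPredict(fit, fm)
    expect_equal(nrow(pred), length(ds))
    expect_true(all(pred$score >= 0 & pred$score <= 1),
                label = paste(kind, "scores in [0,1]"))
    expect_gt(mean(pred$call == peptideLabels(ds)), 0.5)
  }
})

test_that("saved models reload with their layout guard intact", {
  ds <- biasedFixture(20)
  fm <- encodeDataset(ds, list(encoder188()))
  fit <- acpTrain(fm, modelConfig())
  path <- tempfile(fileext = ".rds")
  saveACPModel(fit, path)
  back <- loadACPModel(path)
  expect_identical(acpPredict(back, fm)$score, acpPredict(fit, fm)$score)
  expect_error(acpPredict(back, encodeDataset(ds, miniEncoders())),
               "layout mismatch")
})

test_that("standardization parameters are fitted on training data only", {
  train <- biasedFixture(30, seed = 6)
  test <- biasedFixture(30, seed = 7)
  fmTrain <- encodeDataset(train, list(encoder188()))
  fmTest <- encodeDataset(test, list(encoder188()))
  fit <- acpTrain(fmTrain, modelConfig(classifier = "logistic_regression",
                                       standardize = TRUE))
  expect_equal(unname(fit@center), unname(colMeans(featureValues(fmTrain))))
  expect_equal(nrow(acpPredict(fit, fmTest)), 30L)
})
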