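#' Model configuration
#'
#' Hyperparameters for the classifier and the comparison harness. The
#' gradient-boosting defaults follow the common library defaults (100
#' trees, learning rate 0.1, depth 3); every alternative classifier trains
#' and predicts through the same interface so feature/classifier sweeps
#' share one code path.
#'
#' @param nTrees Ensemble size for tree ensembles.
#' @param learningRate Boosting shrinkage, positive.
#' @param maxDepth Per-tree depth for boosted trees / decision tree.
#' @param seed RNG seed for stochastic backends.
#' @param classifier One of `gbdt`, `xgboost`, `random_forest`, `adaboost`,
#'   `decision_tree`, `knn`, `logistic_regression`, `gaussian_nb`.
#' @param standardize Standardize features (fit on training data only)
#'   before distance-/margin-based classifiers; tree models are
#'   scale-invariant and default to raw features.
#' @param k Neighbor count for `knn`.
#' @return A list of class `ACPModelConfig`.
#' @export
#' @examples
#' modelConfig(classifier = "random_forest")
modelConfig <- function(nTrees = 100L, learningRate = 0.1, maxDepth = 3L,
                        seed = 42L,
                        classifier = c("gbdt", "xgboost", "random_forest",
                                       "adaboost", "decision_tree", "knn",
                                       "logistic_regression", "gaussian_nb"),
                        standardize = FALSE, k = 5L) {
  stopifnot(nTrees >= 1L, learningRate > 0, maxDepth >= 1L)
  structure(list(nTrees = as.integer(nTrees), learningRate = learningRate,
                 maxDepth = as.integer(maxDepth), seed = as.integer(seed),
                 classifier = match.arg(classifier),
                 standardize = isTRUE(standardize), k = as.integer(k)),
            class = "ACPModelConfig")
}

#' Train a peptide classifier
#'
#' Fits the configured classifier on a labeled [FeatureMatrix-class].
#' Deterministic under a fixed config seed. The returned model records the
#' feature layout and refuses to predict on differently encoded input.
#'
#' @param fm A labeled [FeatureMatrix-class] with both classes present and
#'   finite values.
#' @param config An `ACPModelConfig` from [modelConfig()].
#' @return An [ACPModel-class].
#' @export
#' @examples
#' ps <- generateFixture(30, 30, seed = 1, bias = c(K = 3, R = 3))
#' fm <- encodeDataset(ps, list(encoder188()))
#' fit <- acpTrain(fm, modelConfig())
acpTrain <- function(fm, config = modelConfig()) {
  stopifnot(is(fm, "FeatureMatrix"), inherits(config, "ACPModelConfig"))
  y <- peptideLabels(fm)
  if (length(y) == 0L) stop("training requires labels")
  if (nlevels(droplevels(y)) < 2L)
    stop("training requires both classes; got only '",
         as.character(unique(y)), "'")
  x <- featureValues(fm)
  if (!all(is.finite(x)))
    stop("non-finite feature values in training matrix")
  center <- numeric(0); scale <- numeric(0)
  if (config$standardize) {
    center <- colMeans(x)
    scale <- apply(x, 2L, stats::sd)
    scale[scale == 0] <- 1
    x <- sweep(sweep(x, 2L, center), 2L, scale, "/")
  }
  backend <- fitBackend(x, y, config)
  new("ACPModel", backend = backend, config = unclass(config),
      layoutVersion = layoutVersion(fm), featureNames = colnames(x),
      classCounts = c(`non-ACP` = sum(y == "non-ACP"),
                      ACP = sum(y == "ACP")),
      center = center, scale = scale)
}

fitBackend <- function(x, y, config) {
  y01 <- as.integer(y == "ACP")
  switch(config$classifier,
    gbdt = {
      # plain gradient boosting: no L2 penalty, exact greedy splits
      dtrain <- xgboost::xgb.DMatrix(x, label = y01)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      eta = config$learningRate,
                      max_depth = config$maxDepth, lambda = 0, alpha = 0,
                      tree_method = "exact", nthread = 1,
                      seed = config$seed),
        data = dtrain, nrounds = config$nTrees, verbose = 0)
    },
    xgboost = {
      dtrain <- xgboost::xgb.DMatrix(x, label = y01)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      eta = config$learningRate,
                      max_depth = config$maxDepth, nthread = 1,
                      seed = config$seed),
        data = dtrain, nrounds = config$nTrees, verbose = 0)
    },
    random_forest = withSeed(config$seed,
      randomForest::randomForest(x = x, y = y, ntree = config$nTrees)),
    adaboost = fitSamme(x, y01, nTrees = config$nTrees),
    decision_tree = {
      df <- data.frame(.y = y, x, check.names = FALSE)
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(maxdepth = 30L,
                                                  xval = 0L))
    },
    knn = list(x = x, y = y, k = config$k),
    logistic_regression = glmnet::glmnet(
      x, y, family = "binomial", alpha = 0,
      lambda = 1 / nrow(x), standardize = FALSE),
    gaussian_nb = {
      keep <- apply(x, 2L, function(col)
        min(tapply(col, y, stats::sd)) > 0)
      if (!any(keep)) stop("no informative features for naive Bayes")
      list(fit = e1071::naiveBayes(x[, keep, drop = FALSE], y),
           keep = which(keep))
    })
}

# Minimal SAMME booster over depth-1 rpart stumps (no installed R package
# provides AdaBoost). Deterministic: rpart is deterministic given weights.
fitSamme <- function(x, y01, nTrees) {
  n <- nrow(x)
  w <- rep(1 / n, n)
  df <- data.frame(.y = factor(y01, levels = c(0L, 1L)), x,
                   check.names = FALSE)
  stumps <- list(); alphas <- numeric(0)
  for (m in seq_len(nTrees)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = rpart::rpart.control(maxdepth = 1L,
                                                       xval = 0L,
                                                       cp = -1))
    pred <- as.integer(as.character(predict(fit, df, type = "class")))
    miss <- pred != y01
    err <- sum(w[miss])
    if (err <= 0 || err >= 0.5) {
      if (err <= 0) { stumps <- c(stumps, list(fit)); alphas <- c(alphas, 1) }
      break
    }
    a <- 0.5 * log((1 - err) / err)
    stumps <- c(stumps, list(fit)); alphas <- c(alphas, a)
    w <- w * exp(a * ifelse(miss, 1, -1))
    w <- w / sum(w)
  }
  list(stumps = stumps, alphas = alphas)
}

#' Predict anticancer calls for encoded peptides
#'
#' Scores each row with the fitted backend and calls the anticancer class at
#' the fixed threshold 0.5; a score of exactly 0.5 is called positive.
#' Prediction is row-independent: scoring rows one at a time equals batch
#' scoring.
#'
#' @param model An [ACPModel-class].
#' @param fm A [FeatureMatrix-class] with the same `layoutVersion` the model
#'   was trained on.
#' @return A data.frame with columns `id`, `score` (probability-like score
#'   in `[0, 1]` for the ACP class) and `call` (factor `non-ACP`/`ACP`).
#' @export
acpPredict <- function(model, fm) {
  stopifnot(is(model, "ACPModel"), is(fm, "FeatureMatrix"))
  if (!identical(model@layoutVersion, layoutVersion(fm)))
    stop(sprintf("feature layout mismatch: model '%s' vs input '%s'",
                 model@layoutVersion, layoutVersion(fm)))
  x <- featureValues(fm)
  if (nrow(x) == 0L)
    return(data.frame(id = character(0), score = numeric(0),
                      call = factor(character(0), levels = .LABEL_LEVELS)))
  if (length(model@center))
    x <- sweep(sweep(x, 2L, model@center), 2L, model@scale, "/")
  score <- scoreBackend(model@backend, model@config, x)
  score <- pmin(pmax(score, 0), 1)
  data.frame(id = rownames(x), score = unname(score),
             call = factor(ifelse(score >= 0.5, "ACP", "non-ACP"),
                           levels = .LABEL_LEVELS),
             row.names = NULL)
}

scoreBackend <- function(backend, config, x) {
  switch(config$classifier,
    gbdt = ,
    xgboost = predict(backend, xgboost::xgb.DMatrix(x)),
    random_forest = predict(backend, x, type = "prob")[, "ACP"],
    adaboost = {
      if (!length(backend$stumps)) return(rep(0.5, nrow(x)))
      df <- data.frame(x, check.names = FALSE)
      votes <- vapply(backend$stumps, function(s)
        as.numeric(as.character(predict(s, df, type = "class"))),
        numeric(nrow(df)))
      votes <- matrix(votes, nrow = nrow(df))
      as.vector(votes %*% backend$alphas) / sum(backend$alphas)
    },
    decision_tree = predict(backend, data.frame(x, check.names = FALSE),
                            type = "prob")[, "ACP"],
    knn = {
      pr <- class::knn(backend$x, x, backend$y, k = backend$k,
                       prob = TRUE, use.all = TRUE)
      p <- attr(pr, "prob")
      ifelse(pr == "ACP", p, 1 - p)
    },
    logistic_regression =
      as.vector(predict(backend, x, type = "response")),
    gaussian_nb = predict(backend$fit,
                          x[, backend$keep, drop = FALSE],
                          type = "raw")[, "ACP"])
}

setMethod("show", "ACPModel", function(object) {
  cat(sprintf("ACPModel (%s): %d features, trained on %d ACP / %d non-ACP\n",
              object@config$classifier, length(object@featureNames),
              object@classCounts[["ACP"]], object@classCounts[["non-ACP"]]))
  cat("  layout:", object@layoutVersion, "\n")
})

#' Save / load a trained model
#'
#' The artifact bundles the fitted backend, the configuration and the
#' feature layout fingerprint, so a reloaded model still refuses
#' differently encoded input.
#'
#' @param model An [ACPModel-class].
#' @param path File path.
#' @return `saveACPModel`: `path` invisibly; `loadACPModel`: the model.
#' @export
saveACPModel <- function(model, path) {
  stopifnot(is(model, "ACPModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveACPModel
#' @export
loadACPModel <- function(path) {
  m <- readRDS(path)
  if (!is(m, "ACPModel")) stop("not an ACPModel artifact: ", path)
  m
}
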