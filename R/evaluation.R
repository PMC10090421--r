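#' Confusion counts from truth and calls
#'
#' @param truth,call Factors (or values coercible) with levels
#'   `non-ACP`/`ACP`; `ACP` is the positive class.
#' @return Named integer vector `TP`, `FP`, `TN`, `FN`.
#' @export
#' @examples
#' confusionFromCalls(c("ACP", "non-ACP"), c("ACP", "ACP"))
confusionFromCalls <- function(truth, call) {
  truth <- normalizeLabels(truth, length(truth))
  call <- normalizeLabels(call, length(call))
  stopifnot(length(truth) == length(call))
  c(TP = sum(truth == "ACP" & call == "ACP"),
    FP = sum(truth == "non-ACP" & call == "ACP"),
    TN = sum(truth == "non-ACP" & call == "non-ACP"),
    FN = sum(truth == "ACP" & call == "non-ACP"))
}

#' Threshold metrics from a confusion table
#'
#' Sensitivity `SE = TP/(TP+FN)`, specificity `SP = TN/(TN+FP)`, accuracy
#' `ACC = (TP+TN)/total`, and the Matthews correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FN)(TP+FP)(TN+FP)(TN+FN))`.
#' A metric whose marginal is zero is undefined and reported as `NaN` with
#' a warning, never silently 0; an all-zero table is an error.
#'
#' @param counts Named vector with elements `TP`, `FP`, `TN`, `FN`.
#' @return Named numeric vector `se`, `sp`, `acc`, `mcc` (proportions, not
#'   percentages).
#' @export
#' @examples
#' classMetrics(c(TP = 45, FP = 10, TN = 40, FN = 5))
classMetrics <- function(counts) {
  counts <- counts[c("TP", "FP", "TN", "FN")]
  if (anyNA(counts) || any(counts < 0)) stop("invalid confusion counts")
  # double precision: marginal products overflow integers for n in the hundreds
  tp <- as.numeric(counts[["TP"]]); fp <- as.numeric(counts[["FP"]])
  tn <- as.numeric(counts[["TN"]]); fn <- as.numeric(counts[["FN"]])
  total <- tp + fp + tn + fn
  if (total == 0) stop("empty evaluation: all confusion counts are zero")
  se <- if (tp + fn > 0) tp / (tp + fn) else {
    warning("SE undefined: no actual positives"); NaN
  }
  sp <- if (tn + fp > 0) tn / (tn + fp) else {
    warning("SP undefined: no actual negatives"); NaN
  }
  denom2 <- (tp + fn) * (tp + fp) * (tn + fp) * (tn + fn)
  mcc <- if (denom2 > 0) (tp * tn - fp * fn) / sqrt(denom2) else {
    warning("MCC undefined: a confusion-table marginal is zero"); NaN
  }
  c(se = se, sp = sp, acc = (tp + tn) / total, mcc = mcc)
}

#' Area under the ROC curve
#'
#' The probability that a random positive scores above a random negative,
#' ties counted half — the Mann-Whitney U statistic normalized by
#' `nPos * nNeg`, computed via midranks.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Labels coercible to `non-ACP`/`ACP`; both classes must be
#'   present.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' aucScore(c(0.9, 0.8, 0.4, 0.2), c(1, 0, 1, 0))
aucScore <- function(scores, labels) {
  labels <- normalizeLabels(labels, length(labels))
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  nPos <- sum(labels == "ACP"); nNeg <- sum(labels == "non-ACP")
  if (nPos == 0L || nNeg == 0L)
    stop("AUC requires both classes in 'labels'")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == "ACP"]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

evalReport <- function(truth, score, call, protocol,
                       perFold = data.frame(), notes = character(0)) {
  counts <- confusionFromCalls(truth, call)
  metrics <- c(classMetrics(counts), auc = aucScore(score, truth))
  new("EvalReport", counts = counts, metrics = metrics,
      protocol = protocol, perFold = perFold, notes = notes)
}

#' @rdname EvalReport-class
#' @export
setMethod("confusionCounts", "EvalReport", function(x) x@counts)

#' @rdname EvalReport-class
#' @export
setMethod("evalMetrics", "EvalReport", function(x) x@metrics)

#' @rdname EvalReport-class
#' @export
setMethod("perFoldReports", "EvalReport", function(x) x@perFold)

setMethod("show", "EvalReport", function(object) {
  m <- object@metrics
  cat(sprintf("EvalReport [%s] on %d record(s)\n", object@protocol,
              sum(object@counts)))
  cat(sprintf("  TP=%d FP=%d TN=%d FN=%d\n", object@counts[["TP"]],
              object@counts[["FP"]], object@counts[["TN"]],
              object@counts[["FN"]]))
  cat(sprintf("  SE=%.1f SP=%.1f ACC=%.1f MCC=%.1f AUC=%.1f (%%)\n",
              100 * m[["se"]], 100 * m[["sp"]], 100 * m[["acc"]],
              100 * m[["mcc"]], 100 * m[["auc"]]))
  for (nt in object@notes) cat("  note:", nt, "\n")
})

#' Permute labels for null calibration
#'
#' Randomly reassigns the existing labels to records, breaking any
#' label-sequence association while preserving class counts. Under a
#' label permutation a sound evaluation protocol must score at chance.
#'
#' @param x A labeled [PeptideSet-class] or [FeatureMatrix-class].
#' @param seed Permutation seed.
#' @return An object of the same class with permuted labels.
#' @export
#' @examples
#' ps <- generateFixture(5, 5, seed = 1)
#' peptideLabels(permuteLabels(ps, seed = 2))
setGeneric("permuteLabels", function(x, seed = 1L)
  standardGeneric("permuteLabels"))

#' @rdname permuteLabels
#' @export
setMethod("permuteLabels", "PeptideSet", function(x, seed = 1L) {
  if (!length(x@label)) stop("no labels to permute")
  new("PeptideSet", seqs = x@seqs,
      label = withSeed(seed, sample(x@label)), datasetName = x@datasetName)
})

#' @rdname permuteLabels
#' @export
setMethod("permuteLabels", "FeatureMatrix", function(x, seed = 1L) {
  if (!length(x@label)) stop("no labels to permute")
  new("FeatureMatrix", values = x@values,
      label = withSeed(seed, sample(x@label)),
      layoutVersion = x@layoutVersion)
})

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin so fold sizes differ by at most one per class.
stratifiedFolds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  withSeed(seed, {
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      folds[idx[sample.int(length(idx))]] <-
        rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Stratified k-fold cross-validation
#'
#' Splits a labeled dataset into k stratified folds, trains on k-1 folds
#' and scores the held-out fold, then computes the report metrics once on
#' the pooled out-of-fold predictions (per-fold metrics are retained in
#' `perFoldReports`). Both encoders are stateless, so encoding the full
#' dataset once before splitting cannot leak information across folds. The
#' fold seed is independent of the model seed in `config`.
#'
#' @param x A labeled [PeptideSet-class], or an already encoded labeled
#'   [FeatureMatrix-class] (then `encoders` is ignored).
#' @param encoders Encoder list for [encodeDataset()].
#' @param config Model configuration ([modelConfig()]).
#' @param k Number of folds (default 10); each class must have at least k
#'   records.
#' @param seed Fold-assignment seed.
#' @return An [EvalReport-class] with protocol `cv<k>`.
#' @export
#' @examples
#' ps <- generateFixture(20, 20, seed = 1, bias = c(K = 4, R = 4))
#' crossValidate(ps, list(encoder188()), k = 4)
crossValidate <- function(x, encoders = list(encoder188()),
                          config = modelConfig(), k = 10L, seed = 1L) {
  fm <- if (is(x, "FeatureMatrix")) x else encodeDataset(x, encoders)
  y <- peptideLabels(fm)
  if (length(y) == 0L) stop("cross-validation requires labels")
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  if (min(table(y)) < k)
    stop(sprintf("each class needs at least k=%d records", k))
  folds <- stratifiedFolds(y, k, seed)
  n <- nrow(fm)
  score <- numeric(n); call <- character(n)
  perFold <- vector("list", k)
  for (f in seq_len(k)) {
    hold <- folds == f
    fit <- acpTrain(fm[which(!hold)], config)
    pred <- acpPredict(fit, fm[which(hold)])
    score[hold] <- pred$score
    call[hold] <- as.character(pred$call)
    cm <- classMetrics(confusionFromCalls(y[hold], pred$call))
    perFold[[f]] <- data.frame(fold = f, n = sum(hold),
                               se = cm[["se"]], sp = cm[["sp"]],
                               acc = cm[["acc"]], mcc = cm[["mcc"]],
                               auc = aucScore(pred$score, y[hold]))
  }
  evalReport(y, score, call, protocol = sprintf("cv%d", k),
             perFold = do.call(rbind, perFold))
}

#' Independent-test evaluation
#'
#' One fit on the training set, one evaluation on the test set. Record ids
#' shared between the two sets are flagged (warn-only): `train == test` is
#' resubstitution, not generalization.
#'
#' @param train,test Labeled [PeptideSet-class] objects.
#' @param encoders Encoder list applied to both sets.
#' @param config Model configuration.
#' @return An [EvalReport-class] with protocol `independent`.
#' @export
independentTest <- function(train, test, encoders = list(encoder188()),
                            config = modelConfig()) {
  stopifnot(is(train, "PeptideSet"), is(test, "PeptideSet"))
  notes <- character(0)
  shared <- intersect(names(train), names(test))
  if (length(shared)) {
    notes <- sprintf("%d record id(s) shared between train and test%s",
                     length(shared),
                     if (length(shared) == length(test))
                       " (resubstitution)" else "")
    warning(notes)
  }
  fit <- acpTrain(encodeDataset(train, encoders), config)
  testFm <- encodeDataset(test, encoders)
  pred <- acpPredict(fit, testFm)
  evalReport(peptideLabels(test), pred$score, pred$call,
             protocol = "independent", notes = notes)
}

#' Format an evaluation report as a one-row table
#'
#' Percent formatting with one decimal place (90.4, not 0.904), columns in
#' the order SE, SP, ACC, MCC, AUC; internal values remain proportions.
#'
#' @param x An [EvalReport-class] or a named list of them (one row each).
#' @return A data.frame with columns `SE`, `SP`, `ACC`, `MCC`, `AUC`.
#' @export
reportTable <- function(x) {
  if (is(x, "EvalReport")) x <- list(report = x)
  rows <- lapply(x, function(r) {
    m <- evalMetrics(r)
    data.frame(SE = round(100 * m[["se"]], 1),
               SP = round(100 * m[["sp"]], 1),
               ACC = round(100 * m[["acc"]], 1),
               MCC = round(100 * m[["mcc"]], 1),
               AUC = round(100 * m[["auc"]], 1))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(x)
  out
}

#' @rdname reportTable
#' @param path Output file path.
#' @return `writeReportTSV`: `path` invisibly.
#' @export
writeReportTSV <- function(x, path) {
  tab <- reportTable(x)
  utils::write.table(cbind(model = rownames(tab), tab), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Classifier / feature sweep harness
#'
#' Runs cross-validation for each named configuration through the shared
#' interface, enabling feature-set and classifier comparisons.
#'
#' @param ds Labeled [PeptideSet-class].
#' @param configs Named list of `ACPModelConfig` objects.
#' @param encoders Encoder list.
#' @inheritParams crossValidate
#' @return Named list of [EvalReport-class] objects (pass to
#'   [reportTable()]).
#' @export
sweepClassifiers <- function(ds, configs, encoders = list(encoder188()),
                             k = 10L, seed = 1L) {
  fm <- encodeDataset(ds, encoders)
  lapply(configs, function(cfg)
    crossValidate(fm, config = cfg, k = k, seed = seed))
}
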