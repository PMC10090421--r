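# Independent brute-force oracles. Deliberately written as explicit loops,
# not vectorized, so they share no code path with the implementation.

randomPeptide <- function(lenRange = c(10L, 50L)) {
  L <- sample(seq.int(lenRange[1], lenRange[2]), 1L)
  paste(sample(aminoAcids(), L, replace = TRUE), collapse = "")
}

# CTD oracle: explicit residue loop, explicit pair loop, explicit sorted
# occurrence lists for the distribution block.
oracleCTD21 <- function(seq, grouping) {
  res <- strsplit(seq, "")[[1]]
  L <- length(res)
  groupOf <- function(ch) {
    for (gi in 1:3) if (ch %in% grouping[[gi]]) return(gi)
    stop("residue outside alphabet")
  }
  g <- vapply(res, groupOf, integer(1))

  comp <- numeric(3)
  for (i in seq_len(L)) comp[g[i]] <- comp[g[i]] + 1
  comp <- comp / L

  trans <- numeric(3)
  if (L > 1) {
    for (i in seq_len(L - 1)) {
      pair <- sort(c(g[i], g[i + 1]))
      if (pair[1] == 1 && pair[2] == 2) trans[1] <- trans[1] + 1
      if (pair[1] == 1 && pair[2] == 3) trans[2] <- trans[2] + 1
      if (pair[1] == 2 && pair[2] == 3) trans[3] <- trans[3] + 1
    }
    trans <- trans / (L - 1)
  }

  distr <- numeric(15)
  for (gi in 1:3) {
    occ <- sort(which(g == gi))
    n <- length(occ)
    if (n > 0) {
      ks <- c(1,
              max(1, ceiling(n * 0.25)),
              max(1, ceiling(n * 0.50)),
              max(1, ceiling(n * 0.75)),
              n)
      for (q in 1:5) distr[(gi - 1) * 5 + q] <- occ[ks[q]] / L
    }
  }
  c(comp, trans, distr)
}

# Metric oracle: expand counts to raw (truth, call) pairs and recount.
oracleMetricsFromCounts <- function(tp, fp, tn, fn) {
  truth <- c(rep(1, tp), rep(0, fp), rep(0, tn), rep(1, fn))
  call <- c(rep(1, tp), rep(1, fp), rep(0, tn), rep(0, fn))
  TP <- 0; FP <- 0; TN <- 0; FN <- 0
  for (i in seq_along(truth)) {
    if (truth[i] == 1 && call[i] == 1) TP <- TP + 1
    if (truth[i] == 0 && call[i] == 1) FP <- FP + 1
    if (truth[i] == 0 && call[i] == 0) TN <- TN + 1
    if (truth[i] == 1 && call[i] == 0) FN <- FN + 1
  }
  c(se = TP / (TP + FN), sp = TN / (TN + FP),
    acc = (TP + TN) / (TP + TN + FP + FN),
    mcc = (TP * TN - FP * FN) /
      sqrt((TP + FN) * (TP + FP) * (TN + FP) * (TN + FN)))
}

# AUC oracle: enumerate all positive-negative pairs; ties count half.
oracleAUCpairs <- function(scores, labels01) {
  pos <- scores[labels01 == 1]
  neg <- scores[labels01 == 0]
  wins <- 0
  for (p in pos) for (n in neg) {
    if (p > n) wins <- wins + 1
    else if (p == n) wins <- wins + 0.5
  }
  wins / (length(pos) * length(neg))
}

# AUC oracle 2: trapezoidal integration of the empirical ROC curve.
trapezoidAUC <- function(scores, labels01) {
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  nPos <- sum(labels01 == 1); nNeg <- sum(labels01 == 0)
  tpr <- fpr <- numeric(length(thr))
  for (i in seq_along(thr)) {
    tpr[i] <- sum(scores >= thr[i] & labels01 == 1) / nPos
    fpr[i] <- sum(scores >= thr[i] & labels01 == 0) / nNeg
  }
  auc <- 0
  for (i in seq_len(length(thr) - 1))
    auc <- auc + (fpr[i + 1] - fpr[i]) * (tpr[i + 1] + tpr[i]) / 2
  auc
}

miniEncoders <- function() list(encoder188(), encoderAAIndex(aaindexMini()))

evalReportForTest <- function() {
  counts <- c(TP = 45L, FP = 10L, TN = 40L, FN = 5L)
  new("EvalReport", counts = counts,
      metrics = c(classMetrics(counts), auc = 0.9),
      protocol = "independent", perFold = data.frame(),
      notes = character(0))
}

writeTempFasta <- function(lines) {
  fa <- tempfile(fileext = ".fasta")
  writeLines(lines, fa)
  fa
}
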