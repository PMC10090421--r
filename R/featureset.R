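#' Encoder descriptors for encodeDataset
#'
#' An encoder is a plain list with fields `name` (provenance prefix), `dim`
#' (output length), and `encode` (function from one sequence string to a
#' named numeric vector). `encoder188()` wraps [encode188()];
#' `encoderAAIndex()` wraps [encodeAAIndex()] for a given property table.
#' Additional descriptors can be plugged in by constructing the same
#' structure.
#'
#' @param groupings Grouping tables for the 188D encoder (default
#'   [ctdGroupings()]).
#' @return An object of class `ACPEncoder`.
#' @export
#' @examples
#' enc <- encoder188()
#' enc$dim
encoder188 <- function(groupings = ctdGroupings()) {
  if (length(groupings) != 8L) stop("exactly 8 grouping tables are required")
  for (p in names(groupings)) checkGrouping(groupings[[p]], p)
  structure(list(name = "d188", dim = 188L,
                 layout = "d188/v1",
                 encode = function(seq) encode188(seq, groupings)),
            class = "ACPEncoder")
}

#' @rdname encoder188
#' @param table An [AAIndexTable-class] for the AAindex encoder.
#' @export
encoderAAIndex <- function(table) {
  stopifnot(is(table, "AAIndexTable"))
  P <- length(table)
  ids <- propertyIds(table)
  structure(list(name = "aaidx", dim = 20L * P,
                 layout = sprintf("aaidx/v1/P%d/%s..%s", P, ids[1], ids[P]),
                 encode = function(seq) encodeAAIndex(seq, table)),
            class = "ACPEncoder")
}

#' Encode a dataset into a feature matrix
#'
#' Applies an ordered list of encoders to every record and concatenates
#' their outputs column-wise: row i is the merged descriptor of record i, in
#' dataset order (no sorting). Column names are prefixed with the encoder
#' name (`d188:...`, `aaidx:...`). The merged configuration used throughout
#' the package is the 188D block first, the AAindex block second.
#'
#' @param ds A [PeptideSet-class].
#' @param encoders List of encoders from [encoder188()] /
#'   [encoderAAIndex()], applied in order.
#' @return A [FeatureMatrix-class] of dimension `length(ds)` x
#'   `sum(dims)`, carrying the dataset labels and a layout fingerprint.
#' @export
#' @examples
#' ps <- generateFixture(3, 3, seed = 1)
#' fm <- encodeDataset(ps, list(encoder188()))
#' dim(featureValues(fm))
encodeDataset <- function(ds, encoders = list(encoder188())) {
  stopifnot(is(ds, "PeptideSet"), length(encoders) >= 1L)
  ok <- vapply(encoders, function(e) inherits(e, "ACPEncoder"), logical(1))
  if (!all(ok)) stop("encoders must be ACPEncoder objects")
  seqs <- as.character(peptides(ds))
  colNames <- unlist(lapply(encoders, function(e) {
    probe <- names(e$encode("ACDEFGHIKL"))
    if (length(probe) != e$dim) stop("encoder '", e$name,
                                     "' dimension mismatch")
    paste0(e$name, ":", probe)
  }))
  layout <- paste(vapply(encoders, `[[`, character(1), "layout"),
                  collapse = "+")
  m <- matrix(0, nrow = length(seqs), ncol = length(colNames),
              dimnames = list(names(ds), colNames))
  for (i in seq_along(seqs)) {
    row <- tryCatch(
      unlist(lapply(encoders, function(e) e$encode(seqs[i]))),
      error = function(e)
        stop(sprintf("encoding failed for record '%s': %s",
                     names(ds)[i], conditionMessage(e)), call. = FALSE))
    m[i, ] <- row
  }
  new("FeatureMatrix", values = m, label = peptideLabels(ds),
      layoutVersion = layout)
}

#' @rdname FeatureMatrix-class
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) x@values)

#' @rdname FeatureMatrix-class
#' @export
setMethod("layoutVersion", "FeatureMatrix", function(x) x@layoutVersion)

#' @rdname FeatureMatrix-class
#' @export
setMethod("peptideLabels", "FeatureMatrix", function(x) x@label)

#' @rdname FeatureMatrix-class
#' @export
setMethod("dim", "FeatureMatrix", function(x) dim(x@values))

#' @rdname FeatureMatrix-class
#' @param i Row index vector.
#' @param j,...,drop Ignored (column slicing would change the layout).
#' @export
setMethod("[", "FeatureMatrix", function(x, i, j, ..., drop = TRUE) {
  lab <- if (length(x@label)) x@label[i] else x@label
  new("FeatureMatrix", values = x@values[i, , drop = FALSE], label = lab,
      layoutVersion = x@layoutVersion)
})

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d peptide(s) x %d feature(s)\n",
              nrow(object@values), ncol(object@values)))
  cat("  layout:", object@layoutVersion, "\n")
  if (length(object@label))
    cat(sprintf("  labeled: %d ACP / %d non-ACP\n",
                sum(object@label == "ACP"), sum(object@label == "non-ACP")))
})

#' Export / import a feature matrix as CSV
#'
#' Human-auditable serialization: a `# layout: <version>` comment line, then
#' a header row and one row per peptide with `id` and (when labeled)
#' `label` columns before the features. `readFeatureCSV` restores the
#' identical [FeatureMatrix-class].
#'
#' @param x A [FeatureMatrix-class].
#' @param path CSV file path.
#' @return `writeFeatureCSV`: `path` invisibly. `readFeatureCSV`: a
#'   [FeatureMatrix-class].
#' @export
writeFeatureCSV <- function(x, path) {
  stopifnot(is(x, "FeatureMatrix"))
  df <- data.frame(id = rownames(x@values), check.names = FALSE)
  if (length(x@label)) df$label <- as.character(x@label)
  df <- cbind(df, as.data.frame(x@values, check.names = FALSE))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# layout: ", x@layoutVersion), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureCSV
#' @export
readFeatureCSV <- function(path) {
  first <- readLines(path, n = 1L, encoding = "UTF-8")
  if (!grepl("^# layout: ", first)) stop("missing '# layout:' header line")
  layout <- sub("^# layout: ", "", first)
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  lab <- if ("label" %in% colnames(df)) df$label else NULL
  feats <- setdiff(colnames(df), c("id", "label"))
  m <- as.matrix(df[, feats, drop = FALSE])
  rownames(m) <- df$id
  new("FeatureMatrix", values = m,
      label = normalizeLabels(lab, nrow(m)), layoutVersion = layout)
}
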