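#' Construct a PeptideSet
#'
#' Validates, uppercases and assembles peptide sequences into a
#' [PeptideSet-class]. Lowercase letters are uppercased silently; any
#' character outside the 20-letter alphabet (including B, J, O, U, X, Z and
#' gap symbols) is a hard error, because both encoders are undefined for
#' such residues.
#'
#' @param sequences Character vector of sequences, or an
#'   [Biostrings::AAStringSet].
#' @param ids Record identifiers; taken from `names(sequences)` when `NULL`.
#' @param label `NULL` for an unlabeled set, or a vector coercible to the
#'   levels `non-ACP`/`ACP` — either one value per record or a single value
#'   recycled to all records. `TRUE`/`"positive"`/`"ACP"`/`1` mean the
#'   anticancer class.
#' @param name Dataset name.
#' @param strictLength When `TRUE`, enforce the typical anticancer-peptide
#'   length range 10--50; by default out-of-range lengths are accepted
#'   (published datasets may contain outliers).
#'
#' @return A [PeptideSet-class].
#' @export
#' @examples
#' ps <- PeptideSet(c(p1 = "ACDE", p2 = "KKRW"), label = "ACP")
#' nPositive(ps)
PeptideSet <- function(sequences, ids = NULL, label = NULL,
                       name = "peptides", strictLength = FALSE) {
  if (is(sequences, "AAStringSet")) sequences <- as.character(sequences)
  if (!is.character(sequences))
    stop("'sequences' must be character or an AAStringSet")
  if (is.null(ids)) ids <- names(sequences)
  if (length(sequences) > 0 && is.null(ids))
    stop("record ids are required (names of 'sequences' or 'ids')")
  sequences <- toupper(unname(sequences))
  for (i in seq_along(sequences)) {
    if (!nzchar(sequences[i]))
      stop(sprintf("record '%s': empty sequence", ids[i]))
    bad <- invalidResidues(sequences[i])
    if (length(bad))
      stop(sprintf("record '%s': character(s) %s outside the 20-letter amino-acid alphabet",
                   ids[i], paste0("'", bad, "'", collapse = ", ")))
  }
  if (strictLength) {
    len <- nchar(sequences)
    off <- which(len < 10L | len > 50L)
    if (length(off))
      stop(sprintf("strict length check failed for record(s) %s (length outside 10-50)",
                   paste0("'", ids[off], "'", collapse = ", ")))
  }
  lab <- normalizeLabels(label, length(sequences))
  new("PeptideSet",
      seqs = Biostrings::AAStringSet(stats::setNames(sequences, ids)),
      label = lab, datasetName = name)
}

# Coerce user-supplied labels to the canonical factor; NULL -> length-0.
normalizeLabels <- function(label, n) {
  if (is.null(label) || length(label) == 0L)
    return(factor(character(0), levels = .LABEL_LEVELS))
  if (is.logical(label)) label <- ifelse(label, "ACP", "non-ACP")
  if (is.numeric(label)) label <- ifelse(label > 0, "ACP", "non-ACP")
  label <- as.character(label)
  label[label %in% c("positive", "pos", "1")] <- "ACP"
  label[label %in% c("negative", "neg", "0", "non-acp", "nonACP")] <- "non-ACP"
  if (!all(label %in% .LABEL_LEVELS))
    stop("labels must be coercible to non-ACP/ACP; got: ",
         paste(setdiff(unique(label), .LABEL_LEVELS), collapse = ", "))
  if (length(label) == 1L) label <- rep(label, n)
  if (length(label) != n)
    stop("label must be a single value or one per record")
  factor(label, levels = .LABEL_LEVELS)
}

#' @rdname PeptideSet-class
#' @export
setMethod("peptides", "PeptideSet", function(x) x@seqs)

#' @rdname PeptideSet-class
#' @export
setMethod("peptideLabels", "PeptideSet", function(x) x@label)

#' @rdname PeptideSet-class
#' @export
setMethod("datasetName", "PeptideSet", function(x) x@datasetName)

#' @rdname PeptideSet-class
#' @export
setMethod("nPositive", "PeptideSet",
          function(x) sum(x@label == "ACP"))

#' @rdname PeptideSet-class
#' @export
setMethod("nNegative", "PeptideSet",
          function(x) sum(x@label == "non-ACP"))

#' @rdname PeptideSet-class
#' @export
setMethod("length", "PeptideSet", function(x) length(x@seqs))

#' @rdname PeptideSet-class
#' @export
setMethod("names", "PeptideSet", function(x) names(x@seqs))

#' @rdname PeptideSet-class
#' @param i Index vector.
#' @param j,...,drop Ignored.
#' @export
setMethod("[", "PeptideSet", function(x, i, j, ..., drop = TRUE) {
  lab <- if (length(x@label)) x@label[i] else x@label
  new("PeptideSet", seqs = x@seqs[i], label = lab,
      datasetName = x@datasetName)
})

#' Concatenate PeptideSets
#'
#' Used e.g. to combine one-FASTA-per-class files into a labeled dataset.
#' All sets must be labeled, or none.
#'
#' @param x,... `PeptideSet` objects.
#' @return A combined [PeptideSet-class] named after `x`.
#' @export
setMethod("c", "PeptideSet", function(x, ...) {
  sets <- c(list(x), list(...))
  labeled <- vapply(sets, function(s) length(s@label) > 0L, logical(1))
  if (any(labeled) && !all(labeled))
    stop("cannot combine labeled and unlabeled PeptideSets")
  lab <- if (all(labeled))
    factor(unlist(lapply(sets, function(s) as.character(s@label))),
           levels = .LABEL_LEVELS)
  else factor(character(0), levels = .LABEL_LEVELS)
  new("PeptideSet",
      seqs = do.call(c, lapply(sets, function(s) s@seqs)),
      label = lab, datasetName = x@datasetName)
})

setMethod("show", "PeptideSet", function(object) {
  cat(sprintf("PeptideSet '%s': %d sequence(s)\n",
              object@datasetName, length(object)))
  if (length(object@label))
    cat(sprintf("  labeled: %d ACP / %d non-ACP\n",
                nPositive(object), nNegative(object)))
  else cat("  unlabeled\n")
  if (length(object))
    cat(sprintf("  lengths: %d-%d\n",
                min(Biostrings::width(object@seqs)),
                max(Biostrings::width(object@seqs))))
})

#' Read peptides from a FASTA file
#'
#' Reads plain FASTA (wrapped or unwrapped lines), uppercases sequences and
#' validates them against the 20-letter alphabet. Labels follow the
#' one-file-per-class layout: pass `label` to apply one class to every
#' record, or attach a sidecar table afterwards with [applyLabels()].
#'
#' @param path FASTA file path.
#' @inheritParams PeptideSet
#' @param name Dataset name; defaults to the file name.
#' @return A [PeptideSet-class].
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "ACDE", ">p2", "KKRW"), fa)
#' readPeptideFasta(fa, label = "ACP")
readPeptideFasta <- function(path, label = NULL, name = basename(path),
                             strictLength = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) stop("empty FASTA file: ", path)
  aas <- Biostrings::readAAStringSet(path)
  if (length(aas) == 0L) stop("no FASTA records in: ", path)
  ids <- vapply(strsplit(names(aas), "[ \t]"), `[`, character(1), 1L)
  PeptideSet(as.character(aas), ids = ids, label = label, name = name,
             strictLength = strictLength)
}

#' Write a PeptideSet to FASTA
#'
#' Sequences are written unwrapped, one line per record.
#'
#' @param x A [PeptideSet-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writePeptideFasta <- function(x, path) {
  stopifnot(is(x, "PeptideSet"))
  Biostrings::writeXStringSet(x@seqs, path, width = 20000L)
  invisible(path)
}

#' Attach labels from a sidecar table
#'
#' Secondary label dialect: a two-column TSV (id, label; no header) mapping
#' record ids to classes.
#'
#' @param x A [PeptideSet-class].
#' @param path Path to the TSV sidecar.
#' @return A labeled [PeptideSet-class] in the original record order.
#' @export
applyLabels <- function(x, path) {
  stopifnot(is(x, "PeptideSet"))
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("id", "label"),
                           colClasses = "character", quote = "",
                           fileEncoding = "UTF-8")
  miss <- setdiff(names(x), tab$id)
  if (length(miss))
    stop("no label for record(s): ", paste(miss, collapse = ", "))
  lab <- tab$label[match(names(x), tab$id)]
  new("PeptideSet", seqs = x@seqs,
      label = normalizeLabels(lab, length(x)),
      datasetName = x@datasetName)
}

#' Generate a synthetic labeled peptide dataset
#'
#' Emits random peptides over the 20-letter alphabet with lengths uniform on
#' `lenRange`, split into a positive (ACP) and a negative class. With `bias`,
#' positive-class residues are drawn from a composition re-weighted towards
#' the named residues, so a classifier can beat chance; the default bias
#' example `c(K = 3, R = 3)` mimics the cationic character of real
#' anticancer peptides. Deterministic under a fixed seed: the generator is a
#' pure function of its arguments.
#'
#' @param nPos,nNeg Number of positive / negative records.
#' @param lenRange Integer length range (inclusive), within `[1, 1000]`.
#' @param seed RNG seed.
#' @param bias `NULL` for identically distributed classes, or a named
#'   numeric vector of sampling-weight multipliers applied to the positive
#'   class (baseline weight 1 per residue).
#' @param name Dataset name.
#' @return A labeled [PeptideSet-class] with `nPos + nNeg` records
#'   (positives first).
#' @export
#' @examples
#' ps <- generateFixture(5, 5, seed = 7)
#' nPositive(ps)
generateFixture <- function(nPos, nNeg, lenRange = c(10L, 50L), seed = 1L,
                            bias = NULL, name = "fixture") {
  stopifnot(nPos >= 0, nNeg >= 0, length(lenRange) == 2L,
            lenRange[1] >= 1, lenRange[2] <= 1000,
            lenRange[1] <= lenRange[2])
  aa <- aminoAcids()
  wNeg <- stats::setNames(rep(1, 20), aa)
  wPos <- wNeg
  if (!is.null(bias)) {
    if (is.null(names(bias)) || !all(names(bias) %in% aa))
      stop("bias must be named by amino-acid letters")
    if (any(bias < 0)) stop("bias weights must be non-negative")
    wPos[names(bias)] <- bias
  }
  drawSeqs <- function(n, w, prefix) {
    if (n == 0) return(character(0))
    lens <- sample(seq.int(lenRange[1], lenRange[2]), n, replace = TRUE)
    s <- vapply(lens, function(L)
      paste(sample(aa, L, replace = TRUE, prob = w / sum(w)), collapse = ""),
      character(1))
    stats::setNames(s, sprintf("%s_%s_%04d", name, prefix, seq_len(n)))
  }
  withSeed(seed, {
    pos <- drawSeqs(nPos, wPos, "ACP")
    neg <- drawSeqs(nNeg, wNeg, "nonACP")
  })
  PeptideSet(c(pos, neg),
             label = rep(c("ACP", "non-ACP"), c(nPos, nNeg)),
             name = name)
}
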