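# AAindex1 "I" records list values in this residue order (two lines of 10).
.AAINDEX1_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                     "L", "K", "M", "F", "P", "S", "T", "V", "W", "Y")

#' Construct an AAIndexTable
#'
#' @param values Numeric matrix or data.frame, properties x 20, with
#'   property accessions as rownames and amino-acid one-letter codes as
#'   colnames (any column order; reordered to [aminoAcids()]).
#' @return An [AAIndexTable-class].
#' @export
#' @examples
#' m <- matrix(rnorm(40), 2, 20, dimnames = list(c("P1", "P2"), aminoAcids()))
#' aaindexTable(m)
aaindexTable <- function(values) {
  values <- as.matrix(values)
  if (is.null(colnames(values)) ||
      !setequal(colnames(values), aminoAcids()))
    stop("columns must be the 20 amino-acid letters")
  new("AAIndexTable", values = values[, aminoAcids(), drop = FALSE])
}

#' @rdname AAIndexTable-class
#' @export
setMethod("propertyIds", "AAIndexTable", function(x) rownames(x@values))

#' @rdname AAIndexTable-class
#' @export
setMethod("length", "AAIndexTable", function(x) nrow(x@values))

setMethod("show", "AAIndexTable", function(object) {
  cat(sprintf("AAIndexTable: %d propertie(s) x 20 amino acids\n",
              nrow(object@values)))
  ids <- rownames(object@values)
  cat("  ", paste(utils::head(ids, 5), collapse = ", "),
      if (length(ids) > 5) ", ...", "\n", sep = "")
})

#' Read an AAindex table from the TSV fixture dialect
#'
#' Tab-separated, one property per row: a `property_id` column followed by
#' 20 columns headed by the amino-acid letters. Properties containing any
#' missing value are dropped with a message; retaining zero properties is an
#' error.
#'
#' @param path TSV file path.
#' @return An [AAIndexTable-class]; property order is file order.
#' @export
readAAIndexTSV <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, quote = "",
                           na.strings = c("NA", ""), fileEncoding = "UTF-8")
  if (!"property_id" %in% colnames(tab))
    stop("TSV must have a 'property_id' column")
  m <- as.matrix(tab[, setdiff(colnames(tab), "property_id"), drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- tab$property_id
  dropIncompleteProperties(m)
}

dropIncompleteProperties <- function(m) {
  keep <- apply(m, 1L, function(r) all(is.finite(r)))
  if (any(!keep))
    message(sum(!keep), " propertie(s) dropped for missing values: ",
            paste(utils::head(rownames(m)[!keep], 5), collapse = ", "))
  if (!any(keep)) stop("zero properties retained after NA filtering")
  aaindexTable(m[keep, , drop = FALSE])
}

#' Read an AAindex1 flat file
#'
#' Parses the H/I record structure of the AAindex1 database release: each
#' entry's accession from its `H` line and its 20 values from the two lines
#' following `I` (residue order A R N D C Q E G H I / L K M F P S T V W Y).
#' Entries with `NA` values are dropped as in [readAAIndexTSV()].
#'
#' @param path AAindex1 flat-file path.
#' @return An [AAIndexTable-class]; property order is file order.
#' @export
readAAIndex1 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  hs <- grep("^H ", lines)
  if (!length(hs)) stop("no AAindex1 'H' records found in: ", path)
  ids <- character(0)
  rows <- list()
  for (h in hs) {
    acc <- trimws(sub("^H ", "", lines[h]))
    iLine <- h + which(grepl("^I ", lines[(h + 1):length(lines)]))[1]
    if (is.na(iLine) || iLine + 2 > length(lines))
      stop("unparseable AAindex1 record: ", acc)
    vals <- suppressWarnings(as.numeric(unlist(
      strsplit(trimws(lines[c(iLine + 1, iLine + 2)]), "[ \t]+"))))
    if (length(vals) != 20L)
      stop("unparseable AAindex1 record (expected 20 values): ", acc)
    ids <- c(ids, acc)
    rows[[length(rows) + 1L]] <- vals
  }
  m <- do.call(rbind, rows)
  dimnames(m) <- list(ids, .AAINDEX1_ORDER)
  dropIncompleteProperties(m[, aminoAcids(), drop = FALSE])
}

#' The full AAindex1 property table
#'
#' Builds the complete AAindex1 table from the copy of the database
#' distributed with the seqinr package (544 indices; the 13 indices with
#' missing values are dropped, leaving 531 complete properties). Use this
#' for full-scale encoding; unit-scale work can use the small TSV fixture
#' shipped under `extdata`.
#'
#' @return An [AAIndexTable-class] with 531 properties.
#' @export
aaindexFull <- function() {
  env <- new.env()
  utils::data("aaindex", package = "seqinr", envir = env)
  aaidx <- env$aaindex
  three <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
             Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
             Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
             Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V")
  m <- t(vapply(aaidx, function(p) {
    v <- p$I
    names(v) <- three[names(v)]
    v[aminoAcids()]
  }, numeric(20)))
  colnames(m) <- aminoAcids()
  rownames(m) <- vapply(aaidx, function(p) p$H, character(1))
  suppressMessages(dropIncompleteProperties(m))
}

#' Bundled small AAindex fixture table
#'
#' Six classical complete indices (Kyte-Doolittle hydropathy, Hopp-Woods
#' hydrophilicity, molecular weight, isoelectric point, residue volume, net
#' charge) shipped as a TSV under `extdata`; the file also carries one
#' deliberately incomplete property that is dropped on load. Suitable for
#' unit-scale merged encoding without the full database.
#'
#' @return An [AAIndexTable-class] with 6 properties.
#' @export
#' @examples
#' length(aaindexMini())
aaindexMini <- function() {
  suppressMessages(readAAIndexTSV(
    system.file("extdata", "aaindex_mini.tsv", package = "acpGBDT",
                mustWork = TRUE)))
}

#' Truncate a sequence to its first ten plus last ten residues
#'
#' The AAindex encoder requires equal-length input; variable-length peptides
#' are reduced to the first `min(10, L)` plus last `min(10, L)` residues
#' (for `10 <= L < 20` the overlap is duplicated). Only when `L < 10` is the
#' result shorter than 20; it is then right-padded with the pad symbol `-`,
#' which contributes 0 for every property, and flagged in `padMask`.
#'
#' @param seq A single validated sequence string.
#' @return List with `residues` (length-20 string, possibly containing `-`
#'   pads) and `padMask` (logical vector of 20, `TRUE` at pad positions).
#' @export
#' @examples
#' truncate20("ACDEFGHIKLMN")$residues
truncate20 <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) stop("empty sequence")
  res <- splitResidues(seq)
  L <- length(res)
  k <- min(10L, L)
  out <- c(res[seq_len(k)], res[seq.int(L - k + 1L, L)])
  pad <- rep(FALSE, 20L)
  if (length(out) < 20L) {
    pad[(length(out) + 1L):20L] <- TRUE
    out <- c(out, rep("-", 20L - length(out)))
  }
  list(residues = paste(out, collapse = ""), padMask = pad)
}

#' Encode a peptide with per-residue AAindex values
#'
#' After truncation to 20 residues ([truncate20()]), each position is
#' replaced by its P property values; the layout is position-major (all P
#' values of position 1, then position 2, ...), giving a vector of length
#' `20 * P`. Pad positions contribute 0 for every property. The encoding
#' depends only on the first ten and last ten residues of the source
#' sequence.
#'
#' @param seq A single validated sequence string.
#' @param table An [AAIndexTable-class].
#' @return Named numeric vector of length `20 * length(table)`.
#' @export
#' @examples
#' tbl <- aaindexTable(matrix(1:20, 1, 20,
#'   dimnames = list("P1", aminoAcids())))
#' length(encodeAAIndex("GLFDIIKKIAESF", tbl))
encodeAAIndex <- function(seq, table) {
  stopifnot(is(table, "AAIndexTable"))
  t20 <- truncate20(seq)
  res <- splitResidues(t20$residues)
  P <- nrow(table@values)
  vals <- matrix(0, nrow = P, ncol = 20L)
  real <- !t20$padMask
  vals[, real] <- table@values[, res[real], drop = FALSE]
  nm <- paste0(rep(sprintf("pos%02d", 1:20), each = P), "_",
               rep(rownames(table@values), 20L))
  stats::setNames(as.vector(vals), nm)
}
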