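#' @import methods
#' @importFrom Biostrings AAStringSet readAAStringSet writeXStringSet width
#' @importFrom BiocGenerics width
NULL

#' The 20-letter amino-acid alphabet, alphabetical order
#'
#' Canonical residue order used for composition vectors and AAindex tables.
#' Both encoders are undefined outside this alphabet.
#'
#' @return Character vector of the 20 standard one-letter amino-acid codes.
#' @export
#' @examples
#' aminoAcids()
aminoAcids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

.LABEL_LEVELS <- c("non-ACP", "ACP")

#' PeptideSet: labeled peptide sequences
#'
#' An ordered collection of validated peptide sequences (20-letter alphabet)
#' with unique identifiers and an optional binary anticancer/non-anticancer
#' label. Either every record is labeled or none is.
#'
#' @slot seqs An [Biostrings::AAStringSet] of validated sequences; names are
#'   the record ids.
#' @slot label Factor with levels `non-ACP`, `ACP`; length 0 (unlabeled) or
#'   one per sequence.
#' @slot datasetName Single string naming the dataset (e.g. `"Train-500"`).
#'
#' @seealso [PeptideSet()], [readPeptideFasta()], [generateFixture()]
#' @export
setClass("PeptideSet",
  slots = c(seqs = "AAStringSet", label = "factor", datasetName = "character"))

setValidity("PeptideSet", function(object) {
  n <- length(object@seqs)
  ids <- names(object@seqs)
  if (n > 0 && (is.null(ids) || any(!nzchar(ids))))
    return("every record needs a non-empty id")
  if (anyDuplicated(ids))
    return(paste0("duplicate record ids: ",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (n > 0 && any(Biostrings::width(object@seqs) < 1L))
    return("zero-length sequence")
  if (!identical(levels(object@label), .LABEL_LEVELS))
    return(sprintf("label levels must be %s",
                   paste(.LABEL_LEVELS, collapse = "/")))
  if (length(object@label) != 0L && length(object@label) != n)
    return("label must be absent or one per record")
  if (anyNA(object@label))
    return("label must not contain NA (drop labels entirely instead)")
  if (length(object@datasetName) != 1L)
    return("datasetName must be a single string")
  TRUE
})

#' AAIndexTable: amino-acid physicochemical index table
#'
#' A set of AAindex-style properties, each assigning one finite numeric value
#' to each of the 20 amino acids. Property order is fixed (file order) and
#' determines feature-column order; properties with missing values are
#' dropped at load time.
#'
#' @slot values Numeric matrix, properties x 20; rownames are property
#'   accessions, colnames the alphabet of [aminoAcids()].
#'
#' @seealso [aaindexTable()], [readAAIndexTSV()], [readAAIndex1()],
#'   [aaindexFull()]
#' @export
setClass("AAIndexTable", slots = c(values = "matrix"))

setValidity("AAIndexTable", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be numeric")
  if (!identical(colnames(v), aminoAcids()))
    return("columns must be the 20 amino acids in alphabetical order")
  if (nrow(v) < 1L) return("no properties retained")
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    return("property ids must be present and unique")
  if (!all(is.finite(v))) return("all property values must be finite")
  TRUE
})

#' FeatureMatrix: encoded peptides with stable column provenance
#'
#' Dense numeric matrix of n peptides x d features. Column names carry an
#' encoder provenance prefix (`d188:` or `aaidx:`); `layoutVersion`
#' fingerprints the encoder configuration so a model trained on one layout
#' refuses differently encoded input.
#'
#' @slot values Numeric matrix; rownames are peptide ids, colnames unique
#'   feature names.
#' @slot label Factor as in [PeptideSet-class]; length 0 or `nrow(values)`.
#' @slot layoutVersion Single string identifying the column layout.
#'
#' @seealso [encodeDataset()]
#' @export
setClass("FeatureMatrix",
  slots = c(values = "matrix", label = "factor", layoutVersion = "character"))

setValidity("FeatureMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be numeric")
  if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
    return("feature names must be present and unique")
  if (nrow(v) > 0 && (is.null(rownames(v)) || anyDuplicated(rownames(v))))
    return("row ids must be present and unique")
  if (!identical(levels(object@label), .LABEL_LEVELS))
    return("label levels must be non-ACP/ACP")
  if (length(object@label) != 0L && length(object@label) != nrow(v))
    return("label must be absent or one per row")
  if (length(object@layoutVersion) != 1L)
    return("layoutVersion must be a single string")
  TRUE
})

#' ACPModel: a fitted peptide classifier
#'
#' Wraps a fitted backend estimator together with the model configuration,
#' the feature layout it was trained on, and training metadata. Prediction
#' refuses a [FeatureMatrix-class] whose `layoutVersion` differs from
#' training.
#'
#' @slot backend Fitted estimator state (backend-specific).
#' @slot config Model configuration list from [modelConfig()].
#' @slot layoutVersion Layout fingerprint of the training features.
#' @slot featureNames Training feature-column names, in order.
#' @slot classCounts Named integer, training records per class.
#' @slot center,scale Per-feature standardization parameters (length 0 when
#'   `standardize = FALSE`), fitted on training data only.
#'
#' @seealso [acpTrain()], [acpPredict()]
#' @export
setClass("ACPModel",
  slots = c(backend = "ANY", config = "list", layoutVersion = "character",
            featureNames = "character", classCounts = "integer",
            center = "numeric", scale = "numeric"))

#' EvalReport: binary-classifier evaluation summary
#'
#' Confusion counts plus sensitivity, specificity, accuracy, Matthews
#' correlation and ROC AUC for one evaluation protocol: pooled ten-fold
#' cross-validation (with per-fold reports retained) or a single independent
#' test.
#'
#' @slot counts Named integer `TP`, `FP`, `TN`, `FN`.
#' @slot metrics Named numeric `se`, `sp`, `acc`, `mcc`, `auc`
#'   (proportions / correlation, not percentages).
#' @slot protocol Single string, e.g. `"cv10"` or `"independent"`.
#' @slot perFold Per-fold metric data.frame (empty for independent tests).
#' @slot notes Character vector of advisory flags (e.g. resubstitution).
#'
#' @seealso [crossValidate()], [independentTest()], [reportTable()]
#' @export
setClass("EvalReport",
  slots = c(counts = "integer", metrics = "numeric", protocol = "character",
            perFold = "data.frame", notes = "character"))

setValidity("EvalReport", function(object) {
  if (!identical(names(object@counts), c("TP", "FP", "TN", "FN")))
    return("counts must be named TP, FP, TN, FN")
  if (any(object@counts < 0L)) return("negative confusion counts")
  if (!identical(names(object@metrics), c("se", "sp", "acc", "mcc", "auc")))
    return("metrics must be named se, sp, acc, mcc, auc")
  TRUE
})
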