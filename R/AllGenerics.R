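#' @rdname PeptideSet-class
#' @param x,object A `PeptideSet`.
#' @export
setGeneric("peptides", function(x) standardGeneric("peptides"))

#' @rdname PeptideSet-class
#' @export
setGeneric("peptideLabels", function(x) standardGeneric("peptideLabels"))

#' @rdname PeptideSet-class
#' @export
setGeneric("datasetName", function(x) standardGeneric("datasetName"))

#' @rdname PeptideSet-class
#' @export
setGeneric("nPositive", function(x) standardGeneric("nPositive"))

#' @rdname PeptideSet-class
#' @export
setGeneric("nNegative", function(x) standardGeneric("nNegative"))

#' @rdname FeatureMatrix-class
#' @param x,object A `FeatureMatrix`.
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname FeatureMatrix-class
#' @export
setGeneric("layoutVersion", function(x) standardGeneric("layoutVersion"))

#' @rdname AAIndexTable-class
#' @param x,object An `AAIndexTable`.
#' @export
setGeneric("propertyIds", function(x) standardGeneric("propertyIds"))

#' @rdname EvalReport-class
#' @param x,object An `EvalReport`.
#' @export
setGeneric("confusionCounts", function(x) standardGeneric("confusionCounts"))

#' @rdname EvalReport-class
#' @export
setGeneric("evalMetrics", function(x) standardGeneric("evalMetrics"))

#' @rdname EvalReport-class
#' @export
setGeneric("perFoldReports", function(x) standardGeneric("perFoldReports"))
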