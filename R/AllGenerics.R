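#' @import methods
NULL

#' @export
setGeneric("exprData", function(x) standardGeneric("exprData"))

#' @export
setGeneric("exprUnit", function(x) standardGeneric("exprUnit"))

#' @export
setGeneric("geneNames", function(x) standardGeneric("geneNames"))

#' @export
setGeneric("tissueNames", function(x) standardGeneric("tissueNames"))

#' @export
setGeneric("temperatureNames", function(x) standardGeneric("temperatureNames"))

#' @export
setGeneric("isBalanced", function(x, ...) standardGeneric("isBalanced"))

#' @export
setGeneric("cellMeans", function(x, temperature, ...) standardGeneric("cellMeans"))

#' @export
setGeneric("temperatureGrandMean", function(x, temperature)
  standardGeneric("temperatureGrandMean"))

#' @export
setGeneric("fitSspAnova", function(x, ...) standardGeneric("fitSspAnova"))

#' @export
setGeneric("anovaTable", function(x) standardGeneric("anovaTable"))

#' @export
setGeneric("ammiDecompose", function(x, temperature, nAxes = 2L, ...)
  standardGeneric("ammiDecompose"))

#' @export
setGeneric("ggeDecompose", function(x, partition = "symmetric", ...)
  standardGeneric("ggeDecompose"))

#' @export
setGeneric("singularValues", function(x) standardGeneric("singularValues"))

#' @export
setGeneric("geneScores", function(x, ...) standardGeneric("geneScores"))

#' @export
setGeneric("tissueScores", function(x, ...) standardGeneric("tissueScores"))

#' @export
setGeneric("varianceExplained", function(x) standardGeneric("varianceExplained"))

#' @export
setGeneric("tissueRelationships", function(x) standardGeneric("tissueRelationships"))

#' @export
setGeneric("whichWonWhere", function(x, ...) standardGeneric("whichWonWhere"))

#' @export
setGeneric("meanVsStability", function(x) standardGeneric("meanVsStability"))

#' @export
setGeneric("idealPointRanking", function(x) standardGeneric("idealPointRanking"))

#' @export
setGeneric("ggeRankings", function(x) standardGeneric("ggeRankings"))

#' @export
setGeneric("simulateExpression", function(spec, ...) standardGeneric("simulateExpression"))
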