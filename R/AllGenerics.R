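#' @rdname PairedExpressionSet-class
#' @param x a \code{PairedExpressionSet} (or other object with a method).
#' @export
setGeneric("pairId", function(x) standardGeneric("pairId"))

#' @rdname PairedExpressionSet-class
#' @export
setGeneric("sampleGroup", function(x) standardGeneric("sampleGroup"))

#' @rdname quantileNormalize
#' @export
setGeneric("quantileNormalize", function(x) standardGeneric("quantileNormalize"))

#' @rdname RocSummary-class
#' @param object a \code{RocSummary} or \code{PanelModel}.
#' @export
setGeneric("auc", function(object) standardGeneric("auc"))

#' @rdname RocSummary-class
#' @export
setGeneric("aucSE", function(object) standardGeneric("aucSE"))

#' @rdname PanelModel-class
#' @param object a \code{PanelModel}.
#' @export
setGeneric("panelMarkers", function(object) standardGeneric("panelMarkers"))
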