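#' Accessors for predstat classes
#'
#' Small accessor generics so user code never reaches into slots.
#'
#' @param x A predstat S4 object.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("alphabet", function(x) standardGeneric("alphabet"))
#' @rdname accessors
#' @export
setGeneric("markovOrder", function(x) standardGeneric("markovOrder"))
#' @rdname accessors
#' @export
setGeneric("probTable", function(x) standardGeneric("probTable"))
#' @rdname accessors
#' @export
setGeneric("sourceLabel", function(x) standardGeneric("sourceLabel"))
#' @rdname accessors
#' @export
setGeneric("symbols", function(x) standardGeneric("symbols"))
#' @rdname accessors
#' @export
setGeneric("trials", function(x) standardGeneric("trials"))
#' @rdname accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))
#' @rdname accessors
#' @export
setGeneric("curveValues", function(x) standardGeneric("curveValues"))
#' @rdname accessors
#' @export
setGeneric("indexValue", function(x) standardGeneric("indexValue"))
#' @rdname accessors
#' @export
setGeneric("complexityBits", function(x) standardGeneric("complexityBits"))
#' @rdname accessors
#' @export
setGeneric("entropyRateBits", function(x) standardGeneric("entropyRateBits"))
#' @rdname accessors
#' @export
setGeneric("marginalEntropyBits",
           function(x) standardGeneric("marginalEntropyBits"))

#' @rdname accessors
#' @export
setMethod("alphabet", "MarkovSource", function(x) x@alphabet)
#' @rdname accessors
#' @export
setMethod("alphabet", "SymbolSequence", function(x) x@alphabet)
#' @rdname accessors
#' @export
setMethod("alphabet", "ResponseSet", function(x) x@alphabet)
#' @rdname accessors
#' @export
setMethod("markovOrder", "MarkovSource", function(x) x@order)
#' @rdname accessors
#' @export
setMethod("probTable", "MarkovSource", function(x) x@probs)
#' @rdname accessors
#' @export
setMethod("sourceLabel", "MarkovSource", function(x) x@label)
#' @rdname accessors
#' @export
setMethod("sourceLabel", "SymbolSequence", function(x) x@sourceLabel)
#' @rdname accessors
#' @export
setMethod("symbols", "SymbolSequence", function(x) x@symbols)
#' @rdname accessors
#' @export
setMethod("trials", "Block", function(x) x@trials)
#' @rdname accessors
#' @export
setMethod("records", "ResponseSet", function(x) x@records)
#' @rdname accessors
#' @export
setMethod("curveValues", "StrategyCurve", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("indexValue", "StrategyIndex", function(x) x@value)
#' @rdname accessors
#' @export
setMethod("complexityBits", "SourceSummary", function(x) x@complexityBits)
#' @rdname accessors
#' @export
setMethod("entropyRateBits", "SourceSummary", function(x) x@entropyRateBits)
#' @rdname accessors
#' @export
setMethod("marginalEntropyBits", "SourceSummary",
          function(x) x@marginalEntropyBits)
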