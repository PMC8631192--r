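#' @name accessors
#' @title Accessors for ProphageKit classes
#'
#' @description Slot accessors: `genomeId()`, `genomeSeq()`, `isCircular()`,
#' `genomeFeatures()` for [GenomeRecord-class]; `hostTree()`, `phageTree()`,
#' `tipMap()` for [TreePair-class]; `eventCounts()`, `totalCost()`,
#' `nodeMap()`, `eventTable()` for [Reconciliation-class]; `mprCount()`,
#' `mprSample()` for [MPRSet-class]; `scenarioPair()`, `trueEvents()` for
#' [CophylogenyScenario-class]; `latentPeriod()`, `burstSize()` for
#' [GrowthFit-class].
#'
#' @param x an object of the documented class.
#' @return the slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))
#' @rdname accessors
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))
#' @rdname accessors
#' @export
setGeneric("isCircular", function(x) standardGeneric("isCircular"))
#' @rdname accessors
#' @export
setGeneric("genomeFeatures", function(x) standardGeneric("genomeFeatures"))
#' @rdname accessors
#' @export
setGeneric("hostTree", function(x) standardGeneric("hostTree"))
#' @rdname accessors
#' @export
setGeneric("phageTree", function(x) standardGeneric("phageTree"))
#' @rdname accessors
#' @export
setGeneric("tipMap", function(x) standardGeneric("tipMap"))
#' @rdname accessors
#' @export
setGeneric("eventCounts", function(x) standardGeneric("eventCounts"))
#' @rdname accessors
#' @export
setGeneric("totalCost", function(x) standardGeneric("totalCost"))
#' @rdname accessors
#' @export
setGeneric("nodeMap", function(x) standardGeneric("nodeMap"))
#' @rdname accessors
#' @export
setGeneric("eventTable", function(x) standardGeneric("eventTable"))
#' @rdname accessors
#' @export
setGeneric("mprCount", function(x) standardGeneric("mprCount"))
#' @rdname accessors
#' @export
setGeneric("mprSample", function(x) standardGeneric("mprSample"))
#' @rdname accessors
#' @export
setGeneric("scenarioPair", function(x) standardGeneric("scenarioPair"))
#' @rdname accessors
#' @export
setGeneric("trueEvents", function(x) standardGeneric("trueEvents"))
#' @rdname accessors
#' @export
setGeneric("latentPeriod", function(x) standardGeneric("latentPeriod"))
#' @rdname accessors
#' @export
setGeneric("burstSize", function(x) standardGeneric("burstSize"))
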