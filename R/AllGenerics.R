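#' @include utils.R
NULL

#' Accessor generics
#'
#' Accessors for the core S4 classes: \code{transcripts} and \code{proteins}
#' return the sequence sets of a \linkS4class{VenomeTruth},
#' \code{trueAbundance} its ground-truth relative abundances,
#' \code{contaminantIds} the identifiers of spiked-in contaminant proteins,
#' \code{threshold} the abundance cutoff of a \linkS4class{ThresholdResult},
#' and \code{corCoef}/\code{pValue}/\code{nPairs} the components of a
#' \linkS4class{CorrelationResult}.
#'
#' @param x an object of the appropriate class.
#' @param ... further arguments passed to methods.
#' @return The slot value; see the class documentation for details.
#' @name accessors
#' @aliases transcripts proteins trueAbundance contaminantIds threshold
#'   corCoef pValue nPairs
#' @examples
#' truth <- sampleVenome(generatorConfig(nTranscripts = 5, seed = 1))
#' length(transcripts(truth))
#' head(trueAbundance(truth))
NULL

#' @rdname accessors
#' @export
setGeneric("transcripts", function(x, ...) standardGeneric("transcripts"))

#' @rdname accessors
#' @export
setGeneric("proteins", function(x, ...) standardGeneric("proteins"))

#' @rdname accessors
#' @export
setGeneric("trueAbundance", function(x, ...) standardGeneric("trueAbundance"))

#' @rdname accessors
#' @export
setGeneric("contaminantIds",
           function(x, ...) standardGeneric("contaminantIds"))

#' @rdname accessors
#' @export
setGeneric("threshold", function(x, ...) standardGeneric("threshold"))

#' @rdname accessors
#' @export
setGeneric("corCoef", function(x, ...) standardGeneric("corCoef"))

#' @rdname accessors
#' @export
setGeneric("pValue", function(x, ...) standardGeneric("pValue"))

#' @rdname accessors
#' @export
setGeneric("nPairs", function(x, ...) standardGeneric("nPairs"))
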