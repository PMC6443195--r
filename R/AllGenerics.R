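#' @include AllClasses.R
NULL

#' Accessors for model parameters and ensembles
#'
#' Standard accessor generics for the [ModelParams-class],
#' [ReplicateResult-class] and [ArchitectureEnsemble-class] containers.
#' Slots are never meant to be reached with `@`.
#'
#' @param x an object of the documented classes.
#' @return the corresponding slot value.
#' @name accessors
#' @aliases popSize nLoci thetaVec stopFraction muVec rankedFreqs
#'   locusFreqs nReplicates sourceTag generationsElapsed metricAtStop
#'   stoppedFreqs locusOrder modelParamsOf
NULL

#' @rdname accessors
#' @export
setGeneric("popSize", function(x) standardGeneric("popSize"))

#' @rdname accessors
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))

#' @rdname accessors
#' @export
setGeneric("thetaVec", function(x) standardGeneric("thetaVec"))

#' @rdname accessors
#' @export
setGeneric("stopFraction", function(x) standardGeneric("stopFraction"))

#' @rdname accessors
#' @export
setGeneric("muVec", function(x) standardGeneric("muVec"))

#' @rdname accessors
#' @export
setGeneric("rankedFreqs", function(x) standardGeneric("rankedFreqs"))

#' @rdname accessors
#' @export
setGeneric("locusFreqs", function(x) standardGeneric("locusFreqs"))

#' @rdname accessors
#' @export
setGeneric("nReplicates", function(x) standardGeneric("nReplicates"))

#' @rdname accessors
#' @export
setGeneric("sourceTag", function(x) standardGeneric("sourceTag"))

#' @rdname accessors
#' @export
setGeneric("generationsElapsed", function(x) standardGeneric("generationsElapsed"))

#' @rdname accessors
#' @export
setGeneric("metricAtStop", function(x) standardGeneric("metricAtStop"))

#' @rdname accessors
#' @export
setGeneric("stoppedFreqs", function(x) standardGeneric("stoppedFreqs"))

#' @rdname accessors
#' @export
setGeneric("locusOrder", function(x) standardGeneric("locusOrder"))

#' @rdname accessors
#' @export
setGeneric("modelParamsOf", function(x) standardGeneric("modelParamsOf"))
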