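#' @include AllClasses.R
NULL

#' @rdname propensities
#' @export
setGeneric("propensities", function(network, state, params) {
  standardGeneric("propensities")
})

#' @rdname validateNetwork
#' @export
setGeneric("validateNetwork", function(network) {
  standardGeneric("validateNetwork")
})

#' @rdname simulateExact
#' @export
setGeneric("simulateExact", function(network, ...) {
  standardGeneric("simulateExact")
})

#' @rdname ensembleFinalStates
#' @export
setGeneric("ensembleFinalStates", function(network, ...) {
  standardGeneric("ensembleFinalStates")
})

#' @rdname simulateDGA
#' @export
setGeneric("simulateDGA", function(network, ...) {
  standardGeneric("simulateDGA")
})

#' Accessors for ReactionNetwork objects
#'
#' @param x a [ReactionNetwork-class].
#' @return \code{speciesNames}, \code{parameterNames}, \code{reactionNames},
#'   \code{indicatorSpecies}: character vectors; \code{stoichiometry}: the
#'   integer reaction-by-species matrix; \code{rateLaws}: the list of rate
#'   laws; \code{nReactions}, \code{nSpecies}: counts;
#'   \code{initialState}: named numeric default state;
#'   \code{externalScalars}: named numeric external inputs.
#' @name network-accessors
#' @aliases speciesNames parameterNames reactionNames stoichiometry rateLaws
#'   nReactions nSpecies indicatorSpecies initialState externalScalars
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))

#' @rdname network-accessors
#' @export
setGeneric("parameterNames", function(x) standardGeneric("parameterNames"))

#' @rdname network-accessors
#' @export
setGeneric("reactionNames", function(x) standardGeneric("reactionNames"))

#' @rdname network-accessors
#' @export
setGeneric("stoichiometry", function(x) standardGeneric("stoichiometry"))

#' @rdname network-accessors
#' @export
setGeneric("rateLaws", function(x) standardGeneric("rateLaws"))

#' @rdname network-accessors
#' @export
setGeneric("nReactions", function(x) standardGeneric("nReactions"))

#' @rdname network-accessors
#' @export
setGeneric("nSpecies", function(x) standardGeneric("nSpecies"))

#' @rdname network-accessors
#' @export
setGeneric("indicatorSpecies", function(x) standardGeneric("indicatorSpecies"))

#' @rdname network-accessors
#' @export
setGeneric("initialState", function(x) standardGeneric("initialState"))

#' @rdname network-accessors
#' @export
setGeneric("externalScalars", function(x) standardGeneric("externalScalars"))

#' Accessors for TrajectoryBatch objects
#'
#' @param x a [TrajectoryBatch-class].
#' @return \code{finalStates}: trajectories-by-species matrix;
#'   \code{occupancy}: trajectories-by-states soft occupancy matrix;
#'   \code{elapsedTimes}: numeric vector.
#' @name batch-accessors
#' @aliases finalStates readoutStates snapshotStates occupancy elapsedTimes
#' @export
setGeneric("finalStates", function(x) standardGeneric("finalStates"))

#' @rdname batch-accessors
#' @export
setGeneric("readoutStates", function(x) standardGeneric("readoutStates"))

#' @rdname batch-accessors
#' @export
setGeneric("snapshotStates", function(x) standardGeneric("snapshotStates"))

#' @rdname batch-accessors
#' @export
setGeneric("occupancy", function(x) standardGeneric("occupancy"))

#' @rdname batch-accessors
#' @export
setGeneric("elapsedTimes", function(x) standardGeneric("elapsedTimes"))

#' @rdname gradientOf
#' @export
setGeneric("gradientOf", function(batch, ...) standardGeneric("gradientOf"))
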