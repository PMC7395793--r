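## Accessor generics.  Slot access from user code should go through these.

#' @name accessors
#' @title Accessors for circuit state objects
#' @description Read-only accessors for the S4 state classes:
#' the ground-truth mixing matrix of an [OdorWorld-class], the learned
#' feedforward/lateral/readout weight matrices, the weight precisions, the
#' effective trial counter and the current firing rates.
#' @param object an `OdorWorld`, `BulbState`, `PiriformState`,
#'   `RewardState` or `SparseCodingState` object.
#' @return the corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("mixingMatrix", function(object) standardGeneric("mixingMatrix"))
#' @rdname accessors
#' @export
setMethod("mixingMatrix", "OdorWorld", function(object) object@W)

#' @rdname accessors
#' @export
setGeneric("feedforwardWeights",
           function(object) standardGeneric("feedforwardWeights"))
#' @rdname accessors
#' @export
setMethod("feedforwardWeights", "BulbState", function(object) object@wF)

#' @rdname accessors
#' @export
setGeneric("lateralWeights",
           function(object) standardGeneric("lateralWeights"))
#' @rdname accessors
#' @export
setMethod("lateralWeights", "BulbState", function(object) object@wL)

#' @rdname accessors
#' @export
setGeneric("readoutWeights",
           function(object) standardGeneric("readoutWeights"))
#' @rdname accessors
#' @export
setMethod("readoutWeights", "PiriformState", function(object) object@wP)

#' @rdname accessors
#' @export
setGeneric("lateralInhibition",
           function(object) standardGeneric("lateralInhibition"))
#' @rdname accessors
#' @export
setMethod("lateralInhibition", "PiriformState", function(object) object@J)

#' @rdname accessors
#' @export
setGeneric("precisions", function(object) standardGeneric("precisions"))
#' @rdname accessors
#' @export
setMethod("precisions", "BulbState", function(object) object@rho)
#' @rdname accessors
#' @export
setMethod("precisions", "PiriformState", function(object) object@rhoP)

#' @rdname accessors
#' @export
setGeneric("trialCount", function(object) standardGeneric("trialCount"))
#' @rdname accessors
#' @export
setMethod("trialCount", "BulbState", function(object) object@t)

#' @rdname accessors
#' @export
setGeneric("granuleRates", function(object) standardGeneric("granuleRates"))
#' @rdname accessors
#' @export
setMethod("granuleRates", "BulbState", function(object) object@cbar)

#' @rdname accessors
#' @export
setGeneric("mtRates", function(object) standardGeneric("mtRates"))
#' @rdname accessors
#' @export
setMethod("mtRates", "BulbState", function(object) object@m)

#' @rdname accessors
#' @export
setGeneric("piriformRates",
           function(object) standardGeneric("piriformRates"))
#' @rdname accessors
#' @export
setMethod("piriformRates", "PiriformState", function(object) object@pbar)

#' @rdname accessors
#' @export
setGeneric("associationWeights",
           function(object) standardGeneric("associationWeights"))
#' @rdname accessors
#' @export
setMethod("associationWeights", "RewardState", function(object) object@abar)

#' @rdname accessors
#' @export
setGeneric("dictionary", function(object) standardGeneric("dictionary"))
#' @rdname accessors
#' @export
setMethod("dictionary", "SparseCodingState", function(object) object@wHat)
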