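#' @export
setGeneric("residueTypes", function(x) standardGeneric("residueTypes"))

#' @export
setGeneric("nStates", function(x, residueType) standardGeneric("nStates"))

#' @export
setGeneric("nChi", function(x, residueType) standardGeneric("nChi"))

#' @export
setGeneric("modalChis", function(x, residueType) standardGeneric("modalChis"))

#' @export
setGeneric("stateNames", function(x, residueType) standardGeneric("stateNames"))

#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @export
setGeneric("states", function(x) standardGeneric("states"))

#' @export
setGeneric("probabilities", function(x) standardGeneric("probabilities"))

#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @export
setGeneric("condition", function(x) standardGeneric("condition"))

#' @export
setGeneric("residueId", function(x) standardGeneric("residueId"))

#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @export
setGeneric("spaceGroup", function(x) standardGeneric("spaceGroup"))

#' @export
setGeneric("cellParameters", function(x) standardGeneric("cellParameters"))
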