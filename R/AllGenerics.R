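#' @importClassesFrom GenomicRanges GRanges
NULL

#' Evaluate the opening free energy of an opening model
#'
#' @param sigma numeric vector of superhelical densities
#' @param model a \linkS4class{SigmoidOpening} or
#'   \linkS4class{MeltingProfile}
#' @return opening free energy in kcal/mol, one value per \code{sigma}
#' @export
setGeneric("openingEnergy", function(sigma, model)
    standardGeneric("openingEnergy"))

#' @rdname CouplingResult-class
#' @param object a CouplingResult
#' @export
setGeneric("rates", function(object) standardGeneric("rates"))

#' @rdname CouplingResult-class
#' @export
setGeneric("foldChanges", function(object) standardGeneric("foldChanges"))

#' @rdname CouplingResult-class
#' @export
setGeneric("promoterSigma", function(object)
    standardGeneric("promoterSigma"))

#' @rdname CouplingResult-class
#' @export
setGeneric("converged", function(object) standardGeneric("converged"))

setMethod("rates", "CouplingResult", function(object) object@rates)
setMethod("foldChanges", "CouplingResult", function(object)
    object@foldChanges)
setMethod("promoterSigma", "CouplingResult", function(object)
    object@promoterSigma)
setMethod("converged", "CouplingResult", function(object) object@converged)
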