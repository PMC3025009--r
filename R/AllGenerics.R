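#' @rdname MetabolicNetwork-class
#' @param object,x a \code{MetabolicNetwork} (or other package object).
#' @export
setGeneric("metabolites", function(x) standardGeneric("metabolites"))

#' @rdname MetabolicNetwork-class
#' @export
setGeneric("reactions", function(x) standardGeneric("reactions"))

#' @rdname MetabolicNetwork-class
#' @export
setGeneric("stoichiometry", function(x) standardGeneric("stoichiometry"))

#' @rdname MetabolicNetwork-class
#' @export
setGeneric("lowerBounds", function(x) standardGeneric("lowerBounds"))

#' @rdname MetabolicNetwork-class
#' @export
setGeneric("upperBounds", function(x) standardGeneric("upperBounds"))

#' @rdname MetabolicNetwork-class
#' @export
setGeneric("biomassReaction", function(x) standardGeneric("biomassReaction"))

#' @rdname MetabolicNetwork-class
#' @export
setGeneric("exchangeReactions",
           function(x) standardGeneric("exchangeReactions"))

#' @rdname MetabolicNetwork-class
#' @export
setGeneric("geneRules", function(x) standardGeneric("geneRules"))

#' @rdname MetabolicNetwork-class
#' @export
setGeneric("coreNutrients", function(x) standardGeneric("coreNutrients"))

#' @rdname MetabolicNetwork-class
#' @export
setGeneric("modelMetadata", function(x) standardGeneric("modelMetadata"))

#' @rdname Medium-class
#' @export
setGeneric("uptakeBounds", function(x) standardGeneric("uptakeBounds"))

#' @rdname Medium-class
#' @export
setGeneric("excludedChemical",
           function(x) standardGeneric("excludedChemical"))

#' @rdname FluxDistribution-class
#' @export
setGeneric("flux", function(x) standardGeneric("flux"))

#' @rdname FluxDistribution-class
#' @export
setGeneric("objectiveValue", function(x) standardGeneric("objectiveValue"))

#' @rdname FluxDistribution-class
#' @export
setGeneric("solverStatus", function(x) standardGeneric("solverStatus"))

#' Knockout set of a design or knockout vector
#' @param x a \code{BiosensorDesign}, \code{CouplingDesign} or
#'   \code{KnockoutVector}.
#' @return character vector of knocked-out reaction ids.
#' @export
setGeneric("knockouts", function(x) standardGeneric("knockouts"))

#' @rdname BiosensorDesign-class
#' @export
setGeneric("verified", function(x) standardGeneric("verified"))

#' @rdname BiosensorDesign-class
#' @export
setGeneric("chemical", function(x) standardGeneric("chemical"))

#' @rdname CouplingDesign-class
#' @export
setGeneric("maxRate", function(x) standardGeneric("maxRate"))

#' @rdname CouplingDesign-class
#' @export
setGeneric("guaranteedRate", function(x) standardGeneric("guaranteedRate"))
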