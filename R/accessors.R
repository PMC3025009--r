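#' @rdname MetabolicNetwork-class
setMethod("metabolites", "MetabolicNetwork", function(x) x@metabolites)

#' @rdname MetabolicNetwork-class
setMethod("reactions", "MetabolicNetwork", function(x) x@reactions)

#' @rdname MetabolicNetwork-class
setMethod("stoichiometry", "MetabolicNetwork", function(x) {
  S <- x@S
  dimnames(S) <- list(x@metabolites, x@reactions)
  S
})

#' @rdname MetabolicNetwork-class
setMethod("lowerBounds", "MetabolicNetwork",
          function(x) stats::setNames(x@lowerBounds, x@reactions))

#' @rdname MetabolicNetwork-class
setMethod("upperBounds", "MetabolicNetwork",
          function(x) stats::setNames(x@upperBounds, x@reactions))

#' @rdname MetabolicNetwork-class
setMethod("biomassReaction", "MetabolicNetwork", function(x) x@biomassReaction)

#' @rdname MetabolicNetwork-class
setMethod("exchangeReactions", "MetabolicNetwork",
          function(x) x@exchangeReactions)

#' @rdname MetabolicNetwork-class
setMethod("geneRules", "MetabolicNetwork",
          function(x) stats::setNames(x@geneRules, x@reactions))

#' @rdname MetabolicNetwork-class
setMethod("coreNutrients", "MetabolicNetwork", function(x) x@coreNutrients)

#' @rdname MetabolicNetwork-class
setMethod("modelMetadata", "MetabolicNetwork", function(x) x@metadata)

#' @rdname Medium-class
setMethod("uptakeBounds", "Medium", function(x) x@uptakeBounds)

#' @rdname Medium-class
setMethod("excludedChemical", "Medium", function(x) x@excludedChemical)

#' @rdname FluxDistribution-class
setMethod("flux", "FluxDistribution", function(x) x@flux)

#' @rdname FluxDistribution-class
setMethod("objectiveValue", "FluxDistribution", function(x) x@objectiveValue)

#' @rdname FluxDistribution-class
setMethod("solverStatus", "FluxDistribution", function(x) x@status)

#' @rdname knockouts
setMethod("knockouts", "KnockoutVector",
          function(x) x@candidateReactions[!x@y])

#' @rdname knockouts
setMethod("knockouts", "BiosensorDesign", function(x) x@knockouts)

#' @rdname knockouts
setMethod("knockouts", "CouplingDesign", function(x) x@knockouts)

#' @rdname BiosensorDesign-class
setMethod("verified", "BiosensorDesign", function(x) x@verified)

#' @rdname BiosensorDesign-class
setMethod("chemical", "BiosensorDesign", function(x) x@chemical)

#' @rdname CouplingDesign-class
setMethod("maxRate", "CouplingDesign", function(x) x@maxRate)

#' @rdname CouplingDesign-class
setMethod("guaranteedRate", "CouplingDesign", function(x) x@guaranteedRate)

setMethod("show", "MetabolicNetwork", function(object) {
  cat("MetabolicNetwork:", length(object@reactions), "reactions,",
      length(object@metabolites), "metabolites\n")
  cat("  exchange reactions:", length(object@exchangeReactions), "\n")
  cat("  biomass reaction:  ", object@biomassReaction, "\n")
  if (length(object@coreNutrients))
    cat("  core nutrients:    ",
        paste(object@coreNutrients, collapse = ", "), "\n")
})

setMethod("show", "Medium", function(object) {
  cat("Medium with", length(object@uptakeBounds), "open uptake exchange(s)\n")
  if (length(object@excludedChemical))
    cat("  excluded chemical:", object@excludedChemical, "\n")
})

setMethod("show", "FluxDistribution", function(object) {
  cat("FluxDistribution (", object@status, "): ", object@objectiveReaction,
      " = ", format(object@objectiveValue), "\n", sep = "")
})

setMethod("show", "KnockoutVector", function(object) {
  ko <- object@candidateReactions[!object@y]
  cat("KnockoutVector:", length(ko), "of up to", object@k, "knockouts",
      if (length(ko)) paste0("(", paste(ko, collapse = ", "), ")"), "\n")
})

setMethod("show", "BiosensorDesign", function(object) {
  cat("BiosensorDesign for", object@chemical,
      sprintf("[%s medium]\n", object@mediumKind))
  cat("  knockouts:      ",
      if (length(object@knockouts)) paste(object@knockouts, collapse = ", ")
      else "(none)", "\n")
  cat("  growth with C:  ", format(object@growthWithC), "\n")
  cat("  growth without C:", format(object@growthWithoutC), "\n")
  cat("  verified:       ", object@verified, "\n")
  if (!is.na(object@insensitiveYield))
    cat("  yield-insensitive:", object@insensitiveYield, "\n")
})

setMethod("show", "CouplingDesign", function(object) {
  cat("CouplingDesign:", object@target, "coupled to", object@coupledTo, "\n")
  cat("  knockouts:      ",
      if (length(object@knockouts)) paste(object@knockouts, collapse = ", ")
      else "(none)", "\n")
  cat("  max rate:       ", format(object@maxRate), "\n")
  cat("  guaranteed rate:", format(object@guaranteedRate), "\n")
  cat("  growth floor:   ", format(object@minGrowth), "\n")
})

#' Construct a solver configuration
#'
#' @param zeroTolerance growth values at or below this count as zero (used by
#'   the no-growth condition of the biosensor program). Default 1e-6.
#' @param massBalanceTolerance allowed residual of \eqn{Sv=0}. Default 1e-6.
#' @param milpGap relative MILP gap. Default 1e-9.
#' @param bigM linearization/dual-bound magnitude. Default 1000.
#' @param timeLimit per-solve limit, seconds. Default 120.
#' @param growthThreshold minimal growth with the sensed chemical for a
#'   design to be considered viable. Default 1e-3.
#' @param insensitivityTolerance relative slope tolerance for yield
#'   insensitivity. Default 0.01.
#' @return a \code{SolveConfig}.
#' @export
solveConfig <- function(zeroTolerance = 1e-6, massBalanceTolerance = 1e-6,
                        milpGap = 1e-9, bigM = 1000, timeLimit = 120,
                        growthThreshold = 1e-3,
                        insensitivityTolerance = 0.01) {
  new("SolveConfig", zeroTolerance = zeroTolerance,
      massBalanceTolerance = massBalanceTolerance, milpGap = milpGap,
      bigM = bigM, timeLimit = timeLimit, growthThreshold = growthThreshold,
      insensitivityTolerance = insensitivityTolerance)
}

#' Construct a knockout vector
#'
#' @param network a \code{MetabolicNetwork}.
#' @param knockedOut reaction ids to knock out (zeros of y).
#' @param k knockout budget; defaults to the number of knockouts.
#' @param candidates candidate-reaction universe; defaults to
#'   \code{\link{candidateReactions}} of the network.
#' @return a \code{KnockoutVector}.
#' @export
knockoutVector <- function(network, knockedOut = character(),
                           k = max(3L, length(knockedOut)),
                           candidates = candidateReactions(network)) {
  knockedOut <- as.character(knockedOut)
  if (!all(knockedOut %in% candidates))
    stop("knockedOut reactions must belong to the candidate set: ",
         paste(setdiff(knockedOut, candidates), collapse = ", "))
  new("KnockoutVector", candidateReactions = candidates,
      y = !(candidates %in% knockedOut), k = as.integer(k))
}
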