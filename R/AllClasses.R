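#' @import methods
#' @importFrom Matrix Matrix sparseMatrix colSums rowSums t
NULL

#' MetabolicNetwork: a constraint-based metabolic network model
#'
#' Holds the stoichiometric matrix \eqn{S} (one row per metabolite, one column
#' per reaction), per-reaction flux bounds in mmol/gDW/h, reversibility flags,
#' the set of exchange (boundary) reactions, the biomass reaction, and
#' optional gene-association strings. Steady-state behaviour of the network is
#' the set of flux vectors \eqn{v} with \eqn{S v = 0} and
#' \eqn{lb \le v \le ub}.
#'
#' The sign convention for exchange reactions is: uptake is a negative flux
#' (bounded below by minus the uptake capacity), secretion is a positive flux.
#'
#' @slot metabolites character vector of metabolite identifiers (n).
#' @slot reactions character vector of reaction identifiers (m).
#' @slot S sparse n x m stoichiometric matrix (\code{dgCMatrix}).
#' @slot lowerBounds,upperBounds numeric flux bounds, one per reaction.
#' @slot reversible logical, one per reaction.
#' @slot exchangeReactions identifiers of boundary pseudo-reactions.
#' @slot biomassReaction identifier of the growth reaction.
#' @slot geneRules gene-association strings (reporting only; "" if unknown).
#' @slot coreNutrients metabolite ids always opened in a minimal medium
#'   (ions, phosphate, sulfate, ammonium, oxygen, water, protons, CO2, ...).
#' @slot metadata free-form list (e.g. declared carbon source, planted
#'   ground truth for generated toy networks).
#' @export
setClass("MetabolicNetwork",
  representation(
    metabolites = "character",
    reactions = "character",
    S = "Matrix",
    lowerBounds = "numeric",
    upperBounds = "numeric",
    reversible = "logical",
    exchangeReactions = "character",
    biomassReaction = "character",
    geneRules = "character",
    coreNutrients = "character",
    metadata = "list"
  )
)

setValidity("MetabolicNetwork", function(object) {
  msg <- character()
  n <- length(object@metabolites)
  m <- length(object@reactions)
  if (!all(dim(object@S) == c(n, m)))
    msg <- c(msg, sprintf("S must be %d x %d, got %d x %d",
                          n, m, nrow(object@S), ncol(object@S)))
  if (anyDuplicated(object@metabolites))
    msg <- c(msg, "duplicated metabolite ids")
  if (anyDuplicated(object@reactions))
    msg <- c(msg, "duplicated reaction ids")
  if (length(object@lowerBounds) != m || length(object@upperBounds) != m ||
      length(object@reversible) != m)
    msg <- c(msg, "bounds and reversible must have one entry per reaction")
  if (length(msg) == 0L) {
    zero <- which(Matrix::colSums(object@S != 0) == 0)
    if (length(zero))
      msg <- c(msg, paste0("all-zero stoichiometry column(s): ",
                           paste(object@reactions[zero], collapse = ", ")))
    bad <- which(object@lowerBounds > object@upperBounds)
    if (length(bad))
      msg <- c(msg, paste0("lower bound exceeds upper bound for: ",
                           paste(object@reactions[bad], collapse = ", ")))
    irrevNeg <- which(!object@reversible & object@lowerBounds < 0)
    if (length(irrevNeg))
      msg <- c(msg, paste0("irreversible reaction with negative lower bound: ",
                           paste(object@reactions[irrevNeg], collapse = ", ")))
    if (length(object@biomassReaction) != 1L ||
        !(object@biomassReaction %in% object@reactions)) {
      msg <- c(msg, "biomassReaction must name exactly one existing reaction")
    } else if (object@reversible[match(object@biomassReaction,
                                       object@reactions)]) {
      msg <- c(msg, "biomass reaction must be irreversible")
    }
    if (!all(object@exchangeReactions %in% object@reactions))
      msg <- c(msg, "exchangeReactions must be a subset of reactions")
    if (!all(object@coreNutrients %in% object@metabolites))
      msg <- c(msg, "coreNutrients must be a subset of metabolites")
    if (length(object@geneRules) != m)
      msg <- c(msg, "geneRules must have one entry per reaction")
  }
  if (length(msg)) msg else TRUE
})

#' Medium: a set of opened uptake exchanges
#'
#' A growth medium is represented as a map from exchange-reaction id to a
#' maximal uptake rate (positive magnitude, mmol/gDW/h). Applying a medium to
#' a network sets the lower bound of each listed exchange to minus its uptake
#' rate and closes (lower bound 0) every other exchange; secretion stays
#' governed by the model's upper bounds.
#'
#' @slot uptakeBounds named numeric vector; names are exchange reaction ids.
#' @slot excludedChemical metabolite id whose uptake must remain closed
#'   (length 0 when nothing is excluded).
#' @export
setClass("Medium",
  representation(uptakeBounds = "numeric", excludedChemical = "character")
)

setValidity("Medium", function(object) {
  msg <- character()
  ub <- object@uptakeBounds
  if (length(ub) && (is.null(names(ub)) || any(!nzchar(names(ub)))))
    msg <- c(msg, "uptakeBounds must be fully named by exchange reaction id")
  if (anyDuplicated(names(ub)))
    msg <- c(msg, "duplicated exchange reaction ids in uptakeBounds")
  if (length(ub) && (any(!is.finite(ub)) || any(ub < 0)))
    msg <- c(msg, "uptake magnitudes must be finite and >= 0")
  if (length(object@excludedChemical) > 1L)
    msg <- c(msg, "at most one excluded chemical")
  if (length(msg)) msg else TRUE
})

#' KnockoutVector: Boolean knockout pattern over candidate reactions
#'
#' \code{y[i] = TRUE} means the i-th candidate reaction is active;
#' \code{FALSE} means knocked out (both flux bounds forced to zero in any
#' constrained solve). At most \code{k} concurrent knockouts are allowed.
#'
#' @slot candidateReactions ordered reaction-id vector.
#' @slot y logical vector aligned with \code{candidateReactions}.
#' @slot k maximal number of concurrent knockouts.
#' @export
setClass("KnockoutVector",
  representation(candidateReactions = "character", y = "logical",
                 k = "integer")
)

setValidity("KnockoutVector", function(object) {
  msg <- character()
  if (length(object@y) != length(object@candidateReactions))
    msg <- c(msg, "y must align with candidateReactions")
  if (anyNA(object@y)) msg <- c(msg, "y must not contain NA")
  if (length(object@k) != 1L || is.na(object@k) || object@k < 0L)
    msg <- c(msg, "k must be a single non-negative integer")
  if (length(msg) == 0L && sum(!object@y) > object@k)
    msg <- c(msg, sprintf("%d knockouts exceed budget k = %d",
                          sum(!object@y), object@k))
  if (length(msg)) msg else TRUE
})

#' FluxDistribution: one steady-state flux vector
#'
#' @slot flux named numeric vector of reaction rates (mmol/gDW/h).
#' @slot objectiveValue value of the optimized flux.
#' @slot objectiveReaction id of the optimized reaction.
#' @slot status one of "optimal", "infeasible", "unbounded".
#' @export
setClass("FluxDistribution",
  representation(flux = "numeric", objectiveValue = "numeric",
                 objectiveReaction = "character", status = "character")
)

setValidity("FluxDistribution", function(object) {
  if (!object@status %in% c("optimal", "infeasible", "unbounded"))
    return("status must be optimal, infeasible or unbounded")
  TRUE
})

#' SolveConfig: numerical tolerances and solver parameters
#'
#' @slot zeroTolerance growth below this counts as "no growth" (objective
#'   units); used for the inner no-growth cap of the biosensor program.
#' @slot massBalanceTolerance allowed residual of \eqn{S v = 0} when checking
#'   returned flux vectors.
#' @slot milpGap relative MILP optimality gap requested from the solver.
#' @slot bigM magnitude bound used to linearize products of binary knockout
#'   variables with dual variables; also caps dual variables.
#' @slot timeLimit per-solve wall-clock limit in seconds.
#' @slot growthThreshold minimal growth a biosensor must reach with its
#'   sensed chemical present for the design to count as viable.
#' @slot insensitivityTolerance maximal relative slope difference between the
#'   poor- and rich-medium yield curves for a sensor to be called
#'   yield-insensitive.
#' @export
setClass("SolveConfig",
  representation(zeroTolerance = "numeric", massBalanceTolerance = "numeric",
                 milpGap = "numeric", bigM = "numeric", timeLimit = "numeric",
                 growthThreshold = "numeric",
                 insensitivityTolerance = "numeric")
)

setValidity("SolveConfig", function(object) {
  vals <- c(object@zeroTolerance, object@massBalanceTolerance,
            object@milpGap, object@bigM, object@timeLimit,
            object@growthThreshold, object@insensitivityTolerance)
  if (length(vals) != 7L || any(!is.finite(vals)) || any(vals <= 0))
    return("all tolerances/parameters must be single strictly positive values")
  TRUE
})

#' BiosensorDesign: an ultra-auxotrophic biosensor strain design
#'
#' A knockout set that makes growth strictly dependent on the sensed
#' chemical: the strain grows on medium M plus the chemical, and cannot grow
#' on any medium lacking it, even one containing every other transportable
#' nutrient.
#'
#' @slot chemical sensed metabolite id.
#' @slot mediumKind "minimal" or "rich".
#' @slot knockouts reaction ids knocked out.
#' @slot growthWithC growth rate on M plus the sensed chemical.
#' @slot growthWithoutC maximal growth rate on rich medium minus the chemical.
#' @slot verified TRUE when the two independent FBA checks passed.
#' @slot insensitiveYield TRUE/FALSE once classified by
#'   \code{\link{yieldSensitivity}}; NA before.
#' @export
setClass("BiosensorDesign",
  representation(chemical = "character", mediumKind = "character",
                 knockouts = "character", growthWithC = "numeric",
                 growthWithoutC = "numeric", verified = "logical",
                 insensitiveYield = "logical")
)

#' CouplingDesign: a growth- or proxy-coupled production strain design
#'
#' @slot target metabolite id whose secretion is engineered.
#' @slot coupledTo "biomass" or the proxy metabolite id.
#' @slot knockouts reaction ids knocked out.
#' @slot maxRate best-case target secretion at inner-optimal coupled flux.
#' @slot guaranteedRate worst-case (guaranteed) secretion over alternative
#'   inner optima; NA when not computed.
#' @slot minGrowth biomass viability floor enforced.
#' @slot growth growth rate at the reported solution.
#' @export
setClass("CouplingDesign",
  representation(target = "character", coupledTo = "character",
                 knockouts = "character", maxRate = "numeric",
                 guaranteedRate = "numeric", minGrowth = "numeric",
                 growth = "numeric")
)

setValidity("CouplingDesign", function(object) {
  if (!is.na(object@guaranteedRate) && !is.na(object@maxRate) &&
      object@guaranteedRate > object@maxRate + 1e-6)
    return("guaranteedRate must not exceed maxRate")
  TRUE
})

#' BilevelProblem: a two-level knockout-design program
#'
#' The outer level searches over a shared knockout pattern y (and an outer
#' flux vector) to optimize one flux; the inner level is a linear program in
#' its own flux vector under the same y, whose optimum is either forced to be
#' attained ("optimal", OptKnock-style coupling) or capped near zero
#' ("max_zero", the no-growth condition of the ultra-auxotrophy design).
#'
#' @slot network the shared MetabolicNetwork.
#' @slot outerObjective,innerObjective reaction ids.
#' @slot outerSense,innerSense "max" or "min".
#' @slot outerMedium,innerMedium Medium objects for the two levels.
#' @slot innerConstraint "optimal" or "max_zero".
#' @slot innerCap cap used when innerConstraint is "max_zero".
#' @slot candidates knockout-candidate reaction ids (shared by both levels).
#' @slot k knockout budget.
#' @slot minGrowth biomass lower bound applied at both levels (0 = none).
#' @export
setClass("BilevelProblem",
  representation(network = "MetabolicNetwork",
                 outerObjective = "character", outerSense = "character",
                 innerObjective = "character", innerSense = "character",
                 outerMedium = "Medium", innerMedium = "Medium",
                 innerConstraint = "character", innerCap = "numeric",
                 candidates = "character", k = "integer",
                 minGrowth = "numeric")
)

setValidity("BilevelProblem", function(object) {
  msg <- character()
  rxns <- object@network@reactions
  if (!object@outerObjective %in% rxns)
    msg <- c(msg, "outerObjective is not a reaction of the network")
  if (!object@innerObjective %in% rxns)
    msg <- c(msg, "innerObjective is not a reaction of the network")
  if (!object@innerConstraint %in% c("optimal", "max_zero"))
    msg <- c(msg, "innerConstraint must be 'optimal' or 'max_zero'")
  if (!all(object@candidates %in% rxns))
    msg <- c(msg, "candidates must be reactions of the network")
  if (length(msg)) msg else TRUE
})
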