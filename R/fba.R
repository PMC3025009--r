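# Flux balance analysis and related single-level linear programs.

.buildFluxLP <- function(network, medium = NULL, objective, knockouts = NULL,
                         extraBounds = NULL, sense = "max") {
  b <- .resolveBounds(network, medium, knockouts, extraBounds)
  mod <- .lpModel(sense)
  .lpAddVars(mod, network@reactions, lb = b$lb, ub = b$ub)
  S <- network@S
  Sl <- Matrix::summary(S)  # triplets i j x
  for (i in seq_along(network@metabolites)) {
    rows <- Sl$i == i
    if (!any(rows)) next
    .lpAddRow(mod, vars = Sl$j[rows], coefs = Sl$x[rows], dir = "=",
              rhs = 0, name = network@metabolites[i])
  }
  if (!is.null(objective))
    .lpSetObj(mod, objective, 1)
  mod
}

.massBalanceResidual <- function(network, fluxVec) {
  max(abs(as.numeric(network@S %*% fluxVec[network@reactions])))
}

#' Flux balance analysis
#'
#' Maximizes (or minimizes) one reaction flux subject to steady-state mass
#' balance \eqn{S v = 0}, the model's flux bounds, the medium's uptake
#' bounds, zero bounds for knocked-out reactions, and optional per-reaction
#' bound overrides.
#'
#' @param network a \code{MetabolicNetwork}.
#' @param medium a \code{Medium}, or NULL to use the raw model bounds.
#' @param objective reaction id to optimize; defaults to the biomass
#'   reaction.
#' @param knockouts a \code{KnockoutVector}, a character vector of reaction
#'   ids, or NULL/empty for the wild type.
#' @param extraBounds named list of \code{c(lb, ub)} overrides (NA keeps the
#'   resolved bound).
#' @param sense "max" or "min".
#' @param config a \code{\link{solveConfig}}.
#' @return a \code{\link{FluxDistribution}}; its status is "infeasible" only
#'   if the constraints conflict, "unbounded" if the objective is unbounded
#'   (a diagnostic names reactions with infinite bounds that may form an
#'   unbounded cycle).
#' @export
fba <- function(network, medium = NULL, objective = biomassReaction(network),
                knockouts = NULL, extraBounds = NULL,
                sense = c("max", "min"), config = solveConfig()) {
  sense <- match.arg(sense)
  if (!objective %in% network@reactions)
    stop("objective is not a reaction of the network: ", objective)
  mod <- .buildFluxLP(network, medium, objective, knockouts, extraBounds,
                      sense)
  res <- .lpSolve(mod, config)
  if (res$status == "unbounded") {
    loose <- network@reactions[!is.finite(mod$ub) | !is.finite(mod$lb)]
    warning("objective '", objective, "' is unbounded; reactions with ",
            "infinite bounds (unbounded cycle candidates): ",
            paste(loose, collapse = ", "))
  }
  fluxVec <- if (is.null(res$values))
    stats::setNames(rep(NA_real_, length(network@reactions)),
                    network@reactions)
  else res$values
  fd <- new("FluxDistribution", flux = fluxVec,
            objectiveValue = if (is.na(res$objective)) NA_real_
                             else res$objective,
            objectiveReaction = objective, status = res$status)
  if (fd@status == "optimal") {
    resid <- .massBalanceResidual(network, fd@flux)
    if (resid > config@massBalanceTolerance)
      warning(sprintf("mass-balance residual %.3g exceeds tolerance %.3g",
                      resid, config@massBalanceTolerance))
  }
  fd
}

# Returns the network with a transient secretion exchange added for
# `chemical` when it has none, plus the exchange id.
.ensureSecretionExchange <- function(network, chemical) {
  ex <- exchangeFor(network, chemical)
  if (!is.na(ex)) return(list(network = network, exchange = ex))
  i <- match(chemical, network@metabolites)
  exId <- paste0("EX_", chemical, "_transient")
  message("adding transient secretion exchange '", exId, "' for ", chemical)
  S2 <- cbind(network@S, Matrix::sparseMatrix(
    i = i, j = 1L, x = -1, dims = c(length(network@metabolites), 1L)))
  net2 <- metabolicNetwork(
    metabolites = network@metabolites,
    reactions = c(network@reactions, exId), S = S2,
    lowerBounds = c(network@lowerBounds, 0),
    upperBounds = c(network@upperBounds, 1000),
    biomassReaction = network@biomassReaction,
    reversible = c(network@reversible, FALSE),
    exchangeReactions = c(network@exchangeReactions, exId),
    geneRules = c(network@geneRules, ""),
    coreNutrients = network@coreNutrients, metadata = network@metadata)
  list(network = net2, exchange = exId)
}

#' Maximal production rate of a chemical at a viability floor
#'
#' Maximizes the secretion flux of a chemical while constraining the biomass
#' flux to at least \code{minGrowth}. If the chemical has no exchange
#' reaction, a transient secretion exchange is added (and reported).
#'
#' @inheritParams fba
#' @param chemical metabolite id to secrete.
#' @param minGrowth biomass viability floor (default 0.1, the conventional
#'   threshold of growth-coupled design methods).
#' @return the maximal secretion rate; NA with attribute
#'   \code{status = "infeasible"} when the viability floor cannot be met
#'   (distinguished from a feasible zero production).
#' @export
maxProduction <- function(network, medium, chemical, minGrowth = 0.1,
                          knockouts = NULL, config = solveConfig()) {
  stopifnot(minGrowth >= 0)
  tmp <- .ensureSecretionExchange(network, chemical)
  eb <- list(c(minGrowth, NA))
  names(eb) <- tmp$network@biomassReaction
  fd <- fba(tmp$network, medium, objective = tmp$exchange,
            knockouts = knockouts, extraBounds = eb, config = config)
  if (fd@status != "optimal") {
    out <- NA_real_
    attr(out, "status") <- fd@status
    return(out)
  }
  out <- fd@objectiveValue
  attr(out, "status") <- "optimal"
  out
}

#' Feasible flux range of one reaction
#'
#' Minimizes and maximizes a single flux over the feasible region (two LP
#' solves); used for big-M calibration and for bracketing inner-problem
#' optima.
#'
#' @inheritParams fba
#' @param reaction reaction id.
#' @return numeric \code{c(min, max)}; both 0 for a blocked reaction.
#' @export
fluxBounds <- function(network, medium = NULL, reaction,
                       knockouts = NULL, extraBounds = NULL,
                       config = solveConfig()) {
  lo <- fba(network, medium, objective = reaction, knockouts = knockouts,
            extraBounds = extraBounds, sense = "min", config = config)
  hi <- fba(network, medium, objective = reaction, knockouts = knockouts,
            extraBounds = extraBounds, sense = "max", config = config)
  if (lo@status == "infeasible" || hi@status == "infeasible")
    stop("feasible region is empty; no flux range for ", reaction)
  c(min = if (lo@status == "unbounded") -Inf else lo@objectiveValue,
    max = if (hi@status == "unbounded") Inf else hi@objectiveValue)
}
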