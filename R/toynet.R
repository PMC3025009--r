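# Deterministic synthetic metabolic networks with planted auxotrophy and
# coupling structure, plus brute-force oracles that solve the design
# problems by exhaustive enumeration of knockout subsets and plain FBA.
#
# The generated topology emulates the pathway structure underlying
# auxotrophy design: a sensed chemical C synthesized from the carbon source
# by one or more parallel routes, optionally also reachable from an
# importable salvage precursor P (the tryptophan-from-indole motif), a
# biomass drain fed by C, and optional production motifs for a target
# chemical D and a detectable proxy X.

#' Specification of a synthetic toy network
#'
#' @param routes number of parallel synthesis routes from the carbon source
#'   to the sensed chemical (>= 1).
#' @param salvage add an importable precursor P with a transport reaction
#'   P -> C, so that blocking synthesis alone does not abolish growth
#'   without C (minimal biosensor cut-set size grows by one).
#' @param motif production-coupling motif: "none"; "coproduct" (target D and
#'   proxy X are co-products of a single reaction, hard-wired coupling);
#'   "bypass" (a C-only route can be knocked out to force flux through a
#'   co-producing route, and a proxy-only branch competes with a
#'   target+proxy branch).
#' @param decoys number of inert side-branch reactions added to enlarge the
#'   knockout-candidate universe (0-3).
#' @param seed integer seed; capacities are small integers derived from it
#'   arithmetically, so the emitted network is bit-reproducible across
#'   platforms.
#' @return a list of class \code{"toySpec"}.
#' @export
toySpec <- function(routes = 1L, salvage = FALSE,
                    motif = c("none", "coproduct", "bypass"),
                    decoys = 1L, seed = 1L) {
  motif <- match.arg(motif)
  stopifnot(routes >= 1L, decoys >= 0L, decoys <= 3L)
  structure(list(routes = as.integer(routes), salvage = isTRUE(salvage),
                 motif = motif, decoys = as.integer(decoys),
                 seed = as.integer(seed)),
            class = "toySpec")
}

# small-integer capacity in 3..9, fully determined by (seed, slot)
.toyCap <- function(seed, slot) 3L + (seed * 5L + slot * 13L) %% 7L

#' Generate a synthetic toy network
#'
#' The network uses unit stoichiometry and small-integer flux caps so that
#' oracle comparisons are free of floating-point sensitivity. Ground truth
#' (sensed chemical, carbon source, target, proxy, minimal biosensor
#' cut-sets) is recorded in \code{modelMetadata(net)$truth}.
#'
#' @param spec a \code{\link{toySpec}}.
#' @return a validated \code{\link{MetabolicNetwork}}.
#' @export
generateToy <- function(spec = toySpec()) {
  stopifnot(inherits(spec, "toySpec"))
  mets <- c("A", "C")
  rxn <- list()  # name -> list(stoich (named), lb, ub)
  addRxn <- function(name, stoich, lb, ub)
    rxn[[name]] <<- list(stoich = stoich, lb = lb, ub = ub)
  addRxn("EX_A", c(A = -1), 0, 100)
  synth <- character()  # reactions producing C (biosensor must cut them all)
  for (i in seq_len(spec$routes)) {
    id <- sprintf("SYN%d", i)
    addRxn(id, c(A = -1, C = 1), 0, .toyCap(spec$seed, i))
    synth <- c(synth, id)
  }
  if (spec$salvage) {
    mets <- c(mets, "P")
    addRxn("TP", c(P = -1, C = 1), 0, .toyCap(spec$seed, 11L))
    addRxn("EX_P", c(P = -1), 0, 100)
    synth <- c(synth, "TP")
  }
  target <- proxy <- NA_character_
  if (spec$motif != "none") {
    mets <- c(mets, "D", "X")
    target <- "D"; proxy <- "X"
    if (spec$motif == "coproduct") {
      addRxn("PDX", c(A = -1, D = 1, X = 1), 0, .toyCap(spec$seed, 21L))
    } else {
      # bypass: C-only route PRD competes with nothing (it also makes D);
      # proxy-only branch PX competes with the target+proxy branch PDX
      addRxn("PRD", c(A = -1, C = 1, D = 1), 0, .toyCap(spec$seed, 22L))
      synth <- c(synth, "PRD")
      addRxn("PX", c(A = -1, X = 1), 0, .toyCap(spec$seed, 23L))
      addRxn("PDX", c(A = -1, D = 1, X = 1), 0, .toyCap(spec$seed, 24L))
    }
    addRxn("EX_D", c(D = -1), 0, 100)
    addRxn("EX_X", c(X = -1), 0, 100)
  }
  for (j in seq_len(spec$decoys)) {
    zm <- sprintf("Z%d", j)
    mets <- c(mets, zm)
    st <- c(-1, 1); names(st) <- c("A", zm)
    addRxn(sprintf("DK%d", j), st, 0, .toyCap(spec$seed, 30L + j))
    st2 <- -1; names(st2) <- zm
    addRxn(sprintf("EX_Z%d", j), st2, 0, 100)
  }
  addRxn("BIOMASS", c(C = -1), 0, 100)
  addRxn("EX_C", c(C = -1), 0, 100)
  ids <- names(rxn)
  S <- matrix(0, nrow = length(mets), ncol = length(ids),
              dimnames = list(mets, ids))
  for (j in seq_along(ids)) {
    st <- rxn[[j]]$stoich
    S[names(st), j] <- st
  }
  net <- metabolicNetwork(
    metabolites = mets, reactions = ids, S = S,
    lowerBounds = vapply(rxn, `[[`, 0, "lb"),
    upperBounds = vapply(rxn, `[[`, 0, "ub"),
    biomassReaction = "BIOMASS",
    metadata = list(
      id = sprintf("toy_r%d_s%d_%s_d%d_seed%d", spec$routes, spec$salvage,
                   spec$motif, spec$decoys, spec$seed),
      carbon_source = "A",
      truth = list(chemical = "C", carbon = "A", target = target,
                   proxy = proxy, minimal_cut = synth,
                   cut_size = length(synth))))
  net
}

.checkCandidateCount <- function(candidates, limit = 15L) {
  if (length(candidates) > limit)
    stop("candidate set too large for exhaustive enumeration (",
         length(candidates), " > ", limit, ")")
}

.subsetsUpTo <- function(items, k) {
  out <- list(character())
  for (size in seq_len(min(k, length(items)))) {
    cmb <- utils::combn(items, size, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

# media used by biosensor design and verification for one network/chemical
.biosensorMedia <- function(network, chemicalId, mediumKind, uptake = 10,
                            carbonSource = NULL) {
  base <- if (mediumKind == "minimal")
    makeMedium(network, "minimal", carbonSource = carbonSource,
               defaultUptake = uptake)
  else
    makeMedium(network, "rich", exclude = chemicalId,
               defaultUptake = uptake)
  withC <- mediumPlusChemical(network, base, chemicalId, uptake)
  richNoC <- makeMedium(network, "rich", exclude = chemicalId,
                        defaultUptake = uptake)
  list(base = base, withC = withC, richNoC = richNoC)
}

.growthOrZero <- function(network, medium, ko, config) {
  fd <- fba(network, medium, knockouts = ko, config = config)
  if (fd@status != "optimal") 0 else fd@objectiveValue
}

#' Brute-force enumeration of all biosensor knockout sets
#'
#' Independent oracle for the bi-level design program: every knockout subset
#' of size at most k is scored by two plain FBA solves (growth on M plus the
#' chemical; growth on rich medium minus the chemical), exactly the
#' semantics of \code{\link{verifyDesign}}.
#'
#' @param network a \code{MetabolicNetwork}.
#' @param chemicalId sensed metabolite id.
#' @param mediumKind "minimal" or "rich".
#' @param k maximal subset size.
#' @param config a \code{\link{solveConfig}}.
#' @param candidates candidate reactions (<= 15; exhaustive bound).
#' @param uptake uptake magnitude for opened exchanges.
#' @return list of character vectors (each a working knockout set, sorted),
#'   ordered by size then lexicographically.
#' @export
bruteForceBiosensor <- function(network, chemicalId,
                                mediumKind = c("minimal", "rich"), k = 3L,
                                config = solveConfig(),
                                candidates = candidateReactions(network),
                                uptake = 10) {
  mediumKind <- match.arg(mediumKind)
  .checkCandidateCount(candidates)
  med <- .biosensorMedia(network, chemicalId, mediumKind, uptake)
  hits <- list()
  for (ko in .subsetsUpTo(candidates, k)) {
    gWith <- .growthOrZero(network, med$withC, ko, config)
    if (gWith < config@growthThreshold) next
    gWithout <- .growthOrZero(network, med$richNoC, ko, config)
    if (gWithout > config@zeroTolerance) next
    hits[[length(hits) + 1L]] <- sort(ko)
  }
  key <- vapply(hits, function(s)
    sprintf("%02d|%s", length(s), paste(s, collapse = ",")), "")
  hits[order(key)]
}

# Score one knockout set for a coupling design: inner optimum under the
# viability floor, then the best and worst target secretion over the
# inner-optimal face.
.nestedScore <- function(network, medium, targetExchange, innerObjective,
                         ko, minGrowth, config) {
  ebBase <- list(c(minGrowth, NA))
  names(ebBase) <- network@biomassReaction
  innerOpt <- fba(network, medium, objective = innerObjective,
                  knockouts = ko, extraBounds = ebBase, config = config)
  if (innerOpt@status != "optimal")
    return(list(feasible = FALSE, maxRate = NA_real_,
                guaranteedRate = NA_real_, innerOpt = NA_real_,
                growth = NA_real_))
  fstar <- innerOpt@objectiveValue
  eb <- ebBase
  eb[[innerObjective]] <- c(fstar - 1e-7 * max(1, abs(fstar)), NA)
  hi <- fba(network, medium, objective = targetExchange, knockouts = ko,
            extraBounds = eb, sense = "max", config = config)
  lo <- fba(network, medium, objective = targetExchange, knockouts = ko,
            extraBounds = eb, sense = "min", config = config)
  list(feasible = TRUE, maxRate = hi@objectiveValue,
       guaranteedRate = lo@objectiveValue, innerOpt = fstar,
       growth = unname(hi@flux[network@biomassReaction]))
}

#' Brute-force oracle for growth- and proxy-coupled strain design
#'
#' Enumerates every knockout subset of size at most k; for each, solves the
#' inner LP (maximal growth, or maximal proxy secretion, under the viability
#' floor), fixes its optimum, and measures the best- and worst-case target
#' secretion on the optimal face. Returns the best subset for the requested
#' sense together with all optimal subsets (ties within 1e-6).
#'
#' @param network a \code{MetabolicNetwork}.
#' @param target metabolite id whose secretion is designed.
#' @param coupledTo "biomass" or a proxy metabolite id.
#' @param medium the producer-strain \code{Medium}.
#' @param k maximal subset size.
#' @param minGrowth biomass viability floor.
#' @param sense "max" (optimistic) or "guaranteed_min".
#' @param config a \code{\link{solveConfig}}.
#' @param candidates candidate reactions (<= 15).
#' @return list with \code{knockouts}, \code{rate}, \code{allOptimal} (list
#'   of optimal subsets), and the per-subset score table.
#' @export
bruteForceCoupling <- function(network, target, coupledTo = "biomass",
                               medium, k = 2L, minGrowth = 0.1,
                               sense = c("max", "guaranteed_min"),
                               config = solveConfig(),
                               candidates = candidateReactions(network)) {
  sense <- match.arg(sense)
  .checkCandidateCount(candidates)
  tgt <- .ensureSecretionExchange(network, target)
  innerObjective <- if (identical(coupledTo, "biomass"))
    tgt$network@biomassReaction
  else {
    px <- .ensureSecretionExchange(tgt$network, coupledTo)
    tgt$network <- px$network
    px$exchange
  }
  subsets <- .subsetsUpTo(candidates, k)
  rates <- numeric(length(subsets))
  feas <- logical(length(subsets))
  for (i in seq_along(subsets)) {
    sc <- .nestedScore(tgt$network, medium, tgt$exchange, innerObjective,
                       subsets[[i]], minGrowth, config)
    feas[i] <- sc$feasible
    rates[i] <- if (!sc$feasible) -Inf else
      if (sense == "max") sc$maxRate else sc$guaranteedRate
  }
  if (!any(feas))
    return(list(knockouts = character(), rate = 0,
                allOptimal = list(character()), rates = rates,
                subsets = subsets))
  best <- max(rates[feas])
  optIdx <- which(feas & rates >= best - 1e-6)
  sizes <- lengths(subsets[optIdx])
  keys <- vapply(subsets[optIdx], function(s)
    sprintf("%02d|%s", length(s), paste(sort(s), collapse = ",")), "")
  pick <- optIdx[order(sizes, keys)][1]
  list(knockouts = sort(subsets[[pick]]), rate = best,
       allOptimal = lapply(subsets[optIdx], sort),
       rates = rates, subsets = subsets)
}
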