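# Growth- and proxy-coupled strain design: OptKnock, RobustKnock, and the
# proxy variants that couple target-chemical secretion to the secretion of
# a detectable proxy metabolite instead of biomass.
#
# All four methods share one engine. The inner objective is the coupled
# flux (biomass, or the proxy's secretion exchange); the outer objective is
# the target's secretion exchange. "max" sense returns the best-case target
# secretion at inner-optimal coupled flux (OptKnock semantics); "min" sense
# returns the guaranteed worst case over alternative inner optima
# (RobustKnock semantics). Every incumbent knockout pattern proposed by the
# MILP is re-scored by plain nested FBA solves; a pattern whose MILP value
# disagrees with its FBA score (possible only through big-M artifacts, e.g.
# when a pattern cannot sustain the viability floor) is excluded by an
# integer cut and the search repeated until the MILP bound meets the best
# verified pattern.

.couplingEngine <- function(network, target, innerChemical, medium, k,
                            minGrowth, sense, config,
                            candidates) {
  tgt <- .ensureSecretionExchange(network, target)
  net <- tgt$network
  if (identical(innerChemical, "biomass")) {
    innerObjective <- net@biomassReaction
    coupledTo <- "biomass"
  } else {
    px <- .ensureSecretionExchange(net, innerChemical)
    net <- px$network
    innerObjective <- px$exchange
    coupledTo <- innerChemical
  }
  bp <- bilevelProblem(net, outerObjective = tgt$exchange,
                       outerSense = sense,
                       innerObjective = innerObjective,
                       outerMedium = medium, innerMedium = medium,
                       innerConstraint = "optimal",
                       candidates = candidates, k = k,
                       minGrowth = minGrowth)
  h <- reformulateToMILP(bp, config)
  tol <- function(v) 1e-6 * max(1, abs(v))
  best <- NULL
  for (i in seq_len(60L)) {
    r <- solveMILP(h, config)
    if (r$status != "optimal") break
    if (!is.null(best) && r$objective <= best$rate + tol(best$rate)) break
    sc <- .nestedScore(net, medium, tgt$exchange, innerObjective,
                       r$knockouts, minGrowth, config)
    rate <- if (!sc$feasible) -Inf else
      if (sense == "max") sc$maxRate else sc$guaranteedRate
    if (sc$feasible && abs(r$objective - rate) <= tol(r$objective)) {
      # exact agreement: refine to the fewest knockouts at this value
      r2 <- .solveFewestKnockouts(h, r$objective, config)
      ko <- if (r2$status == "optimal")
        .extractKnockouts(r2$values, h$candidates) else r$knockouts
      sc2 <- .nestedScore(net, medium, tgt$exchange, innerObjective, ko,
                          minGrowth, config)
      rate2 <- if (!sc2$feasible) -Inf else
        if (sense == "max") sc2$maxRate else sc2$guaranteedRate
      if (sc2$feasible && abs(rate2 - rate) <= tol(rate)) {
        best <- list(rate = rate2, ko = ko, score = sc2)
      } else {
        best <- list(rate = rate, ko = r$knockouts, score = sc)
      }
      break
    }
    # disagreement: keep the verified value, exclude the pattern, re-solve
    if (sc$feasible && (is.null(best) || rate > best$rate))
      best <- list(rate = rate, ko = r$knockouts, score = sc)
    if (length(r$knockouts) == 0L) break   # cannot cut the wild type
    addIntegerCut(h, r$knockouts)
  }
  if (is.null(best))
    return(new("CouplingDesign", target = target, coupledTo = coupledTo,
               knockouts = character(), maxRate = 0,
               guaranteedRate = 0, minGrowth = minGrowth,
               growth = NA_real_))
  new("CouplingDesign", target = target, coupledTo = coupledTo,
      knockouts = sort(best$ko), maxRate = best$score$maxRate,
      guaranteedRate = best$score$guaranteedRate, minGrowth = minGrowth,
      growth = best$score$growth)
}

#' OptKnock: couple target secretion to biomass formation
#'
#' Searches for up to k reaction knockouts such that, when the cell then
#' maximizes growth, the target chemical is secreted. The returned
#' \code{maxRate} is the best-case secretion at growth-optimal flux; the
#' worst case over alternative growth optima is reported alongside as
#' \code{guaranteedRate}.
#'
#' @param network a \code{MetabolicNetwork}.
#' @param target metabolite id to over-produce (a secretion exchange is
#'   added transiently when absent).
#' @param medium the producer-strain \code{Medium} (typically glucose
#'   minimal).
#' @param k knockout budget (default 3).
#' @param minGrowth biomass viability floor (default 0.1).
#' @param config a \code{\link{solveConfig}}.
#' @param candidates knockout-candidate reactions.
#' @return a \code{CouplingDesign}; \code{maxRate} 0 when no coupling is
#'   achievable.
#' @export
optKnock <- function(network, target, medium, k = 3L, minGrowth = 0.1,
                     config = solveConfig(),
                     candidates = candidateReactions(network)) {
  .couplingEngine(network, target, "biomass", medium, k, minGrowth,
                  "max", config, candidates)
}

#' RobustKnock: maximize the guaranteed target secretion
#'
#' Max-min variant of \code{\link{optKnock}}: maximizes, over knockout
#' patterns, the minimal target secretion across all alternative
#' growth-optimal flux distributions, so the reported rate is guaranteed by
#' the model constraints.
#'
#' @inheritParams optKnock
#' @return a \code{CouplingDesign} whose \code{guaranteedRate} is the
#'   designed value.
#' @export
robustKnock <- function(network, target, medium, k = 3L, minGrowth = 0.1,
                        config = solveConfig(),
                        candidates = candidateReactions(network)) {
  .couplingEngine(network, target, "biomass", medium, k, minGrowth,
                  "min", config, candidates)
}

#' OptKnock-proxy: couple target secretion to a proxy metabolite
#'
#' Variant of \code{\link{optKnock}} that couples the target's production to
#' the secretion of a proxy metabolite (one with an available biosensor)
#' instead of biomass: the inner level maximizes proxy secretion, subject to
#' the biomass viability floor which is enforced at both levels.
#'
#' @inheritParams optKnock
#' @param proxy proxy metabolite id (must differ from the target); passing
#'   "biomass" reduces the method to plain \code{\link{optKnock}}.
#' @return a \code{CouplingDesign}.
#' @export
optKnockProxy <- function(network, target, proxy, medium, k = 3L,
                          minGrowth = 0.1, config = solveConfig(),
                          candidates = candidateReactions(network)) {
  if (identical(proxy, target))
    stop("proxy must differ from the target chemical")
  .couplingEngine(network, target, proxy, medium, k, minGrowth,
                  "max", config, candidates)
}

#' RobustKnock-proxy: guaranteed target secretion at optimal proxy secretion
#'
#' @inheritParams optKnockProxy
#' @return a \code{CouplingDesign} whose \code{guaranteedRate} is the
#'   designed value; never exceeds the \code{maxRate} of
#'   \code{\link{optKnockProxy}} on identical inputs.
#' @export
robustKnockProxy <- function(network, target, proxy, medium, k = 3L,
                             minGrowth = 0.1, config = solveConfig(),
                             candidates = candidateReactions(network)) {
  if (identical(proxy, target))
    stop("proxy must differ from the target chemical")
  .couplingEngine(network, target, proxy, medium, k, minGrowth,
                  "min", config, candidates)
}

#' Run a proxy-coupling method over a targets-by-proxies matrix
#'
#' @param network a \code{MetabolicNetwork}.
#' @param targets,proxies metabolite id vectors (nonempty).
#' @param medium producer-strain \code{Medium}.
#' @param method "optknock_proxy" or "robustknock_proxy".
#' @param k,minGrowth,config,candidates as in \code{\link{optKnockProxy}}.
#' @return list with \code{rates} (targets x proxies matrix of the designed
#'   rate), \code{knockouts} (matrix-indexed list of knockout sets),
#'   \code{perTargetCount} (number of proxies with rate > 1e-6 per target),
#'   \code{knockoutUnion}, and \code{failures} (per-cell error messages).
#' @export
couplingMatrix <- function(network, targets, proxies, medium,
                           method = c("optknock_proxy", "robustknock_proxy"),
                           k = 3L, minGrowth = 0.1, config = solveConfig(),
                           candidates = candidateReactions(network)) {
  method <- match.arg(method)
  stopifnot(length(targets) > 0, length(proxies) > 0)
  fun <- if (method == "optknock_proxy") optKnockProxy else robustKnockProxy
  rates <- matrix(NA_real_, length(targets), length(proxies),
                  dimnames = list(targets, proxies))
  kos <- vector("list", length(targets) * length(proxies))
  dim(kos) <- dim(rates); dimnames(kos) <- dimnames(rates)
  failures <- character()
  for (ti in seq_along(targets)) for (pi in seq_along(proxies)) {
    if (identical(targets[ti], proxies[pi])) next
    cell <- tryCatch(
      fun(network, targets[ti], proxies[pi], medium, k, minGrowth,
          config, candidates),
      error = function(e) e)
    if (inherits(cell, "error")) {
      failures <- c(failures, sprintf("%s x %s: %s", targets[ti],
                                      proxies[pi], conditionMessage(cell)))
      next
    }
    rates[ti, pi] <- if (method == "optknock_proxy") cell@maxRate else
      cell@guaranteedRate
    kos[[ti, pi]] <- cell@knockouts
  }
  perTargetCount <- apply(rates, 1, function(r) sum(r > 1e-6, na.rm = TRUE))
  list(rates = rates, knockouts = kos, perTargetCount = perTargetCount,
       knockoutUnion = sort(unique(unlist(kos))), failures = failures,
       method = method)
}

#' Write a coupling matrix as wide TSV
#'
#' @param cm result of \code{\link{couplingMatrix}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeCouplingMatrix <- function(cm, path) {
  df <- data.frame(target = rownames(cm$rates), cm$rates,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
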