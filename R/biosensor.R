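# Ultra-auxotrophic biosensor design, verification, enumeration and
# spent-medium yield-sensitivity classification.
#
# A biosensor strain for chemical C is ultra-auxotrophic: it grows on medium
# M supplemented with C, and cannot grow on any medium lacking C, even one
# containing every other transportable nutrient. The design search is a
# bi-level program: the outer level picks up to k knockouts and a flux
# distribution with maximal growth on M + C; the inner level forces the
# maximal growth on rich-minus-C to (numerical) zero.

.extractKnockouts <- function(values, candidates) {
  yv <- values[.yName(candidates)]
  candidates[yv < 0.5]
}

.newBiosensorDesign <- function(chemicalId, mediumKind, ko, gWith, gWithout,
                                verified) {
  new("BiosensorDesign", chemical = chemicalId, mediumKind = mediumKind,
      knockouts = sort(ko), growthWithC = gWith, growthWithoutC = gWithout,
      verified = verified, insensitiveYield = NA)
}

#' Verify a biosensor design by two independent FBA solves
#'
#' Checks (i) growth on medium M plus the sensed chemical, and (ii) no
#' growth on rich medium minus the chemical, using plain FBA with the
#' design's knockouts -- independent of the MILP that proposed the design.
#' This is the acceptance oracle for every design the MILP emits.
#'
#' @param network a \code{MetabolicNetwork}.
#' @param design a \code{BiosensorDesign}.
#' @param config a \code{\link{solveConfig}}.
#' @param uptake uptake magnitude for opened exchanges.
#' @return the design with \code{growthWithC}, \code{growthWithoutC} and
#'   \code{verified} recomputed.
#' @export
verifyDesign <- function(network, design, config = solveConfig(),
                         uptake = 10) {
  med <- .biosensorMedia(network, design@chemical, design@mediumKind,
                         uptake)
  gWith <- .growthOrZero(network, med$withC, design@knockouts, config)
  gWithout <- .growthOrZero(network, med$richNoC, design@knockouts, config)
  .newBiosensorDesign(design@chemical, design@mediumKind, design@knockouts,
                      gWith, gWithout,
                      gWith >= config@growthThreshold &&
                        gWithout <= config@zeroTolerance)
}

.biosensorProblem <- function(network, chemicalId, mediumKind, k, config,
                              candidates, uptake) {
  med <- .biosensorMedia(network, chemicalId, mediumKind, uptake)
  bilevelProblem(network,
                 outerObjective = network@biomassReaction,
                 outerSense = "max",
                 innerObjective = network@biomassReaction,
                 outerMedium = med$withC, innerMedium = med$richNoC,
                 innerConstraint = "max_zero",
                 innerCap = config@zeroTolerance,
                 candidates = candidates, k = k,
                 minGrowth = config@growthThreshold)
}

#' Design an ultra-auxotrophic biosensor strain
#'
#' Solves the bi-level knockout program for the sensed chemical: maximize
#' growth on M plus the chemical over knockout patterns whose maximal growth
#' on rich-minus-chemical is (numerically) zero. Among maximal-growth
#' patterns, one with the fewest knockouts is returned. Every returned
#' design is re-verified with \code{\link{verifyDesign}}; in the rare event
#' of a verification failure the pattern is excluded by an integer cut and
#' the search repeated.
#'
#' @param network a \code{MetabolicNetwork}.
#' @param chemicalId sensed metabolite id; must be transportable.
#' @param mediumKind "minimal" or "rich" base medium M.
#' @param k knockout budget.
#' @param config a \code{\link{solveConfig}}.
#' @param candidates knockout-candidate reactions.
#' @param uptake uptake magnitude for opened exchanges.
#' @return a verified \code{BiosensorDesign}, or NULL when no knockout set
#'   within the budget achieves ultra-auxotrophy (an infeasible design
#'   search is a result, not an error).
#' @export
designBiosensor <- function(network, chemicalId,
                            mediumKind = c("minimal", "rich"), k = 3L,
                            config = solveConfig(),
                            candidates = candidateReactions(network),
                            uptake = 10) {
  mediumKind <- match.arg(mediumKind)
  if (!chemicalId %in% transportableChemicals(network))
    stop("chemical is not transportable: ", chemicalId)
  bp <- .biosensorProblem(network, chemicalId, mediumKind, k, config,
                          candidates, uptake)
  h <- reformulateToMILP(bp, config)
  .nextBiosensorDesign(h, network, chemicalId, mediumKind, config, uptake)
}

# solve + fewest-knockouts refinement + verification, with integer-cut
# retries; returns NULL when the MILP is infeasible
.nextBiosensorDesign <- function(h, network, chemicalId, mediumKind, config,
                                 uptake, maxRetries = 25L) {
  for (i in seq_len(maxRetries)) {
    r <- solveMILP(h, config)
    if (r$status != "optimal") return(NULL)
    r2 <- .solveFewestKnockouts(h, r$objective, config)
    ko <- if (r2$status == "optimal")
      .extractKnockouts(r2$values, h$candidates) else r$knockouts
    design <- verifyDesign(network,
                           .newBiosensorDesign(chemicalId, mediumKind, ko,
                                               NA_real_, NA_real_, FALSE),
                           config, uptake)
    if (design@verified) return(design)
    if (length(ko) == 0L) return(NULL)  # unverifiable wild type: no design
    addIntegerCut(h, ko)
  }
  stop("biosensor search did not stabilize after ", maxRetries,
       " verification retries (numerical trouble; adjust bigM/tolerances)")
}

#' Enumerate alternative biosensor designs via integer cuts
#'
#' Repeats \code{\link{designBiosensor}} and, after each returned design,
#' excludes its exact knockout pattern with an integer cut, until the MILP
#' becomes infeasible or \code{maxAlternatives} designs were found. All
#' returned knockout sets are distinct and verified.
#'
#' @inheritParams designBiosensor
#' @param maxAlternatives stop after this many designs.
#' @return list of \code{BiosensorDesign} objects (empty when the chemical
#'   admits no design).
#' @export
enumerateDesigns <- function(network, chemicalId,
                             mediumKind = c("minimal", "rich"), k = 3L,
                             maxAlternatives = Inf, config = solveConfig(),
                             candidates = candidateReactions(network),
                             uptake = 10) {
  mediumKind <- match.arg(mediumKind)
  if (!chemicalId %in% transportableChemicals(network))
    stop("chemical is not transportable: ", chemicalId)
  bp <- .biosensorProblem(network, chemicalId, mediumKind, k, config,
                          candidates, uptake)
  h <- reformulateToMILP(bp, config)
  out <- list()
  while (length(out) < maxAlternatives) {
    d <- .nextBiosensorDesign(h, network, chemicalId, mediumKind, config,
                              uptake)
    if (is.null(d)) break
    out[[length(out) + 1L]] <- d
    if (length(d@knockouts) == 0L) break  # wild-type design: nothing to cut
    addIntegerCut(h, d@knockouts)
  }
  out
}

#' Growth-yield curves of a biosensor under poor and rich supplementation
#'
#' For each uptake rate of the sensed chemical, maximizes growth under (a)
#' the minimal base medium and (b) rich supplementation (all transportable
#' nutrients except the chemical). The slope of each curve is the biomass
#' yield per unit chemical; a sensor whose two slopes agree within the
#' configured relative tolerance quantifies the chemical reliably even in
#' poor spent medium ("insensitive"), otherwise accurate quantification
#' requires rich supplementation.
#'
#' @param network a \code{MetabolicNetwork}.
#' @param design a verified \code{BiosensorDesign}.
#' @param uptakeGrid chemical-uptake rates; default 10 evenly spaced points
#'   in (0, uptake].
#' @param config a \code{\link{solveConfig}}.
#' @param uptake maximal uptake magnitude (grid upper end).
#' @return list with \code{uptake} (grid, 0 prepended), \code{poor} and
#'   \code{rich} growth curves, per-point yields, the \code{insensitive}
#'   flag, and the updated \code{design}.
#' @export
yieldSensitivity <- function(network, design, uptakeGrid = NULL,
                             config = solveConfig(), uptake = 10) {
  if (!design@verified)
    stop("design must be verified before sensitivity analysis")
  if (is.null(uptakeGrid))
    uptakeGrid <- seq(uptake / 10, uptake, length.out = 10)
  stopifnot(all(uptakeGrid > 0))
  uptakeGrid <- sort(uptakeGrid)
  medPoor <- makeMedium(network, "minimal",
                        carbonSource = network@metadata$carbon_source)
  medRich <- makeMedium(network, "rich", exclude = design@chemical)
  ex <- exchangeFor(network, design@chemical)
  if (is.na(ex)) stop("sensed chemical has no exchange: ", design@chemical)
  curve <- function(med) {
    vapply(uptakeGrid, function(a) {
      eb <- list(c(-a, 0))
      names(eb) <- ex
      fd <- fba(network, med, knockouts = design@knockouts,
                extraBounds = eb, config = config)
      if (fd@status != "optimal") 0 else fd@objectiveValue
    }, 0)
  }
  poor <- curve(medPoor)
  rich <- curve(medRich)
  tolM <- 1e-7 * max(1, max(poor), max(rich))
  if (any(diff(poor) < -tolM) || any(diff(rich) < -tolM))
    stop("internal error: non-monotone growth curve (violates LP ",
         "monotonicity in the uptake bound)")
  yieldPoor <- poor / uptakeGrid
  yieldRich <- rich / uptakeGrid
  relDiff <- abs(yieldPoor - yieldRich) /
    pmax(yieldRich, yieldPoor, .Machine$double.eps)
  insensitive <- all(relDiff <= config@insensitivityTolerance)
  design@insensitiveYield <- insensitive
  list(uptake = c(0, uptakeGrid), poor = c(0, poor), rich = c(0, rich),
       yieldPoor = yieldPoor, yieldRich = yieldRich,
       insensitive = insensitive, design = design)
}

#' Write biosensor designs as TSV or JSON
#'
#' @param designs list of \code{BiosensorDesign} objects.
#' @param path output file; format chosen by extension (.tsv or .json).
#' @param network optional network used to attach gene-association strings.
#' @return \code{path}, invisibly.
#' @export
writeDesigns <- function(designs, path, network = NULL) {
  rows <- lapply(designs, function(d) {
    genes <- if (is.null(network)) "" else
      paste(geneRules(network)[d@knockouts], collapse = "; ")
    list(chemical = d@chemical, medium_kind = d@mediumKind,
         knockouts = paste(d@knockouts, collapse = ";"),
         gene_rules = genes,
         growth_with_C = d@growthWithC,
         growth_without_C = d@growthWithoutC,
         verified = d@verified,
         insensitive_yield = d@insensitiveYield)
  })
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(rows, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    df <- do.call(rbind, lapply(rows, function(r)
      data.frame(r, stringsAsFactors = FALSE)))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
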