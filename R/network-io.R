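# Model construction and I/O: COBRA-style JSON (read/write), SBML (read),
# medium files, transportable-chemical and knockout-candidate universes.

#' Construct a metabolic network model
#'
#' Low-level constructor used by the readers and the toy-network generator.
#' Exchange reactions are auto-detected (a single nonzero stoichiometric
#' entry) when not given.
#'
#' @param metabolites metabolite ids.
#' @param reactions reaction ids.
#' @param S stoichiometric matrix (n metabolites x m reactions), dense or
#'   sparse.
#' @param lowerBounds,upperBounds per-reaction flux bounds (mmol/gDW/h).
#' @param biomassReaction id of the growth reaction.
#' @param reversible per-reaction flags; default \code{lowerBounds < 0}.
#' @param exchangeReactions boundary reactions; auto-detected if NULL.
#' @param geneRules optional gene-association strings.
#' @param coreNutrients metabolite ids of the minimal-medium core set.
#' @param metadata free-form list.
#' @return a validated \code{\link{MetabolicNetwork}}.
#' @export
metabolicNetwork <- function(metabolites, reactions, S, lowerBounds,
                             upperBounds, biomassReaction,
                             reversible = lowerBounds < 0,
                             exchangeReactions = NULL,
                             geneRules = rep("", length(reactions)),
                             coreNutrients = character(),
                             metadata = list()) {
  S <- Matrix::Matrix(S, sparse = TRUE)
  if (is.null(exchangeReactions)) {
    nnz <- Matrix::colSums(S != 0)
    # the biomass drain also has a single-entry column; it is not boundary
    exchangeReactions <- setdiff(reactions[nnz == 1L], biomassReaction)
  }
  new("MetabolicNetwork", metabolites = as.character(metabolites),
      reactions = as.character(reactions), S = S,
      lowerBounds = as.numeric(lowerBounds),
      upperBounds = as.numeric(upperBounds),
      reversible = as.logical(reversible),
      exchangeReactions = as.character(exchangeReactions),
      biomassReaction = as.character(biomassReaction),
      geneRules = as.character(geneRules),
      coreNutrients = as.character(coreNutrients), metadata = metadata)
}

.guessBiomass <- function(ids, objective = NULL) {
  if (!is.null(objective) && length(objective) == 1L) return(objective)
  hit <- grep("biomass|growth", ids, ignore.case = TRUE, value = TRUE)
  if (length(hit)) return(hit[1])
  NULL
}

#' Read a metabolic network model from SBML or COBRA-style JSON
#'
#' @param path file path.
#' @param format "json" or "sbml"; guessed from the file extension by
#'   default.
#' @param biomassReaction optional explicit biomass reaction id; otherwise
#'   taken from the model objective, or matched by name.
#' @return a validated \code{\link{MetabolicNetwork}}.
#' @export
readMetabolicModel <- function(path,
                               format = c("auto", "json", "sbml"),
                               biomassReaction = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  if (!file.exists(path)) stop("model file not found: ", path)
  switch(format,
         json = .readModelJSON(path, biomassReaction),
         sbml = .readModelSBML(path, biomassReaction))
}

.readModelJSON <- function(path, biomassReaction = NULL) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("JSON parse failure in '", path, "': ",
                         conditionMessage(e)))
  if (is.null(doc$metabolites) || is.null(doc$reactions))
    stop("not a COBRA-style JSON model (missing element ",
         if (is.null(doc$metabolites)) "'metabolites'" else "'reactions'",
         "): ", path)
  mets <- vapply(doc$metabolites, function(m) as.character(m$id), "")
  rxns <- vapply(doc$reactions, function(r) as.character(r$id), "")
  m <- length(rxns)
  ii <- integer(); jj <- integer(); xx <- numeric()
  lb <- numeric(m); ub <- numeric(m); gr <- character(m)
  objCoef <- numeric(m)
  for (j in seq_len(m)) {
    r <- doc$reactions[[j]]
    sm <- r$metabolites
    if (length(sm)) {
      idx <- match(names(sm), mets)
      if (anyNA(idx))
        stop("reaction '", rxns[j], "' references unknown metabolite(s): ",
             paste(names(sm)[is.na(idx)], collapse = ", "))
      ii <- c(ii, idx); jj <- c(jj, rep(j, length(sm)))
      xx <- c(xx, vapply(sm, as.numeric, 0))
    }
    lb[j] <- if (is.null(r$lower_bound)) -1000 else as.numeric(r$lower_bound)
    ub[j] <- if (is.null(r$upper_bound)) 1000 else as.numeric(r$upper_bound)
    gr[j] <- if (is.null(r$gene_reaction_rule)) "" else
      as.character(r$gene_reaction_rule)
    objCoef[j] <- if (is.null(r$objective_coefficient)) 0 else
      as.numeric(r$objective_coefficient)
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(mets), m))
  biomass <- biomassReaction
  if (is.null(biomass) && !is.null(doc$biomass_reaction))
    biomass <- doc$biomass_reaction
  if (is.null(biomass))
    biomass <- .guessBiomass(rxns, if (any(objCoef != 0))
      rxns[which(objCoef != 0)][1] else NULL)
  if (is.null(biomass))
    stop("missing biomass reaction: no objective coefficient set and no ",
         "reaction id matches 'biomass'/'growth' in ", path)
  metabolicNetwork(
    metabolites = mets, reactions = rxns, S = S, lowerBounds = lb,
    upperBounds = ub, biomassReaction = biomass, geneRules = gr,
    coreNutrients = as.character(unlist(doc$core_nutrients)),
    metadata = if (is.null(doc$metadata)) list() else doc$metadata)
}

.xattr <- function(node, name) {
  a <- xml2::xml_attrs(node)
  for (key in c(name, paste0("fbc:", name))) {
    if (key %in% names(a)) return(a[[key]])
  }
  NA_character_
}

.readModelSBML <- function(path, biomassReaction = NULL) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e)
                    stop("SBML parse failure in '", path, "': ",
                         conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  model <- xml2::xml_find_first(doc, ".//model")
  if (inherits(model, "xml_missing"))
    stop("SBML parse failure: no <model> element in ", path)
  spNodes <- xml2::xml_find_all(model, ".//listOfSpecies/species")
  boundary <- xml2::xml_attr(spNodes, "boundaryCondition") %in% "true"
  spIds <- xml2::xml_attr(spNodes, "id")
  mets <- spIds[!boundary]
  # global flux-bound parameters (SBML L3 fbc style)
  parNodes <- xml2::xml_find_all(model, "./listOfParameters/parameter")
  pars <- stats::setNames(as.numeric(xml2::xml_attr(parNodes, "value")),
                          xml2::xml_attr(parNodes, "id"))
  rxNodes <- xml2::xml_find_all(model, ".//listOfReactions/reaction")
  if (length(rxNodes) == 0L)
    stop("SBML parse failure: no reactions in ", path)
  rxns <- xml2::xml_attr(rxNodes, "id")
  m <- length(rxns)
  ii <- integer(); jj <- integer(); xx <- numeric()
  lb <- numeric(m); ub <- numeric(m); gr <- character(m)
  for (j in seq_len(m)) {
    node <- rxNodes[[j]]
    rev <- !(xml2::xml_attr(node, "reversible") %in% "false")
    refs <- function(xp, sign) {
      sr <- xml2::xml_find_all(node, xp)
      sp <- xml2::xml_attr(sr, "species")
      st <- as.numeric(xml2::xml_attr(sr, "stoichiometry"))
      st[is.na(st)] <- 1
      keep <- sp %in% mets   # boundary species drop out of S
      idx <- match(sp[keep], mets)
      if (length(idx)) {
        ii <<- c(ii, idx); jj <<- c(jj, rep(j, length(idx)))
        xx <<- c(xx, sign * st[keep])
      }
    }
    refs("./listOfReactants/speciesReference", -1)
    refs("./listOfProducts/speciesReference", +1)
    # bounds: L2 COBRA kineticLaw parameters, or L3 fbc parameter refs
    kl <- xml2::xml_find_all(node,
      "./kineticLaw//parameter[@id='LOWER_BOUND' or @id='UPPER_BOUND']")
    lbj <- ubj <- NA_real_
    if (length(kl)) {
      kid <- xml2::xml_attr(kl, "id")
      kv <- as.numeric(xml2::xml_attr(kl, "value"))
      lbj <- kv[match("LOWER_BOUND", kid)]
      ubj <- kv[match("UPPER_BOUND", kid)]
    }
    lbRef <- .xattr(node, "lowerFluxBound")
    ubRef <- .xattr(node, "upperFluxBound")
    if (!is.na(lbRef) && lbRef %in% names(pars)) lbj <- pars[[lbRef]]
    if (!is.na(ubRef) && ubRef %in% names(pars)) ubj <- pars[[ubRef]]
    lb[j] <- if (is.na(lbj)) (if (rev) -1000 else 0) else lbj
    ub[j] <- if (is.na(ubj)) 1000 else ubj
    gp <- xml2::xml_find_first(node, ".//geneProductAssociation")
    gr[j] <- if (inherits(gp, "xml_missing")) "" else
      paste(xml2::xml_attr(
        xml2::xml_find_all(gp, ".//geneProductRef"), "geneProduct"),
        collapse = " or ")
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(length(mets), m))
  biomass <- biomassReaction
  if (is.null(biomass)) {
    fluxObj <- xml2::xml_find_first(doc, ".//fluxObjective")
    if (!inherits(fluxObj, "xml_missing"))
      biomass <- .xattr(fluxObj, "reaction")
  }
  if (is.null(biomass) || is.na(biomass))
    biomass <- .guessBiomass(rxns)
  if (is.null(biomass))
    stop("missing biomass reaction: no flux objective and no reaction id ",
         "matches 'biomass'/'growth' in ", path)
  metabolicNetwork(metabolites = mets, reactions = rxns, S = S,
                   lowerBounds = lb, upperBounds = ub,
                   biomassReaction = biomass, geneRules = gr)
}

#' Write a model in the COBRA-style JSON dialect
#'
#' The dialect mirrors the common COBRA JSON schema (so published models load
#' unmodified) with optional extra top-level fields \code{biomass_reaction},
#' \code{core_nutrients} and \code{metadata}.
#'
#' @param network a \code{MetabolicNetwork}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeModelJSON <- function(network, path) {
  S <- stoichiometry(network)
  rx <- lapply(seq_along(network@reactions), function(j) {
    col <- S[, j]
    nz <- which(col != 0)
    list(id = network@reactions[j],
         metabolites = as.list(stats::setNames(unname(col[nz]),
                                               network@metabolites[nz])),
         lower_bound = network@lowerBounds[j],
         upper_bound = network@upperBounds[j],
         gene_reaction_rule = network@geneRules[j],
         objective_coefficient =
           as.numeric(network@reactions[j] == network@biomassReaction))
  })
  doc <- list(
    id = if (!is.null(network@metadata$id)) network@metadata$id else "model",
    metabolites = lapply(network@metabolites, function(id) list(id = id)),
    reactions = rx,
    biomass_reaction = network@biomassReaction,
    core_nutrients = as.list(network@coreNutrients),
    metadata = network@metadata)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Chemicals that can be taken up from the growth medium
#'
#' A metabolite is transportable when it crosses the system boundary through
#' an exchange reaction and is connected to the interior of the network by at
#' least one non-exchange (transport or conversion) reaction. This set is
#' both the biosensor-candidate universe and the rich-medium nutrient set.
#'
#' @param network a \code{MetabolicNetwork}.
#' @return sorted character vector of metabolite ids.
#' @export
transportableChemicals <- function(network) {
  S <- network@S
  exIdx <- match(network@exchangeReactions, network@reactions)
  if (length(exIdx) == 0L) return(character())
  inIdx <- setdiff(seq_along(network@reactions), exIdx)
  hasExchange <- Matrix::rowSums(S[, exIdx, drop = FALSE] != 0) > 0
  hasInterior <- Matrix::rowSums(S[, inIdx, drop = FALSE] != 0) > 0
  sort(network@metabolites[hasExchange & hasInterior])
}

#' Exchange reaction carrying a given metabolite
#'
#' @param network a \code{MetabolicNetwork}.
#' @param metabolite metabolite id.
#' @return exchange reaction id, or NA if the metabolite has none.
#' @export
exchangeFor <- function(network, metabolite) {
  i <- match(metabolite, network@metabolites)
  if (is.na(i)) stop("unknown metabolite: ", metabolite)
  exIdx <- match(network@exchangeReactions, network@reactions)
  hit <- exIdx[which(network@S[i, exIdx] != 0)]
  if (length(hit) == 0L) return(NA_character_)
  network@reactions[hit[1]]
}

#' Knockout-candidate reactions
#'
#' The candidate universe excludes exchange reactions and the biomass
#' reaction (knocking out a boundary flux is a medium change, not a genetic
#' intervention), plus any explicitly excluded reactions (e.g. spontaneous or
#' diffusion reactions).
#'
#' @param network a \code{MetabolicNetwork}.
#' @param exclude additional reaction ids to exclude.
#' @return character vector of reaction ids, in network order.
#' @export
candidateReactions <- function(network, exclude = character()) {
  setdiff(network@reactions,
          c(network@exchangeReactions, network@biomassReaction, exclude))
}

#' Build a growth medium
#'
#' A minimal medium opens the uptake of the core nutrients plus one carbon
#' source; a rich medium opens the uptake of every transportable chemical
#' (optionally excluding one, e.g. the sensed chemical). Each opened exchange
#' gets uptake magnitude \code{defaultUptake} unless overridden.
#'
#' @param network a \code{MetabolicNetwork}.
#' @param kind "minimal" or "rich".
#' @param carbonSource carbon-source metabolite id (minimal medium); default
#'   from \code{modelMetadata(network)$carbon_source}.
#' @param exclude metabolite id whose uptake must stay closed.
#' @param defaultUptake uptake magnitude (mmol/gDW/h) for opened exchanges.
#' @param uptakes named numeric overrides (exchange reaction id -> rate).
#' @return a \code{\link{Medium}}.
#' @export
makeMedium <- function(network, kind = c("minimal", "rich"),
                       carbonSource = NULL, exclude = NULL,
                       defaultUptake = 10, uptakes = NULL) {
  kind <- match.arg(kind)
  transportable <- transportableChemicals(network)
  if (!is.null(exclude) && !exclude %in% transportable)
    stop("excluded chemical is not transportable: ", exclude)
  if (kind == "minimal") {
    if (is.null(carbonSource))
      carbonSource <- network@metadata$carbon_source
    if (is.null(carbonSource))
      stop("minimal medium needs a carbon source (argument or model ",
           "metadata 'carbon_source')")
    if (!carbonSource %in% transportable)
      stop("carbon source is not transportable: ", carbonSource)
    nutrients <- union(network@coreNutrients, carbonSource)
  } else {
    nutrients <- union(transportable, network@coreNutrients)
  }
  nutrients <- setdiff(nutrients, exclude)
  ex <- vapply(nutrients, function(m) exchangeFor(network, m), "")
  ex <- ex[!is.na(ex)]
  ub <- stats::setNames(rep(defaultUptake, length(ex)), unname(ex))
  if (!is.null(uptakes)) {
    known <- intersect(names(uptakes), names(ub))
    ub[known] <- uptakes[known]
  }
  new("Medium", uptakeBounds = ub,
      excludedChemical = if (is.null(exclude)) character() else exclude)
}

#' Add one chemical's uptake to a medium
#'
#' Used to form the outer-level medium M plus the sensed chemical C.
#'
#' @param network a \code{MetabolicNetwork}.
#' @param medium a \code{Medium}.
#' @param chemicalId metabolite id to open.
#' @param uptake uptake magnitude.
#' @return a new \code{Medium}.
#' @export
mediumPlusChemical <- function(network, medium, chemicalId, uptake = 10) {
  ex <- exchangeFor(network, chemicalId)
  if (is.na(ex)) stop("chemical has no exchange reaction: ", chemicalId)
  ub <- medium@uptakeBounds
  ub[ex] <- uptake
  new("Medium", uptakeBounds = ub,
      excludedChemical = setdiff(medium@excludedChemical, chemicalId))
}

#' Read/write a medium file
#'
#' Medium files are flat YAML or JSON maps \code{exchange_id: uptake_bound}.
#'
#' @param path file path (.yaml/.yml or .json).
#' @param network optional network; when given, keys are checked against its
#'   exchange reactions.
#' @return \code{readMedium}: a \code{Medium}.
#' @export
readMedium <- function(path, network = NULL) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::fromJSON(path)
  ub <- unlist(vals)
  if (!is.null(network) &&
      !all(names(ub) %in% network@exchangeReactions))
    stop("medium keys are not exchange reactions of the network: ",
         paste(setdiff(names(ub), network@exchangeReactions),
               collapse = ", "))
  new("Medium", uptakeBounds = ub, excludedChemical = character())
}

#' @rdname readMedium
#' @param medium a \code{Medium} to write.
#' @export
writeMedium <- function(medium, path) {
  vals <- as.list(medium@uptakeBounds)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(vals, path)
  else jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Resolve per-reaction bounds for a (network, medium, knockouts, overrides)
# combination: closed exchanges get uptake lower bound 0, open ones
# -uptake; knockouts force both bounds to 0; extraBounds applied last.
.resolveBounds <- function(network, medium = NULL, knockouts = NULL,
                           extraBounds = NULL) {
  lb <- network@lowerBounds
  ub <- network@upperBounds
  names(lb) <- names(ub) <- network@reactions
  if (!is.null(medium)) {
    ex <- network@exchangeReactions
    lb[ex] <- pmax(lb[ex], 0)
    open <- intersect(names(medium@uptakeBounds), ex)
    lb[open] <- -medium@uptakeBounds[open]
  }
  if (!is.null(knockouts)) {
    ko <- if (is(knockouts, "KnockoutVector"))
      knockouts@candidateReactions[!knockouts@y]
    else as.character(knockouts)
    if (length(ko)) {
      bad <- setdiff(ko, network@reactions)
      if (length(bad)) stop("unknown knockout reaction(s): ",
                            paste(bad, collapse = ", "))
      lb[ko] <- 0; ub[ko] <- 0
    }
  }
  if (!is.null(extraBounds)) {
    for (id in names(extraBounds)) {
      b <- extraBounds[[id]]
      if (!id %in% network@reactions)
        stop("extraBounds names unknown reaction: ", id)
      if (!is.na(b[1])) lb[id] <- b[1]
      if (!is.na(b[2])) ub[id] <- b[2]
    }
  }
  list(lb = lb, ub = ub)
}
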