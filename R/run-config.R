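# Run configuration and driver tying the modules together. A RunConfig is a
# plain named list that serializes to one YAML file from which a run can be
# reproduced exactly; runDesign() executes the named method and writes
# result files, a log with per-solve statistics, and the resolved config.

.runMethods <- c("design-biosensor", "enumerate", "verify", "sensitivity",
                 "optknock", "robustknock", "optknock-proxy",
                 "robustknock-proxy", "matrix", "toygen")

#' Build a run configuration
#'
#' @param method one of design-biosensor, enumerate, verify, sensitivity,
#'   optknock, robustknock, optknock-proxy, robustknock-proxy, matrix,
#'   toygen.
#' @param model path to an SBML/JSON model, or NULL for toygen.
#' @param format model format ("auto", "json", "sbml").
#' @param chemicalId sensed chemical (biosensor methods).
#' @param target,proxy target/proxy metabolite ids (strain-design methods);
#'   \code{target} and \code{proxy} may be vectors for \code{matrix}.
#' @param knockouts knockout reaction ids (verify/sensitivity).
#' @param mediumKind "minimal" or "rich".
#' @param carbonSource carbon source for minimal media (defaults to the
#'   model's declared one).
#' @param k knockout budget.
#' @param minGrowth biomass viability floor.
#' @param uptake uptake magnitude for opened exchanges.
#' @param maxAlternatives cap for enumerate.
#' @param toy list of \code{\link{toySpec}} arguments (toygen).
#' @param outputDir directory for result files.
#' @param seed integer seed (toy generation; recorded for reproducibility).
#' @param solver LP/MILP backend; only "glpk" is supported.
#' @param bigM,zeroTolerance,timeLimit solver parameters (see
#'   \code{\link{solveConfig}}).
#' @return a list of class \code{"runConfig"}.
#' @export
runConfig <- function(method, model = NULL, format = "auto",
                      chemicalId = NULL, target = NULL, proxy = NULL,
                      knockouts = NULL, mediumKind = "minimal",
                      carbonSource = NULL, k = 3L, minGrowth = 0.1,
                      uptake = 10, maxAlternatives = 100L, toy = list(),
                      outputDir = ".", seed = 1L, solver = "glpk",
                      bigM = 1000, zeroTolerance = 1e-6, timeLimit = 120) {
  if (!method %in% .runMethods)
    stop("unknown method '", method, "'; choose one of: ",
         paste(.runMethods, collapse = ", "))
  if (!identical(solver, "glpk"))
    stop("unsupported solver '", solver, "'; only glpk is available")
  cfg <- list(method = method, model = model, format = format,
              chemicalId = chemicalId, target = target, proxy = proxy,
              knockouts = knockouts, mediumKind = mediumKind,
              carbonSource = carbonSource, k = as.integer(k),
              minGrowth = minGrowth, uptake = uptake,
              maxAlternatives = maxAlternatives, toy = toy,
              outputDir = outputDir, seed = as.integer(seed),
              solver = solver, bigM = bigM, zeroTolerance = zeroTolerance,
              timeLimit = timeLimit)
  class(cfg) <- "runConfig"
  cfg
}

#' @rdname runConfig
#' @param path YAML file path.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(runConfig, cfg[intersect(names(cfg), names(formals(runConfig)))])
}

#' @rdname runConfig
#' @param cfg a \code{runConfig}.
#' @export
writeRunConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg)[!vapply(unclass(cfg), is.null, TRUE)], path)
  invisible(path)
}

.designToRow <- function(d) {
  if (is(d, "BiosensorDesign"))
    list(chemical = d@chemical, medium_kind = d@mediumKind,
         knockouts = paste(d@knockouts, collapse = ";"),
         growth_with_C = d@growthWithC,
         growth_without_C = d@growthWithoutC, verified = d@verified)
  else
    list(target = d@target, coupled_to = d@coupledTo,
         knockouts = paste(d@knockouts, collapse = ";"),
         max_rate = d@maxRate, guaranteed_rate = d@guaranteedRate,
         min_growth = d@minGrowth, growth = d@growth)
}

.writeRows <- function(rows, base) {
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(lapply(r, function(x) if (is.null(x)) NA else x),
               stringsAsFactors = FALSE)))
  utils::write.table(df, paste0(base, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(rows, paste0(base, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paste0(base, c(".tsv", ".json"))
}

#' Execute a configured run
#'
#' Loads (or generates) the model, executes the configured method, and
#' writes result files, the resolved configuration
#' (\code{resolved_config.yaml}, from which the run can be reproduced), and
#' a log with per-step status and wall time. Input errors (unknown method,
#' missing ids) are raised before any solve.
#'
#' @param cfg a \code{\link{runConfig}} (or path to its YAML file).
#' @return invisibly, a list with \code{status} (0 on success), and
#'   \code{files} written.
#' @export
runDesign <- function(cfg) {
  if (is.character(cfg)) cfg <- readRunConfig(cfg)
  stopifnot(inherits(cfg, "runConfig"))
  dir.create(cfg$outputDir, showWarnings = FALSE, recursive = TRUE)
  logFile <- file.path(cfg$outputDir, "run.log")
  logLines <- character()
  note <- function(...) {
    logLines <<- c(logLines, paste0(format(Sys.time(), "%H:%M:%S "), ...))
  }
  config <- solveConfig(zeroTolerance = cfg$zeroTolerance, bigM = cfg$bigM,
                        timeLimit = cfg$timeLimit)
  set.seed(cfg$seed)
  t0 <- proc.time()[["elapsed"]]
  files <- character()
  needs <- function(field) {
    if (is.null(cfg[[field]]))
      stop("method '", cfg$method, "' requires '", field, "'")
  }
  if (cfg$method == "toygen") {
    net <- generateToy(do.call(toySpec, c(cfg$toy, list(seed = cfg$seed))))
    out <- file.path(cfg$outputDir, "toy_model.json")
    writeModelJSON(net, out)
    files <- out
    note("toygen: wrote ", out)
  } else {
    needs("model")
    net <- readMetabolicModel(cfg$model, cfg$format)
    note("loaded model: ", length(reactions(net)), " reactions, ",
         length(metabolites(net)), " metabolites")
    base <- file.path(cfg$outputDir, "result")
    medium <- function() makeMedium(net, cfg$mediumKind,
                                    carbonSource = cfg$carbonSource,
                                    defaultUptake = cfg$uptake)
    files <- switch(
      cfg$method,
      "design-biosensor" = {
        needs("chemicalId")
        d <- designBiosensor(net, cfg$chemicalId, cfg$mediumKind, cfg$k,
                             config, uptake = cfg$uptake)
        note("design-biosensor: ",
             if (is.null(d)) "infeasible" else paste("knockouts:",
               paste(d@knockouts, collapse = ",")))
        .writeRows(if (is.null(d)) list() else list(.designToRow(d)), base)
      },
      "enumerate" = {
        needs("chemicalId")
        ds <- enumerateDesigns(net, cfg$chemicalId, cfg$mediumKind, cfg$k,
                               cfg$maxAlternatives, config,
                               uptake = cfg$uptake)
        note("enumerate: ", length(ds), " design(s)")
        .writeRows(lapply(ds, .designToRow), base)
      },
      "verify" = {
        needs("chemicalId")
        d <- .newBiosensorDesign(cfg$chemicalId, cfg$mediumKind,
                                 cfg$knockouts %||% character(),
                                 NA_real_, NA_real_, FALSE)
        d <- verifyDesign(net, d, config, cfg$uptake)
        note("verify: ", d@verified)
        .writeRows(list(.designToRow(d)), base)
      },
      "sensitivity" = {
        needs("chemicalId")
        d <- .newBiosensorDesign(cfg$chemicalId, cfg$mediumKind,
                                 cfg$knockouts %||% character(),
                                 NA_real_, NA_real_, FALSE)
        d <- verifyDesign(net, d, config, cfg$uptake)
        ys <- yieldSensitivity(net, d, config = config, uptake = cfg$uptake)
        out <- paste0(base, "_curves.tsv")
        utils::write.table(
          data.frame(uptake = ys$uptake, growth_poor = ys$poor,
                     growth_rich = ys$rich), out, sep = "\t",
          quote = FALSE, row.names = FALSE)
        note("sensitivity: insensitive = ", ys$insensitive)
        out
      },
      "optknock" = , "robustknock" = {
        needs("target")
        fun <- if (cfg$method == "optknock") optKnock else robustKnock
        d <- fun(net, cfg$target, medium(), cfg$k, cfg$minGrowth, config)
        note(cfg$method, ": rate ",
             if (cfg$method == "optknock") d@maxRate else d@guaranteedRate)
        .writeRows(list(.designToRow(d)), base)
      },
      "optknock-proxy" = , "robustknock-proxy" = {
        needs("target"); needs("proxy")
        fun <- if (cfg$method == "optknock-proxy") optKnockProxy
               else robustKnockProxy
        d <- fun(net, cfg$target, cfg$proxy, medium(), cfg$k,
                 cfg$minGrowth, config)
        note(cfg$method, ": rate ",
             if (cfg$method == "optknock-proxy") d@maxRate
             else d@guaranteedRate)
        .writeRows(list(.designToRow(d)), base)
      },
      "matrix" = {
        needs("target"); needs("proxy")
        cm <- couplingMatrix(net, cfg$target, cfg$proxy, medium(),
                             "optknock_proxy", cfg$k, cfg$minGrowth,
                             config)
        out <- paste0(base, "_matrix.tsv")
        writeCouplingMatrix(cm, out)
        note("matrix: ", sum(cm$rates > 1e-6, na.rm = TRUE),
             " coupled cell(s)")
        out
      })
  }
  note(sprintf("done in %.2f s", proc.time()[["elapsed"]] - t0))
  resolved <- file.path(cfg$outputDir, "resolved_config.yaml")
  writeRunConfig(cfg, resolved)
  writeLines(logLines, logFile)
  invisible(list(status = 0L, files = c(files, resolved, logFile)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
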