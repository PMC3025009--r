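# Bi-level to single-level MILP machinery.
#
# A level's linear program is held as a plain description ("desc"): variables
# with constant bounds, rows whose right-hand side may be affine in the
# binary knockout variables y (rhs = rhs0 + ycoef * y), and a maximization
# objective. One generic routine dualizes such a description: the dual system
# (dual feasibility plus big-M linearization of dual-times-y products) is
# itself a desc, together with a linear expression that, for every feasible
# point of the dual system, upper-bounds the primal optimum (weak duality).
#
# The three program shapes built here:
#  * no-growth cap  — dual system of the inner LP + (dual objective <= eps):
#    forces the inner maximum below eps (ultra-auxotrophy).
#  * optimistic coupling — primal vars + dual system + (primal objective >=
#    dual objective): pins the shared flux vector to the inner-optimal face;
#    the outer objective is then maximized over that face (OptKnock sense).
#  * robust coupling — the minimization of the outer objective over the
#    pinned face is dualized a second time; maximizing the negated second
#    dual objective over y yields the guaranteed (max-min) value
#    (RobustKnock sense).

.yName <- function(rxn) paste0("y.", rxn)

.descNew <- function() list(vars = list(), rows = list(),
                            obj = list(vars = character(), coef = numeric()))

.descAddVar <- function(desc, name, lb, ub) {
  desc$vars[[name]] <- c(lb = unname(lb), ub = unname(ub))
  desc
}

.descAddRow <- function(desc, name, vars, coef, dir, rhs0 = 0,
                        y = character(), ycoef = numeric()) {
  keep <- coef != 0
  desc$rows[[name]] <- list(vars = vars[keep], coef = coef[keep], dir = dir,
                            rhs0 = rhs0, y = y, ycoef = ycoef)
  desc
}

# LP of one level: flux variables under a medium, knockout-candidate bounds
# linked to y, mass balance, maximization of one reaction flux.
.descFluxLP <- function(network, medium, objective, candidates,
                        minGrowth = 0, prefix = "v.") {
  b <- .resolveBounds(network, medium)
  if (minGrowth > 0)
    b$lb[network@biomassReaction] <- minGrowth
  desc <- .descNew()
  vn <- paste0(prefix, network@reactions)
  isCand <- network@reactions %in% candidates
  for (j in seq_along(network@reactions)) {
    lbj <- b$lb[j]; ubj <- b$ub[j]
    if (isCand[j]) {
      # widen static bounds; the y-linked rows impose the active bounds
      desc <- .descAddVar(desc, vn[j], min(lbj, 0), max(ubj, 0))
      yj <- .yName(network@reactions[j])
      if (ubj != 0)
        desc <- .descAddRow(desc, paste0(prefix, "ub.", network@reactions[j]),
                            vn[j], 1, "<=", 0, y = yj, ycoef = ubj)
      if (lbj != 0)
        desc <- .descAddRow(desc, paste0(prefix, "lb.", network@reactions[j]),
                            vn[j], 1, ">=", 0, y = yj, ycoef = lbj)
    } else {
      desc <- .descAddVar(desc, vn[j], lbj, ubj)
    }
  }
  Sl <- Matrix::summary(network@S)
  for (i in seq_along(network@metabolites)) {
    hit <- Sl$i == i
    desc <- .descAddRow(desc, paste0(prefix, "mb.", network@metabolites[i]),
                        vn[Sl$j[hit]], Sl$x[hit], "=", 0)
  }
  desc$obj <- list(vars = paste0(prefix, objective), coef = 1)
  desc
}

# Dualize a desc (primal sense: max). Returns the dual system as a desc plus
# the dual-objective expression (vars, coef) over the dual system's
# variables. For binary y, any feasible point of the dual system satisfies
# expression >= primal optimum; equality is attainable whenever the dual
# optimum lies within the big-M box.
.dualDesc <- function(desc, M, prefix) {
  dual <- .descNew()
  expr <- list(vars = character(), coef = numeric())
  addExpr <- function(v, cf) {
    if (cf != 0) {
      expr$vars <<- c(expr$vars, v); expr$coef <<- c(expr$coef, cf)
    }
  }
  rowNames <- names(desc$rows)
  # transpose map: primal var -> (dual row var, coef)
  At <- new.env(parent = emptyenv())
  addAt <- function(pvar, dvar, cf) {
    e <- At[[pvar]]
    if (is.null(e)) e <- list(vars = character(), coef = numeric())
    e$vars <- c(e$vars, dvar); e$coef <- c(e$coef, cf)
    At[[pvar]] <- e
  }
  for (rn in rowNames) {
    r <- desc$rows[[rn]]
    # normalize to <= (flip >=); equality keeps a free dual
    flip <- if (r$dir == ">=") -1 else 1
    wName <- paste0(prefix, "w.", rn)
    if (r$dir == "=") {
      dual <- .descAddVar(dual, wName, -M, M)
      wLo <- -M; wHi <- M
    } else {
      dual <- .descAddVar(dual, wName, 0, M)
      wLo <- 0; wHi <- M
    }
    for (t in seq_along(r$vars))
      addAt(r$vars[t], wName, flip * r$coef[t])
    addExpr(wName, flip * r$rhs0)
    if (length(r$y)) {                       # parametric rhs: need z = w * y
      zName <- paste0(prefix, "z.", rn)
      dual <- .descAddVar(dual, zName, min(wLo, 0), max(wHi, 0))
      g <- flip * r$ycoef
      addExpr(zName, g)
      # z = w * y exactly for binary y, given w in [wLo, wHi]:
      dual <- .descAddRow(dual, paste0(prefix, "zu.", rn), zName, 1, "<=",
                          0, y = r$y, ycoef = wHi)
      if (wLo != 0)
        dual <- .descAddRow(dual, paste0(prefix, "zl.", rn), zName, 1, ">=",
                            0, y = r$y, ycoef = wLo)
      dual <- .descAddRow(dual, paste0(prefix, "zw1.", rn),
                          c(zName, wName), c(1, -1), "<=", -wLo,
                          y = r$y, ycoef = wLo)
      dual <- .descAddRow(dual, paste0(prefix, "zw2.", rn),
                          c(zName, wName), c(1, -1), ">=", -wHi,
                          y = r$y, ycoef = wHi)
    }
  }
  # bound duals
  for (vn in names(desc$vars)) {
    bb <- desc$vars[[vn]]
    if (is.finite(bb["ub"])) {
      tn <- paste0(prefix, "t.", vn)     # for x <= ub
      dual <- .descAddVar(dual, tn, 0, M)
      addAt(vn, tn, 1)
      addExpr(tn, bb[["ub"]])
    }
    if (is.finite(bb["lb"])) {
      en <- paste0(prefix, "e.", vn)     # for x >= lb
      dual <- .descAddVar(dual, en, 0, M)
      addAt(vn, en, -1)
      addExpr(en, -bb[["lb"]])
    }
  }
  # dual feasibility: one equality per primal variable
  objMap <- stats::setNames(desc$obj$coef, desc$obj$vars)
  for (vn in names(desc$vars)) {
    e <- At[[vn]]
    cj <- if (vn %in% names(objMap)) objMap[[vn]] else 0
    if (is.null(e)) {
      if (cj != 0)
        stop("dualization failed: objective variable '", vn,
             "' appears in no row and has no finite bound")
      next
    }
    dual <- .descAddRow(dual, paste0(prefix, "df.", vn), e$vars, e$coef,
                        "=", cj)
  }
  list(desc = dual, expr = expr)
}

# Add a desc's variables and rows to an LP model under construction. Rows
# with y-parametric right-hand sides become ordinary rows with the y
# variables moved to the left-hand side (y variables must already exist).
.materialize <- function(mod, desc) {
  vn <- names(desc$vars)
  lb <- vapply(desc$vars, `[[`, 0, "lb")
  ub <- vapply(desc$vars, `[[`, 0, "ub")
  .lpAddVars(mod, vn, lb = lb, ub = ub)
  for (rn in names(desc$rows)) {
    r <- desc$rows[[rn]]
    vars <- r$vars; coef <- r$coef
    if (length(r$y)) {
      vars <- c(vars, r$y)
      coef <- c(coef, -r$ycoef)
    }
    .lpAddRow(mod, vars, coef, r$dir, r$rhs0, name = rn)
  }
  invisible(mod)
}

.descMerge <- function(a, b) {
  a$vars <- c(a$vars, b$vars)
  a$rows <- c(a$rows, b$rows)
  a
}

#' Construct a bi-level knockout-design problem
#'
#' @param network a \code{MetabolicNetwork}.
#' @param outerObjective,innerObjective reaction ids optimized by the outer
#'   and inner level.
#' @param outerSense "max" for the optimistic value of the outer objective
#'   over the inner-optimal face, "min" for the guaranteed (worst-case)
#'   value.
#' @param outerMedium,innerMedium \code{Medium} objects. For
#'   \code{innerConstraint = "optimal"} both levels share one flux vector and
#'   the outer medium is used.
#' @param innerConstraint "optimal" (the inner optimum must be attained;
#'   coupling designs) or "max_zero" (the inner maximum is forced below
#'   \code{innerCap}; ultra-auxotrophy designs).
#' @param innerCap cap for "max_zero" problems.
#' @param candidates knockout-candidate reactions (shared by both levels).
#' @param k knockout budget.
#' @param minGrowth biomass viability floor. Applied at both levels for
#'   "optimal" problems; for "max_zero" problems it constrains the outer
#'   level only (the inner level is precisely the no-growth condition).
#' @return a \code{BilevelProblem}.
#' @export
bilevelProblem <- function(network, outerObjective,
                           outerSense = c("max", "min"),
                           innerObjective, outerMedium, innerMedium,
                           innerConstraint = c("optimal", "max_zero"),
                           innerCap = 1e-6,
                           candidates = candidateReactions(network),
                           k = 3L, minGrowth = 0) {
  new("BilevelProblem", network = network,
      outerObjective = outerObjective, outerSense = match.arg(outerSense),
      innerObjective = innerObjective, innerSense = "max",
      outerMedium = outerMedium, innerMedium = innerMedium,
      innerConstraint = match.arg(innerConstraint), innerCap = innerCap,
      candidates = candidates, k = as.integer(k), minGrowth = minGrowth)
}

#' Reformulate a bi-level problem as a single-level MILP
#'
#' Replaces the inner linear program by its dual system with big-M
#' linearization of the products of dual variables and the binary knockout
#' variables; "optimal" problems additionally carry the shared primal flux
#' vector and a strong-duality coupling row, and "min"-sense (guaranteed)
#' problems dualize the resulting minimization a second time.
#'
#' @param problem a \code{\link{bilevelProblem}}.
#' @param config a \code{\link{solveConfig}}; \code{bigM} must exceed every
#'   attainable flux magnitude (checked against the model bounds).
#' @return a MILP handle (class \code{"milpHandle"}) for
#'   \code{\link{solveMILP}} and \code{\link{addIntegerCut}}.
#' @export
reformulateToMILP <- function(problem, config = solveConfig()) {
  net <- problem@network
  M <- config@bigM
  allBounds <- c(.resolveBounds(net, problem@outerMedium)$lb,
                 .resolveBounds(net, problem@outerMedium)$ub,
                 .resolveBounds(net, problem@innerMedium)$lb,
                 .resolveBounds(net, problem@innerMedium)$ub)
  maxBound <- max(abs(allBounds[is.finite(allBounds)]), 0)
  if (maxBound >= 0.99 * M)
    stop(sprintf("big-M calibration error: bigM = %g does not dominate the ",
                 M), sprintf("attainable flux magnitude %g", maxBound))
  mod <- .lpModel("max")
  cand <- problem@candidates
  .lpAddVars(mod, .yName(cand), lb = 0, ub = 1, binary = TRUE)
  .lpAddRow(mod, .yName(cand), rep(1, length(cand)), ">=",
            length(cand) - problem@k, name = "budget")
  outerVar <- NULL
  dualExpr <- NULL
  innerVar <- NULL
  if (problem@innerConstraint == "max_zero") {
    innerDesc <- .descFluxLP(net, problem@innerMedium,
                             problem@innerObjective, cand, minGrowth = 0,
                             prefix = "u.")
    dd <- .dualDesc(innerDesc, M, "d1.")
    .materialize(mod, dd$desc)
    dualExpr <- dd$expr
    # Scale the cap row to unit magnitude: mixing tiny right-hand sides with
    # big-M-sized coefficients destabilizes the simplex. A scaled cap below
    # the solver's own feasibility tolerance is posed as exactly 0 -- the
    # solver's row tolerance then provides the effective epsilon, and the
    # two-FBA verification of every emitted design re-checks the no-growth
    # condition against zeroTolerance independently.
    capScale <- max(abs(dd$expr$coef), 1)
    capRhs <- problem@innerCap / capScale
    if (capRhs < 1e-7) capRhs <- 0
    .lpAddRow(mod, dd$expr$vars, dd$expr$coef / capScale, "<=", capRhs,
              name = "nogrowth.cap")
    outerDesc <- .descFluxLP(net, problem@outerMedium,
                             problem@outerObjective, cand,
                             minGrowth = problem@minGrowth, prefix = "v.")
    .materialize(mod, outerDesc)
    outerVar <- paste0("v.", problem@outerObjective)
    .lpSetObj(mod, outerVar, 1)
  } else {
    primalDesc <- .descFluxLP(net, problem@outerMedium,
                              problem@innerObjective, cand,
                              minGrowth = problem@minGrowth, prefix = "v.")
    dd <- .dualDesc(primalDesc, M, "d1.")
    dualExpr <- dd$expr
    innerVar <- paste0("v.", problem@innerObjective)
    if (problem@outerSense == "max") {
      .materialize(mod, primalDesc)
      .materialize(mod, dd$desc)
      .lpAddRow(mod, c(innerVar, dd$expr$vars), c(1, -dd$expr$coef), ">=",
                0, name = "strongdual")
      outerVar <- paste0("v.", problem@outerObjective)
      .lpSetObj(mod, outerVar, 1)
    } else {
      # guaranteed sense: dualize the minimization of the outer objective
      # over the face pinned by the strong-duality row. A primal feasibility
      # copy of the flux LP is kept in the MILP so that knockout patterns
      # whose level problem is infeasible (e.g. viability floor unreachable)
      # are excluded by constraints rather than mispriced by capped duals.
      .materialize(mod, primalDesc)
      minDesc <- .descMerge(primalDesc, dd$desc)
      minDesc <- .descAddRow(minDesc, "strongdual",
                             c(innerVar, dd$expr$vars),
                             c(1, -dd$expr$coef), ">=", 0)
      minDesc$obj <- list(vars = paste0("v.", problem@outerObjective),
                          coef = -1)       # min d'v == -max (-d)'v
      dd2 <- .dualDesc(minDesc, M, "d2.")
      .materialize(mod, dd2$desc)
      .lpSetObj(mod, dd2$expr$vars, -dd2$expr$coef)
    }
  }
  structure(list(mod = mod, problem = problem, config = config,
                 outerVar = outerVar, innerVar = innerVar,
                 dualExpr = dualExpr, candidates = cand),
            class = "milpHandle")
}

#' Exclude one knockout pattern from a MILP
#'
#' Appends an integer cut making the given zero-pattern of y infeasible
#' while leaving every other pattern feasible; used to enumerate alternative
#' optimal knockout sets.
#'
#' @param handle a MILP handle from \code{\link{reformulateToMILP}}.
#' @param knockoutSet nonempty character vector of candidate reaction ids.
#' @return the updated handle, invisibly.
#' @export
addIntegerCut <- function(handle, knockoutSet) {
  stopifnot(inherits(handle, "milpHandle"))
  if (length(knockoutSet) == 0L)
    stop("refusing to cut the empty knockout set (the wild type is never ",
         "a returned design)")
  if (!all(knockoutSet %in% handle$candidates))
    stop("knockoutSet contains non-candidate reaction(s): ",
         paste(setdiff(knockoutSet, handle$candidates), collapse = ", "))
  act <- setdiff(handle$candidates, knockoutSet)
  .lpAddRow(handle$mod, .yName(c(knockoutSet, act)),
            c(rep(1, length(knockoutSet)), rep(-1, length(act))), ">=",
            1 - length(act),
            name = sprintf("cut.%d", length(handle$mod$rows) + 1L))
  invisible(handle)
}

#' Solve a reformulated MILP
#'
#' @param handle a MILP handle from \code{\link{reformulateToMILP}}.
#' @param config optional \code{\link{solveConfig}} overriding the handle's.
#' @return list with \code{status}, \code{objective}, \code{knockouts}
#'   (reaction ids with y = 0), \code{y} (named logical) and the raw
#'   variable \code{values}. Dual and flux magnitudes are certified to stay
#'   below 0.99 * bigM.
#' @export
solveMILP <- function(handle, config = NULL) {
  stopifnot(inherits(handle, "milpHandle"))
  if (is.null(config)) config <- handle$config
  res <- .lpSolve(handle$mod, config)
  if (res$status != "optimal")
    return(list(status = res$status, objective = NA_real_,
                knockouts = character(), y = NULL, values = NULL))
  yv <- res$values[.yName(handle$candidates)]
  y <- stats::setNames(yv > 0.5, handle$candidates)
  # Certify the magnitudes that carry meaning: flux variables, and the value
  # of the inner dual objective. Dual variables on degenerate rays (zero
  # objective contribution) may legitimately sit on the big-M box; semantic
  # correctness of every accepted design is established independently by the
  # callers' FBA verification, so those are not flagged.
  fluxVals <- res$values[startsWith(names(res$values), "v.") |
                           startsWith(names(res$values), "u.")]
  worstFlux <- if (length(fluxVals))
    max(abs(fluxVals[is.finite(fluxVals)]), 0) else 0
  if (worstFlux >= 0.99 * config@bigM)
    stop(sprintf("big-M calibration error: flux magnitude %g reached ",
                 worstFlux),
         sprintf("0.99 * bigM = %g; increase bigM", 0.99 * config@bigM))
  exprValue <- if (!is.null(handle$dualExpr))
    sum(handle$dualExpr$coef * res$values[handle$dualExpr$vars]) else NA_real_
  list(status = "optimal", objective = res$objective,
       knockouts = handle$candidates[!y], y = y, values = res$values,
       dualObjective = exprValue)
}

# Re-solve with a secondary objective: keep the primary objective within
# tol of `best` and maximize the number of active candidate reactions
# (i.e. prefer the fewest knockouts among near-optimal solutions).
.solveFewestKnockouts <- function(handle, best, config = NULL) {
  if (is.null(config)) config <- handle$config
  mod <- handle$mod
  primary <- which(mod$obj != 0)
  tol <- 1e-7 * max(1, abs(best))
  rowId <- .lpAddRow(mod, primary, mod$obj[primary], ">=", best - tol,
                     name = "fix.primary")
  oldObj <- mod$obj
  .lpSetObj(mod, .yName(handle$candidates),
            rep(1, length(handle$candidates)))
  res <- .lpSolve(mod, config)
  # restore
  mod$obj <- oldObj
  mod$rows[[rowId]] <- NULL
  mod$rowNames <- mod$rowNames[-rowId]
  res
}
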