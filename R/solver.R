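# Internal LP/MILP interface. Problems are built incrementally in an
# environment, written in CPLEX LP format, and solved with the GLPK
# command-line solver (glpsol), which must be on the PATH. Variables are
# renamed x1..xn on disk; results are mapped back to user names.

.glpsolPath <- function() {
  p <- Sys.which("glpsol")
  if (!nzchar(p))
    stop("the GLPK solver executable 'glpsol' was not found on the PATH")
  p
}

#' Is the GLPK solver available?
#' @return TRUE if the \code{glpsol} executable is on the PATH.
#' @export
glpkAvailable <- function() nzchar(Sys.which("glpsol"))

.lpModel <- function(sense = c("max", "min")) {
  mod <- new.env(parent = emptyenv())
  mod$sense <- match.arg(sense)
  mod$names <- character()
  mod$lb <- numeric()
  mod$ub <- numeric()
  mod$obj <- numeric()
  mod$binary <- logical()
  mod$rows <- list()      # each: list(idx, coef, dir, rhs)
  mod$rowNames <- character()
  mod
}

.lpAddVars <- function(mod, names, lb = 0, ub = Inf, obj = 0,
                       binary = FALSE) {
  n <- length(names)
  if (any(names %in% mod$names))
    stop("duplicate variable name(s): ",
         paste(intersect(names, mod$names), collapse = ", "))
  mod$names <- c(mod$names, names)
  mod$lb <- c(mod$lb, rep_len(lb, n))
  mod$ub <- c(mod$ub, rep_len(ub, n))
  mod$obj <- c(mod$obj, rep_len(obj, n))
  mod$binary <- c(mod$binary, rep_len(binary, n))
  invisible(seq.int(length(mod$names) - n + 1L, length(mod$names)))
}

.lpVarIdx <- function(mod, vars) {
  if (is.numeric(vars)) return(as.integer(vars))
  idx <- match(vars, mod$names)
  if (anyNA(idx))
    stop("unknown variable(s): ", paste(vars[is.na(idx)], collapse = ", "))
  idx
}

.lpAddRow <- function(mod, vars, coefs, dir, rhs, name = NULL) {
  stopifnot(dir %in% c("<=", ">=", "="), length(coefs) == length(vars))
  idx <- .lpVarIdx(mod, vars)
  keep <- coefs != 0
  if (!any(keep)) {
    # constant row: check consistency immediately
    ok <- switch(dir, "<=" = 0 <= rhs, ">=" = 0 >= rhs, "=" = rhs == 0)
    if (!ok) stop("constant infeasible row added: 0 ", dir, " ", rhs)
    return(invisible(NULL))
  }
  mod$rows[[length(mod$rows) + 1L]] <-
    list(idx = idx[keep], coef = as.numeric(coefs[keep]), dir = dir,
         rhs = as.numeric(rhs))
  mod$rowNames <- c(mod$rowNames,
                    if (is.null(name)) sprintf("r%d", length(mod$rows))
                    else name)
  invisible(length(mod$rows))
}

.lpSetObj <- function(mod, vars, coefs) {
  mod$obj[] <- 0
  mod$obj[.lpVarIdx(mod, vars)] <- coefs
  invisible(mod)
}

.lpSetBounds <- function(mod, vars, lb = NULL, ub = NULL) {
  idx <- .lpVarIdx(mod, vars)
  if (!is.null(lb)) mod$lb[idx] <- lb
  if (!is.null(ub)) mod$ub[idx] <- ub
  invisible(mod)
}

.fmtNum <- function(x) sprintf("%.17g", x)

.lpWrite <- function(mod, path) {
  con <- file(path, "w")
  on.exit(close(con))
  terms <- function(idx, coef) {
    tt <- sprintf("%+.17g x%d", coef, idx)
    grp <- ceiling(seq_along(tt) / 8)            # wrap long rows
    paste(vapply(split(tt, grp), paste, "", collapse = " "),
          collapse = "\n   ")
  }
  writeLines(if (mod$sense == "max") "Maximize" else "Minimize", con)
  # list every variable (zero coefficients included) so that glpsol's
  # column numbering, which follows first appearance, matches ours
  writeLines(paste0(" obj: ", terms(seq_along(mod$names), mod$obj)), con)
  writeLines("Subject To", con)
  for (i in seq_along(mod$rows)) {
    r <- mod$rows[[i]]
    writeLines(sprintf(" c%d: %s %s %s", i, terms(r$idx, r$coef), r$dir,
                       .fmtNum(r$rhs)), con)
  }
  writeLines("Bounds", con)
  for (j in seq_along(mod$names)) {
    if (mod$binary[j]) next
    lb <- mod$lb[j]; ub <- mod$ub[j]
    if (lb == -Inf && ub == Inf) {
      writeLines(sprintf(" x%d free", j), con)
    } else if (lb == ub) {
      writeLines(sprintf(" x%d = %s", j, .fmtNum(lb)), con)
    } else {
      writeLines(sprintf(" %s <= x%d <= %s",
                         if (lb == -Inf) "-inf" else .fmtNum(lb), j,
                         if (ub == Inf) "+inf" else .fmtNum(ub)), con)
    }
  }
  if (any(mod$binary)) {
    writeLines("Binary", con)
    writeLines(sprintf(" x%d", which(mod$binary)), con)
  }
  writeLines("End", con)
  invisible(path)
}

# Solve the model; returns list(status, objective, values). status is one of
# "optimal", "infeasible", "unbounded", "error". MILP is used automatically
# when the model holds binary variables.
.lpSolve <- function(mod, config = solveConfig()) {
  exe <- .glpsolPath()
  lpf <- tempfile(fileext = ".lp")
  solf <- tempfile(fileext = ".sol")
  on.exit(unlink(c(lpf, solf)))
  .lpWrite(mod, lpf)
  args <- c("--lp", lpf, "-w", solf,
            "--tmlim", sprintf("%d", max(1L, as.integer(config@timeLimit))))
  out <- suppressWarnings(system2(exe, args, stdout = TRUE, stderr = TRUE))
  logtxt <- paste(out, collapse = "\n")
  isMip <- any(mod$binary)
  if (grepl("NO PRIMAL FEASIBLE|NO INTEGER FEASIBLE|HAS NO.*FEASIBLE",
            logtxt) && !grepl("NO DUAL FEASIBLE", logtxt))
    return(list(status = "infeasible", objective = NA_real_,
                values = NULL, log = logtxt))
  if (grepl("NO DUAL FEASIBLE|UNBOUNDED", logtxt))
    return(list(status = "unbounded", objective = NA_real_,
                values = NULL, log = logtxt))
  if (!file.exists(solf))
    return(list(status = "error", objective = NA_real_, values = NULL,
                log = logtxt))
  lines <- readLines(solf)
  lines <- lines[!startsWith(lines, "c") & nzchar(lines)]
  sline <- strsplit(lines[startsWith(lines, "s")][1], "\\s+")[[1]]
  vals <- rep(NA_real_, length(mod$names))
  jlines <- lines[startsWith(lines, "j")]
  if (isMip) {
    status <- switch(sline[5], o = "optimal", n = "infeasible",
                     f = "feasible", "error")
    objective <- as.numeric(sline[6])
    for (ln in jlines) {
      f <- strsplit(ln, "\\s+")[[1]]
      vals[as.integer(f[2])] <- as.numeric(f[3])
    }
  } else {
    status <- switch(sline[5], f = "optimal", i = "infeasible",
                     n = "infeasible", "error")
    if (sline[6] == "n") status <- "unbounded"  # dual infeasible
    objective <- as.numeric(sline[7])
    for (ln in jlines) {
      f <- strsplit(ln, "\\s+")[[1]]
      vals[as.integer(f[2])] <- as.numeric(f[4])
    }
  }
  if (status %in% c("infeasible", "unbounded", "error"))
    return(list(status = status, objective = NA_real_, values = NULL,
                log = logtxt))
  names(vals) <- mod$names
  list(status = status, objective = objective, values = vals, log = logtxt)
}
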