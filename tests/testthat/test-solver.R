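# The internal GLPK interface: LP/MILP status handling and correctness of
# optima against an independent vertex-enumeration oracle.

test_that("glpsol is available and solves a known LP", {
  expect_true(glpkAvailable())
  mod <- auxoDesign:::.lpModel("max")
  auxoDesign:::.lpAddVars(mod, c("x", "y"), lb = c(0, -5), ub = c(8, 8),
                          obj = c(1, 2))
  auxoDesign:::.lpAddRow(mod, c("x", "y"), c(1, 1), "<=", 10)
  auxoDesign:::.lpAddRow(mod, c("x", "y"), c(1, -1), ">=", -5)
  res <- auxoDesign:::.lpSolve(mod)
  expect_identical(res$status, "optimal")
  # optimum where x+y = 10 meets x-y = -5: (2.5, 7.5), objective 17.5
  expect_equal(res$objective, 17.5, tolerance = 1e-9)
  expect_equal(unname(res$values["x"]), 2.5, tolerance = 1e-9)
  expect_equal(unname(res$values["y"]), 7.5, tolerance = 1e-9)
})

test_that("infeasible and unbounded problems are told apart", {
  mod <- auxoDesign:::.lpModel("max")
  auxoDesign:::.lpAddVars(mod, "x", lb = 0, ub = Inf, obj = 1)
  auxoDesign:::.lpAddRow(mod, "x", 1, ">=", 5)
  auxoDesign:::.lpAddRow(mod, "x", 1, "<=", 2)
  expect_identical(auxoDesign:::.lpSolve(mod)$status, "infeasible")

  mod2 <- auxoDesign:::.lpModel("max")
  auxoDesign:::.lpAddVars(mod2, c("x", "y"), lb = -Inf, ub = Inf, obj = c(1, 0))
  auxoDesign:::.lpAddRow(mod2, c("x", "y"), c(1, -1), ">=", 5)
  expect_identical(auxoDesign:::.lpSolve(mod2)$status, "unbounded")
})

test_that("binary variables give MILP solutions", {
  # knapsack: values 6,5,4 weights 3,2,2, capacity 4 -> take items 2+3 = 9
  mod <- auxoDesign:::.lpModel("max")
  auxoDesign:::.lpAddVars(mod, c("a", "b", "c"), obj = c(6, 5, 4),
                          binary = TRUE)
  auxoDesign:::.lpAddRow(mod, c("a", "b", "c"), c(3, 2, 2), "<=", 4)
  res <- auxoDesign:::.lpSolve(mod)
  expect_identical(res$status, "optimal")
  expect_equal(res$objective, 9, tolerance = 1e-9)
  expect_equal(unname(res$values[c("b", "c")]), c(1, 1), tolerance = 1e-9)
})

test_that("LP optima agree with brute-force vertex enumeration", {
  # random-looking but fixed 2-variable LPs; the oracle enumerates all
  # constraint-pair intersections and picks the best feasible one
  cases <- list(
    list(A = rbind(c(1, 2), c(3, 1), c(-1, 1)), b = c(14, 15, 4),
         obj = c(2, 3)),
    list(A = rbind(c(1, 1), c(1, -2), c(-2, 1)), b = c(9, 2, 1),
         obj = c(5, 4)),
    list(A = rbind(c(2, 1), c(1, 3)), b = c(10, 15), obj = c(1, 1)))
  for (cs in cases) {
    # oracle: vertices from all pairs of tight constraints (incl. axes)
    Afull <- rbind(cs$A, c(-1, 0), c(0, -1))
    bfull <- c(cs$b, 0, 0)
    best <- -Inf
    for (i in seq_len(nrow(Afull) - 1)) for (j in (i + 1):nrow(Afull)) {
      M <- Afull[c(i, j), ]
      if (abs(det(M)) < 1e-12) next
      v <- solve(M, bfull[c(i, j)])
      if (all(Afull %*% v <= bfull + 1e-9))
        best <- max(best, sum(cs$obj * v))
    }
    mod <- auxoDesign:::.lpModel("max")
    auxoDesign:::.lpAddVars(mod, c("x", "y"), obj = cs$obj)
    for (r in seq_len(nrow(cs$A)))
      auxoDesign:::.lpAddRow(mod, c("x", "y"), cs$A[r, ], "<=", cs$b[r])
    res <- auxoDesign:::.lpSolve(mod)
    expect_identical(res$status, "optimal")
    expect_equal(res$objective, best, tolerance = 1e-8)
  }
})

test_that("variable bounds and fixed variables are honored", {
  mod <- auxoDesign:::.lpModel("min")
  auxoDesign:::.lpAddVars(mod, c("x", "y", "z"), lb = c(-3, 2, 5),
                          ub = c(4, 2, Inf), obj = c(1, 1, 1))
  auxoDesign:::.lpAddRow(mod, c("x", "y", "z"), c(1, 1, 1), ">=", 0)
  res <- auxoDesign:::.lpSolve(mod)
  expect_equal(res$objective, -3 + 2 + 5, tolerance = 1e-9)
  expect_equal(unname(res$values["y"]), 2)  # fixed by lb == ub
})
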