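# The MILP reformulation machinery: strong duality against direct LP
# solves, reduction to FBA at k = 0, integer cuts, big-M calibration.

couplingProblem <- function(net, med, k, sense = "max",
                            cand = candidateReactions(net),
                            target = "EX_D", minGrowth = 0.1) {
  bilevelProblem(net, outerObjective = target, outerSense = sense,
                 innerObjective = biomassReaction(net), outerMedium = med,
                 innerMedium = med, innerConstraint = "optimal",
                 candidates = cand, k = k, minGrowth = minGrowth)
}

test_that("with all reactions active the reformulation admits exactly the LP optimum", {
  net <- generateToy(toySpec(1, FALSE, "bypass", 1, 9))
  med <- minimalMedium(net)
  h <- reformulateToMILP(couplingProblem(net, med, k = 0L))
  r <- solveMILP(h)
  expect_identical(r$status, "optimal")
  expect_identical(r$knockouts, character(0))
  # the shared flux vector attains the plain-FBA growth optimum exactly
  growthLP <- objectiveValue(fba(net, med))
  expect_equal(unname(r$values[h$innerVar]), growthLP, tolerance = 1e-6)
  # strong-duality residual at the returned solution
  expect_lt(abs(unname(r$values[h$innerVar]) - r$dualObjective), 1e-6)
})

test_that("an infeasible inner problem reports infeasible, not unbounded", {
  net <- generateToy(toySpec(1, FALSE, "bypass", 0, 2))
  med <- minimalMedium(net)
  h <- reformulateToMILP(couplingProblem(net, med, k = 0L, minGrowth = 50))
  r <- solveMILP(h)
  expect_identical(r$status, "infeasible")
})

test_that("a k = 0 bi-level problem reduces to plain FBA", {
  net <- generateToy(toySpec(2, TRUE, "bypass", 1, 3))
  med <- minimalMedium(net)
  d <- optKnock(net, "D", med, k = 0L)
  sc <- auxoDesign:::.nestedScore(net, med, exchangeFor(net, "D"),
                                  biomassReaction(net), character(),
                                  0.1, solveConfig())
  expect_equal(d@maxRate, sc$maxRate, tolerance = 1e-6)
  expect_identical(d@knockouts, character(0))
})

test_that("integer cuts exclude exactly one pattern", {
  net <- generateToy(toySpec(1, FALSE, "bypass", 1, 5))
  med <- minimalMedium(net)
  h <- reformulateToMILP(couplingProblem(net, med, k = 1L))
  r1 <- solveMILP(h)
  expect_identical(r1$status, "optimal")
  # cutting a pattern the optimum does not use leaves the solution alone
  unused <- setdiff(h$candidates, r1$knockouts)[1]
  addIntegerCut(h, unused)
  r2 <- solveMILP(h)
  expect_equal(r2$objective, r1$objective, tolerance = 1e-9)
  expect_identical(r2$knockouts, r1$knockouts)
  # cutting the optimal pattern forces a different one (or a worse optimum)
  if (length(r1$knockouts)) {
    addIntegerCut(h, r1$knockouts)
    r3 <- solveMILP(h)
    if (r3$status == "optimal")
      expect_false(identical(r3$knockouts, r1$knockouts))
  }
  expect_error(addIntegerCut(h, character()), "empty")
  expect_error(addIntegerCut(h, "EX_A"), "non-candidate")
})

test_that("iterated integer cuts terminate after the brute-force design count", {
  net <- generateToy(toySpec(1, TRUE, "none", 1, 8))
  cfg <- solveConfig()
  bf <- bruteForceBiosensor(net, "C", "minimal", k = 3, config = cfg)
  designs <- enumerateDesigns(net, "C", "minimal", k = 3, config = cfg)
  expect_length(designs, length(bf))
  expectEqualSets(knockoutKeys(designs), bf)
})

test_that("an undersized big-M raises a calibration error at reformulation", {
  net <- generateToy(toySpec(1, FALSE, "bypass", 0, 4))
  med <- minimalMedium(net)
  cfg <- solveConfig(bigM = 50)   # model upper bounds reach 100
  expect_error(reformulateToMILP(couplingProblem(net, med, k = 1L), cfg),
               "big-M calibration")
})
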