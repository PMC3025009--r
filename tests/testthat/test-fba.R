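# Flux balance analysis, production ceilings, flux ranges, and their LP
# invariants.

test_that("a linear chain carries the full uptake into biomass", {
  net <- chainNet()
  med <- minimalMedium(net)
  fd <- fba(net, med)
  expect_identical(solverStatus(fd), "optimal")
  expect_equal(objectiveValue(fd), 10, tolerance = 1e-9)
  # cutting the only internal step abolishes growth
  fd0 <- fba(net, med, knockouts = "R1")
  expect_equal(objectiveValue(fd0), 0, tolerance = 1e-9)
})

test_that("parallel routes add their capacities (hand-computed LP)", {
  net <- branchedNet()
  med <- minimalMedium(net, uptake = 20)
  expect_equal(objectiveValue(fba(net, med)), 11, tolerance = 1e-9)
  expect_equal(objectiveValue(fba(net, med, knockouts = "R1")), 7,
               tolerance = 1e-9)
})

test_that("maxProduction trades biomass for product linearly", {
  net <- productNet()
  med <- minimalMedium(net)
  expect_equal(as.numeric(maxProduction(net, med, "P", minGrowth = 0.1)),
               9.9, tolerance = 1e-8)
  expect_equal(as.numeric(maxProduction(net, med, "P", minGrowth = 0)),
               10, tolerance = 1e-9)
  # an unreachable viability floor is infeasible, not zero
  res <- maxProduction(net, med, "P", minGrowth = 50)
  expect_true(is.na(res))
  expect_identical(attr(res, "status"), "infeasible")
  # a feasible floor with zero production stays a plain 0
  net2 <- chainNet()
  out0 <- maxProduction(net2, minimalMedium(net2), "A", minGrowth = 0,
                        knockouts = "R1")
  expect_equal(as.numeric(out0), 0, tolerance = 1e-9)
  expect_identical(attr(out0, "status"), "optimal")
})

test_that("a transient secretion exchange is added and reported", {
  S <- rbind(A = c(-1, -1, -1), Q = c(0, 1, 0))
  net <- metabolicNetwork(rownames(S), c("EX_A", "MKQ", "BIOMASS"), S,
                          c(0, 0, 0), c(100, 100, 100),
                          biomassReaction = "BIOMASS",
                          metadata = list(carbon_source = "A"))
  expect_message(
    out <- maxProduction(net, minimalMedium(net), "Q", minGrowth = 0),
    "transient secretion exchange")
  expect_equal(as.numeric(out), 10, tolerance = 1e-9)
})

test_that("fluxBounds brackets blocked, irreversible and optimal fluxes", {
  net <- generateToy(toySpec(2, FALSE, "none", 1, 6))
  med <- minimalMedium(net)
  for (r in reactions(net)) {
    fb <- fluxBounds(net, med, r)
    expect_lte(fb["min"], fb["max"])
  }
  # blocked reaction: knock out its only substrate supplier
  fb <- fluxBounds(net, med, "BIOMASS", knockouts = c("SYN1", "SYN2"))
  expect_equal(unname(fb), c(0, 0), tolerance = 1e-9)
  # irreversible reactions have nonnegative minima
  expect_gte(fluxBounds(net, med, "SYN1")["min"], -1e-9)
  # bounds bracket the flux of any optimal FBA solution, reaction by reaction
  fd <- fba(net, med)
  for (r in reactions(net)) {
    fb <- fluxBounds(net, med, r)
    expect_gte(flux(fd)[[r]], fb[["min"]] - 1e-6)
    expect_lte(flux(fd)[[r]], fb[["max"]] + 1e-6)
  }
})

test_that("FBA optima dominate feasible points and shrink under knockouts", {
  net <- branchedNet()
  med <- minimalMedium(net, uptake = 20)
  opt <- objectiveValue(fba(net, med))
  # hand-supplied feasible flux vector: route capacities 3 and 5
  vfeas <- c(EX_A = -8, R1 = 3, R2 = 5, BIOMASS = 8)
  expect_equal(max(abs(as.numeric(stoichiometry(net) %*% vfeas))), 0)
  expect_gte(opt, vfeas[["BIOMASS"]])
  # monotone restriction: adding knockouts never increases the optimum
  for (ko in list("R1", "R2", c("R1", "R2"))) {
    expect_lte(objectiveValue(fba(net, med, knockouts = ko)), opt + 1e-9)
  }
})

test_that("an empty knockout argument equals an all-ones knockout vector", {
  net <- generateToy(toySpec(1, TRUE, "none", 1, 2))
  med <- minimalMedium(net)
  kv <- knockoutVector(net, character(), k = 3)
  f1 <- fba(net, med)
  f2 <- fba(net, med, knockouts = kv)
  expect_equal(objectiveValue(f1), objectiveValue(f2), tolerance = 1e-9)
  # and the knockout vector enforces its budget
  expect_error(knockoutVector(net, c("SYN1", "TP"), k = 1), "budget|exceed")
})

test_that("unbounded objectives are reported with a diagnostic", {
  S <- rbind(A = c(-1, 1))
  net <- metabolicNetwork("A", c("EX_A", "FREE"), S, c(0, 0),
                          c(Inf, Inf), biomassReaction = "FREE",
                          exchangeReactions = "EX_A")
  expect_warning(fd <- fba(net, NULL, objective = "FREE"),
                 "unbounded")
  expect_identical(solverStatus(fd), "unbounded")
})
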