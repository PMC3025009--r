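# Ultra-auxotrophic biosensor design, verification semantics, enumeration,
# and yield-sensitivity classification.

test_that("a single synthesis route needs exactly its one cut", {
  net <- generateToy(toySpec(1, FALSE, "none", 1, 1))
  d <- designBiosensor(net, "C", "minimal", k = 1)
  expect_s4_class(d, "BiosensorDesign")
  expect_identical(knockouts(d), "SYN1")
  expect_true(verified(d))
  expect_gte(d@growthWithC, 1e-3)
  expect_lte(d@growthWithoutC, 1e-6)
})

test_that("a salvage import route forces a double knockout", {
  # synthesis + importable precursor: the single cut is auxotrophic in the
  # classic sense but not ultra-auxotrophic, exactly the indole situation
  net <- generateToy(toySpec(1, TRUE, "none", 0, 2))
  expect_null(designBiosensor(net, "C", "minimal", k = 1))
  d <- designBiosensor(net, "C", "minimal", k = 2)
  expect_identical(knockouts(d), c("SYN1", "TP"))
  # the classic single-knockout strain grows on rich medium without C
  single <- verifyDesign(net, new("BiosensorDesign", chemical = "C",
                                  mediumKind = "minimal",
                                  knockouts = "SYN1",
                                  growthWithC = NA_real_,
                                  growthWithoutC = NA_real_,
                                  verified = FALSE,
                                  insensitiveYield = NA))
  expect_false(verified(single))
  expect_gt(single@growthWithoutC, 1e-3)
})

test_that("the wild type never verifies for a synthesizable chemical", {
  net <- generateToy(toySpec(2, FALSE, "none", 0, 3))
  wt <- verifyDesign(net, new("BiosensorDesign", chemical = "C",
                              mediumKind = "minimal",
                              knockouts = character(),
                              growthWithC = NA_real_,
                              growthWithoutC = NA_real_, verified = FALSE,
                              insensitiveYield = NA))
  expect_false(verified(wt))
})

test_that("enumeration returns each alternative single cut once, then stops", {
  net <- twoStepNet()   # either sequential step blocks synthesis
  designs <- enumerateDesigns(net, "C", "minimal", k = 1)
  expectEqualSets(knockoutKeys(designs), list("S1", "S2"))
  one <- enumerateDesigns(net, "C", "minimal", k = 1, maxAlternatives = 1)
  expect_length(one, 1L)
  # infeasible budget: no designs at all
  expect_length(enumerateDesigns(net, "C", "minimal", k = 0), 0L)
})

test_that("designs emitted by the MILP always pass independent verification", {
  for (seed in c(4, 5, 6)) {
    net <- generateToy(toySpec(1 + seed %% 2, seed %% 2 == 0, "none",
                               1, seed))
    kk <- modelMetadata(net)$truth$cut_size
    d <- designBiosensor(net, "C", "minimal", k = kk)
    expect_true(verified(verifyDesign(net, d)))
  }
})

test_that("yield curves start at zero, never decrease, and stay concave", {
  net <- generateToy(toySpec(1, TRUE, "none", 0, 4))
  d <- designBiosensor(net, "C", "minimal", k = 2)
  ys <- yieldSensitivity(net, d)
  for (curve in list(ys$poor, ys$rich)) {
    expect_equal(curve[1], 0, tolerance = 1e-9)
    expect_true(all(diff(curve) >= -1e-7))
    expect_true(all(diff(diff(curve)) <= 1e-7))    # concavity
  }
  # the unit-stoichiometry sensor converts C one-to-one in either medium
  expect_true(ys$insensitive)
  expect_true(ys$design@insensitiveYield)
})

test_that("a carbon-limited sensor is flagged yield-sensitive", {
  net <- sensitiveNet()
  d <- designBiosensor(net, "C", "minimal", k = 1)
  expect_identical(knockouts(d), "SYN1")
  ys <- yieldSensitivity(net, d)
  expect_false(ys$insensitive)
  # rich supplementation can only help: rich curve dominates the poor one
  expect_true(all(ys$rich >= ys$poor - 1e-7))
})

test_that("designs serialize to TSV and JSON", {
  net <- generateToy(toySpec(1, FALSE, "none", 0, 5))
  d <- designBiosensor(net, "C", "minimal", k = 1)
  tf <- tempfile(fileext = ".tsv")
  writeDesigns(list(d), tf, net)
  tab <- utils::read.delim(tf)
  expect_identical(tab$chemical, "C")
  expect_identical(tab$knockouts, "SYN1")
  jf <- tempfile(fileext = ".json")
  writeDesigns(list(d), jf, net)
  expect_identical(jsonlite::fromJSON(jf)$chemical, "C")
})

test_that("non-transportable chemicals are rejected up front", {
  net <- chainNet()   # B has no exchange
  expect_error(designBiosensor(net, "B", "minimal", k = 1),
               "not transportable")
})
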