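# OptKnock / RobustKnock and the proxy variants against the brute-force
# nested-LP oracle, plus their ordering invariants.

test_that("knocking out the bypass couples production to growth", {
  net <- generateToy(toySpec(1, FALSE, "bypass", 0, 13))
  med <- minimalMedium(net)
  oracle <- bruteForceCoupling(net, "D", "biomass", med, k = 1,
                               sense = "guaranteed_min")
  d <- robustKnock(net, "D", med, k = 1)
  expect_equal(guaranteedRate(d), oracle$rate, tolerance = 1e-6)
  expect_true(any(vapply(oracle$allOptimal, identical, TRUE,
                         y = knockouts(d))))
  expect_gt(guaranteedRate(d), 0)
})

test_that("alternative optima separate OptKnock from RobustKnock", {
  # wild type: a C-only route and a C+D co-producing route tie for growth,
  # so the optimistic rate is positive but nothing is guaranteed
  net <- generateToy(toySpec(1, FALSE, "bypass", 1, 14))
  # keep the uptake below the C-only route's capacity so the wild type can
  # reach optimal growth without touching the co-producing route
  med <- minimalMedium(net, uptake = 8)
  ok0 <- optKnock(net, "D", med, k = 0L)
  rk0 <- robustKnock(net, "D", med, k = 0L)
  expect_gt(maxRate(ok0), 0)
  expect_equal(guaranteedRate(rk0), 0, tolerance = 1e-6)
})

test_that("a hard-wired co-product motif guarantees what it promises", {
  net <- generateToy(toySpec(1, FALSE, "coproduct", 0, 9))
  med <- minimalMedium(net)
  dm <- optKnockProxy(net, "D", "X", med, k = 0L)
  dg <- robustKnockProxy(net, "D", "X", med, k = 0L)
  # D and X leave through one reaction: optimistic equals guaranteed
  expect_equal(maxRate(dm), guaranteedRate(dg), tolerance = 1e-6)
  expect_gt(guaranteedRate(dg), 0)
})

test_that("one knockout raises the guaranteed proxy-coupled rate over wild type", {
  net <- generateToy(toySpec(1, FALSE, "bypass", 0, 16))
  med <- minimalMedium(net)
  g0 <- guaranteedRate(robustKnockProxy(net, "D", "X", med, k = 0L))
  oracle <- bruteForceCoupling(net, "D", "X", med, k = 1,
                               sense = "guaranteed_min")
  d <- robustKnockProxy(net, "D", "X", med, k = 1)
  expect_equal(guaranteedRate(d), oracle$rate, tolerance = 1e-6)
  expect_gt(guaranteedRate(d), g0)
  expect_true(any(vapply(oracle$allOptimal, identical, TRUE,
                         y = knockouts(d))))
})

test_that("coupling with proxy = biomass reduces to plain OptKnock", {
  net <- generateToy(toySpec(1, TRUE, "bypass", 1, 17))
  med <- minimalMedium(net)
  a <- optKnock(net, "D", med, k = 2L)
  b <- optKnockProxy(net, "D", "biomass", med, k = 2L)
  expect_identical(knockouts(a), knockouts(b))
  expect_equal(maxRate(a), maxRate(b), tolerance = 1e-12)
  expect_equal(guaranteedRate(a), guaranteedRate(b), tolerance = 1e-12)
})

test_that("guaranteed <= optimistic <= unconstrained ceiling on every motif toy", {
  cfg <- solveConfig()
  for (seed in c(13, 14, 16, 9, 11)) {
    motif <- if (seed %in% c(9, 11)) "coproduct" else "bypass"
    net <- generateToy(toySpec(1 + seed %% 2, FALSE, motif, 1, seed))
    med <- minimalMedium(net)
    ceilingRate <- as.numeric(maxProduction(net, med, "D", minGrowth = 0.1))
    ok <- optKnock(net, "D", med, k = 2L, config = cfg)
    rk <- robustKnock(net, "D", med, k = 2L, config = cfg)
    expect_lte(guaranteedRate(rk), maxRate(ok) + 1e-6)
    expect_lte(maxRate(ok), ceilingRate + 1e-6)
    okp <- optKnockProxy(net, "D", "X", med, k = 2L, config = cfg)
    rkp <- robustKnockProxy(net, "D", "X", med, k = 2L, config = cfg)
    expect_lte(guaranteedRate(rkp), maxRate(okp) + 1e-6)
    expect_lte(maxRate(okp), ceilingRate + 1e-6)
  }
})

test_that("the coupling matrix reproduces single-pair calls", {
  net <- generateToy(toySpec(1, FALSE, "bypass", 1, 18))
  med <- minimalMedium(net)
  cm <- couplingMatrix(net, targets = c("D", "Z1"), proxies = c("X", "C"),
                       med, method = "optknock_proxy", k = 1L)
  expect_identical(dim(cm$rates), c(2L, 2L))
  single <- optKnockProxy(net, "D", "X", med, k = 1L)
  expect_equal(cm$rates["D", "X"], maxRate(single), tolerance = 1e-6)
  expect_identical(cm$knockouts[["D", "X"]], knockouts(single))
  tf <- tempfile(fileext = ".tsv")
  writeCouplingMatrix(cm, tf)
  tab <- utils::read.delim(tf, check.names = FALSE)
  expect_identical(dim(tab), c(2L, 3L))
})

test_that("proxy must differ from the target", {
  net <- generateToy(toySpec(1, FALSE, "coproduct", 0, 9))
  med <- minimalMedium(net)
  expect_error(optKnockProxy(net, "D", "D", med), "differ")
})
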