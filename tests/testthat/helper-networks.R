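# Hand-built fixture networks, constructed in code. Sign convention:
# exchange columns carry -1, so uptake is a negative flux.

# linear chain: EX_A -> A -> B -> biomass, unit stoichiometry
chainNet <- function(cap = 10) {
  S <- rbind(A = c(-1, -1, 0),
             B = c(0, 1, -1))
  metabolicNetwork(
    metabolites = rownames(S),
    reactions = c("EX_A", "R1", "BIOMASS"),
    S = S, lowerBounds = c(0, 0, 0), upperBounds = c(100, cap, 100),
    biomassReaction = "BIOMASS",
    metadata = list(carbon_source = "A"))
}

# two routes A -> B with capacities 4 and 7; uptake 20 -> growth 11
branchedNet <- function() {
  S <- rbind(A = c(-1, -1, -1, 0),
             B = c(0, 1, 1, -1))
  metabolicNetwork(
    metabolites = rownames(S),
    reactions = c("EX_A", "R1", "R2", "BIOMASS"),
    S = S, lowerBounds = c(0, 0, 0, 0), upperBounds = c(100, 4, 7, 100),
    biomassReaction = "BIOMASS",
    metadata = list(carbon_source = "A"))
}

# precursor toy with an explicit product exchange
productNet <- function() {
  S <- rbind(A = c(-1, -1, -1, 0),
             P = c(0, 1, 0, -1))
  metabolicNetwork(
    metabolites = rownames(S),
    reactions = c("EX_A", "MKP", "BIOMASS", "EX_P"),
    S = S, lowerBounds = c(0, 0, 0, 0),
    upperBounds = c(100, 100, 100, 100),
    biomassReaction = "BIOMASS",
    metadata = list(carbon_source = "A"))
}

# two sequential synthesis steps A -> I -> C: two alternative single cuts
twoStepNet <- function() {
  S <- rbind(A = c(-1, -1, 0, 0, 0),
             I = c(0, 1, -1, 0, 0),
             C = c(0, 0, 1, -1, -1))
  metabolicNetwork(
    metabolites = rownames(S),
    reactions = c("EX_A", "S1", "S2", "BIOMASS", "EX_C"),
    S = S, lowerBounds = c(0, 0, 0, 0, 0),
    upperBounds = c(100, 20, 20, 100, 100),
    biomassReaction = "BIOMASS",
    metadata = list(carbon_source = "A"))
}

# biosensor whose biomass yield per unit C saturates in poor medium (carbon
# limits the B supply) but not under rich supplementation (B importable):
# a yield-sensitive sensor in the spent-medium sense
sensitiveNet <- function() {
  S <- rbind(A = c(-1, -2, -1, 0, 0, 0),
             B = c(0, 1, 0, -1, 0, -1),
             C = c(0, 0, 1, -1, -1, 0))
  metabolicNetwork(
    metabolites = rownames(S),
    reactions = c("EX_A", "RB", "SYN1", "BIOMASS", "EX_C", "EX_B"),
    S = S, lowerBounds = c(0, 0, 0, 0, 0, 0),
    upperBounds = c(100, 100, 5, 100, 100, 100),
    biomassReaction = "BIOMASS",
    metadata = list(carbon_source = "A"))
}

minimalMedium <- function(net, uptake = 10)
  makeMedium(net, "minimal", defaultUptake = uptake)

expectEqualSets <- function(got, want) {
  gk <- sort(vapply(got, function(s) paste(sort(s), collapse = ","), ""))
  wk <- sort(vapply(want, function(s) paste(sort(s), collapse = ","), ""))
  expect_identical(unname(gk), unname(wk))
}

knockoutKeys <- function(designs)
  lapply(designs, function(d) knockouts(d))

# the seeded toy battery shared by the oracle-equivalence and invariant
# suites: 20 specifications covering route multiplicity, salvage import,
# both coupling motifs, and decoy counts
batterySpecs <- function() {
  specs <- list()
  add <- function(...) specs[[length(specs) + 1L]] <<- toySpec(...)
  add(1, FALSE, "none", 0, 1);  add(1, FALSE, "none", 2, 2)
  add(2, FALSE, "none", 1, 3);  add(3, FALSE, "none", 0, 4)
  add(1, TRUE, "none", 1, 5);   add(2, TRUE, "none", 0, 6)
  add(1, TRUE, "none", 2, 7);   add(2, TRUE, "none", 1, 8)
  add(1, FALSE, "coproduct", 0, 9);  add(1, FALSE, "coproduct", 1, 10)
  add(2, FALSE, "coproduct", 0, 11); add(1, TRUE, "coproduct", 1, 12)
  add(1, FALSE, "bypass", 0, 13); add(1, FALSE, "bypass", 1, 14)
  add(1, FALSE, "bypass", 2, 15); add(1, TRUE, "bypass", 0, 16)
  add(1, TRUE, "bypass", 1, 17);  add(2, FALSE, "bypass", 0, 18)
  add(1, FALSE, "coproduct", 2, 19); add(2, TRUE, "none", 2, 20)
  specs
}
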