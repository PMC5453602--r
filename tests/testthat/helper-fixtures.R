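# Hand-built toy models used as LP/constraint oracles. Kept independent of
# make_toy_model so generator and solver can check each other.

# EX_in -(ub intake)-> A -(ub cap, gene gAB)-> B -> biomass
linear_model <- function(cap = 5, intake = 10) {
  stoich_model(
    metabolite_ids = c("A", "B"),
    reaction_ids = c("EX_in", "AB", "BIOMASS"),
    S = matrix(c(1, -1, 0,
                 0, 1, -1), 2, 3, byrow = TRUE),
    lb = c(0, 0, 0), ub = c(intake, cap, 1000),
    gpr = c("", "gAB", ""),
    objective = "BIOMASS", exchange = c(TRUE, FALSE, TRUE))
}

# two parallel routes (ub 3 and ub 4) converging on biomass, intake ub 10
branched_model <- function() {
  stoich_model(
    metabolite_ids = c("A", "B"),
    reaction_ids = c("EX_in", "R1", "R2", "BIOMASS"),
    S = matrix(c(1, -1, -1, 0,
                 0, 1, 1, -1), 2, 4, byrow = TRUE),
    lb = rep(0, 4), ub = c(10, 3, 4, 1000),
    gpr = c("", "g1", "g2", ""),
    objective = "BIOMASS", exchange = c(TRUE, FALSE, FALSE, TRUE))
}

# single step gated by an isozyme pair (g1 or g2), capacity 6
isozyme_model <- function() {
  stoich_model(
    metabolite_ids = c("A", "B"),
    reaction_ids = c("EX_in", "ISO", "BIOMASS"),
    S = matrix(c(1, -1, 0,
                 0, 1, -1), 2, 3, byrow = TRUE),
    lb = rep(0, 3), ub = c(10, 6, 1000),
    gpr = c("", "(g1 or g2)", ""),
    objective = "BIOMASS", exchange = c(TRUE, FALSE, TRUE))
}

# one-edge network: TF1 is a direct activator of `target` with given FDR
one_edge_network <- function(target, fdr, sign = "activator",
                             evidence = "direct", prom_prob = NA_real_) {
  influence_network(data.frame(
    tf = "TF1", target = target, evidence = evidence, sign = sign,
    fdr = fdr, prom_prob = prom_prob, stringsAsFactors = FALSE))
}
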