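# Shared fixtures: the bundled model is built once per test run; a small
# toy network with an enumerable feasible set backs the brute-force
# optimality oracle; an SBML snippet exercises the import hook.

the_net <- reduced_network()
the_kin <- kinetic_params()

# Toy network: substrate A taken up at a fixed rate and split between
# biomass and two secreted products; after the uptake pin the feasible
# set is a 2-simplex, so the optimum can be found by grid enumeration.
toy_network <- function(uptake = 10) {
  mets <- data.frame(
    id = c("A_c", "A_e", "X_e", "C_e", "D_e"),
    compartment = c("c", "e", "e", "e", "e"),
    molar_mass = c(90, 90, 1000, 90, 90),
    carbon = c(3, 3, 3, 3, 3),
    stringsAsFactors = FALSE)
  rx <- list(
    T_A  = c(A_e = -1, A_c = 1),
    BIO  = c(A_c = -1, X_e = 1),
    R2   = c(A_c = -1, C_e = 1),
    R3   = c(A_c = -1, D_e = 1),
    EX_A = c(A_e = -1),
    EX_X = c(X_e = -1),
    EX_C = c(C_e = -1),
    EX_D = c(D_e = -1))
  S <- matrix(0, nrow(mets), length(rx), dimnames = list(mets$id, names(rx)))
  for (j in seq_along(rx)) S[names(rx[[j]]), j] <- rx[[j]]
  rxns <- data.frame(id = names(rx), lb = 0, ub = 1000,
                     is_exchange = grepl("^EX_", names(rx)),
                     atp_production = 0, stringsAsFactors = FALSE)
  rxns$lb[rxns$id == "EX_A"] <- -uptake
  rxns$ub[rxns$id == "EX_A"] <- -uptake
  net <- structure(list(
    S = S, mets = mets, rxns = rxns, biomass_id = "BIO",
    composition = biomass_composition(), ngam = 0,
    atp_flux_ids = character(0),
    exchange_map = c(A_e = "EX_A", X_e = "EX_X", C_e = "EX_C",
                     D_e = "EX_D")),
    class = "metabolic_network")
  qr_t <- qr(t(S))
  net$S_rank_rows <- sort(qr_t$pivot[seq_len(qr_t$rank)])
  validate_network(net)
}

# brute-force grid search of Z = mu / sum(v^2) on the toy network
toy_bruteforce_Z <- function(uptake = 10, n_grid = 400) {
  best <- -Inf
  for (vb in seq(0, uptake, length.out = n_grid)) {
    for (v2 in seq(0, uptake - vb, length.out = n_grid)) {
      v3 <- uptake - vb - v2
      ssq <- 2 * uptake^2 + 2 * (vb^2 + v2^2 + v3^2)
      z <- vb / ssq
      if (z > best) best <- z
    }
  }
  best
}

# minimal SBML Level 3 + fbc rendering of the toy network
write_toy_sbml <- function(path, uptake = 10) {
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"',
    '      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"',
    '      level="3" version="1" fbc:required="false">',
    '<model id="toy">',
    '<listOfCompartments>',
    '<compartment id="c" constant="true"/>',
    '<compartment id="ext" constant="true"/>',
    '</listOfCompartments>',
    '<listOfSpecies>',
    '<species id="A_c" compartment="c" constant="false" boundaryCondition="false" hasOnlySubstanceUnits="false"/>',
    '<species id="A_e" compartment="ext" constant="false" boundaryCondition="false" hasOnlySubstanceUnits="false"/>',
    '<species id="X_e" compartment="ext" constant="false" boundaryCondition="false" hasOnlySubstanceUnits="false"/>',
    '<species id="C_e" compartment="ext" constant="false" boundaryCondition="false" hasOnlySubstanceUnits="false"/>',
    '</listOfSpecies>',
    '<listOfParameters>',
    sprintf('<parameter id="lb_up" value="%g" constant="true"/>', -uptake),
    sprintf('<parameter id="ub_up" value="%g" constant="true"/>', -uptake),
    '<parameter id="lb0" value="0" constant="true"/>',
    '<parameter id="ub1000" value="1000" constant="true"/>',
    '</listOfParameters>',
    '<listOfReactions>',
    '<reaction id="T_A" reversible="false" fast="false" lowerFluxBound="lb0" upperFluxBound="ub1000">',
    '<listOfReactants><speciesReference species="A_e" stoichiometry="1" constant="true"/></listOfReactants>',
    '<listOfProducts><speciesReference species="A_c" stoichiometry="1" constant="true"/></listOfProducts>',
    '</reaction>',
    '<reaction id="BIO" reversible="false" fast="false" lowerFluxBound="lb0" upperFluxBound="ub1000">',
    '<listOfReactants><speciesReference species="A_c" stoichiometry="1" constant="true"/></listOfReactants>',
    '<listOfProducts><speciesReference species="X_e" stoichiometry="1" constant="true"/></listOfProducts>',
    '</reaction>',
    '<reaction id="R2" reversible="false" fast="false" lowerFluxBound="lb0" upperFluxBound="ub1000">',
    '<listOfReactants><speciesReference species="A_c" stoichiometry="1" constant="true"/></listOfReactants>',
    '<listOfProducts><speciesReference species="C_e" stoichiometry="1" constant="true"/></listOfProducts>',
    '</reaction>',
    '<reaction id="EX_A" reversible="true" fast="false" lowerFluxBound="lb_up" upperFluxBound="ub_up">',
    '<listOfReactants><speciesReference species="A_e" stoichiometry="1" constant="true"/></listOfReactants>',
    '</reaction>',
    '<reaction id="EX_X" reversible="false" fast="false" lowerFluxBound="lb0" upperFluxBound="ub1000">',
    '<listOfReactants><speciesReference species="X_e" stoichiometry="1" constant="true"/></listOfReactants>',
    '</reaction>',
    '<reaction id="EX_C" reversible="false" fast="false" lowerFluxBound="lb0" upperFluxBound="ub1000">',
    '<listOfReactants><speciesReference species="C_e" stoichiometry="1" constant="true"/></listOfReactants>',
    '</reaction>',
    '</listOfReactions>',
    '<fbc:listOfObjectives fbc:activeObjective="obj">',
    '<fbc:objective fbc:id="obj" fbc:type="maximize">',
    '<fbc:listOfFluxObjectives>',
    '<fbc:fluxObjective fbc:reaction="BIO" fbc:coefficient="1"/>',
    '</fbc:listOfFluxObjectives>',
    '</fbc:objective>',
    '</fbc:listOfObjectives>',
    '</model>',
    '</sbml>')
  writeLines(lines, path)
  path
}

# carbon balance of the exchange fluxes of a flux vector (should be ~0)
net_carbon_residual <- function(net, v) {
  carb <- net$mets$carbon
  ex <- which(net$rxns$is_exchange)
  tot <- 0
  for (j in ex) {
    m <- which(net$S[, j] != 0)
    tot <- tot + sum(net$S[m, j] * v[j] * carb[m])
  }
  tot
}
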