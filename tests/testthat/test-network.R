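# Reduced network construction, biomass composition and network I/O.

test_that("bundled network has one exchange per extracellular species", {
  ex <- the_net$mets$id[the_net$mets$compartment == "e"]
  for (m in ex)
    expect_equal(sum(the_net$S[m, the_net$rxns$is_exchange] != 0), 1)
  # glycerol in; PDO, acetate, butyrate, lactate, butanol, ethanol, H2,
  # CO2, biomass out
  expect_setequal(names(the_net$exchange_map),
                  c("glyc_e", "pdo_e", "ac_e", "but_e", "lac_e", "eth_e",
                    "buoh_e", "h2_e", "co2_e", "biomass_e"))
  expect_lt(the_net$rxns$lb[the_net$rxns$id == "EX_glyc"], 0)
})

test_that("every internal reaction conserves carbon exactly", {
  carb <- the_net$mets$carbon
  bal <- t(the_net$S[, !the_net$rxns$is_exchange]) %*% carb
  expect_true(all(abs(bal) < 1e-9))
})

test_that("PDO synthesis consumes exactly one NADH per PDO", {
  s <- the_net$S[, "PDOR"]
  expect_equal(unname(s["nadh_c"]), -1)
  expect_equal(unname(s["pdo_e"]), 1)
  expect_equal(unname(s["glyc_c"]), -1)
})

test_that("growth is feasible with glycerol as the only carbon source", {
  fs <- flux_state_at(the_net, 20, the_kin)
  expect_gt(fs$mu, 0)
  expect_gt(fs$fluxes[["EX_pdo"]], 0)
})

test_that("validation catches orphan metabolites and bad bounds", {
  bad <- the_net
  bad$S <- rbind(bad$S, orphan_c = 0)
  bad$mets <- rbind(bad$mets,
                    data.frame(id = "orphan_c", compartment = "c",
                               molar_mass = 1, carbon = 0))
  expect_error(validate_network(bad), "orphan metabolite")
  bad2 <- the_net
  bad2$rxns$lb[2] <- bad2$rxns$ub[2] + 1
  expect_error(validate_network(bad2), "bound")
})

test_that("JSON round trip preserves stoichiometry, bounds and composition", {
  f <- tempfile(fileext = ".json")
  write_network(the_net, f)
  n2 <- load_network(f)
  expect_equal(n2$S, the_net$S)
  expect_equal(n2$rxns$lb, the_net$rxns$lb)
  expect_equal(n2$rxns$ub, the_net$rxns$ub)
  expect_equal(n2$biomass_id, the_net$biomass_id)
  expect_equal(biomass_molecular_weight(n2$composition),
               biomass_molecular_weight(the_net$composition))
  # the bundled serialization ships with the package and matches the code
  bundled <- system.file("extdata", "cbu_reduced_network.json",
                         package = "pdodfba")
  n3 <- load_network(bundled)
  expect_equal(n3$S, the_net$S)
})

test_that("a JSON network with an all-zero metabolite row is rejected", {
  f <- tempfile(fileext = ".json")
  obj <- jsonlite::read_json(system.file("extdata",
                                         "cbu_reduced_network.json",
                                         package = "pdodfba"))
  obj$metabolites[[length(obj$metabolites) + 1]] <-
    list(id = "ghost_c", compartment = "c", molar_mass = 1, carbon = 0)
  jsonlite::write_json(obj, f, auto_unbox = TRUE)
  expect_error(load_network(f), "orphan")
})

test_that("the SBML import hook reads species, bounds and the objective", {
  f <- tempfile(fileext = ".xml")
  write_toy_sbml(f, uptake = 10)
  net <- load_network(f, format = "sbml")
  expect_s3_class(net, "metabolic_network")
  expect_equal(net$biomass_id, "BIO")
  expect_equal(unname(net$rxns$lb[net$rxns$id == "EX_A"]), -10)
  expect_equal(unname(net$S["A_c", "T_A"]), 1)
  expect_equal(unname(net$S["A_e", "T_A"]), -1)
})
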