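# The instantaneous flux optimization: feasibility invariants, the
# brute-force optimality oracle, multistart consistency, and the
# regime phenotypes.

test_that("starvation gives zero growth and zero exchange fluxes", {
  fs <- flux_state_at(the_net, 0, the_kin)
  expect_equal(fs$mu, 0)
  expect_equal(fs$objective_value, 0)
  expect_true(all(abs(fs$fluxes[grepl("^EX_", names(fs$fluxes))]) < 1e-6))
})

test_that("every returned flux state satisfies S v = 0 and the bounds", {
  for (G in c(46, 30, 15, 8, 2, 0.3)) {
    fs <- flux_state_at(the_net, G, the_kin)
    v <- fs$fluxes
    expect_lt(max(abs(the_net$S %*% v)), 1e-6)
    U <- -v[["EX_glyc"]]
    cap <- acetate_secretion_bound(U, the_kin)
    expect_true(all(v >= the_net$rxns$lb - 1e-6))
    expect_true(all(v <= the_net$rxns$ub + 1e-6))
    expect_lte(v[["ACK"]], cap + 1e-6)
  }
})

test_that("carbon is conserved between uptake, products and biomass", {
  for (G in c(40, 20, 5)) {
    fs <- flux_state_at(the_net, G, the_kin)
    # relative to the carbon uptake flux
    rel <- net_carbon_residual(the_net, fs$fluxes) /
      (3 * abs(fs$fluxes[["EX_glyc"]]))
    expect_lt(abs(rel), 1e-6)
  }
})

test_that("optimum matches brute-force enumeration on the toy network", {
  toy <- toy_network(uptake = 10)
  fs <- solve_flux_state(toy, objective_spec(w = 1))
  z_grid <- toy_bruteforce_Z(uptake = 10, n_grid = 500)
  expect_equal(fs$objective_value, z_grid, tolerance = 1e-4)
  # the solver's allocation is the analytic optimum: all substrate to
  # biomass (the ratio rewards the numerator; spreading carbon into the
  # byproducts only adds squared flux)
  expect_equal(fs$mu, 10, tolerance = 1e-6)
})

test_that("multistart seeds agree on the optimum (convex subproblems)", {
  for (G in c(35, 12)) {
    f1 <- flux_state_at(the_net, G, the_kin)
    f2 <- flux_state_at(the_net, G, the_kin,
                        warm_start = rep(0.5, nrow(the_net$rxns)))
    expect_equal(f1$objective_value, f2$objective_value, tolerance = 1e-6)
    expect_equal(f1$mu, f2$mu, tolerance = 1e-6)
  }
})

test_that("growth rate is non-decreasing in the prescribed uptake", {
  ctx <- pdodfba:::.dfba_ctx(the_net, the_kin)
  mus <- vapply(seq(0.5, 30, length.out = 12), function(U) {
    lb <- ctx$lb0; ub <- ctx$ub0
    lb[ctx$jg] <- -U; ub[ctx$jg] <- -U
    ub[ctx$jack] <- acetate_secretion_bound(U, the_kin)
    r <- pdodfba:::.flux_opt_cpp(ctx$Sr, lb, ub, ctx$bio, 0.04, ctx$a, NULL)
    r$mu
  }, 0)
  expect_true(all(diff(mus) > -1e-6))
})

test_that("relaxing the acetate ceiling never decreases the optimum Z", {
  ctx <- pdodfba:::.dfba_ctx(the_net, the_kin)
  U <- 30
  zs <- vapply(c(0.5, 1, 2, 4, 8), function(cap) {
    lb <- ctx$lb0; ub <- ctx$ub0
    lb[ctx$jg] <- -U; ub[ctx$jg] <- -U
    ub[ctx$jack] <- cap
    pdodfba:::.flux_opt_cpp(ctx$Sr, lb, ub, ctx$bio, 0.04, ctx$a, NULL)$Z
  }, 0)
  expect_true(all(diff(zs) > -1e-10))
})

test_that("acetate outruns butyrate secretion in the excess regime", {
  fs <- flux_state_at(the_net, 30, the_kin)   # w = 0.04
  expect_equal(fs$w, 0.04)
  expect_gt(fs$fluxes[["EX_ac"]], fs$fluxes[["EX_but"]])
  # acetate sits at its allosteric ceiling
  U <- -fs$fluxes[["EX_glyc"]]
  expect_equal(fs$fluxes[["ACK"]], acetate_secretion_bound(U, the_kin),
               tolerance = 1e-5)
})

test_that("the convex QP helper reproduces an analytic solution", {
  # minimize 0.5||x||^2 - c'x s.t. x1 + x2 + x3 = 0 (via S), box [-1, 1]:
  # with c = (1, 0.5, 0), the KKT solution is x = c - mean(c)
  S <- matrix(1, 1, 3)
  cv <- c(1, 0.5, 0)
  r <- pdodfba:::.qp_solve_cpp(diag(3), cv, S, rep(-1, 3), rep(1, 3))
  expect_equal(as.numeric(r$x), cv - mean(cv), tolerance = 1e-8)
})

test_that("the literal product objective form is exposed", {
  toy <- toy_network(uptake = 4)
  fs <- solve_flux_state(toy, objective_spec(w = 1, form = "product"))
  # maximizing mu * sum(v^2) drives all substrate to biomass as well,
  # and the attained value matches the closed form at that corner
  expect_equal(fs$mu, 4, tolerance = 1e-3)
  expect_equal(fs$objective_value, 4 * (2 * 16 + 2 * 16),
               tolerance = 1e-2)
})
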