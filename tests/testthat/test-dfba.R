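# The DFBA engine: degenerate inputs, analytic growth oracle, approach
# agreement, mass conservation, and fed-batch behavior.

test_that("no biomass means frozen concentrations", {
  sp <- dfba_spec(the_net, the_kin, glycerol0 = 20, X0 = 0, tf = 5,
                  G = 20, approach = "soa")
  tr <- dfba(sp)
  expect_true(all(abs(tr$states$glycerol - 20) < 1e-9))
  expect_true(all(tr$states$pdo == 0))
})

test_that("after exhaustion biomass decays at the limitation death rate", {
  sp <- dfba_spec(the_net, the_kin, glycerol0 = 1.2, X0 = 0.8, tf = 30,
                  G = 300, approach = "soa")
  tr <- dfba(sp)
  s <- tr$states
  expect_true(all(s$glycerol > -1e-12))
  late <- s[s$time >= 25, ]
  # growth has stopped; decay rate matches kd_lim
  rate <- diff(log(late$X)) / diff(late$time)
  expect_equal(mean(rate), -the_kin$kd_lim, tolerance = 0.02)
})

test_that("short-horizon growth matches the exponential closed form", {
  # constant conditions: high glycerol, short window, so mu is constant
  sp <- dfba_spec(the_net, the_kin, glycerol0 = 46, X0 = 0.05, tf = 1,
                  G = 400, approach = "soa")
  tr <- dfba(sp)
  mu <- tr$states$mu[1]
  kd <- the_kin$kd_exc
  X_exact <- 0.05 * exp((mu - kd) * 1)
  expect_equal(tr$states$X[nrow(tr$states)], X_exact, tolerance = 5e-3)
})

test_that("DA refines SOA: final states converge as the step shrinks", {
  sp <- scenario("batch_limited", the_net, the_kin, approach = "da", G = 50)
  da <- dfba(sp)
  soa_fine <- dfba(dfba_spec(the_net, the_kin, glycerol0 = 10, X0 = 0.1,
                             tf = 12, G = 800, approach = "soa"))
  f_da <- da$states[nrow(da$states), c("glycerol", "pdo", "X")]
  f_soa <- soa_fine$states[nrow(soa_fine$states), c("glycerol", "pdo", "X")]
  expect_true(all(abs(unlist(f_da) - unlist(f_soa)) /
                    pmax(abs(unlist(f_da)), 0.1) < 0.01))
})

test_that("SOA converges to DA at first order in the step size", {
  ref <- dfba(scenario("batch_limited", the_net, the_kin,
                       approach = "da", G = 50))
  ref_pdo <- ref$states$pdo[nrow(ref$states)]
  errs <- vapply(c(25, 50, 100, 200), function(G) {
    tr <- dfba(dfba_spec(the_net, the_kin, glycerol0 = 10, X0 = 0.1,
                         tf = 12, G = G, approach = "soa"))
    abs(tr$states$pdo[nrow(tr$states)] - ref_pdo)
  }, 0)
  expect_true(all(diff(errs) < 0))
  # halving the step roughly halves the error (order ~ 1)
  ratio <- errs[-length(errs)] / errs[-1]
  expect_true(all(ratio > 1.4 & ratio < 3.2))
})

test_that("the three approaches agree on the glycerol-limited scenario", {
  pdo_f <- vapply(c("soa", "da", "doa"), function(a) {
    tr <- dfba(scenario("batch_limited", the_net, the_kin,
                        approach = a, G = 100))
    tr$states$pdo[nrow(tr$states)]
  }, 0)
  expect_lt(max(dist(pdo_f)), 0.07)
})

test_that("DOA refuses horizons that cross the objective switch", {
  sp <- dfba_spec(the_net, the_kin, glycerol0 = 20, X0 = 0.15, tf = 18,
                  approach = "doa")
  expect_error(dfba(sp), "DOA cannot be employed")
})

test_that("collocation families give indistinguishable DOA solutions", {
  pdo_f <- vapply(c("legendre", "chebyshev1"), function(fam) {
    sp <- scenario("batch_limited", the_net, the_kin, approach = "doa",
                   G = 60)
    sp$collocation <- list(family = fam, n_points = 6)
    tr <- dfba(sp)
    tr$states$pdo[nrow(tr$states)]
  }, 0)
  expect_lt(abs(diff(pdo_f)), 0.02)
})

test_that("discrete mass balances close at every SOA step", {
  sp <- dfba_spec(the_net, the_kin, glycerol0 = 15, X0 = 0.2, tf = 8,
                  G = 80, approach = "soa")
  tr <- dfba(sp)
  s <- tr$states
  mw <- the_net$mets$molar_mass[match(pdodfba:::.species_map,
                                      the_net$mets$id)] / 1000
  ex_cols <- the_net$exchange_map[pdodfba:::.species_map]
  dt <- diff(s$time)[1]
  for (g in seq_len(nrow(s) - 1)) {
    v <- tr$fluxes[g, ex_cols]
    pred <- unlist(s[g, names(pdodfba:::.species_map)]) + v * mw * s$X[g] * dt
    got <- unlist(s[g + 1, names(pdodfba:::.species_map)])
    expect_true(all(abs(pmax(pred, 0) - got) < 1e-6 * max(1, max(got))))
  }
})

test_that("zero feed reduces the fed-batch integrator to the batch one", {
  feed0 <- feed_policy("constant", alpha = 0, glycerol_pct = 20)
  a <- dfba(dfba_spec(the_net, the_kin, glycerol0 = 12, X0 = 0.3, tf = 6,
                      G = 60, approach = "soa", feed = feed0))
  b <- dfba(dfba_spec(the_net, the_kin, glycerol0 = 12, X0 = 0.3, tf = 6,
                      G = 60, approach = "soa"))
  expect_equal(a$states$pdo, b$states$pdo, tolerance = 1e-9)
  expect_equal(a$states$V, rep(1, nrow(a$states)))
})

test_that("fed-batch volume is monotone and capped at V_max", {
  feed <- feed_policy("constant", alpha = 0.02, glycerol_pct = 20,
                      V_max = 1.5)
  tr <- dfba(dfba_spec(the_net, the_kin, glycerol0 = 20, X0 = 0.2, tf = 40,
                       G = 200, approach = "soa", feed = feed))
  V <- tr$states$V
  expect_true(all(diff(V) > -1e-12))
  expect_true(all(V <= 1.5 + 1e-9))
  expect_equal(max(V), 1.5, tolerance = 1e-6)
})

test_that("the fed-batch glycerol mass balance closes", {
  feed <- feed_policy("constant", alpha = 0.01, glycerol_pct = 25)
  tr <- dfba(dfba_spec(the_net, the_kin, glycerol0 = 20, X0 = 0.2, tf = 20,
                       G = 400, approach = "soa", feed = feed))
  m <- trajectory_metrics(tr)
  s <- tr$states
  # fed + initial = residual + consumed; consumed is also the integral of
  # the uptake flux (Euler quadrature at the step points)
  dt <- diff(s$time)[1]
  upt <- -tr$fluxes[-nrow(s), "EX_glyc"] * s$X[-nrow(s)] * s$V[-nrow(s)] *
    0.09209 * dt
  expect_equal(m$glycerol_consumed, sum(upt),
               tolerance = 1e-6 * max(1, m$glycerol_consumed))
})

test_that("pH-coupled feeding follows the proton secretion flux", {
  feed <- feed_policy("ph_coupled", beta = 5e-4, glycerol_pct = 25)
  tr <- dfba(dfba_spec(the_net, the_kin, glycerol0 = 30, X0 = 0.2, tf = 10,
                       G = 100, approach = "soa", feed = feed))
  s <- tr$states
  g <- 50  # mid-run step
  vh <- sum(tr$fluxes[g, c("EX_ac", "EX_but", "EX_lac")])
  F_expect <- 5e-4 * vh * s$X[g] * s$V[g]
  F_obs <- (s$V[g + 1] - s$V[g]) / diff(s$time)[1]
  expect_equal(F_obs, F_expect, tolerance = 1e-8)
})

test_that("trajectory metrics do the arithmetic", {
  sp <- dfba_spec(the_net, the_kin, glycerol0 = 10, X0 = 0.1, tf = 10,
                  G = 10, approach = "soa")
  tr <- dfba(sp)
  # synthetic trajectory: 10 g/L PDO at 10 h in 1 L
  tr$states$pdo <- seq(0, 10, length.out = 11)
  tr$states$glycerol <- seq(20, 0, length.out = 11)
  m <- trajectory_metrics(tr)
  expect_equal(m$q_pdo, 1, tolerance = 1e-9)
  expect_equal(m$final_pdo, 10)
  expect_equal(m$yield_mass, 0.5, tolerance = 1e-9)
  # zero-PDO trajectory
  tr$states$pdo[] <- 0
  m0 <- trajectory_metrics(tr)
  expect_equal(m0$q_pdo, 0)
  # nothing consumed: yields undefined and flagged
  tr$states$glycerol[] <- 20
  expect_warning(m1 <- trajectory_metrics(tr), "yields undefined")
  expect_true(is.na(m1$yield_mol))
})
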