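# Design-space scans: degenerate rows, monotonicity, classification and
# consistency of the selected optimum.

test_that("zero inoculum makes a zero-productivity row", {
  sc <- batch_factorial_scan(X0_grid = c(0, 0.1),
                             glycerol_grid = c(10, 20),
                             network = the_net, kinetics = the_kin,
                             tf = 40, G = 60)
  tab <- sc$table
  expect_true(all(tab$q_pdo[tab$X0 == 0] == 0))
  expect_true(all(tab$q_pdo[tab$X0 == 0.1] > 0))
  expect_equal(sum(tab$class == "optimal"), 1)
})

test_that("productivity is monotone in the inoculum at fixed glycerol", {
  sc <- batch_factorial_scan(X0_grid = c(0.02, 0.06, 0.12),
                             glycerol_grid = 30,
                             network = the_net, kinetics = the_kin,
                             tf = 60, G = 80)
  q <- sc$table$q_pdo[order(sc$table$X0)]
  expect_true(all(diff(q) > 0))
})

test_that("the optimum's metrics equal a recomputed single simulation", {
  sc <- batch_factorial_scan(X0_grid = c(0.05, 0.12),
                             glycerol_grid = c(20, 40),
                             network = the_net, kinetics = the_kin,
                             tf = 60, G = 80)
  opt <- sc$optimum
  m <- trajectory_metrics(dfba(dfba_spec(the_net, the_kin,
                                         glycerol0 = opt$glycerol0,
                                         X0 = opt$X0, tf = 60, G = 80,
                                         approach = "soa")))
  expect_equal(opt$q_pdo, m$q_pdo, tolerance = 1e-9)
  expect_equal(opt$final_pdo, m$final_pdo, tolerance = 1e-9)
})

test_that("fed-batch outcomes classify by mode and residual", {
  m_ok <- list(final_pdo = 30, residual_glycerol = 1,
               mass_conversion_fed = 0.5)
  m_res <- list(final_pdo = 30, residual_glycerol = 8,
                mass_conversion_fed = 0.5)
  m_dead <- list(final_pdo = 0.1, residual_glycerol = 90,
                 mass_conversion_fed = 0.001)
  expect_equal(classify_fedbatch_outcome(m_ok, "constant"), "suboptimal")
  expect_equal(classify_fedbatch_outcome(m_res, "ph_coupled"),
               "unconsumed_glycerol")
  expect_equal(classify_fedbatch_outcome(m_res, "constant"), "infeasible")
  expect_equal(classify_fedbatch_outcome(m_dead, "ph_coupled"),
               "infeasible")
  expect_equal(classify_fedbatch_outcome(NULL, "constant"), "infeasible")
})

test_that("over-feeding creates the infeasible zone; the pH selection
          honors the conversion constraint", {
  sc <- fedbatch_scan("constant", pct_grid = c(10, 45),
                      rate_grid = c(0.004, 0.05),
                      network = the_net, kinetics = the_kin,
                      tf = 30, G = 60)
  tab <- sc$table
  # the aggressive corner (high feed rate x concentrated feed) overloads
  worst <- tab[tab$rate > 0.02 & tab$pct == 45, ]
  expect_equal(worst$class, "infeasible")
  expect_true(any(tab$class %in% c("suboptimal", "optimal")))
  # every grid point is classified exactly once
  expect_true(all(tab$class %in% c("infeasible", "suboptimal",
                                   "unconsumed_glycerol", "optimal")))
  expect_equal(nrow(tab), 4)
})
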