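# Population balance model: degenerate ensembles, dispersion profiles,
# nesting/reproducibility, convergence, and validation against
# observations.

small_spec <- scenario("batch_excess", the_net, the_kin,
                       approach = "soa", G = 18)

test_that("zero heterogeneity gives a zero RSD profile", {
  pb <- run_pbm(group = "acetate3", rsd = 0, n_cells = 3,
                spec = small_spec, seed = 1)
  rp <- rsd_profile(pb)
  expect_true(all(rp$rsd_pct < 1e-9))
  # ensemble mean with rsd -> 0 equals the unperturbed trajectory
  base_tr <- dfba(small_spec)
  expect_equal(pb$mean_profile, base_tr$states$pdo, tolerance = 1e-9)
})

test_that("the RSD profile follows the two-point formula", {
  fake <- structure(list(times = c(0, 1), pdo = cbind(c(0, 9), c(0, 11)),
                         mean_profile = c(0, 10), final_pdo = c(9, 11),
                         group = "acetate3", rsd = 0.3, n_cells = 2,
                         failures = 0L, seed = 1),
                    class = "pbm_result")
  rp <- rsd_profile(fake)
  expect_equal(rp$rsd_pct[1], 0)                       # zero-mean flagged 0
  expect_equal(rp$rsd_pct[2], 100 * stats::sd(c(9, 11)) / 10)
})

test_that("ensembles are reproducible and nested in the cell count", {
  p1 <- run_pbm(group = "death2", rsd = 0.3, n_cells = 8,
                spec = small_spec, seed = 21)
  p2 <- run_pbm(group = "death2", rsd = 0.3, n_cells = 8,
                spec = small_spec, seed = 21)
  expect_identical(p1$pdo, p2$pdo)
  p3 <- run_pbm(group = "death2", rsd = 0.3, n_cells = 4,
                spec = small_spec, seed = 21)
  expect_identical(p3$pdo, p1$pdo[, 1:4])
  p4 <- run_pbm(group = "death2", rsd = 0.3, n_cells = 8,
                spec = small_spec, seed = 22)
  expect_false(identical(p4$pdo, p1$pdo))
})

test_that("convergence scan reports deviations against the largest n", {
  cs <- convergence_scan(n_grid = c(10, 25, 60), group = "death2",
                         rsd = 0.3, spec = small_spec, seed = 5)
  expect_equal(cs$rel_dev_pct[3], 0)
  expect_true(all(cs$rel_dev_pct >= 0))
  # zero dispersion: identical draws, zero deviation at every n
  cs0 <- convergence_scan(n_grid = c(5, 10), group = "death2", rsd = 0,
                          spec = small_spec, seed = 5)
  expect_true(all(cs0$rel_dev_pct == 0))
})

test_that("Monte-Carlo error of the ensemble mean shrinks like 1/sqrt(n)", {
  # planted-variance toy model: the PBM mean over n cells of iid
  # final titers has standard error sigma/sqrt(n)
  set.seed(8)
  sigma <- 0.4
  draws <- matrix(rnorm(3200 * 30, mean = 20, sd = sigma), 3200)
  se <- vapply(c(50, 200, 800, 3200), function(n)
    stats::sd(colMeans(draws[seq_len(n), , drop = FALSE])), 0)
  ratio <- se[-4] / se[-1]
  expect_equal(ratio, rep(2, 3), tolerance = 0.35)
})

test_that("perturbing composition and kinetics yields ordered dispersions", {
  groups <- c("precursors44", "acetate3", "all57")
  rsds <- vapply(groups, function(g) {
    pb <- run_pbm(group = g, rsd = 0.3, n_cells = 60,
                  spec = small_spec, seed = 31)
    rp <- rsd_profile(pb)
    rp$rsd_pct[nrow(rp)]
  }, 0)
  # precursor composition perturbs the PDO prediction least; the combined
  # group is at least as dispersed as any single one up to MC error
  expect_lt(rsds[["precursors44"]], rsds[["acetate3"]])
  mc_slack <- rsds[["all57"]] / sqrt(60)
  expect_gt(rsds[["all57"]], max(rsds[c("precursors44", "acetate3")]) -
              3 * mc_slack)
})

test_that("maximum dispersion falls in the decelerated growth phase", {
  pb <- run_pbm(group = "all57", rsd = 0.3, n_cells = 60,
                spec = scenario("batch_excess", the_net, the_kin,
                                approach = "soa", G = 36), seed = 31)
  rp <- rsd_profile(pb)
  t_max <- rp$time[which.max(rp$rsd_pct)]
  base_tr <- dfba(scenario("batch_excess", the_net, the_kin,
                           approach = "soa", G = 36))
  # deceleration: after the growth-rate peak, before exhaustion
  s <- base_tr$states
  t_exhaust <- s$time[which(s$glycerol < 0.1)[1]]
  t_mu_peak <- s$time[which.max(s$mu * s$X)]
  expect_gt(t_max, t_mu_peak * 0.8)
  expect_lt(t_max, t_exhaust + 1)
})

test_that("self-generated observations validate perfectly", {
  pb <- run_pbm(group = "acetate3", rsd = 0.1, n_cells = 10,
                spec = small_spec, seed = 3)
  obs <- data.frame(time = c(6, 12, 18, 24),
                    pdo = stats::approx(pb$times, pb$base_profile,
                                        xout = c(6, 12, 18, 24))$y)
  v <- suppressWarnings(validate_against_observations(pb, obs))
  expect_equal(v$correlation_pct, 100, tolerance = 1e-6)
  expect_lt(v$standard_error_pct, 1e-6)
  # 5% multiplicative noise still correlates above 95%
  set.seed(12)
  obs$pdo <- obs$pdo * (1 + 0.05 * rnorm(4))
  v2 <- validate_against_observations(pb, obs)
  expect_gt(v2$correlation_pct, 95)
  expect_error(validate_against_observations(pb, obs[1:2, ]),
               "fewer than 3")
})

test_that("a synthetic culture comparison lands near the reported
          validation error", {
  # fine time resolution so the comparison measures model-vs-data scatter,
  # not integrator bias
  pb <- run_pbm(group = "all57", rsd = 0.3, n_cells = 40,
                spec = scenario("batch_excess", the_net, the_kin,
                                approach = "soa", G = 112), seed = 17)
  obs <- generate_batch_observations("excess", n_points = 8,
                                     noise_sd = 0.05, seed = 41,
                                     network = the_net, kinetics = the_kin)
  v <- validate_against_observations(pb, obs)
  # same order as the reported few-percent standard error, high correlation
  expect_lt(v$standard_error_pct, 10)
  expect_gt(v$correlation_pct, 97)
})
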