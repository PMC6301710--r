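# MPSA and PRCC: sampling, classification, the K-S machinery, and
# planted-signal recovery.

test_that("ensemble sampling honors the per-group RSDs", {
  base <- base_parameters(the_net, the_kin)
  ens <- sample_parameter_ensemble(base, K = 10000, seed = 3)
  emp <- apply(ens$samples, 2, stats::sd) / colMeans(ens$samples)
  grp <- parameter_groups()
  gly <- names(base) %in% grp$glycerol3
  # truncation to positives nudges the empirical RSD only slightly
  expect_true(all(emp[gly] > 0.19 & emp[gly] < 0.21))
  expect_true(all(emp[!gly] > 0.28 & emp[!gly] < 0.315))
  expect_true(all(ens$samples > 0))
})

test_that("zero RSD reproduces the base values; sampling is reproducible", {
  base <- base_parameters(the_net, the_kin)
  rsd0 <- stats::setNames(rep(0, length(base)), names(base))
  ens0 <- sample_parameter_ensemble(base, rsd_map = rsd0, K = 5, seed = 1)
  expect_equal(unname(ens0$samples),
               matrix(rep(base, each = 5), 5), tolerance = 1e-12)
  e1 <- sample_parameter_ensemble(base, K = 50, seed = 9)
  e2 <- sample_parameter_ensemble(base, K = 50, seed = 9)
  expect_identical(e1$samples, e2$samples)
})

test_that("squared-error statistic has its closed forms", {
  x <- c(1, 2, 3, 4)
  expect_equal(mse_profile(x, x), 0)
  expect_equal(mse_profile(x, x + 2), 4)            # constant offset c -> c^2
  expect_equal(mse_profile(x, x + 2, mean = FALSE), 16)
  expect_error(mse_profile(x, 1:3), "length mismatch")
  # a PDO profile offset by exactly 6 g/L sits on the class boundary
  expect_equal(mse_profile(x, x + 6), mpsa_thresholds()[["pdo"]])
})

test_that("classification uses strict exceedance of the thresholds", {
  th <- mpsa_thresholds()
  m <- rbind(pdo = c(th[["pdo"]], 0, 2 * th[["pdo"]]))
  m <- matrix(c(th[["pdo"]], 0, 2 * th[["pdo"]]), 3, 1,
              dimnames = list(NULL, "pdo"))
  acc <- classify_profiles(m, th)
  expect_equal(as.vector(acc), c(TRUE, TRUE, FALSE))
})

test_that("K-S statistic matches brute-force ECDF enumeration", {
  expect_equal(ks_statistic(c(1, 2, 3), c(2, 3, 4)), 1 / 3)
  expect_equal(ks_statistic(1:5, 1:5), 0)
  expect_equal(ks_statistic(1:3, 7:9), 1)            # disjoint supports
  expect_warning(na <- ks_statistic(numeric(0), 1:3), "not classifiable")
  expect_true(is.na(na))
  # agrees with stats::ks.test on random samples
  set.seed(4)
  x <- rnorm(40); y <- rnorm(35, 0.5)
  expect_equal(ks_statistic(x, y),
               unname(stats::ks.test(x, y)$statistic), tolerance = 1e-12)
  # invariant under monotone rescaling
  expect_equal(ks_statistic(exp(x), exp(y)), ks_statistic(x, y))
})

test_that("K-S critical value follows 1.36/sqrt(K)", {
  expect_equal(round(ks_critical_value(2280), 4), 0.0285)
  expect_equal(ks_critical_value(100), 0.136)
  k <- c(10, 100, 1000, 1e6)
  expect_true(all(diff(ks_critical_value(k)) < 0))
  expect_lt(ks_critical_value(1e8), 1e-3)
})

test_that("MPSA recovers a planted signal and ignores a null parameter", {
  base <- c(a = 1, b = 1, d = 1)
  ens <- sample_parameter_ensemble(base, K = 600, seed = 5)
  # output depends on 'a' alone; 'b' and 'd' are inert
  sim <- function(v) {
    pdo <- rep(4 * v[["a"]], 3)
    list(pdo = pdo, q_pdo = v[["a"]], y_pdo_s = 0.5)
  }
  obs <- list(time = 1:3, pdo = rep(4, 3), q_pdo = 1, y_pdo_s = 0.5)
  th <- c(pdo = 1, q_pdo = 0.057^2, y_pdo_s = 0.052^2)
  mp <- run_mpsa(ens, sim, obs, thresholds = th)
  ks_pdo <- mp$ks[, "pdo"]
  expect_equal(names(which.max(ks_pdo)), "a")
  expect_gt(ks_pdo[["a"]], mp$d_crit)
  # inert parameters stay below the proper two-sample critical value
  n1 <- sum(mp$acceptable[, "pdo"]); n2 <- sum(!mp$acceptable[, "pdo"])
  crit2 <- 1.36 * sqrt((n1 + n2) / (n1 * n2))
  expect_lt(ks_pdo[["b"]], crit2)
  expect_lt(ks_pdo[["d"]], crit2)
  expect_equal(mp$failures, 0)
})

test_that("PRCC recovers a planted monotone signal", {
  base <- stats::setNames(rep(1, 12), paste0("p", 1:12))
  ens <- sample_parameter_ensemble(base, K = 400, seed = 6)
  set.seed(7)
  y <- 2 * ens$samples[, "p1"] + 0.02 * rnorm(400)
  pr <- run_prcc(ens, cbind(out = y))
  expect_gt(pr$prcc["p1", "out"], 0.95)
  expect_true(all(abs(pr$prcc[paste0("p", 2:12), "out"]) < 0.2))
  # strictly decreasing noise-free relation gives -1
  pr2 <- run_prcc(ens, cbind(out = -3 * ens$samples[, "p2"]))
  expect_equal(pr2$prcc["p2", "out"], -1, tolerance = 1e-6)
  expect_true(all(abs(pr2$prcc) <= 1 + 1e-12))
  # rank-based: invariant under monotone rescaling of the output
  pr3 <- run_prcc(ens, cbind(out = exp(y)))
  expect_equal(pr3$prcc["p1", "out"], pr$prcc["p1", "out"],
               tolerance = 1e-9)
  expect_warning(pr4 <- run_prcc(ens, cbind(out = rep(1, 400))),
                 "constant output")
  expect_true(all(pr4$prcc == 0))
})

test_that("glycerol kinetics dominate the full-pipeline PRCC with the
          reported signs", {
  base <- base_parameters(the_net, the_kin)
  ens <- sample_parameter_ensemble(base, K = 150, seed = 11)
  sim <- dfba_output_simulator(the_net, the_kin)
  outs <- matrix(NA_real_, 150, 2, dimnames = list(NULL, c("q_pdo",
                                                           "y_pdo_s")))
  for (k in 1:150) {
    # draws with ks >= ki are invalid parameter sets; skipped rows are
    # dropped by the rank-correlation step
    o <- tryCatch(sim(ens$samples[k, ]), error = function(e) NULL)
    if (!is.null(o)) outs[k, ] <- c(o$q_pdo, o$y_pdo_s)
  }
  pr <- run_prcc(ens, outs)
  expect_gt(pr$prcc["vmax_gly", "q_pdo"], 0)
  expect_gt(pr$prcc["ki_gly", "q_pdo"], 0)
  expect_lt(pr$prcc["ks_gly", "q_pdo"], 0)
})

test_that("sensitivity tables export in long format", {
  base <- c(a = 1, b = 2)
  ens <- sample_parameter_ensemble(base, K = 30, seed = 2)
  pr <- run_prcc(ens, cbind(out = ens$samples[, "a"]))
  tab <- sensitivity_table(pr)
  expect_setequal(names(tab),
                  c("parameter", "output", "statistic", "value",
                    "significant"))
  expect_equal(nrow(tab), 2)
})
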