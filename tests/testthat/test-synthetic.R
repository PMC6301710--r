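# Synthetic fermentation data and kinetic parameter recovery.

test_that("noise-free observations lie exactly on the model trajectory", {
  obs <- generate_batch_observations("excess", n_points = 6, noise_sd = 0,
                                     floor_sd = 0, seed = 1,
                                     network = the_net, kinetics = the_kin)
  tr <- dfba(scenario("batch_excess", the_net, the_kin,
                      approach = "da", G = 120))
  ref <- stats::approx(tr$states$time, tr$states$pdo, xout = obs$time)$y
  expect_equal(obs$pdo, ref, tolerance = 1e-6)
  expect_equal(nrow(obs), 6)
  expect_equal(attr(obs, "regime"), "excess")
})

test_that("observation tables satisfy their invariants", {
  for (reg in c("excess", "limitation")) {
    obs <- generate_batch_observations(reg, n_points = 7, seed = 3,
                                       network = the_net,
                                       kinetics = the_kin)
    expect_true(all(diff(obs$time) > 0))
    expect_true(all(as.matrix(obs[-1]) >= 0))
    if (reg == "limitation") expect_lt(obs$glycerol[1], 15)
  }
  expect_error(generate_batch_observations(n_points = 2), "at least 3")
  # irregular preset samples earlier
  o1 <- generate_batch_observations("excess", n_points = 6, seed = 1,
                                    sampling = "irregular",
                                    network = the_net, kinetics = the_kin)
  o2 <- generate_batch_observations("excess", n_points = 6, seed = 1,
                                    network = the_net, kinetics = the_kin)
  expect_lt(o1$time[1], o2$time[1])
})

test_that("observation tables round-trip through CSV", {
  obs <- generate_batch_observations("excess", seed = 2,
                                     network = the_net,
                                     kinetics = the_kin)
  f <- tempfile(fileext = ".csv")
  write_observations(obs, f)
  back <- read_observations(f)
  expect_equal(back$pdo, obs$pdo, tolerance = 1e-9)
  expect_equal(attr(back, "regime"), "excess")
})

test_that("uptake kinetics data generator follows the model curve", {
  d <- generate_uptake_kinetics_data(the_kin, noise_sd = 0)
  expect_equal(d$uptake_flux,
               glycerol_uptake_bound(d$glycerol_mM, the_kin))
  peak <- which.max(d$uptake_flux)
  expect_true(all(diff(d$uptake_flux[seq_len(peak)]) > 0))
  expect_true(all(diff(d$uptake_flux[peak:nrow(d)]) < 0))
  expect_error(generate_uptake_kinetics_data(the_kin,
                                             concentrations = c(100, 800)),
               "ki_gly")
  # heavy noise draws are truncated at zero
  dn <- generate_uptake_kinetics_data(the_kin, noise_sd = 3, seed = 8)
  expect_true(all(dn$uptake_flux >= 0))
})

test_that("noise-free fits recover the generating constants to 0.1%", {
  d <- generate_uptake_kinetics_data(the_kin, noise_sd = 0)
  fit <- fit_glycerol_kinetics(d)
  expect_equal(unname(coef(fit)[c("vmax_gly", "ks_gly", "ki_gly")]),
               c(174.86, 482.1, 755.4), tolerance = 1e-3)
  da <- generate_acetate_kinetics_data(the_kin, noise_sd = 0)
  fa <- fit_acetate_kinetics(da)
  expect_equal(unname(coef(fa)[c("v0_aa", "vinf_aa", "R_aa")]),
               c(0.1578, 11.50, 0.0859), tolerance = 1e-3)
  # fitted logistic is monotone by construction
  pr <- predict(fa, data.frame(v_gly = seq(0, 80, by = 2)))
  expect_true(all(diff(pr) > 0))
})

test_that("noisy fits stay within their confidence intervals", {
  d <- generate_uptake_kinetics_data(the_kin,
                                     concentrations = seq(20, 730,
                                                          length.out = 30),
                                     noise_sd = 0.10, seed = 33)
  fit <- fit_glycerol_kinetics(d)
  truth <- c(vmax_gly = 174.86, ks_gly = 482.1, ki_gly = 755.4)
  ci <- fit$ci
  expect_true(all(truth >= ci[, "lower"] & truth <= ci[, "upper"]))
})

test_that("under-determined and poorly identifiable data are flagged", {
  d <- generate_uptake_kinetics_data(the_kin,
                                     concentrations = c(100, 300, 500))
  expect_error(fit_glycerol_kinetics(d), "under-determined")
  expect_error(fit_acetate_kinetics(data.frame(v_gly = 1:3,
                                               v_acetate_max = 1:3)),
               "under-determined")
  # acetate data saturating early: vinf poorly determined, flagged wide
  ds <- generate_acetate_kinetics_data(the_kin, v_gly = seq(0, 8, by = 1),
                                       noise_sd = 0.05, seed = 3)
  fs <- fit_acetate_kinetics(ds)
  expect_false(fs$identifiable)
  expect_true("vinf_aa" %in% fs$wide_parameters ||
                "R_aa" %in% fs$wide_parameters)
})

test_that("repeated noisy fits are unbiased within Monte-Carlo error", {
  ests <- t(vapply(1:60, function(i) {
    d <- generate_uptake_kinetics_data(
      the_kin, concentrations = seq(20, 730, length.out = 25),
      noise_sd = 0.05, seed = 100 + i)
    coef(fit_glycerol_kinetics(d))
  }, c(vmax_gly = 0, ks_gly = 0, ki_gly = 0)))
  truth <- c(174.86, 482.1, 755.4)
  bias <- colMeans(ests) - truth
  mc_se <- apply(ests, 2, stats::sd) / sqrt(60)
  expect_true(all(abs(bias) < 4 * mc_se + 0.01 * truth))
})
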