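# Pseudo-experimental data: fermentation observation tables emulating the
# reference batch cultures, synthetic kinetics measurements, and the
# nonlinear least-squares recovery of the kinetic constraint models.

#' Generate pseudo-experimental batch observations
#'
#' Simulates a bundled batch scenario and samples it at `n_points` times,
#' adding multiplicative Gaussian noise (default 5 % of the value) plus an
#' additive detection floor (0.05 g/L), truncated at zero.  The observed
#' variables follow the standard chromatography panel: biomass, glycerol,
#' PDO, acetate, butyrate and lactate.
#'
#' @param regime `"limitation"` (initial glycerol below 15 g/L) or
#'   `"excess"`
#' @param n_points number of sampling times (>= 3; the reference excess
#'   culture uses 6)
#' @param noise_sd multiplicative noise SD (fraction of the value)
#' @param floor_sd additive noise SD in g/L (detection floor)
#' @param seed RNG seed
#' @param sampling `"regular"` sampling grid, or `"irregular"` (denser
#'   early, as fermentations are usually sampled)
#' @param culture_id identifier stored with the table
#' @param network,kinetics model components
#' @return an `observation_table`: data.frame with columns `time`,
#'   `biomass`, `glycerol`, `pdo`, `acetate`, `butyrate`, `lactate` and
#'   attributes `culture_id`, `regime`, `noise`
#' @export
generate_batch_observations <- function(regime = c("excess", "limitation"),
                                        n_points = 6, noise_sd = 0.05,
                                        floor_sd = 0.05, seed = 1,
                                        sampling = c("regular", "irregular"),
                                        culture_id = NULL,
                                        network = reduced_network(),
                                        kinetics = kinetic_params()) {
  regime <- match.arg(regime)
  sampling <- match.arg(sampling)
  if (n_points < 3) stop("'n_points' must be at least 3")
  sc <- if (regime == "excess") "batch_excess" else "batch_limited"
  sp <- scenario(sc, network = network, kinetics = kinetics,
                 approach = "da", G = 120)
  tr <- dfba(sp)
  s <- tr$states
  u <- seq_len(n_points) / n_points
  if (sampling == "irregular") u <- u^1.5
  times <- sp$t0 + u * (sp$tf - sp$t0)
  cols <- c(biomass = "X", glycerol = "glycerol", pdo = "pdo",
            acetate = "acetate", butyrate = "butyrate",
            lactate = "lactate")
  clean <- vapply(cols, function(cl)
    stats::approx(s$time, s[[cl]], xout = times)$y, numeric(n_points))
  set.seed(.sub_seed(seed, 17L))
  noisy <- clean * (1 + noise_sd * stats::rnorm(length(clean))) +
    floor_sd * stats::rnorm(length(clean))
  noisy <- pmax(noisy, 0)
  out <- data.frame(time = times, noisy)
  colnames(out) <- c("time", names(cols))
  structure(out,
            culture_id = if (is.null(culture_id))
              paste0(regime, "_1") else culture_id,
            regime = regime,
            noise = c(multiplicative = noise_sd, additive = floor_sd),
            class = c("observation_table", "data.frame"))
}

#' Synthetic glycerol-uptake kinetics measurements
#'
#' Evaluates the Ghose-Tyagi uptake model at the given glycerol
#' concentrations and adds multiplicative Gaussian noise; negative draws
#' are truncated to zero.
#'
#' @param param_truth generating [kinetic_params()]
#' @param concentrations glycerol concentrations in mM (within `[0, ki)`)
#' @param noise_sd multiplicative noise SD (fraction; 0 for exact data)
#' @param seed RNG seed
#' @return data.frame with `glycerol_mM` and `uptake_flux`
#' @export
generate_uptake_kinetics_data <- function(param_truth = kinetic_params(),
                                          concentrations = seq(25, 725,
                                                               by = 25),
                                          noise_sd = 0, seed = 1) {
  if (any(concentrations < 0 | concentrations >= param_truth$ki_gly))
    stop("concentrations must lie in [0, ki_gly)")
  v <- glycerol_uptake_bound(concentrations, param_truth)
  set.seed(.sub_seed(seed, 29L))
  v <- pmax(v * (1 + noise_sd * stats::rnorm(length(v))), 0)
  data.frame(glycerol_mM = concentrations, uptake_flux = v)
}

#' Synthetic acetate-ceiling measurements
#'
#' Evaluates the logistic acetate secretion ceiling at the given glycerol
#' uptake fluxes, with optional multiplicative noise.
#'
#' @param param_truth generating [kinetic_params()]
#' @param v_gly glycerol uptake fluxes (mmol/gDW/h)
#' @param noise_sd multiplicative noise SD
#' @param seed RNG seed
#' @return data.frame with `v_gly` and `v_acetate_max`
#' @export
generate_acetate_kinetics_data <- function(param_truth = kinetic_params(),
                                           v_gly = seq(0, 60, by = 4),
                                           noise_sd = 0, seed = 1) {
  v <- acetate_secretion_bound(v_gly, param_truth)
  set.seed(.sub_seed(seed, 31L))
  v <- pmax(v * (1 + noise_sd * stats::rnorm(length(v))), 0)
  data.frame(v_gly = v_gly, v_acetate_max = v)
}

# multistart nonlinear least squares via minpack.lm
.nls_multistart <- function(formula, data, starts_list, lower) {
  best <- NULL
  for (st in starts_list) {
    fit <- tryCatch(
      minpack.lm::nlsLM(formula, data = data, start = st, lower = lower,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stop("nonlinear least squares failed from all starts")
  best
}

# shared post-processing: estimates, SEs, Wald CIs, identifiability flag
.kinetic_fit_result <- function(best, data, class_name) {
  fit <- best$fit
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(est)))
  ci <- cbind(lower = est - 1.96 * se, upper = est + 1.96 * se)
  wide <- is.na(se) | (1.96 * se > abs(est))
  structure(list(coefficients = est, se = se, ci = ci, sse = best$rss,
                 fit = fit, data = data,
                 identifiable = !any(wide), wide_parameters =
                   names(est)[wide]),
            class = c(class_name, "kinetic_fit"))
}

#' Fit the Ghose-Tyagi glycerol uptake model
#'
#' Nonlinear least squares (Levenberg-Marquardt, multistart) of
#' `vmax*G/(ks+G)*(1-G/ki)` to (concentration, flux) data.  Requires at
#' least 5 points; data lying entirely on one side of the curve's peak are
#' flagged as poorly identifiable through wide Wald intervals.
#'
#' @param data data.frame with `glycerol_mM` and `uptake_flux`
#' @return a `kinetic_fit` object with coefficients `vmax_gly`, `ks_gly`,
#'   `ki_gly`, standard errors, 95 % intervals, residual SSE and an
#'   identifiability flag
#' @export
fit_glycerol_kinetics <- function(data) {
  if (nrow(data) < 5) stop("under-determined: at least 5 points are needed")
  gmax <- max(data$glycerol_mM)
  vmax0 <- max(data$uptake_flux)
  starts <- list(
    list(vmax_gly = 4 * vmax0, ks_gly = gmax / 2, ki_gly = 1.5 * gmax),
    list(vmax_gly = 2 * vmax0, ks_gly = gmax / 4, ki_gly = 1.1 * gmax),
    list(vmax_gly = 8 * vmax0, ks_gly = gmax, ki_gly = 2.5 * gmax))
  best <- .nls_multistart(
    uptake_flux ~ vmax_gly * glycerol_mM / (ks_gly + glycerol_mM) *
      (1 - glycerol_mM / ki_gly),
    data, starts, lower = c(1e-6, 1e-6, max(data$glycerol_mM) * 1.0001))
  .kinetic_fit_result(best, data, "glycerol_kinetic_fit")
}

#' Fit the logistic acetate-ceiling model
#'
#' Nonlinear least squares of
#' `vinf*v0*exp(R*v)/(vinf + v0*(exp(R*v)-1))` to (uptake flux, acetate
#' ceiling) data; at least 4 points are required.  The fitted curve is
#' monotone by construction.  Data saturating too early (or never) leave
#' the corresponding parameter with a wide interval, which is flagged.
#'
#' @param data data.frame with `v_gly` and `v_acetate_max`
#' @return a `kinetic_fit` with coefficients `v0_aa`, `vinf_aa`, `R_aa`
#' @export
fit_acetate_kinetics <- function(data) {
  if (nrow(data) < 4) stop("under-determined: at least 4 points are needed")
  vmax0 <- max(data$v_acetate_max)
  v00 <- max(min(data$v_acetate_max), 1e-3)
  starts <- list(
    list(v0_aa = v00, vinf_aa = 1.2 * vmax0, R_aa = 0.1),
    list(v0_aa = v00 / 2, vinf_aa = 2 * vmax0, R_aa = 0.05),
    list(v0_aa = 2 * v00, vinf_aa = 1.05 * vmax0, R_aa = 0.2))
  best <- .nls_multistart(
    v_acetate_max ~ vinf_aa * v0_aa * exp(R_aa * v_gly) /
      (vinf_aa + v0_aa * (exp(R_aa * v_gly) - 1)),
    data, starts, lower = c(1e-8, 1e-6, 1e-6))
  .kinetic_fit_result(best, data, "acetate_kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("Kinetic model fit (nonlinear least squares, multistart):\n")
  tab <- cbind(estimate = x$coefficients, se = x$se, x$ci)
  print(signif(tab, 5))
  cat(sprintf("residual SSE %.4g; %s\n", x$sse,
              if (x$identifiable) "all parameters identifiable"
              else paste("wide intervals:",
                         paste(x$wide_parameters, collapse = ", "))))
  invisible(x)
}

#' @export
coef.kinetic_fit <- function(object, ...) object$coefficients

#' @export
predict.kinetic_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  stats::predict(object$fit, newdata = newdata)
}

#' @export
residuals.kinetic_fit <- function(object, ...) stats::residuals(object$fit)

#' Write / read observation tables
#'
#' CSV round trip for [generate_batch_observations()] tables; a small
#' `#key: value` header carries the culture id, regime and noise model.
#'
#' @param x an `observation_table`
#' @param path file path
#' @return `write_observations` returns `path`; `read_observations` the
#'   table
#' @export
write_observations <- function(x, path) {
  stopifnot(inherits(x, "observation_table"))
  hdr <- c(paste0("#culture_id: ", attr(x, "culture_id")),
           paste0("#regime: ", attr(x, "regime")),
           paste0("#noise: ", paste(attr(x, "noise"), collapse = ",")))
  writeLines(hdr, path)
  suppressWarnings(utils::write.table(x, path, append = TRUE, sep = ",",
                                      row.names = FALSE, quote = FALSE))
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  hdr <- readLines(path, n = 3)
  val <- function(i) sub("^#[a-z_]+: ", "", hdr[i])
  out <- utils::read.csv(path, comment.char = "#")
  noise <- as.numeric(strsplit(val(3), ",")[[1]])
  structure(out, culture_id = val(1), regime = val(2),
            noise = c(multiplicative = noise[1], additive = noise[2]),
            class = c("observation_table", "data.frame"))
}
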