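# Numerical population balance model: a Monte-Carlo ensemble of
# whole-culture simulations, each "cell line" carrying its own draw of the
# perturbable input parameters (biomass composition, death constants,
# acetate-secretion kinetics - the glycerol uptake kinetics are excluded),
# aggregated into dispersion profiles of the predicted PDO formation.

#' Specify and run a population balance model ensemble
#'
#' Runs `n_cells` independent whole-culture simulations; in each, the
#' parameters of the chosen group are drawn from normal distributions with
#' relative standard deviation `rsd` (truncated to positive values) while
#' all other parameters stay at base.  Simulations use the static
#' optimization approach at the spec's grid resolution.  Each cell's draw
#' is derived from `(seed, cell index)`, so ensembles of increasing size
#' are nested and reproducible.
#'
#' @param group one of `"precursors44"`, `"macromolecules8"`, `"death2"`,
#'   `"acetate3"`, `"all57"`
#' @param rsd relative standard deviation of the perturbation (default 0.30)
#' @param n_cells number of modeled cell lines (>= 2)
#' @param spec the culture to simulate (default: the bundled
#'   glycerol-excess batch at reduced time resolution `G = 36`)
#' @param seed base RNG seed
#' @param network,kinetics base model used when `spec` is NULL
#' @return an object of class `pbm_result`: matrix of PDO profiles
#'   (time x cell), the ensemble mean profile, the RSD profile, the
#'   final-PDO distribution and bookkeeping
#' @export
run_pbm <- function(group = c("all57", "precursors44", "macromolecules8",
                              "death2", "acetate3"),
                    rsd = 0.30, n_cells = 1000, spec = NULL, seed = 1,
                    network = reduced_network(),
                    kinetics = kinetic_params()) {
  group <- match.arg(group)
  if (n_cells < 2) stop("'n_cells' must be at least 2")
  if (rsd < 0) stop("'rsd' must be non-negative")
  if (is.null(spec))
    spec <- scenario("batch_excess", network = network,
                     kinetics = kinetics, approach = "soa", G = 36)
  spec$approach <- "soa"
  pars <- parameter_groups()[[group]]
  base <- base_parameters(spec$network, spec$kinetics)[pars]

  times <- spec$t0 + (spec$tf - spec$t0) * (0:spec$G) / spec$G
  pdo <- matrix(NA_real_, length(times), n_cells)
  X <- matrix(NA_real_, length(times), n_cells)
  failures <- 0L
  for (cell in seq_len(n_cells)) {
    set.seed(.sub_seed(seed, cell))
    draw <- stats::rnorm(length(base), base, rsd * base)
    for (t in 1:100) {
      bad <- draw <= 0
      if (!any(bad)) break
      draw[bad] <- stats::rnorm(sum(bad), base[bad], rsd * base[bad])
    }
    draw[draw <= 0] <- base[draw <= 0]
    names(draw) <- names(base)
    tr <- tryCatch({
      mod <- apply_parameters(draw, spec$network, spec$kinetics)
      sp <- spec; sp$network <- mod$network; sp$kinetics <- mod$kinetics
      dfba(sp)
    }, error = function(e) NULL)
    if (is.null(tr)) { failures <- failures + 1L; next }
    pdo[, cell] <- tr$states$pdo
    X[, cell] <- tr$states$X
  }
  ok <- colSums(is.na(pdo)) == 0
  if (sum(ok) < 2) stop("fewer than 2 successful PBM simulations")
  pdo <- pdo[, ok, drop = FALSE]
  mean_profile <- rowMeans(pdo)
  base_profile <- dfba(spec)$states$pdo
  structure(list(times = times, pdo = pdo, mean_profile = mean_profile,
                 base_profile = base_profile,
                 final_pdo = pdo[nrow(pdo), ],
                 group = group, rsd = rsd, n_cells = n_cells,
                 failures = failures, seed = seed),
            class = "pbm_result")
}

#' RSD profile of predicted PDO formation
#'
#' Pointwise relative standard deviation (standard deviation over mean, in
#' percent) of PDO across the ensemble at every grid time; reported as 0
#' where the mean PDO is zero.
#'
#' @param result a [run_pbm()] result
#' @return data.frame with `time` and `rsd_pct`
#' @export
rsd_profile <- function(result) {
  stopifnot(inherits(result, "pbm_result"))
  if (ncol(result$pdo) < 2) stop("at least 2 successful runs are required")
  m <- rowMeans(result$pdo)
  s <- apply(result$pdo, 1, stats::sd)
  data.frame(time = result$times,
             rsd_pct = ifelse(m > 0, 100 * s / m, 0))
}

#' Cell-count convergence of the PBM
#'
#' For each ensemble size in `n_grid`, computes the mean final PDO of the
#' (nested) ensemble and reports the relative deviation from the largest
#' ensemble.
#'
#' @param n_grid increasing vector of cell counts
#' @param ... passed to [run_pbm()] (group, rsd, spec, seed, ...)
#' @return data.frame with `n_cells`, `mean_final_pdo`, `rel_dev_pct`
#'   (percent deviation from the largest ensemble)
#' @export
convergence_scan <- function(n_grid = c(100, 300, 900, 3300), ...) {
  n_grid <- sort(n_grid)
  res <- run_pbm(n_cells = max(n_grid), ...)
  means <- vapply(n_grid, function(n)
    mean(res$final_pdo[seq_len(min(n, length(res$final_pdo)))]), 0)
  ref <- means[length(means)]
  data.frame(n_cells = n_grid, mean_final_pdo = means,
             rel_dev_pct = 100 * abs(means - ref) / ref)
}

#' Biomass-composition RSD sweep
#'
#' The dispersion of the biomass molecular weight under composition
#' perturbation serves as an indirect diagnostic for choosing the
#' composition RSD.  For each RSD in `rsds`, draws `n` perturbed
#' compositions (precursors and macromolecule fractions) and reports the
#' resulting relative standard deviation of the biomass molecular weight.
#'
#' @param rsds composition RSD levels to evaluate
#' @param n draws per level
#' @param seed RNG seed
#' @param network base network (for the default composition)
#' @return data.frame with `rsd` and `mw_rsd_pct`
#' @export
composition_rsd_sweep <- function(rsds = c(0.10, 0.20, 0.30), n = 1000,
                                  seed = 1, network = reduced_network()) {
  grp <- parameter_groups()
  pars <- c(grp$precursors44, grp$macromolecules8)
  base <- base_parameters(network)[pars]
  out <- vapply(rsds, function(r) {
    set.seed(.sub_seed(seed, round(1e4 * r)))
    mws <- vapply(seq_len(n), function(i) {
      draw <- abs(stats::rnorm(length(base), base, r * base))
      names(draw) <- names(base)
      comp <- apply_parameters(draw, network)$network$composition
      biomass_molecular_weight(comp)
    }, 0)
    100 * stats::sd(mws) / mean(mws)
  }, 0)
  data.frame(rsd = rsds, mw_rsd_pct = out)
}

#' Compare PBM predictions with observations
#'
#' Linear regression of observed PDO on the dynamic model's prediction
#' (the unperturbed trajectory of the PBM's culture) at matched times;
#' reports the relative standard error (residual standard error over the
#' mean observed value, percent), the correlation coefficient (percent),
#' and pointwise prediction bands from the ensemble quantiles.
#'
#' @param result a [run_pbm()] result
#' @param observations data.frame with `time` and `pdo` columns (g/L)
#' @param level band coverage (default 0.95)
#' @return list with `standard_error_pct`, `correlation_pct`, the fitted
#'   regression, and a data.frame of matched points with prediction bands
#' @export
validate_against_observations <- function(result, observations,
                                          level = 0.95) {
  stopifnot(inherits(result, "pbm_result"))
  obs <- observations[observations$time >= min(result$times) &
                        observations$time <= max(result$times), ]
  if (nrow(obs) < 3) stop("fewer than 3 observations inside the horizon")
  base <- if (is.null(result$base_profile)) result$mean_profile
          else result$base_profile
  pred <- stats::approx(result$times, base, xout = obs$time)$y
  fit <- stats::lm(obs$pdo ~ pred)
  se <- summary(fit)$sigma / mean(obs$pdo) * 100
  r <- stats::cor(pred, obs$pdo) * 100
  a <- (1 - level) / 2
  qs <- t(apply(result$pdo, 1, stats::quantile, probs = c(a, 1 - a)))
  lo <- stats::approx(result$times, qs[, 1], xout = obs$time)$y
  hi <- stats::approx(result$times, qs[, 2], xout = obs$time)$y
  list(standard_error_pct = se, correlation_pct = r, fit = fit,
       matched = data.frame(time = obs$time, observed = obs$pdo,
                            predicted = pred, lower = lo, upper = hi))
}

#' @export
print.pbm_result <- function(x, ...) {
  rp <- rsd_profile(x)
  cat(sprintf("PBM ensemble: %d cells (%d failed), group %s at %.0f%% RSD\n",
              x$n_cells, x$failures, x$group, 100 * x$rsd))
  cat(sprintf("  mean final PDO %.2f g/L; end-of-culture RSD %.2f%%; max RSD %.2f%%\n",
              mean(x$final_pdo), rp$rsd_pct[nrow(rp)], max(rp$rsd_pct)))
  invisible(x)
}

#' @export
plot.pbm_result <- function(x, ...) {
  rp <- rsd_profile(x)
  oldpar <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(oldpar))
  qs <- t(apply(x$pdo, 1, stats::quantile, probs = c(0.025, 0.5, 0.975)))
  graphics::matplot(x$times, qs, type = "l", lty = c(2, 1, 2),
                    col = "black", xlab = "time (h)", ylab = "PDO (g/L)",
                    main = sprintf("%s, %.0f%% RSD", x$group, 100 * x$rsd))
  graphics::plot(rp$time, rp$rsd_pct, type = "l", lwd = 2,
                 xlab = "time (h)", ylab = "RSD of PDO (%)")
  invisible(x)
}
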